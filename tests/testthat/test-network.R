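# Reaction-network construction, rate laws, derivatives and moiety
# bookkeeping.

test_that("variant flags are uniquely determined by id", {
  expect_equal(variant_info(1)$otud7b_upstream, "INSR")
  expect_equal(variant_info(3)$otud7b_upstream, "INSR")
  expect_equal(variant_info(2)$otud7b_upstream, "IRS")
  expect_equal(variant_info(4)$otud7b_upstream, "IRS")
  expect_false(variant_info(1)$mlst8_required_for_mtorc1)
  expect_false(variant_info(2)$mlst8_required_for_mtorc1)
  expect_true(variant_info(3)$mlst8_required_for_mtorc1)
  expect_true(variant_info(4)$mlst8_required_for_mtorc1)
  expect_equal(variant_info("4P")$mtorc2_activator, "pIRS")
  expect_equal(variant_info(4)$mtorc2_activator, "pAKT_T308")
  expect_error(variant_info(7), "unknown model variant")
  expect_error(build_network("5"), "unknown model variant")
})

test_that("OTUD7B substrate and mTORC1 pools follow the variant wiring", {
  enz <- function(v) {
    rx <- net_of(v)$reactions
    rx[[which(vapply(rx, `[[`, "", "name") == "OTUD7B_activation")]]$enzyme
  }
  expect_equal(enz(1), "pINSR")
  expect_equal(enz(4), "pIRS")
  # MLST8ub enters the mTORC1 pools only in the gated variants
  expect_true("mTORC1_assembly" %in% colnames(net_of(4)$stoich))
  expect_false("mTORC1_assembly" %in% colnames(net_of(1)$stoich))
  expect_true("mTORC1i" %in% net_of(4)$conservation$MLST8)
  expect_false("mTORC1i" %in% net_of(1)$conservation$MLST8)
})

test_that("variants 2 and 4 differ only in the mTORC1/MLST8 reactions", {
  n2 <- vapply(net_of(2)$reactions, `[[`, "", "name")
  n4 <- vapply(net_of(4)$reactions, `[[`, "", "name")
  expect_equal(setdiff(n4, n2),
               c("mTORC1_assembly", "mTORC1_disassembly"))
  shared <- intersect(n4, n2)
  r2 <- net_of(2)$reactions[match(shared, n2)]
  r4 <- net_of(4)$reactions[match(shared, n4)]
  expect_identical(r2, r4)
  # 1 vs 3 share OTUD7B wiring; 3 vs 4 share the MLST8/mTORC1 wiring
  get <- function(v, nm) {
    rx <- net_of(v)$reactions
    rx[[which(vapply(rx, `[[`, "", "name") == nm)]]
  }
  expect_identical(get(1, "OTUD7B_activation"), get(3, "OTUD7B_activation"))
  expect_identical(get(3, "mTORC1_assembly"), get(4, "mTORC1_assembly"))
})

test_that("rate laws evaluate to their closed forms", {
  net <- net_of(4)
  p <- default_parameters()
  zero <- stats::setNames(numeric(length(net$species)), net$species)
  expect_true(all(rate_vector(net, zero, p, insulin = 0) == 0))

  # Michaelis-Menten half-saturation: substrate = Km -> kcat*E/2
  st <- zero
  st["mTORC1a"] <- 7
  st["S6K1"] <- p[["Km_11b"]]
  v <- rate_vector(net, st, p, 0)
  expect_equal(v[["S6K1_phosphorylation"]], p[["k_f11b"]] * 7 / 2)

  # mass action k*A*B
  st <- zero
  st["MLST8_free"] <- 2
  st["SIN1_free"] <- 3
  v <- rate_vector(net, st, p, 0)
  expect_equal(v[["mTORC2_assembly"]], p[["k_f6"]] * 6)

  # inhibited activation k*X/(1 + I/ki)
  st <- zero
  st["mTORC1i"] <- 10
  st["TSC2a"] <- p[["k_i1"]]
  v <- rate_vector(net, st, p, 0)
  expect_equal(v[["mTORC1_activation"]], p[["k_f11a"]] * 10 / 2)

  neg <- zero
  neg["AKT"] <- -1
  expect_error(rate_vector(net, neg, p, 0), "negative")
})

test_that("ode_rhs matches the brute-force reaction-list evaluator", {
  set.seed(11)
  for (v in c("1", "2", "3", "4", "4P")) {
    net <- net_of(v)
    p <- default_parameters()
    for (i in 1:3) {
      st <- random_state(net)
      expect_lt(max(abs(ode_rhs(net, st, p, 70) -
                          brute_rhs(net, st, p, 70))), 1e-12)
    }
  }
})

test_that("derivatives of every conservation group sum to zero", {
  set.seed(12)
  for (v in c("1", "4", "4P")) {
    net <- net_of(v)
    st <- random_state(net)
    d <- ode_rhs(net, st, default_parameters(), 100)
    for (g in net$conservation) {
      expect_lt(abs(sum(d[g])), 1e-12)
    }
  }
})

test_that("conserved_totals sums moiety members", {
  net <- net_of(4)
  st <- stats::setNames(numeric(length(net$species)), net$species)
  st["SIN1_free"] <- 1
  st["mTORC2"] <- 2
  st["amTORC2"] <- 3
  tot <- conserved_totals(net, st)
  expect_equal(tot[["SIN1"]], 6)
  expect_equal(tot[["MLST8"]], 5)
  zero <- stats::setNames(numeric(length(net$species)), net$species)
  expect_true(all(conserved_totals(net, zero) == 0))
  expect_error(conserved_totals(net, st[-1]), "missing species")
})

test_that("network JSON export round-trips losslessly", {
  f <- withr::local_tempfile(fileext = ".json")
  net <- net_of(4)
  write_network_json(net, f)
  back <- read_network_json(f)
  expect_identical(back$variant, net$variant)
  expect_identical(back$reactions, net$reactions)
  expect_identical(back$conservation, net$conservation)
})

test_that("parameter tables round-trip through CSV and JSON", {
  p <- default_parameters()
  for (ext in c(".csv", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_parameters(parameter_bounds(p), f)
    back <- read_parameters(f)
    expect_equal(unname(back[param_names()]), unname(p), tolerance = 1e-12)
    expect_true(all(c("lower_bound", "upper_bound") %in%
                      names(attr(back, "bounds"))))
  }
})
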