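# Relative -> absolute abundance inference, nanomolar conversion and model
# customization.

toy_tables <- function() {
  rel <- tibble::tibble(
    protein = c("A", "B"),
    ref1 = c(10, 20), x1 = c(20, 10), x2 = c(5, 40))
  ref <- tibble::tibble(protein = c("A", "B"), ref1 = c(1000, 500))
  list(rel = rel, ref = ref)
}

test_that("validate_and_filter drops exactly the lines with gaps", {
  t <- toy_tables()
  out <- validate_and_filter(t$rel, c("A", "B"))
  expect_equal(nrow(out$drop_report), 0)
  expect_identical(out$table, t$rel)

  rel2 <- t$rel
  rel2$x1[2] <- NA
  out2 <- validate_and_filter(rel2, c("A", "B"))
  expect_equal(out2$drop_report$cell_line, "x1")
  expect_equal(out2$drop_report$missing_proteins, "B")
  expect_false("x1" %in% names(out2$table))
  expect_error(validate_and_filter(t$rel, c("A", "Z")),
               "absent from table")
  rel3 <- t$rel
  rel3$x1[1] <- NA
  rel3$x2[1] <- NA
  rel3$ref1[1] <- NA
  expect_warning(validate_and_filter(rel3, "A"), "all cell lines dropped")
})

test_that("infer_absolute applies the reference-anchored ratio average", {
  t <- toy_tables()
  # target = the reference line itself: ratio 1, exact iBAQ column
  self <- infer_absolute(t$rel, t$ref, "ref1")
  expect_equal(self$abundance, c(1000, 500))
  expect_equal(self$se, c(0, 0))
  # single reference, ratio 2 -> 2000
  one <- infer_absolute(t$rel, t$ref, "x1")
  expect_equal(one$abundance[one$protein == "A"], 2000)
  expect_equal(one$abundance[one$protein == "B"], 250)
  expect_error(infer_absolute(t$rel, t$ref, "nope"), "not in the relative")
  orphan <- tibble::tibble(protein = "A", ref1 = 1000)
  expect_warning(out <- infer_absolute(t$rel, orphan, "x1"),
                 "excluded: B")
  expect_equal(out$protein, "A")
})

test_that("inference recovers a proportionality-generated ground truth", {
  for (n_refs in c(1, 3, 7)) {
    spec <- synthetic_cohort_spec(n_lines = 10, n_refs = n_refs)
    tabs <- make_proteomics_tables(spec, seed = 31)
    truth <- mtorswitch:::as_abundance_matrix(tabs$truth)
    for (cl in c("line_04", "line_10")) {
      got <- infer_absolute(tabs$relative, tabs$reference, cl)
      expect_rel_equal(got$abundance, truth[got$protein, cl], 1e-10)
      expect_true(all(got$se < 1e-10 * max(truth)))
    }
  }
})

test_that("averaging references equals the mean of single-reference runs", {
  spec <- synthetic_cohort_spec(n_lines = 6, n_refs = 3, sdlog = 0.5)
  tabs <- make_proteomics_tables(spec, seed = 8)
  # perturb the relative table so single-reference estimates differ
  rel <- tabs$relative
  relm <- mtorswitch:::as_abundance_matrix(rel)
  set.seed(9)
  relm <- relm * exp(stats::rnorm(length(relm), 0, 0.2))
  rel[, -1] <- as.data.frame(relm)
  full <- infer_absolute(rel, tabs$reference, "line_06")
  singles <- lapply(tabs$ref_lines, function(j) {
    infer_absolute(rel, tabs$reference[, c("protein", j)], "line_06")
  })
  manual <- rowMeans(vapply(singles, `[[`, numeric(nrow(full)),
                            "abundance"))
  expect_rel_equal(full$abundance, manual, 1e-12)
})

test_that("nanomolar conversion anchors the model-protein mean at 100", {
  expect_equal(unname(to_nanomolar(c(p1 = 7, p2 = 21))), c(50, 150))
  expect_equal(unname(to_nanomolar(rep(3, 5) |>
                                     stats::setNames(letters[1:5]))),
               rep(100, 5))
  set.seed(5)
  x <- stats::setNames(stats::rlnorm(8, 2, 1), letters[1:8])
  conc <- to_nanomolar(x)
  expect_equal(mean(conc), 100, tolerance = 1e-9)
  # within-line ratios preserved exactly
  expect_equal(unname(conc / conc[1]), unname(x / x[1]), tolerance = 1e-12)
  expect_error(to_nanomolar(c(a = 1, b = 0)), "positive")
  expect_error(to_nanomolar(c(a = 1), c("a", "b")), "missing")
})

test_that("customize_model swaps exactly the mapped totals", {
  base <- default_totals()
  same <- customize_model(base, base)
  expect_equal(unname(same[names(base)]), unname(base))
  conc <- base
  conc[["SIN1"]] <- 2 * base[["SIN1"]]
  out <- customize_model(base, conc["SIN1"])
  expect_equal(out[["SIN1"]], 2 * base[["SIN1"]])
  expect_equal(out[names(base) != "SIN1"], base[names(base) != "SIN1"])
  expect_error(customize_model(base, c(x = 1), c(x = "NotAGroup")),
               "unknown groups")
})

test_that("cohort_scan of one line matches dose_response", {
  net <- net_of(4)
  p <- ref4()
  tot <- default_totals()
  cs <- cohort_scan(list(only = tot), net, p, n_points = 7)
  dr <- dose_response(net, p, tot, "SIN1", n_points = 7)
  expect_equal(cs$value, dr$value)
  expect_equal(cs$normalized, dr$normalized)
  expect_s3_class(attr(cs, "reports")$only, "biphasic_report")
  # identical lines give identical rows
  cs2 <- cohort_scan(list(a = tot, b = tot), net, p, n_points = 5)
  expect_equal(cs2$value[cs2$cell_line == "a"],
               cs2$value[cs2$cell_line == "b"])
})
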