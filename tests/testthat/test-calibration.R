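# Objective function, GA calibration, ensemble selection and clustering.

make_small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- make_reference_parameters(4, seed = 929)
      spec <- synthetic_study_spec(noise_sd = 0)
      cache <<- list(truth = truth, spec = spec,
                     data = simulate_blot_data(spec, truth, seed = 1))
    }
    cache
  }
})

test_that("objective matches a brute-force double-loop recomputation", {
  st <- make_small_study()
  net <- net_of(4)
  p <- default_parameters()
  J <- objective(p, st$data, net)

  # independent recomputation: explicit loops over datasets and time points
  Jref <- 0
  for (cn in unique(st$data$condition)) {
    sub <- st$data[st$data$condition == cn, ]
    ap <- apply_perturbations(default_totals(), p,
                              st$spec$conditions[[cn]])
    tr <- simulate_network(net, ap$params, totals = ap$totals,
                           protocol = mtor_protocol(
                             grid = sort(unique(sub$time_min))))
    for (obs in unique(sub$observable)) {
      d <- sub[sub$observable == obs, ]
      sim <- observable_series(tr, obs)[match(d$time_min, tr$time)]
      if (max(sim) > 1e-9) sim <- sim / max(sim)
      for (i in seq_len(nrow(d))) {
        Jref <- Jref + d$weight[i] * (d$value[i] - sim[i])^2
      }
    }
  }
  expect_lt(abs(J - Jref), 1e-12 * max(1, Jref))
})

test_that("objective is zero at the generating truth and additive", {
  st <- make_small_study()
  net <- net_of(4)
  expect_lt(objective(st$truth, st$data, net), 1e-10)

  # single dataset, one time point, residual 2 -> J = 4 (normalization
  # pins the simulated single point to 1, so use value = 3)
  one <- tibble::tibble(condition = "WT", observable = "pS6K1_obs",
                        time_min = 60, value = 3, weight = 1)
  attr(one, "spec") <- st$spec
  expect_equal(objective(st$truth, one, net), 4, tolerance = 1e-9)

  d1 <- st$data[st$data$observable == "pS6K1_obs", ]
  d2 <- st$data[st$data$observable != "pS6K1_obs", ]
  attr(d1, "spec") <- st$spec
  attr(d2, "spec") <- st$spec
  p <- default_parameters()
  expect_equal(objective(p, st$data, net),
               objective(p, d1, net) + objective(p, d2, net),
               tolerance = 1e-10)
  bad <- dplyr::mutate(d1, observable = "mystery")
  attr(bad, "spec") <- st$spec
  expect_error(objective(p, bad, net), "unknown observables")
})

test_that("fit_ga is deterministic under seed with monotone best-so-far", {
  st <- make_small_study()
  net <- net_of(4)
  cfg <- ga_config(population = 8, generations = 6, runs = 1)
  free <- c("k_f3", "k_f4", "k_f6")
  f1 <- fit_ga(st$data, net, cfg, seed = 5, free = free)
  f2 <- fit_ga(st$data, net, cfg, seed = 5, free = free)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$J, f2$J)
  expect_true(all(diff(f1$best_per_generation) <= 0))
  expect_gte(f1$J, 0)
  badb <- parameter_bounds(default_parameters())
  badb$lower_bound[1] <- badb$upper_bound[1] * 2
  expect_error(fit_ga(st$data, net, cfg, free = param_names(),
                      bounds = badb), "infeasible bounds")
})

test_that("multi_start sorts runs by J and is order-invariant", {
  st <- make_small_study()
  net <- net_of(4)
  cfg <- ga_config(population = 8, generations = 4, runs = 3)
  free <- c("k_f3", "k_f4", "k_f6")
  res <- multi_start(st$data, net, cfg, seeds = c(2, 7, 9), free = free)
  expect_length(res, 3)
  J <- vapply(res, `[[`, numeric(1), "J")
  expect_true(all(diff(J) >= 0))
  res2 <- multi_start(st$data, net, cfg, seeds = c(9, 2, 7), free = free)
  expect_equal(sort(vapply(res2, `[[`, numeric(1), "J")), sort(J))
  expect_error(multi_start(st$data, net, cfg, seeds = c(1, 1)),
               "distinct")
  # non-identifiability: independent starts spread in J
  expect_gt(stats::sd(J), 0)
})

test_that("select_best applies threshold and feature checks", {
  st <- make_small_study()
  net <- net_of(4)
  good <- structure(list(params = st$truth, J = 0.01, seed = 1,
                         config = ga_config(), free = param_names(),
                         best_per_generation = 0.01, accepted = NA),
                    class = "fit_result")
  expect_length(select_best(list(good), net, threshold_J = 1e-6), 0)
  expect_length(select_best(list(good), net, threshold_J = Inf,
                            checks = list()), 1)
  acc <- select_best(list(good), net, threshold_J = 1)
  expect_length(acc, 1)
  expect_true(all(acc[[1]]$check_log))

  # a parameterization with a crippled deubiquitinase never shows the
  # MLST8 overshoot and must be excluded even at low J
  flat <- good
  flat$params[["k_f3"]] <- st$truth[["k_f3"]] * 1e-4
  out <- select_best(list(flat), net, threshold_J = Inf)
  expect_length(out, 0)
})

test_that("ensemble envelopes bound their members", {
  st <- make_small_study()
  net <- net_of(4)
  mk <- function(p) structure(list(params = p, J = 0, seed = 1,
                                   config = ga_config(),
                                   free = param_names(),
                                   best_per_generation = 0,
                                   accepted = TRUE),
                              class = "fit_result")
  proto <- mtor_protocol(grid = seq(0, 60, 10))
  env1 <- ensemble_envelope(list(mk(st$truth)), net, proto)
  expect_true(all(env1$sd == 0))
  expect_true(all(env1$n == 1))
  env2 <- ensemble_envelope(list(mk(st$truth), mk(st$truth)), net, proto)
  expect_true(all(env2$sd == 0))
  expect_equal(env2$mean, env1$mean)
  p2 <- st$truth * 1.15
  env3 <- ensemble_envelope(list(mk(st$truth), mk(p2)), net, proto)
  # mean within pointwise member range
  tr1 <- observable_table(simulate_network(net, st$truth,
                                           protocol = proto),
                          normalize = TRUE)
  tr2 <- observable_table(simulate_network(net, p2, protocol = proto),
                          normalize = TRUE)
  lo <- pmin(tr1$value, tr2$value)
  hi <- pmax(tr1$value, tr2$value)
  key <- paste(tr1$observable, tr1$time)
  m <- env3$mean[match(key, paste(env3$observable, env3$time))]
  expect_true(all(m >= lo - 1e-12 & m <= hi + 1e-12))
})

test_that("hierarchical clustering recovers separated parameter clusters", {
  mk <- function(p) structure(list(params = p, J = 0, seed = 1,
                                   config = ga_config(),
                                   free = param_names(),
                                   accepted = TRUE),
                              class = "fit_result")
  p <- default_parameters()
  expect_error(cluster_fits(list(mk(p))), "at least two")
  cl <- cluster_fits(list(mk(p), mk(p)))
  expect_equal(cl$heights, 0)
  set.seed(9)
  near <- replicate(4, mk(p * 10^stats::rnorm(length(p), 0, 0.05)),
                    simplify = FALSE)
  far <- replicate(4, mk(p * 100 * 10^stats::rnorm(length(p), 0, 0.05)),
                   simplify = FALSE)
  cl2 <- cluster_fits(c(near, far), k = 2)
  expect_equal(unname(cl2$labels[1:4]), rep(cl2$labels[[1]], 4))
  expect_equal(unname(cl2$labels[5:8]), rep(cl2$labels[[5]], 4))
  expect_false(cl2$labels[[1]] == cl2$labels[[5]])
})
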