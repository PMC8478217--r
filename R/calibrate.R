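# Least-squares calibration against peak-normalized time-course data with a
# multi-start genetic algorithm, ensemble selection and summarization.

#' Genetic-algorithm configuration
#'
#' Desk scale (the default used throughout the tests and examples) runs a
#' population of 40 for 100 generations, 5 independent starts. Paper scale
#' (population 200, 800 generations, 500 starts) reproduces the full
#' calibration protocol and is selected with `scale = "paper"`.
#'
#' @param scale `"desk"` or `"paper"`, or override the counts directly.
#' @param population,generations,runs Override individual counts.
#' @param elite Number of elite individuals copied unchanged per generation.
#' @param mutation_sd Gaussian mutation step in log10 units.
#' @param mutation_prob Per-gene mutation probability.
#' @param crossover_prob Probability a child is produced by blend crossover.
#' @return List of class `ga_config`.
#' @export
ga_config <- function(scale = c("desk", "paper"), population = NULL,
                      generations = NULL, runs = NULL, elite = 2,
                      mutation_sd = 0.15, mutation_prob = 0.25,
                      crossover_prob = 0.9) {
  scale <- match.arg(scale)
  def <- if (scale == "desk") c(40, 100, 5) else c(200, 800, 500)
  cfg <- list(population = population %||% def[1],
              generations = generations %||% def[2],
              runs = runs %||% def[3],
              elite = elite, mutation_sd = mutation_sd,
              mutation_prob = mutation_prob,
              crossover_prob = crossover_prob, scale = scale)
  stopifnot(cfg$population >= 2, cfg$generations >= 1, cfg$runs >= 1)
  structure(cfg, class = "ga_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Least-squares objective against peak-normalized datasets
#'
#' `J = sum_j w_j * sum_i (data_ji - sim_j(t_i))^2` where the simulated
#' observables are peak-normalized per condition (over the dataset's time
#' points) before comparison, mirroring how blot quantifications are
#' processed. A failed simulation returns the large finite `penalty`.
#'
#' @param params Kinetic parameters.
#' @param datasets A tibble with columns `condition`, `observable`,
#'   `time_min`, `value`, `weight` (e.g. from [simulate_blot_data()]).
#' @param network An `mtor_network`.
#' @param conditions Named list of perturbation lists keyed by the
#'   condition names appearing in `datasets`; defaults to the spec attached
#'   to the datasets.
#' @param totals Moiety totals.
#' @param insulin Stimulus (nM).
#' @param map Observable map.
#' @param penalty Objective value reported when simulation fails.
#' @return The scalar objective J (>= 0).
#' @export
objective <- function(params, datasets, network, conditions = NULL,
                      totals = default_totals(), insulin = 100,
                      map = observable_map(), penalty = 1e6) {
  stopifnot(nrow(datasets) > 0)
  conditions <- conditions %||% attr(datasets, "spec")$conditions
  if (is.null(conditions)) {
    stop("no condition definitions: pass `conditions` or datasets carrying",
         " a study spec", call. = FALSE)
  }
  unknown <- setdiff(unique(datasets$observable), names(map))
  if (length(unknown)) {
    stop("datasets reference unknown observables: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  J <- 0
  for (cn in unique(datasets$condition)) {
    if (!cn %in% names(conditions)) {
      stop("condition '", cn, "' has no perturbation definition",
           call. = FALSE)
    }
    sub <- datasets[datasets$condition == cn, ]
    grid <- sort(unique(c(0, sub$time_min)))
    tr <- tryCatch({
      ap <- apply_perturbations(totals, params, conditions[[cn]])
      suppressWarnings(simulate_network(
        network, ap$params, totals = ap$totals,
        protocol = mtor_protocol(insulin = insulin, grid = grid)))
    }, error = function(e) NULL)
    if (is.null(tr)) return(penalty)
    for (obs in unique(sub$observable)) {
      d <- sub[sub$observable == obs, ]
      y <- observable_series(tr, obs, map)[match(d$time_min, grid)]
      peak <- max(y)
      if (is.finite(peak) && peak > 1e-9) y <- y / peak
      J <- J + sum(d$weight * (d$value - y)^2)
    }
  }
  J
}

#' Fit parameters with a genetic algorithm
#'
#' Real-coded GA searching in log10 space within the supplied bounds:
#' Latin-hypercube initialization, tournament selection (size 2), blend
#' crossover, Gaussian mutation, elitism. Deterministic under `seed`. Only
#' parameters named in `free` are searched; the rest stay at `start`.
#'
#' @inheritParams objective
#' @param config A [ga_config()].
#' @param seed Integer seed for this run.
#' @param start Full parameter vector supplying fixed values (default
#'   [default_parameters()]).
#' @param free Names of parameters to fit (default: all kinetic
#'   parameters).
#' @param bounds Bounds tibble (`name`, `lower_bound`, `upper_bound`);
#'   default [parameter_bounds()] of `start`.
#' @return A `fit_result` list: `params` (full vector), `J`, `seed`,
#'   `config`, `best_per_generation`, `accepted` (NA until
#'   [select_best()]).
#' @export
fit_ga <- function(datasets, network, config = ga_config(), seed = 1,
                   start = default_parameters(), free = param_names(),
                   bounds = parameter_bounds(start), ...) {
  stopifnot(inherits(config, "ga_config"))
  bad <- setdiff(free, bounds$name)
  if (length(bad)) stop("no bounds for free parameters: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  b <- bounds[match(free, bounds$name), ]
  if (any(b$lower_bound >= b$upper_bound) || any(b$lower_bound <= 0)) {
    stop("infeasible bounds: need 0 < lower < upper", call. = FALSE)
  }
  lo <- log10(b$lower_bound)
  hi <- log10(b$upper_bound)
  d <- length(free)
  evalJ <- function(x) {
    p <- start
    p[free] <- 10^x
    objective(p, datasets, network, ...)
  }

  set.seed(seed)
  pop <- t(lo + t(lhs::randomLHS(config$population, d)) * (hi - lo))
  fit <- apply(pop, 1, evalJ)
  best_per_gen <- numeric(config$generations)
  for (g in seq_len(config$generations)) {
    ord <- order(fit)
    newpop <- pop[ord[seq_len(config$elite)], , drop = FALSE]
    while (nrow(newpop) < config$population) {
      pick <- function() {
        ij <- sample.int(config$population, 2)
        ij[which.min(fit[ij])]
      }
      p1 <- pop[pick(), ]
      p2 <- pop[pick(), ]
      child <- if (stats::runif(1) < config$crossover_prob) {
        a <- stats::runif(d, -0.25, 1.25)   # blend (BLX-like)
        a * p1 + (1 - a) * p2
      } else p1
      mut <- stats::runif(d) < config$mutation_prob
      child[mut] <- child[mut] +
        stats::rnorm(sum(mut), 0, config$mutation_sd)
      newpop <- rbind(newpop, pmin(pmax(child, lo), hi))
    }
    pop <- newpop
    fit <- c(fit[ord[seq_len(config$elite)]],
             apply(pop[-seq_len(config$elite), , drop = FALSE], 1, evalJ))
    best_per_gen[g] <- min(fit)
  }
  ibest <- which.min(fit)
  params <- start
  params[free] <- 10^pop[ibest, ]
  structure(list(params = params, J = fit[ibest], seed = seed,
                 config = config, free = free,
                 best_per_generation = cummin(best_per_gen),
                 accepted = NA),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> J =", signif(x$J, 5), " seed =", x$seed,
      " accepted =", x$accepted, "\n")
  invisible(x)
}

#' Independent multi-start GA runs
#'
#' @inheritParams fit_ga
#' @param seeds Distinct integer seeds, one per run (default
#'   `seq_len(config$runs)`).
#' @return List of `fit_result`, sorted ascending by J.
#' @export
multi_start <- function(datasets, network, config = ga_config(),
                        seeds = seq_len(config$runs), ...) {
  if (anyDuplicated(seeds)) stop("seeds must be distinct", call. = FALSE)
  res <- purrr::map(seeds, function(s) {
    fit_ga(datasets, network, config, seed = s, ...)
  })
  res[order(vapply(res, `[[`, numeric(1), "J"))]
}

#' Automated feature checks standing in for visual fit inspection
#'
#' Each check receives a peak-normalized observable table (columns `time`,
#' `observable`, `value`) of a wild-type insulin-stimulation simulation and
#' returns a logical. Defaults: (a) deubiquitinated MLST8 overshoots
#' (max > 1.2 x final value); (b) pS6K1 rises after pAKT S473 (downstream
#' kinetics ordering).
#'
#' @return Named list of check functions.
#' @export
feature_checks <- function() {
  first_rise <- function(tab, obs) {
    y <- tab$value[tab$observable == obs]
    t <- tab$time[tab$observable == obs]
    i <- which(y > y[1] + 0.05 * (max(y) - y[1]))[1]
    if (is.na(i)) Inf else t[i]
  }
  list(
    mlst8_overshoot = function(tab) {
      y <- tab$value[tab$observable == "MLST8_deub_obs"]
      length(y) > 0 && max(y) > 1.2 * y[length(y)]
    },
    s6k1_after_akt = function(tab) {
      first_rise(tab, "pS6K1_obs") > first_rise(tab, "pAKT_S473_obs")
    }
  )
}

#' Select the accepted best-fit ensemble
#'
#' A fit is accepted iff its objective value is at or below the cut-off
#' threshold and every feature check passes on its wild-type simulation
#' (the programmatic stand-in for visual inspection of fit quality).
#'
#' @param results List of `fit_result` (e.g. from [multi_start()]).
#' @param network An `mtor_network`.
#' @param threshold_J Objective cut-off (> 0).
#' @param checks Named list of check functions (default
#'   [feature_checks()]; use `list()` to disable).
#' @param totals Moiety totals.
#' @param protocol Stimulation protocol for the check simulations.
#' @param map Observable map.
#' @return The accepted subset (possibly empty, with a message), each with
#'   `accepted = TRUE` and a `check_log` field.
#' @export
select_best <- function(results, network, threshold_J,
                        checks = feature_checks(),
                        totals = default_totals(),
                        protocol = mtor_protocol(), map = observable_map()) {
  stopifnot(threshold_J > 0)
  out <- purrr::map(results, function(r) {
    r$accepted <- FALSE
    r$check_log <- logical(0)
    if (r$J > threshold_J) return(r)
    ok <- TRUE
    if (length(checks)) {
      tab <- tryCatch({
        tr <- suppressWarnings(simulate_network(network, r$params,
                                                protocol = protocol,
                                                totals = totals))
        observable_table(tr, map, normalize = TRUE)
      }, error = function(e) NULL)
      if (is.null(tab)) ok <- FALSE else {
        r$check_log <- vapply(checks, function(f) isTRUE(f(tab)),
                              logical(1))
        ok <- all(r$check_log)
      }
    }
    r$accepted <- ok
    r
  })
  acc <- purrr::keep(out, ~ isTRUE(.x$accepted))
  if (!length(acc)) message("no fits accepted at threshold ", threshold_J)
  acc
}

#' Ensemble mean and standard-deviation envelopes
#'
#' @param accepted Non-empty list of accepted `fit_result`s.
#' @param network An `mtor_network`.
#' @param protocol Stimulation protocol.
#' @param totals Moiety totals.
#' @param map Observable map.
#' @return An `ensemble_envelope` tibble: `observable`, `time`, `mean`,
#'   `sd`, `n` (peak-normalized curves across members).
#' @export
ensemble_envelope <- function(accepted, network, protocol = mtor_protocol(),
                              totals = default_totals(),
                              map = observable_map()) {
  stopifnot(length(accepted) >= 1)
  curves <- purrr::imap_dfr(accepted, function(r, i) {
    tr <- simulate_network(network, r$params, protocol = protocol,
                           totals = totals)
    dplyr::mutate(observable_table(tr, map, normalize = TRUE), member = i)
  })
  out <- curves |>
    dplyr::group_by(.data$observable, .data$time) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
      n = dplyr::n(), .groups = "drop")
  class(out) <- c("ensemble_envelope", class(out))
  out
}

#' Plot ensemble envelopes
#'
#' @param object An `ensemble_envelope`.
#' @param ... Unused.
#' @return A ggplot with mean curves and +/- 1 sd ribbons per observable.
#' @export
autoplot.ensemble_envelope <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable) +
    ggplot2::labs(x = "time (min)", y = "peak-normalized signal")
}

#' Hierarchical clustering of accepted parameter sets
#'
#' Agglomerative clustering (Euclidean distance, average linkage) of the
#' log10 fitted-parameter vectors; deterministic.
#'
#' @param accepted List of >= 2 accepted `fit_result`s.
#' @param k Number of clusters for the label cut (default 2).
#' @return List with `tree` (an `hclust`), `heights` and `labels`
#'   (cluster membership at the `k` cut).
#' @export
cluster_fits <- function(accepted, k = 2) {
  if (length(accepted) < 2) {
    stop("need at least two fits to cluster", call. = FALSE)
  }
  free <- accepted[[1]]$free %||% param_names()
  m <- t(vapply(accepted, function(r) log10(unname(r$params[free])),
                numeric(length(free))))
  colnames(m) <- free
  tree <- stats::hclust(stats::dist(m), method = "average")
  list(tree = tree, heights = tree$height,
       labels = stats::cutree(tree, k = min(k, nrow(m))))
}

#' Summarize fit results
#'
#' @param x A list of `fit_result`s.
#' @param ... Unused.
#' @return Tibble with one row per run: `seed`, `J`, `accepted`.
#' @export
tidy.fit_result <- function(x, ...) {
  tibble::tibble(seed = x$seed, J = x$J, accepted = x$accepted)
}

#' @rdname tidy.fit_result
#' @param x A `fit_result`.
#' @export
glance.fit_result <- function(x, ...) {
  tibble::tibble(J = x$J, generations = length(x$best_per_generation),
                 population = x$config$population, seed = x$seed)
}
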