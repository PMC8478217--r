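# Dose-response scanning, the biphasic index, sensitivity ranking and the
# mTORC1 total-activity decomposition.

#' Steady-state dose-response scan of one protein or parameter
#'
#' For each fold on a log-spaced grid the target is perturbed
#' (`fold_change`), the system is pre-equilibrated and driven to its
#' stimulated steady state, and the observable is recorded. Scans are warm
#' started by continuation from the neighbouring fold. Points whose steady
#' state is not reached within the budget are flagged invalid (`valid`
#' column) and excluded from normalization.
#'
#' @param network An `mtor_network`.
#' @param params Kinetic parameters.
#' @param totals Moiety totals.
#' @param item Protein total (e.g. `"SIN1"`) or parameter name.
#' @param observable Observable name (see [observable_map()]).
#' @param fold_range Two-element range of fold changes (default
#'   `c(0.01, 1000)`).
#' @param n_points Grid size (default 61 log-spaced points).
#' @param insulin Stimulus level (nM).
#' @param map Observable map.
#' @return A `dose_response` tibble: `item`, `fold`, `value` (raw nM),
#'   `normalized` (peak = 1), `valid`; attributes `observable`, `peak_index`.
#' @export
dose_response <- function(network, params, totals = default_totals(),
                          item, observable = "pS6K1_obs",
                          fold_range = c(0.01, 1000), n_points = 61,
                          insulin = 100, map = observable_map()) {
  stopifnot(all(fold_range > 0), n_points >= 2)
  if (!observable %in% names(map)) {
    stop("unknown observable '", observable, "'", call. = FALSE)
  }
  folds <- 10^seq(log10(fold_range[1]), log10(fold_range[2]),
                  length.out = n_points)
  vals <- rep(NA_real_, n_points)
  valid <- rep(FALSE, n_points)
  st <- NULL
  for (i in seq_along(folds)) {
    ss <- tryCatch(
      suppressWarnings(
        steady_state(network, params, totals,
                     perturbation(item, "fold_change", folds[i]),
                     insulin = insulin, start = st)),
      error = function(e) NULL)
    if (!is.null(ss)) {
      st <- ss
      vals[i] <- observable_value(ss, observable, map)
      valid[i] <- isTRUE(attr(ss, "stationary"))
    }
  }
  peak <- max(vals[valid], na.rm = TRUE)
  normalized <- if (is.finite(peak) && peak > 0) vals / peak else
    rep(NA_real_, n_points)
  out <- tibble::tibble(item = item, fold = folds, value = vals,
                        normalized = normalized, valid = valid)
  class(out) <- c("dose_response", class(out))
  attr(out, "observable") <- observable
  attr(out, "peak_index") <- which.max(normalized)
  out
}

#' Biphasic index of a peak-normalized response curve
#'
#' `BI = y_norm(first) - y_norm(last)` on the peak-normalized curve. A
#' strictly increasing curve that starts at 0 and peaks at the last grid
#' point gives BI = -1; a strictly decreasing curve from an initial peak to
#' 0 gives BI = +1; interior values indicate a biphasic curve, more
#' pronounced the closer BI is to 0. BI is bounded in [-1, 1] for any
#' non-negative peak-normalized curve.
#'
#' @param curve A [dose_response()] result, or a numeric vector already
#'   peak-normalized (max = 1).
#' @param epsilon Classification margin (default 0.05): `BI <= -1 + epsilon`
#'   is `"increasing"`, `BI >= 1 - epsilon` is `"decreasing"`, otherwise
#'   `"biphasic"`.
#' @return A list of class `biphasic_report` with `bi` and `classification`.
#' @export
#' @examples
#' biphasic_index(seq(0, 1, length.out = 61))  # BI = -1, increasing
biphasic_index <- function(curve, epsilon = 0.05) {
  y <- if (inherits(curve, "dose_response")) {
    curve$normalized[curve$valid]
  } else as.numeric(curve)
  y <- y[is.finite(y)]
  if (length(y) < 2) stop("need at least two finite points", call. = FALSE)
  if (abs(max(y) - 1) > 1e-8) {
    stop("curve must be peak-normalized (max = 1); got max = ",
         signif(max(y), 6), call. = FALSE)
  }
  bi <- y[1] - y[length(y)]
  cls <- if (bi <= -1 + epsilon) "increasing"
         else if (bi >= 1 - epsilon) "decreasing"
         else "biphasic"
  structure(list(bi = bi, classification = cls), class = "biphasic_report")
}

#' @export
print.biphasic_report <- function(x, ...) {
  cat("<biphasic_report> BI =", signif(x$bi, 4), "->", x$classification,
      "\n")
  invisible(x)
}

#' Plot a dose-response curve
#'
#' @param object A `dose_response` tibble.
#' @param ... Unused.
#' @return A ggplot object (log-scaled fold axis).
#' @export
autoplot.dose_response <- function(object, ...) {
  ggplot2::ggplot(object[object$valid, ],
                  ggplot2::aes(.data$fold, .data$normalized)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = paste0(object$item[1], " (fold of nominal)"),
                  y = paste0(attr(object, "observable"),
                             " (peak-normalized steady state)"))
}

#' Two-dimensional steady-state perturbation scan
#'
#' @inheritParams dose_response
#' @param items Character vector of two distinct targets.
#' @param folds1,folds2 Fold grids for the two targets.
#' @return Tibble with `fold1`, `fold2`, `value`; attribute `items`.
#' @export
scan_2d <- function(network, params, totals = default_totals(), items,
                    folds1 = 10^seq(-2, 3, length.out = 13),
                    folds2 = 10^seq(-2, 3, length.out = 13),
                    observable = "pS6K1_obs", insulin = 100,
                    map = observable_map()) {
  stopifnot(length(items) == 2)
  if (items[1] == items[2]) stop("items must be distinct", call. = FALSE)
  rows <- purrr::map_dfr(folds2, function(f2) {
    st <- NULL
    vals <- numeric(length(folds1))
    for (i in seq_along(folds1)) {
      ss <- suppressWarnings(steady_state(
        network, params, totals,
        list(perturbation(items[1], "fold_change", folds1[i]),
             perturbation(items[2], "fold_change", f2)),
        insulin = insulin, start = st))
      st <- ss
      vals[i] <- observable_value(ss, observable, map)
    }
    tibble::tibble(fold1 = folds1, fold2 = f2, value = vals)
  })
  attr(rows, "items") <- items
  attr(rows, "observable") <- observable
  rows
}

#' Rank parameters or proteins by their effect on biphasicness
#'
#' For each item, its value is swept over `perturb_range` (fold changes of
#' nominal, default 0.001-1000); at every setting the SIN1 -> `observable`
#' dose-response is recomputed and its biphasic index taken. The score is
#' the BI range (max - min) over the sweep; larger scores mean the item
#' shapes the biphasic response more strongly. Items are ranked descending.
#'
#' @inheritParams dose_response
#' @param items Character vector of parameter and/or protein-total names.
#' @param perturb_range Sweep range in fold change (default `c(0.001, 1000)`).
#' @param n_perturb Sweep grid size per item (default 21).
#' @param scan_item Perturbed axis of the inner dose-response (default
#'   `"SIN1"`).
#' @param n_scan Grid size of the inner dose-response (default 61).
#' @return A `bi_ranking` tibble: `item`, `score`, `bi_min`, `bi_max`,
#'   `rank` (1 = largest score).
#' @export
rank_by_bi <- function(network, params, totals = default_totals(), items,
                       perturb_range = c(0.001, 1000), n_perturb = 21,
                       scan_item = "SIN1", observable = "pS6K1_obs",
                       fold_range = c(0.01, 1000), n_scan = 61,
                       insulin = 100, map = observable_map()) {
  sweep <- 10^seq(log10(perturb_range[1]), log10(perturb_range[2]),
                  length.out = n_perturb)
  known <- c(names(totals), param_names())
  bad <- setdiff(items, known)
  if (length(bad)) stop("unknown items: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  res <- purrr::map_dfr(items, function(it) {
    bis <- vapply(sweep, function(f) {
      pp <- params
      tt <- totals
      if (it %in% names(totals)) tt[it] <- tt[it] * f else
        pp[it] <- pp[it] * f
      dr <- tryCatch(
        dose_response(network, pp, tt, scan_item, observable,
                      fold_range = fold_range, n_points = n_scan,
                      insulin = insulin, map = map),
        error = function(e) NULL)
      if (is.null(dr) || sum(dr$valid) < 2 ||
          !any(is.finite(dr$normalized))) return(NA_real_)
      biphasic_index(dr)$bi
    }, numeric(1))
    tibble::tibble(item = it,
                   score = diff(range(bis, na.rm = TRUE)),
                   bi_min = min(bis, na.rm = TRUE),
                   bi_max = max(bis, na.rm = TRUE))
  })
  res <- dplyr::arrange(res, dplyr::desc(.data$score))
  res$rank <- seq_len(nrow(res))
  class(res) <- c("bi_ranking", class(res))
  res
}

#' Plot a biphasic-sensitivity ranking
#'
#' @param object A `bi_ranking` tibble.
#' @param ... Unused.
#' @return A ggplot bar chart ordered by score.
#' @export
autoplot.bi_ranking <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(stats::reorder(.data$item, .data$score),
                               .data$score)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "BI variation (max - min over sweep)")
}

#' Decompose total mTORC1 kinase activity
#'
#' Total activity is the product of mTORC1 abundance (active + inactive
#' pool, nM) and the activity potential per molecule (active fraction times
#' the catalytic constant toward S6K1, normalized by the same product at a
#' nominal state so the nominal potential is 1).
#'
#' @param state A steady state or any species vector.
#' @param params Kinetic parameters.
#' @param network The `mtor_network` the state belongs to.
#' @param nominal_state Optional reference state for normalizing the
#'   per-molecule potential; defaults to `state` itself (potential 1).
#' @return A tibble with `abundance`, `potential`, `total`. If abundance is
#'   zero, `total` is 0 and `potential` is `NA`.
#' @export
mtorc1_total_activity <- function(state, params, network,
                                  nominal_state = NULL) {
  pool <- function(s) unname(s[["mTORC1i"]] + s[["mTORC1a"]])
  per_molecule <- function(s) {
    p <- pool(s)
    if (p <= 0) return(NA_real_)
    unname((s[["mTORC1a"]] / p) * params[["k_f11b"]])
  }
  ab <- pool(state)
  pot <- per_molecule(state)
  norm <- if (is.null(nominal_state)) pot else per_molecule(nominal_state)
  pot <- if (is.na(pot)) NA_real_ else pot / norm
  tibble::tibble(
    abundance = ab,
    potential = pot,
    total = if (ab <= 0) 0 else ab * pot
  )
}
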