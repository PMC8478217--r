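# Synthetic-data generators: ground-truth parameterizations, noisy
# peak-normalized time-course datasets emulating quantified Western blots,
# and internally consistent relative/absolute proteomics tables.

#' Specification of a synthetic time-course study
#'
#' Emulates the structure of an insulin-stimulation blot-quantification
#' study: a handful of peak-normalized observables sampled at a coarse time
#' grid under wild-type and perturbed conditions, with multiplicative
#' log-normal noise (densitometry is positive and right-skewed).
#'
#' @param variant Model variant id.
#' @param observables Observable names to record.
#' @param times Sampling times in minutes (start at 0).
#' @param noise_sd Standard deviation of the log-normal noise on the log
#'   scale (0 = noise free; default 0.1).
#' @param conditions Named list of perturbation lists. Defaults to wild
#'   type, TRAF2 knockdown (fold 0.1) and SIN1 null.
#' @param insulin Stimulus (nM).
#' @return List of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(
    variant = 4,
    observables = c("pAKT_S473_obs", "pAKT_T308_obs", "pS6K1_obs",
                    "pTSC2_obs", "MLST8_deub_obs", "pIRS_obs"),
    times = c(0, 2, 5, 10, 15, 30, 60, 120),
    noise_sd = 0.1,
    conditions = list(
      WT = list(),
      TRAF2_kd = list(perturbation("TRAF2", "fold_change", 0.1)),
      SIN1_null = list(perturbation("SIN1", "set_value", 0))
    ),
    insulin = 100) {
  stopifnot(noise_sd >= 0, times[1] == 0, all(diff(times) > 0))
  structure(list(variant = variant, observables = observables,
                 times = times, noise_sd = noise_sd,
                 conditions = conditions, insulin = insulin),
            class = "synthetic_study_spec")
}

# qualitative screen a candidate truth/reference set must pass; returns a
# named logical vector so failures can be logged
reference_screen <- function(params, variant = 4,
                             totals = default_totals(), n_scan = 31) {
  checks <- c(simulates = FALSE, pakt_induced = FALSE,
              ps6k1_induced = FALSE, mlst8_overshoot = FALSE,
              sin1_scan_biphasic = FALSE, pakt_scan_monotone = FALSE)
  net <- build_network(variant)
  tr <- tryCatch(suppressWarnings(simulate_network(net, params,
                                                   totals = totals)),
                 error = function(e) NULL)
  if (is.null(tr)) return(checks)
  checks["simulates"] <- TRUE
  ind <- function(obs, factor) {
    y <- observable_series(tr, obs)
    max(y) > factor * max(y[1], 1e-6)
  }
  checks["pakt_induced"] <- ind("pAKT_S473_obs", 5)
  checks["ps6k1_induced"] <- ind("pS6K1_obs", 2)
  # only the IRS-wired variants (double negative feedback on OTUD7B) are
  # expected to reproduce the strong deubiquitinated-MLST8 overshoot
  if (net$variant$otud7b_upstream == "IRS") {
    m <- observable_series(tr, "MLST8_deub_obs")
    checks["mlst8_overshoot"] <- max(m) > 1.2 * m[length(m)]
  } else {
    checks["mlst8_overshoot"] <- TRUE
  }
  # scan checks always interrogate the MLST8-gated wiring (model 4)
  net4 <- if (identical(net$variant$id, "4")) net else build_network(4)
  dr1 <- tryCatch(dose_response(net4, params, totals, "SIN1", "pS6K1_obs",
                                n_points = n_scan),
                  error = function(e) NULL)
  dr2 <- tryCatch(dose_response(net4, params, totals, "SIN1",
                                "pAKT_S473_obs", n_points = n_scan),
                  error = function(e) NULL)
  if (!is.null(dr1)) {
    pk <- attr(dr1, "peak_index")
    checks["sin1_scan_biphasic"] <-
      pk > 1 && pk < n_scan &&
      biphasic_index(dr1)$classification == "biphasic"
  }
  if (!is.null(dr2)) {
    checks["pakt_scan_monotone"] <-
      biphasic_index(dr2)$classification == "increasing"
  }
  checks
}

#' Draw a screened reference/truth parameterization
#'
#' Draws kinetic constants log-uniformly within `jitter` decades of the
#' curated nominal set ([default_parameters()]), then rejects and redraws
#' until the qualitative screen passes: the insulin step induces pAKT S473
#' and pS6K1, deubiquitinated MLST8 overshoots, the model-4 SIN1 -> pS6K1
#' scan is biphasic and the SIN1 -> pAKT S473 scan is monotone increasing.
#' Deterministic under `seed`.
#'
#' @param variant Variant id.
#' @param seed Integer seed.
#' @param jitter Half-width of the log10-uniform draw around nominal
#'   (default 0.1 decades, i.e. within 1.26-fold).
#' @param max_tries Rejection budget.
#' @return Named parameter vector with attributes `seed` and `screen`
#'   (the named logical screen outcome).
#' @export
make_reference_parameters <- function(variant = 4, seed = 1, jitter = 0.1,
                                      max_tries = 20) {
  nominal <- default_parameters()
  set.seed(seed)
  last <- NULL
  for (i in seq_len(max_tries)) {
    cand <- nominal * 10^stats::runif(length(nominal), -jitter, jitter)
    names(cand) <- names(nominal)
    screen <- reference_screen(cand, variant)
    last <- structure(cand, seed = seed, screen = screen, draws = i)
    if (all(screen)) return(last)
  }
  stop("no candidate passed the qualitative screen within ", max_tries,
       " draws; last screen: ",
       paste(names(screen)[!screen], collapse = ", "), call. = FALSE)
}

#' Simulate noisy peak-normalized blot-style datasets
#'
#' For each condition and observable the ground-truth model is simulated,
#' sampled at the study time points, multiplied by log-normal noise and
#' peak-normalized. Observable/condition pairs whose true signal never
#' exceeds `min_peak` (e.g. pAKT S473 in SIN1-null cells) are skipped and
#' listed in the `skipped` attribute.
#'
#' @param spec A [synthetic_study_spec()].
#' @param truth Ground-truth kinetic parameters.
#' @param totals Moiety totals.
#' @param seed Integer seed for the noise.
#' @param min_peak Smallest true peak (nM) worth quantifying.
#' @return A tibble of class `blot_datasets` with columns `condition`,
#'   `observable`, `time_min`, `value`, `weight`; attribute `truth_curves`
#'   holds the noise-free peak-normalized truth in the same layout.
#' @export
simulate_blot_data <- function(spec = synthetic_study_spec(), truth,
                               totals = default_totals(), seed = 1,
                               min_peak = 1e-3) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  net <- build_network(spec$variant)
  set.seed(seed)
  protocol <- mtor_protocol(insulin = spec$insulin, grid = spec$times)
  out <- list()
  truth_rows <- list()
  skipped <- character()
  for (cn in names(spec$conditions)) {
    ap <- apply_perturbations(totals, truth, spec$conditions[[cn]])
    tr <- simulate_network(net, ap$params, protocol = protocol,
                           totals = ap$totals)
    for (obs in spec$observables) {
      y <- observable_series(tr, obs)
      if (max(y) < min_peak) {
        skipped <- c(skipped, paste(cn, obs, sep = ":"))
        next
      }
      noisy <- y * exp(stats::rnorm(length(y), 0, spec$noise_sd))
      out[[paste(cn, obs)]] <- tibble::tibble(
        condition = cn, observable = obs, time_min = spec$times,
        value = peak_normalize(noisy), weight = 1)
      truth_rows[[paste(cn, obs)]] <- tibble::tibble(
        condition = cn, observable = obs, time_min = spec$times,
        value = peak_normalize(y), weight = 1)
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("blot_datasets", class(res))
  attr(res, "truth_curves") <- dplyr::bind_rows(truth_rows)
  attr(res, "skipped") <- skipped
  attr(res, "spec") <- spec
  res
}

#' Specification of a synthetic proteomics cohort
#'
#' @param n_lines Number of cell lines.
#' @param n_refs Number of reference (absolute-abundance) lines, taken as
#'   the first `n_refs` lines.
#' @param proteins Protein names (default: the model proteins).
#' @param base_profile Expected absolute-abundance profile (arbitrary
#'   copy-number units) around which lines vary; defaults to the model
#'   totals, i.e. the reference (MEF-like) expression profile.
#' @param sdlog Cell-to-cell log-normal spread on the natural-log scale
#'   (default 0.3, a realistic ~30% coefficient of variation).
#' @param rel_scale_sdlog Spread of the per-protein proportionality
#'   constants linking the relative table to absolute truth.
#' @param missingness Fraction of relative-table entries blanked to NA
#'   (never in reference lines' required proteins; default 0).
#' @return List of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_lines = 25, n_refs = 3,
                                  proteins = names(default_totals()),
                                  base_profile = default_totals(),
                                  sdlog = 0.3, rel_scale_sdlog = 1,
                                  missingness = 0) {
  stopifnot(n_refs <= n_lines, missingness >= 0, missingness < 1,
            sdlog >= 0)
  structure(list(n_lines = n_lines, n_refs = n_refs, proteins = proteins,
                 base_profile = base_profile[proteins], sdlog = sdlog,
                 rel_scale_sdlog = rel_scale_sdlog,
                 missingness = missingness),
            class = "synthetic_cohort_spec")
}

#' Generate internally consistent relative/absolute proteomics tables
#'
#' Draws a ground-truth absolute-abundance matrix (proteins x lines,
#' log-normal around the base profile), derives the relative table by
#' scaling each protein's row with a positive per-protein proportionality
#' constant (relative expression is comparable across lines within a
#' protein, as in CCLE-style data), restricts the truth to the reference
#' lines for the iBAQ-like absolute table, and optionally blanks a fraction
#' of relative entries (recording the positions).
#'
#' @param spec A [synthetic_cohort_spec()].
#' @param seed Integer seed.
#' @return List with `relative` (tibble, first column `protein`), `reference`
#'   (same layout, reference lines only), `truth` (ground-truth absolute
#'   matrix as tibble), `missing_positions` (tibble protein/cell_line), and
#'   `lines`/`ref_lines` name vectors.
#' @export
make_proteomics_tables <- function(spec = synthetic_cohort_spec(),
                                   seed = 1) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  set.seed(seed)
  np <- length(spec$proteins)
  lines <- sprintf("line_%02d", seq_len(spec$n_lines))
  refs <- lines[seq_len(spec$n_refs)]
  truth <- matrix(
    spec$base_profile * exp(stats::rnorm(np * spec$n_lines, 0, spec$sdlog)),
    nrow = np, dimnames = list(spec$proteins, lines))
  rel_scale <- exp(stats::rnorm(np, 0, spec$rel_scale_sdlog))
  relative <- truth * rel_scale
  miss <- tibble::tibble(protein = character(), cell_line = character())
  if (spec$missingness > 0) {
    # reference lines stay complete so they can anchor the inference
    eligible <- which(col(relative) > spec$n_refs)
    idx <- eligible[stats::runif(length(eligible)) < spec$missingness]
    if (length(idx)) {
      relative[idx] <- NA_real_
      miss <- tibble::tibble(
        protein = rownames(relative)[(idx - 1) %% np + 1],
        cell_line = colnames(relative)[(idx - 1) %/% np + 1])
    }
  }
  as_tab <- function(m) {
    tibble::as_tibble(cbind(
      tibble::tibble(protein = rownames(m)),
      tibble::as_tibble(as.data.frame(m))))
  }
  list(relative = as_tab(relative),
       reference = as_tab(truth[, refs, drop = FALSE]),
       truth = as_tab(truth),
       missing_positions = miss,
       lines = lines, ref_lines = refs)
}
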