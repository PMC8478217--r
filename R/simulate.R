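# Integration, equilibration, perturbations and observables.

#' Stimulus protocol
#'
#' Insulin is applied as a step at t = 0 and held constant (sustained
#' stimulation). Serum-starved basal conditions are emulated by mandatory
#' pre-equilibration at insulin 0.
#'
#' @param insulin Insulin step level in nM (default 100).
#' @param duration Length of the stimulated run in minutes.
#' @param grid Output time grid (minutes), strictly increasing from 0.
#' @param pre_equilibration Equilibrate at insulin 0 before stimulating.
#' @return A list of class `mtor_protocol`.
#' @export
mtor_protocol <- function(insulin = 100, duration = 120,
                          grid = seq(0, duration, by = 1),
                          pre_equilibration = TRUE) {
  stopifnot(insulin >= 0, grid[1] == 0, all(diff(grid) > 0))
  structure(list(insulin = insulin, duration = max(grid), grid = grid,
                 pre_equilibration = pre_equilibration),
            class = "mtor_protocol")
}

#' Specify a perturbation
#'
#' @param target Name of a protein total (moiety, e.g. `"TRAF2"`, `"SIN1"`)
#'   or of a kinetic parameter (e.g. `"k_f4"`).
#' @param mode `"fold_change"` (multiply the nominal value) or `"set_value"`.
#' @param magnitude Positive fold for `fold_change`; any non-negative value
#'   for `set_value` (genetic nulls use 0).
#' @return A list of class `mtor_perturbation`.
#' @export
#' @examples
#' perturbation("TRAF2", "fold_change", 0.1)  # TRAF2-/- knockdown (90% loss)
#' perturbation("SIN1", "set_value", 0)       # SIN1-null
perturbation <- function(target, mode = c("fold_change", "set_value"),
                         magnitude) {
  mode <- match.arg(mode)
  if (mode == "fold_change" && magnitude <= 0) {
    stop("fold_change magnitude must be > 0", call. = FALSE)
  }
  if (magnitude < 0) stop("magnitude must be >= 0", call. = FALSE)
  structure(list(target = target, mode = mode, magnitude = magnitude),
            class = "mtor_perturbation")
}

#' Apply perturbations to totals and parameters
#'
#' @param totals Named moiety totals.
#' @param params Named kinetic parameters.
#' @param perturbations A list of [perturbation()] objects (or a single one).
#' @return List with perturbed `totals` and `params`.
#' @export
apply_perturbations <- function(totals, params, perturbations = list()) {
  if (inherits(perturbations, "mtor_perturbation")) {
    perturbations <- list(perturbations)
  }
  for (p in perturbations) {
    if (p$target %in% names(totals)) {
      totals[[p$target]] <- if (p$mode == "fold_change") {
        totals[[p$target]] * p$magnitude
      } else p$magnitude
    } else if (p$target %in% names(params)) {
      params[[p$target]] <- if (p$mode == "fold_change") {
        params[[p$target]] * p$magnitude
      } else p$magnitude
    } else {
      stop("unknown perturbation target '", p$target, "'", call. = FALSE)
    }
  }
  list(totals = totals, params = params)
}

# low-level integration over `times` at fixed insulin, compiled RHS.
# Falls back to looser tolerances and then to radau for pathologically stiff
# corners of parameter space (extreme fold perturbations in scans).
integrate_raw <- function(network, params, state, times, insulin,
                          rtol = 1e-8, atol = 1e-10) {
  attempts <- list(
    list(rtol = rtol, atol = atol, method = "lsoda"),
    list(rtol = max(rtol, 1e-6), atol = max(atol, 1e-8), method = "lsoda"),
    list(rtol = max(rtol, 1e-6), atol = max(atol, 1e-8), method = "radau")
  )
  y0 <- unname(state[network$species])
  prm <- compiled_parms(network, params, insulin)
  err <- NULL
  for (a in attempts) {
    out <- tryCatch(
      suppressWarnings(deSolve::ode(
        y = y0, times = times, func = "mtor_derivs", parms = prm,
        dllname = "mtorswitch", initfunc = "mtor_initmod",
        rtol = a$rtol, atol = a$atol, method = a$method, maxsteps = 1e5)),
      error = function(e) e)
    if (!inherits(out, "error") && attr(out, "istate")[1] >= 0 &&
        nrow(out) == length(times)) {
      m <- t(out[, -1, drop = FALSE])
      rownames(m) <- network$species
      colnames(m) <- NULL
      return(m)
    }
    err <- if (inherits(out, "error")) conditionMessage(out) else
      paste("solver stopped near t =", signif(max(out[, 1]), 4), "min")
  }
  stop("ODE integration failed: ", err, call. = FALSE)
}

# compiled RHS evaluated at one state
rhs_fast <- function(network, state, params, insulin) {
  f <- deSolve::DLLfunc(
    y = unname(state[network$species]), times = 0,
    func = "mtor_derivs", parms = compiled_parms(network, params, insulin),
    dllname = "mtorswitch", initfunc = "mtor_initmod")
  stats::setNames(f$dy, network$species)
}

# integrate in chunks until max |dx/dt| < tol; returns state + attributes
relax_to_steady <- function(network, params, state, insulin,
                            tol = 1e-9, t_budget = 1e5, chunk = 500,
                            rtol = 1e-8, atol = 1e-10) {
  t_done <- 0
  repeat {
    res <- max(abs(rhs_fast(network, state, params, insulin)))
    if (res < tol || t_done >= t_budget) break
    m <- integrate_raw(network, params, state, c(0, chunk), insulin,
                       rtol = rtol, atol = atol)
    state <- stats::setNames(m[, 2], network$species)
    t_done <- t_done + chunk
    chunk <- min(chunk * 2, 2e4)
  }
  attr(state, "residual") <- max(abs(rhs_fast(network, state, params,
                                              insulin)))
  attr(state, "stationary") <- attr(state, "residual") < tol
  state
}

#' Basal (insulin-free) steady state
#'
#' Starts from the fully unmodified pools of [initial_state()] and relaxes
#' the system at insulin 0 until the residual `max |dx/dt|` falls below
#' `tol` (default 1e-9 nM/min).
#'
#' @param network An `mtor_network`.
#' @param params Kinetic parameters.
#' @param totals Moiety totals (nM).
#' @param tol Residual tolerance (nM/min).
#' @param t_budget Maximum equilibration time (min).
#' @return Named basal state with attributes `residual` and `stationary`.
#' @export
pre_equilibrate <- function(network, params, totals = default_totals(),
                            tol = 1e-9, t_budget = 1e5) {
  state <- initial_state(network, totals)
  out <- relax_to_steady(network, params, state, insulin = 0,
                         tol = tol, t_budget = t_budget)
  if (!attr(out, "stationary")) {
    warning("pre-equilibration did not converge: residual ",
            signif(attr(out, "residual"), 3), " nM/min", call. = FALSE)
  }
  out
}

#' Simulate an insulin-stimulation time course
#'
#' @param network An `mtor_network`.
#' @param params Kinetic parameters.
#' @param basal Basal state (from [pre_equilibrate()]); if `NULL` it is
#'   computed from `totals`.
#' @param protocol An [mtor_protocol()].
#' @param totals Moiety totals, used when `basal` is `NULL`.
#' @return An `mtor_trajectory`: list with `time`, species x time matrix
#'   `conc`, and `provenance`.
#' @export
simulate_network <- function(network, params, basal = NULL,
                             protocol = mtor_protocol(),
                             totals = default_totals()) {
  stopifnot(inherits(protocol, "mtor_protocol"))
  if (is.null(basal)) {
    basal <- if (protocol$pre_equilibration) {
      pre_equilibrate(network, params, totals)
    } else initial_state(network, totals)
  }
  conc <- integrate_raw(network, params, basal, protocol$grid,
                        protocol$insulin)
  structure(
    list(time = protocol$grid, conc = conc,
         provenance = list(variant = network$variant$id,
                           insulin = protocol$insulin,
                           totals = conserved_totals(network, basal))),
    class = "mtor_trajectory")
}

#' @export
print.mtor_trajectory <- function(x, ...) {
  cat("<mtor_trajectory> variant ", x$provenance$variant, ", ",
      length(x$time), " time points over ", max(x$time), " min, insulin ",
      x$provenance$insulin, " nM\n", sep = "")
  invisible(x)
}

#' Tidy a trajectory into long format
#'
#' @param x An `mtor_trajectory`.
#' @param ... Unused.
#' @return Tibble with columns `time`, `species`, `value`.
#' @export
tidy.mtor_trajectory <- function(x, ...) {
  tibble::tibble(
    time = rep(x$time, each = nrow(x$conc)),
    species = rep(rownames(x$conc), times = length(x$time)),
    value = as.vector(x$conc)
  )
}

#' Stimulated steady state under perturbations
#'
#' Applies the perturbations, pre-equilibrates at insulin 0, relaxes at the
#' stimulated insulin level until `max |dx/dt| < tol`, then attempts one
#' damped-Newton refinement (minimum-norm step via the pseudo-inverse, which
#' respects the conserved directions).
#'
#' @inheritParams pre_equilibrate
#' @param perturbations List of [perturbation()] objects.
#' @param insulin Stimulated insulin level (nM).
#' @param start Optional warm-start state (e.g. a neighbouring steady state
#'   in a dose-response continuation); its moieties are rescaled to the
#'   perturbed totals before relaxing, and pre-equilibration is skipped.
#' @return Named steady state with attributes `residual` and `stationary`.
#' @export
steady_state <- function(network, params, totals = default_totals(),
                         perturbations = list(), insulin = 100,
                         tol = 1e-9, t_budget = 1e5, start = NULL) {
  ap <- apply_perturbations(totals, params, perturbations)
  if (is.null(start)) {
    state <- pre_equilibrate(network, ap$params, ap$totals, tol = tol)
  } else {
    state <- rescale_moieties(network, start, ap$totals)
  }
  out <- relax_to_steady(network, ap$params, state, insulin,
                         tol = tol, t_budget = t_budget)
  out <- newton_refine(network, ap$params, out, insulin)
  if (!attr(out, "stationary")) {
    warning("steady state not reached (non-stationary): residual ",
            signif(attr(out, "residual"), 3), " nM/min", call. = FALSE)
  }
  out
}

# project a state onto new moiety totals by proportional rescaling
rescale_moieties <- function(network, state, totals) {
  state <- state[network$species]
  for (g in names(network$conservation)) {
    sp <- network$conservation[[g]]
    cur <- sum(state[sp])
    if (cur > 0) {
      state[sp] <- state[sp] * totals[[g]] / cur
    } else if (totals[[g]] > 0) {
      # repopulate an emptied moiety in its unmodified pool
      seed <- initial_state(network, totals)
      state[sp] <- seed[sp]
    }
  }
  state
}

# one damped Newton step using a forward-difference Jacobian of the
# compiled RHS; kept only if it reduces the residual
newton_refine <- function(network, params, state, insulin) {
  f0 <- rhs_fast(network, state, params, insulin)
  r0 <- max(abs(f0))
  n <- length(state)
  J <- matrix(0, n, n)
  h <- pmax(1e-7 * abs(state), 1e-9)
  for (i in seq_len(n)) {
    xp <- state
    xp[i] <- xp[i] + h[i]
    J[, i] <- (rhs_fast(network, xp, params, insulin) - f0) / h[i]
  }
  sv <- svd(J)
  keep <- sv$d > max(sv$d) * 1e-10
  delta <- -sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% f0) / sv$d[keep])
  for (alpha in c(1, 0.5, 0.25)) {
    cand <- state + alpha * drop(delta)
    if (any(cand < -1e-12)) next
    cand[cand < 0] <- 0
    r1 <- max(abs(rhs_fast(network, cand, params, insulin)))
    if (r1 < r0) {
      attributes(cand) <- NULL
      cand <- stats::setNames(cand, network$species)
      attr(cand, "residual") <- r1
      attr(cand, "stationary") <- TRUE
      return(cand)
    }
  }
  state
}

#' Default observable map
#'
#' Named linear combinations of species matching how quantified blots are
#' reported: phospho-signals pool the doubly phosphorylated AKT form, and
#' deubiquitinated MLST8 pools every unubiquitinated MLST8-containing form.
#'
#' @return Named list of named coefficient vectors.
#' @export
observable_map <- function() {
  list(
    pAKT_S473_obs = c(pAKT_S473 = 1, ppAKT = 1),
    pAKT_T308_obs = c(pAKT_T308 = 1, ppAKT = 1),
    pS6K1_obs = c(pS6K1 = 1),
    pTSC2_obs = c(pTSC2 = 1),
    MLST8_deub_obs = c(MLST8_free = 1, mTORC2 = 1, amTORC2 = 1),
    mTORC2_obs = c(amTORC2 = 1),
    pIRS_obs = c(pIRS = 1)
  )
}

#' Extract an observable time series from a trajectory
#'
#' @param trajectory An `mtor_trajectory`.
#' @param name Observable name.
#' @param map Observable map (default [observable_map()]).
#' @return Numeric vector over the trajectory's time grid.
#' @export
observable_series <- function(trajectory, name, map = observable_map()) {
  if (!name %in% names(map)) {
    stop("unknown observable '", name, "'; known: ",
         paste(names(map), collapse = ", "), call. = FALSE)
  }
  co <- map[[name]]
  drop(co %*% trajectory$conc[names(co), , drop = FALSE])
}

# evaluate an observable on a single state vector
observable_value <- function(state, name, map = observable_map()) {
  co <- map[[name]]
  sum(co * state[names(co)])
}

#' All observables of a trajectory as a tibble
#'
#' @inheritParams observable_series
#' @param normalize Peak-normalize each observable curve.
#' @return Tibble with `time`, `observable`, `value`.
#' @export
observable_table <- function(trajectory, map = observable_map(),
                             normalize = FALSE) {
  purrr::map_dfr(names(map), function(nm) {
    y <- observable_series(trajectory, nm, map)
    if (normalize) y <- peak_normalize(y)
    tibble::tibble(time = trajectory$time, observable = nm, value = y)
  })
}

#' Peak-normalize a series
#'
#' Divides by the maximum so the peak equals 1 (the convention used for
#' quantified blot curves and dose-response scans).
#'
#' @param series Numeric vector with at least one positive entry.
#' @return Series divided by its maximum.
#' @export
peak_normalize <- function(series) {
  m <- max(series)
  if (!is.finite(m) || m <= 0) {
    stop("peak normalization requires a positive maximum", call. = FALSE)
  }
  series / m
}

#' Plot an insulin-response trajectory's observables
#'
#' @param object An `mtor_trajectory`.
#' @param map Observable map.
#' @param normalize Peak-normalize each curve (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mtor_trajectory <- function(object, map = observable_map(),
                                     normalize = TRUE, ...) {
  dat <- observable_table(object, map, normalize = normalize)
  ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable) +
    ggplot2::labs(x = "time (min)",
                  y = if (normalize) "peak-normalized signal" else "nM")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
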