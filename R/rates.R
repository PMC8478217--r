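# Rate laws, right-hand side and moiety bookkeeping (pure-R reference path;
# simulation uses the compiled equivalent in src/).

#' Evaluate all reaction rates
#'
#' Mass-action association `k*A*B`, first-order conversion `k*X`,
#' Michaelis-Menten catalysis `kcat*E*S/(Km+S)` and TSC2a-inhibited
#' activation `k*X/(1+I/k_i)`. Insulin enters as the catalytic "enzyme" of
#' INSR activation.
#'
#' @param network An [build_network()] object.
#' @param state Named non-negative species vector (nM), see [mtor_species()].
#' @param params Named positive kinetic parameters, see [param_names()].
#' @param insulin Insulin concentration (nM).
#' @return Named numeric vector of per-reaction rates (nM/min).
#' @export
rate_vector <- function(network, state, params, insulin = 0) {
  stopifnot(inherits(network, "mtor_network"))
  params <- check_parameters(params)
  state <- state[network$species]
  if (anyNA(state)) stop("state is missing species required by the variant",
                         call. = FALSE)
  if (any(state < 0)) stop("negative concentrations are not allowed",
                           call. = FALSE)
  if (insulin < 0) stop("insulin must be >= 0", call. = FALSE)

  vapply(network$reactions, function(r) {
    p <- params[r$params]
    switch(r$law,
      mm = {
        E <- if (r$enzyme == "insulin") insulin else state[[r$enzyme]]
        S <- state[[r$substrate]]
        p[[1]] * E * S / (p[[2]] + S)
      },
      mass_action = p[[1]] * state[[r$a]] * state[[r$b]],
      first_order = p[[1]] * state[[r$substrate]],
      inhibited = p[[1]] * state[[r$substrate]] /
        (1 + state[[r$inhibitor]] / p[[2]]),
      stop("unknown rate law ", r$law)
    )
  }, numeric(1), USE.NAMES = TRUE) |>
    stats::setNames(vapply(network$reactions, `[[`, "", "name"))
}

#' Species derivatives (stoichiometry x rates)
#'
#' @inheritParams rate_vector
#' @return Named numeric vector of d(concentration)/dt (nM/min) per species.
#' @export
ode_rhs <- function(network, state, params, insulin = 0) {
  v <- rate_vector(network, state, params, insulin)
  drop(network$stoich %*% v) |> stats::setNames(network$species)
}

#' Conserved moiety totals of a state
#'
#' @inheritParams rate_vector
#' @return Named numeric vector, one total per conservation group.
#' @export
conserved_totals <- function(network, state) {
  stopifnot(inherits(network, "mtor_network"))
  if (anyNA(state[network$species])) {
    stop("state is missing species required by the variant", call. = FALSE)
  }
  vapply(network$conservation, function(g) sum(state[g]), numeric(1))
}

#' Initial (fully unmodified) state from moiety totals
#'
#' Places every moiety in its unmodified pool. In variants 1-2 the raptor
#' total seeds the inactive mTORC1 pool directly (MLST8 is not part of
#' mTORC1); in variants 3-4/4P it seeds free raptor and mTORC1 assembles
#' from ubiquitinated MLST8.
#'
#' @param network An `mtor_network`.
#' @param totals Named moiety totals, see [default_totals()].
#' @return Named species vector.
#' @export
initial_state <- function(network, totals = default_totals()) {
  stopifnot(inherits(network, "mtor_network"))
  miss <- setdiff(names(network$conservation), names(totals))
  if (length(miss)) stop("missing totals: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(totals < 0)) stop("totals must be >= 0", call. = FALSE)
  x <- stats::setNames(numeric(length(network$species)), network$species)
  x["INSR"] <- totals[["INSR"]]
  x["IRS"] <- totals[["IRS"]]
  x["OTUD7B"] <- totals[["OTUD7B"]]
  x["MLST8_free"] <- totals[["MLST8"]]
  x["SIN1_free"] <- totals[["SIN1"]]
  if (network$variant$mlst8_required_for_mtorc1) {
    x["Raptor_free"] <- totals[["Raptor"]]
  } else {
    x["mTORC1i"] <- totals[["Raptor"]]
  }
  x["AKT"] <- totals[["AKT"]]
  x["TSC2a"] <- totals[["TSC2"]]
  x["S6K1"] <- totals[["S6K1"]]
  x["TRAF2"] <- totals[["TRAF2"]]
  x
}

# parameter vector handed to the compiled RHS: kinetics + insulin + wiring
compiled_parms <- function(network, params, insulin) {
  v <- network$variant
  c(unname(check_parameters(params)),
    insulin,
    as.numeric(v$otud7b_upstream == "IRS"),
    as.numeric(v$mlst8_required_for_mtorc1),
    as.numeric(v$mtorc2_activator == "pIRS"))
}
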