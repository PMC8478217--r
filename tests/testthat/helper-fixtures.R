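# Shared fixtures: networks are cheap to build, steady states are cached
# per test file via these helpers.

net_of <- local({
  cache <- list()
  function(variant) {
    key <- as.character(variant)
    if (is.null(cache[[key]])) cache[[key]] <<- build_network(variant)
    cache[[key]]
  }
})

ref4 <- function() reference_parameters(4)

# a random strictly positive state for rate-law tests
random_state <- function(net, scale = 50) {
  x <- stats::setNames(stats::runif(length(net$species), 0, scale),
                       net$species)
  x
}

# independent brute-force RHS: re-derives each law from the reaction list
# and accumulates stoichiometry, without touching the package's matrix path
brute_rhs <- function(net, state, params, insulin) {
  d <- stats::setNames(numeric(length(net$species)), net$species)
  for (r in net$reactions) {
    v <- switch(r$law,
      mm = {
        E <- if (r$enzyme == "insulin") insulin else state[[r$enzyme]]
        params[[r$params[["kcat"]]]] * E * state[[r$substrate]] /
          (params[[r$params[["Km"]]]] + state[[r$substrate]])
      },
      mass_action = params[[r$params[["k"]]]] * state[[r$a]] * state[[r$b]],
      first_order = params[[r$params[["k"]]]] * state[[r$substrate]],
      inhibited = params[[r$params[["k"]]]] * state[[r$substrate]] /
        (1 + state[[r$inhibitor]] / params[[r$params[["ki"]]]])
    )
    d[names(r$stoich)] <- d[names(r$stoich)] + r$stoich * v
  }
  d
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-12)), tol)
}
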