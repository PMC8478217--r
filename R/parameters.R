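# Kinetic parameters, protein totals and their bounds.

#' Canonical kinetic-parameter names
#'
#' Order matters: the compiled right-hand side receives parameters in this
#' order. Catalytic constants are `/min` per nM of enzyme (`k_f*`, `k_r4`),
#' association constants `/nM/min` (`k_f5`, `k_f6`), first-order reversals
#' `/min`, Michaelis constants `Km_*` and the TSC2a inhibition constant
#' `k_i1` in nM.
#'
#' @return Character vector of parameter names.
#' @export
param_names <- function() {
  c("k_f1", "Km_1", "k_r1", "k_f1b", "Km_1b",
    "k_f2", "Km_2", "k_r2", "k_f2b", "Km_2b", "k_r2b",
    "k_f3", "Km_3", "k_r3",
    "k_f4", "Km_4", "k_r4", "Km_4b",
    "k_f5", "k_r5",
    "k_f6", "k_r6",
    "k_f7", "Km_7", "k_f7b", "k_r7",
    "k_f8", "Km_8", "k_r8",
    "k_f9", "Km_9", "k_r9",
    "k_f10a", "Km_10a", "k_f10b", "Km_10b", "k_r10a", "k_r10b",
    "k_f11a", "k_i1", "k_r11",
    "k_f11b", "Km_11b", "k_r11b",
    "k_f12a", "Km_12a", "k_f12b", "Km_12b", "k_r12")
}

#' Default (nominal) kinetic parameters
#'
#' A curated nominal set around which calibration bounds and the synthetic
#' truth generator are centred. Units: nM and minutes.
#'
#' @return Named numeric vector over [param_names()].
#' @export
default_parameters <- function() {
  p <- c(
    k_f1 = 0.2,   Km_1 = 40,   k_r1 = 0.3,  k_f1b = 1,    Km_1b = 40,
    k_f2 = 1,     Km_2 = 40,   k_r2 = 0.3,
    k_f2b = 1,    Km_2b = 40,  k_r2b = 0.05,
    k_f3 = 0.5,   Km_3 = 40,   k_r3 = 0.3,
    k_f4 = 12,    Km_4 = 40,   k_r4 = 0.8,  Km_4b = 40,
    k_f5 = 0.045, k_r5 = 0.2,
    k_f6 = 0.02,  k_r6 = 0.2,
    k_f7 = 0.5,   Km_7 = 40,   k_f7b = 0.005, k_r7 = 0.3,
    k_f8 = 0.5,   Km_8 = 40,   k_r8 = 0.5,
    k_f9 = 0.5,   Km_9 = 40,   k_r9 = 0.3,
    k_f10a = 0.5, Km_10a = 40, k_f10b = 0.05, Km_10b = 40,
    k_r10a = 0.3, k_r10b = 0.3,
    k_f11a = 10,  k_i1 = 0.2,  k_r11 = 1,
    k_f11b = 2,   Km_11b = 50, k_r11b = 0.5,
    k_f12a = 0.01, Km_12a = 50, k_f12b = 5, Km_12b = 30, k_r12 = 0.1
  )
  p[param_names()]
}

#' Default protein totals (nM)
#'
#' One total per conserved moiety, order-10-100 nM, chosen so the mean over
#' the ten model proteins is exactly 100 nM (the anchor the nanomolar
#' conversion of [to_nanomolar()] preserves).
#'
#' @return Named numeric vector of moiety totals.
#' @export
default_totals <- function() {
  c(INSR = 120, IRS = 120, OTUD7B = 120, MLST8 = 120, SIN1 = 60,
    Raptor = 80, AKT = 120, TSC2 = 120, S6K1 = 130, TRAF2 = 10)
}

#' Calibration bounds for the kinetic parameters
#'
#' Log-uniform bounds spanning `fold` down/up of the nominal value
#' (default 1e3, i.e. six decades per parameter).
#'
#' @param params Nominal parameter vector (default [default_parameters()]).
#' @param fold Half-range in fold change (default `1e3`).
#' @return Tibble with `name`, `value`, `lower_bound`, `upper_bound`.
#' @export
parameter_bounds <- function(params = default_parameters(), fold = 1e3) {
  stopifnot(all(params > 0), fold > 1)
  tibble::tibble(
    name = names(params),
    value = unname(params),
    lower_bound = unname(params) / fold,
    upper_bound = unname(params) * fold
  )
}

#' Read / write parameter tables
#'
#' CSV files carry columns `name,value,lower_bound,upper_bound`
#' (bounds optional); JSON files carry the same records.
#'
#' @param path File path.
#' @param params Named numeric vector, or a bounds tibble as produced by
#'   [parameter_bounds()].
#' @return `read_parameters()` returns a named numeric vector (attribute
#'   `bounds` holds the full tibble when bounds are present).
#' @export
write_parameters <- function(params, path) {
  tab <- if (is.data.frame(params)) params else
    tibble::tibble(name = names(params), value = unname(params))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(tab, path, digits = NA)
  } else {
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  tab <- if (grepl("\\.json$", path)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  }
  stopifnot(all(c("name", "value") %in% names(tab)))
  p <- stats::setNames(tab$value, tab$name)
  attr(p, "bounds") <- tab
  p
}

#' Reference parameterization shipped with the package
#'
#' One curated kinetic parameter set per variant, produced by
#' [make_reference_parameters()] (rejection sampling under the qualitative
#' screen) and frozen under `inst/extdata/`; the JSON provenance sidecar
#' records the generating seed. These sets reproduce the qualitative study
#' behaviours: SIN1 -> pS6K1 biphasic with pAKT S473 monotone (variant 4),
#' the MLST8 overshoot, and the TRAF2-knockdown buffering of pS6K1 in
#' MLST8-gated variants.
#'
#' @param variant Variant id.
#' @return Named numeric parameter vector.
#' @export
reference_parameters <- function(variant = 4) {
  v <- variant_info(variant)
  f <- system.file("extdata", paste0("reference_params_model", v$id, ".csv"),
                   package = "mtorswitch")
  if (f == "") stop("no shipped reference parameterization for variant ",
                    v$id, call. = FALSE)
  p <- read_parameters(f)
  attr(p, "bounds") <- NULL
  p[param_names()]
}

# validate a parameter vector against the canonical names
check_parameters <- function(params) {
  miss <- setdiff(param_names(), names(params))
  if (length(miss)) {
    stop("missing parameters: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(params[param_names()])) ||
      any(params[param_names()] <= 0)) {
    stop("all kinetic parameters must be finite and > 0", call. = FALSE)
  }
  invisible(params[param_names()])
}
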