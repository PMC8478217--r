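# Plain-text interchange: network JSON, trajectory CSV + provenance
# sidecar, calibration dataset CSV.

#' Export / import a reaction network as JSON
#'
#' The document lists the variant flags, species, reactions (law kind,
#' parameter names, stoichiometry) and conservation groups, and round-trips
#' losslessly through [read_network_json()].
#'
#' @param network An `mtor_network`.
#' @param path Output path (`.json`).
#' @return `write_network_json()` the path, invisibly;
#'   `read_network_json()` an `mtor_network`.
#' @export
write_network_json <- function(network, path) {
  stopifnot(inherits(network, "mtor_network"))
  doc <- list(
    variant = network$variant,
    species = network$species,
    reactions = purrr::map(network$reactions, function(r) {
      r$stoich <- as.list(r$stoich)
      r$params <- as.list(r$params)
      r
    }),
    conservation = network$conservation
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  v <- doc$variant
  v$mlst8_required_for_mtorc1 <- isTRUE(v$mlst8_required_for_mtorc1)
  net <- build_network(v)
  # integrity check against the canonical constructor
  if (!identical(unlist(doc$species), net$species)) {
    stop("species list does not match variant ", v$id, call. = FALSE)
  }
  net
}

#' Write / read a trajectory as long CSV with a JSON provenance sidecar
#'
#' @param trajectory An `mtor_trajectory`.
#' @param path CSV path; provenance goes to `<path>.json`.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(tidy(trajectory), path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(trajectory$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write calibration datasets (condition, observable, time, value,
#' weight)
#'
#' @param datasets A datasets tibble (see [simulate_blot_data()]).
#' @param path CSV path.
#' @return `read_datasets_csv()` returns the tibble.
#' @export
write_datasets_csv <- function(datasets, path) {
  utils::write.csv(
    datasets[, c("condition", "observable", "time_min", "value", "weight")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_datasets_csv
#' @export
read_datasets_csv <- function(path) {
  tab <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("condition", "observable", "time_min", "value")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("dataset CSV missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!"weight" %in% names(tab)) tab$weight <- 1
  tab
}
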