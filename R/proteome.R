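# Absolute-abundance inference from relative proteomics anchored to
# iBAQ-style references, nanomolar conversion and per-cell-line model
# customization.

# coerce a proteins-x-lines tibble (first column protein ids) to a matrix
as_abundance_matrix <- function(tab) {
  stopifnot(is.data.frame(tab), ncol(tab) >= 2)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}

#' Drop cell lines with missing required proteins
#'
#' Mirrors the cohort filtering step: a cell line with no detectable
#' expression of any required model protein cannot be customized and is
#' dropped (never imputed).
#'
#' @param relative Relative-abundance table: tibble/data frame whose first
#'   column is the protein identifier and remaining columns are cell lines.
#' @param required_proteins Proteins every retained line must quantify.
#' @return List with `table` (filtered tibble) and `drop_report` (tibble
#'   `cell_line`, `missing_proteins`).
#' @export
validate_and_filter <- function(relative, required_proteins) {
  stopifnot(length(required_proteins) >= 1)
  m <- as_abundance_matrix(relative)
  miss_prot <- setdiff(required_proteins, rownames(m))
  if (length(miss_prot)) {
    stop("required proteins absent from table: ",
         paste(miss_prot, collapse = ", "), call. = FALSE)
  }
  sub <- m[required_proteins, , drop = FALSE]
  bad <- apply(sub, 2, function(x) any(!is.finite(x) | x <= 0))
  report <- purrr::map_dfr(colnames(sub)[bad], function(cl) {
    tibble::tibble(
      cell_line = cl,
      missing_proteins = paste(
        required_proteins[!is.finite(sub[, cl]) | sub[, cl] <= 0],
        collapse = ";"))
  })
  if (all(bad)) {
    warning("all cell lines dropped: every line misses a required protein",
            call. = FALSE)
  }
  keep <- c(names(relative)[1], colnames(m)[!bad])
  list(table = relative[, keep, drop = FALSE], drop_report = report)
}

#' Infer absolute protein abundance for one cell line
#'
#' For each protein i and reference line j, the absolute abundance of the
#' target line x is estimated as `IBAQ(i, j) * REL(i, x) / REL(i, j)` and
#' averaged over the available references; the standard error across
#' references is reported.
#'
#' @param relative Relative-abundance table (first column protein ids).
#' @param reference Absolute-reference table (same layout; its cell lines
#'   must also appear in `relative`).
#' @param target_line Cell-line column to infer.
#' @return Tibble `protein`, `abundance`, `se`, `n_refs`. Proteins absent
#'   from the reference table are flagged with a warning and excluded.
#' @export
infer_absolute <- function(relative, reference, target_line) {
  rel <- as_abundance_matrix(relative)
  ref <- as_abundance_matrix(reference)
  if (!target_line %in% colnames(rel)) {
    stop("target line '", target_line, "' not in the relative table",
         call. = FALSE)
  }
  refs <- intersect(colnames(ref), colnames(rel))
  if (!length(refs)) {
    stop("no reference line is shared with the relative table",
         call. = FALSE)
  }
  dropped <- setdiff(rownames(rel), rownames(ref))
  if (length(dropped)) {
    warning("proteins absent from the reference table excluded: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  prot <- intersect(rownames(rel), rownames(ref))
  purrr::map_dfr(prot, function(i) {
    est <- vapply(refs, function(j) {
      ref[i, j] * rel[i, target_line] / rel[i, j]
    }, numeric(1))
    est <- est[is.finite(est)]
    tibble::tibble(
      protein = i,
      abundance = mean(est),
      se = if (length(est) > 1) stats::sd(est) / sqrt(length(est)) else 0,
      n_refs = length(est))
  })
}

#' Convert absolute abundances to nanomolar concentrations
#'
#' Rescales one cell line's abundances so the mean over the model proteins
#' equals 100 nM (anchoring each line's total model-protein concentration
#' to the reference MEF-like level): `conc(i) = abundance(i) * 100 /
#' mean(abundance over model proteins)`.
#'
#' @param abundances Named numeric vector (or `infer_absolute()` tibble)
#'   of absolute abundances for one cell line.
#' @param model_proteins Proteins defining the normalizing mean (default:
#'   all supplied).
#' @return Named numeric vector of concentrations in nM over
#'   `model_proteins`.
#' @export
to_nanomolar <- function(abundances, model_proteins = NULL) {
  if (is.data.frame(abundances)) {
    abundances <- stats::setNames(abundances$abundance, abundances$protein)
  }
  if (is.null(model_proteins)) model_proteins <- names(abundances)
  miss <- setdiff(model_proteins, names(abundances))
  if (length(miss)) stop("abundances missing for: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  x <- abundances[model_proteins]
  if (any(!is.finite(x) | x <= 0)) {
    stop("abundances must be positive for all model proteins",
         call. = FALSE)
  }
  x * 100 / mean(x)
}

#' Customize model totals for a cell line
#'
#' Replaces each mapped conservation-group total with the line's inferred
#' nanomolar concentration; unmapped groups keep their base values.
#'
#' @param base_totals Named base totals (see [default_totals()]).
#' @param concentrations Named nM concentrations (e.g. [to_nanomolar()]).
#' @param mapping Named character vector `protein -> conservation group`;
#'   defaults to identity over the shared names.
#' @return Named totals vector with attribute `customized` listing the
#'   groups replaced.
#' @export
customize_model <- function(base_totals, concentrations, mapping = NULL) {
  if (is.null(mapping)) {
    shared <- intersect(names(concentrations), names(base_totals))
    mapping <- stats::setNames(shared, shared)
  }
  bad <- setdiff(unname(mapping), names(base_totals))
  if (length(bad)) stop("mapping references unknown groups: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  out <- base_totals
  for (prot in names(mapping)) {
    out[[mapping[[prot]]]] <- unname(concentrations[[prot]])
  }
  attr(out, "customized") <- unname(mapping)
  out
}

#' Cohort-wide dose-response scan
#'
#' Runs one peak-normalized dose-response per customized cell line and
#' attaches a per-line biphasic report. Per-line failures are isolated:
#' the failing line is reported in the `failed` attribute, not fatal.
#'
#' @param cohort_totals Named list of per-line totals vectors
#'   (e.g. from [customize_model()]).
#' @param network An `mtor_network`.
#' @param params Kinetic parameters.
#' @param item Perturbed target (default `"SIN1"`).
#' @param observable Observable name.
#' @param ... Passed to [dose_response()] (e.g. `n_points`).
#' @return A tibble: `cell_line`, `fold`, `value`, `normalized`, `valid`,
#'   plus attribute `reports` (named list of [biphasic_index()] results).
#' @export
cohort_scan <- function(cohort_totals, network, params, item = "SIN1",
                        observable = "pS6K1_obs", ...) {
  stopifnot(length(cohort_totals) >= 1)
  if (is.null(names(cohort_totals))) {
    names(cohort_totals) <- sprintf("line_%02d", seq_along(cohort_totals))
  }
  reports <- list()
  failed <- character()
  rows <- purrr::map_dfr(names(cohort_totals), function(cl) {
    dr <- tryCatch(
      dose_response(network, params, cohort_totals[[cl]], item,
                    observable, ...),
      error = function(e) NULL)
    if (is.null(dr)) {
      failed <<- c(failed, cl)
      return(NULL)
    }
    reports[[cl]] <<- biphasic_index(dr)
    dplyr::mutate(tibble::as_tibble(dr), cell_line = cl, .before = 1)
  })
  attr(rows, "reports") <- reports
  attr(rows, "failed") <- failed
  rows
}
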