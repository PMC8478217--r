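# Model variants and reaction-network construction for the insulin/PI3K/mTOR
# family with the MLST8 (de)ubiquitination switch.

#' Species names of the mTOR switch models
#'
#' All five variants share one 24-species state vector (unused pools stay at
#' zero, e.g. `Raptor_free` in variants 1-2 where the mTORC1 pools are plain
#' raptor pools). `TRAF2` is carried as a state so knockouts can scale it, but
#' it is a constant catalyst: no reaction consumes it.
#'
#' @return Character vector of species names in canonical order.
#' @export
mtor_species <- function() {
  c("INSR", "pINSR",
    "IRS", "pIRS", "iIRS",
    "OTUD7B", "aOTUD7B",
    "MLST8_free", "MLST8ub_free",
    "SIN1_free", "Raptor_free",
    "mTORC2", "amTORC2",
    "mTORC1i", "mTORC1a",
    "AKT", "pAKT_T308", "pAKT_S473", "ppAKT",
    "TSC2a", "pTSC2",
    "S6K1", "pS6K1",
    "TRAF2")
}

#' Describe a model variant
#'
#' Five variants are supported. They differ in two structural hypotheses:
#' whether the deubiquitinase OTUD7B is activated at the receptor (`INSR`) or
#' downstream of the insulin-receptor substrates (`IRS`), and whether
#' ubiquitinated MLST8 is required to assemble mTORC1 (raptor-MLST8ub
#' complexes) or mTORC1 is a plain raptor pool. Variant `"4P"` is variant 4
#' with mTORC2 activated by pIRS instead of the AKT positive feedback.
#'
#' @param id Variant identifier: one of `1`, `2`, `3`, `4`, `"4P"`.
#' @return A list with fields `id`, `otud7b_upstream` (`"INSR"` or `"IRS"`),
#'   `mlst8_required_for_mtorc1` (logical) and `mtorc2_activator`
#'   (`"pAKT_T308"` or `"pIRS"`).
#' @export
#' @examples
#' variant_info(4)
variant_info <- function(id) {
  id <- as.character(id)
  if (!id %in% c("1", "2", "3", "4", "4P")) {
    stop("unknown model variant '", id,
         "'; valid variants are 1, 2, 3, 4, 4P", call. = FALSE)
  }
  list(
    id = id,
    otud7b_upstream = if (id %in% c("1", "3")) "INSR" else "IRS",
    mlst8_required_for_mtorc1 = id %in% c("3", "4", "4P"),
    mtorc2_activator = if (id == "4P") "pIRS" else "pAKT_T308"
  )
}

# internal reaction constructors -------------------------------------------

.rx_mm <- function(name, enzyme, substrate, product, kcat, Km) {
  st <- stats::setNames(c(-1, 1), c(substrate, product))
  list(name = name, law = "mm", enzyme = enzyme, substrate = substrate,
       params = c(kcat = kcat, Km = Km), stoich = st)
}

.rx_fo <- function(name, from, to, k) {
  st <- stats::setNames(c(-1, 1), c(from, to))
  list(name = name, law = "first_order", substrate = from,
       params = c(k = k), stoich = st)
}

.rx_assoc <- function(name, a, b, complex, k) {
  st <- stats::setNames(c(-1, -1, 1), c(a, b, complex))
  list(name = name, law = "mass_action", a = a, b = b,
       params = c(k = k), stoich = st)
}

.rx_dissoc <- function(name, complex, a, b, k) {
  st <- stats::setNames(c(-1, 1, 1), c(complex, a, b))
  list(name = name, law = "first_order", substrate = complex,
       params = c(k = k), stoich = st)
}

.rx_inhib <- function(name, from, to, k, inhibitor, ki) {
  st <- stats::setNames(c(-1, 1), c(from, to))
  list(name = name, law = "inhibited", substrate = from,
       inhibitor = inhibitor, params = c(k = k, ki = ki), stoich = st)
}

#' Build a reaction network for one model variant
#'
#' Assembles the canonical reaction list: insulin-dependent INSR activation
#' with the mTORC1-Grb10 negative feedback, IRS phosphorylation with the
#' S6K1 negative feedback (pIRS -> iIRS, slow recovery), OTUD7B activation by
#' pINSR or pIRS depending on the variant, the TRAF2/OTUD7B (de)ubiquitination
#' cycle on MLST8 (`k_f4`/`k_r4`), MLST8-SIN1 association into mTORC2
#' (`k_f6`), mTORC2 activation (AKT positive feedback, or pIRS in variant 4P)
#' plus a small insulin-independent basal activation, the lumped
#' IRS -> pAKT T308 cascade, mTORC2-catalyzed AKT S473 phosphorylation, TSC2
#' phosphorylation by pAKT T308 (`k_f12a`) and ppAKT (`k_f12b`),
#' TSC2a-inhibited mTORC1 activation (inhibition constant `k_i1`), and
#' mTORC1a-catalyzed S6K1 phosphorylation (`k_f11b`). Variants 3, 4 and 4P
#' additionally contain MLST8ub-raptor association (`k_f5`) so the mTORC1
#' pools are raptor-MLST8ub complexes; in variants 1-2 the mTORC1 pools are
#' raptor pools and ubiquitinated MLST8 acts only as a SIN1-sequestration
#' sink. Protein-protein binding uses mass action; catalysis uses
#' Michaelis-Menten; reversals are first order.
#'
#' @param variant Variant id (see [variant_info()]) or the list it returns.
#' @return An object of class `mtor_network`: list with `variant`, `species`,
#'   `reactions`, stoichiometry matrix `stoich` (species x reactions) and
#'   `conservation` (named list of species groups).
#' @export
#' @examples
#' net <- build_network(4)
#' net
build_network <- function(variant) {
  v <- if (is.list(variant)) variant else variant_info(variant)
  otud7b_enzyme <- if (v$otud7b_upstream == "INSR") "pINSR" else "pIRS"
  mtorc2_enzyme <- if (v$mtorc2_activator == "pIRS") "pIRS" else "pAKT_T308"

  rx <- list(
    .rx_mm("INSR_activation", "insulin", "INSR", "pINSR", "k_f1", "Km_1"),
    .rx_fo("INSR_deactivation", "pINSR", "INSR", "k_r1"),
    .rx_mm("INSR_feedback_mTORC1", "mTORC1a", "pINSR", "INSR", "k_f1b", "Km_1b"),
    .rx_mm("IRS_phosphorylation", "pINSR", "IRS", "pIRS", "k_f2", "Km_2"),
    .rx_fo("IRS_dephosphorylation", "pIRS", "IRS", "k_r2"),
    .rx_mm("IRS_inhibition_S6K1", "pS6K1", "pIRS", "iIRS", "k_f2b", "Km_2b"),
    .rx_fo("IRS_recovery", "iIRS", "IRS", "k_r2b"),
    .rx_mm("OTUD7B_activation", otud7b_enzyme, "OTUD7B", "aOTUD7B",
           "k_f3", "Km_3"),
    .rx_fo("OTUD7B_deactivation", "aOTUD7B", "OTUD7B", "k_r3"),
    .rx_mm("MLST8_ubiquitination", "TRAF2", "MLST8_free", "MLST8ub_free",
           "k_f4", "Km_4"),
    .rx_mm("MLST8_deubiquitination", "aOTUD7B", "MLST8ub_free", "MLST8_free",
           "k_r4", "Km_4b"),
    .rx_assoc("mTORC2_assembly", "MLST8_free", "SIN1_free", "mTORC2", "k_f6"),
    .rx_dissoc("mTORC2_disassembly", "mTORC2", "MLST8_free", "SIN1_free",
               "k_r6"),
    .rx_mm("mTORC2_activation", mtorc2_enzyme, "mTORC2", "amTORC2",
           "k_f7", "Km_7"),
    .rx_fo("mTORC2_basal_activation", "mTORC2", "amTORC2", "k_f7b"),
    .rx_fo("mTORC2_deactivation", "amTORC2", "mTORC2", "k_r7"),
    .rx_mm("AKT_T308_phosphorylation", "pIRS", "AKT", "pAKT_T308",
           "k_f8", "Km_8"),
    .rx_fo("AKT_T308_dephosphorylation", "pAKT_T308", "AKT", "k_r8"),
    .rx_mm("AKT_S473_phosphorylation", "amTORC2", "AKT", "pAKT_S473",
           "k_f9", "Km_9"),
    .rx_fo("AKT_S473_dephosphorylation", "pAKT_S473", "AKT", "k_r9"),
    .rx_mm("ppAKT_from_T308", "amTORC2", "pAKT_T308", "ppAKT",
           "k_f10a", "Km_10a"),
    .rx_mm("ppAKT_from_S473", "pIRS", "pAKT_S473", "ppAKT",
           "k_f10b", "Km_10b"),
    .rx_fo("ppAKT_S473_dephosphorylation", "ppAKT", "pAKT_T308", "k_r10a"),
    .rx_fo("ppAKT_T308_dephosphorylation", "ppAKT", "pAKT_S473", "k_r10b"),
    .rx_inhib("mTORC1_activation", "mTORC1i", "mTORC1a", "k_f11a",
              "TSC2a", "k_i1"),
    .rx_fo("mTORC1_deactivation", "mTORC1a", "mTORC1i", "k_r11"),
    .rx_mm("S6K1_phosphorylation", "mTORC1a", "S6K1", "pS6K1",
           "k_f11b", "Km_11b"),
    .rx_fo("S6K1_dephosphorylation", "pS6K1", "S6K1", "k_r11b"),
    .rx_mm("TSC2_phosphorylation_T308", "pAKT_T308", "TSC2a", "pTSC2",
           "k_f12a", "Km_12a"),
    .rx_mm("TSC2_phosphorylation_ppAKT", "ppAKT", "TSC2a", "pTSC2",
           "k_f12b", "Km_12b"),
    .rx_fo("TSC2_dephosphorylation", "pTSC2", "TSC2a", "k_r12")
  )

  if (v$mlst8_required_for_mtorc1) {
    rx <- c(rx, list(
      .rx_assoc("mTORC1_assembly", "MLST8ub_free", "Raptor_free", "mTORC1i",
                "k_f5"),
      .rx_dissoc("mTORC1_disassembly", "mTORC1i", "MLST8ub_free",
                 "Raptor_free", "k_r5")
    ))
  }

  species <- mtor_species()
  S <- matrix(0, nrow = length(species), ncol = length(rx),
              dimnames = list(species, vapply(rx, `[[`, "", "name")))
  for (j in seq_along(rx)) S[names(rx[[j]]$stoich), j] <- rx[[j]]$stoich

  mlst8_group <- c("MLST8_free", "MLST8ub_free", "mTORC2", "amTORC2")
  if (v$mlst8_required_for_mtorc1) {
    mlst8_group <- c(mlst8_group, "mTORC1i", "mTORC1a")
  }
  conservation <- list(
    INSR   = c("INSR", "pINSR"),
    IRS    = c("IRS", "pIRS", "iIRS"),
    OTUD7B = c("OTUD7B", "aOTUD7B"),
    MLST8  = mlst8_group,
    SIN1   = c("SIN1_free", "mTORC2", "amTORC2"),
    Raptor = c("Raptor_free", "mTORC1i", "mTORC1a"),
    AKT    = c("AKT", "pAKT_T308", "pAKT_S473", "ppAKT"),
    TSC2   = c("TSC2a", "pTSC2"),
    S6K1   = c("S6K1", "pS6K1"),
    TRAF2  = "TRAF2"
  )

  structure(
    list(variant = v, species = species, reactions = rx, stoich = S,
         conservation = conservation),
    class = "mtor_network"
  )
}

#' @export
print.mtor_network <- function(x, ...) {
  v <- x$variant
  cat("<mtor_network> variant ", v$id, "\n",
      "  OTUD7B activated by: ", v$otud7b_upstream, "\n",
      "  MLST8 required for mTORC1: ", v$mlst8_required_for_mtorc1, "\n",
      "  mTORC2 activator: ", v$mtorc2_activator, "\n",
      "  ", length(x$species), " species, ", length(x$reactions),
      " reactions, ", length(x$conservation), " conserved moieties\n",
      sep = "")
  invisible(x)
}

#' Tidy a reaction network into a tibble of reactions
#'
#' @param x An `mtor_network`.
#' @param ... Unused.
#' @return A tibble with one row per reaction: `reaction`, `law`, `substrate`,
#'   `enzyme` (NA for non-catalytic laws) and the parameter names it uses.
#' @export
tidy.mtor_network <- function(x, ...) {
  purrr::map_dfr(x$reactions, function(r) {
    tibble::tibble(
      reaction = r$name,
      law = r$law,
      substrate = if (r$law == "mass_action") paste(r$a, r$b, sep = "+")
                  else r$substrate,
      enzyme = if (r$law == "mm") r$enzyme
               else if (r$law == "inhibited") r$inhibitor
               else NA_character_,
      parameters = paste(unname(r$params), collapse = ",")
    )
  })
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
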