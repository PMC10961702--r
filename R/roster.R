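# Assay roster: the 14 AR in vitro assays, their biological roles, and the
# agonist / antagonist pathway decomposition. The agonist pathway spans
# A1-A11, the antagonist pathway A1-A6 plus A12-A14; the two overlap exactly
# on the upstream assays A1-A6 (receptor binding, coregulator recruitment,
# nuclear translocation).

N_ASSAYS <- 14L

#' Assay identifiers A1..A14
#'
#' @return Character vector `c("A1", ..., "A14")`.
#' @export
assay_ids <- function() paste0("A", seq_len(N_ASSAYS))

#' Default 14-assay androgen-receptor roster
#'
#' Returns the roster of the 14 ToxCast/Tox21 AR assays with their endpoint
#' names, biological roles, and membership in the agonist (A1-A11) and
#' antagonist (A1-A6, A12-A14) pathways.
#'
#' @return A data frame with columns `assay`, `endpoint_name`, `role`,
#'   `in_agonist_pathway`, `in_antagonist_pathway`.
#' @export
#' @examples
#' ar_roster()
ar_roster <- function() {
  roster <- data.frame(
    assay = assay_ids(),
    endpoint_name = c(
      "NVS_NR_hAR",
      "NVS_NR_cAR",
      "NVS_NR_rAR",
      "OT_AR_ARSRC1_0480",
      "OT_AR_ARSRC1_0960",
      "UPITT_HCI_U2OS_AR_TIF2_Nucleoli_Agonist",
      "ATG_AR_TRANS_up",
      "OT_AR_ARELUC_AG_1440",
      "TOX21_AR_BLA_Agonist_ratio",
      "TOX21_AR_LUC_MDAKB2_Agonist",
      "ACEA_AR_agonist_80h",
      "UPITT_HCI_U2OS_AR_TIF2_Nucleoli_Antagonist",
      "TOX21_AR_BLA_Antagonist_ratio",
      "TOX21_AR_LUC_MDAKB2_Antagonist_0.5nM_R1881"
    ),
    role = c(
      rep("receptor-binding", 3L),
      rep("coregulator-recruitment", 2L),
      "nuclear-translocation-agonist",
      "RNA-reporter",
      rep("protein-reporter-agonist", 3L),
      "proliferation",
      "nuclear-translocation-antagonist",
      rep("protein-reporter-antagonist", 2L)
    ),
    in_agonist_pathway = c(rep(1L, 11L), rep(0L, 3L)),
    in_antagonist_pathway = c(rep(1L, 6L), rep(0L, 5L), rep(1L, 3L)),
    stringsAsFactors = FALSE
  )
  validate_roster(roster)
  roster
}

#' Validate an assay roster
#'
#' Checks the structural invariants of a roster: exactly 14 assays, the two
#' pathways overlap exactly on the shared upstream assays, and the
#' mode-specific assays belong to one pathway only.
#'
#' @param roster A roster data frame as returned by [ar_roster()].
#' @return The roster, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_roster <- function(roster) {
  required <- c("assay", "endpoint_name", "role",
                "in_agonist_pathway", "in_antagonist_pathway")
  missing <- setdiff(required, names(roster))
  if (length(missing) > 0L) {
    stop("roster is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(roster) != N_ASSAYS) {
    stop("roster must contain exactly ", N_ASSAYS, " assays, got ",
         nrow(roster))
  }
  if (!identical(roster$assay, assay_ids())) {
    stop("roster assays must be A1..A14 in order")
  }
  ag <- roster$assay[roster$in_agonist_pathway == 1L]
  ant <- roster$assay[roster$in_antagonist_pathway == 1L]
  if (length(intersect(ag, ant)) == 0L) {
    stop("agonist and antagonist pathways must share the upstream assays")
  }
  orphan <- roster$assay[roster$in_agonist_pathway == 0L &
                           roster$in_antagonist_pathway == 0L]
  if (length(orphan) > 0L) {
    stop("assay(s) belong to neither pathway: ", paste(orphan, collapse = ", "))
  }
  invisible(roster)
}

#' Assays shared by the agonist and antagonist pathways
#'
#' @param roster A roster data frame.
#' @return Character vector of shared assay ids (A1-A6 for the default roster).
#' @export
shared_assays <- function(roster = ar_roster()) {
  roster$assay[roster$in_agonist_pathway == 1L &
                 roster$in_antagonist_pathway == 1L]
}
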