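#' Treatment-intensity protocols
#'
#' The four expert-defined therapy-intensity groups used throughout the
#' pipeline, in canonical order. The order is used only for deterministic
#' tie-breaking (less burdensome protocols first); it carries no ordinal
#' meaning in the models.
#'
#' @return Character vector of the four protocol names.
#' @export
#' @examples
#' aml_protocols()
aml_protocols <- function() {
  c("target", "regular", "low_intensity", "high_intensity")
}

#' Curated clinical feature panel
#'
#' The 11 expert-selected clinical features: five continuous measurements,
#' five categorical descriptors (including the treatment-intensity protocol),
#' and the overall-survival class label.
#'
#' @return Character vector of 11 clinical feature names.
#' @export
aml_clinical_panel <- function() {
  c("diagnosis_age", "bm_blast_pct", "mutation_count", "pb_blast_pct",
    "wbc", "gender", "is_white", "cytogenetic_group", "eln_risk",
    "treatment_intensity", "overall_survival_status")
}

#' Reference gene-expression panel
#'
#' The 22 genes selected by the L1-penalised expression screen on the
#' original AML cohort; used as the default signal panel by the synthetic
#' generator.
#'
#' @return Character vector of 22 gene symbols.
#' @export
aml_expression_panel <- function() {
  c("CCDC144A", "CPNE8", "CYP2E1", "CYTL1", "HAS1", "KIAA0141",
    "KIAA1549", "LAMA2", "LTK", "MICALL2", "MX1", "PPM1H", "PTH2R",
    "PTP4A3", "RAD21", "RGS9BP", "SLC29A2", "TMED4", "TNFSF11", "TNK1",
    "TSKS", "XIST")
}

#' Reference gene-mutation panel
#'
#' The 10 genes retained by the chi-square mutation screen (p < 0.1) on the
#' original AML cohort; used as the default signal panel by the synthetic
#' generator.
#'
#' @return Character vector of 10 gene symbols.
#' @export
aml_mutation_panel <- function() {
  c("SRSF2", "U2AF1", "RIF1", "PRKAA2", "CALR", "CADM2", "PTPN11",
    "PHF6", "CTNNA2", "TP53")
}

# Outcome labels; "deceased" is the positive class for all metrics.
.aml_outcomes <- c("deceased", "living")

.aml_eln_levels <- c("favorable", "intermediate", "adverse")

# Clinical columns that must parse as numbers.
.aml_numeric_clinical <- c("diagnosis_age", "bm_blast_pct", "mutation_count",
                           "pb_blast_pct", "wbc", "is_white")

#' Normalise a category label
#'
#' Lower-snake-case normalisation applied to all categorical values and
#' column headers at load time: lower-case, non-alphanumeric runs collapsed
#' to a single underscore, leading/trailing underscores stripped.
#'
#' @param x character vector.
#' @return normalised character vector; `NA` stays `NA`.
#' @export
#' @examples
#' normalize_label(c("Bone Marrow Aspirate", "De novo", "LIVING"))
normalize_label <- function(x) {
  out <- tolower(trimws(as.character(x)))
  out <- gsub("[^a-z0-9]+", "_", out)
  out <- gsub("^_+|_+$", "", out)
  out[is.na(x)] <- NA_character_
  out
}

# Map assorted survival-status encodings onto the two canonical labels.
.canon_survival <- function(x) {
  y <- normalize_label(x)
  y[grepl("living|alive", y)] <- "living"
  y[grepl("deceased|dead", y)] <- "deceased"
  y
}
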