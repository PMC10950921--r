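#' Construct a multimodal AML cohort
#'
#' Bundles the three modality tables of one cohort — clinical, gene
#' mutation, gene expression — keyed by `patient_id`, together with the
#' modality panels (ordered feature-name lists) and free-form provenance
#' metadata. All three tables are patients-as-rows after construction and
#' share the same `patient_id` order.
#'
#' @param clinical data.frame with a `patient_id` column and clinical
#'   features (see [aml_clinical_panel()] for the canonical schema).
#' @param mutation data.frame: `patient_id` plus one 0/1 column per gene.
#' @param expression data.frame: `patient_id` plus one numeric column per
#'   gene.
#' @param provenance named list of free-text metadata.
#' @return An object of class `aml_cohort` with elements `clinical`,
#'   `mutation`, `expression`, `panels` (list with `clinical`, `mutation`,
#'   `expression` name vectors) and `provenance`.
#' @export
aml_cohort <- function(clinical, mutation, expression, provenance = list()) {
  stopifnot(is.data.frame(clinical), is.data.frame(mutation),
            is.data.frame(expression))
  for (nm in c("clinical", "mutation", "expression")) {
    tab <- get(nm)
    if (!"patient_id" %in% names(tab)) {
      stop("`", nm, "` table lacks a patient_id column")
    }
  }
  ids <- as.character(clinical$patient_id)
  align <- function(tab) {
    tab$patient_id <- as.character(tab$patient_id)
    extra <- setdiff(tab$patient_id, ids)
    if (length(extra)) {
      stop("modality table contains patient ids absent from the clinical ",
           "table: ", paste(utils::head(extra, 5), collapse = ", "))
    }
    missing_ids <- setdiff(ids, tab$patient_id)
    if (length(missing_ids)) {
      pad <- tab[rep(NA_integer_, length(missing_ids)), , drop = FALSE]
      pad$patient_id <- missing_ids
      tab <- rbind(tab, pad)
    }
    tab[match(ids, tab$patient_id), , drop = FALSE]
  }
  mutation <- align(mutation)
  expression <- align(expression)
  rownames(clinical) <- rownames(mutation) <- rownames(expression) <- NULL
  structure(
    list(
      clinical = clinical,
      mutation = mutation,
      expression = expression,
      panels = list(
        clinical = setdiff(names(clinical), "patient_id"),
        mutation = setdiff(names(mutation), "patient_id"),
        expression = setdiff(names(expression), "patient_id")
      ),
      provenance = provenance
    ),
    class = "aml_cohort"
  )
}

#' @export
print.aml_cohort <- function(x, ...) {
  cat("AML cohort:", n_patients(x), "patients\n")
  cat("  clinical features :", length(x$panels$clinical), "\n")
  cat("  mutation genes    :", length(x$panels$mutation), "\n")
  cat("  expression genes  :", length(x$panels$expression), "\n")
  if (length(x$provenance$notes)) {
    cat("  notes:", paste(x$provenance$notes, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort an [aml_cohort()].
#' @return integer count.
#' @export
n_patients <- function(cohort) nrow(cohort$clinical)

#' Subset a cohort by patient
#'
#' @param cohort an [aml_cohort()].
#' @param i logical, integer, or character (patient id) index.
#' @return the subsetted `aml_cohort`.
#' @export
subset_cohort <- function(cohort, i) {
  if (is.character(i)) i <- match(i, cohort$clinical$patient_id)
  out <- cohort
  out$clinical <- cohort$clinical[i, , drop = FALSE]
  out$mutation <- cohort$mutation[i, , drop = FALSE]
  out$expression <- cohort$expression[i, , drop = FALSE]
  rownames(out$clinical) <- rownames(out$mutation) <-
    rownames(out$expression) <- NULL
  out
}

# -- reading ---------------------------------------------------------------

.default_missing_markers <- c("", "na", "n/a")

.read_delim_chr <- function(path, delimiter, normalize_headers = TRUE) {
  tab <- utils::read.delim(path, sep = delimiter, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, stringsAsFactors = FALSE,
                           comment.char = "")
  hdr <- if (normalize_headers) normalize_label(names(tab)) else names(tab)
  if (anyDuplicated(hdr)) {
    stop("duplicate header names in ", basename(path), ": ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  }
  names(tab) <- hdr
  tab
}

.blank_missing <- function(tab, markers) {
  for (j in seq_along(tab)) {
    v <- tab[[j]]
    v[tolower(trimws(v)) %in% tolower(markers)] <- NA_character_
    tab[[j]] <- v
  }
  tab
}

.parse_numeric_col <- function(v, col, file) {
  out <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & is.na(out))
  if (length(bad)) {
    stop("non-numeric value ", dQuote(v[bad[1]]), " in column ",
         dQuote(col), ", row ", bad[1], " of ", basename(file))
  }
  out
}

.find_id_col <- function(tab, file) {
  hit <- which(normalize_label(names(tab)) %in%
                 c("patient_id", "patient_identifier", "id"))
  if (length(hit)) hit[1] else 1L
}

# Gene tables keep their column symbols verbatim (gene symbols are
# case-sensitive identifiers); only the patient-id header is canonicalised.
.read_gene_table <- function(path, delimiter, markers, orientation) {
  tab <- .read_delim_chr(path, delimiter, normalize_headers = FALSE)
  tab <- .blank_missing(tab, markers)
  if (orientation == "genes_in_rows") {
    genes <- tab[[1]]
    vals <- t(as.matrix(tab[, -1, drop = FALSE]))
    out <- data.frame(patient_id = rownames(vals), stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(vals, stringsAsFactors = FALSE))
    names(out) <- c("patient_id", genes)
    rownames(out) <- NULL
    tab <- out
  } else {
    idc <- .find_id_col(tab, path)
    names(tab)[idc] <- "patient_id"
    tab <- tab[, c(idc, setdiff(seq_along(tab), idc)), drop = FALSE]
  }
  for (g in setdiff(names(tab), "patient_id")) {
    tab[[g]] <- .parse_numeric_col(tab[[g]], g, path)
  }
  tab
}

#' Read a multimodal cohort from three delimited tables
#'
#' Reads the clinical, mutation and expression tables, normalises headers
#' and category labels to lower snake case, maps the configured missing
#' markers to `NA`, and joins the modalities on `patient_id`. Patients
#' present in the clinical table but absent from a genetic table are kept
#' with all-`NA` genetic values and recorded in
#' `provenance$unmatched`; genetic-only patients are an error (the clinical
#' table is the patient registry).
#'
#' @param clinical_path,mutation_path,expression_path file paths to
#'   delimited text tables with a header row and a patient-id column.
#' @param delimiter field delimiter, tab by default.
#' @param missing_markers values (case-insensitive) read as missing.
#' @param orientation `"patients_in_rows"` (default) or `"genes_in_rows"`
#'   for the two genetic tables (first column = gene symbol, one column per
#'   patient).
#' @return an [aml_cohort()].
#' @export
read_cohort <- function(clinical_path, mutation_path, expression_path,
                        delimiter = "\t",
                        missing_markers = .default_missing_markers,
                        orientation = c("patients_in_rows", "genes_in_rows")) {
  orientation <- match.arg(orientation)

  clin <- .read_delim_chr(clinical_path, delimiter)
  clin <- .blank_missing(clin, missing_markers)
  idc <- .find_id_col(clin, clinical_path)
  names(clin)[idc] <- "patient_id"
  clin <- clin[, c(idc, setdiff(seq_along(clin), idc)), drop = FALSE]

  original_labels <- list()
  for (col in setdiff(names(clin), "patient_id")) {
    if (col %in% .aml_numeric_clinical) {
      clin[[col]] <- .parse_numeric_col(clin[[col]], col, clinical_path)
    } else {
      original_labels[[col]] <- sort(unique(stats::na.omit(clin[[col]])))
      clin[[col]] <- if (col == "overall_survival_status") {
        .canon_survival(clin[[col]])
      } else {
        normalize_label(clin[[col]])
      }
    }
  }

  mut <- .read_gene_table(mutation_path, delimiter, missing_markers,
                          orientation)
  expr <- .read_gene_table(expression_path, delimiter, missing_markers,
                           orientation)

  ids <- as.character(clin$patient_id)
  unmatched <- list(
    mutation = setdiff(ids, mut$patient_id),
    expression = setdiff(ids, expr$patient_id)
  )
  genetic_only <- setdiff(union(mut$patient_id, expr$patient_id), ids)
  if (length(genetic_only)) {
    clin_pad <- clin[rep(NA_integer_, length(genetic_only)), , drop = FALSE]
    clin_pad$patient_id <- genetic_only
    clin <- rbind(clin, clin_pad)
    unmatched$clinical <- genetic_only
  }

  aml_cohort(clin, mut, expr,
             provenance = list(
               source = c(clinical = clinical_path, mutation = mutation_path,
                          expression = expression_path),
               original_labels = original_labels,
               unmatched = unmatched
             ))
}

# -- writing ---------------------------------------------------------------

.fmt_table <- function(tab) {
  for (j in seq_along(tab)) {
    if (is.numeric(tab[[j]])) {
      v <- sprintf("%.17g", tab[[j]])
      v[is.na(tab[[j]])] <- NA_character_
      tab[[j]] <- v
    }
  }
  tab
}

#' Write a cohort to three delimited tables
#'
#' Writes `clinical.tsv`, `mutation.tsv` and `expression.tsv` under
#' `out_dir`. Numeric values are written with 17 significant digits so that
#' [read_cohort()] after `write_cohort()` reproduces the cohort
#' field-for-field (round-trip contract); missing values are written as
#' `NA`.
#'
#' @param cohort an [aml_cohort()].
#' @param out_dir output directory (created if absent).
#' @param delimiter field delimiter, tab by default.
#' @return named character vector of the three written paths.
#' @export
write_cohort <- function(cohort, out_dir, delimiter = "\t") {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir)
  }
  paths <- c(clinical = file.path(out_dir, "clinical.tsv"),
             mutation = file.path(out_dir, "mutation.tsv"),
             expression = file.path(out_dir, "expression.tsv"))
  for (nm in names(paths)) {
    utils::write.table(.fmt_table(cohort[[nm]]), paths[[nm]],
                       sep = delimiter, quote = FALSE, na = "NA",
                       row.names = FALSE)
  }
  paths
}

# -- validation ------------------------------------------------------------

.violation <- function(patient_id, field, rule, message) {
  data.frame(patient_id = as.character(patient_id), field = field,
             rule = rule, message = message, stringsAsFactors = FALSE)
}

#' Validate cohort invariants
#'
#' Checks the structural invariants of a cohort and reports one descriptor
#' per violation: duplicate patient ids, blast percentages outside
#' \[0, 100\], unknown ELN-risk / treatment-intensity / gender categories,
#' non-binary `is_white`, and non-binary mutation flags. Missing values are
#' not violations (they are the imputation stage's job).
#'
#' @param cohort an [aml_cohort()].
#' @return data.frame with columns `patient_id`, `field`, `rule`,
#'   `message`; zero rows iff the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  out <- list()
  clin <- cohort$clinical
  ids <- clin$patient_id

  dup <- unique(ids[duplicated(ids)])
  for (d in dup) {
    out[[length(out) + 1L]] <-
      .violation(d, "patient_id", "duplicate_id",
                 sprintf("patient id %s occurs %d times", d, sum(ids == d)))
  }

  check_range <- function(field) {
    v <- clin[[field]]
    bad <- which(!is.na(v) & (v < 0 | v > 100))
    lapply(bad, function(i) {
      .violation(ids[i], field, "out_of_range",
                 sprintf("%s = %g outside [0, 100]", field, v[i]))
    })
  }
  check_levels <- function(field, levels) {
    v <- clin[[field]]
    bad <- which(!is.na(v) & !(v %in% levels))
    lapply(bad, function(i) {
      .violation(ids[i], field, "unknown_category",
                 sprintf("%s = %s not in {%s}", field, v[i],
                         paste(levels, collapse = ", ")))
    })
  }

  for (f in intersect(c("bm_blast_pct", "pb_blast_pct"), names(clin))) {
    out <- c(out, check_range(f))
  }
  if ("eln_risk" %in% names(clin)) {
    out <- c(out, check_levels("eln_risk", .aml_eln_levels))
  }
  if ("treatment_intensity" %in% names(clin)) {
    out <- c(out, check_levels("treatment_intensity", aml_protocols()))
  }
  if ("gender" %in% names(clin)) {
    out <- c(out, check_levels("gender", c("male", "female")))
  }
  if ("overall_survival_status" %in% names(clin)) {
    out <- c(out, check_levels("overall_survival_status", .aml_outcomes))
  }
  if ("is_white" %in% names(clin)) {
    v <- clin$is_white
    bad <- which(!is.na(v) & !(v %in% c(0, 1)))
    out <- c(out, lapply(bad, function(i) {
      .violation(ids[i], "is_white", "non_binary",
                 sprintf("is_white = %g is not 0/1", v[i]))
    }))
  }

  mut <- cohort$mutation
  for (g in cohort$panels$mutation) {
    v <- mut[[g]]
    bad <- which(!is.na(v) & !(v %in% c(0, 1)))
    out <- c(out, lapply(bad, function(i) {
      .violation(mut$patient_id[i], g, "non_binary",
                 sprintf("mutation flag %s = %g is not 0/1", g, v[i]))
    }))
  }

  if (length(out)) do.call(rbind, out) else
    .violation(character(), character(), character(), character())
}
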