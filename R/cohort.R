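#' Cohort table of regional VT estimates
#'
#' Validates a per-subject, per-ROI table of total distribution volume (VT)
#' estimates with disease group, TSPO binding genotype and covariates.
#' Genotype must be HAB or MAB: low-affinity binders (LAB) are rejected
#' because [18F]-FEPPA is not quantifiable in LABs and they are excluded from
#' TSPO PET cohorts by design.
#'
#' @param df data.frame with columns `subject_id`, `disease` (HC/PD),
#'   `genotype` (HAB/MAB), `roi`, `vt` (mL/cm^3) and optionally `pct_cov`,
#'   `injected_amount` (mCi) and clinical covariates (`updrs`, `ledd`,
#'   `duration`).
#' @return The validated data.frame with class `cohort_table`; `disease` and
#'   `genotype` are factors with levels HC/PD and HAB/MAB.
#' @export
cohort_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  required <- c("subject_id", "disease", "genotype", "roi", "vt")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) > 0L) {
    if (any(df$genotype == "LAB")) {
      stop("genotype LAB is not permitted: [18F]-FEPPA is not quantifiable ",
           "in low-affinity binders", call. = FALSE)
    }
    bad_gen <- setdiff(unique(as.character(df$genotype)), c("HAB", "MAB"))
    if (length(bad_gen)) {
      stop("genotype must be HAB or MAB; found: ",
           paste(bad_gen, collapse = ", "), call. = FALSE)
    }
    bad_dis <- setdiff(unique(as.character(df$disease)), c("HC", "PD"))
    if (length(bad_dis)) {
      stop("disease must be HC or PD; found: ",
           paste(bad_dis, collapse = ", "), call. = FALSE)
    }
    key <- paste(df$subject_id, df$roi, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate (subject, roi) rows", call. = FALSE)
    }
    ok <- is.na(df$vt) | df$vt > 0
    if (!all(ok)) stop("vt must be positive where present", call. = FALSE)
  }
  df$disease <- factor(as.character(df$disease), levels = c("HC", "PD"))
  df$genotype <- factor(as.character(df$genotype), levels = c("HAB", "MAB"))
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read a cohort table from a delimited file
#'
#' Comma- or tab-delimited, auto-detected; empty fields are missing values.
#'
#' @param path file path.
#' @return A validated [cohort_table()].
#' @export
read_cohort_table <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = "",
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    # preserve an empty but well-formed table
    for (cc in c("subject_id", "disease", "genotype", "roi")) {
      if (!cc %in% names(df)) df[[cc]] <- character(0)
    }
    if (!"vt" %in% names(df)) df$vt <- numeric(0)
  }
  cohort_table(df)
}

#' Write a cohort table
#' @param table a [cohort_table()] (or compatible data.frame).
#' @param path output path; `.tsv` selects tab separation.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(table, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(table, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
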