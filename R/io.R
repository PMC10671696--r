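# Cohort CSV schema. One row per subject; lipids in mmol/L; regimen encoded
# "drug:mg;drug:mg" (empty = untreated); missing values as empty cells.
cohort_columns <- function() {
  c(
    id = "character", role = "character", age_years = "numeric",
    sex = "character",
    fh_first_degree_pcvd = "logical",
    fh_first_degree_hyperlipidemia = "logical",
    fh_relative_fh_diagnosis = "logical",
    fh_child_high_ldl = "logical",
    ph_premature_cad = "logical",
    ph_premature_cerebral_peripheral = "logical",
    sign_tendon_xanthoma = "logical",
    sign_relative_tendon_xanthoma = "logical",
    sign_arcus_under_45 = "logical",
    sign_xanthelasma = "logical",
    pre_tc = "numeric", pre_ldl = "numeric", pre_hdl = "numeric",
    pre_tg = "numeric", on_ldl = "numeric", peak_ldl = "numeric",
    regimen = "character",
    genetic_confirmed = "logical",
    excluded_alternative_diagnosis = "logical"
  )
}

#' Read a cohort CSV
#'
#' Reads and validates the standard cohort file: one row per subject, lipid
#' concentrations in mmol/L, treatment regimens encoded `"drug:mg;drug:mg"`
#' and missing values as empty cells. The header is validated before any
#' computation; unknown columns produce a warning and are carried through
#' untouched. Range checks reject impossible ages and lipid values that look
#' like mg/dL input (LDL-C or TC above 30 mmol/L) with a conversion hint.
#'
#' @param path Path to the CSV file.
#' @param mgdl If `TRUE`, lipid columns are taken to be mg/dL and converted
#'   to mmol/L (x 0.02586). Off by default; mmol/L is the working unit
#'   everywhere.
#' @return A cohort tibble.
#' @export
read_cohort <- function(path, mgdl = FALSE) {
  if (!file.exists(path)) {
    stop("cohort file not found: ", path, call. = FALSE)
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA")),
    error = function(e) stop("cannot read cohort file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (nrow(df) == 0) {
    stop("cohort file has no subjects: ", path, call. = FALSE)
  }
  schema <- cohort_columns()
  missing <- setdiff(names(schema), names(df))
  if (length(missing) > 0) {
    stop("cohort file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(names(df), names(schema))
  if (length(unknown) > 0) {
    warning("cohort file has unknown column(s), carried through: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (col in names(schema)) {
    df[[col]] <- switch(schema[[col]],
      character = as.character(df[[col]]),
      numeric = as.numeric(df[[col]]),
      logical = as.logical(df[[col]])
    )
  }
  lipid_cols <- c("pre_tc", "pre_ldl", "pre_hdl", "pre_tg", "on_ldl",
                  "peak_ldl")
  if (mgdl) {
    for (col in lipid_cols) df[[col]] <- df[[col]] * 0.02586
  }
  validate_cohort(df)
  tibble::as_tibble(df)
}

validate_cohort <- function(df) {
  if (anyDuplicated(df$id)) {
    stop("duplicate subject ids in cohort", call. = FALSE)
  }
  bad_age <- !is.na(df$age_years) & (df$age_years < 0 | df$age_years > 120)
  if (any(bad_age)) {
    stop("implausible age for subject(s): ",
         paste(df$id[bad_age], collapse = ", "), call. = FALSE)
  }
  for (col in c("pre_tc", "pre_ldl", "pre_hdl", "pre_tg", "on_ldl",
                "peak_ldl")) {
    v <- df[[col]]
    if (any(!is.na(v) & v < 0)) {
      stop("negative values in ", col, call. = FALSE)
    }
  }
  for (col in c("pre_tc", "pre_ldl", "on_ldl", "peak_ldl")) {
    v <- df[[col]]
    high <- !is.na(v) & v > 30
    if (any(high)) {
      stop(col, " above 30 mmol/L for subject(s) ",
           paste(df$id[high], collapse = ", "),
           "; values look like mg/dL - re-read with mgdl = TRUE ",
           "(mg/dL x 0.02586 = mmol/L)", call. = FALSE)
    }
  }
  bad_role <- !df$role %in% c("proband", "cascade_relative")
  if (any(bad_role)) {
    stop("role must be 'proband' or 'cascade_relative'; offending subject(s): ",
         paste(df$id[bad_role], collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: writing then reading a cohort returns an
#' identical tibble.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' The packaged synthetic adult cohort
#'
#' Loads the 31-subject adult cohort shipped with the package. This is a
#' *synthetic reconstruction*, not patient data: subjects were constructed
#' so that the cohort is simultaneously consistent with published
#' diagnostic-performance rows (criterion-by-criterion confusion matrices)
#' and the published group means (pretreatment LDL-C and total cholesterol
#' by genotype and role, peak LDL-C, family pCVD history rates). See the
#' generation script in `data-raw/` and the methods vignette.
#'
#' @return A cohort tibble of 31 adults (26 genotype-positive, 5 negative).
#' @export
fh_adult_cohort <- function() {
  read_cohort(system.file("extdata", "adult_cohort_synthetic.csv",
                          package = "fhdx"))
}

#' Write a report table
#'
#' Writes an evaluation or spectrum table as TSV (tab-separated, `NA` as
#' empty cell), the format used by the analysis drivers under `analysis/`.
#'
#' @param table A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
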