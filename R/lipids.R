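#' Friedewald estimate of LDL-C
#'
#' LDL-C = TC - HDL-C - TG/2.2 (all mmol/L). The estimate is not reported
#' (returned as `NA`) when triglycerides exceed 4.5 mmol/L (strict `>`;
#' TG of exactly 4.5 is still reported) or when the arithmetic yields a
#' negative value, in which case a warning is raised.
#'
#' @param tc Total cholesterol, mmol/L.
#' @param hdl HDL cholesterol, mmol/L.
#' @param tg Triglycerides, mmol/L.
#' @param tg_max Suppression threshold for triglycerides (default 4.5).
#' @return Numeric vector of LDL-C estimates; `NA` where suppressed.
#' @export
#' @examples
#' friedewald_ldl(5, 1, 2.2)   # 3.0
#' friedewald_ldl(5, 1, 4.6)   # NA: TG above 4.5
friedewald_ldl <- function(tc, hdl, tg, tg_max = 4.5) {
  stopifnot(is.numeric(tc), is.numeric(hdl), is.numeric(tg))
  if (any(tc < 0 | hdl < 0 | tg < 0, na.rm = TRUE)) {
    stop("lipid concentrations must be non-negative", call. = FALSE)
  }
  ldl <- tc - hdl - tg / 2.2
  suppressed_tg <- !is.na(tg) & tg > tg_max
  negative <- !suppressed_tg & !is.na(ldl) & ldl < 0
  if (any(negative)) {
    warning("Friedewald estimate negative for ", sum(negative),
            " observation(s); suppressed", call. = FALSE)
  }
  ldl[suppressed_tg | negative] <- NA_real_
  ldl
}

#' Parse a treatment regimen string
#'
#' Regimens are encoded `"drug:mg;drug:mg"` (e.g. `"rosuvastatin:20;ezetimibe:10"`).
#' An empty string or `NA` means untreated. Drug names are case-insensitive.
#'
#' @param regimen A single regimen string.
#' @return A tibble with columns `drug` and `dose` (mg/day); zero rows when
#'   untreated.
#' @export
parse_regimen <- function(regimen) {
  if (length(regimen) != 1) {
    stop("parse_regimen() takes a single regimen string", call. = FALSE)
  }
  if (is.na(regimen) || !nzchar(trimws(regimen))) {
    return(tibble::tibble(drug = character(), dose = numeric()))
  }
  parts <- strsplit(trimws(regimen), ";", fixed = TRUE)[[1]]
  parts <- parts[nzchar(trimws(parts))]
  parsed <- lapply(parts, function(p) {
    kv <- strsplit(trimws(p), ":", fixed = TRUE)[[1]]
    if (length(kv) != 2 || is.na(suppressdose <- suppressWarnings(as.numeric(kv[2])))) {
      stop("cannot parse regimen component '", p,
           "'; expected 'drug:mg'", call. = FALSE)
    }
    tibble::tibble(drug = tolower(trimws(kv[1])), dose = suppressdose)
  })
  out <- dplyr::bind_rows(parsed)
  if (any(out$dose <= 0)) {
    stop("regimen doses must be positive", call. = FALSE)
  }
  statins <- setdiff(out$drug, "ezetimibe")
  if (length(statins) > 1) {
    stop("regimen has more than one statin: ", paste(statins, collapse = ", "),
         call. = FALSE)
  }
  if (sum(out$drug == "ezetimibe") > 1) {
    stop("regimen lists ezetimibe more than once", call. = FALSE)
  }
  out
}

#' Treatment intensity of a lipid-lowering regimen
#'
#' Translates a regimen into the dimensionless treatment-intensity multiplier:
#' the factor by which on-treatment LDL-C is scaled to estimate the untreated
#' level. Factors come from the configured dose-specific table
#' (`correction_factors`), with statin and ezetimibe factors combined
#' multiplicatively by default. The untreated regimen has intensity exactly
#' 1.0 (identity); `untreated_as_zero = TRUE` switches to coding untreated
#' subjects as 0 instead, for compatibility with analyses that use that
#' convention.
#'
#' @param regimen A regimen string (`"drug:mg;drug:mg"`), or a data frame as
#'   returned by [parse_regimen()].
#' @param config An `fh_config`, a path to one, or `NULL` for the default.
#' @param untreated_as_zero If `TRUE`, code an empty regimen as intensity 0.
#' @return A list of class `fh_intensity` with elements `intensity` and
#'   `implied_fractional_reduction` (= 1 - 1/intensity).
#' @export
#' @examples
#' treatment_intensity("simvastatin:40")$intensity          # within 1.7-1.9
#' treatment_intensity("")$intensity                        # 1.0, untreated
treatment_intensity <- function(regimen, config = NULL, untreated_as_zero = FALSE) {
  cfg <- as_fh_config(config)
  components <- if (is.data.frame(regimen)) regimen else parse_regimen(regimen)
  table <- cfg$correction_factors$drugs
  if (nrow(components) == 0) {
    intensity <- if (untreated_as_zero) 0 else cfg$correction_factors$untreated_intensity
    reduction <- if (intensity >= 1) 1 - 1 / intensity else NA_real_
    return(structure(list(intensity = intensity,
                          implied_fractional_reduction = reduction),
                     class = "fh_intensity"))
  }
  factors <- vapply(seq_len(nrow(components)), function(i) {
    drug <- components$drug[i]
    dose <- components$dose[i]
    entry <- table[[drug]]
    if (is.null(entry)) {
      stop("no correction factor for drug '", drug, "'", call. = FALSE)
    }
    f <- entry[[as.character(dose)]]
    if (is.null(f)) {
      stop("no correction factor for ", drug, " at ", dose,
           " mg; doses in table: ", paste(names(entry), collapse = ", "),
           call. = FALSE)
    }
    as.numeric(f)
  }, numeric(1))
  rule <- cfg$correction_factors$combination_rule %||% "multiplicative"
  intensity <- switch(rule,
    multiplicative = prod(factors),
    stop("unknown combination_rule: ", rule, call. = FALSE)
  )
  structure(list(intensity = intensity,
                 implied_fractional_reduction = 1 - 1 / intensity),
            class = "fh_intensity")
}

#' @export
print.fh_intensity <- function(x, ...) {
  cat(sprintf("Treatment intensity: %.3f (implied LDL-C reduction %.1f%%)\n",
              x$intensity, 100 * x$implied_fractional_reduction))
  invisible(x)
}

#' Estimate untreated LDL-C from an on-treatment value
#'
#' Multiplies the on-treatment LDL-C by the regimen's treatment intensity.
#' Applying the implied fractional reduction to the estimate recovers the
#' on-treatment input exactly (algebraic inverse).
#'
#' @param on_treatment_ldl On-treatment LDL-C, mmol/L (> 0).
#' @inheritParams treatment_intensity
#' @return Estimated untreated LDL-C, mmol/L.
#' @export
#' @examples
#' estimate_untreated_ldl(3.0, "rosuvastatin:10")  # 3.0 * 2.0 = 6.0
#' estimate_untreated_ldl(5.0, "")                 # untreated: 5.0
estimate_untreated_ldl <- function(on_treatment_ldl, regimen, config = NULL) {
  stopifnot(is.numeric(on_treatment_ldl), length(on_treatment_ldl) == 1)
  if (is.na(on_treatment_ldl) || on_treatment_ldl <= 0) {
    stop("on_treatment_ldl must be a positive value", call. = FALSE)
  }
  on_treatment_ldl * treatment_intensity(regimen, config)$intensity
}

#' Observed fractional LDL-C reduction on treatment
#'
#' (pretreatment - on-treatment) / pretreatment. A negative reduction (LDL-C
#' rose on treatment) is reported as 0 with a warning.
#'
#' @param pretreatment_ldl Pretreatment LDL-C, mmol/L.
#' @param on_treatment_ldl On-treatment LDL-C, mmol/L.
#' @return Fractional reduction in `[0, 1]` (vectorised).
#' @export
#' @examples
#' observed_reduction(8.0, 4.0)   # 0.5
observed_reduction <- function(pretreatment_ldl, on_treatment_ldl) {
  stopifnot(is.numeric(pretreatment_ldl), is.numeric(on_treatment_ldl))
  if (any(pretreatment_ldl <= 0, na.rm = TRUE)) {
    stop("pretreatment_ldl must be positive", call. = FALSE)
  }
  r <- (pretreatment_ldl - on_treatment_ldl) / pretreatment_ldl
  neg <- !is.na(r) & r < 0
  if (any(neg)) {
    warning(sum(neg), " subject(s) had on-treatment LDL-C above pretreatment; ",
            "reduction reported as 0", call. = FALSE)
    r[neg] <- 0
  }
  r
}

#' Treatment-intensity diagnostic rule
#'
#' Calls a subject positive when treatment intensity is at or above the
#' threshold (default 1.8, inclusive) *and* the observed pretreatment to
#' on-treatment LDL-C reduction falls inside the configured "around 50%"
#' band (default \[0.40, 0.70\]). Subjects whose regimen, pretreatment or
#' on-treatment LDL-C is missing cannot be assessed and return `NA`
#' (excluded, not called negative).
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @param config An `fh_config`, a path to one, or `NULL` for the default.
#' @return Logical vector, one call per subject (`NA` = not assessable).
#' @export
intensity_criterion <- function(cohort, config = NULL) {
  cfg <- as_fh_config(config)
  thr <- cfg$intensity_criterion$threshold
  band <- cfg$intensity_criterion$reduction_band
  assessable <- !is.na(cohort$pre_ldl) & !is.na(cohort$on_ldl) &
    !is.na(cohort$regimen) & nzchar(trimws(cohort$regimen))
  out <- rep(NA, nrow(cohort))
  if (any(assessable)) {
    intensity <- regimen_intensities(cohort$regimen[assessable], cfg)
    reduction <- suppressWarnings(
      observed_reduction(cohort$pre_ldl[assessable], cohort$on_ldl[assessable]))
    out[assessable] <- intensity >= thr &
      reduction >= band[1] & reduction <= band[2]
  }
  out
}

#' Combined intensity + LDL-C diagnostic rule
#'
#' Positive when the treatment-intensity rule ([intensity_criterion()]) is
#' positive *and* pretreatment LDL-C is at or above the configured cutoff
#' (default 5.5 mmol/L, inclusive). Subjects not assessable by the intensity
#' rule return `NA`.
#'
#' @inheritParams intensity_criterion
#' @return Logical vector, one call per subject (`NA` = not assessable).
#' @export
combined_criterion <- function(cohort, config = NULL) {
  cfg <- as_fh_config(config)
  cutoff <- cfg$intensity_criterion$ldl_cutoff_combined
  intensity_call <- intensity_criterion(cohort, cfg)
  ifelse(is.na(intensity_call), NA,
         intensity_call & !is.na(cohort$pre_ldl) & cohort$pre_ldl >= cutoff)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
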