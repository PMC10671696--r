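#' Select the LDL-C value used for criterion scoring
#'
#' FH criteria are defined on untreated LDL-C. For each subject this returns,
#' in order of preference: the measured pretreatment LDL-C; otherwise the
#' on-treatment LDL-C corrected to an untreated estimate via the regimen's
#' treatment intensity ([estimate_untreated_ldl()]). Under `policy = "peak"`
#' the highest LDL-C ever recorded (`peak_ldl`) is used where available,
#' falling back to the standard order. Provenance is recorded for every
#' value.
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @param config An `fh_config`, a path to one, or `NULL` for the default.
#' @param policy `"pretreatment_first"` (default) or `"peak"`; `NULL` uses
#'   the config's `ldl_selection$policy`.
#' @return A tibble with columns `id`, `ldl` (mmol/L) and `provenance`
#'   (`"measured"`, `"corrected"` or `"peak"`).
#' @export
select_ldl_for_scoring <- function(cohort, config = NULL, policy = NULL) {
  cfg <- as_fh_config(config)
  policy <- policy %||% (cfg$ldl_selection$policy %||% "pretreatment_first")
  if (!policy %in% c("pretreatment_first", "peak")) {
    stop("unknown LDL selection policy: ", policy, call. = FALSE)
  }
  n <- nrow(cohort)
  ldl <- rep(NA_real_, n)
  provenance <- rep(NA_character_, n)

  treated <- !is.na(cohort$regimen) & nzchar(trimws(cohort$regimen))
  use_peak <- policy == "peak" & !is.na(cohort$peak_ldl)
  ldl[use_peak] <- cohort$peak_ldl[use_peak]
  provenance[use_peak] <- "peak"

  use_measured <- is.na(provenance) & !is.na(cohort$pre_ldl)
  ldl[use_measured] <- cohort$pre_ldl[use_measured]
  provenance[use_measured] <- "measured"

  use_corrected <- is.na(provenance) & !is.na(cohort$on_ldl) & treated
  if (any(use_corrected)) {
    intensities <- regimen_intensities(cohort$regimen[use_corrected], cfg)
    ldl[use_corrected] <- cohort$on_ldl[use_corrected] * intensities
    provenance[use_corrected] <- "corrected"
  }
  if (anyNA(provenance)) {
    stop("subject '", cohort$id[which(is.na(provenance))[1]],
         "' has no usable LDL-C source ",
         "(no pretreatment value and no on-treatment value with a regimen)",
         call. = FALSE)
  }
  tibble::tibble(id = cohort$id, ldl = ldl, provenance = provenance)
}

# intensity per regimen string, computed once per distinct regimen
regimen_intensities <- function(regimens, cfg) {
  distinct <- unique(regimens)
  lookup <- vapply(distinct, function(r) {
    treatment_intensity(r, cfg)$intensity
  }, numeric(1))
  unname(lookup[match(regimens, distinct)])
}

is_pediatric <- function(cohort) {
  if (any(is.na(cohort$age_years))) {
    stop("age_years is missing for subject(s): ",
         paste(cohort$id[is.na(cohort$age_years)], collapse = ", "),
         call. = FALSE)
  }
  cohort$age_years < 18
}

col_or_false <- function(cohort, name) {
  if (name %in% names(cohort)) {
    v <- cohort[[name]]
    !is.na(v) & v
  } else {
    rep(FALSE, nrow(cohort))
  }
}

ldl_band_points <- function(ldl, bands) {
  mins <- vapply(bands, function(b) as.numeric(b$min), numeric(1))
  pts <- vapply(bands, function(b) as.numeric(b$points), numeric(1))
  ord <- order(mins, decreasing = TRUE)
  mins <- mins[ord]
  pts <- pts[ord]
  vapply(ldl, function(x) {
    hit <- which(x >= mins)
    if (length(hit) == 0) 0 else pts[hit[1]]
  }, numeric(1))
}

dlcnc_category <- function(score, cat_cfg) {
  dplyr::case_when(
    score > cat_cfg$definite_gt ~ "definite",
    score >= cat_cfg$probable_min ~ "probable",
    score >= cat_cfg$possible_min ~ "possible",
    TRUE ~ "negative"
  )
}

score_dlcnc_impl <- function(cohort, cfg, modified, use_genetic) {
  dl <- cfg$dlcnc
  sel <- select_ldl_for_scoring(cohort, cfg)
  bands <- if (modified) dl$ldl_bands_modified else dl$ldl_bands
  ldl_pts <- ldl_band_points(sel$ldl, bands)

  fam_cfg <- dl$family_history
  fam_base <- pmax(
    col_or_false(cohort, "fh_first_degree_pcvd") * fam_cfg$first_degree_pcvd,
    col_or_false(cohort, "fh_first_degree_hyperlipidemia") *
      fam_cfg$first_degree_hyperlipidemia,
    col_or_false(cohort, "fh_child_high_ldl") * fam_cfg$child_under18_high_ldl
  )
  # optional extra weighting of family pCVD as its own item
  if (isTRUE(dl$family_pcvd_separately)) {
    both <- col_or_false(cohort, "fh_first_degree_pcvd") &
      col_or_false(cohort, "fh_first_degree_hyperlipidemia")
    fam_base <- pmax(fam_base, both * (fam_cfg$first_degree_pcvd +
                                         fam_cfg$first_degree_hyperlipidemia))
  }
  clin_cfg <- dl$clinical_history
  clin <- pmax(
    col_or_false(cohort, "ph_premature_cad") * clin_cfg$premature_cad,
    col_or_false(cohort, "ph_premature_cerebral_peripheral") *
      clin_cfg$premature_cerebral_or_peripheral
  )
  sign_cfg <- dl$physical_signs
  signs <- pmax(
    col_or_false(cohort, "sign_tendon_xanthoma") * sign_cfg$tendon_xanthoma,
    col_or_false(cohort, "sign_arcus_under_45") * sign_cfg$arcus_under_45
  )
  dna <- if (use_genetic) {
    col_or_false(cohort, "genetic_confirmed") * dl$dna_variant
  } else {
    rep(0, nrow(cohort))
  }
  score <- ldl_pts + fam_base + clin + signs + dna
  category <- dlcnc_category(score, dl$categories)
  call <- score >= dl$binary_cutoff

  pediatric <- is_pediatric(cohort)
  suppress <- identical(dl$pediatric_policy, "suppress") & pediatric
  category[suppress] <- NA_character_
  call[suppress] <- NA

  tibble::tibble(
    id = cohort$id,
    criterion = if (modified) "modified_DLCNC" else "DLCNC",
    score = score,
    category = category,
    binary_call = call,
    pediatric_not_validated = pediatric,
    ldl_used = sel$ldl,
    ldl_provenance = sel$provenance
  )
}

#' Dutch Lipid Clinic Network score
#'
#' Scores each subject with the DLCNC point system: LDL-C band points
#' (>=8.5 -> 8, 6.5-8.4 -> 5, 5.0-6.4 -> 3, 4.0-4.9 -> 1), family history
#' (1-2), personal clinical history (1-2), physical signs (tendon xanthomata
#' 6, arcus cornealis under 45 y 4) and a pathogenic DNA variant (8), taking
#' the highest applicable item within each group. Categories: definite
#' (score > 8), probable (6-8), possible (3-5), otherwise negative. The
#' binary call applies the configured positivity cutoff (default score >= 3).
#'
#' The score is not validated in subjects under 18; pediatric results are
#' flagged (`pediatric_not_validated`) and can be suppressed entirely via the
#' config's `dlcnc$pediatric_policy: suppress`.
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @param config An `fh_config`, a path to one, or `NULL` for the default.
#' @param use_genetic Include the DNA-variant item when a confirmed genetic
#'   result is present (default `TRUE`). Set `FALSE` when the score is being
#'   assessed *against* the genetic result.
#' @return A tibble with one row per subject: `id`, `criterion`, `score`,
#'   `category`, `binary_call`, `pediatric_not_validated`, `ldl_used`,
#'   `ldl_provenance`.
#' @export
score_dlcnc <- function(cohort, config = NULL, use_genetic = TRUE) {
  score_dlcnc_impl(cohort, as_fh_config(config), modified = FALSE, use_genetic)
}

#' Chinese-modified Dutch Lipid Clinic Network score
#'
#' Identical to [score_dlcnc()] except that the LDL-C bands use the lower
#' cutoffs proposed for Chinese populations (>=6 -> 8, 5-5.9 -> 5,
#' 3.5-4.9 -> 3, 2.5-3.4 -> 1), giving a score at least as high as the
#' original for every subject (higher sensitivity, lower specificity).
#'
#' @inheritParams score_dlcnc
#' @return As [score_dlcnc()], with `criterion = "modified_DLCNC"`.
#' @export
score_modified_dlcnc <- function(cohort, config = NULL, use_genetic = TRUE) {
  score_dlcnc_impl(cohort, as_fh_config(config), modified = TRUE, use_genetic)
}

#' Simon Broome Register criteria
#'
#' Definite FH: LDL-C above the age cutoff (adult > 4.9, child > 4.0 mmol/L,
#' strict) together with tendon xanthomata (in the subject or, if configured,
#' a relative) or a pathogenic DNA variant. Possible FH: LDL-C above the
#' cutoff together with a first-degree family history of premature
#' cardiovascular disease or hyperlipidemia. The binary call is positive for
#' definite or possible.
#'
#' @inheritParams score_dlcnc
#' @return A tibble with `id`, `criterion`, `category`
#'   (definite/possible/negative), `binary_call`, `ldl_used`,
#'   `ldl_provenance`.
#' @export
classify_simon_broome <- function(cohort, config = NULL, use_genetic = TRUE) {
  cfg <- as_fh_config(config)
  sb <- cfg$simon_broome
  sel <- select_ldl_for_scoring(cohort, cfg)
  pediatric <- is_pediatric(cohort)
  cutoff <- ifelse(pediatric, sb$ldl_cutoff_child, sb$ldl_cutoff_adult)
  above <- sel$ldl > cutoff

  xanthoma <- col_or_false(cohort, "sign_tendon_xanthoma")
  if (isTRUE(sb$relative_xanthoma_counts)) {
    xanthoma <- xanthoma | col_or_false(cohort, "sign_relative_tendon_xanthoma")
  }
  dna <- if (use_genetic) col_or_false(cohort, "genetic_confirmed") else FALSE
  famhist <- col_or_false(cohort, "fh_first_degree_pcvd") |
    col_or_false(cohort, "fh_first_degree_hyperlipidemia")

  category <- dplyr::case_when(
    above & (xanthoma | dna) ~ "definite",
    above & famhist ~ "possible",
    TRUE ~ "negative"
  )
  tibble::tibble(
    id = cohort$id,
    criterion = "SimonBroome",
    category = category,
    binary_call = category != "negative",
    ldl_used = sel$ldl,
    ldl_provenance = sel$provenance
  )
}

#' MEDPED criteria
#'
#' Positive when pretreatment total cholesterol exceeds (strict `>`) the
#' configured threshold for the subject's age band (<20, 20-29, 30-39, >=40)
#' and degree of relatedness to a known FH case. Subjects with a relative
#' diagnosed with FH use the first-degree column; others use the
#' general-population column. The shipped thresholds are the published
#' MEDPED total-cholesterol table (mmol/L).
#'
#' @inheritParams score_dlcnc
#' @return A tibble with `id`, `criterion`, `category` (positive/negative),
#'   `binary_call`, `tc_used`, `tc_threshold`.
#' @export
classify_medped <- function(cohort, config = NULL) {
  cfg <- as_fh_config(config)
  mp <- cfg$medped
  if (any(is.na(cohort$age_years))) {
    stop("MEDPED needs age for subject(s): ",
         paste(cohort$id[is.na(cohort$age_years)], collapse = ", "),
         call. = FALSE)
  }
  band <- findInterval(cohort$age_years, mp$age_breaks) + 1L
  degree <- ifelse(col_or_false(cohort, "fh_relative_fh_diagnosis"),
                   "first_degree", "general")
  threshold <- vapply(seq_len(nrow(cohort)), function(i) {
    as.numeric(mp$thresholds[[degree[i]]][band[i]])
  }, numeric(1))
  tc <- cohort$pre_tc
  call <- !is.na(tc) & tc > threshold
  call[is.na(tc)] <- NA
  tibble::tibble(
    id = cohort$id,
    criterion = "MEDPED",
    category = ifelse(is.na(call), NA_character_,
                      ifelse(call, "positive", "negative")),
    binary_call = call,
    tc_used = tc,
    tc_threshold = threshold
  )
}

#' Japanese FH Management Criteria
#'
#' Heterozygous pattern: positive when LDL-C is above the age cutoff
#' (adult > 4.7, child > 3.6 mmol/L, strict) together with xanthomata or a
#' family history of premature cardiovascular disease or hyperlipidemia.
#' A separate homozygous-pattern flag (`hofh_flag`) is raised when total
#' cholesterol exceeds 15.5 mmol/L.
#'
#' @inheritParams score_dlcnc
#' @return A tibble with `id`, `criterion`, `category`, `binary_call`,
#'   `hofh_flag`, `ldl_used`, `ldl_provenance`.
#' @export
classify_jfhmc <- function(cohort, config = NULL) {
  cfg <- as_fh_config(config)
  jf <- cfg$jfhmc
  sel <- select_ldl_for_scoring(cohort, cfg)
  pediatric <- is_pediatric(cohort)
  cutoff <- ifelse(pediatric, jf$ldl_cutoff_child, jf$ldl_cutoff_adult)
  xanthoma <- col_or_false(cohort, "sign_tendon_xanthoma") |
    col_or_false(cohort, "sign_xanthelasma")
  famhist <- col_or_false(cohort, "fh_first_degree_pcvd") |
    col_or_false(cohort, "fh_first_degree_hyperlipidemia")
  call <- sel$ldl > cutoff & (xanthoma | famhist)
  tc <- cohort$pre_tc
  hofh <- !is.na(tc) & tc > jf$hofh_tc_cutoff
  tibble::tibble(
    id = cohort$id,
    criterion = "JFHMC",
    category = ifelse(call, "positive", "negative"),
    binary_call = call,
    hofh_flag = hofh,
    ldl_used = sel$ldl,
    ldl_provenance = sel$provenance
  )
}

#' Hong Kong expert-panel recommendation
#'
#' Adults: positive when LDL-C > 5 mmol/L, or > 4.5 mmol/L with a family
#' history of FH or premature cardiovascular disease. Children: positive
#' when LDL-C > 3.6 mmol/L with a family history, or LDL-C > 4.9 mmol/L, or
#' physical signs are present. All comparisons strict. A subject with
#' unknown family history is treated the same as one with a documented
#' absence (family history is optional in this instrument).
#'
#' @inheritParams score_dlcnc
#' @return A tibble with `id`, `criterion`, `category`, `binary_call`,
#'   `ldl_used`, `ldl_provenance`.
#' @export
classify_hk_panel <- function(cohort, config = NULL) {
  cfg <- as_fh_config(config)
  hk <- cfg$hk_panel
  sel <- select_ldl_for_scoring(cohort, cfg)
  pediatric <- is_pediatric(cohort)
  famhist <- col_or_false(cohort, "fh_relative_fh_diagnosis") |
    col_or_false(cohort, "fh_first_degree_pcvd")
  signs <- col_or_false(cohort, "sign_tendon_xanthoma") |
    col_or_false(cohort, "sign_arcus_under_45") |
    col_or_false(cohort, "sign_xanthelasma")
  adult_call <- sel$ldl > hk$adult_ldl |
    (sel$ldl > hk$adult_ldl_with_history & famhist)
  child_call <- (sel$ldl > hk$child_ldl_with_history & famhist) |
    sel$ldl > hk$child_ldl | signs
  call <- ifelse(pediatric, child_call, adult_call)
  tibble::tibble(
    id = cohort$id,
    criterion = "HK_panel",
    category = ifelse(call, "positive", "negative"),
    binary_call = call,
    ldl_used = sel$ldl,
    ldl_provenance = sel$provenance
  )
}

#' Evaluate all enabled criteria on a cohort
#'
#' Runs every enabled criterion in a fixed, deterministic order and binds
#' the per-subject results into one long tibble.
#'
#' @inheritParams score_dlcnc
#' @param criteria Character vector naming the criteria to run, any of
#'   `"DLCNC"`, `"modified_DLCNC"`, `"SimonBroome"`, `"MEDPED"`, `"JFHMC"`,
#'   `"HK_panel"` (default: all six, in that order).
#' @return A long tibble of criterion results; columns not produced by a
#'   criterion (e.g. `score`) are `NA` for its rows.
#' @export
evaluate_all_criteria <- function(cohort, config = NULL,
                                  criteria = c("DLCNC", "modified_DLCNC",
                                               "SimonBroome", "MEDPED",
                                               "JFHMC", "HK_panel"),
                                  use_genetic = TRUE) {
  cfg <- as_fh_config(config)
  criteria <- match.arg(criteria, several.ok = TRUE)
  runners <- list(
    DLCNC = function() score_dlcnc(cohort, cfg, use_genetic),
    modified_DLCNC = function() score_modified_dlcnc(cohort, cfg, use_genetic),
    SimonBroome = function() classify_simon_broome(cohort, cfg, use_genetic),
    MEDPED = function() classify_medped(cohort, cfg),
    JFHMC = function() classify_jfhmc(cohort, cfg),
    HK_panel = function() classify_hk_panel(cohort, cfg)
  )
  dplyr::bind_rows(lapply(criteria, function(nm) runners[[nm]]()))
}
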