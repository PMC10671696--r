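#' Configuration for the synthetic cohort generator
#'
#' Returns the generator's default parameters, optionally overridden via
#' named arguments. The defaults emulate the structure of a two-hospital
#' FH genetic-testing study: 19 adult and 12 pediatric probands with
#' genotype prevalences of 16/19 and 6/12, cascade relatives sampled per
#' proband (10/12 positive among adult relatives), pretreatment LDL-C
#' drawn from zero-truncated normals per genotype x role stratum
#' (positive probands mean 8.77, negative probands 6.53, positive cascade
#' relatives 6.60 mmol/L; the positive-adult mixture mean is then 7.94),
#' family history of premature CVD at 69.2% vs 0% by genotype, statin +/-
#' ezetimibe regimens with on-treatment LDL-C derived from the regimen's
#' treatment intensity with multiplicative noise, and peak LDL-C exceeding
#' the pretreatment value for a configurable fraction of subjects.
#'
#' Stratum standard deviations default to 1.5 mmol/L (group means are
#' published without dispersion, so the SD is a modelling assumption; see
#' the methods vignette).
#'
#' @param ... Named overrides of any default listed above; unknown names
#'   are an error.
#' @return A list of class `fh_cohort_config`.
#' @export
#' @examples
#' cohort_config(n_adult_probands = 100, seed = 7)$n_adult_probands
cohort_config <- function(...) {
  cfg <- list(
    n_adult_probands = 19L,
    n_pediatric_probands = 12L,
    cascade_lambda_adult = 12 / 19,
    cascade_lambda_pediatric = 0.25,
    prevalence = list(adult_proband = 16 / 19, pediatric_proband = 0.5,
                      cascade = 10 / 12),
    ldl = list(
      adult_proband_pos = c(mean = 8.77, sd = 1.5),
      adult_proband_neg = c(mean = 6.53, sd = 1.5),
      adult_cascade_pos = c(mean = 6.60, sd = 1.5),
      adult_cascade_neg = c(mean = 4.80, sd = 1.2),
      pediatric_pos = c(mean = 8.20, sd = 1.5),
      pediatric_neg = c(mean = 5.50, sd = 1.5)
    ),
    hdl = c(mean = 1.2, sd = 0.25),
    tg_meanlog = log(1.4),
    tg_sdlog = 0.35,
    family_pcvd_rate = c(positive = 0.692, negative = 0),
    family_hyperlipidemia_rate = c(positive = 0.95, negative = 0.4),
    fh_relative_rate = c(positive = 0.8, negative = 0.3),
    sign_rates = list(
      tendon_xanthoma = c(positive = 0.15, negative = 0.02),
      xanthelasma = c(positive = 0.10, negative = 0.05),
      arcus_under_45 = c(positive = 0.05, negative = 0.02)
    ),
    regimen_distribution = list(
      positive = data.frame(
        regimen = c("rosuvastatin:20;ezetimibe:10", "rosuvastatin:20",
                    "atorvastatin:80", "atorvastatin:40", "rosuvastatin:10",
                    "simvastatin:40"),
        prob = c(0.25, 0.20, 0.15, 0.20, 0.10, 0.10)
      ),
      negative = data.frame(
        regimen = c("simvastatin:10", "simvastatin:20", "pravastatin:40",
                    "atorvastatin:10"),
        prob = c(0.3, 0.3, 0.2, 0.2)
      )
    ),
    treated_fraction = c(proband = 1.0, cascade = 0.8),
    reduction_noise_sd = 0.08,
    pretreatment_available = 0.74,
    peak_available = 0.8,
    fraction_peak_exceeds = 0.5,
    peak_uplift = c(mean = 0.47, sd = 0.3),
    compound_het_fraction = 4 / 22,
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown cohort_config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  validate_cohort_config(cfg)
  structure(cfg, class = c("fh_cohort_config", "list"))
}

validate_cohort_config <- function(cfg) {
  probs <- c(unlist(cfg$prevalence), cfg$family_pcvd_rate,
             cfg$family_hyperlipidemia_rate, cfg$fh_relative_rate,
             unlist(cfg$sign_rates), cfg$treated_fraction,
             cfg$pretreatment_available, cfg$peak_available,
             cfg$fraction_peak_exceeds, cfg$compound_het_fraction)
  if (any(probs < 0 | probs > 1)) {
    stop("cohort_config probabilities must lie in [0, 1]", call. = FALSE)
  }
  sds <- vapply(cfg$ldl, function(x) x[["sd"]], numeric(1))
  if (any(sds <= 0)) {
    stop("cohort_config LDL standard deviations must be positive",
         call. = FALSE)
  }
  invisible(cfg)
}

# normal truncated at zero (lipids cannot be negative)
rtrunc0 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

# analytic mean of the zero-truncated normal (used by recovery tests)
trunc0_mean <- function(mean, sd) {
  a <- -mean / sd
  mean + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
}

# P(X > q) for the zero-truncated normal
trunc0_upper <- function(q, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  (1 - stats::pnorm(q, mean, sd)) / (1 - lo)
}

# Deterministic substream per subject: a stratum base plus a within-stratum
# counter, so enlarging one stratum never perturbs subjects already drawn.
substream_seed <- function(seed, base, counter) {
  as.integer((as.numeric(seed) * 48271 + base + counter) %% 2147483647)
}

#' Generate a synthetic FH study cohort
#'
#' Draws a full cohort (adult and pediatric probands plus cascade-screened
#' first-degree relatives) from the generative model described in
#' [cohort_config()]. Generation is a pure function of `(config, seed)`:
#' the same inputs give a byte-identical cohort, and each subject draws
#' from its own counter-based substream so enlarging a stratum does not
#' change subjects already generated. Cascade relatives inherit nothing
#' mechanistically: their genotype is sampled marginally at the cascade
#' prevalence (no pedigree simulation).
#'
#' @param config An `fh_cohort_config` from [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A cohort tibble in the standard schema (see [read_cohort()]).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 42))
#' table(cohort$role, cohort$genetic_confirmed)
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  cfg <- config
  if (!inherits(cfg, "fh_cohort_config")) {
    stop("config must come from cohort_config()", call. = FALSE)
  }
  seed <- seed %||% cfg$seed

  subjects <- list()
  # adult probands: stratum base 0; pediatric: 1e6; cascade: 2e6 + 200*proband
  for (i in seq_len(cfg$n_adult_probands)) {
    subjects[[length(subjects) + 1]] <-
      simulate_subject(cfg, substream_seed(seed, 0, i),
                       id = sprintf("AP%03d", i), role = "proband",
                       pediatric = FALSE,
                       prevalence = cfg$prevalence$adult_proband)
  }
  for (i in seq_len(cfg$n_pediatric_probands)) {
    subjects[[length(subjects) + 1]] <-
      simulate_subject(cfg, substream_seed(seed, 1e6, i),
                       id = sprintf("PP%03d", i), role = "proband",
                       pediatric = TRUE,
                       prevalence = cfg$prevalence$pediatric_proband)
  }
  # cascade relatives per adult proband (relative counts drawn from their
  # own substream so they are stable too)
  for (i in seq_len(cfg$n_adult_probands)) {
    set.seed(substream_seed(seed, 3e6, i))
    k <- stats::rpois(1, cfg$cascade_lambda_adult)
    for (j in seq_len(k)) {
      subjects[[length(subjects) + 1]] <-
        simulate_subject(cfg, substream_seed(seed, 2e6 + 200 * i, j),
                         id = sprintf("AC%03d_%d", i, j),
                         role = "cascade_relative", pediatric = FALSE,
                         prevalence = cfg$prevalence$cascade)
    }
  }
  for (i in seq_len(cfg$n_pediatric_probands)) {
    set.seed(substream_seed(seed, 3.5e6, i))
    k <- stats::rpois(1, cfg$cascade_lambda_pediatric)
    for (j in seq_len(k)) {
      subjects[[length(subjects) + 1]] <-
        simulate_subject(cfg, substream_seed(seed, 4e6 + 200 * i, j),
                         id = sprintf("PC%03d_%d", i, j),
                         role = "cascade_relative", pediatric = TRUE,
                         prevalence = cfg$prevalence$cascade)
    }
  }
  fields <- names(subjects[[1]])
  cols <- lapply(fields, function(f) {
    unlist(lapply(subjects, `[[`, f), use.names = FALSE)
  })
  names(cols) <- fields
  cohort <- tibble::as_tibble(cols)
  validate_cohort(cohort)
  cohort
}

simulate_subject <- function(cfg, subseed, id, role, pediatric, prevalence) {
  set.seed(subseed)
  positive <- stats::runif(1) < prevalence
  geno <- if (positive) "positive" else "negative"

  stratum <- if (pediatric) {
    if (positive) "pediatric_pos" else "pediatric_neg"
  } else if (role == "proband") {
    if (positive) "adult_proband_pos" else "adult_proband_neg"
  } else {
    if (positive) "adult_cascade_pos" else "adult_cascade_neg"
  }
  par <- cfg$ldl[[stratum]]
  pre_ldl <- rtrunc0(1, par[["mean"]], par[["sd"]])
  hdl <- rtrunc0(1, cfg$hdl[["mean"]], cfg$hdl[["sd"]])
  tg <- stats::rlnorm(1, cfg$tg_meanlog, cfg$tg_sdlog)
  pre_tc <- pre_ldl + hdl + tg / 2.2
  age <- if (pediatric) stats::runif(1, 5, 17) else stats::runif(1, 25, 70)
  sex <- if (stats::runif(1) < 0.5) "F" else "M"

  fam_pcvd <- stats::runif(1) < cfg$family_pcvd_rate[[geno]]
  fam_lip <- stats::runif(1) < cfg$family_hyperlipidemia_rate[[geno]]
  fh_rel <- role == "cascade_relative" ||
    stats::runif(1) < cfg$fh_relative_rate[[geno]]
  xan <- stats::runif(1) < cfg$sign_rates$tendon_xanthoma[[geno]]
  xel <- stats::runif(1) < cfg$sign_rates$xanthelasma[[geno]]
  arc <- stats::runif(1) < cfg$sign_rates$arcus_under_45[[geno]]

  treated_p <- cfg$treated_fraction[[if (role == "proband") "proband" else "cascade"]]
  treated <- stats::runif(1) < treated_p
  regimen <- ""
  on_ldl <- NA_real_
  if (treated) {
    dist <- cfg$regimen_distribution[[geno]]
    pick <- sample.int(nrow(dist), 1, prob = dist$prob)
    regimen <- dist$regimen[pick]
    intensity <- treatment_intensity(regimen)$intensity
    on_ldl <- pre_ldl / intensity *
      exp(stats::rnorm(1, 0, cfg$reduction_noise_sd))
  }
  # pretreatment record sometimes unavailable for treated subjects, in which
  # case scoring falls back to the corrected on-treatment value
  pre_recorded <- !treated || stats::runif(1) < cfg$pretreatment_available

  peak <- NA_real_
  if (stats::runif(1) < cfg$peak_available) {
    peak <- pre_ldl
    if (stats::runif(1) < cfg$fraction_peak_exceeds) {
      peak <- pre_ldl + abs(stats::rnorm(1, cfg$peak_uplift[["mean"]],
                                         cfg$peak_uplift[["sd"]]))
    }
  }

  # a plain list keeps per-subject construction cheap; rows are bound once
  list(
    id = id, role = role, age_years = round(age, 1), sex = sex,
    fh_first_degree_pcvd = fam_pcvd,
    fh_first_degree_hyperlipidemia = fam_lip,
    fh_relative_fh_diagnosis = fh_rel,
    fh_child_high_ldl = FALSE,
    ph_premature_cad = FALSE,
    ph_premature_cerebral_peripheral = FALSE,
    sign_tendon_xanthoma = xan,
    sign_relative_tendon_xanthoma = FALSE,
    sign_arcus_under_45 = arc,
    sign_xanthelasma = xel,
    pre_tc = if (pre_recorded) round(pre_tc, 2) else NA_real_,
    pre_ldl = if (pre_recorded) round(pre_ldl, 2) else NA_real_,
    pre_hdl = if (pre_recorded) round(hdl, 2) else NA_real_,
    pre_tg = if (pre_recorded) round(tg, 2) else NA_real_,
    on_ldl = if (treated) round(on_ldl, 2) else NA_real_,
    peak_ldl = if (!is.na(peak)) round(peak, 2) else NA_real_,
    regimen = regimen,
    genetic_confirmed = positive,
    excluded_alternative_diagnosis = FALSE
  )
}

#' Assign LDLR variants to genotype-positive subjects
#'
#' Links each genotype-positive subject to one variant (or two, with the
#' configured compound-heterozygous fraction) drawn with probability
#' proportional to the per-variant proband counts in the supplied variant
#' table. Links are sampled independently per subject from a seeded stream.
#'
#' @param cohort A cohort tibble.
#' @param variants A variant tibble from [read_variant_table()].
#' @param seed Integer seed.
#' @param compound_het_fraction Probability a positive subject carries two
#'   variants (default 4/22).
#' @return A tibble with one row per subject-variant link: `id`, `cdna`,
#'   `consequence`, `receptor_class`.
#' @export
generate_variant_assignments <- function(cohort, variants, seed = 1L,
                                         compound_het_fraction = 4 / 22) {
  positives <- cohort$id[!is.na(cohort$genetic_confirmed) &
                           cohort$genetic_confirmed]
  weights <- variants$n_probands / sum(variants$n_probands)
  rows <- lapply(seq_along(positives), function(i) {
    set.seed(substream_seed(seed, 5e6, i))
    two <- stats::runif(1) < compound_het_fraction
    k <- if (two) 2L else 1L
    picks <- sample.int(nrow(variants), k, replace = FALSE, prob = weights)
    tibble::tibble(
      id = positives[i],
      cdna = variants$cdna[picks],
      consequence = variants$consequence[picks],
      receptor_class = variants$receptor_class[picks]
    )
  })
  dplyr::bind_rows(rows)
}
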