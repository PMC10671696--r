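#' Confusion matrix from truth and calls
#'
#' Tabulates binary diagnostic calls against a reference truth. Subjects
#' with a missing call or missing truth are excluded from the counts and
#' reported in the `n_excluded` field (per-criterion exclusion, never
#' imputation).
#'
#' @param truth Logical (or 0/1) vector: reference status (e.g. genetically
#'   confirmed FH).
#' @param calls Logical (or 0/1) vector of the same length: criterion calls.
#' @return An object of class `fh_confusion`: a list with integer `tp`,
#'   `fp`, `fn`, `tn`, plus `n` (included) and `n_excluded`.
#' @export
#' @examples
#' confusion(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
confusion <- function(truth, calls) {
  if (length(truth) != length(calls)) {
    stop("truth and calls must have the same length", call. = FALSE)
  }
  if (length(truth) == 0) {
    stop("empty input: no subjects to tabulate", call. = FALSE)
  }
  truth <- as.logical(truth)
  calls <- as.logical(calls)
  keep <- !is.na(truth) & !is.na(calls)
  if (!any(keep)) {
    stop("no subjects with both truth and call available", call. = FALSE)
  }
  t <- truth[keep]
  c_ <- calls[keep]
  new_confusion(
    tp = sum(t & c_), fp = sum(!t & c_),
    fn = sum(t & !c_), tn = sum(!t & !c_),
    n_excluded = sum(!keep)
  )
}

new_confusion <- function(tp, fp, fn, tn, n_excluded = 0L) {
  cm <- list(tp = as.integer(tp), fp = as.integer(fp),
             fn = as.integer(fn), tn = as.integer(tn),
             n = as.integer(tp + fp + fn + tn),
             n_excluded = as.integer(n_excluded))
  if (any(unlist(cm[c("tp", "fp", "fn", "tn")]) < 0)) {
    stop("confusion counts must be non-negative", call. = FALSE)
  }
  if (cm$n == 0) {
    stop("confusion matrix is empty", call. = FALSE)
  }
  structure(cm, class = "fh_confusion")
}

#' @export
print.fh_confusion <- function(x, ...) {
  cat(sprintf("Confusion matrix (n = %d, excluded = %d)\n", x$n, x$n_excluded))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("call +", "call -"), c("truth +", "truth -")))
  print(t(m))
  invisible(x)
}

#' Diagnostic metrics of a confusion matrix
#'
#' Sensitivity, specificity, positive and negative predictive values,
#' accuracy and prevalence as fractions in `[0, 1]`. A metric whose
#' denominator is zero is undefined and returned as `NA` (never 0).
#'
#' @param cm An `fh_confusion` (from [confusion()]) or a list/vector with
#'   `tp`, `fp`, `fn`, `tn`.
#' @return A tibble with one row: `tp`, `fp`, `fn`, `tn`, `n`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`, `prevalence`.
#' @export
#' @examples
#' metrics(confusion(c(1, 1, 0), c(1, 0, 0)))
metrics <- function(cm) {
  cm <- as_confusion(cm)
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  tibble::tibble(
    tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn, n = cm$n,
    sensitivity = ratio(cm$tp, cm$tp + cm$fn),
    specificity = ratio(cm$tn, cm$tn + cm$fp),
    ppv = ratio(cm$tp, cm$tp + cm$fp),
    npv = ratio(cm$tn, cm$tn + cm$fn),
    accuracy = ratio(cm$tp + cm$tn, cm$n),
    prevalence = ratio(cm$tp + cm$fn, cm$n)
  )
}

as_confusion <- function(cm) {
  if (inherits(cm, "fh_confusion")) {
    return(cm)
  }
  cm <- as.list(cm)
  new_confusion(cm$tp, cm$fp, cm$fn, cm$tn, cm$n_excluded %||% 0L)
}

#' Two-sided Fisher exact test p-value
#'
#' Exact two-sided p for a 2x2 table by the standard convention: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' no more probable than the observed one. Delegates to
#' [stats::fisher.test()], which implements exactly this convention.
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value (a single number).
#' @export
#' @examples
#' fisher_exact_p(matrix(c(12, 0, 4, 3), 2))   # 0.036 to 3 d.p.
fisher_exact_p <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) {
    stop("fisher_exact_p() needs a 2x2 table", call. = FALSE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("table entries must be non-negative integers", call. = FALSE)
  }
  stats::fisher.test(table)$p.value
}

#' Empirical ROC curve
#'
#' Builds the empirical ROC of a numeric score against a binary truth, with
#' a "higher score = more diseased" orientation. Candidate thresholds are
#' the midpoints between consecutive distinct score values, plus sentinels
#' below and above the observed range; at threshold t the call is
#' `score >= t`. AUC is computed by the trapezoid rule and equals the
#' rank statistic P(score+ > score-) + 0.5 P(tie).
#'
#' @param scores Numeric vector of scores.
#' @param truth Logical (or 0/1) vector of reference status.
#' @return An object of class `fh_roc`: a tibble of `threshold`,
#'   `sensitivity`, `specificity` with attributes `auc` and `youden`
#'   (see [youden_optimal()]).
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.logical(truth)
  keep <- !is.na(scores) & !is.na(truth)
  scores <- scores[keep]
  truth <- truth[keep]
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs both positive and negative subjects", call. = FALSE)
  }
  s <- sort(unique(scores))
  thresholds <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
                  s[length(s)] + 1)
  se <- vapply(thresholds, function(t) sum(truth & scores >= t) / n_pos,
               numeric(1))
  sp <- vapply(thresholds, function(t) sum(!truth & scores < t) / n_neg,
               numeric(1))
  curve <- tibble::tibble(threshold = thresholds, sensitivity = se,
                          specificity = sp)
  # trapezoid over (FPR, TPR) sorted by increasing FPR
  fpr <- 1 - sp
  ord <- order(fpr, se)
  auc <- sum(diff(fpr[ord]) * (se[ord][-1] + se[ord][-length(se)]) / 2)
  out <- structure(curve, class = c("fh_roc", class(curve)), auc = auc)
  attr(out, "youden") <- youden_optimal(out)
  out
}

#' AUC of an ROC curve
#' @param curve An `fh_roc` from [roc_curve()].
#' @return The area under the curve.
#' @export
roc_auc <- function(curve) {
  attr(curve, "auc")
}

#' Youden-optimal threshold of an ROC curve
#'
#' Maximises J = sensitivity + specificity - 1 over the curve's thresholds.
#' Ties are broken toward the lower threshold, i.e. the more sensitive
#' operating point.
#'
#' @param curve An `fh_roc` from [roc_curve()].
#' @return A list with `threshold`, `J`, `sensitivity`, `specificity`.
#' @export
youden_optimal <- function(curve) {
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j == max(j))
  pick <- best[which.min(curve$threshold[best])]
  list(threshold = curve$threshold[pick], J = j[pick],
       sensitivity = curve$sensitivity[pick],
       specificity = curve$specificity[pick])
}

#' Reconstruct integer confusion matrices from rounded published metrics
#'
#' Published diagnostic-performance tables usually print percentages rounded
#' to one decimal without the underlying counts. This exhaustively
#' enumerates every integer confusion matrix with `n <= n_max` whose metrics
#' round (half-up, one decimal, percent scale) to all supplied values, and
#' returns them ordered by total n. With enough independent metrics the
#' smallest solution is typically the published matrix, allowing unprinted
#' metrics of the same row to be recovered.
#'
#' @param targets Named numeric vector of rounded percentages; names among
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`, `prevalence`.
#'   At least two must be supplied.
#' @param n_max Maximum total count to search (default 60).
#' @param digits Decimal places of the published rounding (default 1).
#' @return A tibble of matching matrices (`tp`, `fp`, `fn`, `tn`, `n`),
#'   ordered by `n` then `tp`; zero rows if nothing matches.
#' @export
#' @examples
#' reconstruct_confusion(
#'   c(sensitivity = 84.6, specificity = 40.0, ppv = 88.0, npv = 33.3),
#'   n_max = 40
#' )
reconstruct_confusion <- function(targets, n_max = 60, digits = 1) {
  allowed <- c("sensitivity", "specificity", "ppv", "npv", "accuracy",
               "prevalence")
  if (is.null(names(targets)) || !all(names(targets) %in% allowed)) {
    stop("targets must be named among: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  if (length(targets) < 2) {
    stop("need at least two independent metrics to reconstruct",
         call. = FALSE)
  }
  # all (tp, fp, fn) with tp+fp+fn <= n_max; tn = n - (tp+fp+fn) for each n
  base <- expand.grid(tp = 0:n_max, fp = 0:n_max, fn = 0:n_max)
  base <- base[base$tp + base$fp + base$fn <= n_max, ]
  s <- base$tp + base$fp + base$fn
  reps <- n_max - s + 1L
  grid <- data.frame(
    tp = rep(base$tp, reps), fp = rep(base$fp, reps), fn = rep(base$fn, reps),
    n = sequence(reps, from = s)
  )
  grid$tn <- grid$n - grid$tp - grid$fp - grid$fn
  grid <- grid[grid$n > 0, ]

  pct <- function(num, den) {
    out <- ifelse(den > 0, round_half_up(100 * num / den, digits), NA_real_)
    out
  }
  value <- list(
    sensitivity = pct(grid$tp, grid$tp + grid$fn),
    specificity = pct(grid$tn, grid$tn + grid$fp),
    ppv = pct(grid$tp, grid$tp + grid$fp),
    npv = pct(grid$tn, grid$tn + grid$fn),
    accuracy = pct(grid$tp + grid$tn, grid$n),
    prevalence = pct(grid$tp + grid$fn, grid$n)
  )
  keep <- rep(TRUE, nrow(grid))
  for (nm in names(targets)) {
    keep <- keep & !is.na(value[[nm]]) &
      abs(value[[nm]] - round_half_up(targets[[nm]], digits)) < 1e-9
  }
  out <- grid[keep, c("tp", "fp", "fn", "tn", "n")]
  out <- out[order(out$n, out$tp), ]
  tibble::as_tibble(out)
}

#' Diagnostic performance of criteria on a cohort
#'
#' Evaluates each requested criterion's binary call against the genetic
#' result and reports, per criterion: the confusion counts, the effective n
#' (subjects with both a call and a genetic result; missing inputs are
#' excluded per criterion, never imputed), prevalence in the evaluated
#' subset, the standard metrics as rounded percentages, and a two-sided
#' Fisher exact p for the call x genotype table.
#'
#' Criterion calls are computed *without* their genetic-study items
#' (`use_genetic = FALSE` by default here) since the genetic result is the
#' reference standard being predicted.
#'
#' @param cohort A cohort tibble with a logical `genetic_confirmed` column.
#' @param config An `fh_config`, a path to one, or `NULL` for the default.
#' @param criteria Character vector of criteria to evaluate; any of the six
#'   clinical criteria plus `"LDL55"` (pretreatment LDL-C >= 5.5 mmol/L),
#'   `"intensity"` (treatment-intensity rule) and `"combined"` (intensity +
#'   LDL-C rule).
#' @param use_genetic Passed through to the clinical criteria (default
#'   `FALSE`; see above).
#' @return A tibble with one row per criterion: `criterion`, `tp`, `fp`,
#'   `fn`, `tn`, `n_effective`, `n_excluded`, `prevalence_pct`,
#'   `sensitivity_pct`, `specificity_pct`, `ppv_pct`, `npv_pct`,
#'   `accuracy_pct`, `fisher_p`.
#' @export
evaluate_criteria_on_cohort <- function(cohort, config = NULL,
                                        criteria = c("SimonBroome", "MEDPED",
                                                     "JFHMC", "HK_panel",
                                                     "LDL55", "intensity",
                                                     "combined"),
                                        use_genetic = FALSE) {
  cfg <- as_fh_config(config)
  if (!"genetic_confirmed" %in% names(cohort)) {
    stop("cohort needs a genetic_confirmed column as the reference standard",
         call. = FALSE)
  }
  truth <- as.logical(cohort$genetic_confirmed)
  get_calls <- function(name) {
    switch(name,
      DLCNC = score_dlcnc(cohort, cfg, use_genetic)$binary_call,
      modified_DLCNC = score_modified_dlcnc(cohort, cfg, use_genetic)$binary_call,
      SimonBroome = classify_simon_broome(cohort, cfg, use_genetic)$binary_call,
      MEDPED = classify_medped(cohort, cfg)$binary_call,
      JFHMC = classify_jfhmc(cohort, cfg)$binary_call,
      HK_panel = classify_hk_panel(cohort, cfg)$binary_call,
      LDL55 = cohort$pre_ldl >= cfg$intensity_criterion$ldl_cutoff_combined,
      intensity = intensity_criterion(cohort, cfg),
      combined = combined_criterion(cohort, cfg),
      stop("unknown criterion: ", name, call. = FALSE)
    )
  }
  rows <- lapply(criteria, function(nm) {
    cm <- confusion(truth, get_calls(nm))
    m <- metrics(cm)
    p <- fisher_exact_p(matrix(c(cm$tp, cm$fp, cm$fn, cm$tn), 2, 2))
    tibble::tibble(
      criterion = nm,
      tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
      n_effective = cm$n, n_excluded = cm$n_excluded,
      prevalence_pct = percent_half_up(m$prevalence),
      sensitivity_pct = percent_half_up(m$sensitivity),
      specificity_pct = percent_half_up(m$specificity),
      ppv_pct = percent_half_up(m$ppv),
      npv_pct = percent_half_up(m$npv),
      accuracy_pct = percent_half_up(m$accuracy),
      fisher_p = p
    )
  })
  dplyr::bind_rows(rows)
}
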