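# Build a one-row cohort tibble with sensible adult defaults; override any
# field by name. Used throughout to express criterion scenarios compactly.
make_subject <- function(id = "S1", age_years = 45, role = "proband",
                         pre_ldl = NA_real_, pre_tc = NA_real_,
                         on_ldl = NA_real_, peak_ldl = NA_real_,
                         regimen = "", genetic_confirmed = FALSE, ...) {
  base <- tibble::tibble(
    id = id, role = role, age_years = age_years, sex = "F",
    fh_first_degree_pcvd = FALSE,
    fh_first_degree_hyperlipidemia = FALSE,
    fh_relative_fh_diagnosis = FALSE,
    fh_child_high_ldl = FALSE,
    ph_premature_cad = FALSE,
    ph_premature_cerebral_peripheral = FALSE,
    sign_tendon_xanthoma = FALSE,
    sign_relative_tendon_xanthoma = FALSE,
    sign_arcus_under_45 = FALSE,
    sign_xanthelasma = FALSE,
    pre_tc = pre_tc, pre_ldl = pre_ldl, pre_hdl = 1.2, pre_tg = 1.5,
    on_ldl = on_ldl, peak_ldl = peak_ldl,
    regimen = regimen,
    genetic_confirmed = genetic_confirmed,
    excluded_alternative_diagnosis = FALSE
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

make_cohort <- function(...) {
  dplyr::bind_rows(...)
}

# Independent Fisher oracle: enumerate all 2x2 tables with the observed
# margins and sum hypergeometric probabilities <= that of the observed table.
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Independent AUC oracle: P(score_pos > score_neg) + 0.5 P(tie), brute force
# over all positive x negative pairs.
auc_oracle <- function(scores, truth) {
  pos <- scores[truth]
  neg <- scores[!truth]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Independent slow reconstruction oracle (quadruple loop); only for tiny n.
reconstruct_oracle <- function(targets, n_max) {
  rh <- function(x) floor(x * 10 + 0.5) / 10
  hits <- list()
  for (tp in 0:n_max) for (fp in 0:(n_max - tp)) {
    for (fn in 0:(n_max - tp - fp)) for (tn in 0:(n_max - tp - fp - fn)) {
      n <- tp + fp + fn + tn
      if (n == 0) next
      vals <- c(
        sensitivity = if (tp + fn > 0) rh(100 * tp / (tp + fn)) else NA,
        specificity = if (tn + fp > 0) rh(100 * tn / (tn + fp)) else NA,
        ppv = if (tp + fp > 0) rh(100 * tp / (tp + fp)) else NA,
        npv = if (tn + fn > 0) rh(100 * tn / (tn + fn)) else NA,
        accuracy = rh(100 * (tp + tn) / n)
      )
      ok <- all(vapply(names(targets), function(nm) {
        !is.na(vals[nm]) && abs(vals[nm] - targets[nm]) < 1e-9
      }, logical(1)))
      if (ok) hits[[length(hits) + 1]] <- data.frame(tp, fp, fn, tn, n)
    }
  }
  out <- do.call(rbind, hits)
  out[order(out$n, out$tp), , drop = FALSE]
}
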