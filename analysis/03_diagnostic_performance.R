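#!/usr/bin/env Rscript
# Diagnostic performance of each criterion against the genetic result on the
# packaged synthetic adult cohort: confusion counts, sensitivity/specificity/
# PPV/NPV/accuracy, Fisher exact p per row, and ROC/Youden analyses of the
# quantitative scores (pretreatment LDL-C, DLCNC and modified DLCNC scores,
# treatment intensity). Criterion calls are computed without their DNA items
# since the genetic result is the reference standard.
#
# The cohort is a reconstruction built to match the published per-criterion
# confusion matrices, so the table below reproduces those rows exactly; the
# ROC statistics, which depend on the full joint distribution of scores that
# no publication prints, are internally consistent but cohort-specific.
#
#   Rscript analysis/03_diagnostic_performance.R

suppressPackageStartupMessages(library(fhdx))
dir.create("results", showWarnings = FALSE)

cohort <- fh_adult_cohort()
perf <- evaluate_criteria_on_cohort(cohort)
write_report(perf, "results/diagnostic_performance.tsv")
cat("criterion performance against genetic results:\n")
print(as.data.frame(perf[, c("criterion", "sensitivity_pct",
                             "specificity_pct", "ppv_pct", "npv_pct",
                             "accuracy_pct", "n_effective", "fisher_p")]),
      digits = 3)

# quantitative scores: ROC, AUC, Youden-optimal cutoffs
truth <- cohort$genetic_confirmed
scores <- list(
  pretreatment_ldl = cohort$pre_ldl,
  dlcnc_score = score_dlcnc(cohort, use_genetic = FALSE)$score,
  modified_dlcnc_score = score_modified_dlcnc(cohort, use_genetic = FALSE)$score,
  treatment_intensity = vapply(cohort$regimen, function(r) {
    treatment_intensity(r)$intensity
  }, numeric(1))
)
roc_rows <- lapply(names(scores), function(nm) {
  curve <- roc_curve(scores[[nm]], truth)
  opt <- youden_optimal(curve)
  points <- cbind(score = nm, as.data.frame(curve))
  write_report(points, file.path("results",
                                 paste0("roc_points_", nm, ".tsv")))
  data.frame(score = nm, auc = roc_auc(curve), cutoff = opt$threshold,
             J = opt$J, sensitivity = opt$sensitivity,
             specificity = opt$specificity)
})
roc_tab <- do.call(rbind, roc_rows)
write_report(roc_tab, "results/roc_summary.tsv")
cat("\nROC summaries (Youden-optimal cutoffs):\n")
print(roc_tab, digits = 3, row.names = FALSE)
cat("wrote results/diagnostic_performance.tsv, roc_summary.tsv, roc_points_*.tsv\n")
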