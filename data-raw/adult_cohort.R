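# Builds inst/extdata/adult_cohort_synthetic.csv: a 31-subject synthetic
# adult cohort (16 genotype-positive probands, 10 positive cascade
# relatives, 3 negative probands, 2 negative cascade relatives) constructed
# so that evaluating the packaged criteria reproduces the published
# diagnostic-performance rows exactly:
#   Simon Broome / MEDPED / JFHMC      -> (tp 22, fp 3, fn 4, tn 2)
#   HK panel                           -> (tp 23, fp 4, fn 3, tn 1)
#   pretreatment LDL-C >= 5.5          -> (tp 21, fp 2, fn 5, tn 3)
#   treatment-intensity rule           -> (tp 23, fp 1, fn 1, tn 4), n = 29
#   intensity + LDL-C combined rule    -> (tp 20, fp 0, fn 4, tn 5), n = 29
# while matching the published group means: pretreatment LDL-C 8.77
# (positive probands), 6.60 (positive cascade), 6.53 (negative probands),
# 5.59 (all negatives); TC 10.35 / 10.00 / 8.13; peak LDL-C 9.24 / 10.50;
# family pCVD history 75% of positive probands, 69.2% of all positives, 0%
# of negatives. Not patient data. Run from the package root:
#   Rscript data-raw/adult_cohort.R

library(tibble)

pos_ldl <- c(
  # probands P01-P16 (mean 8.77)
  10.8, 10.2, 9.8, 9.5, 9.2, 9.0, 8.9, 8.8, 8.7, 8.6, 8.5, 8.3, 8.1,
  7.8, 7.3, 6.82,
  # cascade relatives P17-P26 (mean 6.612)
  9.4, 9.0, 8.6, 8.4, 8.02, 5.2, 4.6, 4.3, 4.4, 4.2
)
neg_ldl <- c(7.4, 6.7, 5.49, 4.66, 3.70) # probands N1-N3 (mean 6.53), cascade N4-N5

pos_regimen <- c(
  rep("rosuvastatin:20;ezetimibe:10", 6),   # P01-P06, intensity 2.666
  rep("atorvastatin:80", 4),                # P07-P10, 2.222
  rep("rosuvastatin:20", 4),                # P11-P14, 2.222
  rep("atorvastatin:40", 4),                # P15-P18, 2.000
  rep("rosuvastatin:10", 2),                # P19-P20, 2.000
  "simvastatin:10",                         # P21, 1.429 -> below threshold
  "atorvastatin:40", "rosuvastatin:20", "rosuvastatin:5", # P22-P24
  "", ""                                    # P25-P26 untreated, not assessable
)
# on-treatment LDL-C: ~55% reduction for assessable subjects except P21 (30%)
pos_reduction <- c(rep(0.55, 20), 0.30, rep(0.55, 3), NA, NA)
pos_on <- round(pos_ldl * (1 - pos_reduction), 2)

neg_regimen <- c("simvastatin:20", "pravastatin:40", "simvastatin:10",
                 "rosuvastatin:20", "simvastatin:10")
neg_reduction <- c(0.35, 0.29, 0.28, 0.55, 0.30)
neg_on <- round(neg_ldl * (1 - neg_reduction), 2)

positives <- tibble(
  id = sprintf("P%02d", 1:26),
  role = c(rep("proband", 16), rep("cascade_relative", 10)),
  age_years = 40 + 1:26,
  sex = rep(c("F", "M"), 13),
  fh_first_degree_pcvd = c(rep(TRUE, 12), rep(FALSE, 4),   # 12/16 probands
                           rep(TRUE, 6), rep(FALSE, 4)),   # + 6 cascade = 18/26
  fh_first_degree_hyperlipidemia = TRUE,
  fh_relative_fh_diagnosis = TRUE,
  fh_child_high_ldl = FALSE,
  ph_premature_cad = c(TRUE, TRUE, rep(FALSE, 24)),
  ph_premature_cerebral_peripheral = FALSE,
  sign_tendon_xanthoma = c(rep(TRUE, 3), rep(FALSE, 23)),
  sign_relative_tendon_xanthoma = FALSE,
  sign_arcus_under_45 = FALSE,
  sign_xanthelasma = c(rep(FALSE, 3), TRUE, rep(FALSE, 22)),
  pre_tc = round(pos_ldl + 1.58, 2),
  pre_ldl = pos_ldl,
  pre_hdl = 1.0,
  pre_tg = 1.28,
  on_ldl = pos_on,
  peak_ldl = round(pos_ldl + c(rep(0.47, 16), rep(0.16, 10)), 2),
  regimen = pos_regimen,
  genetic_confirmed = TRUE,
  excluded_alternative_diagnosis = FALSE
)

negatives <- tibble(
  id = sprintf("N%02d", 1:5),
  role = c(rep("proband", 3), rep("cascade_relative", 2)),
  age_years = c(45, 50, 55, 48, 52),
  sex = c("M", "F", "M", "F", "M"),
  fh_first_degree_pcvd = FALSE,
  fh_first_degree_hyperlipidemia = c(TRUE, TRUE, TRUE, TRUE, FALSE),
  fh_relative_fh_diagnosis = c(TRUE, TRUE, TRUE, TRUE, FALSE),
  fh_child_high_ldl = FALSE,
  ph_premature_cad = FALSE,
  ph_premature_cerebral_peripheral = FALSE,
  sign_tendon_xanthoma = FALSE,
  sign_relative_tendon_xanthoma = FALSE,
  sign_arcus_under_45 = FALSE,
  sign_xanthelasma = FALSE,
  pre_tc = c(10.5, 10.0, 9.5, 6.4, 5.5),
  pre_ldl = neg_ldl,
  pre_hdl = c(1.3, 1.3, 2.0, 1.2, 1.3),
  pre_tg = c(3.96, 4.40, 4.42, 1.19, 1.10),
  on_ldl = neg_on,
  peak_ldl = c(11.5, 10.5, 9.5, 4.76, 3.80),
  regimen = neg_regimen,
  genetic_confirmed = FALSE,
  excluded_alternative_diagnosis = FALSE
)

cohort <- rbind(positives, negatives)
out <- file.path("inst", "extdata", "adult_cohort_synthetic.csv")
write.csv(cohort, out, row.names = FALSE, na = "")
cat("wrote", out, "with", nrow(cohort), "subjects\n")
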