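#!/usr/bin/env Rscript
# Stage 4 — statistical screening.
#
# Spearman-screens every (site, feature) pair against the clinical deltas,
# runs ROC/Youden analysis (non-responders as the positive class) for the
# features significant against delta-PSA, combines the two strongest by the
# AND rule, and checks feature-volume independence. Writes the correlation,
# ROC and confusion tables plus a JSON bundle under results/screen/.

library(hetpet)

patient <- read.csv("results/features_patient.csv", stringsAsFactors = FALSE)
deltas <- read.csv("results/deltas.csv", stringsAsFactors = FALSE)

res <- run_screen(patient, deltas)
write_screen(res, "results/screen")

sig <- subset(res$correlations, clinical == "delta_psa" & !is.na(p_value) &
                p_value < res$alpha)
message(nrow(sig), " (site, feature) pairs significant against delta-PSA ",
        "of ", res$n_tests, " tests at alpha = ", res$alpha, ":")
for (i in seq_len(nrow(sig)))
  message(sprintf("  %s %-15s rs = %+0.3f  p = %.4f", sig$site[i],
                  sig$feature[i], sig$rs[i], sig$p_value[i]))
bone <- subset(res$correlations, clinical == "delta_psa" & site == "bone" &
                 !is.na(rs))
bone <- bone[order(-abs(bone$rs)), ][seq_len(min(3, nrow(bone))), ]
message("Strongest bone-lesion correlations with delta-PSA this draw:")
for (i in seq_len(nrow(bone)))
  message(sprintf("  %-15s rs = %+0.3f  p = %.4f", bone$feature[i],
                  bone$rs[i], bone$p_value[i]))
if (!is.null(res$roc))
  for (i in seq_len(nrow(res$roc)))
    message(sprintf("  ROC %s %-15s AUC %.3f (%.2f-%.2f), cutoff %s %.3f",
                    res$roc$site[i], res$roc$feature[i], res$roc$auc[i],
                    res$roc$ci_low[i], res$roc$ci_high[i],
                    ifelse(res$roc$direction[i] == "greater", ">", "<="),
                    res$roc$cutoff[i]))
if (!is.null(res$combined))
  message(sprintf("  combined (%s, AND): sensitivity %.2f%%, specificity %.2f%%",
                  res$combined$features, 100 * res$combined$sensitivity,
                  100 * res$combined$specificity))
message("Wrote results/screen/")
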