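#!/usr/bin/env Rscript
# Stage 3 — clinical response labelling.
#
# Computes post-minus-pre deltas for PSA, alkaline phosphatase and bone
# alkaline phosphatase; a strictly negative delta defines a responder.
# Writes the per-patient deltas and the responder summary.

library(hetpet)

clinical <- read_clinical("results/cohort/clinical.csv")
deltas <- compute_deltas(clinical)
write.csv(deltas, "results/deltas.csv", row.names = FALSE)

summary_tab <- summarize_response(deltas)
write.csv(summary_tab, "results/response_summary.csv", row.names = FALSE)
jsonlite::write_json(summary_tab, "results/response_summary.json",
                     auto_unbox = TRUE, digits = NA)

for (i in seq_len(nrow(summary_tab)))
  message(sprintf("  %-20s %d/%d (%.2f%%)", summary_tab$measure[i],
                  summary_tab$count[i], summary_tab$n[i],
                  summary_tab$percent[i]))
message("Wrote results/deltas.csv and results/response_summary.{csv,json}")
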