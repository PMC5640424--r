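#!/usr/bin/env Rscript
# Replay the traffic-light feedback engine over the registration log:
# every value is judged against the mean of the previous five registered
# values at the moment of registration (>15% orange, >20% red). Writes the
# per-registration feedback table and reports how often patients were asked
# to repeat a measurement.

suppressMessages(library(smssaudit))

smss <- read_smss_log("results/sim/smss.csv")
fb <- replay_feedback(smss)

readr::write_csv(
  fb[, c("patient_id", "measurement_date", "slot", "light", "kind", "advice")],
  "results/feedback.csv"
)

active <- fb[!fb$skipped, ]
share <- mean(active$kind == "action_feedback")
cat(sprintf("%d registrations replayed; lights: %s\n", nrow(active),
            paste(names(table(active$light)), table(active$light),
                  sep = "=", collapse = ", ")))
cat(sprintf("repeat-measurement requests (action feedback): %.1f%% of registrations\n",
            100 * share))
cat("feedback table written to results/feedback.csv\n")
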