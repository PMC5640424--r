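#!/usr/bin/env Rscript
# Audit adherence to the system's feedback: did patients repeat the
# measurement after action feedback, measure again after an orange day
# conclusion, and contact the hospital after a red one? Delayed
# registration makes the advice stale, which is the dominant failure mode.

suppressMessages(library(smssaudit))

device <- read_device_log("results/sim/device.csv")
smss <- read_smss_log("results/sim/smss.csv")
contacts <- read_contact_log("results/sim/contacts.csv")

fb <- replay_feedback(smss)
audit <- audit_feedback_adherence(fb, device, smss, contacts)
print(audit)

out <- jsonlite::toJSON(unclass(audit), auto_unbox = TRUE, pretty = TRUE,
                        digits = 6)
dir.create("results", showWarnings = FALSE)
writeLines(out, "results/feedback_audit.json")
cat("audit written to results/feedback_audit.json\n")
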