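#!/usr/bin/env Rscript
# Simulate the study cohort: 43 patients monitored over one post-transplant
# year under the four-phase schedule, with the default behavioral profile
# (imperfect adherence, batched/delayed registration, lowest-value selection,
# under-reporting, typos, rounding, phantoms, unflagged test strips).
# Writes the four interchange CSVs plus the labelled ground truth.

suppressMessages(library(smssaudit))

seed <- 17L
out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_cohort(n_patients = 43, seed = seed)

write_device_log(sim$device, file.path(out_dir, "device.csv"))
write_smss_log(sim$smss, file.path(out_dir, "smss.csv"))
write_contact_log(sim$contacts, file.path(out_dir, "contacts.csv"))
readr::write_csv(sim$truth, file.path(out_dir, "truth.csv"))
readr::write_csv(sim$starts, file.path(out_dir, "starts.csv"))

cat(sprintf("cohort: %d patients, %d device values (%d test-flagged), %d registrations, %d contacts\n",
            length(unique(sim$device$patient_id)), nrow(sim$device),
            sum(sim$device$is_test), nrow(sim$smss), nrow(sim$contacts)))
cat(sprintf("ground truth: %d phantoms, %d underreports, %d typos, %d rounded\n",
            sum(sim$truth$is_phantom), sum(sim$truth$is_underreport),
            sum(sim$truth$is_typo), sum(sim$truth$is_rounded)))
cat("logs written to", out_dir, "\n")
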