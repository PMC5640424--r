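#!/usr/bin/env Rscript
# Score adherence to the measurement and registration schedules per phase
# (28/15/12/37 requested days) and quantify the delay between measurement
# and registration.

suppressMessages(library(smssaudit))

device <- read_device_log("results/sim/device.csv")
smss <- read_smss_log("results/sim/smss.csv")
starts <- readr::read_csv("results/sim/starts.csv", show_col_types = FALSE)

dev_events <- tibble::tibble(patient_id = device$patient_id[!device$is_test],
                             date = as.Date(device$timestamp[!device$is_test]))
reg_events <- tibble::tibble(patient_id = smss$patient_id,
                             date = smss$measurement_date)

adh_m <- score_adherence(dev_events, starts, basis = "measured")
adh_r <- score_adherence(reg_events, starts, basis = "registered")
readr::write_csv(dplyr::bind_rows(adh_m, adh_r), "results/adherence.csv")

cat("adherent-or-overadherent patients per phase:\n")
cat("  measured basis:\n")
print(cohort_adherence(adh_m)$per_phase)
cat("  registered basis:\n")
print(cohort_adherence(adh_r)$per_phase)
cat(sprintf("patients nonadherent in >=2 phases (measured): %d; (registered): %d\n",
            length(cohort_adherence(adh_m)$repeat_nonadherent),
            length(cohort_adherence(adh_r)$repeat_nonadherent)))

ds <- delay_stats(smss, device)
cat(sprintf("registration delay: mean %.1f days (SD %.1f), max %d days\n",
            ds$mean_delay, ds$sd_delay, ds$max_delay))
pp <- ds$per_patient
cat(sprintf("  %d/%d patients always registered same-day, %d had mean delay <1 day, %d had mean delay >3 days\n",
            sum(pp$always_same_day), nrow(pp), sum(pp$mean_delay_lt_1),
            sum(pp$mean_delay_gt_3)))
readr::write_csv(pp, "results/delay_per_patient.csv")
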