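#!/usr/bin/env Rscript
# Classify patient outcomes at 12 months (all sites) and 24/36 months
# (the two 36-month sites), tabulate retention, and estimate conditional
# retention among those still in care.

suppressMessages({library(artcost); library(dplyr)})

cohort <- read_patient_records("results/patients.csv")

out12 <- classify_outcomes(cohort, 12, grace_days = 90)
sites36 <- filter(cohort, site_id %in% c("site2", "site6"))
out24 <- classify_outcomes(sites36, 24)
out36 <- classify_outcomes(sites36, 36)

retention <- retention_table(bind_rows(out12, out24, out36))
write_table(out12, "results/outcomes_12m.csv")
write_table(bind_rows(out24, out36), "results/outcomes_multiyear.csv")
write_table(retention, "results/retention.csv",
            meta = list(grace_days = 90, stage = "outcomes"))

ov <- retention[retention$site_id == "all" &
                  retention$endpoint_months == 12, ]
cat(sprintf("12-month outcomes: %.0f%% retained, %.0f%% died, %.0f%% LTFU (n = %d)\n",
            ov$pct_retained, ov$pct_died, ov$pct_ltfu, ov$n))
cat(sprintf("Conditional retention 12 -> 24 months (36-month sites): %.0f%%\n",
            100 * conditional_retention(bind_rows(out12 |>
              filter(site_id %in% c("site2", "site6")), out24), 12, 24)))
cat(sprintf("Conditional retention 24 -> 36 months: %.0f%%\n",
            100 * conditional_retention(bind_rows(out24, out36), 24, 36)))
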