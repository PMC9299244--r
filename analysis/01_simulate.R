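#!/usr/bin/env Rscript
# Step 1: simulate the default surveillance scenario.
#
# One synthetic "database" of 20,000 persons followed from September 2008
# through May 2010: a 9-month historic period and a 9-month vaccination
# campaign (~19% coverage), 93 negative-control outcomes with baseline rates
# 0.008-0.05 events per person-year, winter-peaking seasonality, and
# confounded uptake (frailty raises outcome rates, visit rates and the
# vaccination hazard; a health-seeking score raises visits and uptake).
# Tables are written in the delimited-file interchange format under
# scratch/sim/; a small summary table goes to results/tables/.

suppressMessages(library(vaxeval))
suppressMessages(library(data.table))

cfg <- sim_config(n_persons = 20000, seed = 2026)
tabs <- simulate_tables(cfg)
write_tables(tabs, "scratch/sim")

vax <- tabs$vaccination
summary <- data.table(
  n_persons = cfg$n_persons,
  n_vaccinated = uniqueN(vax$person_id),
  n_doses = nrow(vax),
  n_visits = nrow(tabs$visit_occurrence),
  n_outcomes = nrow(tabs$outcome),
  n_negative_controls = cfg$n_negative_controls,
  study_start = cfg$study_start, study_end = cfg$study_end,
  historic_start = cfg$historic_start, historic_end = cfg$historic_end)
fwrite(summary, "results/tables/simulation_summary.csv")

cat(sprintf(paste0(
  "Simulated %d persons; %d received %d vaccine doses during the campaign\n",
  "(coverage %.1f%%); %s outpatient visits; %s first-occurrence outcome\n",
  "events across %d negative-control outcomes.\n"),
  summary$n_persons, summary$n_vaccinated, summary$n_doses,
  100 * summary$n_vaccinated / summary$n_persons,
  format(summary$n_visits, big.mark = ","),
  format(summary$n_outcomes, big.mark = ","), cfg$n_negative_controls))
cat("Tables written to scratch/sim; summary in results/tables/simulation_summary.csv\n")
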