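#!/usr/bin/env Rscript

## Step 1 — simulate the study cohort.
##
## Draws the 41 typically-developing (TD) and 21 CLN3 subjects with their
## ground-truth injected MMN amplitudes under the default effect map (robust
## TD MMN at every SOA; CLN3: robust at 900 ms, marginal at 450 ms, absent at
## 1800 ms; opposite-signed age trends), and writes the subject table and one
## example session schedule.

suppressPackageStartupMessages(library(oddballmmn))

seed <- 20260926
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(41, 21, cohort_config(), seed = seed)
write.csv(cohort$subjects, "results/subjects.csv", row.names = FALSE)

sched <- build_session_schedule(seed = derive_seed(seed, "example-schedule"))
write_events_tsv(sched, "results/example_schedule.tsv")

cat("Cohort:", nrow(cohort$subjects), "subjects written to results/subjects.csv\n")
cat("Injected group means (uV):\n")
agg <- aggregate(cohort$subjects[, c("mmn_450", "mmn_900", "mmn_1800")],
                 by = list(group = cohort$subjects$group), FUN = mean)
print(agg, digits = 3)
cat("Example schedule:", nrow(sched$events), "events in",
    length(unique(sched$events$block)), "blocks ->",
    "results/example_schedule.tsv\n")
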