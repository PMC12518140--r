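#!/usr/bin/env Rscript
# Tumour growth: ellipsoid volumes from caliper length/width, group
# mean +/- SEM trajectories, and the low-dose recurrence check.

suppressPackageStartupMessages(library(ribpet))

caliper <- read.csv("results/cohort/caliper.csv")
summary_tab <- growth_summary(caliper)
write.csv(summary_tab, "results/growth_summary.csv", row.names = FALSE)

for (grp in unique(summary_tab$group)) {
  s <- summary_tab[summary_tab$group == grp, ]
  message(sprintf(
    "group %s Gy: %d -> %d animals over follow-up; volume %.0f -> %.0f mm3",
    grp, s$n[1], s$n[nrow(s)], s$mean_volume[1], s$mean_volume[nrow(s)]))
}

s5 <- summary_tab[summary_tab$group == "5", ]
message(sprintf("5 Gy minimum mean volume at day %.1f (recurrence afterwards)",
                s5$day[which.min(s5$mean_volume)]))

censored <- tapply(caliper$day, caliper$animal_id, max)
n_cens <- sum(censored < max(caliper$day))
message(n_cens, " animals censored at the burden limit before final follow-up")
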