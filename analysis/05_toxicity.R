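#!/usr/bin/env Rscript
# Toxicity: grip-strength deficit in irradiated animals and its
# correlation with the fraction of PET counts in the spinal cord.

suppressPackageStartupMessages(library(ribpet))

grip <- read.csv("results/cohort/grip.csv")
spine <- read.csv("results/cohort/pet_counts.csv")

gm <- grip_metrics(grip, from_week = 6, threshold = 100)
write.csv(gm, "results/grip_metrics.csv", row.names = FALSE)

irr <- gm[gm$group == "irradiated", ]
ctl <- gm[gm$group == "control", ]
message(sprintf(
  "median grip strength: control %.1f +/- %.1f, irradiated %.1f +/- %.1f (SE of median)",
  median(ctl$median_strength), se_median(ctl$median_strength),
  median(irr$median_strength), se_median(irr$median_strength)))

mood <- mood_median_test(ctl$median_strength, irr$median_strength)
mw <- mann_whitney(irr$frac_below, ctl$frac_below)
message(sprintf("Mood's median test p = %.4g; Mann-Whitney (frac below) p = %.4g",
                mood$p_value, mw$p_value))

sf <- spine_fraction(spine$spine_counts, spine$total_counts)
irr <- irr[match(spine$animal_id, irr$animal_id), ]
c1 <- pearson_corr(sf, irr$median_strength)
c2 <- pearson_corr(sf, irr$frac_below)
message(sprintf("spine fraction vs median strength: r = %.3f (95%% CI %.3f..%.3f), p = %.4g",
                c1$r, c1$ci95[1], c1$ci95[2], c1$p_value))
message(sprintf("spine fraction vs deficit fraction: r = %.3f, p = %.4g",
                c2$r, c2$p_value))

write_report_json(list(mood_p = mood$p_value, mann_whitney_p = mw$p_value,
                       r_strength = c1$r, r_frac_below = c2$r),
                  "results/toxicity.json")
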