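test_that("generators are fully deterministic given the spec seed", {
  spec <- cohort_spec(seed = 42)
  a <- gen_washout_series(spec, "5"); b <- gen_washout_series(spec, "5")
  expect_identical(a, b)
  expect_identical(gen_growth(spec), gen_growth(spec))
  expect_identical(gen_grip(spec), gen_grip(spec))
  other <- gen_washout_series(cohort_spec(seed = 43), "5")
  expect_false(identical(a[[1]]$values, other[[1]]$values))
  # generation does not disturb the caller's RNG stream
  set.seed(1); r1 <- stats::runif(1)
  set.seed(1); invisible(gen_washout_series(spec, "20")); r2 <- stats::runif(1)
  expect_identical(r1, r2)
})

test_that("noise-free washout series are exact model curves with the group contrast", {
  spec <- cohort_spec(seed = 3)
  s5 <- gen_washout_series(spec, "5", noise = "none")
  expect_length(s5, spec$n_low)
  tr <- attr(s5[[1]], "truth")
  expect_equal(s5[[1]]$values,
               washout_activity(tr, spec$mixture, s5[[1]]$times),
               tolerance = 1e-12)
  expect_equal(tr$Ws, 0.5)
  s20 <- gen_washout_series(spec, "20", noise = "none")
  expect_equal(attr(s20[[1]], "truth")$Ws, 0.95)
})

test_that("fitted washout parameters reproduce the dose contrast through the pipeline", {
  spec <- cohort_spec(seed = 9)
  mix <- spec$mixture
  fits5 <- lapply(gen_washout_series(spec, "5"), fit_washout_auto, mix = mix)
  fits20 <- lapply(gen_washout_series(spec, "20"), fit_washout_auto, mix = mix)
  # low dose: fast component detected in (nearly) every animal
  chose5 <- vapply(fits5, function(f) f$selection$chosen, character(1))
  expect_gte(mean(chose5 == "double"), 0.9)
  # fitted slow-weight ordering matches the generating contrast
  ws5 <- stats::median(vapply(fits5, function(f) f$fit2$params$Ws, numeric(1)))
  ws20 <- stats::median(vapply(fits20, function(f) f$fit2$params$Ws, numeric(1)))
  expect_gt(ws20, ws5)
})

test_that("synthetic volumes are separable and carry detectable range shifts", {
  spec <- cohort_spec(seed = 5)
  vols <- gen_volumes(spec, spacing = c(1, 1, 0.2), extent_xy = c(8, 6))
  # separability: the BEV profile matches the generating depth profile
  prof <- normalize_max(bev_profile(vols$dose))
  ref <- normalize_max(vols$sobp$profile)
  # compare on the same grid (volume z-grid equals profile grid here)
  expect_equal(prof$values, ref$values, tolerance = 1e-9)
  # injected 2 mm shift is recovered by the peak metric
  sh <- gen_volumes(spec, spacing = c(1, 1, 0.2), extent_xy = c(8, 6),
                    activity_shift_mm = 2)
  d <- range_shift(normalize_max(bev_profile(sh$activity)),
                   normalize_max(bev_profile(vols$activity)), "peak")
  expect_equal(d, 2, tolerance = 0.1)
  # default pair: activity peak sits at the 80% dose fall-off
  gap <- peak_depth(normalize_max(bev_profile(vols$activity))) -
    distal_falloff_depth(prof, 0.8)
  expect_lte(abs(gap), 0.5)
})

test_that("growth cohort encodes control growth, high-dose control and low-dose recurrence", {
  spec <- cohort_spec(seed = 21)
  tab <- gen_growth(spec, noise = "none")
  ctl <- tab[tab$group == "0" & tab$animal_id == tab$animal_id[1], ]
  g <- spec$growth
  expect_equal(ctl$volume_mm3 / ctl$volume_mm3[1],
               exp(g$growth_rate * ctl$day), tolerance = 1e-9)
  # every high-dose animal regresses below its initial volume
  for (id in unique(tab$animal_id[tab$group == "20"])) {
    v <- tab$volume_mm3[tab$animal_id == id]
    expect_lt(v[length(v)], v[1])
  }
  # low-dose group mean has its minimum at the regrowth day
  noisy <- gen_growth(spec)
  s <- growth_summary(noisy)
  s5 <- s[s$group == "5", ]
  expect_equal(s5$day[which.min(s5$mean_volume)], g$regrowth_day)
  # controls that reach the burden limit are censored (shorter follow-up)
  n_per_animal <- table(tab$animal_id[tab$group == "0"])
  expect_true(any(n_per_animal < length(unique(tab$day))))
  for (id in names(n_per_animal)) {
    d <- tab[tab$animal_id == id, ]
    before_last <- utils::head(d, -1)
    expect_true(all(pmax(before_last$a_mm, before_last$b_mm) <
                      g$burden_limit_mm))
  }
})

test_that("grip generator yields the injected deficit and spine correlation", {
  spec <- cohort_spec(seed = 17)
  gg <- gen_grip(spec)
  gm <- grip_metrics(gg$grip)
  irr <- gm[gm$group == "irradiated", ]
  ctl <- gm[gm$group == "control", ]
  expect_lt(stats::median(irr$median_strength),
            stats::median(ctl$median_strength))
  sf <- spine_fraction(gg$spine$spine_counts, gg$spine$total_counts)
  irr <- irr[match(gg$spine$animal_id, irr$animal_id), ]
  expect_lt(pearson_corr(sf, irr$median_strength)$r, 0)

  # zero toxicity slope: no systematic group difference
  flat <- gen_grip(spec, slope = 0)
  gmf <- grip_metrics(flat$grip)
  diff_means <- abs(mean(gmf$median_strength[gmf$group == "irradiated"]) -
                      mean(gmf$median_strength[gmf$group == "control"]))
  expect_lt(diff_means, 3 * spec$grip$noise_sd)
})

test_that("toxicity effect is detectable across seeds at the default effect size", {
  neg <- 0; mood_sig <- 0
  n_seeds <- 20
  for (seed in seq_len(n_seeds)) {
    spec <- cohort_spec(seed = seed)
    gg <- gen_grip(spec)
    gm <- grip_metrics(gg$grip)
    irr <- gm[gm$group == "irradiated", ]
    ctl <- gm[gm$group == "control", ]
    sf <- spine_fraction(gg$spine$spine_counts, gg$spine$total_counts)
    irr <- irr[match(gg$spine$animal_id, irr$animal_id), ]
    if (pearson_corr(sf, irr$median_strength)$r < 0) neg <- neg + 1
    if (mood_median_test(ctl$median_strength,
                         irr$median_strength)$p_value < 0.05)
      mood_sig <- mood_sig + 1
  }
  expect_gte(neg / n_seeds, 0.95)
  expect_gte(mood_sig / n_seeds, 0.8)
})
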