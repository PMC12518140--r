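#' Synthetic preclinical cohort generator
#'
#' Seeded generator for every input the analysis pipeline consumes:
#' post-irradiation time-activity series with dose-dependent washout,
#' separable 3D dose/activity volumes, caliper tumour-growth tables with
#' burden-limit censoring, and grip-strength records correlated with spine
#' PET counts. All randomness derives from the seed in the spec; identical
#' specs give byte-identical outputs.
#'
#' The true washout parameters are NOT literature estimates: they are
#' chosen to encode the qualitative dose contrast (a prominent fast
#' component at low dose that disappears at high dose) and are recorded in
#' the spec so estimator consistency can be checked against them.
#'
#' @name synthetic-cohort
NULL

#' Cohort specification
#'
#' @param seed Integer seed; all generator output is a deterministic
#'   function of the spec including this seed.
#' @param n_control,n_low,n_high Animals per dose group (0 / 5 / 20 Gy arm
#'   of the washout study).
#' @param washout_truth Named list (`"5"`, `"20"`) of
#'   [bio_washout_params()]: the group-level true washout parameters.
#' @param washout_jitter_cv Lognormal coefficient of variation applied
#'   per animal to the true `ks` and `kf`.
#' @param A0 True activity (counts/bin) at end of irradiation.
#' @param bin_width,t_total Sampling bin width and total follow-up, s.
#' @param mixture [decay_mixture()] of the implanted emitters.
#' @param beam [beam_config()] used for volume generation.
#' @param growth List of tumour-growth parameters: `v0_mm3`,
#'   `v0_cv`, `growth_rate` (1/day, controls), `regression_rate` (1/day,
#'   irradiated), `regrowth_day` and `regrowth_rate` (low dose),
#'   `caliper_cv`, `burden_limit_mm`.
#' @param grip List of grip/toxicity parameters: `n_control`,
#'   `n_irradiated`, `baseline`, `slope` (force units per unit spine
#'   fraction), `noise_sd`, `spine_frac_meanlog`, `spine_frac_sdlog`,
#'   `total_counts`, `weeks`.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(seed = 1L,
                        n_control = 27L, n_low = 7L, n_high = 8L,
                        washout_truth = list(
                          "5"  = bio_washout_params(5e4, Ws = 0.5,
                                                    ks = 3e-4, kf = 5e-3),
                          "20" = bio_washout_params(5e4, Ws = 0.95,
                                                    ks = 3e-4, kf = 5e-3)),
                        washout_jitter_cv = 0.2,
                        A0 = 5e4, bin_width = 60, t_total = 1800,
                        mixture = c11_beam_mixture(),
                        beam = beam_config(),
                        growth = list(v0_mm3 = 60, v0_cv = 0.3,
                                      growth_rate = 0.2,
                                      regression_rate = 0.1,
                                      regrowth_day = 14,
                                      regrowth_rate = 0.12,
                                      caliper_cv = 0.1,
                                      burden_limit_mm = 15),
                        grip = list(n_control = 8L, n_irradiated = 13L,
                                    baseline = 120, slope = 600,
                                    noise_sd = 10,
                                    spine_frac_meanlog = log(0.04),
                                    spine_frac_sdlog = 0.4,
                                    total_counts = 1e6,
                                    weeks = seq(2, 26, by = 2))) {
  stopifnot(n_control >= 1, n_low >= 1, n_high >= 1)
  structure(list(
    seed = as.integer(seed), n_control = n_control, n_low = n_low,
    n_high = n_high, washout_truth = washout_truth,
    washout_jitter_cv = washout_jitter_cv, A0 = A0,
    bin_width = bin_width, t_total = t_total, mixture = mixture,
    beam = beam, growth = growth, grip = grip
  ), class = "cohort_spec")
}

# run a block with a deterministic sub-seed without disturbing the
# caller's RNG state
with_spec_seed <- function(spec, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((spec$seed + offset) %% .Machine$integer.max)
  force(code)
}

#' Generate post-irradiation washout series for a dose group
#'
#' Each animal gets per-animal lognormal jitter on the true `ks` and `kf`,
#' the full decay-times-washout model evaluated at the bin centres, and
#' Poisson counting noise (`noise = "none"` gives the exact curves).
#'
#' @param spec A [cohort_spec()].
#' @param group `"5"` or `"20"` (Gy).
#' @param noise `"poisson"` or `"none"`.
#' @return List of [time_activity_series()], one per animal, each with an
#'   attribute `truth` holding that animal's [bio_washout_params()].
#' @export
gen_washout_series <- function(spec, group = c("5", "20"),
                               noise = c("poisson", "none")) {
  group <- match.arg(group); noise <- match.arg(noise)
  stopifnot(inherits(spec, "cohort_spec"))
  truth <- spec$washout_truth[[group]]
  n <- if (group == "5") spec$n_low else spec$n_high
  times <- seq(spec$bin_width / 2, spec$t_total - spec$bin_width / 2,
               by = spec$bin_width)
  cv <- spec$washout_jitter_cv
  sdl <- sqrt(log(1 + cv^2))
  with_spec_seed(spec, offset = if (group == "5") 101L else 102L, {
    lapply(seq_len(n), function(i) {
      ks_i <- truth$ks * stats::rlnorm(1, -sdl^2 / 2, sdl)
      kf_i <- truth$kf * stats::rlnorm(1, -sdl^2 / 2, sdl)
      if (ks_i > kf_i) { tmp <- ks_i; ks_i <- kf_i; kf_i <- tmp }
      p_i <- bio_washout_params(spec$A0, truth$Ws, ks_i, kf_i)
      mu <- washout_activity(p_i, spec$mixture, times)
      vals <- if (noise == "poisson") stats::rpois(length(mu), mu) else mu
      s <- time_activity_series(times, vals, bin_width = spec$bin_width)
      attr(s, "truth") <- p_i
      attr(s, "animal_id") <- sprintf("%sGy_%02d", group, i)
      s
    })
  })
}

#' Generate matched 3D dose and activity volumes
#'
#' Separable fields: the SOBP dose (resp. implanted-activity) depth profile
#' times transverse Gaussians with the beam-spot FWHMs. Optional Poisson
#' noise emulates counting statistics in the activity map.
#'
#' @param spec A [cohort_spec()].
#' @param modulation SOBP modulation width, mm.
#' @param spacing Voxel spacing (x, y, z), mm.
#' @param extent_xy Half-extent of the transverse grid (x, y), mm.
#' @param noise `"none"` or `"poisson"` (applied to the activity volume,
#'   scaled so the peak voxel has mean `peak_counts`).
#' @param peak_counts Mean counts in the hottest activity voxel when
#'   `noise = "poisson"`.
#' @param activity_shift_mm Rigid shift applied to the activity depth
#'   profile (emulates a range discrepancy to be detected).
#' @return List with `dose` and `activity` ([volume3d()]), the underlying
#'   `sobp` solution and `activity_profile`.
#' @export
gen_volumes <- function(spec, modulation = 12, spacing = c(0.5, 0.5, 0.1),
                        extent_xy = c(15, 10), noise = c("none", "poisson"),
                        peak_counts = 1e3, activity_shift_mm = 0) {
  noise <- match.arg(noise)
  stopifnot(inherits(spec, "cohort_spec"))
  cfg <- spec$beam
  depths <- seq(0, cfg$range_mm * 1.15, by = spacing[3])
  sobp <- build_sobp(cfg, depths, modulation)
  act <- implanted_activity_profile(cfg, depths, ranges = sobp$ranges,
                                    weights = sobp$weights)
  act_vals <- act$values
  if (activity_shift_mm != 0) {
    k <- round(activity_shift_mm / spacing[3])
    act_vals <- if (k >= 0) c(numeric(k), utils::head(act_vals, -k))
    else c(utils::tail(act_vals, k), numeric(-k))
  }
  x <- seq(-extent_xy[1], extent_xy[1], by = spacing[1])
  y <- seq(-extent_xy[2], extent_xy[2], by = spacing[2])
  gx <- stats::dnorm(x, 0, cfg$spot_fwhm_x / 2.3548)
  gy <- stats::dnorm(y, 0, cfg$spot_fwhm_y / 2.3548)
  sep_volume <- function(prof_z) {
    v <- outer(gx, gy) %o% prof_z
    volume3d(v, spacing, origin = c(-extent_xy[1], -extent_xy[2], 0))
  }
  dose_vol <- sep_volume(sobp$profile$values)
  act_arr <- outer(gx, gy) %o% act_vals
  act_arr <- act_arr / max(act_arr) * peak_counts
  if (noise == "poisson")
    act_arr <- with_spec_seed(spec, 201L, {
      array(stats::rpois(length(act_arr), act_arr), dim = dim(act_arr))
    })
  act_vol <- volume3d(act_arr, spacing,
                      origin = c(-extent_xy[1], -extent_xy[2], 0))
  list(dose = dose_vol, activity = act_vol, sobp = sobp,
       activity_profile = depth_profile(depths, pmax(act_vals, 0)))
}

# deterministic per-animal growth curve, mm^3
growth_curve <- function(days, group, v0, g) {
  switch(group,
    "0"  = v0 * exp(g$growth_rate * days),
    "5"  = ifelse(days <= g$regrowth_day,
                  v0 * exp(-g$regression_rate * days),
                  v0 * exp(-g$regression_rate * g$regrowth_day) *
                    exp(g$regrowth_rate * (days - g$regrowth_day))),
    "20" = v0 * exp(-g$regression_rate * days),
    stop("unknown group"))
}

#' Generate the tumour-growth cohort table
#'
#' Controls grow exponentially; the high-dose group regresses
#' monotonically; the low-dose group regresses then regrows from
#' `regrowth_day`. Caliper length/width are back-computed from the true
#' volume (assuming a = b) with multiplicative lognormal measurement
#' noise, and animals are censored once the measured diameter reaches the
#' burden limit (their later timepoints are removed).
#'
#' @param spec A [cohort_spec()].
#' @param days Measurement days (default twice weekly for 28 days).
#' @param noise `"lognormal"` or `"none"`.
#' @return Data frame with `animal_id`, `group`, `day`, `a_mm`, `b_mm`,
#'   `volume_mm3` and attribute `truth` (per-animal `v0`).
#' @export
gen_growth <- function(spec, days = seq(0, 28, by = 3.5),
                       noise = c("lognormal", "none")) {
  noise <- match.arg(noise)
  stopifnot(inherits(spec, "cohort_spec"))
  g <- spec$growth
  groups <- c(rep("0", spec$n_control), rep("5", spec$n_low),
              rep("20", spec$n_high))
  sdl_v0 <- sqrt(log(1 + g$v0_cv^2))
  sdl_cal <- sqrt(log(1 + g$caliper_cv^2))
  with_spec_seed(spec, 301L, {
    rows <- lapply(seq_along(groups), function(i) {
      grp <- groups[i]
      v0 <- g$v0_mm3 * stats::rlnorm(1, -sdl_v0^2 / 2, sdl_v0)
      vol <- growth_curve(days, grp, v0, g)
      a_true <- (3 * vol / (4 * pi))^(1 / 3)
      noise_a <- if (noise == "lognormal")
        stats::rlnorm(length(days), -sdl_cal^2 / 2, sdl_cal) else 1
      noise_b <- if (noise == "lognormal")
        stats::rlnorm(length(days), -sdl_cal^2 / 2, sdl_cal) else 1
      a <- a_true * noise_a; b <- a_true * noise_b
      d <- data.frame(animal_id = sprintf("%sGy_g%02d", grp, i),
                      group = grp, day = days, a_mm = a, b_mm = b,
                      volume_mm3 = ellipsoid_volume(a, b))
      hit <- which(pmax(a, b) >= g$burden_limit_mm)
      if (length(hit)) d <- d[seq_len(min(hit)), , drop = FALSE]
      attr(d, "v0") <- v0
      d
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- vapply(rows, attr, numeric(1), "v0")
    out
  })
}

#' Generate grip-strength records and spine PET counts
#'
#' Each irradiated animal draws a lognormal spine-count fraction; its grip
#' peak force at every timepoint is `baseline - slope * spine_fraction`
#' plus Gaussian noise. Controls share the baseline with no deficit and no
#' spine activity record.
#'
#' @param spec A [cohort_spec()].
#' @param slope Overrides the spec's toxicity slope (force units per unit
#'   spine fraction); `NULL` keeps the spec value.
#' @return List with `grip` (data frame: `animal_id`, `group`, `week`,
#'   `peak_force`) and `spine` (data frame: `animal_id`, `spine_counts`,
#'   `total_counts`).
#' @export
gen_grip <- function(spec, slope = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  gp <- spec$grip
  if (!is.null(slope)) gp$slope <- slope
  with_spec_seed(spec, 401L, {
    spine_frac <- stats::rlnorm(gp$n_irradiated, gp$spine_frac_meanlog,
                                gp$spine_frac_sdlog)
    spine_frac <- pmin(spine_frac, 1)
    ids_irr <- sprintf("irr_%02d", seq_len(gp$n_irradiated))
    ids_ctl <- sprintf("ctl_%02d", seq_len(gp$n_control))
    grip_rows <- list()
    for (i in seq_len(gp$n_control)) {
      f <- gp$baseline + stats::rnorm(length(gp$weeks), 0, gp$noise_sd)
      grip_rows[[length(grip_rows) + 1L]] <- data.frame(
        animal_id = ids_ctl[i], group = "control", week = gp$weeks,
        peak_force = pmax(f, 0))
    }
    for (i in seq_len(gp$n_irradiated)) {
      f <- gp$baseline - gp$slope * spine_frac[i] +
        stats::rnorm(length(gp$weeks), 0, gp$noise_sd)
      grip_rows[[length(grip_rows) + 1L]] <- data.frame(
        animal_id = ids_irr[i], group = "irradiated", week = gp$weeks,
        peak_force = pmax(f, 0))
    }
    total <- stats::rpois(gp$n_irradiated, gp$total_counts)
    spine <- data.frame(animal_id = ids_irr,
                        spine_counts = round(spine_frac * total),
                        total_counts = total)
    grip <- do.call(rbind, grip_rows)
    rownames(grip) <- NULL
    list(grip = grip, spine = spine)
  })
}
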