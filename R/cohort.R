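#' Tumour growth and toxicity statistics
#'
#' Caliper-based ellipsoid tumour volumetrics with group summaries, and the
#' grip-strength toxicity analysis linking PET counts in the spinal cord to
#' forelimb performance.
#'
#' @name cohort-stats
NULL

#' Ellipsoid tumour volume from caliper length and width
#'
#' \deqn{V = \frac{4}{3}\pi \, a \, b \, c, \qquad c = (a+b)/2}
#' with `a` the measured length and `b` the width; the unmeasured depth `c`
#' is taken as their average. The formula uses the caliper readings
#' directly (no conversion to semi-axes), as is conventional for this
#' volumetric index.
#'
#' @param a,b Caliper length and width in mm (nonnegative, vectorized).
#' @return Volume in mm^3.
#' @export
#' @examples
#' ellipsoid_volume(1, 1)  # 4*pi/3
ellipsoid_volume <- function(a, b) {
  if (any(a < 0) || any(b < 0)) stop("caliper measurements must be nonnegative")
  (4 / 3) * pi * a * b * (a + b) / 2
}

#' Per-group tumour volume summary over time
#'
#' Group mean volume and standard error of the mean at each study day.
#' Animals censored earlier (euthanized at the burden limit) simply drop
#' out of later timepoints; no imputation is performed. A group-day with a
#' single animal gets `sem = NA` and is flagged.
#'
#' @param cohort Data frame with columns `animal_id`, `group`, `day`,
#'   `volume_mm3`.
#' @return Data frame with `group`, `day`, `n`, `mean_volume`, `sem`,
#'   `single_animal`.
#' @export
growth_summary <- function(cohort) {
  need <- c("animal_id", "group", "day", "volume_mm3")
  if (!all(need %in% names(cohort)))
    stop("cohort must have columns ", paste(need, collapse = ", "))
  if (nrow(cohort) == 0) stop("empty cohort")
  agg <- do.call(rbind, lapply(
    split(cohort, list(cohort$group, cohort$day), drop = TRUE),
    function(d) {
      n <- nrow(d)
      data.frame(group = d$group[1], day = d$day[1], n = n,
                 mean_volume = mean(d$volume_mm3),
                 sem = if (n > 1) stats::sd(d$volume_mm3) / sqrt(n) else NA_real_,
                 single_animal = n == 1L)
    }))
  agg <- agg[order(agg$group, agg$day), ]
  rownames(agg) <- NULL
  agg
}

#' Standard error of the median
#'
#' Asymptotic normal-theory estimate `1.2533 * s / sqrt(n)`, where
#' `1.2533 = sqrt(pi/2)` is the efficiency factor of the median relative
#' to the mean.
#'
#' @param values Numeric vector, n >= 2.
#' @return Scalar standard error.
#' @export
se_median <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  sqrt(pi / 2) * stats::sd(values) / sqrt(n)
}

#' Per-animal grip-strength metrics
#'
#' Median peak force over the analysis window (weeks >= `from_week`,
#' excluding the early post-irradiation period where no radiation effect is
#' assumed) and the fraction of timepoints below a deficit threshold.
#' Forces are kept in as-recorded instrument units.
#'
#' @param records Data frame with columns `animal_id`, `week`,
#'   `peak_force` (and optionally `group`).
#' @param from_week First week included (default 6).
#' @param threshold Deficit threshold in as-recorded force units
#'   (default 100).
#' @return Data frame with `animal_id`, `n_timepoints`, `median_strength`,
#'   `frac_below` (plus `group` if present in the input).
#' @export
grip_metrics <- function(records, from_week = 6, threshold = 100) {
  need <- c("animal_id", "week", "peak_force")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  rec <- records[records$week >= from_week, , drop = FALSE]
  if (nrow(rec) == 0) stop("no records at or after from_week")
  out <- do.call(rbind, lapply(split(rec, rec$animal_id), function(d) {
    res <- data.frame(animal_id = d$animal_id[1],
                      n_timepoints = nrow(d),
                      median_strength = stats::median(d$peak_force),
                      frac_below = mean(d$peak_force < threshold))
    if ("group" %in% names(d)) res$group <- d$group[1]
    res
  }))
  rownames(out) <- NULL
  out
}

#' Mood's median test
#'
#' Two-sample test of equal medians: counts of observations above the
#' pooled median form a 2x2 table tested by Pearson's chi-square (without
#' continuity correction). Observations equal to the pooled median are
#' counted as "not above".
#'
#' @param a,b Numeric samples.
#' @return List with `statistic`, `p_value`, `table`, `degenerate` (TRUE
#'   when a margin is empty, in which case `p_value = 1`).
#' @export
mood_median_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 values")
  m <- stats::median(c(a, b))
  tab <- rbind(a = c(above = sum(a > m), not_above = sum(a <= m)),
               b = c(above = sum(b > m), not_above = sum(b <= m)))
  if (any(colSums(tab) == 0))
    return(list(statistic = 0, p_value = 1, table = tab, degenerate = TRUE))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       table = tab, degenerate = FALSE)
}

#' Mann-Whitney U test
#'
#' Wilcoxon rank-sum test reported on the U scale; exact p-value for small
#' tie-free samples, normal approximation otherwise (the default behaviour
#' of [stats::wilcox.test()]).
#'
#' @param a,b Numeric samples.
#' @return List with `U`, `p_value`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) stop("both samples must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y Paired numeric vectors (n >= 3 for the CI).
#' @return List with `r`, `p_value`, `ci95` (length 2), `degenerate`
#'   (TRUE when either variable is constant; then `r` is `NA`).
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  if (length(x) < 3L) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_,
                ci95 = c(NA_real_, NA_real_), degenerate = TRUE))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       ci95 = as.numeric(ct$conf.int), degenerate = FALSE)
}

#' Fraction of PET counts in the spinal cord
#'
#' @param spine_counts Counts in the spinal-cord region.
#' @param total_counts Counts in the whole image (> 0);
#'   `spine_counts <= total_counts`.
#' @return Dimensionless fraction in \[0, 1\] (vectorized).
#' @export
spine_fraction <- function(spine_counts, total_counts) {
  if (any(total_counts <= 0)) stop("total_counts must be positive")
  if (any(spine_counts < 0) || any(spine_counts > total_counts))
    stop("need 0 <= spine_counts <= total_counts")
  spine_counts / total_counts
}
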