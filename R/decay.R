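#' Positron-emitter decay mixtures
#'
#' A C-11 ion beam implants a mixture of positron emitters in tissue: the
#' projectile itself plus short-lived fragments produced during irradiation.
#' The total physical decay factor is a fraction-weighted sum of exponentials,
#' one term per isotope.
#'
#' @name decay-mixture
NULL

#' Construct a single isotope
#'
#' @param name Text label, e.g. `"11C"`.
#' @param half_life_s Half-life in seconds; must be positive.
#' @param fraction Nonnegative weight of this isotope in the implanted
#'   fragment mixture.
#' @return An object of class `isotope`.
#' @export
isotope <- function(name, half_life_s, fraction) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(half_life_s) || half_life_s <= 0)
    stop("half_life_s must be positive and finite")
  if (!is.finite(fraction) || fraction < 0)
    stop("fraction must be nonnegative")
  structure(
    list(name = name, half_life_s = half_life_s, fraction = fraction),
    class = "isotope"
  )
}

#' Construct a decay mixture
#'
#' Fractions are renormalized to sum to exactly 1 at construction; the raw
#' input weights are retained in the `raw_fractions` attribute.
#'
#' @param isotopes List of [isotope()] objects, at least one.
#' @return An object of class `decay_mixture`: a data frame with columns
#'   `name`, `half_life_s`, `fraction`.
#' @export
decay_mixture <- function(isotopes) {
  if (length(isotopes) < 1L) stop("at least one isotope is required")
  stopifnot(all(vapply(isotopes, inherits, logical(1), "isotope")))
  raw <- vapply(isotopes, `[[`, numeric(1), "fraction")
  if (sum(raw) <= 0) stop("fractions must not all be zero")
  mix <- data.frame(
    name        = vapply(isotopes, `[[`, character(1), "name"),
    half_life_s = vapply(isotopes, `[[`, numeric(1), "half_life_s"),
    fraction    = raw / sum(raw),
    stringsAsFactors = FALSE
  )
  structure(mix, raw_fractions = raw,
            class = c("decay_mixture", "data.frame"))
}

#' The C-11 beam positron-emitter mixture
#'
#' Default mixture implanted by a C-11 ion beam in tissue: 96% 11C
#' (T1/2 = 20.34 min), 3% 10C (T1/2 = 19 s) from projectile fragmentation,
#' and 0.5% 15O (T1/2 = 2.04 min) from target fragmentation. The printed
#' weights sum to 0.995 and are renormalized to 1.
#'
#' @return A [decay_mixture()] with three isotopes.
#' @export
#' @examples
#' m <- c11_beam_mixture()
#' fraction_remaining(m, 60)
c11_beam_mixture <- function() {
  decay_mixture(list(
    isotope("11C", 20.34 * 60, 0.96),
    isotope("10C", 19,         0.03),
    isotope("15O", 2.04 * 60,  0.005)
  ))
}

#' Pure single-isotope mixture
#'
#' Convenience constructor, mostly for tests and decay-correction of a
#' signal dominated by one emitter.
#'
#' @inheritParams isotope
#' @return A [decay_mixture()] with one isotope of fraction 1.
#' @export
pure_mixture <- function(name = "11C", half_life_s = 20.34 * 60) {
  decay_mixture(list(isotope(name, half_life_s, 1)))
}

#' Fraction of initial activity remaining after physical decay
#'
#' Evaluates the weighted multi-exponential physical decay factor
#' \deqn{f(t) = \sum_i w_i \, 2^{-t/T_{1/2,i}}}
#' Equals 1 at `t = 0` and decreases strictly with `t`.
#'
#' @param mix A [decay_mixture()].
#' @param t Time(s) since end of irradiation, in seconds; nonnegative,
#'   vectorized.
#' @return Numeric vector in (0, 1], same length as `t`.
#' @export
fraction_remaining <- function(mix, t) {
  stopifnot(inherits(mix, "decay_mixture"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be nonnegative")
  vapply(t, function(ti) sum(mix$fraction * 2^(-ti / mix$half_life_s)),
         numeric(1))
}

#' Time-activity series
#'
#' Sampled activity (or counts per bin) versus time. Units are arbitrary:
#' no absolute Bq calibration is attempted because it depends on the
#' reconstruction chain.
#'
#' @param times Strictly increasing times in seconds.
#' @param values Nonnegative activities/counts, same length as `times`.
#' @param bin_width Sampling bin width in seconds.
#' @param t_zero One of `"end_of_irradiation"` or `"start_of_irradiation"`:
#'   what `t = 0` refers to.
#' @return An object of class `time_activity_series`.
#' @export
time_activity_series <- function(times, values, bin_width = NA_real_,
                                 t_zero = c("end_of_irradiation",
                                            "start_of_irradiation")) {
  t_zero <- match.arg(t_zero)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) < 1L) stop("series must be non-empty")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("times must be finite and strictly increasing")
  if (any(!is.finite(values)) || any(values < 0))
    stop("values must be finite and nonnegative")
  structure(
    list(times = times, values = values, bin_width = bin_width,
         t_zero = t_zero),
    class = "time_activity_series"
  )
}

#' @export
print.time_activity_series <- function(x, ...) {
  cat(sprintf("<time_activity_series> %d points, t in [%.6g, %.6g] s (t0 = %s)\n",
              length(x$times), min(x$times), max(x$times), x$t_zero))
  invisible(x)
}

#' @export
as.data.frame.time_activity_series <- function(x, ...) {
  data.frame(t_s = x$times, value = x$values)
}

#' Correct a time-activity series for physical decay
#'
#' Divides the measured values element-wise by [fraction_remaining()], so a
#' series generated by pure physical decay becomes constant and what remains
#' is the biological washout factor.
#'
#' @param series A [time_activity_series()] with
#'   `t_zero = "end_of_irradiation"`.
#' @param mix A [decay_mixture()].
#' @param min_fraction Underflow guard: if the decay factor falls below this
#'   at any sampled time (all half-lives long exceeded), the correction is
#'   refused rather than dividing by a vanishing number.
#' @return A decay-corrected [time_activity_series()].
#' @export
decay_correct <- function(series, mix, min_fraction = 1e-12) {
  stopifnot(inherits(series, "time_activity_series"))
  if (series$t_zero != "end_of_irradiation")
    stop("decay_correct expects t = 0 at the end of irradiation")
  f <- fraction_remaining(mix, series$times)
  if (any(f < min_fraction))
    stop("physical decay factor underflow: times far exceed all half-lives")
  time_activity_series(series$times, series$values / f,
                       bin_width = series$bin_width, t_zero = series$t_zero)
}
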