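#' Biological washout kinetics
#'
#' After irradiation with a C-11 beam, the measured PET activity decreases
#' both by physical decay of the implanted emitters and by biological
#' washout — removal of the emitters from the irradiated site by perfusion.
#' The model is the product
#' \deqn{A(t) = A_0 \sum_i w_i 2^{-t/T_{1/2,i}} \times
#'       [W_s e^{-k_s t} + (1-W_s) e^{-k_f t}]}
#' with a slow (`ks`) and a fast (`kf`) washout component weighted by `Ws`.
#' A single-component model (`Ws = 1`) is nested inside the two-component
#' one, so the need for the fast component is decided by an F-test.
#'
#' @name washout-kinetics
NULL

#' Evaluate the washout activity model
#'
#' @param p List with elements `A0`, `Ws`, `ks`, `kf`, `n_components` (1 or
#'   2); see [bio_washout_params()].
#' @param mix A [decay_mixture()] giving the physical decay factor.
#' @param t Time(s) since end of irradiation, seconds; vectorized.
#' @return Activity at `t`, same units as `A0`.
#' @export
washout_activity <- function(p, mix, t) {
  p <- bio_washout_params(p$A0, p$Ws, p$ks, p$kf, p$n_components)
  p$A0 * fraction_remaining(mix, t) * bio_factor(p, t)
}

#' Validated washout parameter set
#'
#' @param A0 Activity at end of irradiation (> 0, arbitrary units).
#' @param Ws Weight of the slow component, in \[0, 1\].
#' @param ks Slow rate constant, 1/s.
#' @param kf Fast rate constant, 1/s; `ks <= kf`.
#' @param n_components 1 or 2. With 1 component `Ws` is forced to 1 and
#'   `kf` is unused.
#' @return A named list of class `bio_washout_params`.
#' @export
bio_washout_params <- function(A0, Ws = 1, ks, kf = ks, n_components = 2L) {
  n_components <- as.integer(n_components)
  stopifnot(n_components %in% c(1L, 2L))
  if (n_components == 1L) { Ws <- 1; kf <- ks }
  if (!is.finite(A0) || A0 <= 0) stop("A0 must be positive")
  if (!is.finite(Ws) || Ws < 0 || Ws > 1) stop("Ws must lie in [0, 1]")
  if (!is.finite(ks) || !is.finite(kf) || ks < 0 || kf < ks)
    stop("rate constants must satisfy 0 <= ks <= kf")
  structure(list(A0 = A0, Ws = Ws, ks = ks, kf = kf,
                 n_components = n_components),
            class = "bio_washout_params")
}

# biological factor only (physical decay divided out)
bio_factor <- function(p, t) {
  p$Ws * exp(-p$ks * t) + (1 - p$Ws) * exp(-p$kf * t)
}

#' Fit the washout model to a time-activity series
#'
#' Weighted least squares with Poisson-approximation weights
#' `1/max(value, 1)` (variance of a count is approximately its mean),
#' minimized by Levenberg–Marquardt with box bounds
#' `0 <= Ws <= 1`, `1e-8 <= ks, kf <= 1` 1/s. Initialization is a
#' deterministic multi-start grid (`ks` in \{1e-4, 1e-3\}, `kf` in
#' \{1e-2, 1e-1\}, `Ws` in \{0.3, 0.7\}; `A0` from the first observation);
#' the start with the best chi-square wins. After a two-component fit the
#' labels are sorted so that `ks <= kf` always holds.
#'
#' @param series A [time_activity_series()] with t = 0 at end of
#'   irradiation and positive values.
#' @param mix A [decay_mixture()].
#' @param n_components 1 (single exponential washout) or 2.
#' @param t_max Fit window: only points with `t <= t_max` seconds are used
#'   (default 1800 s, the first 30 min after exposure).
#' @return A list of class `washout_fit`: `params`
#'   ([bio_washout_params()]), `chi2`, `dof`, `n_free`, `param_se` (named,
#'   `NA` where the curvature is degenerate), `converged`, `n_points`.
#' @export
fit_washout <- function(series, mix, n_components = 2L, t_max = 1800) {
  stopifnot(inherits(series, "time_activity_series"))
  n_components <- as.integer(n_components)
  stopifnot(n_components %in% c(1L, 2L))
  keep <- series$times <= t_max
  t <- series$times[keep]; y <- series$values[keep]
  min_pts <- if (n_components == 1L) 8L else 12L
  if (length(t) < min_pts)
    stop(sprintf("need at least %d points for a %d-component fit",
                 min_pts, n_components))
  if (all(y == 0)) stop("all-zero series cannot be fitted")
  w <- 1 / pmax(y, 1)
  fphys <- fraction_remaining(mix, t)
  A0_start <- max(y[1] / fphys[1], .Machine$double.eps)

  lb_k <- 1e-8; ub_k <- 1
  if (n_components == 1L) {
    starts <- lapply(c(1e-5, 1e-4, 1e-3, 1e-2),
                     function(k) c(A0 = A0_start, ks = k))
    resid_fn <- function(par) {
      sqrt(w) * (y - par[["A0"]] * fphys * exp(-par[["ks"]] * t))
    }
    lower <- c(A0 = 1e-12, ks = lb_k); upper <- c(A0 = Inf, ks = ub_k)
  } else {
    grid <- expand.grid(ks = c(1e-4, 1e-3), kf = c(1e-2, 1e-1),
                        Ws = c(0.3, 0.7))
    starts <- lapply(seq_len(nrow(grid)), function(i) {
      c(A0 = A0_start, Ws = grid$Ws[i], ks = grid$ks[i], kf = grid$kf[i])
    })
    resid_fn <- function(par) {
      bio <- par[["Ws"]] * exp(-par[["ks"]] * t) +
        (1 - par[["Ws"]]) * exp(-par[["kf"]] * t)
      sqrt(w) * (y - par[["A0"]] * fphys * bio)
    }
    lower <- c(A0 = 1e-12, Ws = 0, ks = lb_k, kf = lb_k)
    upper <- c(A0 = Inf,   Ws = 1, ks = ub_k, kf = ub_k)
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all fit starts failed")

  par <- best$par
  se <- tryCatch({
    covm <- solve(best$hessian) * best$deviance /
      (length(t) - length(par))
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, length(par)))
  names(se) <- names(par)

  if (n_components == 2L && par[["ks"]] > par[["kf"]]) {
    par[c("ks", "kf")] <- par[c("kf", "ks")]
    se[c("ks", "kf")] <- se[c("kf", "ks")]
    par[["Ws"]] <- 1 - par[["Ws"]]
  }

  params <- if (n_components == 1L)
    bio_washout_params(par[["A0"]], 1, par[["ks"]], n_components = 1L)
  else
    bio_washout_params(par[["A0"]], par[["Ws"]], par[["ks"]], par[["kf"]],
                       n_components = 2L)
  n_free <- length(par)
  structure(list(
    params = params,
    chi2 = best$deviance,
    dof = length(t) - n_free,
    n_free = n_free,
    param_se = se,
    converged = best$info %in% 1:4,
    n_points = length(t)
  ), class = "washout_fit")
}

#' @export
print.washout_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<washout_fit> %d-component: A0 = %.4g, Ws = %.3f, ks = %.3e, kf = %.3e 1/s\n",
    p$n_components, p$A0, p$Ws, p$ks, p$kf))
  cat(sprintf("  chi2 = %.4g on %d d.o.f. (converged: %s)\n",
              x$chi2, x$dof, x$converged))
  invisible(x)
}

#' Nested F-test between single- and two-component washout fits
#'
#' Primary decision rule is the standard nested F-statistic
#' \deqn{F = \frac{(\chi^2_1 - \chi^2_2)/(p_2 - p_1)}{\chi^2_2/\mathrm{dof}_2}}
#' with p-value from the F distribution. The bare chi-square ratio
#' \eqn{\chi^2_1/\chi^2_2} is also reported, since it is sometimes quoted
#' as "the F-test" in the imaging literature but has no reference
#' distribution of its own.
#'
#' @param fit1 One-component [fit_washout()] result (restricted model).
#' @param fit2 Two-component fit of the same series (extended model).
#' @param alpha Significance level for preferring the two-component model.
#' @return List of class `washout_model_selection`: `F`, `p_value`,
#'   `chi2_ratio`, `df1`, `df2`, `chosen` (`"single"` or `"double"`),
#'   `convention = "nested_F"`.
#' @export
f_test <- function(fit1, fit2, alpha = 0.05) {
  stopifnot(inherits(fit1, "washout_fit"), inherits(fit2, "washout_fit"))
  if (fit1$params$n_components != 1L || fit2$params$n_components != 2L)
    stop("fit1 must be the 1-component fit, fit2 the 2-component fit")
  if (fit1$n_points != fit2$n_points)
    stop("fits must come from the same series (point counts differ)")
  if (fit2$dof <= 0) stop("extended model has no residual degrees of freedom")
  df1 <- fit2$n_free - fit1$n_free
  Fstat <- max(0, (fit1$chi2 - fit2$chi2) / df1 / (fit2$chi2 / fit2$dof))
  p <- stats::pf(Fstat, df1, fit2$dof, lower.tail = FALSE)
  structure(list(
    F = Fstat, p_value = p,
    chi2_ratio = fit1$chi2 / fit2$chi2,
    df1 = df1, df2 = fit2$dof,
    chosen = if (p < alpha) "double" else "single",
    convention = "nested_F"
  ), class = "washout_model_selection")
}

#' Fit both models and select by F-test
#'
#' @inheritParams fit_washout
#' @param alpha Significance level passed to [f_test()].
#' @return List with `fit1`, `fit2`, `selection` and `best` (the chosen
#'   fit).
#' @export
fit_washout_auto <- function(series, mix, t_max = 1800, alpha = 0.05) {
  f1 <- fit_washout(series, mix, 1L, t_max = t_max)
  f2 <- fit_washout(series, mix, 2L, t_max = t_max)
  sel <- f_test(f1, f2, alpha = alpha)
  list(fit1 = f1, fit2 = f2, selection = sel,
       best = if (sel$chosen == "double") f2 else f1)
}

#' Median/IQR outlier inclusion mask
#'
#' A value is excluded when it lies outside
#' `[median - 1.5 IQR, median + 1.5 IQR]`, with quartiles computed by
#' linear interpolation. Degenerate groups (IQR = 0) exclude nothing and
#' raise a warning.
#'
#' @param values Numeric vector, at least 4 values.
#' @return Logical inclusion mask (`TRUE` = keep), same length as `values`.
#' @export
detect_outliers <- function(values) {
  if (length(values) < 4L) stop("need at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  if (iqr == 0) {
    warning("IQR is zero; no values excluded")
    return(rep(TRUE, length(values)))
  }
  values >= q[2] - 1.5 * iqr & values <= q[2] + 1.5 * iqr
}

#' Two-sample pooled-variance t-test on fitted parameters
#'
#' Two-sided unpaired t-test assuming equal variances, applied per washout
#' parameter across dose groups. When the pooled variance is zero the test
#' is degenerate: equal means give `t = 0, p = 1`, unequal means are
#' flagged with `p = 0`.
#'
#' @param a,b Numeric vectors of parameter values, each of length >= 2.
#' @return List with `statistic`, `p_value`, `df`, `degenerate`.
#' @export
compare_groups <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, p_value = 1,
                  df = length(a) + length(b) - 2L, degenerate = TRUE))
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, p_value = 0,
                df = length(a) + length(b) - 2L, degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}
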