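# shared fixtures built in code

pure_c11 <- function() pure_mixture("11C", 20.34 * 60)

# exact model series on the standard sampling (60 s bins over 30 min)
model_series <- function(p, mix, times = seq(30, 1770, by = 60)) {
  time_activity_series(times, washout_activity(p, mix, times),
                       bin_width = 60)
}

poisson_series <- function(p, mix, times = seq(30, 1770, by = 60)) {
  mu <- washout_activity(p, mix, times)
  time_activity_series(times, stats::rpois(length(mu), mu), bin_width = 60)
}

# brute-force Mann-Whitney U and exact permutation p (two-sided), for
# tie-free samples with n + m small
mw_exact_oracle <- function(a, b) {
  U <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pooled), n)
  Us <- apply(idx, 2, function(i)
    sum(outer(pooled[i], pooled[-i], ">")) +
      0.5 * sum(outer(pooled[i], pooled[-i], "==")))
  mu <- length(a) * length(b) / 2
  p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
  list(U = U, p_value = p)
}

# brute-force triple-loop BEV profile
bev_oracle <- function(vol, center_xy, half_aperture) {
  dm <- dim(vol$voxels)
  x <- vol$origin[1] + (seq_len(dm[1]) - 1) * vol$spacing[1]
  y <- vol$origin[2] + (seq_len(dm[2]) - 1) * vol$spacing[2]
  out <- numeric(dm[3])
  for (k in seq_len(dm[3])) {
    s <- 0
    for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) {
      if (abs(x[i] - center_xy[1]) <= half_aperture &&
          abs(y[j] - center_xy[2]) <= half_aperture)
        s <- s + vol$voxels[i, j, k]
    }
    out[k] <- s
  }
  out
}
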