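#' Depth profile container
#'
#' Dose or activity versus water-equivalent depth along the beam axis, on a
#' strictly increasing uniform grid. Values are arbitrary units
#' (normalization is a separate, explicit step).
#'
#' @param depths Strictly increasing, uniformly spaced depths in mm.
#' @param values Nonnegative values, same length.
#' @return Object of class `depth_profile` with elements `depths`,
#'   `values`, `step`.
#' @export
depth_profile <- function(depths, values) {
  depths <- as.numeric(depths); values <- as.numeric(values)
  if (length(depths) != length(values))
    stop("depths and values must have equal length")
  if (length(depths) < 2L) stop("need at least two grid points")
  d <- diff(depths)
  if (any(d <= 0)) stop("depths must be strictly increasing")
  if (max(d) - min(d) > 1e-9 * mean(d)) stop("depth grid must be uniform")
  if (any(!is.finite(values)) || any(values < 0))
    stop("values must be finite and nonnegative")
  structure(list(depths = depths, values = values, step = mean(d)),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("<depth_profile> %d points, z in [%.6g, %.6g] mm (step %.4g)\n",
              length(x$depths), min(x$depths), max(x$depths), x$step))
  invisible(x)
}

#' @export
as.data.frame.depth_profile <- function(x, ...) {
  data.frame(depth_mm = x$depths, value = x$values)
}
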