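#' Range-verification metrics on dose/activity volumes
#'
#' The beam range is verified by comparing depth profiles of the planned
#' dose and the measured (or simulated) PET activity: 3D maps are summed
#' over a narrow beam's-eye-view (BEV) aperture into 1D depth profiles,
#' normalized to their maximum, and compared through the activity peak
#' depth and the 80% distal dose fall-off.
#'
#' @name profile-metrics
NULL

#' 3D scalar volume
#'
#' Axis convention: x lateral, y vertical, z beam depth. Coordinates of a
#' voxel centre are `origin + (index - 1) * spacing` per axis.
#'
#' @param voxels 3D numeric array of nonnegative finite values.
#' @param spacing Length-3 positive voxel spacing, mm.
#' @param origin Length-3 coordinate of the first voxel centre, mm.
#' @return Object of class `volume3d`.
#' @export
volume3d <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive numbers")
  if (length(origin) != 3L) stop("origin must have length 3")
  if (any(!is.finite(voxels)) || any(voxels < 0))
    stop("voxel values must be finite and nonnegative")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "volume3d")
}

# voxel-centre coordinates along one axis
axis_coords <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$voxels)[axis]) - 1) * vol$spacing[axis]
}

#' Beam's-eye-view depth profile
#'
#' Sums, per depth slice, all voxels whose x and y centres lie within
#' `+/- half_aperture` of the aperture centre (inclusive bounds).
#'
#' @param vol A [volume3d()].
#' @param center_xy Length-2 aperture centre (x, y) in mm.
#' @param half_aperture Half-width of the square aperture, mm (default the
#'   conventional +/- 1 mm BEV window).
#' @return A [depth_profile()] over the volume's z coordinates.
#' @export
bev_profile <- function(vol, center_xy = c(0, 0), half_aperture = 1) {
  stopifnot(inherits(vol, "volume3d"))
  x <- axis_coords(vol, 1); y <- axis_coords(vol, 2)
  ix <- which(abs(x - center_xy[1]) <= half_aperture)
  iy <- which(abs(y - center_xy[2]) <= half_aperture)
  if (!length(ix) || !length(iy))
    stop("empty aperture: no voxel centres inside the window")
  prof <- apply(vol$voxels[ix, iy, , drop = FALSE], 3, sum)
  depth_profile(axis_coords(vol, 3), prof)
}

#' Normalize a profile to its maximum
#'
#' @param p A [depth_profile()] with a positive maximum.
#' @return A [depth_profile()] with maximum 1.
#' @export
normalize_max <- function(p) {
  stopifnot(inherits(p, "depth_profile"))
  m <- max(p$values)
  if (m <= 0) stop("cannot normalize an all-zero profile")
  depth_profile(p$depths, p$values / m)
}

#' Distal fall-off depth at a fractional level
#'
#' Scanning from the deepest depth towards the peak, returns the first
#' linearly interpolated crossing of `level` on the falling edge beyond the
#' global maximum. Searching distal-to-proximal guarantees the DISTAL
#' crossing even when the entrance region also crosses the level.
#'
#' @param p A [depth_profile()], conventionally max-normalized.
#' @param level Fraction of the maximum (default 0.8, the standard
#'   range-verification anchor).
#' @return Depth in mm of the distal crossing.
#' @export
distal_falloff_depth <- function(p, level = 0.8) {
  stopifnot(inherits(p, "depth_profile"))
  v <- p$values; z <- p$depths
  thr <- level * max(v)
  ipk <- max(which(v == max(v)))          # deepest maximum
  if (level >= 1) return(z[ipk])
  if (ipk == length(v))
    stop("no distal crossing of the requested level beyond the peak")
  for (i in seq(length(v), ipk + 1L)) {
    if (v[i - 1L] >= thr && v[i] < thr) {
      frac <- (v[i - 1L] - thr) / (v[i - 1L] - v[i])
      return(z[i - 1L] + frac * (z[i] - z[i - 1L]))
    }
  }
  stop("no distal crossing of the requested level beyond the peak")
}

#' Peak depth with parabolic refinement
#'
#' Locates the maximal sample (ties broken towards the deeper depth) and
#' refines it by a 3-point parabola through the neighbours, unless the
#' maximum sits on the grid boundary or in a flat plateau.
#'
#' @param p A [depth_profile()].
#' @return Depth in mm of the (refined) maximum.
#' @export
peak_depth <- function(p) {
  stopifnot(inherits(p, "depth_profile"))
  v <- p$values; z <- p$depths
  i <- max(which(v == max(v)))
  if (i == 1L || i == length(v)) return(z[i])
  if (v[i - 1L] >= v[i] || v[i + 1L] >= v[i]) return(z[i])  # plateau edge
  denom <- v[i - 1L] - 2 * v[i] + v[i + 1L]
  if (denom >= 0) return(z[i])  # degenerate curvature
  delta <- 0.5 * (v[i - 1L] - v[i + 1L]) / denom
  z[i] + delta * p$step
}

#' Signed range shift between two profiles
#'
#' `metric(a) - metric(b)`; positive means `a` is deeper.
#'
#' @param a,b [depth_profile()] objects.
#' @param mode `"peak"` ([peak_depth()]) or `"falloff80"`
#'   ([distal_falloff_depth()] at level 0.8).
#' @return Shift in mm.
#' @export
range_shift <- function(a, b, mode = c("peak", "falloff80")) {
  mode <- match.arg(mode)
  metric <- switch(mode,
                   peak = peak_depth,
                   falloff80 = function(p) distal_falloff_depth(p, 0.8))
  metric(a) - metric(b)
}
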