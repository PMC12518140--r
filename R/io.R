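#' File formats
#'
#' Plain-text interchange for all pipeline artefacts: 2-column CSV for
#' time-activity series (with a JSON sidecar holding bin width and the
#' t-zero convention) and depth profiles, CSV for cohort tables, NIfTI for
#' volumes (spacing in the header), JSON for reports. All numeric payloads
#' round-trip at double precision.
#'
#' @name formats
NULL

#' @rdname formats
#' @param series A [time_activity_series()].
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "time_activity_series"))
  write_numeric_csv(as.data.frame(series), path)
  jsonlite::write_json(
    list(bin_width_s = series$bin_width, t_zero = series$t_zero),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname formats
#' @export
read_series_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("t_s", "value") %in% names(d)))
    stop("series CSV must have columns 't_s' and 'value' (got: ",
         paste(names(d), collapse = ", "), ")")
  side <- paste0(path, ".json")
  bw <- NA_real_; tz <- "end_of_irradiation"
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!is.null(meta$bin_width_s)) bw <- as.numeric(meta$bin_width_s)
    if (!is.null(meta$t_zero)) tz <- meta$t_zero
  }
  time_activity_series(d$t_s, d$value, bin_width = bw, t_zero = tz)
}

#' @rdname formats
#' @param profile A [depth_profile()].
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "depth_profile"))
  write_numeric_csv(as.data.frame(profile), path)
  invisible(path)
}

# CSV with shortest round-trippable decimal representation (%.17g),
# so numeric payloads survive write/read at double precision
write_numeric_csv <- function(df, path) {
  fmt <- df
  for (i in seq_along(fmt))
    if (is.numeric(fmt[[i]])) fmt[[i]] <- sprintf("%.17g", fmt[[i]])
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname formats
#' @export
read_profile_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("depth_mm", "value") %in% names(d)))
    stop("profile CSV must have columns 'depth_mm' and 'value' (got: ",
         paste(names(d), collapse = ", "), ")")
  depth_profile(d$depth_mm, d$value)
}

#' @rdname formats
#' @param vol A [volume3d()].
#' @export
write_volume_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname formats
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  volume3d(array(as.numeric(img), dim = dim(img)),
           spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname formats
#' @param report Named list.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
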