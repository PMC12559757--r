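#' Create a volume record
#'
#' The unit flowing through the pipeline: a 3D intensity grid together with
#' its voxel spacing, an orientation tag and patient metadata. Axes follow the
#' LPS patient convention: x grows towards the patient's left, y towards
#' posterior, z towards superior.
#'
#' @param intensities 3D numeric array (x, y, z).
#' @param spacing numeric length-3, voxel spacing in mm per axis; all > 0.
#' @param orientation `"LPS"` or `"other"`.
#' @param meta list with elements `exam_id` (character), `age` (years) and
#'   `cancer_laterality` (`"left"`, `"right"` or `"none"`).
#' @return An object of class `volume_record`.
#' @export
volume_record <- function(intensities,
                          spacing = c(1, 1, 1),
                          orientation = c("LPS", "other"),
                          meta = list(exam_id = "exam", age = NA_real_,
                                      cancer_laterality = "none")) {
  orientation <- match.arg(orientation)
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    abort("`intensities` must be a 3D array.")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive numbers (mm).")
  }
  structure(
    list(intensities = intensities, spacing = spacing,
         orientation = orientation, meta = meta),
    class = "volume_record"
  )
}

#' @export
print.volume_record <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<volume_record> %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm, %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$orientation))
  cat(sprintf("  exam %s, age %s, cancer laterality %s\n",
              x$meta$exam_id %||% "?",
              format(x$meta$age %||% NA), x$meta$cancer_laterality %||% "none"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_volume_array <- function(v) {
  if (inherits(v, "volume_record")) v$intensities else v
}

#' Z-score normalize a volume
#'
#' Rescales intensities to zero mean and unit standard deviation, computed
#' over all voxels of the volume (background included), the whitening step
#' applied before any network sees an image. Shape, spacing and metadata are
#' unchanged.
#'
#' @param v a [volume_record()] or a 3D array.
#' @return The same type as `v`, normalized.
#' @export
zscore_normalize <- function(v) {
  x <- as_volume_array(v)
  mu <- mean(x)
  s <- sd(as.vector(x))
  if (!is.finite(s) || s == 0) {
    abort("Cannot z-score a constant volume (zero variance).")
  }
  y <- (x - mu) / s
  if (inherits(v, "volume_record")) {
    v$intensities <- y
    v
  } else {
    y
  }
}
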