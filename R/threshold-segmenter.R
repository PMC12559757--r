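#' Classical intensity-threshold segmenter
#'
#' A desk-scale baseline (and test oracle), NOT the pipeline's network
#' method: a 1D 3-class k-means on the intensity histogram separates
#' background, fat and bright fibroglandular tissue, exploiting the
#' fat-suppressed T1 convention (dense tissue brightest). Cluster
#' initialization at the min / median / max intensity is deterministic.
#'
#' @param v a [volume_record()] or 3D array (raw or z-scored intensities;
#'   the method is monotone-invariant).
#' @param max_sample maximum number of voxels used to fit the cluster
#'   centers (all voxels are classified).
#' @return A [mask_pair()]: `breast` = fat + dense classes, `dense` = the
#'   brightest class (intersected with breast).
#' @export
segment_threshold <- function(v, max_sample = 2e5) {
  x <- as.vector(as_volume_array(v))
  fit_x <- if (length(x) > max_sample) {
    x[round(seq(1, length(x), length.out = max_sample))]
  } else x
  centers <- sort(c(min(fit_x), median(fit_x), max(fit_x)))
  if (anyDuplicated(centers)) abort("Degenerate intensity histogram; cannot separate 3 classes.")
  km <- kmeans(fit_x, centers = matrix(centers, ncol = 1), iter.max = 50)
  cc <- sort(as.vector(km$centers))
  t_breast <- (cc[1] + cc[2]) / 2
  t_dense <- (cc[2] + cc[3]) / 2
  arr <- as_volume_array(v)
  breast <- arr > t_breast
  dense <- arr > t_dense
  mask_pair(breast, dense & breast)
}

#' @describeIn segment_threshold patch-level interface so the threshold
#'   segmenter can stand in for a model inside [segment_volume()]; the
#'   cutoff is fixed at construction, so patch-wise and whole-volume
#'   application agree exactly.
#' @param cutoff fixed intensity cutoff; probabilities are 1 above it.
#' @export
fixed_cutoff_model <- function(cutoff) {
  structure(list(cutoff = cutoff), class = "fixed_cutoff_model")
}

#' @export
predict_patch.fixed_cutoff_model <- function(model, patch, ...) {
  out <- (patch > model$cutoff) * 1.0
  dim(out) <- dim(patch)
  out
}
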