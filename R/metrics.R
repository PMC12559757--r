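#' Dice similarity coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`, the standard overlap score in \[0, 1\];
#' defined as 1 when both masks are empty.
#'
#' @param a,b logical arrays of identical shape.
#' @return numeric scalar in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) abort("Masks must share a shape.")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1.0)
  2 * sum(a & b) / (na + nb)
}

#' Hausdorff distance between two binary masks
#'
#' The larger of the two directed max-min distances between the foreground
#' voxel-center point sets. Reported in voxel units by default; pass the
#' voxel `spacing` (mm) for a physical distance. Undefined (an error) when
#' either mask is empty.
#'
#' @param a,b logical arrays of identical shape, both non-empty.
#' @param spacing numeric length-3 voxel spacing; `c(1, 1, 1)` gives voxel
#'   units.
#' @return numeric scalar >= 0.
#' @export
hausdorff_distance <- function(a, b, spacing = c(1, 1, 1)) {
  if (!identical(dim(a), dim(b))) abort("Masks must share a shape.")
  if (sum(a) == 0 || sum(b) == 0) {
    abort("Hausdorff distance is undefined for an empty mask.")
  }
  A <- which(array(as.logical(a), dim(a)), arr.ind = TRUE)
  B <- which(array(as.logical(b), dim(b)), arr.ind = TRUE)
  sp <- rep(as.numeric(spacing), length.out = 3)
  A <- sweep(matrix(as.numeric(A), ncol = 3), 2, sp, `*`)
  B <- sweep(matrix(as.numeric(B), ncol = 3), 2, sp, `*`)
  cpp_hausdorff(A, B)
}

#' 6-connected component labelling of a 3D binary mask
#'
#' @param mask logical 3D array.
#' @return integer array of the same shape; 0 = background, components
#'   numbered from 1 in scan order.
#' @export
label_components <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3) abort("`mask` must be a 3D array.")
  cpp_label3d(as.logical(mask), as.integer(dim(mask)))
}
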