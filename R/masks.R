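#' Pair of breast and dense-tissue masks
#'
#' Holds the two binary masks on a common grid: the whole-breast mask and the
#' fibroglandular (dense) tissue mask, the operands of the volumetric density
#' ratio. Containment (`dense` inside `breast`) is required.
#'
#' @param breast logical 3D array.
#' @param dense logical 3D array, same shape, subset of `breast`.
#' @return An object of class `mask_pair`.
#' @export
mask_pair <- function(breast, dense) {
  if (!identical(dim(breast), dim(dense))) {
    abort("`breast` and `dense` masks must share a grid.")
  }
  breast <- array(as.logical(breast), dim(breast))
  dense <- array(as.logical(dense), dim(dense))
  if (any(dense & !breast)) {
    abort("Dense mask extends outside the breast mask; postprocess (intersect) first.")
  }
  structure(list(breast = breast, dense = dense), class = "mask_pair")
}

#' @export
print.mask_pair <- function(x, ...) {
  d <- dim(x$breast)
  cat(sprintf("<mask_pair> %d x %d x %d: %d breast voxels, %d dense voxels\n",
              d[1], d[2], d[3], sum(x$breast), sum(x$dense)))
  invisible(x)
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
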