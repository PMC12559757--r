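#' Build the sliding-window patch grid
#'
#' Start positions for patch-based inference: along each axis, `steps` start
#' indices uniformly spaced (in real arithmetic, then rounded to integers)
#' from 0 to `dim - patch`, deduplicated. The default geometry is a 96^3
#' patch stepped 8 times along x and y and 3 times along z. Full coverage of
#' the volume is verified and is an error to violate (too few steps for the
#' volume size).
#'
#' @param volume_shape integer length-3.
#' @param patch_size integer length-3, each <= the corresponding volume dim.
#' @param steps integer length-3, number of start positions per axis.
#' @return A `patch_grid`: list with `starts` (n x 3 matrix of 0-based start
#'   indices), `patch_size`, `steps`, `volume_shape`.
#' @export
build_patch_grid <- function(volume_shape, patch_size = c(96, 96, 96),
                             steps = c(8, 8, 3)) {
  volume_shape <- as.integer(volume_shape)
  patch_size <- as.integer(rep(patch_size, length.out = 3))
  steps <- as.integer(rep(steps, length.out = 3))
  if (any(patch_size > volume_shape)) {
    abort("Patch exceeds volume; pad the volume first.")
  }
  if (any(steps < 1)) abort("`steps` must be >= 1 per axis.")
  axis_starts <- lapply(1:3, function(a) {
    s <- unique(as.integer(round(seq(0, volume_shape[a] - patch_size[a],
                                     length.out = steps[a]))))
    if (s[length(s)] + patch_size[a] < volume_shape[a] ||
        any(diff(s) > patch_size[a])) {
      abort(sprintf(
        "Axis %d not fully covered: %d steps of a %d-voxel patch cannot cover %d voxels.",
        a, steps[a], patch_size[a], volume_shape[a]))
    }
    s
  })
  starts <- as.matrix(expand.grid(axis_starts[[1]], axis_starts[[2]],
                                  axis_starts[[3]], KEEP.OUT.ATTRS = FALSE))
  dimnames(starts) <- NULL
  structure(list(starts = starts, patch_size = patch_size, steps = steps,
                 volume_shape = volume_shape),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  cat(sprintf("<patch_grid> %d patches of %s over volume %s (steps %s)\n",
              nrow(x$starts), paste(x$patch_size, collapse = "x"),
              paste(x$volume_shape, collapse = "x"),
              paste(x$steps, collapse = "/")))
  invisible(x)
}

#' Fuse overlapping patch predictions by equal-weight averaging
#'
#' Each voxel's fused value is the arithmetic mean of all patch predictions
#' covering it (equal weighting); the per-voxel number of contributors is
#' recorded. A voxel covered by no patch is an error (it names the first
#' uncovered index), never silently zero.
#'
#' @param patch_preds list of `list(start = 0-based length-3 index,
#'   block = 3D array of probabilities)`.
#' @param volume_shape integer length-3.
#' @return list with `probs` (3D array) and `counts` (integer 3D array),
#'   class `probability_volume`.
#' @export
fuse_patches <- function(patch_preds, volume_shape) {
  volume_shape <- as.integer(volume_shape)
  acc <- array(0, volume_shape)
  cnt <- array(0L, volume_shape)
  for (p in patch_preds) {
    s <- as.integer(p$start)
    b <- p$block
    d <- dim(b)
    if (any(s < 0) || any(s + d > volume_shape)) {
      abort("Patch block lies outside the volume bounds.")
    }
    ix <- (s[1] + 1):(s[1] + d[1])
    iy <- (s[2] + 1):(s[2] + d[2])
    iz <- (s[3] + 1):(s[3] + d[3])
    acc[ix, iy, iz] <- acc[ix, iy, iz] + b
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1L
  }
  if (any(cnt == 0L)) {
    bad <- which(cnt == 0L, arr.ind = TRUE)[1, ]
    abort(sprintf("Voxel (%d, %d, %d) covered by no patch.",
                  bad[1], bad[2], bad[3]))
  }
  structure(list(probs = acc / cnt, counts = cnt),
            class = "probability_volume")
}

#' Per-patch prediction generic
#'
#' Maps one normalized intensity patch (3D array) to per-voxel foreground
#' probabilities of the same shape. Implemented by the V-Net model and by the
#' classical threshold segmenter; tests plug in deterministic mocks.
#'
#' @param model a segmentation model object.
#' @param patch 3D numeric array.
#' @param ... passed on to methods.
#' @return 3D array of probabilities in \[0, 1\], same shape as `patch`.
#' @export
predict_patch <- function(model, patch, ...) UseMethod("predict_patch")

#' Segment a volume by patch-based sliding-window inference
#'
#' Runs `predict_patch()` on every sub-volume of the grid, fuses the
#' overlapping probability blocks by equal-weight averaging, and binarizes at
#' `threshold` (voxels with fused probability >= threshold are foreground).
#' Volumes smaller than the patch are zero-padded symmetrically and the
#' padding removed after fusion, so the output mask always matches the input
#' shape.
#'
#' @param model object with a [predict_patch()] method.
#' @param v a [volume_record()] or 3D array, already z-score normalized for
#'   trained models.
#' @param grid a [build_patch_grid()] result for the (padded) shape, or
#'   `NULL` to build one from `patch_size`/`steps`.
#' @param threshold binarization probability, default 0.5.
#' @param patch_size,steps grid geometry used when `grid` is `NULL`.
#' @return logical 3D array, the binary mask.
#' @export
segment_volume <- function(model, v, grid = NULL, threshold = 0.5,
                           patch_size = c(96, 96, 96), steps = c(8, 8, 3)) {
  x <- as_volume_array(v)
  d0 <- dim(x)
  if (!is.null(grid)) patch_size <- grid$patch_size
  patch_size <- as.integer(rep(patch_size, length.out = 3))
  pad_lo <- pmax((patch_size - d0 + 1L) %/% 2L, 0L)
  d_pad <- pmax(d0, patch_size)
  if (any(d_pad > d0)) {
    xp <- array(0, d_pad)
    xp[pad_lo[1] + seq_len(d0[1]), pad_lo[2] + seq_len(d0[2]),
       pad_lo[3] + seq_len(d0[3])] <- x
    x <- xp
  }
  if (is.null(grid)) {
    grid <- build_patch_grid(d_pad, patch_size, steps)
  } else if (!identical(as.integer(grid$volume_shape), as.integer(d_pad))) {
    abort("`grid` was built for a different (padded) volume shape.")
  }
  preds <- lapply(seq_len(nrow(grid$starts)), function(i) {
    s <- grid$starts[i, ]
    blk <- x[(s[1] + 1):(s[1] + patch_size[1]),
             (s[2] + 1):(s[2] + patch_size[2]),
             (s[3] + 1):(s[3] + patch_size[3]), drop = FALSE]
    dim(blk) <- patch_size
    pb <- predict_patch(model, blk)
    if (!identical(dim(pb), as.integer(patch_size)) &&
        !identical(dim(pb), patch_size)) {
      abort("Model output shape does not match the patch size.")
    }
    list(start = s, block = pb)
  })
  fused <- fuse_patches(preds, d_pad)
  probs <- fused$probs[pad_lo[1] + seq_len(d0[1]), pad_lo[2] + seq_len(d0[2]),
                       pad_lo[3] + seq_len(d0[3]), drop = FALSE]
  dim(probs) <- d0
  probs >= threshold
}
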