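#' Specify a synthetic breast phantom
#'
#' Parameters of one phantom exam: grid geometry, the true volumetric density
#' to realize, laterality, the correlation length of the fibroglandular blob
#' field, and the additive intensity noise. Intensities follow the
#' fat-suppressed T1 convention (fibroglandular tissue bright, fat dark,
#' background near zero), so a simple intensity-threshold segmenter is exact
#' on noiseless phantoms.
#'
#' @param grid_shape integer length-3, voxels per axis (each >= 32).
#' @param voxel_spacing numeric length-3, mm per axis.
#' @param target_density fraction in \[0, 1\]: the true dense/breast voxel
#'   ratio to realize.
#' @param breast_half `"bilateral"`, `"left"` or `"right"`.
#' @param texture_scale correlation length (voxels) of the smooth random field
#'   whose upper level set forms the dense tissue.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (intensity units; phantom tissue classes sit at 0 / 80 / 240).
#' @param seed integer RNG seed; identical specs give bit-identical phantoms.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_spacing = c(1, 1, 1),
                         target_density = 0.1,
                         breast_half = c("bilateral", "left", "right"),
                         texture_scale = 4,
                         noise_sd = 5,
                         seed = 1L) {
  breast_half <- match.arg(breast_half)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 32L)) {
    abort("`grid_shape` must be 3 integers, each >= 32.")
  }
  if (!is.numeric(target_density) || target_density < 0 || target_density > 1) {
    abort("`target_density` must lie in [0, 1].")
  }
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (texture_scale <= 0) abort("`texture_scale` must be > 0.")
  structure(
    list(grid_shape = grid_shape, voxel_spacing = as.numeric(voxel_spacing),
         target_density = target_density, breast_half = breast_half,
         texture_scale = texture_scale, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Smooth periodic Gaussian random field via FFT filtering of white noise.
smooth_field <- function(shape, scale) {
  noise <- array(rnorm(prod(shape)), shape)
  kern1 <- function(n) {
    d <- pmin(0:(n - 1), n - (0:(n - 1)))
    k <- exp(-0.5 * (d / scale)^2)
    k / sum(k)
  }
  K <- outer(outer(kern1(shape[1]), kern1(shape[2])), kern1(shape[3]))
  dim(K) <- shape
  g <- Re(fft(fft(noise) * fft(K), inverse = TRUE)) / prod(shape)
  (g - mean(g)) / sd(as.vector(g))
}

ellipsoid_mask <- function(shape, center, radii) {
  x <- (seq_len(shape[1]) - center[1]) / radii[1]
  y <- (seq_len(shape[2]) - center[2]) / radii[2]
  z <- (seq_len(shape[3]) - center[3]) / radii[3]
  e <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  dim(e) <- shape
  e <= 1
}

#' Generate a synthetic breast phantom
#'
#' Builds a 3D breast-like volume with known ground truth. The breast mask is
#' one (or two, bilateral) half-ellipsoid attached to a posterior chest-wall
#' plane; the dense mask is the upper level set of a smooth random field
#' inside the breast, its level chosen so the realized dense/breast voxel
#' ratio matches `target_density` (exact to the nearest voxel). Intensities:
#' background ~ 0, fat 80, dense tissue 240, plus Gaussian noise, quantized to
#' integers in \[0, 4095\] so that a 16-bit DICOM round trip is lossless.
#'
#' @param spec a [phantom_spec()].
#' @param exam_id identifier stored in the volume metadata.
#' @param age,cancer_laterality patient metadata carried on the volume.
#' @return A list with elements `volume` (a [volume_record()]) and `truth`
#'   (a [mask_pair()]).
#' @export
generate_phantom <- function(spec, exam_id = sprintf("phantom-%d", spec$seed),
                             age = 50, cancer_laterality = "none") {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$grid_shape
  with_seed(spec$seed, {
    ychest <- round(0.72 * shape[2])
    wall <- slice.index(array(0, shape), 2) <= ychest
    # single-sided breasts use the bilateral geometry so each breast stays
    # strictly within its half of the volume (patient right = small x in LPS)
    sides <- switch(spec$breast_half,
                    bilateral = list(c(0.27, 0.22), c(0.73, 0.22)),
                    right = list(c(0.27, 0.22)),
                    left = list(c(0.73, 0.22)))
    side_masks <- lapply(sides, function(s) {
      ellipsoid_mask(
        shape,
        center = c(s[1] * shape[1], ychest, 0.5 * shape[3]),
        radii = c(s[2] * shape[1], 0.62 * ychest, 0.36 * shape[3])
      ) & wall
    })
    breast <- Reduce(`|`, side_masks)
    nb <- sum(breast)
    if (nb == 0) abort("Degenerate phantom: empty breast mask.")

    # Calibrate the dense fraction within each breast separately so that both
    # sides of a bilateral phantom realize the target ratio.
    dense <- array(FALSE, shape)
    if (spec$target_density > 0) {
      g <- smooth_field(shape, spec$texture_scale)
      for (side in side_masks) {
        ns <- sum(side)
        k <- round(ns * spec$target_density)
        if (k < 1) {
          abort(sprintf(
            "target_density %.4g infeasible on this grid: dense region would be < 1 voxel (breast side has %d voxels).",
            spec$target_density, ns))
        }
        if (k >= ns) {
          dense <- dense | side
          next
        }
        thr <- sort(g[side], decreasing = TRUE)[k]
        sel <- side & (g >= thr)
        # ties at the threshold could overshoot; trim deterministically
        if (sum(sel) > k) {
          idx <- which(sel)
          drop <- idx[order(g[idx], idx)][seq_len(sum(sel) - k)]
          sel[drop] <- FALSE
        }
        dense <- dense | sel
      }
    }

    intens <- array(0, shape)
    intens[breast] <- 80
    intens[dense] <- 240
    if (spec$noise_sd > 0) {
      intens <- intens + rnorm(length(intens), sd = spec$noise_sd)
    }
    intens <- array(pmin(pmax(round(intens), 0), 4095), shape)

    list(
      volume = volume_record(intens, spacing = spec$voxel_spacing,
                             orientation = "LPS",
                             meta = list(exam_id = exam_id, age = age,
                                         cancer_laterality = cancer_laterality)),
      truth = mask_pair(breast, dense)
    )
  })
}
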