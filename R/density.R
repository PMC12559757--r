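#' Volumetric breast density from a mask pair
#'
#' The headline statistic: the ratio of dense-tissue voxels to whole-breast
#' voxels, `sum(M_dense) / sum(M_breast)`. Requires a non-empty breast mask
#' and a dense mask contained in it (containment failure signals missing
#' postprocessing upstream and is an error, not silently clipped).
#'
#' @param m a [mask_pair()] or a list with `breast` and `dense` logical
#'   arrays.
#' @return numeric scalar in \[0, 1\].
#' @export
compute_density <- function(m) {
  breast <- m$breast; dense <- m$dense
  if (!identical(dim(breast), dim(dense))) abort("Masks must share a grid.")
  nb <- sum(breast)
  if (nb == 0) abort("Empty breast mask: density undefined.")
  if (any(dense & !breast)) {
    abort("Dense mask extends outside the breast mask; intersect masks first.")
  }
  sum(dense) / nb
}

#' Split a breast mask into left and right sides
#'
#' Partition strategy: connected components first, midline fallback. With
#' two or more 6-connected components, every component is assigned to the
#' side of its centroid (larger x = patient left under LPS), anchored by the
#' two largest; a single component spanning the midline is split at the
#' mid-coronal x index of the volume. Every foreground voxel ends up on
#' exactly one side.
#'
#' @param breast logical 3D array, LPS-oriented, non-empty.
#' @return list with logical arrays `left` and `right`.
#' @export
split_laterality <- function(breast) {
  if (sum(breast) == 0) abort("Empty breast mask.")
  d <- dim(breast)
  lab <- label_components(breast)
  ncomp <- max(lab)
  left <- array(FALSE, d)
  right <- array(FALSE, d)
  xs <- slice.index(breast, 1)
  if (ncomp >= 2) {
    cx <- vapply(seq_len(ncomp), function(k) mean(xs[lab == k]), numeric(1))
    sizes <- tabulate(lab[lab > 0], nbins = ncomp)
    big2 <- order(sizes, decreasing = TRUE)[1:2]
    midline <- mean(cx[big2])
    for (k in seq_len(ncomp)) {
      if (cx[k] > midline || (cx[k] == midline && k == big2[which.max(cx[big2])])) {
        left[lab == k] <- TRUE
      } else {
        right[lab == k] <- TRUE
      }
    }
  } else {
    mid <- (d[1] + 1) / 2
    left <- breast & (xs > mid)
    right <- breast & (xs <= mid)
  }
  list(left = left, right = right)
}

#' Per-side density results for one exam
#'
#' Splits the exam's masks by laterality and computes the density ratio for
#' each non-empty side.
#'
#' @param m a [mask_pair()] for the whole exam.
#' @param exam_id identifier copied into the rows.
#' @return tibble with columns `exam_id`, `side`, `breast_voxels`,
#'   `dense_voxels`, `density`.
#' @export
density_by_side <- function(m, exam_id = "exam") {
  sides <- split_laterality(m$breast)
  rows <- lapply(c("left", "right"), function(s) {
    b <- sides[[s]]
    if (sum(b) == 0) return(NULL)
    dn <- m$dense & b
    tibble::tibble(exam_id = exam_id, side = s,
                   breast_voxels = sum(b), dense_voxels = sum(dn),
                   density = sum(dn) / sum(b))
  })
  dplyr::bind_rows(rows)
}

#' Select the density value(s) to report for an exam
#'
#' With a known cancer side only the contralateral normal breast is
#' reported. For screening exams (`cancer_laterality = "none"`) both sides
#' are retained and their mean is added as the exam-level value
#' (`side = "exam"`); `screening_rule` switches this to the left, right or
#' maximum side instead.
#'
#' @param results tibble of per-side rows as from [density_by_side()].
#' @param cancer_laterality `"left"`, `"right"` or `"none"`.
#' @param screening_rule how to summarise bilateral screening exams:
#'   `"mean"` (default), `"left"`, `"right"` or `"max"`.
#' @return tibble of the reported row(s).
#' @export
select_reported_density <- function(results,
                                    cancer_laterality = c("none", "left", "right"),
                                    screening_rule = c("mean", "left", "right", "max")) {
  cancer_laterality <- match.arg(cancer_laterality)
  screening_rule <- match.arg(screening_rule)
  if (nrow(results) == 0) abort("No per-side density results supplied.")
  if (cancer_laterality != "none") {
    contra <- setdiff(c("left", "right"), cancer_laterality)
    out <- dplyr::filter(results, .data$side == contra)
    if (nrow(out) == 0) {
      abort(sprintf("Contralateral (%s) breast missing from results.", contra))
    }
    return(out)
  }
  if (screening_rule %in% c("left", "right")) {
    out <- dplyr::filter(results, .data$side == screening_rule)
    if (nrow(out) == 0) abort(sprintf("Side '%s' missing from results.", screening_rule))
    return(out)
  }
  exam_val <- if (screening_rule == "max") max(results$density) else mean(results$density)
  dplyr::bind_rows(
    results,
    tibble::tibble(exam_id = results$exam_id[1], side = "exam",
                   breast_voxels = sum(results$breast_voxels),
                   dense_voxels = sum(results$dense_voxels),
                   density = exam_val)
  )
}
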