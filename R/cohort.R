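#' Specify a synthetic study cohort
#'
#' Parameters of the phantom cohort generator. Defaults are the study
#' conditions the package's analyses assume: ages uniform over 20–79, mean
#' density near 0.11 with a right-skewed (scaled-beta) distribution whose
#' mass sits mostly below 0.2, a gently decreasing density–age trend, and
#' report categories derived from true density through noisy ordinal
#' thresholds (emulating radiologist variability in density reporting).
#'
#' @param n_exams number of exams (> 0).
#' @param age_range numeric length-2, min and max age in years.
#' @param density_age_slope density units per year; negative for the
#'   decreasing trend with age. Default -0.003/yr.
#' @param density_mean cohort mean density at the mid age. Default 0.11.
#' @param density_dispersion inverse precision of the scaled-beta residual
#'   (0 = degenerate at the mean; default 0.125 gives SDs that shrink with
#'   the mean, as observed in older age groups).
#' @param category_thresholds 3 strictly ascending density cut-points in
#'   (0, 1) defining the 4 ordinal report categories. Default
#'   `c(0.04, 0.10, 0.20)`.
#' @param category_noise probability in \[0, 0.5) that a report is shifted
#'   one category level. This is a free parameter of the generator, not an
#'   estimate of real radiologist variability.
#' @param seed integer RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_exams = 500,
                        age_range = c(20, 79),
                        density_age_slope = -0.003,
                        density_mean = 0.11,
                        density_dispersion = 0.125,
                        category_thresholds = c(0.04, 0.10, 0.20),
                        category_noise = 0.1,
                        seed = 1L) {
  if (n_exams <= 0) abort("`n_exams` must be > 0.")
  if (length(age_range) != 2 || diff(age_range) < 0 || age_range[1] < 18) {
    abort("`age_range` must be ascending ages >= 18.")
  }
  th <- as.numeric(category_thresholds)
  if (length(th) != 3 || any(diff(th) <= 0) || th[1] <= 0 || th[3] >= 1) {
    abort("`category_thresholds` must be 3 strictly ascending values in (0, 1).")
  }
  if (category_noise < 0 || category_noise >= 0.5) {
    abort("`category_noise` must lie in [0, 0.5).")
  }
  if (density_dispersion < 0) abort("`density_dispersion` must be >= 0.")
  structure(
    list(n_exams = as.integer(n_exams), age_range = as.numeric(age_range),
         density_age_slope = density_age_slope, density_mean = density_mean,
         density_dispersion = density_dispersion, category_thresholds = th,
         category_noise = category_noise, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Sample a synthetic cohort
#'
#' Draws per-exam demographics, true volumetric densities, noisy ordinal
#' report categories and report texts. True density is scaled-beta on
#' \[0, 0.8\] with mean `density_mean + density_age_slope * (age - mid age)`,
#' clipped to \[0.005, 0.8\]: positive, right-skewed, and (with the default
#' dispersion) mostly below 0.2. The report category is the threshold bin of
#' the true density, shifted one level with probability `category_noise`
#' (inward at the scale ends), then rendered as free text from the shared
#' keyword templates.
#'
#' Volumes are not materialized here; [realize_exam()] turns any row into a
#' full phantom (volume + ground-truth masks) on demand.
#'
#' @param cs a [cohort_spec()].
#' @return tibble with columns `exam_id`, `age`, `true_density`, `category`
#'   (ordered factor), `report_text`, `laterality` (`left`/`right`/`none`)
#'   and `phantom_seed`.
#' @export
sample_cohort <- function(cs) {
  stopifnot(inherits(cs, "cohort_spec"))
  n <- cs$n_exams
  with_seed(cs$seed, {
    age <- runif(n, cs$age_range[1], cs$age_range[2])
    mid <- mean(cs$age_range)
    mu <- cs$density_mean + cs$density_age_slope * (age - mid)
    mu <- pmin(pmax(mu, 0.005), 0.795)
    if (cs$density_dispersion <= 1e-12) {
      d <- mu
    } else {
      m <- mu / 0.8
      nu <- 1 / cs$density_dispersion
      d <- 0.8 * rbeta(n, m * nu, (1 - m) * nu)
    }
    d <- pmin(pmax(d, 0.005), 0.8)

    true_level <- findInterval(d, cs$category_thresholds) + 1L
    level <- true_level
    flip <- runif(n) < cs$category_noise
    dir <- sample(c(-1L, 1L), n, replace = TRUE)
    shifted <- level + ifelse(flip, dir, 0L)
    # at the ends of the ordinal scale the shift can only go inward
    shifted[flip & shifted < 1L] <- 2L
    shifted[flip & shifted > 4L] <- 3L
    level <- shifted

    laterality <- sample(c("left", "right", "none"), n, replace = TRUE,
                         prob = c(0.25, 0.25, 0.5))
    tibble::tibble(
      exam_id = sprintf("exam-%04d", seq_len(n)),
      age = age,
      true_density = d,
      category = density_category(level),
      report_text = render_report_text(level),
      laterality = laterality,
      phantom_seed = sample.int(.Machine$integer.max - 1L, n)
    )
  })
}

#' Materialize one cohort row as a full phantom exam
#'
#' @param exam a single row of the tibble returned by [sample_cohort()].
#' @param grid_shape,voxel_spacing,texture_scale,noise_sd phantom geometry
#'   and noise, see [phantom_spec()].
#' @return list with `volume` ([volume_record()]) and `truth`
#'   ([mask_pair()]); metadata (age, exam id, cancer laterality) rides on the
#'   volume.
#' @export
realize_exam <- function(exam, grid_shape = c(48, 48, 48),
                         voxel_spacing = c(1, 1, 1), texture_scale = 4,
                         noise_sd = 5) {
  stopifnot(nrow(exam) == 1)
  spec <- phantom_spec(grid_shape = grid_shape, voxel_spacing = voxel_spacing,
                       target_density = exam$true_density,
                       breast_half = "bilateral",
                       texture_scale = texture_scale, noise_sd = noise_sd,
                       seed = exam$phantom_seed)
  generate_phantom(spec, exam_id = exam$exam_id, age = exam$age,
                   cancer_laterality = exam$laterality)
}
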