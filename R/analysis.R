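#' Decade age bin
#'
#' Maps ages to decade labels `"20-29"` ... `"80-89"` (by flooring, so 48.8
#' falls in 40-49). Ages below 18 are an error.
#'
#' @param age numeric vector of ages in years (>= 18).
#' @return factor with decade levels `"10-19"` through `"90-99"` (unused
#'   levels dropped in summaries, kept here so binning is stable).
#' @export
bin_age <- function(age) {
  if (any(is.na(age)) || any(age < 18)) abort("Ages must be >= 18 and non-missing.")
  dec <- floor(age) %/% 10
  lv <- sprintf("%d-%d", (1:9) * 10, (1:9) * 10 + 9)
  factor(sprintf("%d-%d", dec * 10, dec * 10 + 9), levels = lv)
}

#' Density summaries per age decade
#'
#' Per-decade exam count, mean density and sample standard deviation
#' (n-1 denominator; absent for single-exam bins). Decades between the
#' youngest and oldest observed are reported even when empty (n = 0).
#'
#' @param t cohort tibble with columns `age` and `density` (use
#'   `true_density` cohorts via [dplyr::rename()] or pass `density_col`).
#' @param density_col name of the density column, default `"density"`.
#' @return tibble with `age_bin`, `n`, `mean_density`, `sd_density`.
#' @export
summarize_by_age <- function(t, density_col = "density") {
  if (nrow(t) == 0) abort("Empty cohort table.")
  d <- tibble::tibble(age_bin = bin_age(t$age), density = t[[density_col]])
  out <- d %>%
    dplyr::group_by(.data$age_bin, .drop = FALSE) %>%
    dplyr::summarise(n = dplyr::n(),
                     mean_density = ifelse(dplyr::n() > 0, mean(.data$density), NA_real_),
                     sd_density = ifelse(dplyr::n() > 1, sd(.data$density), NA_real_),
                     .groups = "drop")
  occupied <- which(out$n > 0)
  out[min(occupied):max(occupied), ]
}

# first-principles Kendall tau-b with tie-corrected normal-approximation
# p-value (O(n^2) pair counting)
kendall_tau_b <- function(x, y) {
  n <- length(x)
  dx <- sign(outer(x, x, `-`))
  dy <- sign(outer(y, y, `-`))
  up <- upper.tri(dx)
  s <- dx[up] * dy[up]
  C <- sum(s > 0); D <- sum(s < 0)
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  if (denom == 0) abort("Kendall tau-b undefined: a variable is constant.")
  tau <- (C - D) / denom
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
    (9 * n * (n - 1) * (n - 2))
  var_s <- (v0 - vt - vu) / 18 + v1 + v2
  z <- (C - D) / sqrt(var_s)
  list(tau = tau, p = 2 * pnorm(-abs(z)))
}

#' Concordance between report category and MRI density
#'
#' Rank agreement between the ordinal report category (1-4) and the
#' continuous MRI-derived density: tie-corrected Spearman rho (Pearson
#' correlation of midranks, two-sided p via the large-sample t
#' approximation) and Kendall tau-b (tie-corrected, normal-approximation
#' p-value). Rows with unclassifiable category are excluded and counted.
#'
#' @param t cohort tibble with `category` (ordered factor or integer 1-4)
#'   and a density column.
#' @param density_col name of the density column, default `"density"`.
#' @return one-row tibble: `spearman_rho`, `spearman_p`, `kendall_tau`,
#'   `kendall_p`, `n_used`, `n_excluded`.
#' @export
concordance <- function(t, density_col = "density") {
  lev <- as.integer(t$category)
  dens <- t[[density_col]]
  keep <- !is.na(lev) & !is.na(dens)
  n_excluded <- sum(!keep)
  lev <- lev[keep]; dens <- dens[keep]
  n <- length(lev)
  if (n < 10) abort("Need >= 10 classifiable rows for concordance.")
  if (length(unique(lev)) < 2) abort("All categories identical: correlation undefined.")
  rho <- cor(rank(lev), rank(dens))
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  sp_p <- 2 * pt(-abs(tstat), df = n - 2)
  kt <- kendall_tau_b(lev, dens)
  tibble::tibble(spearman_rho = rho, spearman_p = sp_p,
                 kendall_tau = kt$tau, kendall_p = kt$p,
                 n_used = n, n_excluded = n_excluded)
}

#' Fit the single-feature ordinal density classifier
#'
#' Learns three ascending density cut-points that maximize 4-class accuracy
#' against the report categories — the full expressive power of any monotone
#' single-feature classifier, found exactly by dynamic programming over the
#' cut positions of the sorted densities (equivalent to exhaustive midpoint
#' search). Deterministic: ties between optima resolve to the smallest cut
#' indices.
#'
#' @param train cohort tibble with `category` and a density column; all four
#'   categories must be present.
#' @param density_col name of the density column, default `"density"`.
#' @return object of class `density_threshold_classifier` with elements
#'   `thresholds` (ascending length 3), `train_accuracy`, `n_train`.
#' @export
fit_density_classifier <- function(train, density_col = "density") {
  lev <- as.integer(train$category)
  dens <- train[[density_col]]
  keep <- !is.na(lev) & !is.na(dens)
  lev <- lev[keep]; dens <- dens[keep]
  missing_cat <- setdiff(1:4, unique(lev))
  if (length(missing_cat) > 0) {
    abort(paste0("Training rows missing categor",
                 if (length(missing_cat) > 1) "ies " else "y ",
                 paste(density_labels[missing_cat], collapse = ", "), "."))
  }
  ord <- order(dens)
  dens <- dens[ord]; lev <- lev[ord]
  n <- length(dens)
  # A[k, i] = count of class-k rows among the first i sorted densities
  A <- sapply(1:4, function(k) c(0, cumsum(lev == k)))
  # accuracy(i1 <= i2 <= i3) = [A1-A2](i1) + [A2-A3](i2) + [A3-A4](i3) + A4(n)
  f1 <- A[, 1] - A[, 2]; f2 <- A[, 2] - A[, 3]; f3 <- A[, 3] - A[, 4]
  best1 <- numeric(n + 1); arg1 <- integer(n + 1)
  bv <- -Inf; ba <- 0L
  for (i in 0:n) {
    if (f1[i + 1] > bv) { bv <- f1[i + 1]; ba <- i }
    best1[i + 1] <- bv; arg1[i + 1] <- ba
  }
  best2 <- numeric(n + 1); arg2 <- integer(n + 1)
  bv <- -Inf; ba <- 0L
  for (i in 0:n) {
    cand <- best1[i + 1] + f2[i + 1]
    if (cand > bv) { bv <- cand; ba <- i }
    best2[i + 1] <- bv; arg2[i + 1] <- ba
  }
  bv <- -Inf; i3 <- 0L
  for (i in 0:n) {
    cand <- best2[i + 1] + f3[i + 1]
    if (cand > bv) { bv <- cand; i3 <- i }
  }
  total <- bv + A[n + 1, 4]
  i2 <- arg2[i3 + 1]; i1 <- arg1[i2 + 1]
  cut_value <- function(i) {
    if (i == 0) dens[1] / 2
    else if (i == n) (dens[n] + 1) / 2
    else (dens[i] + dens[i + 1]) / 2
  }
  thr <- c(cut_value(i1), cut_value(i2), cut_value(i3))
  structure(list(thresholds = thr, train_accuracy = total / n, n_train = n),
            class = "density_threshold_classifier")
}

#' @export
print.density_threshold_classifier <- function(x, ...) {
  cat(sprintf("<density_threshold_classifier> cut-points %.4f / %.4f / %.4f (train accuracy %.3f, n=%d)\n",
              x$thresholds[1], x$thresholds[2], x$thresholds[3],
              x$train_accuracy, x$n_train))
  invisible(x)
}

#' @export
predict.density_threshold_classifier <- function(object, newdata, density_col = "density", ...) {
  dens <- if (is.numeric(newdata)) newdata else newdata[[density_col]]
  density_category(findInterval(dens, object$thresholds) + 1L)
}

#' @export
tidy.density_threshold_classifier <- function(x, ...) {
  tibble::tibble(term = c("cut_1_2", "cut_2_3", "cut_3_4"),
                 estimate = x$thresholds)
}

#' @export
glance.density_threshold_classifier <- function(x, ...) {
  tibble::tibble(train_accuracy = x$train_accuracy, n_train = x$n_train)
}

#' Evaluate the ordinal classifier on held-out rows
#'
#' Four-class accuracy from the thresholded densities, plus the binary AUC
#' for separating "scattered" (level 2) from "heterogeneously dense"
#' (level 3): the rank-based probability that a random level-3 exam has
#' higher density than a random level-2 exam (ties count 1/2). AUC is `NA`
#' when either class is absent from the test rows.
#'
#' @param model a fitted `density_threshold_classifier`.
#' @param test cohort tibble, disjoint from the training rows.
#' @param density_col name of the density column, default `"density"`.
#' @return one-row tibble: `accuracy_4class`, `auc_binary`, `n_test`.
#' @export
evaluate_classifier <- function(model, test, density_col = "density") {
  lev <- as.integer(test$category)
  dens <- test[[density_col]]
  keep <- !is.na(lev) & !is.na(dens)
  lev <- lev[keep]; dens <- dens[keep]
  pred <- findInterval(dens, model$thresholds) + 1L
  acc <- mean(pred == lev)
  d2 <- dens[lev == 2L]; d3 <- dens[lev == 3L]
  auc <- if (length(d2) == 0 || length(d3) == 0) NA_real_ else {
    cmp <- outer(d3, d2, `-`)
    (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / length(cmp)
  }
  tibble::tibble(accuracy_4class = acc, auc_binary = auc, n_test = length(lev))
}

#' Stratified 80/20 split by category
#'
#' @param t cohort tibble with a `category` column.
#' @param prop training proportion, default 0.8.
#' @param seed RNG seed for the stratified draw.
#' @return list with tibbles `train` and `test`.
#' @export
split_cohort <- function(t, prop = 0.8, seed = 1L) {
  with_seed(seed, {
    idx <- unlist(lapply(split(seq_len(nrow(t)), as.integer(t$category)),
                         function(ix) sample(ix, max(1, round(prop * length(ix))))))
    list(train = t[sort(idx), ], test = t[-sort(idx), ])
  })
}

#' Histogram of density values
#'
#' Right-open bins of width `bin_width` over \[0, 1\] (the last bin closed at
#' 1 so counts always sum to the row count).
#'
#' @param t cohort tibble with a density column.
#' @param bin_width in (0, 0.5], default 0.05.
#' @param density_col name of the density column, default `"density"`.
#' @return tibble with `bin_start`, `bin_end`, `count`.
#' @export
density_histogram <- function(t, bin_width = 0.05, density_col = "density") {
  if (bin_width <= 0 || bin_width > 0.5) abort("`bin_width` must lie in (0, 0.5].")
  dens <- t[[density_col]]
  breaks <- unique(c(seq(0, 1, by = bin_width), 1))
  idx <- findInterval(dens, breaks, rightmost.closed = TRUE)
  nbin <- length(breaks) - 1
  tibble::tibble(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
                 count = tabulate(idx, nbins = nbin))
}
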