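# Shared fixture builders; everything is generated in code at test time.

tiny_phantom <- function(target = 0.15, seed = 1, noise = 0,
                         shape = c(48, 48, 48), half = "bilateral") {
  generate_phantom(phantom_spec(grid_shape = shape, target_density = target,
                                breast_half = half, noise_sd = noise,
                                seed = seed))
}

# noiseless normalized training pairs for the segmenter
training_pairs <- function(n, seed0 = 100, shape = c(48, 48, 48)) {
  lapply(seq_len(n), function(i) {
    td <- c(0.05, 0.1, 0.15, 0.2, 0.25)[(i %% 5) + 1]
    ph <- tiny_phantom(td, seed = seed0 + i, shape = shape)
    list(volume = zscore_normalize(ph$volume), mask = ph$truth$dense)
  })
}

# cohort table with a clean monotone category-density link
monotone_cohort <- function(n_per = 10, gap = 0.05) {
  dens <- c(seq(0.01, 0.03, length.out = n_per),
            seq(0.03 + gap, 0.08, length.out = n_per) + gap,
            seq(0.08 + 3 * gap, 0.18 + 3 * gap, length.out = n_per),
            seq(0.18 + 5 * gap, 0.35 + 5 * gap, length.out = n_per))
  tibble::tibble(
    exam_id = sprintf("e%03d", seq_len(4 * n_per)),
    age = rep(50, 4 * n_per),
    density = dens,
    category = density_category(rep(1:4, each = n_per))
  )
}

# first-principles rank statistics (independent of the package implementation)
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

oracle_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  (C - D) / sqrt((n0 - sum(tx * (tx - 1) / 2)) * (n0 - sum(ty * (ty - 1) / 2)))
}

oracle_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

oracle_hausdorff <- function(a, b) {
  A <- which(a, arr.ind = TRUE); B <- which(b, arr.ind = TRUE)
  dmat <- as.matrix(stats::dist(rbind(A, B)))[seq_len(nrow(A)),
                                              nrow(A) + seq_len(nrow(B)),
                                              drop = FALSE]
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}
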