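test_that("age binning floors into decades and rejects minors", {
  expect_equal(as.character(bin_age(c(29, 30, 48.8, 85))),
               c("20-29", "30-39", "40-49", "80-89"))
  expect_error(bin_age(17), ">= 18")
})

test_that("age summaries use sample SD and keep empty middle bins", {
  t <- tibble::tibble(age = c(25, 25, 45), density = c(0.1, 0.2, 0.3))
  s <- summarize_by_age(t)
  expect_equal(s$mean_density[s$age_bin == "20-29"], 0.15)
  expect_equal(s$sd_density[s$age_bin == "20-29"], sd(c(0.1, 0.2)))
  expect_equal(s$sd_density[s$age_bin == "20-29"], 0.0707, tolerance = 1e-3)
  # single-exam bin: SD absent
  expect_true(is.na(s$sd_density[s$age_bin == "40-49"]))
  # empty bin between occupied decades is reported with n = 0
  expect_equal(s$n[s$age_bin == "30-39"], 0L)
})

test_that("perfect monotone and antitone tables give rho and tau-b of +-1", {
  # matching tie patterns (one density level per category, no ties across
  # categories): both tie-corrected statistics reach exactly 1
  t <- tibble::tibble(age = rep(50, 40),
                      density = rep(c(0.02, 0.07, 0.15, 0.30), each = 10),
                      category = density_category(rep(1:4, each = 10)))
  cs <- concordance(t)
  expect_equal(cs$spearman_rho, 1)
  expect_equal(cs$kendall_tau, 1)
  expect_lt(cs$spearman_p, 1e-10)
  t_rev <- t
  t_rev$density <- rep(c(0.30, 0.15, 0.07, 0.02), each = 10)
  cs_rev <- concordance(t_rev)
  expect_equal(cs_rev$spearman_rho, -1)
  expect_equal(cs_rev$kendall_tau, -1)

  # with within-category density variation the link stays perfect in tau-b
  # terms only up to the tie correction; both remain strongly positive
  cs2 <- concordance(monotone_cohort())
  expect_gt(cs2$spearman_rho, 0.9)
  expect_gt(cs2$kendall_tau, 0.9)
})

test_that("concordance matches first-principles oracles on small random tables", {
  set.seed(19)
  for (i in 1:5) {
    n <- 30
    t <- tibble::tibble(age = rep(40, n),
                        density = runif(n),
                        category = density_category(sample(1:4, n, TRUE)))
    cs <- concordance(t)
    expect_equal(cs$spearman_rho,
                 oracle_spearman(as.integer(t$category), t$density),
                 tolerance = 1e-12)
    expect_equal(cs$kendall_tau,
                 oracle_tau_b(as.integer(t$category), t$density),
                 tolerance = 1e-12)
  }
})

test_that("concordance excludes unclassifiable rows and reports the count", {
  t <- monotone_cohort()
  t$category[1:3] <- NA
  cs <- concordance(t)
  expect_equal(cs$n_excluded, 3)
  expect_equal(cs$n_used, nrow(t) - 3)
})

test_that("degenerate concordance inputs error", {
  t <- monotone_cohort()
  t$category <- density_category(rep(2L, nrow(t)))
  expect_error(concordance(t), "identical")
  expect_error(concordance(monotone_cohort(n_per = 2)[1:5, ]), ">= 10")
})

test_that("separable categories are classified perfectly with interior thresholds", {
  t <- monotone_cohort()
  fit <- fit_density_classifier(t)
  expect_equal(fit$train_accuracy, 1)
  rng <- range(t$density[as.integer(t$category) == 1])
  rng2 <- range(t$density[as.integer(t$category) == 2])
  expect_gt(fit$thresholds[1], rng[2])
  expect_lt(fit$thresholds[1], rng2[1])
  expect_true(all(diff(fit$thresholds) > 0))
  ev <- evaluate_classifier(fit, t)
  expect_equal(ev$accuracy_4class, 1)
  expect_equal(ev$auc_binary, 1)
})

test_that("generating thresholds are recovered from a noise-free cohort", {
  co <- sample_cohort(cohort_spec(n_exams = 400, category_noise = 0, seed = 3))
  fit <- fit_density_classifier(co, density_col = "true_density")
  truth <- c(0.04, 0.10, 0.20)
  for (k in 1:3) {
    below <- max(co$true_density[co$true_density < truth[k]])
    above <- min(co$true_density[co$true_density >= truth[k]])
    expect_gte(fit$thresholds[k], below)
    expect_lte(fit$thresholds[k], above)
  }
  expect_equal(fit$train_accuracy, 1)
})

test_that("fitted thresholds are always ascending across random cohorts", {
  for (s in 1:12) {
    co <- sample_cohort(cohort_spec(n_exams = 150, category_noise = 0.25,
                                    seed = 400 + s))
    if (length(unique(as.integer(co$category))) < 4) next
    fit <- fit_density_classifier(co, density_col = "true_density")
    expect_true(all(diff(fit$thresholds) >= 0))
  }
})

test_that("a missing category is reported by name", {
  t <- monotone_cohort()
  t2 <- t[as.integer(t$category) != 4, ]
  expect_error(fit_density_classifier(t2), "Extremely dense")
})

test_that("the classifier beats majority class on noisy cohorts", {
  co <- sample_cohort(cohort_spec(n_exams = 400, category_noise = 0.2, seed = 77))
  sp <- split_cohort(co, seed = 1)
  fit <- fit_density_classifier(sp$train, density_col = "true_density")
  ev <- evaluate_classifier(fit, sp$test, density_col = "true_density")
  majority <- max(table(as.integer(sp$test$category))) / nrow(sp$test)
  expect_gt(ev$accuracy_4class, majority)
})

test_that("AUC matches the all-pairs oracle and is ~0.5 for shuffled labels", {
  set.seed(23)
  t <- tibble::tibble(age = rep(40, 50), density = runif(50),
                      category = density_category(sample(2:3, 50, TRUE)))
  fit <- list(thresholds = c(0.1, 0.3, 0.6))
  class(fit) <- "density_threshold_classifier"
  ev <- evaluate_classifier(fit, t)
  expect_identical(ev$auc_binary,
                   oracle_auc(t$density[as.integer(t$category) == 3],
                              t$density[as.integer(t$category) == 2]))
  # shuffled: large-n AUC concentrates near 1/2 (3 SE band)
  n <- 2000
  t2 <- tibble::tibble(age = rep(40, n), density = runif(n),
                       category = density_category(sample(2:3, n, TRUE)))
  ev2 <- evaluate_classifier(fit, t2)
  n2 <- sum(as.integer(t2$category) == 2); n3 <- n - n2
  se <- sqrt((n2 + n3 + 1) / (12 * n2 * n3))
  expect_lt(abs(ev2$auc_binary - 0.5), 3 * se)
  # AUC absent when a class is missing
  t3 <- t[as.integer(t$category) == 2, ]
  expect_true(is.na(evaluate_classifier(fit, t3)$auc_binary))
})

test_that("histogram bins are right-open, conserve counts and flag the low mode", {
  t <- tibble::tibble(density = rep(0.05, 7))
  h <- density_histogram(t, bin_width = 0.1)
  expect_equal(h$count[1], 7)
  expect_equal(sum(h$count), 7)
  # boundary value falls in the right-open upper bin
  h2 <- density_histogram(tibble::tibble(density = 0.1), bin_width = 0.1)
  expect_equal(h2$count[2], 1)
  expect_error(density_histogram(t, bin_width = 0.7), "0.5")
})

test_that("tidy and glance methods expose the fitted classifier", {
  fit <- fit_density_classifier(monotone_cohort())
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_equal(td$estimate, fit$thresholds)
  gl <- glance(fit)
  expect_equal(gl$train_accuracy, 1)
  pred <- predict(fit, tibble::tibble(density = c(0.005, 0.5)))
  expect_equal(as.integer(pred), c(1L, 4L))
})
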