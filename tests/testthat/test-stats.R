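test_that("descriptive summaries match closed forms", {
  tab <- data.frame(a = 1:5, b = rep(2, 5), c = c(10, 12, 9, 14, 11))
  d <- describe_measures(tab)
  da <- d[d$variable == "a", ]
  expect_equal(da$median, 3); expect_equal(da$q1, 2); expect_equal(da$q3, 4)
  db <- d[d$variable == "b", ]
  expect_equal(db$sd, 0); expect_equal(db$min, db$max)
  expect_error(describe_measures(tab[0, ]), "2 rows")
})

test_that("Kendall tau-b matches enumeration on canonical cases", {
  expect_equal(kendall_tau(1:3, 1:3)$tau, 1)
  expect_equal(kendall_tau(1:3, 3:1)$tau, -1)
  # 2 concordant, 1 discordant over 3 pairs
  expect_equal(kendall_tau(c(1, 2, 3), c(1, 3, 2))$tau, 1 / 3)
  expect_error(kendall_tau(c(1, 2, 3), c(2, 2, 2)), "zero variance")
})

test_that("Kendall tau-b equals the reference implementation, with ties", {
  # all permutations for n = 3..5 against stats::cor.test
  for (n in 3:5) {
    perms <- asplit(as.matrix(expand.grid(rep(list(1:n), n))), 1)
    perms <- Filter(function(p) !any(duplicated(p)), perms)
    x <- seq_len(n)
    for (p in perms) {
      kt <- kendall_tau(x, as.numeric(p))
      ct <- suppressWarnings(cor.test(x, as.numeric(p), method = "kendall"))
      expect_equal(kt$tau, unname(ct$estimate), tolerance = 1e-12)
    }
  }
  # tied data: tau and the tie-corrected normal-approximation p
  set.seed(14)
  for (i in 1:25) {
    n <- sample(5:9, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    kt <- kendall_tau(x, y)
    ct <- suppressWarnings(cor.test(x, y, method = "kendall"))
    expect_equal(kt$tau, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(kt$p, ct$p.value, tolerance = 1e-9)
  }
})

test_that("the Kendall matrix is symmetric and permutation-invariant", {
  set.seed(2)
  tab <- as.data.frame(matrix(rnorm(60), 15, 4))
  km <- kendall_matrix(tab)
  expect_equal(km$tau, t(km$tau))
  expect_equal(diag(km$tau), rep(1, 4), ignore_attr = TRUE)
  expect_true(all(abs(km$tau) <= 1))
  km2 <- kendall_matrix(tab[sample(15), ])
  expect_equal(km2$tau, km$tau, tolerance = 1e-12)
  # BH adjustment only increases p-values
  kmbh <- kendall_matrix(tab, adjust = "BH")
  expect_true(all(kmbh$p >= km$p - 1e-12, na.rm = TRUE))
})

test_that("ICC(A,1) is exact on frozen oracle values and edge cases", {
  s1 <- c(50.1, 47.3, 52.8, 49.0, 53.5, 45.9)
  s2 <- c(52.0, 49.5, 54.6, 51.2, 55.3, 48.1)   # ~ +2 systematic bias
  r <- icc_intra(s1, s2)
  # frozen from an independent two-way ANOVA implementation
  expect_equal(r$estimate, 0.8040136975, tolerance = 1e-9)
  expect_lt(r$ci["lower"], r$estimate); expect_gt(r$ci["upper"], r$estimate)
  # absolute agreement < consistency under a constant bias
  consistency <- (r$ms["MSR"] - r$ms["MSE"]) / (r$ms["MSR"] + r$ms["MSE"])
  expect_lt(r$estimate, unname(consistency))

  expect_equal(icc_intra(s1, s1)$estimate, 1)
  expect_equal(unname(icc_intra(s1, s1)$ci), c(1, 1))
  expect_error(icc_intra(s1[1:4], s2[1:4]), "at least 5")
  expect_error(icc_intra(rep(1, 6), rep(1, 6)), "zero total variance")
})

test_that("ICC is invariant under a common affine rescaling", {
  set.seed(6)
  b <- rnorm(20, 0, 3)
  s1 <- b + rnorm(20); s2 <- b + rnorm(20)
  r1 <- icc_intra(s1, s2)
  r2 <- icc_intra(5 + 2 * s1, 5 + 2 * s2)
  expect_equal(r2$estimate, r1$estimate, tolerance = 1e-9)
  expect_equal(r2$ci, r1$ci, tolerance = 1e-9)
})

test_that("ICC recovers a known reliability from variance components", {
  # sigma2_b = 9, sigma2_e = 1 -> ICC = 0.9; estimate and CI behaviour
  set.seed(99)
  est <- replicate(50, {
    b <- rnorm(60, 0, 3)
    icc_intra(b + rnorm(60), b + rnorm(60))$estimate
  })
  expect_lt(abs(mean(est) - 0.9), 0.02)
})

test_that("icc_table reports one row per shared measure", {
  co <- generate_cohort(cohort_spec(n = 12, seed = 8))
  t1 <- cohort_measure_table(co)[measure_names()]
  s2 <- lapply(seq_along(co), function(i) {
    lms <- generate_repeat_session(co[[i]], 0.5, seed = 100 + i)
    apply_transform(lms, compute_reorientation(lms))
  })
  t2 <- measure_table(s2)[measure_names()]
  it <- icc_table(t1, t2)
  expect_equal(sort(it$variable), sort(measure_names()))
  expect_true(all(it$icc <= 1))
  expect_true(all(it$ci_low <= it$icc & it$icc <= it$ci_high))
})

test_that("PCA matches the SVD oracle and satisfies its invariants", {
  set.seed(12)
  tab <- as.data.frame(matrix(rnorm(100), 20, 5))
  p <- pca_measures(tab)
  pr <- prcomp(tab, scale. = TRUE)      # independent SVD route
  expect_equal(p$eigenvalues, unname(pr$sdev^2), tolerance = 1e-9)
  expect_equal(sum(p$var_pct), 100, tolerance = 1e-9)
  expect_equal(sum(p$eigenvalues), 5, tolerance = 1e-9)
  # rotation orthogonal; full reconstruction of the standardized table
  expect_equal(crossprod(p$rotation), diag(5), tolerance = 1e-9,
               ignore_attr = TRUE)
  Z <- scale(as.matrix(tab))
  expect_equal(p$scores %*% t(p$rotation), Z, tolerance = 1e-9,
               ignore_attr = TRUE)
  # cos2 of each variable sums to 1 over all dimensions
  expect_equal(unname(rowSums(p$cos2)), rep(1, 5), tolerance = 1e-9)
})

test_that("PCA degenerate inputs behave as documented", {
  x <- rnorm(10)
  two <- data.frame(a = x, b = 2 * x + 3)
  p <- pca_measures(two)
  expect_equal(p$var_pct[1], 100, tolerance = 1e-9)
  expect_error(pca_measures(data.frame(a = rnorm(10), b = rep(1, 10))),
               "constant")
})
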