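test_that("KS statistic matches brute-force ECDF evaluation", {
  expect_equal(ks_statistic(1:5, 1:5), 0)
  expect_equal(ks_statistic(c(1, 2, 3), c(4, 5, 6)), 1)
  set.seed(51)
  for (rep in 1:40) {
    a <- round(rnorm(sample(2:8, 1)), sample(0:2, 1))
    b <- round(rnorm(sample(2:8, 1)), sample(0:2, 1))
    expect_equal(ks_statistic(a, b), ks_bruteforce(a, b), tolerance = 1e-12)
    ## and agrees with the reference implementation
    expect_equal(ks_statistic(a, b),
                 unname(suppressWarnings(ks.test(a, b)$statistic)),
                 tolerance = 1e-12)
  }
  expect_error(ks_statistic(numeric(0), 1:3), "empty")
})

test_that("rank-sum p-values match exhaustive enumeration", {
  ## {1,2} vs {3,4}: the most extreme of the six assignments, two-sided
  expect_equal(ranksum_test(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)
  expect_equal(ranksum_test(c(5), c(5)), 1)
  set.seed(52)
  for (rep in 1:20) {
    a <- rnorm(sample(3:6, 1))
    b <- rnorm(sample(3:6, 1))
    expect_equal(ranksum_test(a, b), wilcox_bruteforce(a, b),
                 tolerance = 1e-12)
  }
  ## clearly separated large samples
  expect_lt(ranksum_test(rnorm(200), rnorm(200, mean = 1)), 1e-10)
  expect_error(ranksum_test(numeric(0), 1), "empty")
})

test_that("build_dvoxels observed column equals the direct computation", {
  set.seed(53)
  n <- 40
  V <- 100
  Y <- matrix(rnorm(n * V), n, V)
  dl <- list(age = runif(n, 18, 88), sex = rbinom(n, 1, 0.5),
             head_motion = runif(n, 0.1, 0.3), handedness = rnorm(n, 80, 20))
  d <- build_dvoxels(Y, model_spec("I", robust = FALSE), dl, dl$age,
                     P = 29, seed = 3)
  expect_equal(dim(d), c(V, 30))
  direct <- run_model_suite(Y, list(model_spec("I", robust = FALSE)), dl)$I$r
  expect_equal(d[, 1], direct, tolerance = 1e-10)
  ## deterministic under the seed
  d2 <- build_dvoxels(Y, model_spec("I", robust = FALSE), dl, dl$age,
                      P = 29, seed = 3)
  expect_identical(d, d2)
  ## voxel-matched model: observed column still matches the suite
  dl$cbf <- matrix(rnorm(n * V), n, V)
  dl$cvh <- matrix(rnorm(n * 3), n, 3)
  d4 <- build_dvoxels(Y, model_spec("IV", robust = FALSE), dl, dl$age,
                      P = 19, seed = 4)
  direct4 <- run_model_suite(Y, list(model_spec("IV", robust = FALSE)),
                             dl)$IV$r
  expect_equal(d4[, 1], direct4, tolerance = 1e-10)
})

test_that("tiny cohorts cannot request more permutations than exist", {
  Y <- matrix(rnorm(5 * 60), 5, 60)
  dl <- list(age = runif(5, 18, 88), sex = c(0, 1, 0, 1, 0),
             head_motion = runif(5), handedness = rnorm(5))
  expect_error(build_dvoxels(Y, model_spec("I"), dl, dl$age, P = 120,
                             seed = 1),
               "distinct")
})

test_that("permuted medians bracket the observed median under the null", {
  set.seed(54)
  n <- 20
  V <- 200
  hits <- 0
  runs <- 30
  for (i in seq_len(runs)) {
    Y <- matrix(rnorm(n * V), n, V)
    dl <- list(age = runif(n, 18, 88), sex = rbinom(n, 1, 0.5),
               head_motion = runif(n), handedness = rnorm(n))
    d <- build_dvoxels(Y, model_spec("I", robust = FALSE), dl, dl$age,
                       P = 39, seed = i)
    med <- apply(d, 2, median)
    lo <- quantile(med[-1], 0.05)
    hi <- quantile(med[-1], 0.95)
    hits <- hits + (med[1] >= lo && med[1] <= hi)
  }
  expect_gte(hits, 0.7 * runs)
})

test_that("median and shape comparisons behave at the null and under shift", {
  set.seed(55)
  n <- 30
  V <- 300
  Y <- matrix(rnorm(n * V), n, V)
  dl <- list(age = runif(n, 18, 88), sex = rbinom(n, 1, 0.5),
             head_motion = runif(n), handedness = rnorm(n))
  d <- build_dvoxels(Y, model_spec("I", robust = FALSE), dl, dl$age,
                     P = 99, seed = 8)
  ms <- compare_median_and_shape(d)
  expect_gt(ms$median_p, 0.01)
  ## shifting the observed distribution makes the median test fire
  d_shift <- d
  d_shift[, 1] <- d_shift[, 1] + 0.5
  expect_lt(compare_median_and_shape(d_shift)$median_p, 1e-3)
  ## observed identical to one permuted draw: the shape test is calibrated
  ## (rarely small) across which draw is substituted
  shape_ps <- vapply(2:31, function(j) {
    d_same <- d
    d_same[, 1] <- d[, j]
    compare_median_and_shape(d_same)$shape_p
  }, numeric(1))
  expect_lte(mean(shape_ps < 0.05), 0.2)
  expect_gt(median(shape_ps), 0.2)
  ## per-permutation variant returns one p per permutation
  pp <- compare_median_and_shape(d, pooled = FALSE)
  expect_length(pp$median_p, 99)
})

test_that("similarity profiles count and ratio have the right structure", {
  ## twenty identical distributions: all KS distances zero, nothing differs
  d0 <- matrix(rep(sort(rnorm(50)), 20), 50, 20)
  r0 <- similarity_np_ratio(d0)
  expect_true(all(r0$similarity == 0))
  expect_equal(r0$np, 0)
  expect_equal(r0$p_ratio, 1)
  expect_false(r0$significant)
  ## symmetry and empty diagonal
  set.seed(56)
  d <- matrix(rnorm(60 * 25), 60, 25)
  r <- similarity_np_ratio(d)
  expect_equal(r$similarity, t(r$similarity))
  expect_true(all(diag(r$similarity) == 0))
  expect_length(r$d_similarity[[1]], 24)
  expect_true(r$p_ratio >= 0 && r$p_ratio <= 1)
  expect_true(r$np >= 0 && r$np <= 24)
  expect_error(similarity_np_ratio(d[, 1:10]), "at least 20")
})

test_that("a gross shape difference is detected, the null is not", {
  set.seed(57)
  n <- 60
  V <- 400
  Y <- matrix(rnorm(n * V), n, V)
  dl <- list(age = runif(n, 18, 88), sex = rbinom(n, 1, 0.5),
             head_motion = runif(n), handedness = rnorm(n))
  d <- build_dvoxels(Y, model_spec("I", robust = FALSE), dl, dl$age,
                     P = 99, seed = 12)
  null_res <- similarity_np_ratio(d)
  expect_false(null_res$significant)
  d_alt <- d
  d_alt[, 1] <- d_alt[, 1] * sqrt(5)
  alt_res <- similarity_np_ratio(d_alt)
  expect_true(alt_res$significant)
  expect_gt(alt_res$np, 90)
})

test_that("tissue variants split the analysis by class", {
  set.seed(58)
  n <- 60
  V <- 300
  Y <- matrix(rnorm(n * V), n, V)
  dl <- list(age = runif(n, 18, 88), sex = rbinom(n, 1, 0.5),
             head_motion = runif(n), handedness = rnorm(n))
  ## all-GM labels: GM result equals the whole-brain result
  all_gm <- rep("GM", V)
  tv <- run_tissue_variants(Y, all_gm, model_spec("I", robust = FALSE),
                            dl, dl$age, P = 29, seed = 2,
                            classes = "GM")
  expect_equal(tv$results$GM$p_ratio, tv$results$whole_brain$p_ratio)
  expect_equal(tv$results$GM$np, tv$results$whole_brain$np)

  ## probability maps: strict > 0.4 threshold
  probs <- list(GM = c(0.39, 0.41, rep(0.9, V - 2)))
  keep <- probs$GM > 0.4
  expect_equal(sum(keep), V - 1)
  tvp <- run_tissue_variants(Y, probs, model_spec("I", robust = FALSE),
                             dl, dl$age, P = 29, seed = 2, classes = "GM")
  expect_equal(tvp$results$GM$n_perm, 29)

  ## missing class is skipped with a warning
  expect_warning(
    run_tissue_variants(Y, all_gm, model_spec("I", robust = FALSE),
                        dl, dl$age, P = 29, seed = 2,
                        classes = c("GM", "CSF")),
    "CSF")
})

test_that("age signal confined to GM voxels fires only the GM variant", {
  set.seed(59)
  n <- 80
  V <- 400
  labels <- rep(c("GM", "WM"), each = V / 2)
  fires_gm <- 0
  fires_wm <- 0
  runs <- 5
  for (i in seq_len(runs)) {
    age <- runif(n, 18, 88)
    Y <- matrix(rnorm(n * V), n, V)
    Y[, labels == "GM"] <- Y[, labels == "GM"] + outer(scale(age)[, 1],
                                                       rep(0.8, V / 2))
    dl <- list(age = age, sex = rbinom(n, 1, 0.5), head_motion = runif(n),
               handedness = rnorm(n))
    tv <- run_tissue_variants(Y, labels, model_spec("I", robust = FALSE),
                              dl, age, P = 99, seed = i * 11,
                              classes = c("GM", "WM"))
    fires_gm <- fires_gm + tv$results$GM$significant
    fires_wm <- fires_wm + tv$results$WM$significant
  }
  expect_gte(fires_gm, 4)
  expect_lte(fires_wm, 1)
})
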