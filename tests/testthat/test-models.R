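test_that("model specifications encode the six nested models", {
  expect_equal(model_spec("I")$predictors, character(0))
  expect_setequal(model_spec("IV")$predictors, c("CBF", "CVH"))
  expect_equal(model_spec("VI")$predictors, "GMV_orth_CVH")
  ## CSF covariate enters exactly when GMV is a predictor
  expect_true("CSF_signal" %in% model_spec("V")$covariates)
  expect_true("CSF_signal" %in% model_spec("VI")$covariates)
  expect_false("CSF_signal" %in% model_spec("IV")$covariates)
  expect_error(model_spec("VII"))
})

test_that("first-stage fit is exact on noiseless data and orthogonal in OLS", {
  set.seed(31)
  n <- 80
  X <- cbind(1, matrix(rnorm(n * 3), n, 3))
  beta <- c(2, -1, 0.5, 3)
  y <- as.numeric(X %*% beta)
  for (rob in c(TRUE, FALSE)) {
    fit <- fit_first_stage(y, X, robust = rob)
    expect_lt(max(abs(fit$residuals)), 1e-8)
    expect_lt(max(abs(fit$coefficients - beta)), 1e-6)
  }
  ## OLS residuals orthogonal to every design column
  y2 <- y + rnorm(n)
  r2 <- fit_first_stage(y2, X, robust = FALSE)$residuals
  expect_lt(max(abs(crossprod(X, r2))), 1e-8)

  expect_error(fit_first_stage(y, cbind(X, X[, 2]), robust = FALSE),
               "collinear")
  expect_error(fit_first_stage(c(NA, y[-1]), X), "missing")
})

test_that("robust fitting beats OLS under gross outliers", {
  set.seed(32)
  n <- 100
  beta <- c(1, 2, -1)
  wins <- 0
  for (rep in 1:50) {
    X <- cbind(1, matrix(rnorm(n * 2), n, 2))
    y <- as.numeric(X %*% beta) + rnorm(n, 0, 0.5)
    out <- sample(n, 10)
    y[out] <- y[out] + sample(c(-1, 1), 10, TRUE) * runif(10, 8, 15)
    b_r <- fit_first_stage(y, X, robust = TRUE)$coefficients
    b_o <- fit_first_stage(y, X, robust = FALSE)$coefficients
    wins <- wins + (sum((b_r - beta)^2) < sum((b_o - beta)^2))
  }
  expect_gt(wins, 40)
})

test_that("GMV orthogonalization removes exactly the CVH-explained part", {
  set.seed(33)
  n <- 500
  cvh <- matrix(rnorm(n * 3), n, 3)
  ## exact linear function of CVH vanishes
  g_lin <- cvh %*% c(1, -2, 0.5) + 3
  expect_lt(max(abs(orthogonalize_gmv(g_lin, cvh))), 1e-8)
  ## output orthogonal to every CVH score
  G <- cvh %*% matrix(rnorm(6), 3, 2) + matrix(rnorm(n * 2), n, 2)
  O <- orthogonalize_gmv(G, cvh)
  expect_lt(max(abs(cor(O, cvh))), 1e-8)
  ## independent GMV passes through essentially unchanged
  G2 <- matrix(rnorm(n * 2), n, 2)
  O2 <- orthogonalize_gmv(G2, cvh)
  expect_true(all(diag(cor(O2, G2)) >= 0.99))
})

test_that("residual-age correlation matches the textbook formula", {
  set.seed(34)
  n <- 60
  age <- runif(n, 18, 88)
  R <- matrix(rnorm(n * 5), n, 5)
  res <- correlate_residuals_age(R, age)
  for (j in 1:5) {
    ct <- cor.test(R[, j], age)
    expect_equal(res$r[j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p[j], ct$p.value, tolerance = 1e-12)
  }
  ## residuals equal to age: perfect correlation
  perfect <- correlate_residuals_age(cbind(age), age)
  expect_equal(perfect$r, 1, tolerance = 1e-12)
  expect_lt(perfect$p, 1e-50)
  ## first-stage design containing age forces zero correlation
  X <- cbind(1, age)
  r0 <- qr.resid(qr(X), rnorm(n))
  expect_lt(abs(correlate_residuals_age(cbind(r0), age)$r), 1e-10)
  ## constant residual vector is flagged, not propagated
  cc <- correlate_residuals_age(cbind(rep(1, n), rnorm(n)), age)
  expect_true(is.na(cc$r[1]) && !is.na(cc$r[2]))
  expect_false(cc$fdr_mask[1])
})

test_that("Benjamini-Hochberg mask matches brute-force step-up", {
  got <- fdr_bh(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_true(all(got$mask))
  expect_false(any(fdr_bh(rep(1, 10), 0.05)$mask))
  expect_equal(fdr_bh(numeric(0), 0.05)$mask, logical(0))
  set.seed(35)
  for (rep in 1:50) {
    p <- runif(sample(5:80, 1))^sample(1:3, 1)
    expect_identical(fdr_bh(p, 0.05)$mask, bh_bruteforce(p, 0.05))
  }
})

test_that("BH keeps the realized false-discovery rate at the nominal level", {
  set.seed(36)
  m <- 200
  ## under the global null every rejection is false: FDR = P(any rejection)
  fdr <- mean(replicate(400, any(fdr_bh(runif(m), 0.05)$mask)))
  expect_lt(fdr, 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
})

test_that("model suite reproduces the mediation pattern on one cohort", {
  co <- default_cohort(seed = 1)
  dl <- cohort_data_list(co)
  suite <- suppressWarnings(run_model_suite(
    co$maps$rsfa, list(model_spec("I"), model_spec("III"),
                       model_spec("IV")), dl))
  n_sig <- vapply(suite, function(r) sum(r$fdr_mask, na.rm = TRUE),
                  numeric(1))
  ## covariates-only model finds widespread residual age effects ...
  expect_gt(n_sig[["I"]], 100)
  ## ... concentrated inside the planted source supports
  support <- colSums(co$truth$source_maps > 0) > 0
  expect_gt(mean(support[suite$I$fdr_mask]), 0.95)
  ## conditioning on the vascular predictors abolishes them
  expect_lt(n_sig[["III"]], n_sig[["I"]] / 4)
  expect_equal(unname(n_sig[["IV"]]), 0)
  ## shrinkage of the correlation distribution, not just the mask
  expect_lt(median(abs(suite$IV$r)), median(abs(suite$I$r)))
})

test_that("a GMV predictor unrelated to RSFA reproduces the covariate-only model", {
  spec <- cohort_spec(n_subjects = 250, seed = 41,
                      mediation = list(cvh_rsfa = 0.6, cbf_rsfa = 0.5,
                                       age_cbf = -0.5, age_gmv = 0,
                                       cvh_gmv = 0))
  co <- simulate_cohort(spec)
  dl <- cohort_data_list(co)
  suite <- suppressWarnings(run_model_suite(
    co$maps$rsfa, list(model_spec("I"), model_spec("V")), dl))
  a <- which(suite$I$fdr_mask)
  b <- which(suite$V$fdr_mask)
  jac <- length(intersect(a, b)) / length(union(a, b))
  expect_gte(jac, 0.8)
})

test_that("component-level analysis agrees with voxel-level conclusions", {
  co <- default_cohort(seed = 1)
  dl <- cohort_data_list(co)
  dec_rsfa <- fit_group_ica(co$maps$rsfa, 4, seed = 7)
  dl_comp <- dl
  dl_comp$cbf <- fit_group_ica(co$maps$cbf, 4, seed = 7)
  dl_comp$gmv <- fit_group_ica(co$maps$gmv, 4, seed = 7)
  suite <- suppressWarnings(run_model_suite(
    dec_rsfa, list(model_spec("I"), model_spec("IV")), dl_comp,
    level = "component"))
  ## age-residual signal present under covariates only, absent under IV
  expect_gt(max(abs(suite$I$r)), 0.3)
  expect_true(all(abs(suite$IV$r) < 0.2))

  ## voxels inside a source support and that source's loadings agree in sign
  m <- match_components(dec_rsfa, co$truth)
  rv <- suppressWarnings(run_model_suite(co$maps$rsfa,
                                         list(model_spec("I")), dl))$I
  for (i in seq_len(nrow(m))) {
    comp_r <- suite$I$r[m$est[i]] * sign(m$r[i])
    sup <- co$truth$source_maps[m$truth[i], ] > 0
    vox_r <- median(rv$r[sup])
    if (abs(comp_r) > 0.15 && abs(vox_r) > 0.15) {
      expect_equal(sign(comp_r), sign(vox_r))
    }
  }
})

test_that("robust and OLS pipelines are deterministic and consistent", {
  co <- default_cohort(seed = 1)
  dl <- cohort_data_list(co)
  s1 <- suppressWarnings(run_model_suite(co$maps$rsfa,
                                         list(model_spec("II")), dl))
  s2 <- suppressWarnings(run_model_suite(co$maps$rsfa,
                                         list(model_spec("II")), dl))
  expect_identical(s1$II$r, s2$II$r)
})
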