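## Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

## Desk-scale cohort with the default mediation structure (age acts on RSFA
## only through CVH and CBF), memoized across test files.
default_cohort <- function(seed = 1, n_subjects = 250) {
  key <- sprintf("cohort-%d-%d", seed, n_subjects)
  if (is.null(.fixture_env[[key]])) {
    spec <- cohort_spec(n_subjects = n_subjects, seed = seed)
    .fixture_env[[key]] <- c(simulate_cohort(spec), list(spec = spec))
  }
  .fixture_env[[key]]
}

## Analysis-ready predictor/covariate list for a cohort, with CVH factor
## scores estimated by the package's own factor pipeline.
cohort_data_list <- function(co, level = "voxel") {
  cm <- normality_transform(as.matrix(
    co$subjects[, c("HR", "LF_HRV", "HF_HRV", "BP_sys", "BP_dia",
                    "WMH", "BMI")]))
  efa <- suppressWarnings(fit_efa(cm, 3))
  labels <- co$truth$tissue_labels
  list(age = co$subjects$age, sex = co$subjects$sex,
       head_motion = co$subjects$head_motion,
       handedness = co$subjects$handedness,
       cvh = efa$scores,
       cbf = co$maps$cbf, gmv = co$maps$gmv,
       CSF_signal = rowMeans(
         co$maps$gmv$values[, labels == "CSF", drop = FALSE]))
}

cvh_raw_matrix <- function(subjects) {
  as.matrix(subjects[, c("HR", "LF_HRV", "HF_HRV", "BP_sys", "BP_dia",
                         "WMH", "BMI")])
}

## Independent normal-equations least-squares oracle: residuals via
## explicit solve of X'X b = X'y (no QR), for cross-checking compute_rsfa
## and first-stage fits.
normal_equations_residuals <- function(X, Y) {
  B <- solve(crossprod(X), crossprod(X, Y))
  Y - X %*% B
}

## Brute-force Benjamini-Hochberg step-up: reject all p <= p_(i*) where
## i* is the largest i with p_(i) <= i q / m, by direct enumeration.
bh_bruteforce <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * q / m)
  mask <- rep(FALSE, m)
  if (length(ok)) mask[p <= ps[max(ok)]] <- TRUE
  mask
}

## Exhaustive two-sample KS oracle: evaluate |F_a - F_b| on the pooled
## support grid directly from counting definitions.
ks_bruteforce <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  Fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  max(abs(Fa - Fb))
}

## Exhaustive two-sided Wilcoxon rank-sum p-value: enumerate all
## choose(n1+n2, n1) group assignments of the pooled sample.
wilcox_bruteforce <- function(a, b) {
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  Ws <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (length(b)) / 2
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-12)
}
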