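## Latent cardiovascular-health (CVH) factors: normality-checked transforms
## of the seven raw measures (heart rate, LF/HF heart-rate variability,
## systolic/diastolic blood pressure, white-matter hyperintensities, BMI)
## followed by exploratory maximum-likelihood factor analysis.

cvh_variables <- c("HR", "LF_HRV", "HF_HRV", "BP_sys", "BP_dia", "WMH", "BMI")

ks_normal_p <- function(x) {
  suppressWarnings(
    stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value
  )
}

#' Normality-checked transform of raw cardiovascular measures
#'
#' Each variable is tested against a normal distribution with its own
#' sample mean and SD (one-sample Kolmogorov-Smirnov test, no Lilliefors
#' correction). Variables failing at `alpha` are log-transformed (they must
#' be strictly positive) and re-tested; the actions taken are recorded.
#'
#' @param raw Subjects x variables numeric matrix or data frame (typically
#'   the 7 CVH columns of a subject table).
#' @param alpha Significance level of the normality test (default 0.05).
#' @return List of class `cvh_matrix`: `values` (transformed matrix),
#'   `transform` (per-variable `"none"` or `"log"`), `ks_p_before`,
#'   `ks_p_after`.
#' @export
normality_transform <- function(raw, alpha = 0.05) {
  X <- as.matrix(raw)
  if (anyNA(X)) stop("missing values in cardiovascular measures")
  if (nrow(X) < 20) stop("need at least 20 subjects for the normality check")
  vars <- colnames(X)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(X)))
  transform <- setNames(rep("none", ncol(X)), vars)
  p_before <- setNames(apply(X, 2, ks_normal_p), vars)
  p_after <- p_before
  for (j in seq_len(ncol(X))) {
    if (p_before[j] < alpha) {
      if (any(X[, j] <= 0)) {
        stop(sprintf("variable %s deviates from normality but has nonpositive values; cannot log-transform",
                     vars[j]))
      }
      X[, j] <- log(X[, j])
      transform[j] <- "log"
      p_after[j] <- ks_normal_p(X[, j])
    }
  }
  structure(list(values = X, transform = transform,
                 ks_p_before = p_before, ks_p_after = p_after),
            class = "cvh_matrix")
}

#' Exploratory maximum-likelihood factor analysis
#'
#' Fits a common-factor model to the standardized variables by maximum
#' likelihood with varimax rotation and regression-method scores. Factors
#' are ordered by explained variance (sum of squared loadings, descending)
#' and sign-fixed so each factor's largest-magnitude loading is positive;
#' scores are standardized to mean 0, SD 1. Uniquenesses are floored at
#' 1e-3; hitting the floor (a Heywood case) raises a warning.
#'
#' @param X A `cvh_matrix` (from [normality_transform()]) or a numeric
#'   matrix.
#' @param k Number of factors (< number of variables).
#' @return List of class `factor_solution`: `loadings` (variables x k),
#'   `uniquenesses`, `scores` (subjects x k, standardized), `k`, `rotation`.
#' @export
fit_efa <- function(X, k) {
  V <- if (inherits(X, "cvh_matrix")) X$values else as.matrix(X)
  p <- ncol(V)
  if (k >= p) stop("number of factors must be below the number of variables")
  Vs <- scale(V)
  fa <- tryCatch(
    stats::factanal(x = Vs, factors = k, rotation = "varimax",
                    scores = "regression",
                    control = list(lower = 1e-3)),
    error = function(e) stop(sprintf("factor analysis failed to converge: %s",
                                     conditionMessage(e)))
  )
  L <- unclass(fa$loadings)[, , drop = FALSE]
  sc <- fa$scores
  if (any(fa$uniquenesses <= 1e-3 + 1e-8)) {
    warning("Heywood case: uniqueness clamped at the 1e-3 floor")
  }
  ## order by explained variance, then fix signs
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  sc <- sc[, ord, drop = FALSE]
  for (j in seq_len(k)) {
    if (L[which.max(abs(L[, j])), j] < 0) {
      L[, j] <- -L[, j]
      sc[, j] <- -sc[, j]
    }
  }
  colnames(L) <- colnames(sc) <- paste0("CVH", seq_len(k))
  structure(list(loadings = L, uniquenesses = fa$uniquenesses,
                 scores = scale(sc), k = k, rotation = "varimax",
                 criteria = fa$criteria),
            class = "factor_solution")
}

#' Choose the number of factors
#'
#' Kaiser rule: number of correlation-matrix eigenvalues exceeding 1.
#' An explicit `override` (e.g. the three-factor structure used throughout
#' the analysis) takes precedence when supplied.
#'
#' @param X A `cvh_matrix` or numeric matrix.
#' @param override Optional fixed factor count.
#' @return Integer factor count.
#' @export
choose_n_factors <- function(X, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  V <- if (inherits(X, "cvh_matrix")) X$values else as.matrix(X)
  ev <- eigen(stats::cor(V), symmetric = TRUE, only.values = TRUE)$values
  sum(ev > 1)
}

#' Tucker congruence between two loading matrices
#'
#' Congruence coefficient per matched factor pair after optimal
#' sign/permutation matching (exhaustive over permutations).
#'
#' @param est,truth Variables x k loading matrices.
#' @return Numeric vector of matched congruence coefficients (length k).
#' @export
tucker_congruence <- function(est, truth) {
  k <- ncol(truth)
  stopifnot(ncol(est) == k)
  phi <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  C <- outer(seq_len(k), seq_len(k),
             Vectorize(function(i, j) phi(est[, i], truth[, j])))
  perms <- permutations_of(k)
  best <- NULL
  best_val <- -Inf
  for (p in perms) {
    v <- sum(C[cbind(p, seq_len(k))])
    if (v > best_val) {
      best_val <- v
      best <- p
    }
  }
  C[cbind(best, seq_len(k))]
}

## all permutations of 1..n (n small)
permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in permutations_of(n - 1)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1]] <- c(i, rest[p])
    }
  }
  out
}
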