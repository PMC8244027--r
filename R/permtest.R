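## Distribution-shape permutation test: compares the distribution of
## voxel-wise age-residual correlations with its permutation null via
## pairwise Kolmogorov-Smirnov similarity profiles and Wilcoxon counting
## (D_Voxels, D_Similarity, Np, and the Np/(P+1) significance ratio).

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' Supremum distance between the empirical CDFs of `a` and `b`, with tie
#' handling; optionally the asymptotic two-sided p-value.
#'
#' @param a,b Nonempty numeric samples.
#' @param return_p Also compute the asymptotic p-value.
#' @return `D` in `[0, 1]`, or `list(D, p)` when `return_p`.
#' @export
ks_statistic <- function(a, b, return_p = FALSE) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  n1 <- length(a)
  n2 <- length(b)
  w <- c(a, b)
  ord <- order(w)
  z <- cumsum(ifelse(ord <= n1, 1 / n1, -1 / n2))
  ws <- w[ord]
  ## at ties, only the value after the last tied observation is a valid
  ## evaluation point of the ECDF difference
  valid <- c(diff(ws) != 0, TRUE)
  D <- max(abs(z[valid]))
  if (!return_p) return(D)
  p <- suppressWarnings(stats::ks.test(a, b, exact = FALSE)$p.value)
  list(D = D, p = p)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when both samples have at most 10 observations and no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction.
#'
#' @param a,b Nonempty numeric samples.
#' @return Two-sided p-value.
#' @export
ranksum_test <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  if (length(unique(c(a, b))) == 1) return(1)   # fully tied: no evidence
  use_exact <- length(a) <= 10 && length(b) <= 10 &&
    !any(duplicated(c(a, b)))
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)$p.value
  )
}

## Residual-age correlations for each column of the (P+1)-wide stack of
## subject orderings. Y: subjects x voxels RSFA; perms: n x (P+1) index
## matrix (column 1 = identity). Returns voxels x (P+1).
dvoxels_from_perms <- function(Y, spec, data, age, perms, level = "voxel") {
  n <- nrow(Y)
  V <- ncol(Y)
  P1 <- ncol(perms)
  covs <- covariate_block(spec, data)
  glob <- global_predictors(spec, data)
  X_shared <- cbind(1, covs, glob)
  vm_preds <- intersect(spec$predictors, spec$voxel_matched)
  out <- matrix(NA_real_, V, P1)
  a_c <- age - mean(age)
  a_n <- sqrt(sum(a_c^2))

  corr_cols <- function(Rm) {
    ## Pearson r of centered age with each column of a residual matrix
    Rc <- sweep(Rm, 2L, colMeans(Rm))
    as.numeric(crossprod(a_c, Rc) / (a_n * sqrt(colSums(Rc^2))))
  }

  if (length(vm_preds) == 0 || level == "component") {
    if (length(vm_preds) && level == "component") {
      for (pr in vm_preds) {
        M <- switch(pr,
          CBF = target_matrix(data$cbf),
          GMV = target_matrix(data$gmv),
          GMV_orth_CVH = orthogonalize_gmv(target_matrix(data$gmv),
                                           data$cvh))
        X_shared <- cbind(X_shared, M)
      }
    }
    qrX <- qr(X_shared)
    for (i in seq_len(P1)) {
      out[, i] <- corr_cols(qr.resid(qrX, Y[perms[, i], , drop = FALSE]))
    }
  } else {
    vm <- lapply(setNames(vm_preds, vm_preds), function(pr) {
      switch(pr,
        CBF = target_matrix(data$cbf),
        GMV = target_matrix(data$gmv),
        GMV_orth_CVH = orthogonalize_gmv(target_matrix(data$gmv), data$cvh))
    })
    for (v in seq_len(V)) {
      Xv <- X_shared
      for (pr in vm_preds) Xv <- cbind(Xv, vm[[pr]][, v])
      qrv <- qr(Xv)
      Yv <- matrix(Y[, v][perms], n, P1)   # permuted copies of this voxel
      out[v, ] <- corr_cols(qr.resid(qrv, Yv))
    }
  }
  out
}

#' Build the observed and permuted correlation distributions (D_Voxels)
#'
#' Column 1 holds the observed voxel-wise age-residual correlations under
#' the model; columns 2..P+1 repeat the computation after jointly permuting
#' the subject labels of the RSFA matrix (one permutation of rows per
#' iteration, shared across voxels, which preserves the spatial correlation
#' structure within each null draw). The first-stage design is the observed
#' one throughout; only RSFA is permuted. Fits are OLS (see the package
#' vignette for the rationale; robust refits inside permutations are
#' available via `robust_perm`).
#'
#' @param rsfa Subjects x voxels matrix (or `map_matrix`).
#' @param spec A [model_spec()] or model-id string.
#' @param data Predictor/covariate list as in [run_model_suite()].
#' @param age Subject ages.
#' @param P Number of permutations (>= 19).
#' @param seed RNG seed.
#' @param robust_perm Recompute robust fits inside permutations (slow;
#'   default `FALSE` uses OLS for observed and permuted alike).
#' @param level `"voxel"` or `"component"`.
#' @return Voxels x (P+1) matrix of correlations, observed first.
#' @export
build_dvoxels <- function(rsfa, spec, data, age, P = 199, seed = 1,
                          robust_perm = FALSE, level = "voxel") {
  if (P < 19) stop("P must be at least 19")
  Y <- target_matrix(rsfa)
  n <- nrow(Y)
  if (n <= 12 && P > factorial(n) - 1) {
    stop(sprintf("P = %d exceeds the %d distinct non-identity permutations of %d subjects",
                 P, factorial(n) - 1, n))
  }
  if (!inherits(spec, "model_spec")) spec <- model_spec(spec)
  perms <- with_seed(substream_seed(seed, "dvoxels"), {
    cbind(seq_len(n),
          vapply(seq_len(P), function(i) sample.int(n), integer(n)))
  })
  if (robust_perm) {
    V <- ncol(Y)
    out <- matrix(NA_real_, V, P + 1)
    for (i in seq_len(P + 1)) {
      res <- first_stage_residual_matrix(Y[perms[, i], , drop = FALSE],
                                         spec, data, level)
      out[, i] <- as.numeric(stats::cor(age, res))
    }
    out
  } else {
    spec$robust <- FALSE
    dvoxels_from_perms(Y, spec, data, age, perms, level)
  }
}

#' Compare the observed distribution's median and shape to the null
#'
#' Wilcoxon rank-sum test (medians) and Kolmogorov-Smirnov test (shapes)
#' of the observed correlation distribution against the permutation null.
#' By default the P permuted distributions are pooled; `pooled = FALSE`
#' instead tests against each permuted distribution separately and returns
#' the per-permutation p-value vectors.
#'
#' @param d Voxels x (P+1) matrix from [build_dvoxels()].
#' @param pooled Pool the permuted columns (default `TRUE`).
#' @return List with `median_p` and `shape_p` (scalars when pooled,
#'   vectors otherwise).
#' @export
compare_median_and_shape <- function(d, pooled = TRUE) {
  obs <- d[, 1]
  if (pooled) {
    null_pool <- as.numeric(d[, -1])
    list(median_p = ranksum_test(obs, null_pool),
         shape_p = ks_statistic(obs, null_pool, return_p = TRUE)$p)
  } else {
    list(
      median_p = apply(d[, -1, drop = FALSE], 2,
                       function(x) ranksum_test(obs, x)),
      shape_p = apply(d[, -1, drop = FALSE], 2,
                      function(x) ks_statistic(obs, x, return_p = TRUE)$p)
    )
  }
}

## Pairwise KS statistic matrix between the columns of d (pre-sorted once).
ks_similarity_matrix <- function(d) {
  P1 <- ncol(d)
  V <- nrow(d)
  sorted <- apply(d, 2, sort)
  sim <- matrix(0, P1, P1)
  for (i in seq_len(P1 - 1)) {
    for (j in (i + 1):P1) {
      sim[i, j] <- sim[j, i] <- ks_statistic(sorted[, i], sorted[, j])
    }
  }
  sim
}

#' Similarity profiles, Np count and significance ratio
#'
#' Computes the pairwise KS-statistic similarity matrix of all P+1
#' correlation distributions; each distribution's similarity profile
#' (D_Similarity) is its row without the diagonal. `np` counts how often
#' the observed profile is statistically different from a permuted profile
#' (Wilcoxon rank-sum, two-sided, at `alpha`). The significance level of
#' the procedure is the Monte-Carlo ratio
#' `p_ratio = (P - np + 1) / (P + 1)`: the (add-one corrected) fraction of
#' the permutation ensemble whose similarity profile the observed profile
#' is indistinguishable from. A small ratio (below `alpha`) means the
#' observed correlation distribution resembles almost none of the null
#' draws and is declared significant.
#'
#' @param d Voxels x (P+1) matrix from [build_dvoxels()].
#' @param alpha Significance level inside the counting (default 0.05).
#' @param tissue_class Tag stored in the result.
#' @return List of class `perm_dist_result`: `similarity`, `d_similarity`
#'   (list of per-index profiles), `np`, `p_ratio`, `significant`,
#'   `median_p`, `shape_p`, `tissue_class`, `n_perm`.
#' @export
similarity_np_ratio <- function(d, alpha = 0.05, tissue_class = "whole_brain") {
  P1 <- ncol(d)
  if (P1 < 20) stop("need at least 20 distributions (P + 1 >= 20)")
  sim <- ks_similarity_matrix(d)
  profiles <- lapply(seq_len(P1), function(i) sim[i, -i])
  np <- sum(vapply(2:P1, function(j) {
    ranksum_test(profiles[[1]], profiles[[j]]) < alpha
  }, logical(1)))
  p_ratio <- (P1 - 1 - np + 1) / P1
  ms <- compare_median_and_shape(d)
  structure(list(similarity = sim, d_similarity = profiles, np = np,
                 p_ratio = p_ratio, significant = p_ratio < alpha,
                 median_p = ms$median_p, shape_p = ms$shape_p,
                 tissue_class = tissue_class, n_perm = P1 - 1),
            class = "perm_dist_result")
}

#' Full distribution-shape permutation test for one model
#'
#' Chains [build_dvoxels()] and [similarity_np_ratio()].
#'
#' @inheritParams build_dvoxels
#' @inheritParams similarity_np_ratio
#' @return A `perm_dist_result`.
#' @export
dist_perm_test <- function(rsfa, spec, data, age, P = 199, alpha = 0.05,
                           seed = 1, tissue_class = "whole_brain",
                           robust_perm = FALSE, level = "voxel") {
  d <- build_dvoxels(rsfa, spec, data, age, P = P, seed = seed,
                     robust_perm = robust_perm, level = level)
  similarity_np_ratio(d, alpha = alpha, tissue_class = tissue_class)
}

#' Tissue-wise distribution-shape permutation tests
#'
#' Repeats the full procedure on the whole brain and on the voxel subsets
#' of each tissue class: voxels with class probability above `threshold`
#' (default 0.4) when probability maps are given, or exact label matches
#' when a label vector is given. Empty classes are skipped with a warning.
#'
#' @param rsfa Subjects x voxels matrix or `map_matrix`.
#' @param tissue Either a factor/character vector of per-voxel labels
#'   (levels among GM/WM/CSF) or a named list of per-voxel probability
#'   vectors.
#' @param spec,data,age,P,alpha,seed,robust_perm As in [dist_perm_test()].
#' @param threshold Probability threshold for class membership.
#' @param classes Tissue classes to test.
#' @return List with `results` (named list of `perm_dist_result`) and
#'   `table` (a data frame with one row per model-variant and the p-ratio
#'   per tissue class, the report layout used for the analysis).
#' @export
run_tissue_variants <- function(rsfa, tissue, spec, data, age, P = 199,
                                alpha = 0.05, seed = 1, threshold = 0.4,
                                classes = c("GM", "WM", "CSF"),
                                robust_perm = FALSE) {
  Y <- target_matrix(rsfa)
  V <- ncol(Y)
  subsets <- list(whole_brain = rep(TRUE, V))
  for (cl in classes) {
    keep <- if (is.list(tissue)) {
      if (is.null(tissue[[cl]])) rep(FALSE, V) else
        as.numeric(tissue[[cl]]) > threshold
    } else {
      as.character(tissue) == cl
    }
    if (!any(keep)) {
      warning(sprintf("no voxels in tissue class %s; skipped", cl))
      next
    }
    subsets[[cl]] <- keep
  }
  results <- lapply(names(subsets), function(nm) {
    dist_perm_test(Y[, subsets[[nm]], drop = FALSE], spec, data, age,
                   P = P, alpha = alpha, seed = seed, tissue_class = nm,
                   robust_perm = robust_perm)
  })
  names(results) <- names(subsets)
  spec_id <- if (inherits(spec, "model_spec")) spec$id else spec
  tab <- data.frame(model = spec_id, t(vapply(results, `[[`, numeric(1),
                                              "p_ratio")))
  list(results = results, table = tab)
}
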