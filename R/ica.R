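## Group spatial ICA of a subjects x voxels modality matrix
## (source-based-morphometry orientation: subjects are observations mixed
## from spatial sources, voxels are samples). PCA order selection by the
## eigenvalue-based MDL criterion; un-mixing by the fastICA fixed-point
## iteration with the log-cosh negentropy contrast.

#' MDL model-order selection from the subject-covariance spectrum
#'
#' Computes, for each candidate order k, the minimum-description-length
#' functional
#' `MDL(k) = -N (p-k) log( GM(l_{k+1..p}) / AM(l_{k+1..p}) )
#'           + k (2p - k + 1)/2 * log N`
#' where `l` are the eigenvalues of the subjects x subjects covariance of
#' the (row-centered) data, `p` the number of subjects and `N` the number
#' of voxels (samples); GM/AM are geometric and arithmetic means. No
#' i.i.d.-subsampling (smoothness) correction is applied. Returns the
#' minimizing k over 1..p-1.
#'
#' @param X Subjects x voxels numeric matrix (or a `map_matrix`).
#' @return Integer order.
#' @export
estimate_order_mdl <- function(X) {
  if (inherits(X, "map_matrix")) X <- X$values
  X <- as.matrix(X)
  p <- nrow(X)
  N <- ncol(X)
  if (p < 3) stop("need at least 3 subjects")
  Xc <- X - rowMeans(X)
  lambda <- sort(eigen(tcrossprod(Xc) / N, symmetric = TRUE,
                       only.values = TRUE)$values, decreasing = TRUE)
  if (max(lambda) <= 0) stop("degenerate covariance: data have zero variance")
  lambda <- pmax(lambda, max(lambda) * 1e-12)
  ks <- seq_len(p - 1)
  mdl <- vapply(ks, function(k) {
    tail_l <- lambda[(k + 1):p]
    gm <- exp(mean(log(tail_l)))
    am <- mean(tail_l)
    -N * (p - k) * log(gm / am) + 0.5 * k * (2 * p - k + 1) * log(N)
  }, numeric(1))
  ks[which.min(mdl)]
}

## One fastICA symmetric fixed-point run on whitened data Z (k x N).
## Returns the orthogonal un-mixing matrix and negentropy objective.
fastica_core <- function(Z, W0, maxit = 1000, tol = 1e-6) {
  k <- nrow(Z)
  N <- ncol(Z)
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W0)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- 1 - G^2
    W_new <- (G %*% t(Z)) / N - diag(rowMeans(gprime), k) %*% W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
    W <- W_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  S <- W %*% Z
  ## log-cosh negentropy approximation per component, against the Gaussian
  ## reference E[log cosh(g)] for g ~ N(0,1)
  g_ref <- 0.3745672
  obj <- sum((rowMeans(log(cosh(S))) - g_ref)^2)
  list(W = W, objective = obj, converged = converged, iterations = it)
}

#' Group spatial ICA of a subjects x voxels matrix
#'
#' Centers each voxel, PCA-reduces the subject space to `k` dimensions,
#' whitens, and runs the fastICA fixed-point algorithm (log-cosh contrast,
#' symmetric decorrelation) from `restarts` seeded random orthogonal
#' initializations, keeping the run with the largest negentropy objective.
#' Sources are sign-fixed to positive skewness and ordered by explained
#' variance; mixing loadings are also returned standardized per component
#' (z-scores) for between-subject analysis.
#'
#' @param X Subjects x voxels matrix or `map_matrix`.
#' @param k Number of components (`k <= min(subjects, voxels)`).
#' @param seed RNG seed for the restarts.
#' @param restarts Number of random initializations (default 5).
#' @param maxit,tol Fixed-point iteration controls.
#' @param mask Optional logical vector of valid voxels; excluded voxels are
#'   reinserted as `NA` in the sources.
#' @return List of class `decomposition`: `sources` (k x voxels), `mixing`
#'   (subjects x k), `loadings_z`, `order`, `modality`, `center`,
#'   `objective`.
#' @export
fit_group_ica <- function(X, k, seed = 1, restarts = 5, maxit = 1000,
                          tol = 1e-6, mask = NULL) {
  modality <- if (inherits(X, "map_matrix")) X$modality else "unknown"
  if (inherits(X, "map_matrix")) X <- X$values
  X <- as.matrix(X)
  n <- nrow(X)
  V_full <- ncol(X)
  if (is.null(mask)) mask <- rep(TRUE, V_full)
  Xm <- X[, mask, drop = FALSE]
  N <- ncol(Xm)
  if (k > min(n, N)) stop("k exceeds min(subjects, voxels)")
  center <- colMeans(Xm)
  Xc <- sweep(Xm, 2L, center)

  ## PCA in subject space: eigen of the n x n covariance over voxels
  C <- tcrossprod(Xc) / N
  eg <- eigen(C, symmetric = TRUE)
  E <- eg$vectors[, seq_len(k), drop = FALSE]
  D <- pmax(eg$values[seq_len(k)], 1e-12)
  Z <- diag(1 / sqrt(D), k) %*% t(E) %*% Xc   # k x N, white over voxels

  best <- NULL
  with_seed(substream_seed(seed, "ica"), {
    for (r in seq_len(restarts)) {
      W0 <- matrix(stats::rnorm(k * k), k, k)
      run <- fastica_core(Z, W0, maxit = maxit, tol = tol)
      if (is.null(best) || (run$converged && !best$converged) ||
          (run$converged == best$converged &&
           run$objective > best$objective)) {
        best <- run
      }
    }
  })
  if (!best$converged) {
    stop(sprintf("fastICA did not converge in %d restarts (%d iterations, last objective %.3g)",
                 restarts, best$iterations, best$objective))
  }
  S <- best$W %*% Z                                   # k x N sources
  A <- E %*% diag(sqrt(D), k) %*% t(best$W)           # n x k mixing

  ## sign convention and explained-variance ordering
  for (j in seq_len(k)) {
    if (skewness(S[j, ]) < 0) {
      S[j, ] <- -S[j, ]
      A[, j] <- -A[, j]
    }
  }
  ord <- order(colSums(A^2), decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]

  sources <- matrix(NA_real_, k, V_full)
  sources[, mask] <- S
  structure(list(sources = sources, mixing = A, loadings_z = scale(A),
                 order = k, modality = modality, center = center,
                 objective = best$objective, mask = mask),
            class = "decomposition")
}

#' Match estimated components to ground-truth sources
#'
#' Optimal one-to-one assignment maximizing total absolute spatial
#' correlation (exhaustive over permutations for up to 8 components,
#' greedy beyond), with the sign of each matched pair.
#'
#' @param est `decomposition` or k x voxels source matrix.
#' @param truth Ground-truth source matrix (k x voxels) or the list from
#'   [generate_spatial_sources()].
#' @return Data frame with columns `est`, `truth`, `r` (signed correlation),
#'   `abs_r`.
#' @export
match_components <- function(est, truth) {
  S_est <- if (inherits(est, "decomposition")) est$sources else as.matrix(est)
  S_tru <- if (is.list(truth) && !is.null(truth$source_maps)) {
    truth$source_maps
  } else {
    as.matrix(truth)
  }
  stopifnot(ncol(S_est) == ncol(S_tru))
  ok <- !apply(is.na(S_est), 2, any)
  ke <- nrow(S_est)
  kt <- nrow(S_tru)
  C <- stats::cor(t(S_est[, ok, drop = FALSE]), t(S_tru[, ok, drop = FALSE]))
  k <- min(ke, kt)
  if (k <= 8 && ke == kt) {
    best <- NULL
    best_val <- -Inf
    for (p in permutations_of(k)) {
      v <- sum(abs(C[cbind(p, seq_len(k))]))
      if (v > best_val) {
        best_val <- v
        best <- p
      }
    }
    pairs <- cbind(est = best, truth = seq_len(k))
  } else {
    ## greedy partial matching for unequal/large decompositions
    Cw <- abs(C)
    pairs <- matrix(NA_integer_, 0, 2, dimnames = list(NULL, c("est", "truth")))
    for (i in seq_len(k)) {
      idx <- arrayInd(which.max(Cw), dim(Cw))
      pairs <- rbind(pairs, idx)
      Cw[idx[1], ] <- -Inf
      Cw[, idx[2]] <- -Inf
    }
  }
  data.frame(est = pairs[, 1], truth = pairs[, 2],
             r = C[pairs], abs_r = abs(C[pairs]))
}
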