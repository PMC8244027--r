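## RSFA map estimation: nuisance GLM with simultaneous DCT band-pass
## filtering, then per-voxel residual standard deviation.

## Orthonormal DCT-II basis (columns k = 1..n-1, the constant term excluded)
## with the frequency of column k equal to k / (2 n TR).
dct_basis <- function(n_volumes, TR) {
  t <- seq_len(n_volumes)
  k <- seq_len(n_volumes - 1)
  B <- sqrt(2 / n_volumes) *
    cos(pi * outer(2 * t - 1, k) / (2 * n_volumes))
  list(basis = B, freq = k / (2 * n_volumes * TR))
}

#' Mean time series over a tissue-probability mask
#'
#' Averages the BOLD signal over all voxels whose tissue probability
#' strictly exceeds `threshold` (default 0.7), one value per volume.
#'
#' @param bold 4D array (x, y, z, t).
#' @param tissue_prob 3D probability map aligned with the BOLD grid.
#' @param threshold Inclusion threshold (voxels with probability
#'   `> threshold` contribute).
#' @param tissue Name used in error messages.
#' @return Numeric vector of length `dim(bold)[4]`.
#' @export
tissue_mean_signal <- function(bold, tissue_prob, threshold = 0.7,
                               tissue = "tissue") {
  d <- dim(bold)
  if (length(d) != 4) stop("bold must be a 4D array")
  if (!all(dim(tissue_prob) == d[1:3])) {
    stop(sprintf("%s probability map grid %s does not match BOLD grid %s",
                 tissue, paste(dim(tissue_prob), collapse = "x"),
                 paste(d[1:3], collapse = "x")))
  }
  mask <- as.numeric(tissue_prob) > threshold
  if (!any(mask)) {
    stop(sprintf("empty %s mask at probability threshold %g",
                 tissue, threshold))
  }
  Y <- matrix(bold, prod(d[1:3]), d[4])
  colMeans(Y[mask, , drop = FALSE])
}

#' DCT band-stop regressor set
#'
#' Returns the discrete-cosine basis columns whose frequencies
#' `k / (2 * n_volumes * TR)` lie outside the passband (below the low edge
#' or above the high edge up to Nyquist). Including these columns in the
#' nuisance GLM band-passes the residual, so filtering and nuisance
#' regression happen simultaneously in one fit.
#'
#' @param n_volumes Number of volumes.
#' @param TR Repetition time, seconds.
#' @param band Passband `(low, high)` in Hz; default 0.0078-0.1 Hz.
#' @return Matrix of regressor columns with attributes `freq` (per-column
#'   frequency, Hz) and `labels`. Zero columns when the passband covers the
#'   whole spectrum.
#' @export
build_dct_bandstop <- function(n_volumes, TR, band = c(0.0078, 0.1)) {
  if (TR <= 0) stop("TR must be positive")
  nyquist <- 1 / (2 * TR)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyquist)) {
    stop(sprintf("passband (%g, %g) Hz must satisfy 0 < low < high < Nyquist (%g Hz)",
                 band[1], band[2], nyquist))
  }
  dct <- dct_basis(n_volumes, TR)
  if (!any(dct$freq >= band[1] & dct$freq <= band[2])) {
    stop("degenerate band: no DCT frequency falls inside the passband")
  }
  keep <- dct$freq < band[1] | dct$freq > band[2]
  out <- dct$basis[, keep, drop = FALSE]
  attr(out, "freq") <- dct$freq[keep]
  attr(out, "labels") <- sprintf("DCT[%.5f Hz]", dct$freq[keep])
  out
}

#' Assemble the nuisance design matrix
#'
#' Columns: intercept, linear trend, six realignment parameters with their
#' backward first differences and squares, WM and CSF mean signals with
#' their differences and squares, and the DCT band-stop set. Derivatives use
#' a zero first element. Zero-variance or collinear duplicate columns are
#' dropped with a warning so the returned design has full column rank.
#'
#' @param motion Matrix/data frame with 6 realignment columns, one row per
#'   volume.
#' @param wm,csf Nuisance mean signals (length `n_volumes`).
#' @param n_volumes Number of volumes.
#' @param dct Output of [build_dct_bandstop()] (or `NULL` for none).
#' @return List with `X` (design matrix) and `labels`.
#' @export
build_nuisance_design <- function(motion, wm, csf, n_volumes, dct = NULL) {
  motion <- as.matrix(motion)
  if (nrow(motion) != n_volumes || ncol(motion) != 6) {
    stop("motion must have 6 columns and one row per volume")
  }
  stopifnot_aligned(n_volumes, wm, csf)
  if (anyNA(motion) || anyNA(wm) || anyNA(csf)) {
    stop("NaN/NA values in nuisance inputs")
  }
  bdiff <- function(x) c(0, diff(x))   # backward difference, zero first
  expand <- function(M, tag) {
    M <- as.matrix(M)
    out <- cbind(M, apply(M, 2, bdiff), M^2)
    colnames(out) <- c(paste0(tag, seq_len(ncol(M))),
                       paste0(tag, seq_len(ncol(M)), "_diff"),
                       paste0(tag, seq_len(ncol(M)), "_sq"))
    out
  }
  X <- cbind(intercept = 1,
             trend = seq_len(n_volumes) - (n_volumes + 1) / 2,
             expand(motion, "motion"),
             expand(cbind(wm), "wm"), expand(cbind(csf), "csf"))
  if (!is.null(dct)) {
    lab <- attr(dct, "labels")
    colnames(dct) <- if (is.null(lab)) paste0("dct", seq_len(ncol(dct))) else lab
    X <- cbind(X, dct)
  }
  ## drop zero-variance (non-intercept) columns, then collinear duplicates
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2,
                        function(x) stats::sd(x) > 0))
  if (any(!keep)) {
    warning(sprintf("dropping %d constant nuisance column(s): %s",
                    sum(!keep), paste(colnames(X)[!keep], collapse = ", ")))
    X <- X[, keep, drop = FALSE]
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    warning(sprintf("dropping %d collinear nuisance column(s): %s",
                    length(dep), paste(dep, collapse = ", ")))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  list(X = X, labels = colnames(X))
}

#' Compute an RSFA map from a BOLD series
#'
#' Per voxel, ordinary least-squares residual of the voxel time series on
#' the nuisance design (which includes the DCT band-stop set, so filtering
#' and nuisance regression are simultaneous); RSFA is the sample standard
#' deviation (N-1 denominator) of that residual. `normalization = "mean"`
#' (default) divides by the voxel's temporal mean of the raw series, giving
#' a coefficient of variation robust to arbitrary scanner intensity
#' scaling; `"raw"` returns the plain SD.
#'
#' @param bold 4D array (x, y, z, t) or a time-by-voxel matrix.
#' @param design Output of [build_nuisance_design()] (or any design matrix).
#' @param normalization `"mean"` or `"raw"`.
#' @param mask Optional logical 3D array/vector; voxels outside get `NA`.
#' @return 3D array (or vector for matrix input) of nonnegative RSFA values.
#' @export
compute_rsfa <- function(bold, design, normalization = c("mean", "raw"),
                         mask = NULL) {
  normalization <- match.arg(normalization)
  X <- if (is.list(design)) design$X else design
  if (is.array(bold) && length(dim(bold)) == 4) {
    d <- dim(bold)
    Y <- t(matrix(bold, prod(d[1:3]), d[4]))
    out_dims <- d[1:3]
  } else {
    Y <- as.matrix(bold)
    out_dims <- NULL
  }
  n <- nrow(Y)
  if (nrow(X) != n) stop("design rows must equal the number of volumes")
  qrX <- qr(X)
  if (qrX$rank >= n) {
    stop("design rank leaves no residual degrees of freedom")
  }
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    stopifnot(length(mask) == ncol(Y))
  } else {
    mask <- rep(TRUE, ncol(Y))
  }
  res <- qr.resid(qrX, Y[, mask, drop = FALSE])
  rsfa_m <- col_sds(res)
  if (normalization == "mean") {
    mu <- colMeans(Y[, mask, drop = FALSE])
    if (any(mu == 0)) stop("zero temporal mean voxel: cannot mean-normalize")
    rsfa_m <- rsfa_m / abs(mu)
  }
  rsfa <- rep(NA_real_, ncol(Y))
  rsfa[mask] <- rsfa_m
  if (!is.null(out_dims)) array(rsfa, dim = out_dims) else rsfa
}

#' Head-motion summary: RMS volume-to-volume displacement
#'
#' Root mean square of the volume-to-volume translation displacement from
#' the first three realignment columns, in the units of the motion table
#' (mm).
#'
#' @param motion Realignment matrix (volumes x >= 3).
#' @return Scalar RMS displacement.
#' @export
head_motion_summary <- function(motion) {
  motion <- as.matrix(motion)
  d <- diff(motion[, 1:3, drop = FALSE])
  sqrt(mean(rowSums(d^2)))
}

#' End-to-end RSFA from BOLD and nuisance inputs
#'
#' Convenience wrapper: extracts WM/CSF mean signals at tissue probability
#' > 0.7, assembles the nuisance design with the DCT band-stop set, and
#' computes the RSFA map.
#'
#' @param bold 4D BOLD array.
#' @param motion Realignment table (volumes x 6).
#' @param wm_prob,csf_prob 3D tissue probability maps.
#' @param band Passband in Hz.
#' @param normalization Passed to [compute_rsfa()].
#' @param TR Repetition time, seconds.
#' @param tissue_threshold Probability threshold for the nuisance masks.
#' @param mask Optional analysis mask.
#' @return 3D RSFA map.
#' @export
rsfa_from_bold <- function(bold, motion, wm_prob, csf_prob,
                           band = c(0.0078, 0.1),
                           normalization = "mean", TR = 1.97,
                           tissue_threshold = 0.7, mask = NULL) {
  n_volumes <- dim(bold)[4]
  wm <- tissue_mean_signal(bold, wm_prob, tissue_threshold, "WM")
  csf <- tissue_mean_signal(bold, csf_prob, tissue_threshold, "CSF")
  dct <- build_dct_bandstop(n_volumes, TR, band)
  design <- build_nuisance_design(motion, wm, csf, n_volumes, dct)
  compute_rsfa(bold, design, normalization, mask)
}
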