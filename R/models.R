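## Two-stage residual analysis: first-stage (robust) regression of RSFA on
## vascular / volumetric predictors plus covariates of no interest, then
## correlation of the residuals with age, FDR-corrected across targets.
## Age never enters the first stage.

#' Define a first-stage model
#'
#' The six nested models:
#' I covariates only; II + CBF; III + CVH; IV + CBF + CVH; V + GMV;
#' VI + GMV orthogonalized with respect to CVH. CBF and GMV are
#' voxel-matched at the voxel level (the predictor is the corresponding
#' voxel's value) and enter as all component loadings at the component
#' level. A CSF-signal covariate of no interest is added automatically
#' whenever GMV (or its orthogonalized form) is a predictor.
#'
#' @param id One of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`, `"VI"`.
#' @param robust Use robust IRLS (bisquare) first-stage fitting; default
#'   `TRUE`.
#' @return List of class `model_spec` with `id`, `predictors`, `covariates`,
#'   `voxel_matched`, `robust`.
#' @export
model_spec <- function(id = c("I", "II", "III", "IV", "V", "VI"),
                       robust = TRUE) {
  id <- match.arg(id)
  predictors <- switch(id,
    I = character(0),
    II = "CBF",
    III = "CVH",
    IV = c("CBF", "CVH"),
    V = "GMV",
    VI = "GMV_orth_CVH")
  covariates <- c("sex", "head_motion", "handedness")
  if (any(predictors %in% c("GMV", "GMV_orth_CVH"))) {
    covariates <- c(covariates, "CSF_signal")
  }
  structure(list(id = id, predictors = predictors, covariates = covariates,
                 voxel_matched = c("CBF", "GMV", "GMV_orth_CVH"),
                 robust = robust),
            class = "model_spec")
}

#' Robust (or OLS) first-stage fit
#'
#' Fits `y` on the design by iteratively reweighted least squares with the
#' bisquare psi function (tuning constant 4.685, scale from the MAD) when
#' `robust`, otherwise ordinary least squares. Residuals are
#' `y - fitted`.
#'
#' @param y Response vector (RSFA values across subjects for one target).
#' @param X Design matrix including the intercept column.
#' @param robust Logical.
#' @return List with `residuals` and `coefficients`.
#' @export
fit_first_stage <- function(y, X, robust = TRUE) {
  X <- as.matrix(X)
  n <- length(y)
  if (anyNA(y) || anyNA(X)) stop("missing values in first-stage inputs")
  if (n <= ncol(X) + 5) stop("too few subjects for the design size")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop(sprintf("rank-deficient first-stage design; collinear column(s): %s",
                 paste(dep, collapse = ", ")))
  }
  ols <- list(residuals = as.numeric(qr.resid(qrX, y)),
              coefficients = qr.coef(qrX, y))
  ## IRLS is degenerate at zero residual scale: an (essentially) exact
  ## linear fit is returned as-is
  if (!robust || stats::mad(ols$residuals) <
        1e-10 * max(stats::sd(y), .Machine$double.eps)) {
    return(ols)
  }
  fit <- MASS::rlm(X, y, psi = MASS::psi.bisquare, c = 4.685,
                   scale.est = "MAD", maxit = 50, acc = 1e-8)
  list(residuals = as.numeric(y - X %*% fit$coefficients),
       coefficients = fit$coefficients)
}

#' Orthogonalize GMV loadings with respect to CVH
#'
#' Replaces each GMV column by its ordinary least-squares residual after
#' regression on the CVH factor scores plus an intercept, removing the
#' cardiovascular-health-related part of the atrophy measure.
#'
#' @param gmv Subjects x k matrix of GMV loadings (or voxel values).
#' @param cvh Subjects x 3 matrix of CVH factor scores.
#' @return Residual matrix of the same shape as `gmv`.
#' @export
orthogonalize_gmv <- function(gmv, cvh) {
  gmv <- as.matrix(gmv)
  cvh <- as.matrix(cvh)
  stopifnot_aligned(nrow(gmv), cvh)
  qr.resid(qr(cbind(1, cvh)), gmv)
}

#' Correlate residuals with age
#'
#' Pearson correlation per target with the two-sided p-value from the
#' t transform on n-2 degrees of freedom. Zero-variance residual vectors
#' yield `NA` and are excluded from FDR correction downstream.
#'
#' @param residuals Subjects x targets matrix (or vector) of first-stage
#'   residuals.
#' @param age Subject age vector.
#' @param model_id Tag stored in the result.
#' @param q FDR level for the Benjamini-Hochberg mask.
#' @return List of class `residual_age_result`: `r`, `p`, `fdr_mask`,
#'   `n_targets`, `model_id`.
#' @export
correlate_residuals_age <- function(residuals, age, model_id = NA_character_,
                                    q = 0.05) {
  R <- as.matrix(residuals)
  n <- nrow(R)
  stopifnot_aligned(n, age)
  if (n < 10) stop("need at least 10 subjects")
  sds <- col_sds(R)
  r <- rep(NA_real_, ncol(R))
  ok <- sds > 0
  r[ok] <- as.numeric(stats::cor(age, R[, ok, drop = FALSE]))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  fdr <- fdr_bh(p, q)
  structure(list(r = r, p = p, fdr_mask = fdr$mask,
                 fdr_critical_p = fdr$critical_p,
                 n_targets = ncol(R), model_id = model_id),
            class = "residual_age_result")
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up procedure at level `q`: reject all hypotheses with p at or below
#' the largest ordered p(i) satisfying `p(i) <= i * q / m`. `NA` p-values
#' are excluded from the correction and never rejected.
#'
#' @param p Vector of p-values in `[0, 1]` (NAs allowed).
#' @param q FDR level (default 0.05).
#' @return List with `mask` (logical) and `critical_p` (the rejection
#'   threshold; 0 when nothing is rejected).
#' @export
fdr_bh <- function(p, q = 0.05) {
  if (length(p) == 0) {
    return(list(mask = logical(0), critical_p = 0))
  }
  mask <- rep(FALSE, length(p))
  ok <- !is.na(p)
  if (any(ok)) {
    padj <- stats::p.adjust(p[ok], method = "BH")
    mask[ok] <- padj <= q
  }
  critical_p <- if (any(mask)) max(p[mask]) else 0
  list(mask = mask, critical_p = critical_p)
}

## Build the covariate block shared by all models: sex coded +/- 0.5,
## handedness and head motion z-scored, plus a z-scored CSF signal when the
## model asks for it.
covariate_block <- function(spec, data) {
  covs <- cbind(sex = data$sex - 0.5,
                head_motion = zscore(data$head_motion),
                handedness = zscore(data$handedness))
  if ("CSF_signal" %in% spec$covariates) {
    if (is.null(data$CSF_signal)) {
      stop("model requires a CSF_signal covariate but none was supplied")
    }
    covs <- cbind(covs, CSF_signal = zscore(data$CSF_signal))
  }
  covs
}

## Assemble the non-voxel-matched predictor columns of a model.
global_predictors <- function(spec, data) {
  P <- NULL
  if ("CVH" %in% spec$predictors) {
    if (is.null(data$cvh)) stop("model requires CVH factor scores")
    P <- cbind(P, as.matrix(data$cvh))
  }
  P
}

#' Run the two-stage suite for a set of models
#'
#' Applies the first-stage fit and the residual-age correlation to every
#' target (voxel or component) for each requested model. At the voxel
#' level, CBF/GMV predictors are taken voxel-by-voxel ("the RSFA values
#' across subjects in a given voxel were predicted by the CBF/GMV values
#' for the corresponding voxel"); at the component level, all predictor-
#' modality component loadings enter jointly.
#'
#' @param rsfa Subjects x targets matrix of RSFA values (voxel values or
#'   component loadings), or a `map_matrix` / `decomposition`.
#' @param specs List of [model_spec()]s (or model-id strings).
#' @param data Named list: `age`, `sex`, `head_motion`, `handedness`, and
#'   as needed `cbf` (subjects x targets or subjects x k loadings), `gmv`,
#'   `cvh` (subjects x 3 scores), `CSF_signal`.
#' @param level `"voxel"` (predictors voxel-matched) or `"component"`
#'   (predictors enter as the full loading set).
#' @param q FDR level.
#' @return Named list of `residual_age_result`, one per model.
#' @export
run_model_suite <- function(rsfa, specs, data, level = c("voxel", "component"),
                            q = 0.05) {
  level <- match.arg(level)
  Y <- target_matrix(rsfa)
  n <- nrow(Y)
  stopifnot_aligned(n, data$age)
  specs <- lapply(specs, function(s) if (inherits(s, "model_spec")) s
                  else model_spec(s))
  names(specs) <- vapply(specs, `[[`, character(1), "id")

  out <- lapply(specs, function(spec) {
    res <- first_stage_residual_matrix(Y, spec, data, level)
    ans <- correlate_residuals_age(res, data$age, model_id = spec$id, q = q)
    ans
  })
  out
}

target_matrix <- function(x) {
  if (inherits(x, "map_matrix")) return(x$values)
  if (inherits(x, "decomposition")) return(x$loadings_z)
  as.matrix(x)
}

## Residuals of every target under one model spec. Voxel-matched predictors
## vary across targets; all other columns are shared, so when the model is
## OLS with no voxel-matched predictor a single QR serves all targets.
first_stage_residual_matrix <- function(Y, spec, data, level) {
  n <- nrow(Y)
  V <- ncol(Y)
  covs <- covariate_block(spec, data)
  glob <- global_predictors(spec, data)

  vm_preds <- intersect(spec$predictors, spec$voxel_matched)
  vm <- list()
  if (length(vm_preds) && level == "voxel") {
    for (pr in vm_preds) {
      M <- switch(pr,
        CBF = target_matrix(data$cbf),
        GMV = target_matrix(data$gmv),
        GMV_orth_CVH = {
          if (is.null(data$cvh)) stop("Model VI requires CVH factor scores")
          orthogonalize_gmv(target_matrix(data$gmv), data$cvh)
        })
      if (is.null(M)) stop(sprintf("model requires %s values", pr))
      if (!all(dim(M) == c(n, V))) {
        stop(sprintf("%s matrix (%dx%d) does not match RSFA targets (%dx%d)",
                     pr, nrow(M), ncol(M), n, V))
      }
      vm[[pr]] <- M
    }
  } else if (length(vm_preds)) {
    ## component level: loadings enter as a shared block
    for (pr in vm_preds) {
      M <- switch(pr,
        CBF = target_matrix(data$cbf),
        GMV = target_matrix(data$gmv),
        GMV_orth_CVH = orthogonalize_gmv(target_matrix(data$gmv), data$cvh))
      glob <- cbind(glob, M)
    }
    vm <- list()
  }

  X_shared <- cbind(intercept = 1, covs, glob)
  if (length(vm) == 0 && !spec$robust) {
    return(qr.resid(qr(X_shared), Y))
  }
  res <- matrix(NA_real_, n, V)
  for (v in seq_len(V)) {
    Xv <- X_shared
    for (pr in names(vm)) Xv <- cbind(Xv, vm[[pr]][, v])
    res[, v] <- fit_first_stage(Y[, v], Xv, robust = spec$robust)$residuals
  }
  res
}
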