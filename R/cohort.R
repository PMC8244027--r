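## Synthetic multimodal cohort generator.
##
## Emulates the statistical structure the downstream analysis assumes:
## three latent cardiovascular-health (CVH) factors with prescribed age
## correlations, spatially structured subject-by-voxel CBF / GMV / RSFA maps
## built from smooth independent sources, with age acting on RSFA only
## through the vascular variables (mediation), and BOLD time series whose
## post-filtering voxel SD matches a target RSFA map.

#' Specify a synthetic cohort
#'
#' Collects every parameter of the synthetic data-generating process in a
#' validated list. The defaults are the desk-scale study conditions used
#' throughout the package: 250 subjects aged 18-88, a 16x16x16 voxel grid,
#' four spatial sources per modality, and latent factor-age correlations of
#' +0.061, -0.417 and +0.713 (blood-pressure, heart-rate/HRV, and
#' WMH/hypertension-burden factors respectively).
#'
#' @param n_subjects Number of subjects (>= 10).
#' @param age_range Numeric length-2, years; ages are drawn uniformly.
#' @param grid_dims Integer length-3 voxel grid dimensions.
#' @param n_sources Number of spatial sources per modality.
#' @param factor_age_correlations Length-3 target correlations between age
#'   and the three latent CVH factors.
#' @param factor_cor 3x3 correlation matrix among the latent factors
#'   (default identity: mutually orthogonal factors, as in a varimax
#'   solution). A scalar is expanded to a compound-symmetric matrix.
#' @param mediation Named list of standardized path coefficients:
#'   `cvh_rsfa` (CVH factor -> RSFA loading), `cbf_rsfa` (CBF loading ->
#'   RSFA loading), `age_cbf` (age -> CBF loading), `age_gmv` (age -> GMV
#'   loading), `cvh_gmv` (CVH factor -> GMV loading).
#' @param direct_age_effect Standardized direct age -> RSFA-loading path;
#'   0 under the vascular-mediation hypothesis.
#' @param loading_noise_sd Residual SD of component loadings.
#' @param voxel_noise_sd SD of i.i.d. voxel noise added to each map.
#' @param source_amplitude Scale applied to the unit-norm source maps when
#'   projecting loadings to voxels.
#' @param shared_sources Logical; if `TRUE` (default) all modalities share
#'   one set of spatial sources, so voxel-matched regression of RSFA on CBF
#'   can absorb the cerebrovascular path exactly. If `FALSE` each modality
#'   gets an independent source layout.
#' @param seed Master RNG seed for the cohort.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 250,
                        age_range = c(18, 88),
                        grid_dims = c(16, 16, 16),
                        n_sources = 4,
                        factor_age_correlations = c(0.061, -0.417, 0.713),
                        factor_cor = diag(3),
                        mediation = list(cvh_rsfa = 0.6, cbf_rsfa = 0.5,
                                         age_cbf = -0.5, age_gmv = -0.5,
                                         cvh_gmv = 0.3),
                        direct_age_effect = 0,
                        loading_noise_sd = 0.5,
                        voxel_noise_sd = 0.05,
                        source_amplitude = 10,
                        shared_sources = TRUE,
                        seed = 1) {
  if (n_subjects < 10) stop("n_subjects must be >= 10")
  if (length(age_range) != 2 || diff(age_range) <= 0) {
    stop("age_range must be (min, max) with min < max")
  }
  if (length(factor_age_correlations) != 3 ||
      any(abs(factor_age_correlations) > 1)) {
    stop("factor_age_correlations must be 3 values in [-1, 1]")
  }
  if (length(factor_cor) == 1) {
    factor_cor <- matrix(factor_cor, 3, 3) + diag(3) * (1 - factor_cor)
  }
  if (loading_noise_sd <= 0 || voxel_noise_sd <= 0) {
    stop("noise SDs must be > 0")
  }
  ## Feasibility of the joint (age, f1, f2, f3) correlation matrix: the
  ## conditional factor covariance given age must be positive semi-definite.
  r <- factor_age_correlations
  cond <- factor_cor - tcrossprod(r)
  ev <- eigen(cond, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf(paste0(
      "infeasible factor-age correlation structure: conditional factor ",
      "covariance has negative eigenvalue %.4f (targets %s with ",
      "sum of squares %.3f)"),
      min(ev), paste(sprintf("%+.3f", r), collapse = ", "), sum(r^2)))
  }
  structure(list(
    n_subjects = as.integer(n_subjects), age_range = age_range,
    grid_dims = as.integer(grid_dims), n_sources = as.integer(n_sources),
    factor_age_correlations = r, factor_cor = factor_cor,
    mediation = mediation, direct_age_effect = direct_age_effect,
    loading_noise_sd = loading_noise_sd, voxel_noise_sd = voxel_noise_sd,
    source_amplitude = source_amplitude, shared_sources = shared_sources,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

## Fixed 7x3 population loading pattern of the raw measures on the latent
## factors: F1 = blood pressure, F2 = heart rate / HRV, F3 = WMH burden with
## hypertensive and low-HRV character. Rows: HR, LF_HRV, HF_HRV, BP_sys,
## BP_dia, WMH, BMI.
cvh_loading_pattern <- function() {
  L <- rbind(
    HR     = c(0.00, -0.90,  0.00),
    LF_HRV = c(0.00,  0.85, -0.38),
    HF_HRV = c(0.00,  0.85, -0.33),
    BP_sys = c(0.86,  0.00,  0.38),
    BP_dia = c(0.90,  0.00,  0.00),
    WMH    = c(0.00,  0.00,  0.90),
    BMI    = c(0.35,  0.00,  0.50)
  )
  colnames(L) <- paste0("F", 1:3)
  L
}

#' Generate the subject table of a synthetic cohort
#'
#' Ages are uniform over `age_range`. The three latent CVH factors are
#' jointly Gaussian given age via a Cholesky construction so their
#' population correlations with (standardized) age equal
#' `factor_age_correlations`. The seven raw cardiovascular measures are
#' linear mixtures of the factors plus unique noise, mapped to realistic
#' units; white-matter hyperintensity volume is exponentiated so its
#' marginal is log-normal (and strictly positive). Sex, handedness and head
#' motion are generated as covariates, with motion mildly age-correlated.
#'
#' @param spec A [cohort_spec()].
#' @return A `data.frame` with one row per subject (columns `subject_id`,
#'   `age`, `sex`, `handedness`, `head_motion`, `HR`, `LF_HRV`, `HF_HRV`,
#'   `BP_sys`, `BP_dia`, `WMH`, `BMI`) and the hidden ground-truth factor
#'   scores in `attr(, "latent_factors")` (subjects x 3).
#' @export
generate_subjects <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  with_seed(substream_seed(spec$seed, "subjects"), {
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    a <- zscore(age)
    r <- spec$factor_age_correlations
    cond <- spec$factor_cor - tcrossprod(r)
    ## chol of the conditional covariance (PSD guaranteed by cohort_spec);
    ## jitter guards exact-singular boundary cases.
    Lc <- chol(cond + diag(3) * 1e-10)
    E <- matrix(stats::rnorm(n * 3), n, 3)
    f <- outer(a, r) + E %*% Lc
    colnames(f) <- paste0("F", 1:3)

    L <- cvh_loading_pattern()
    uniq <- pmax(1 - rowSums(L^2), 0.05)
    X <- f %*% t(L) +
      matrix(stats::rnorm(n * 7), n, 7) %*% diag(sqrt(uniq))
    colnames(X) <- rownames(L)

    tab <- data.frame(
      subject_id = sprintf("sub-%04d", seq_len(n)),
      age = age,
      sex = stats::rbinom(n, 1, 0.5),
      handedness = pmax(-100, pmin(100, 88 + stats::rnorm(n, 0, 18))),
      head_motion = exp(log(0.15) + 0.004 * (age - mean(age)) +
                          stats::rnorm(n, 0, 0.35)),
      HR = 68 + 11 * X[, "HR"],
      LF_HRV = 600 + 140 * X[, "LF_HRV"],
      HF_HRV = 420 + 100 * X[, "HF_HRV"],
      BP_sys = 125 + 17 * X[, "BP_sys"],
      BP_dia = 74 + 10 * X[, "BP_dia"],
      WMH = exp(1.2 + 0.85 * X[, "WMH"]),
      BMI = 26 + 4 * X[, "BMI"],
      stringsAsFactors = FALSE
    )
    attr(tab, "latent_factors") <- f
    tab
  })
}

## Concentric tissue model on the voxel grid: a central CSF core
## (ventricle-like), a WM shell around it, GM elsewhere. Partitions the grid.
tissue_label_map <- function(grid_dims) {
  g <- expand.grid(x = seq_len(grid_dims[1]), y = seq_len(grid_dims[2]),
                   z = seq_len(grid_dims[3]))
  ctr <- (grid_dims + 1) / 2
  d <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2)
  scale <- min(grid_dims) / 16
  lab <- ifelse(d < 3 * scale, "CSF", ifelse(d < 6 * scale, "WM", "GM"))
  factor(lab, levels = c("GM", "WM", "CSF"))
}

#' Generate spatial source maps and tissue labels
#'
#' Places `n_sources` smooth Gaussian blobs on the voxel grid, each with a
#' dominant tissue class (cycling GM, GM, WM, CSF, ...), centers rejection-
#' sampled inside the matching tissue region with a minimum pairwise
#' separation so supports overlap by less than 20 percent. Each source map
#' is thresholded to compact support and normalized to unit Euclidean norm.
#'
#' @param spec A [cohort_spec()].
#' @param modality Tag used to derive the RNG substream (so modalities get
#'   independent layouts when `shared_sources = FALSE`).
#' @return List with `source_maps` (`n_sources` x voxels matrix, unit-norm
#'   rows), `tissue_labels` (factor, one per voxel), `centers`,
#'   `dominant_tissue`, and `grid_dims`.
#' @export
generate_spatial_sources <- function(spec, modality = "shared") {
  stopifnot(inherits(spec, "cohort_spec"))
  gd <- spec$grid_dims
  V <- prod(gd)
  k <- spec$n_sources
  labels <- tissue_label_map(gd)
  sigma <- 1.8 * min(gd) / 16
  min_sep <- 2.8 * sigma            # Gaussian overlap exp(-d^2/4s^2) < 0.15
  g <- expand.grid(x = seq_len(gd[1]), y = seq_len(gd[2]), z = seq_len(gd[3]))
  tissue_cycle <- rep(c("GM", "GM", "WM", "CSF"), length.out = k)

  with_seed(substream_seed(spec$seed, paste0("sources-", modality)), {
    centers <- matrix(NA_real_, k, 3)
    for (j in seq_len(k)) {
      cand_idx <- which(labels == tissue_cycle[j])
      placed <- FALSE
      for (try in seq_len(500)) {
        i <- sample(cand_idx, 1)
        ctr <- as.numeric(g[i, ])
        ## keep blob mass inside the grid
        if (any(ctr < 1 + sigma) || any(ctr > gd - sigma)) next
        if (j == 1 || all(sqrt(rowSums(sweep(centers[seq_len(j - 1), ,
                          drop = FALSE], 2, ctr)^2)) >= min_sep)) {
          centers[j, ] <- ctr
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf("could not place %d sources on a %s grid: increase the grid or reduce n_sources",
                     k, paste(gd, collapse = "x")))
      }
    }
    S <- matrix(0, k, V)
    for (j in seq_len(k)) {
      d2 <- (g$x - centers[j, 1])^2 + (g$y - centers[j, 2])^2 +
        (g$z - centers[j, 3])^2
      b <- exp(-d2 / (2 * sigma^2))
      b[b < 0.01] <- 0              # compact, near-disjoint support
      S[j, ] <- b / sqrt(sum(b^2))
    }
    list(source_maps = S, tissue_labels = labels, centers = centers,
         dominant_tissue = tissue_cycle, grid_dims = gd)
  })
}

#' Generate subject-by-voxel modality maps with planted mediation
#'
#' Realizes the hypothesized generative process at the component-loading
#' level and projects to voxels. CBF loadings depend on age; GMV loadings on
#' age and a CVH factor; RSFA loadings are
#' `cvh_rsfa * factor + cbf_rsfa * CBF_loading + direct_age_effect * age +
#' noise`, so that under `direct_age_effect = 0` age influences RSFA only
#' through the vascular variables. Component `j` is driven by latent factor
#' `((j-1) mod 3) + 1`. Maps are `baseline + loadings %*% sources *
#' source_amplitude + voxel noise`; RSFA maps are truncated at zero.
#'
#' @param subjects Output of [generate_subjects()].
#' @param truth Output of [generate_spatial_sources()] (or a per-modality
#'   named list of such when `shared_sources = FALSE`).
#' @param spec The [cohort_spec()].
#' @return Named list of `map_matrix` objects (`rsfa`, `cbf`, `gmv`), each
#'   with fields `values` (subjects x voxels), `grid_dims`, `tissue_labels`,
#'   `modality`; ground-truth loadings in `attr(, "true_loadings")`.
#' @export
generate_modality_maps <- function(subjects, truth, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- nrow(subjects)
  if (n != spec$n_subjects) stop("subject table does not match spec")
  f <- attr(subjects, "latent_factors")
  if (is.null(f)) stop("subject table lacks latent ground-truth factors")
  a <- zscore(subjects$age)
  k <- spec$n_sources
  fidx <- ((seq_len(k) - 1) %% 3) + 1
  med <- spec$mediation
  per_modality <- !is.null(truth$rsfa)    # list of per-modality layouts
  get_truth <- function(m) if (per_modality) truth[[m]] else truth

  with_seed(substream_seed(spec$seed, "maps"), {
    noise <- function() matrix(stats::rnorm(n * k, 0, spec$loading_noise_sd),
                               n, k)
    A_cbf <- med$age_cbf * matrix(a, n, k) + noise()
    A_gmv <- med$age_gmv * matrix(a, n, k) + med$cvh_gmv * f[, fidx] + noise()
    A_rsfa <- med$cvh_rsfa * f[, fidx] + med$cbf_rsfa * A_cbf +
      spec$direct_age_effect * matrix(a, n, k) + noise()

    baseline <- c(rsfa = 5, cbf = 50, gmv = 0.6)
    loadings <- list(rsfa = A_rsfa, cbf = A_cbf, gmv = A_gmv)
    out <- lapply(names(loadings), function(m) {
      tr <- get_truth(m)
      V <- ncol(tr$source_maps)
      M <- baseline[[m]] +
        loadings[[m]] %*% tr$source_maps * spec$source_amplitude +
        matrix(stats::rnorm(n * V, 0, spec$voxel_noise_sd), n, V)
      if (m == "rsfa") M <- pmax(M, 0)
      structure(list(values = M, grid_dims = tr$grid_dims,
                     tissue_labels = tr$tissue_labels, modality = m),
                class = "map_matrix")
    })
    names(out) <- names(loadings)
    attr(out, "true_loadings") <- loadings
    out
  })
}

#' Generate a BOLD time series realizing a target RSFA map
#'
#' Builds a 4D series as baseline + band-limited stochastic signal scaled
#' per voxel + planted nuisance components (motion-locked drift and global
#' WM/CSF signals). The stochastic signal is white noise projected onto the
#' in-band (0.0078-0.1 Hz by default) discrete-cosine subspace -- the same
#' projector the RSFA estimator uses -- and scaled so the sample SD of each
#' voxel's in-band signal equals the target RSFA value (raw mode).
#'
#' @param target_rsfa Nonnegative numeric vector (one value per voxel) or 3D
#'   array: the RSFA map the series should realize.
#' @param spec A [cohort_spec()] (supplies the RNG seed).
#' @param grid_dims Grid dimensions; inferred when `target_rsfa` is an array.
#' @param n_volumes Retained volumes (default 255, i.e. 261 acquired minus 6
#'   discarded).
#' @param TR Repetition time in seconds (default 1.97).
#' @param band Passband in Hz.
#' @param baseline Mean signal level added to every voxel.
#' @param subject_tag RNG substream tag so different subjects get
#'   independent series.
#' @return List with `bold` (4D array), `TR`, `motion` (volumes x 6 table),
#'   `tissue_probs` (list of 3D arrays `GM`, `WM`, `CSF`).
#' @export
generate_bold_timeseries <- function(target_rsfa, spec, grid_dims = NULL,
                                     n_volumes = 255, TR = 1.97,
                                     band = c(0.0078, 0.1), baseline = 100,
                                     subject_tag = "sub-0001") {
  if (n_volumes <= 0) stop("n_volumes must be positive")
  if (is.array(target_rsfa) && length(dim(target_rsfa)) == 3) {
    grid_dims <- dim(target_rsfa)
    target_rsfa <- as.numeric(target_rsfa)
  }
  if (is.null(grid_dims)) stop("grid_dims required for vector targets")
  if (any(target_rsfa < 0)) stop("target RSFA values must be >= 0")
  V <- prod(grid_dims)
  stopifnot(length(target_rsfa) == V)

  dct <- dct_basis(n_volumes, TR)
  in_band <- dct$freq >= band[1] & dct$freq <= band[2]
  C_in <- dct$basis[, in_band, drop = FALSE]

  labels <- tissue_label_map(grid_dims)
  probs <- lapply(c(GM = "GM", WM = "WM", CSF = "CSF"), function(cl) {
    array(ifelse(labels == cl, 0.9, 0.05), dim = grid_dims)
  })

  with_seed(substream_seed(spec$seed, paste0("bold-", subject_tag)), {
    motion <- apply(matrix(stats::rnorm(n_volumes * 6, 0, 0.02),
                           n_volumes, 6), 2, cumsum)
    colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
    wm_sig <- as.numeric(stats::filter(stats::rnorm(n_volumes, 0, 1.5),
                                       rep(1 / 5, 5), circular = TRUE))
    csf_sig <- as.numeric(stats::filter(stats::rnorm(n_volumes, 0, 2),
                                        rep(1 / 5, 5), circular = TRUE))

    Z <- matrix(stats::rnorm(ncol(C_in) * V), ncol(C_in), V)
    S <- C_in %*% Z                         # in-band stochastic signal
    ## remove the signal's chance overlap with the nuisance regressors the
    ## estimator will use, so the target amplitude survives the GLM: the
    ## nuisance columns are first projected into the in-band subspace, so
    ## the residual stays in-band and orthogonal to the full design
    nuis_design <- build_nuisance_design(motion, wm_sig, csf_sig,
                                         n_volumes, dct = NULL)$X
    N_in <- C_in %*% crossprod(C_in, nuis_design)
    N_in <- N_in[, sqrt(colSums(N_in^2)) > 1e-8, drop = FALSE]
    if (ncol(N_in) > 0) S <- qr.resid(qr(N_in), S)
    sds <- col_sds(S)
    S <- sweep(S, 2L, ifelse(sds > 0, target_rsfa / sds, 0), `*`)

    nuis <- matrix(0, n_volumes, V)
    nuis <- nuis + outer(motion[, 1], stats::rnorm(V, 0, 2))
    nuis[, labels == "WM"] <- nuis[, labels == "WM"] + wm_sig
    nuis[, labels == "CSF"] <- nuis[, labels == "CSF"] + csf_sig

    ## fill time-major, then rotate the time axis to the 4th dimension
    bold <- aperm(array(baseline + S + nuis, dim = c(n_volumes, grid_dims)),
                  c(2, 3, 4, 1))
    list(bold = bold, TR = TR, motion = as.data.frame(motion),
         tissue_probs = probs)
  })
}

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper chaining [generate_subjects()],
#' [generate_spatial_sources()] and [generate_modality_maps()].
#'
#' @param spec A [cohort_spec()].
#' @return List with `subjects`, `truth`, `maps`.
#' @export
simulate_cohort <- function(spec) {
  subjects <- generate_subjects(spec)
  truth <- if (spec$shared_sources) {
    generate_spatial_sources(spec, "shared")
  } else {
    lapply(c(rsfa = "rsfa", cbf = "cbf", gmv = "gmv"),
           function(m) generate_spatial_sources(spec, m))
  }
  maps <- generate_modality_maps(subjects, truth, spec)
  list(subjects = subjects, truth = truth, maps = maps)
}
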