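## Formats, configuration and the end-to-end pipeline: NIfTI maps, TSV
## tables, YAML/JSON configs, a JSON run manifest, and a resumable driver
## chaining simulate -> factors -> ica -> models -> permtest.

#' Read a NIfTI image
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return Numeric array with the NIfTI header attached (RNifti image).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  RNifti::readNifti(path)
}

#' Write a NIfTI image
#'
#' @param img Numeric array (a template's header/affine is preserved when
#'   `img` is an RNifti image).
#' @param path Output path; parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path) {
  if (!dir.exists(dirname(path))) {
    stop(sprintf("parent directory does not exist: %s", dirname(path)))
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that two images share a voxel grid
#'
#' @param a,b Arrays (or paths) to compare.
#' @param name_a,name_b Names used in the error message.
#' @return `TRUE` invisibly; errors on mismatch naming both inputs.
#' @export
check_same_grid <- function(a, b, name_a = "first image",
                            name_b = "second image") {
  if (is.character(a)) a <- read_nifti(a)
  if (is.character(b)) b <- read_nifti(b)
  da <- dim(a)[1:3]
  db <- dim(b)[1:3]
  if (!identical(da, db)) {
    stop(sprintf("grid mismatch: %s is %s but %s is %s",
                 name_a, paste(da, collapse = "x"),
                 name_b, paste(db, collapse = "x")))
  }
  invisible(TRUE)
}

#' Read / write a subject table as TSV
#'
#' Tab-separated with a header row; `read_subject_table` keeps
#' `subject_id` as character.
#'
#' @param path File path.
#' @return A data frame.
#' @export
read_subject_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    colClasses = c(subject_id = "character"),
                    check.names = FALSE)
}

#' @rdname read_subject_table
#' @param tab Data frame to write.
#' @export
write_subject_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Join tables by subject identifier
#'
#' Aligns data frames on `subject_id` (never by row order). By default any
#' mismatch in the subject sets is an error; `mode = "intersect"` instead
#' keeps the common subjects (complete-case policy) and reports how many
#' were dropped.
#'
#' @param ... Two or more data frames with a `subject_id` column.
#' @param mode `"strict"` or `"intersect"`.
#' @return List of aligned data frames (same subject order).
#' @export
align_subjects <- function(..., mode = c("strict", "intersect")) {
  mode <- match.arg(mode)
  tabs <- list(...)
  ids <- lapply(tabs, function(t) t$subject_id)
  common <- Reduce(intersect, ids)
  if (mode == "strict" && !all(vapply(ids, function(i)
    setequal(i, common), logical(1)))) {
    stop(sprintf("subject sets differ across tables (%s common of %s); use mode = \"intersect\" to keep the complete cases",
                 length(common),
                 paste(vapply(ids, length, integer(1)), collapse = "/")))
  }
  dropped <- sum(vapply(ids, length, integer(1))) -
    length(common) * length(tabs)
  if (mode == "intersect" && dropped > 0) {
    message(sprintf("dropping %d incomplete subject rows; %d complete cases retained",
                    dropped, length(common)))
  }
  lapply(tabs, function(t) t[match(common, t$subject_id), , drop = FALSE])
}

#' Build a validated run configuration
#'
#' @param out_dir Output directory for all pipeline artifacts.
#' @param seed Master seed; every stage derives its own substream from it.
#' @param n_subjects,grid_dims,n_sources Cohort size parameters.
#' @param direct_age_effect Planted direct age path (0 under the vascular
#'   mediation hypothesis).
#' @param band Passband, Hz.
#' @param normalization RSFA normalization mode.
#' @param models Model ids to run.
#' @param q FDR level.
#' @param P Permutation count for the distribution-shape test.
#' @param alpha Permutation-test significance level.
#' @param level `"voxel"` or `"component"`.
#' @param n_factors CVH factor count (the three-factor structure by
#'   default).
#' @param ica_order Fixed ICA order per modality, or `NULL` for MDL
#'   selection.
#' @param robust Robust first-stage fitting in the model suite.
#' @param nuisance_threshold,analysis_threshold Tissue probability
#'   thresholds.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, n_subjects = 250,
                       grid_dims = c(16, 16, 16), n_sources = 4,
                       direct_age_effect = 0,
                       band = c(0.0078, 0.1), normalization = "mean",
                       models = c("I", "II", "III", "IV", "V", "VI"),
                       q = 0.05, P = 199, alpha = 0.05,
                       level = "voxel", n_factors = 3, ica_order = NULL,
                       robust = TRUE,
                       nuisance_threshold = 0.7, analysis_threshold = 0.4) {
  stopifnot(q > 0, q < 1, alpha > 0, alpha < 1, P >= 19)
  if (!all(models %in% c("I", "II", "III", "IV", "V", "VI"))) {
    stop("models must be among I..VI")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file; keys match
#'   the arguments of [run_config()].
#' @return A validated `run_config`.
#' @export
load_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  do.call(run_config, cfg)
}

stage_done <- function(out_dir, stage) {
  file.exists(file.path(out_dir, stage, ".done.json"))
}

mark_stage <- function(out_dir, stage, summary) {
  d <- file.path(out_dir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(summary, file.path(d, ".done.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes simulate -> cardiovascular factors -> group ICA -> model suite
#' -> distribution-shape permutation test, writing TSV/NIfTI/JSON artifacts
#' under `config$out_dir`. Each stage is skipped when its `.done.json`
#' marker already exists, so deleting a stage directory re-runs only that
#' stage and those after it that depend on memory state (stages reload
#' their inputs from disk where possible). All randomness derives from
#' `config$seed` through named substreams, so identical config + seed give
#' identical numerical outputs.
#'
#' @param config A [run_config()].
#' @return Invisible list with the in-memory results of each stage and the
#'   manifest path.
#' @export
pipeline_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  od <- config$out_dir
  dir.create(od, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = config[setdiff(names(config), "")],
                   stages = list())
  timing <- function(t) as.numeric(difftime(Sys.time(), t, units = "secs"))

  ## --- simulate ------------------------------------------------------
  ts <- Sys.time()
  spec <- cohort_spec(n_subjects = config$n_subjects,
                      grid_dims = config$grid_dims,
                      n_sources = config$n_sources,
                      direct_age_effect = config$direct_age_effect,
                      seed = config$seed)
  cohort <- simulate_cohort(spec)
  sim_dir <- file.path(od, "simulate")
  if (!stage_done(od, "simulate")) {
    dir.create(sim_dir, showWarnings = FALSE, recursive = TRUE)
    write_subject_table(cohort$subjects,
                        file.path(sim_dir, "subjects.tsv"))
    for (m in names(cohort$maps)) {
      write_nifti(array(t(cohort$maps[[m]]$values),
                        dim = c(config$grid_dims, config$n_subjects)),
                  file.path(sim_dir, paste0(m, "_maps.nii.gz")))
    }
    utils::write.table(
      data.frame(voxel = seq_along(cohort$truth$tissue_labels),
                 tissue = as.character(cohort$truth$tissue_labels)),
      file.path(sim_dir, "tissue_labels.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    mark_stage(od, "simulate", list(n_subjects = config$n_subjects,
                                    n_voxels = prod(config$grid_dims)))
  }
  manifest$stages$simulate <- list(seconds = timing(ts))

  ## --- cardiovascular factors ---------------------------------------
  ts <- Sys.time()
  cvh_raw <- as.matrix(cohort$subjects[, cvh_variables])
  cvh_mat <- normality_transform(cvh_raw)
  k_cvh <- choose_n_factors(cvh_mat, override = config$n_factors)
  efa <- fit_efa(cvh_mat, k_cvh)
  if (!stage_done(od, "factors")) {
    fdir <- file.path(od, "factors")
    dir.create(fdir, showWarnings = FALSE, recursive = TRUE)
    write_subject_table(
      data.frame(subject_id = cohort$subjects$subject_id, efa$scores),
      file.path(fdir, "cvh_scores.tsv"))
    jsonlite::write_json(
      list(transform = as.list(cvh_mat$transform), k = k_cvh,
           rotation = efa$rotation,
           loadings = unclass(efa$loadings)),
      file.path(fdir, "factors.json"), auto_unbox = TRUE, digits = NA)
    mark_stage(od, "factors", list(k = k_cvh))
  }
  manifest$stages$factors <- list(seconds = timing(ts), k = k_cvh)

  ## --- group ICA ------------------------------------------------------
  ts <- Sys.time()
  icas <- lapply(cohort$maps, function(mm) {
    k <- if (is.null(config$ica_order)) estimate_order_mdl(mm)
         else config$ica_order
    fit_group_ica(mm, k, seed = substream_seed(config$seed,
                                               paste0("ica-", mm$modality)))
  })
  if (!stage_done(od, "ica")) {
    idir <- file.path(od, "ica")
    dir.create(idir, showWarnings = FALSE, recursive = TRUE)
    for (m in names(icas)) {
      write_nifti(array(t(icas[[m]]$sources),
                        dim = c(config$grid_dims, icas[[m]]$order)),
                  file.path(idir, paste0(m, "_sources.nii.gz")))
      write_subject_table(
        data.frame(subject_id = cohort$subjects$subject_id,
                   icas[[m]]$loadings_z),
        file.path(idir, paste0(m, "_loadings.tsv")))
    }
    jsonlite::write_json(lapply(icas, function(d)
      list(order = d$order, objective = d$objective)),
      file.path(idir, "ica.json"), auto_unbox = TRUE, digits = NA)
    mark_stage(od, "ica", list(orders = vapply(icas, `[[`, integer(1),
                                               "order")))
  }
  manifest$stages$ica <- list(seconds = timing(ts))

  ## --- model suite ----------------------------------------------------
  ts <- Sys.time()
  labels <- cohort$truth$tissue_labels
  csf_signal <- rowMeans(
    cohort$maps$gmv$values[, labels == "CSF", drop = FALSE])
  data_list <- list(age = cohort$subjects$age, sex = cohort$subjects$sex,
                    head_motion = cohort$subjects$head_motion,
                    handedness = cohort$subjects$handedness,
                    cvh = efa$scores, CSF_signal = csf_signal)
  if (config$level == "voxel") {
    rsfa_targets <- cohort$maps$rsfa
    data_list$cbf <- cohort$maps$cbf
    data_list$gmv <- cohort$maps$gmv
  } else {
    rsfa_targets <- icas$rsfa
    data_list$cbf <- icas$cbf
    data_list$gmv <- icas$gmv
  }
  specs <- lapply(config$models, model_spec, robust = config$robust)
  suite <- run_model_suite(rsfa_targets, specs, data_list,
                           level = config$level, q = config$q)
  if (!stage_done(od, "models")) {
    mdir <- file.path(od, "models")
    dir.create(mdir, showWarnings = FALSE, recursive = TRUE)
    for (id in names(suite)) {
      res <- suite[[id]]
      utils::write.table(
        data.frame(target = seq_along(res$r), r = res$r, p = res$p,
                   fdr_significant = res$fdr_mask),
        file.path(mdir, sprintf("model_%s.tsv", id)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      if (config$level == "voxel") {
        write_nifti(array(res$r, dim = config$grid_dims),
                    file.path(mdir, sprintf("model_%s_r.nii.gz", id)))
        write_nifti(array(-log10(pmax(res$p, 1e-300)),
                          dim = config$grid_dims),
                    file.path(mdir, sprintf("model_%s_mlog10p.nii.gz", id)))
      }
    }
    mark_stage(od, "models",
               lapply(suite, function(r) list(
                 n_significant = sum(r$fdr_mask, na.rm = TRUE),
                 median_abs_r = stats::median(abs(r$r), na.rm = TRUE))))
  }
  manifest$stages$models <- list(
    seconds = timing(ts),
    n_significant = vapply(suite, function(r)
      sum(r$fdr_mask, na.rm = TRUE), numeric(1)))

  ## --- distribution-shape permutation test ---------------------------
  ts <- Sys.time()
  perm_tables <- list()
  perm_results <- list()
  if (!stage_done(od, "permtest")) {
    for (id in config$models) {
      tv <- run_tissue_variants(
        cohort$maps$rsfa, labels, model_spec(id, robust = FALSE),
        data_list_voxel(data_list, cohort), cohort$subjects$age,
        P = config$P, alpha = config$alpha,
        seed = substream_seed(config$seed, paste0("perm-", id)))
      perm_tables[[id]] <- tv$table
      perm_results[[id]] <- lapply(tv$results, function(r)
        list(np = r$np, p_ratio = r$p_ratio, median_p = r$median_p,
             shape_p = r$shape_p))
    }
    pdir <- file.path(od, "permtest")
    dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
    ptab <- do.call(rbind, perm_tables)
    utils::write.table(ptab, file.path(pdir, "p_ratio_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(perm_results, file.path(pdir, "permtest.json"),
                         auto_unbox = TRUE, digits = NA)
    mark_stage(od, "permtest", list(models = config$models, P = config$P))
  } else {
    ptab <- utils::read.delim(file.path(od, "permtest",
                                        "p_ratio_table.tsv"))
  }
  manifest$stages$permtest <- list(seconds = timing(ts))

  manifest$total_seconds <- timing(t0)
  manifest_path <- file.path(od, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(list(cohort = cohort, efa = efa, icas = icas, suite = suite,
                 perm_table = ptab, manifest = manifest_path))
}

## permtest always runs at voxel level on the maps
data_list_voxel <- function(data_list, cohort) {
  dl <- data_list
  dl$cbf <- cohort$maps$cbf
  dl$gmv <- cohort$maps$gmv
  dl
}
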