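#' Pipeline run configuration
#'
#' Bundles every stage's parameters: the phantom specification, the
#' thresholds of the mismatch labeling (CSF diffusivity 800e-6 mm^2/s,
#' 30% MD reduction, 46% CBF reduction, contiguity minimum size), the
#' NCA settings, the model-tuning settings and the master seed.  The
#' object round-trips through YAML unchanged.
#'
#' @param phantom a [phantom_spec()] or a list of its arguments.
#' @param csf_threshold MD cutoff for CSF exclusion (mm^2/s).
#' @param md_reduction,cbf_reduction,min_size labeling parameters, see
#'   [delineate()].
#' @param nca list: `enabled`, `grid_size`, `k_folds`, `max_rows`,
#'   `max_iter`.
#' @param model list: `budget`, `method`, `max_rows_per_rat`, `threshold`.
#' @param importance_repeats permutation repeats per feature and fold.
#' @param seed master seed fanned out to every stage via [child_seed()].
#' @return an object of class `run_config`.
#' @export
run_config <- function(phantom = list(),
                       csf_threshold = 800e-6,
                       md_reduction = 0.30, cbf_reduction = 0.46,
                       min_size = 10L,
                       nca = list(),
                       model = list(),
                       importance_repeats = 3L,
                       seed = 1L) {
  if (!inherits(phantom, "phantom_spec"))
    phantom <- do.call(phantom_spec, c(phantom, list(seed = child_seed(
      seed, "phantom"))))
  nca <- utils::modifyList(list(enabled = TRUE, grid_size = 6L, k_folds = 5L,
                                max_rows = 400L, max_iter = 30L), nca)
  model <- utils::modifyList(list(budget = 3L, method = "bayes",
                                  max_rows_per_rat = 2000L, threshold = 0.5),
                             model)
  structure(list(phantom = phantom, csf_threshold = csf_threshold,
                 md_reduction = md_reduction, cbf_reduction = cbf_reduction,
                 min_size = as.integer(min_size), nca = nca, model = model,
                 importance_repeats = as.integer(importance_repeats),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$phantom <- unclass(cfg$phantom)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config` (for writing).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  ph <- do.call(phantom_spec, cfg$phantom)
  run_config(phantom = ph, csf_threshold = cfg$csf_threshold,
             md_reduction = cfg$md_reduction,
             cbf_reduction = cfg$cbf_reduction, min_size = cfg$min_size,
             nca = cfg$nca, model = cfg$model,
             importance_repeats = cfg$importance_repeats, seed = cfg$seed)
}

#' Map one phantom rat through metrics, perfusion and labeling
#'
#' Fits the diffusion tensor and computes the CSF-excluded metric maps at
#' every timepoint, quantifies perfusion from the single DSC acquisition,
#' applies the mismatch labeling (the perfusion map is reused at later
#' timepoints, as only diffusion is re-acquired), and extracts the
#' 25-feature table referenced to each image's own delineated core.
#'
#' @param rat a [simulate_rat()] object.
#' @param config a [run_config()].
#' @return list with per-timepoint results (`features`, `pdm` and `truth`
#'   label volumes, `pdm_pv`, `truth_pv`, `parenchyma`) and the perfusion
#'   maps.
#' @export
process_rat <- function(rat, config) {
  rcbf <- NULL
  perfusion <- NULL
  out <- list()
  for (ti in seq_along(rat$timepoints)) {
    tp <- rat$timepoints[ti]
    dat <- rat$data[[ti]]
    bm <- brain_mask_from_b0(dat$dwi, rat$scheme)
    tf <- fit_tensor(dat$dwi, rat$scheme, mask = bm,
                     voxel_size = rat$voxel_size)
    mm <- exclude_csf(compute_metrics(tf), config$csf_threshold)
    if (is.null(rcbf)) {
      ds <- dsc_series(rat$dsc, rat$dsc_meta$TR, rat$dsc_meta$TE)
      cc <- signal_to_concentration(ds)
      gf <- fit_gamma_variate(cc$conc, cc$t, baseline_sd = cc$baseline_sd,
                              mask = mm$brain_mask & cc$valid)
      perfusion <- compute_perfusion_maps(gf)
      rcbf <- perfusion$rcbf
    }
    hemis <- split_hemispheres(mm$brain_mask, rat$midline)
    pdm <- delineate(mm, rcbf, hemis, config$md_reduction,
                     config$cbf_reduction, config$min_size)
    ref <- build_ic_reference(mm, pdm)
    feats <- extract_features(mm, pdm, ref, rat_id = rat$rat_id,
                              timepoint = tp)
    out[[paste0("t", tp)]] <- list(
      timepoint = tp, features = feats, pdm = pdm, truth = dat$truth,
      pdm_pv = compute_pv(pdm), truth_pv = dat$truth_pv,
      parenchyma = mm$brain_mask)
  }
  list(timepoints = out, perfusion = perfusion, rat_id = rat$rat_id,
       voxel_size = rat$voxel_size)
}

pred_penumbra_mask <- function(voxels, probs, dim, voxel_size, threshold,
                               min_size, all_voxels) {
  labels <- array(0L, dim)
  labels[all_voxels] <- 3L
  labels[voxels[probs >= threshold]] <- 2L
  lv <- label_volume(labels, NULL, voxel_size)
  if (min_size > 0) lv <- contiguity_correct(lv, min_size)
  lv$labels == 2L
}

#' Run the full pipeline: simulate, map, label, select, train, evaluate
#'
#' Executes every stage under one master seed and returns (and optionally
#' writes) a run report mirroring the standard reporting of a
#' penumbra-segmentation study: per-model classification metrics as
#' median (IQR) by timepoint, McNemar comparisons of the stacking model
#' with each base model, Dice and volume similarity of the predicted
#' penumbra, Pearson and Bland-Altman agreement between model-estimated
#' and mismatch-defined penumbral volumes, permutation feature importance
#' of the random forest under leave-one-rat-out, and the per-class
#' contrast of the top features.
#'
#' When `out_dir` is given, each stage caches its result there
#' (`stage_*.rds`) and a later call with `resume = TRUE` restarts after
#' the last completed stage; a JSON manifest with content hashes of all
#' artifacts is written at the end.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @param resume reuse cached stage outputs when present.
#' @param quiet suppress progress messages.
#' @return an object of class `penumbra_report`; see Details.
#' @export
run_cohort <- function(config, out_dir = NULL, resume = TRUE,
                       quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  cache_path <- function(stage)
    if (is.null(out_dir)) NULL else file.path(out_dir, paste0("stage_",
                                                              stage, ".rds"))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  staged <- function(stage, expr) {
    cp <- cache_path(stage)
    if (!is.null(cp) && resume && file.exists(cp)) {
      say("stage %s: reusing cached result", stage)
      return(readRDS(cp))
    }
    say("stage %s: running", stage)
    val <- force(expr)
    if (!is.null(cp)) saveRDS(val, cp)
    val
  }

  spec <- config$phantom
  ## stage 1: per-rat simulation + mapping + labeling + features
  rats_out <- staged("maps", {
    lapply(seq_len(spec$n_rats), function(i) {
      rat <- simulate_rat(spec, i)
      say("  rat %d/%d", i, spec$n_rats)
      pr <- process_rat(rat, config)
      pr$grid_dim <- spec$grid_shape
      pr
    })
  })
  table <- do.call(rbind, c(unlist(lapply(rats_out, function(r)
    lapply(r$timepoints, `[[`, "features")), recursive = FALSE),
    make.row.names = FALSE))

  ## stage 2: NCA feature selection
  nca_res <- staged("nca", {
    if (!isTRUE(config$nca$enabled)) NULL
    else {
      n_sub <- config$nca$max_rows
      grid <- exp(seq(log(1e-6), log(10),
                      length.out = config$nca$grid_size)) / n_sub
      select_features(table, lambda_grid = grid,
                      k_folds = config$nca$k_folds,
                      seed = child_seed(config$seed, "nca"),
                      max_rows = n_sub, max_iter = config$nca$max_iter)
    }
  })
  features <- if (is.null(nca_res)) feature_names() else nca_res$selected

  ## stage 3: leave-one-rat-out training
  run <- staged("train", {
    plan <- make_folds(table, seed = child_seed(config$seed, "folds"),
                       max_rows_per_rat = config$model$max_rows_per_rat)
    train_cohort(table, plan, features = features,
                 budget = config$model$budget,
                 seed = child_seed(config$seed, "train"),
                 method = config$model$method)
  })

  ## stage 4: evaluation
  report <- staged("evaluate", {
    evaluate_run(run, rats_out, table, config)
  })
  report$config <- config
  report$nca <- nca_res
  class(report) <- "penumbra_report"

  if (!is.null(out_dir)) {
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(run$predictions,
                     file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    files <- list.files(out_dir, full.names = TRUE)
    manifest <- list(seed = config$seed,
                     n_rats = spec$n_rats,
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     artifacts = lapply(files, function(f)
                       list(path = basename(f),
                            md5 = unname(tools::md5sum(f)))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

model_names <- function() c(BASE_FAMILIES, "stack")

evaluate_run <- function(run, rats_out, table, config) {
  preds <- run$predictions
  models <- model_names()
  strata <- unique(preds[, c("rat_id", "timepoint")])

  ## per rat x timepoint x model classification metrics
  cls <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    rows <- preds$rat_id == strata$rat_id[i] &
      preds$timepoint == strata$timepoint[i]
    do.call(rbind, lapply(models, function(m) {
      met <- classification_metrics(preds$label[rows],
                                    preds[[paste0("prob_", m)]][rows],
                                    config$model$threshold)
      cbind(data.frame(rat_id = strata$rat_id[i],
                       timepoint = strata$timepoint[i], model = m),
            as.data.frame(as.list(met)))
    }))
  }))
  metric_summary <- do.call(rbind, lapply(models, function(m) {
    do.call(rbind, lapply(c(unique(cls$timepoint), NA), function(tp) {
      rows <- cls$model == m & (if (is.na(tp)) TRUE else cls$timepoint == tp)
      cbind(data.frame(model = m,
                       timepoint = if (is.na(tp)) "overall" else
                         as.character(tp)),
            summarize_metrics(cls[rows, , drop = FALSE]))
    }))
  }))

  ## McNemar: stacking vs each base, per rat x timepoint
  thr <- config$model$threshold
  mcn <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    rows <- preds$rat_id == strata$rat_id[i] &
      preds$timepoint == strata$timepoint[i]
    y <- preds$label[rows]
    ps <- ifelse(preds$prob_stack[rows] >= thr, "penumbra", "NT")
    do.call(rbind, lapply(BASE_FAMILIES, function(m) {
      pb <- ifelse(preds[[paste0("prob_", m)]][rows] >= thr,
                   "penumbra", "NT")
      ## significant only when the stack is the better of the pair
      res <- mcnemar_compare(ps, pb, y)
      data.frame(rat_id = strata$rat_id[i], timepoint = strata$timepoint[i],
                 base = m, p_value = res$p_value, b = res$b, c = res$c,
                 stack_better = res$b > res$c)
    }))
  }))
  mcn_frequency <- vapply(BASE_FAMILIES, function(m)
    sum(mcn$base == m & mcn$p_value < 0.05 & mcn$stack_better), numeric(1))

  ## segmentation agreement + volumes (stacking model)
  seg <- do.call(rbind, lapply(rats_out, function(r) {
    do.call(rbind, lapply(r$timepoints, function(tpd) {
      rows <- preds$rat_id == r$rat_id & preds$timepoint == tpd$timepoint
      pm <- pred_penumbra_mask(preds$voxel[rows], preds$prob_stack[rows],
                               r$grid_dim, r$voxel_size, thr,
                               config$min_size,
                               all_voxels = preds$voxel[rows])
      truth_pdm <- tpd$pdm$labels == LABEL_CODES[["penumbra"]]
      sa <- segmentation_agreement(pm, truth_pdm, r$voxel_size)
      data.frame(rat_id = r$rat_id, timepoint = tpd$timepoint,
                 dsc = sa$dsc, vs = sa$vs, pv_ml = sa$pv_pred,
                 pv_pdm = sa$pv_truth, pv_truth = tpd$truth_pv)
    }))
  }))

  agreement_pdm <- pv_agreement(seg$pv_ml, seg$pv_pdm)
  agreement_truth <- pv_agreement(seg$pv_ml, seg$pv_truth)

  ## permutation importance of the random forest, leave-one-rat-out
  imp <- lapply(run$plan$rats, function(rt) {
    rows <- preds$rat_id == rt
    permutation_importance(run$models[[rt]]$rf,
                           table[run$plan$folds[[rt]]$test_idx, , drop = FALSE],
                           preds$label[rows],
                           n_repeats = config$importance_repeats,
                           seed = child_seed(config$seed, "imp", rt),
                           threshold = thr)
  })
  imp_mat <- do.call(rbind, imp)
  importance <- sort(apply(imp_mat, 2, median), decreasing = TRUE)
  top6 <- names(importance)[seq_len(min(6L, length(importance)))]
  ## always contrast the diffusivity trio alongside the top features
  contrast <- feature_contrast(table, union(top6, c("MD", "p", "L")))

  list(classification = cls, metric_summary = metric_summary,
       mcnemar = mcn, mcnemar_frequency = mcn_frequency,
       segmentation = seg, agreement_pdm = agreement_pdm,
       agreement_truth = agreement_truth,
       importance = importance, top_features = top6,
       feature_contrast = contrast, features_used = run$features,
       n_rows = nrow(table))
}

report_to_json <- function(report) {
  list(metric_summary = report$metric_summary,
       mcnemar_frequency = as.list(report$mcnemar_frequency),
       segmentation = report$segmentation,
       agreement_pdm = report$agreement_pdm,
       agreement_truth = report$agreement_truth,
       importance = as.list(report$importance),
       top_features = report$top_features,
       feature_contrast = report$feature_contrast,
       features_used = report$features_used,
       n_rows = report$n_rows)
}

#' @export
print.penumbra_report <- function(x, ...) {
  cat("Penumbra estimation run\n")
  cat(sprintf("  feature rows: %d; features used: %d\n", x$n_rows,
              length(x$features_used)))
  ov <- x$metric_summary[x$metric_summary$timepoint == "overall" &
                           x$metric_summary$model == "stack", ]
  for (i in seq_len(nrow(ov)))
    cat(sprintf("  stack %s: %.2f (%.2f, %.2f)\n", ov$metric[i],
                ov$median[i], ov$q25[i], ov$q75[i]))
  cat(sprintf("  DSC %.2f, VS %.2f (medians)\n",
              median(x$segmentation$dsc), median(x$segmentation$vs)))
  cat(sprintf("  PV agreement (vs PDM): r = %.3f, bias%% = %.1f\n",
              x$agreement_pdm$r, x$agreement_pdm$bias_pct))
  cat(sprintf("  top features: %s\n",
              paste(x$top_features, collapse = ", ")))
  invisible(x)
}
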