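#' Voxel-classification metrics
#'
#' Confusion-matrix rates with penumbra as the positive class, plus AUROC
#' computed from the rank statistic (midranks for ties).  When a stratum
#' lacks one class, rates whose denominator is zero and the AUROC are
#' reported as NA rather than 0.
#'
#' @param y_true factor/character of `NT`/`penumbra` truth labels.
#' @param y_prob penumbra probabilities.
#' @param threshold classification cutoff.
#' @return named numeric vector: accuracy, sensitivity, specificity,
#'   precision, f1, auroc.
#' @export
classification_metrics <- function(y_true, y_prob, threshold = 0.5) {
  if (length(y_true) != length(y_prob)) stopf("length mismatch")
  pos <- as.character(y_true) == "penumbra"
  pred <- y_prob >= threshold
  tp <- sum(pos & pred); fn <- sum(pos & !pred)
  tn <- sum(!pos & !pred); fp <- sum(!pos & pred)
  div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  auroc <- if (any(pos) && any(!pos)) {
    r <- rank(y_prob)                          # midranks
    (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  } else NA_real_
  c(accuracy = div(tp + tn, length(pos)), sensitivity = sens,
    specificity = spec, precision = prec, f1 = f1, auroc = auroc)
}

#' Median (IQR) aggregation of per-stratum metrics
#'
#' @param df data.frame of per-stratum metric values.
#' @param cols metric columns to aggregate.
#' @return data.frame with median, q25 and q75 per metric.
#' @export
summarize_metrics <- function(df, cols = c("accuracy", "sensitivity",
                                           "specificity", "precision",
                                           "f1", "auroc")) {
  do.call(rbind, lapply(cols, function(cl) {
    v <- df[[cl]]
    data.frame(metric = cl,
               median = median(v, na.rm = TRUE),
               q25 = unname(quantile(v, 0.25, na.rm = TRUE)),
               q75 = unname(quantile(v, 0.75, na.rm = TRUE)))
  }))
}

#' McNemar comparison of two paired classifiers
#'
#' Counts discordant pairs b (A correct, B wrong) and c (A wrong,
#' B correct); with fewer than 25 discordant pairs an exact two-sided
#' binomial test is used, otherwise the continuity-corrected chi-squared
#' statistic.  With no discordant pairs p = 1 by convention (flagged).
#'
#' @param pred_a,pred_b predicted labels of the two classifiers.
#' @param y_true true labels.
#' @return list with `p_value`, `b`, `c`, `method`, `degenerate`.
#' @export
mcnemar_compare <- function(pred_a, pred_b, y_true) {
  if (length(pred_a) != length(y_true) || length(pred_b) != length(y_true))
    stopf("predictions must be paired with the truth")
  ca <- as.character(pred_a) == as.character(y_true)
  cb <- as.character(pred_b) == as.character(y_true)
  b <- sum(ca & !cb)
  cc <- sum(!ca & cb)
  n <- b + cc
  if (n == 0L)
    return(list(p_value = 1.0, b = b, c = cc, method = "degenerate",
                degenerate = TRUE))
  if (n < 25L) {
    p <- min(1, 2 * stats::pbinom(min(b, cc), n, 0.5))
    method <- "exact"
  } else {
    stat <- (abs(b - cc) - 1)^2 / n
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chisq"
  }
  list(p_value = p, b = b, c = cc, method = method, degenerate = FALSE)
}

#' Segmentation agreement: Dice and volume similarity
#'
#' DSC = 2|A and B| / (|A| + |B|); volume similarity
#' VS = 1 - |V_A - V_B| / (V_A + V_B) with volumes from [compute_pv()].
#' Two empty masks give DSC = VS = 1 by convention (flagged).
#'
#' @param pred_mask,truth_mask 3D logical masks on one grid.
#' @param voxel_size mm per axis.
#' @return list with `dsc`, `vs`, `pv_pred`, `pv_truth`, `empty`.
#' @export
segmentation_agreement <- function(pred_mask, truth_mask, voxel_size) {
  if (!all(dim(pred_mask) == dim(truth_mask))) stopf("grid mismatch")
  a <- sum(pred_mask); b <- sum(truth_mask)
  pv_a <- compute_pv(pred_mask, voxel_size)
  pv_b <- compute_pv(truth_mask, voxel_size)
  if (a + b == 0)
    return(list(dsc = 1, vs = 1, pv_pred = 0, pv_truth = 0, empty = TRUE))
  dsc <- 2 * sum(pred_mask & truth_mask) / (a + b)
  vs <- 1 - abs(pv_a - pv_b) / (pv_a + pv_b)
  list(dsc = dsc, vs = vs, pv_pred = pv_a, pv_truth = pv_b, empty = FALSE)
}

#' Agreement between two sets of penumbral volumes
#'
#' Rat-to-rat Pearson correlation plus Bland-Altman bias, SD of the
#' differences, 95% limits of agreement (bias +/- 1.96 SD) and the bias
#' as a percentage of the mean reference volume.
#'
#' @param ml_pvs model-estimated volumes.
#' @param pdm_pvs reference (mismatch-defined) volumes, paired.
#' @return list with `r`, `p_value`, `bias`, `sd`, `loa`, `bias_pct`,
#'   `n`, `degenerate`.
#' @export
pv_agreement <- function(ml_pvs, pdm_pvs) {
  if (length(ml_pvs) != length(pdm_pvs)) stopf("paired volumes required")
  if (length(ml_pvs) < 3L) stopf("need at least 3 paired volumes")
  diffs <- ml_pvs - pdm_pvs
  bias <- mean(diffs)
  s <- sd(diffs)
  degenerate <- sd(ml_pvs) == 0 || sd(pdm_pvs) == 0
  if (degenerate) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- cor.test(ml_pvs, pdm_pvs)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  list(r = r, p_value = p, bias = bias, sd = s,
       loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
       bias_pct = 100 * bias / mean(pdm_pvs), n = length(diffs),
       degenerate = degenerate)
}

#' Permutation feature importance
#'
#' Importance of a feature = baseline accuracy minus the accuracy after
#' permuting that feature's column in the evaluation rows, averaged over
#' seeded repeats.
#'
#' @param model fitted model accepted by [predict_prob()].
#' @param newdata evaluation rows (data.frame with the fit-time features).
#' @param y_true true labels for `newdata`.
#' @param n_repeats permutations per feature (>= 1).
#' @param seed RNG seed.
#' @param threshold classification cutoff.
#' @return named numeric vector of importances (fit-time feature order).
#' @export
permutation_importance <- function(model, newdata, y_true, n_repeats = 5L,
                                   seed = 1L, threshold = 0.5) {
  if (n_repeats < 1L) stopf("n_repeats must be >= 1")
  feats <- model$features
  truth <- as.character(y_true) == "penumbra"
  base_acc <- mean((predict_prob(model, newdata) >= threshold) == truth)
  with_seed(child_seed(seed, "perm"), {
    imp <- vapply(feats, function(f) {
      mean(vapply(seq_len(n_repeats), function(rep) {
        shuffled <- newdata
        shuffled[[f]] <- sample(shuffled[[f]])
        base_acc - mean((predict_prob(model, shuffled) >= threshold) == truth)
      }, numeric(1)))
    }, numeric(1))
    setNames(imp, feats)
  })
}

#' Per-class contrast of selected features across rats
#'
#' For each feature, computes the per-rat median within each class, the
#' cohort median (IQR) per class, the percentage difference
#' 100 (penumbra - NT) / NT of the class medians, and a paired t-test
#' across rats of the per-rat class medians.
#'
#' @param table feature table with `label` and `rat_id`.
#' @param features feature columns to contrast.
#' @return data.frame, one row per feature.
#' @export
feature_contrast <- function(table, features) {
  rats <- unique(table$rat_id)
  do.call(rbind, lapply(features, function(f) {
    per_rat <- t(vapply(rats, function(r) {
      rows <- table$rat_id == r
      c(pen = median(table[[f]][rows & table$label == "penumbra"]),
        nt = median(table[[f]][rows & table$label == "NT"]))
    }, numeric(2)))
    ok <- rowSums(!is.finite(per_rat)) == 0
    pp <- if (sum(ok) >= 2 && sd(per_rat[ok, "pen"] - per_rat[ok, "nt"]) > 0)
      t.test(per_rat[ok, "pen"], per_rat[ok, "nt"], paired = TRUE)$p.value
    else NA_real_
    med <- function(cls) median(table[[f]][table$label == cls])
    iqr <- function(cls) quantile(table[[f]][table$label == cls],
                                  c(0.25, 0.75))
    pen_m <- med("penumbra"); nt_m <- med("NT")
    data.frame(feature = f, penumbra_median = pen_m,
               penumbra_q25 = unname(iqr("penumbra")[1]),
               penumbra_q75 = unname(iqr("penumbra")[2]),
               nt_median = nt_m,
               nt_q25 = unname(iqr("NT")[1]), nt_q75 = unname(iqr("NT")[2]),
               pct_difference = 100 * (pen_m - nt_m) / nt_m,
               p_value = pp)
  }))
}
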