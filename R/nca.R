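## Neighborhood component analysis for feature selection.
##
## Weighted-L1 neighbor distance with squared weights:
##   d_ij = sum_r w_r^2 |x_ir - x_jr|
## Leave-one-out soft-neighbor probabilities p_ij ~ exp(-d_ij); the
## objective is the expected leave-one-out accuracy minus an L2 penalty,
##   F(w) = mean_i p_i - lambda sum_r w_r^2,
## maximised by projected (w >= 0) gradient ascent with a doubling/halving
## line search from w = 1.

nca_objective_parts <- function(X, y, w) {
  n <- nrow(X); p <- ncol(X)
  D <- matrix(0, n, n)
  for (r in seq_len(p)) D <- D + w[r]^2 * abs(outer(X[, r], X[, r], "-"))
  P <- exp(-D)
  diag(P) <- 0
  rs <- rowSums(P)
  P <- P / ifelse(rs > 0, rs, 1)
  same <- outer(y, y, "==")
  p_i <- rowSums(P * same)
  list(P = P, p_i = p_i, same = same)
}

nca_gradient <- function(X, y, w, lambda, parts) {
  n <- nrow(X); p <- ncol(X)
  M <- parts$P * (parts$p_i - parts$same)   # coefficient of d_ij,r
  g <- numeric(p)
  for (r in seq_len(p))
    g[r] <- sum(M * abs(outer(X[, r], X[, r], "-")))
  2 * w * g / n - 2 * lambda * w
}

nca_fit_raw <- function(X, y, lambda, max_iter = 60L, tol = 1e-6) {
  p <- ncol(X)
  w <- rep(1, p)
  parts <- nca_objective_parts(X, y, w)
  f <- mean(parts$p_i) - lambda * sum(w^2)
  step <- 1
  for (it in seq_len(max_iter)) {
    g <- nca_gradient(X, y, w, lambda, parts)
    improved <- FALSE
    for (ls in 1:20) {
      w_new <- pmax(w + step * g, 0)
      parts_new <- nca_objective_parts(X, y, w_new)
      f_new <- mean(parts_new$p_i) - lambda * sum(w_new^2)
      if (is.finite(f_new) && f_new > f) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
    delta <- f_new - f
    w <- w_new; f <- f_new; parts <- parts_new
    step <- step * 2
    if (delta < tol * max(1, abs(f))) break
  }
  list(w = w, objective = f, expected_accuracy = mean(parts$p_i))
}

## 1-nearest-neighbour prediction under the (squared-)weighted L1 metric
nn1_predict <- function(Xtr, ytr, Xte, w) {
  p <- ncol(Xtr)
  pred <- character(nrow(Xte))
  chunk <- max(1L, floor(2e6 / nrow(Xtr)))
  for (start in seq(1L, nrow(Xte), by = chunk)) {
    rows <- start:min(start + chunk - 1L, nrow(Xte))
    D <- matrix(0, length(rows), nrow(Xtr))
    for (r in seq_len(p))
      D <- D + w[r]^2 * abs(outer(Xte[rows, r], Xtr[, r], "-"))
    pred[rows] <- ytr[max.col(-D, ties.method = "first")]
  }
  pred
}

#' Neighborhood component analysis feature selection
#'
#' Tunes the regularisation strength lambda by k-fold cross-validated
#' 1-nearest-neighbour classification loss over a grid, refits on all rows
#' at the best lambda, and selects the features whose weight exceeds 2%
#' of the maximum weight.  If the cross-validated generalisation error
#' using the selected features exceeds the error with all features,
#' selection is deemed unnecessary and all features are returned with the
#' `bypassed` flag set.
#'
#' @param table a feature table from [extract_features()] (or any
#'   data.frame with the feature columns and a `label` column).
#' @param lambda_grid penalty grid; default 20 log-spaced values in
#'   [1e-6, 10] / n.
#' @param k_folds cross-validation folds for tuning.
#' @param seed RNG seed controlling subsampling and fold assignment.
#' @param max_rows voxel subsample cap for tractability.
#' @param max_iter gradient-ascent iteration cap.
#' @return an object of class `nca_result`: `lambda_grid`, `loss` (mean
#'   CV loss per lambda), `lambda_best`, `weights`, `selected`,
#'   `pre_error`, `post_error`, `bypassed`, `seed`, `n_used`.
#' @export
select_features <- function(table, lambda_grid = NULL, k_folds = 5L,
                            seed = 1L, max_rows = 20000L, max_iter = 60L) {
  feats <- feature_names()
  miss <- setdiff(feats, names(table))
  if (length(miss)) stopf("missing feature columns: %s",
                          paste(miss, collapse = ", "))
  y <- as.character(table$label)
  if (length(unique(y)) < 2L) stopf("need two classes for NCA")
  X <- as.matrix(table[, feats])

  with_seed(child_seed(seed, "nca"), {
    if (nrow(X) > max_rows) {
      keep <- unlist(lapply(split(seq_len(nrow(X)), y), function(ix)
        sample(ix, round(length(ix) * max_rows / nrow(X)))))
      X <- X[keep, , drop = FALSE]; y <- y[keep]
    }
    n <- nrow(X)
    if (is.null(lambda_grid))
      lambda_grid <- exp(seq(log(1e-6), log(10), length.out = 20L)) / n
    if (!length(lambda_grid)) stopf("empty lambda grid")

    mu <- colMeans(X); sg <- apply(X, 2, sd)
    sg[sg <= 0] <- 1
    Z <- sweep(sweep(X, 2, mu), 2, sg, "/")

    fold_id <- integer(n)
    for (ix in split(seq_len(n), y))
      fold_id[ix] <- sample(rep_len(seq_len(k_folds), length(ix)))

    cv_loss <- function(wfun, cols = seq_len(ncol(Z))) {
      mean(vapply(seq_len(k_folds), function(k) {
        tr <- fold_id != k; te <- !tr
        w <- wfun(Z[tr, cols, drop = FALSE], y[tr])
        mean(nn1_predict(Z[tr, cols, drop = FALSE], y[tr],
                         Z[te, cols, drop = FALSE], w) != y[te])
      }, numeric(1)))
    }

    loss <- vapply(lambda_grid, function(lm)
      cv_loss(function(Xtr, ytr)
        nca_fit_raw(Xtr, ytr, lm, max_iter)$w), numeric(1))
    lambda_best <- lambda_grid[which.min(loss)]

    fit <- nca_fit_raw(Z, y, lambda_best, max_iter)
    w <- setNames(fit$w, feats)
    selected <- feats[w > 0.02 * max(w)]
    if (!length(selected)) selected <- feats[which.max(w)]

    pre_error <- cv_loss(function(Xtr, ytr) rep(1, ncol(Xtr)))
    sel_cols <- match(selected, feats)
    post_error <- cv_loss(function(Xtr, ytr) w[sel_cols], cols = sel_cols)
    bypassed <- post_error > pre_error
    if (bypassed) selected <- feats

    structure(list(lambda_grid = lambda_grid, loss = loss,
                   lambda_best = lambda_best, weights = w,
                   selected = selected, pre_error = pre_error,
                   post_error = post_error, bypassed = bypassed,
                   seed = seed, n_used = n),
              class = "nca_result")
  })
}
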