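#' Ischemic-core reference statistics
#'
#' Assembles the n_IC x 11 observation matrix of metric values over the
#' ischemic core and its per-metric mean and SD and 11 x 11 covariance,
#' the reference against which every non-core voxel's distance features
#' are computed.  The covariance is ridge-regularised
#' (S + 1e-6 diag(S)) when ill-conditioned, and a core smaller than 12
#' voxels is flagged as too small for a stable covariance.
#'
#' @param metrics CSF-excluded `metric_maps`.
#' @param labels a [label_volume()] sharing the grid.
#' @return an object of class `ic_reference` with `X`, `mu`, `s`, `S`,
#'   `S_reg` (the matrix actually inverted), flags `regularized` and
#'   `small_core`, and `zero_var` (metrics with floored SD).
#' @export
build_ic_reference <- function(metrics, labels) {
  stopifnot(inherits(metrics, "metric_maps"), inherits(labels, "label_volume"))
  ic <- which(labels$labels == LABEL_CODES[["IC"]])
  if (!length(ic)) stopf("empty ischemic core: no reference available")
  X <- vapply(metric_names(), function(nm) metrics[[nm]][ic],
              numeric(length(ic)))
  X <- matrix(X, nrow = length(ic),
              dimnames = list(NULL, metric_names()))
  keep <- rowSums(!is.finite(X)) == 0
  X <- X[keep, , drop = FALSE]
  if (!nrow(X)) stopf("no finite ischemic-core observations")
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  if (nrow(X) == 1L) s[] <- 0
  zero_var <- !is.finite(s) | s <= 0
  s[zero_var] <- 1e-12
  S <- cov(X)
  if (nrow(X) == 1L) S <- matrix(0, 11, 11, dimnames = dimnames(S) %||%
                                   list(metric_names(), metric_names()))
  regularized <- FALSE
  S_reg <- S
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ill <- min(ev) <= max(ev) * 1e-10 ||
    !is.finite(tryCatch(kappa(S, exact = TRUE), error = function(e) Inf))
  if (ill) {
    dg <- diag(S)
    dg[dg <= 0] <- 1e-12
    S_reg <- S + 1e-6 * diag(dg, nrow(S))
    while (!is.finite(tryCatch(kappa(S_reg, exact = TRUE),
                               error = function(e) Inf)) ||
           kappa(S_reg, exact = TRUE) > 1e12)
      S_reg <- S_reg + diag(max(dg) * 1e-6, nrow(S))
    regularized <- TRUE
  }
  structure(list(X = X, mu = mu, s = s, S = S, S_reg = S_reg,
                 regularized = regularized, small_core = nrow(X) < 12L,
                 zero_var = zero_var, n_ic = nrow(X)),
            class = "ic_reference")
}

feature_names <- function() c(metric_names(), "mahalanobis", "cosine_dist",
                              "correlation_dist",
                              paste0(metric_names(), "_sed"))

## mean |x - y| over reference values y, per query x, in O((n+m) log m)
mean_abs_diff <- function(x, y) {
  m <- length(y)
  ys <- sort(y)
  cs <- c(0, cumsum(ys))
  k <- findInterval(x, ys)
  (x * k - cs[k + 1] + (cs[m + 1] - cs[k + 1]) - x * (m - k)) / m
}

#' Extract the 25 per-voxel features
#'
#' For every penumbra or normal-tissue voxel the feature vector holds the
#' 11 metric values, the Mahalanobis distance to the core distribution,
#' the mean cosine distance and mean correlation distance to all core
#' observations (distance = 1 - similarity), and 11 per-metric
#' standardized Euclidean distances: the mean absolute difference to the
#' core observations scaled by the core SD of that metric.  Voxels whose
#' metric vector has zero norm (cosine undefined) or zero spread
#' (correlation undefined) are dropped; the count is recorded in the
#' `n_dropped` attribute.
#'
#' @param metrics CSF-excluded `metric_maps`.
#' @param labels a [label_volume()].
#' @param ref an [build_ic_reference()] result.
#' @param rat_id,timepoint provenance stamped on every row.
#' @return a data.frame with the 25 feature columns (see
#'   `penumbraDTI:::feature_names`), `label` (factor penumbra/NT),
#'   `rat_id`, `timepoint` and `voxel` (linear grid index).
#' @export
extract_features <- function(metrics, labels, ref, rat_id = "rat",
                             timepoint = NA_real_) {
  stopifnot(inherits(ref, "ic_reference"))
  lab <- labels$labels
  qidx <- which(lab == LABEL_CODES[["penumbra"]] | lab == LABEL_CODES[["NT"]])
  if (!length(qidx)) stopf("no penumbra or normal-tissue voxels to featurise")
  X <- vapply(metric_names(), function(nm) metrics[[nm]][qidx],
              numeric(length(qidx)))
  X <- matrix(X, nrow = length(qidx), dimnames = list(NULL, metric_names()))
  finite <- rowSums(!is.finite(X)) == 0
  nrm <- sqrt(rowSums(X^2))
  ctr <- X - rowMeans(X)
  spread <- sqrt(rowSums(ctr^2))
  ok <- finite & nrm > 0 & spread > 0
  n_dropped <- sum(!ok)
  X <- X[ok, , drop = FALSE]
  qidx <- qidx[ok]

  maha <- sqrt(mahalanobis(X, ref$mu, ref$S_reg))

  Y <- ref$X
  Yn <- Y / sqrt(rowSums(Y^2))
  Yc <- Y - rowMeans(Y)
  Yc <- Yc / sqrt(rowSums(Yc^2))
  ## mean_y [1 - cos(x, y)] = 1 - unit(x) . mean_y unit(y)
  cosine <- 1 - (X / sqrt(rowSums(X^2))) %*% colMeans(Yn)
  xc <- X - rowMeans(X)
  corr <- 1 - (xc / sqrt(rowSums(xc^2))) %*% colMeans(Yc)

  sed <- vapply(metric_names(), function(nm)
    mean_abs_diff(X[, nm], Y[, nm]) / ref$s[nm], numeric(nrow(X)))

  out <- data.frame(X, mahalanobis = as.vector(maha),
                    cosine_dist = as.vector(cosine),
                    correlation_dist = as.vector(corr), sed,
                    check.names = FALSE)
  names(out) <- feature_names()
  out$label <- factor(ifelse(lab[qidx] == LABEL_CODES[["penumbra"]],
                             "penumbra", "NT"), levels = c("NT", "penumbra"))
  out$rat_id <- rat_id
  out$timepoint <- timepoint
  out$voxel <- qidx
  attr(out, "n_dropped") <- n_dropped
  out
}
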