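#' Diffusion acquisition scheme
#'
#' Bundles the b-value and unit gradient direction of every volume of a
#' diffusion-weighted acquisition.  At least one b = 0 volume and six
#' unique non-collinear diffusion-encoding directions are required for the
#' tensor model to be identifiable.
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs numeric matrix (n x 3) of gradient directions; rows of
#'   diffusion-weighted volumes must be unit vectors (tolerance 1e-6).
#' @return an object of class `diffusion_scheme` with elements `b` and `g`.
#' @export
diffusion_scheme <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L) stopf("bvecs must have 3 columns")
  if (length(bvals) != nrow(bvecs)) stopf("bvals/bvecs length mismatch")
  if (any(bvals < 0)) stopf("negative b-value")
  dw <- bvals > 0
  if (sum(!dw) < 1L) stopf("at least one b = 0 volume is required")
  nrm <- sqrt(rowSums(bvecs[dw, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6))
    stopf("diffusion-encoding directions must be unit vectors")
  ug <- unique(round(bvecs[dw, , drop = FALSE], 6))
  if (nrow(ug) < 6L) stopf("need >= 6 unique diffusion-encoding directions")
  structure(list(b = as.numeric(bvals), g = bvecs), class = "diffusion_scheme")
}

#' Default 30-direction scheme
#'
#' Thirty near-uniform non-collinear unit directions on the hemisphere
#' (Fibonacci spiral) at one b-value plus leading b = 0 volumes, matching a
#' typical small-animal single-shell protocol (b = 1,200 s/mm^2, five
#' b = 0 measurements).
#'
#' @param n_dir number of diffusion-encoding directions.
#' @param b b-value of the shell (s/mm^2).
#' @param n_b0 number of b = 0 volumes.
#' @return a [diffusion_scheme()].
#' @export
default_scheme <- function(n_dir = 30L, b = 1200, n_b0 = 5L) {
  i <- seq_len(n_dir) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- i / n_dir          # upper hemisphere only: antipodal dirs are collinear
  r <- sqrt(pmax(0, 1 - z^2))
  g <- cbind(r * cos(phi), r * sin(phi), z)
  g <- g / sqrt(rowSums(g^2))
  diffusion_scheme(c(rep(0, n_b0), rep(b, n_dir)),
                   rbind(matrix(0, n_b0, 3), g))
}

#' Read / write FSL-style gradient tables
#'
#' `bvals` is a single row of b-values, `bvecs` three rows (x, y, z), one
#' column per volume.
#'
#' @param bvals_path,bvecs_path file paths.
#' @return a [diffusion_scheme()].
#' @export
read_scheme <- function(bvals_path, bvecs_path) {
  b <- scan(bvals_path, quiet = TRUE)
  g <- as.matrix(read.table(bvecs_path))
  diffusion_scheme(b, t(g))
}

#' @rdname read_scheme
#' @param scheme a [diffusion_scheme()].
#' @export
write_scheme <- function(scheme, bvals_path, bvecs_path) {
  cat(paste(scheme$b, collapse = " "), "\n", file = bvals_path)
  write.table(format(t(scheme$g), digits = 10), bvecs_path,
              row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(c(bvals_path, bvecs_path))
}

## design matrix of the log-linear tensor model:
## ln S = ln S0 - b g' D g,  beta = (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
tensor_design <- function(b, g) {
  cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Fit the diffusion tensor by log-linear least squares
#'
#' Per masked voxel, solves ln S = ln S0 - b g'Dg by ordinary least squares
#' over all volumes (b = 0 volumes averaged into a single observation), then
#' eigendecomposes the symmetric tensor.  Negative eigenvalues are clamped
#' to zero and flagged; all-zero-signal voxels are flagged invalid.
#'
#' @param dwi 4D array (x, y, z, volume) of signal magnitudes.
#' @param scheme a [diffusion_scheme()] describing the volumes.
#' @param mask 3D logical array of voxels to fit (default: signal > 0 on
#'   the mean b = 0 image).
#' @param voxel_size length-3 numeric, mm per axis.
#' @return an object of class `tensor_field`: 4D `evals` (sorted descending,
#'   mm^2/s), `log_s0`, residual sum of squares `rss`, logical `valid` and
#'   `clamped` maps, `dim`, `voxel_size`.
#' @export
fit_tensor <- function(dwi, scheme, mask = NULL, voxel_size = c(1, 1, 1)) {
  d <- dim(dwi)
  if (length(d) != 4L || d[4] != length(scheme$b))
    stopf("dwi volumes (%s) inconsistent with scheme (%d)",
          paste(d, collapse = "x"), length(scheme$b))
  nvox <- prod(d[1:3])
  S <- matrix(dwi, nvox, d[4])
  b0 <- scheme$b == 0
  s0_mean <- if (sum(b0) > 1) rowMeans(S[, b0, drop = FALSE]) else S[, b0]
  if (is.null(mask)) mask <- array(s0_mean > 0, d[1:3])
  if (!all(dim(mask) == d[1:3])) stopf("mask does not match dwi grid")

  ## averaged-b0 design: one b = 0 row plus the diffusion-weighted rows
  dwv <- !b0
  X <- rbind(c(1, rep(0, 6)),
             tensor_design(scheme$b[dwv], scheme$g[dwv, , drop = FALSE]))
  XtX <- crossprod(X)
  if (rcond(XtX) < 1e-12) stopf("singular design matrix: scheme rejected")

  idx <- which(as.vector(mask))
  Sm <- cbind(s0_mean[idx], S[idx, dwv, drop = FALSE])
  invalid <- rowSums(Sm > 0) == 0
  Sm[Sm <= 0] <- .Machine$double.xmin     # log-domain guard for noisy dips
  Y <- log(t(Sm))                          # nvol x nfit
  beta <- solve(XtX, crossprod(X, Y))      # 7 x nfit
  res <- Y - X %*% beta
  rss_v <- colSums(res^2)

  nfit <- length(idx)
  ev <- matrix(0, nfit, 3)
  clamped_v <- logical(nfit)
  for (v in seq_len(nfit)) {
    Dv <- matrix(c(beta[2, v], beta[5, v], beta[6, v],
                   beta[5, v], beta[3, v], beta[7, v],
                   beta[6, v], beta[7, v], beta[4, v]), 3, 3)
    lam <- eigen(Dv, symmetric = TRUE, only.values = TRUE)$values
    if (any(lam < 0)) {
      lam <- pmax(lam, 0)
      clamped_v[v] <- TRUE
    }
    ev[v, ] <- sort(lam, decreasing = TRUE)
  }
  ev[invalid, ] <- 0

  evals <- array(0, c(d[1:3], 3))
  log_s0 <- rss <- array(NA_real_, d[1:3])
  clamped <- array(FALSE, d[1:3])
  valid <- array(FALSE, d[1:3])
  for (c3 in 1:3) evals[idx + (c3 - 1L) * nvox] <- ev[, c3]
  log_s0[idx] <- beta[1, ]
  rss[idx] <- rss_v
  clamped[idx] <- clamped_v
  valid[idx] <- !invalid
  structure(list(evals = evals, log_s0 = log_s0, rss = rss, valid = valid,
                 clamped = clamped, dim = d[1:3], voxel_size = voxel_size),
            class = "tensor_field")
}

#' Eleven scalar maps from a fitted tensor field
#'
#' Computes the anisotropies (FA, RA), diffusivities (p, q, MD, RD, AD) and
#' tensor measures (L, Cl, Cp, Cs) from the sorted eigenvalues.  The
#' isotropic/deviatoric decomposition satisfies p = sqrt(3) MD and
#' L^2 = p^2 + q^2 identically; the trace-normalised shape measures satisfy
#' Cl + Cp + Cs = 1 on every voxel with positive trace.  Zero-trace voxels
#' get all metrics 0 and are flagged.
#'
#' @param tf a `tensor_field` from [fit_tensor()].
#' @return an object of class `metric_maps`: the 11 named 3D maps, plus
#'   `brain_mask`, `csf_mask` (NULL until [exclude_csf()]), `zero_trace`
#'   flags, `dim`, `voxel_size`.
#' @export
compute_metrics <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  d <- tf$dim
  nvox <- prod(d)
  l1 <- tf$evals[, , , 1, drop = TRUE]
  l2 <- tf$evals[, , , 2, drop = TRUE]
  l3 <- tf$evals[, , , 3, drop = TRUE]
  if (any((l1 < l2 | l2 < l3) & tf$valid, na.rm = TRUE))
    stopf("eigenvalues not sorted descending")
  dim(l1) <- dim(l2) <- dim(l3) <- d
  tr <- l1 + l2 + l3
  zt <- tr <= 0
  trs <- ifelse(zt, 1, tr)               # avoid 0/0; zeroed below
  MD <- tr / 3
  AD <- l1
  RD <- (l2 + l3) / 2
  p <- sqrt(3) * MD
  q <- sqrt((l1 - MD)^2 + (l2 - MD)^2 + (l3 - MD)^2)
  L <- sqrt(l1^2 + l2^2 + l3^2)
  Ls <- ifelse(zt, 1, L)
  FA <- sqrt(1.5) * q / Ls
  RA <- q / ifelse(zt, 1, p)
  Cl <- (l1 - l2) / trs
  Cp <- 2 * (l2 - l3) / trs
  Cs <- 3 * l3 / trs
  maps <- list(FA = FA, RA = RA, p = p, q = q, MD = MD, RD = RD, AD = AD,
               L = L, Cl = Cl, Cp = Cp, Cs = Cs)
  maps <- lapply(maps, function(m) { m[zt] <- 0; m[!tf$valid] <- NA_real_; m })
  structure(c(maps,
              list(brain_mask = tf$valid & !zt, csf_mask = NULL,
                   zero_trace = zt & tf$valid, dim = d,
                   voxel_size = tf$voxel_size)),
            class = "metric_maps")
}

metric_names <- function() c("FA", "RA", "p", "q", "MD", "RD", "AD",
                             "L", "Cl", "Cp", "Cs")

#' Brain mask from the mean b = 0 image
#'
#' Magnitude noise outside the head is Rician, not zero, so the brain is
#' segmented from the background by Otsu thresholding of the mean b = 0
#' signal.  Falls back to `signal > 0` when the histogram is degenerate
#' (e.g. noiseless synthetic data with a uniform brain signal).
#'
#' @param dwi 4D diffusion-weighted array.
#' @param scheme the matching [diffusion_scheme()].
#' @return 3D logical mask.
#' @export
brain_mask_from_b0 <- function(dwi, scheme) {
  d <- dim(dwi)
  b0 <- scheme$b == 0
  S <- matrix(dwi, prod(d[1:3]), d[4])
  s0 <- if (sum(b0) > 1) rowMeans(S[, b0, drop = FALSE]) else S[, b0]
  thr <- tryCatch(otsu_threshold(s0), error = function(e) 0)
  if (!any(s0 > thr)) thr <- 0
  array(s0 > thr, d[1:3])
}

#' Otsu threshold of a set of values
#'
#' Maximises the between-class variance over a fixed-bin histogram; used as
#' a diagnostic alongside the fixed CSF diffusivity threshold.
#'
#' @param x numeric values (NAs dropped).
#' @param nbins histogram resolution.
#' @return the threshold (bin edge) maximising between-class variance.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stopf("need at least two finite values")
  edges <- seq(min(x), max(x), length.out = nbins + 1L)
  h <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), nbins)
  w <- h / sum(h)
  mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  w0 <- cumsum(w)
  mu0 <- cumsum(w * mids)
  mu_t <- mu0[nbins]
  bcv <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  bcv <- bcv[-nbins]
  ## plateau (empty bins between modes): take the middle of the argmax set
  at_max <- which(bcv >= max(bcv) * (1 - 1e-12))
  mean(edges[at_max + 1L])
}

#' Exclude cerebrospinal fluid by a mean-diffusivity threshold
#'
#' Voxels whose MD exceeds the threshold (default 800 x 10^-6 mm^2/s) are
#' classified as CSF and removed from all eleven maps; the remaining brain
#' voxels form the parenchyma mask used by every downstream stage.
#'
#' @param metrics a `metric_maps` object.
#' @param threshold MD cutoff in mm^2/s; must be positive.
#' @return the `metric_maps` with `csf_mask` set, maps masked to parenchyma,
#'   and `brain_mask` replaced by the parenchyma mask.
#' @export
exclude_csf <- function(metrics, threshold = 800e-6) {
  stopifnot(inherits(metrics, "metric_maps"))
  if (threshold <= 0) stopf("CSF threshold must be positive")
  csf <- metrics$brain_mask & !is.na(metrics$MD) & metrics$MD > threshold
  parenchyma <- metrics$brain_mask & !csf
  for (nm in metric_names()) metrics[[nm]][!parenchyma] <- NA_real_
  metrics$csf_mask <- csf
  metrics$brain_mask <- parenchyma
  metrics$csf_threshold <- threshold
  metrics
}
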