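#' Dynamic-susceptibility-contrast series container
#'
#' Wraps a 4D DSC acquisition with its timing metadata and locates the
#' pre-bolus baseline window: the volumes before the first sample of the
#' global mean-signal curve deviating more than 5 SD from the early
#' baseline mean (overridable).
#'
#' @param data 4D array (x, y, z, time) of signal magnitudes.
#' @param TR repetition time (s).
#' @param TE echo time (s).
#' @param baseline_window optional integer range of pre-bolus volume
#'   indices; auto-detected when NULL.
#' @return an object of class `dsc_series`.
#' @export
dsc_series <- function(data, TR, TE, baseline_window = NULL) {
  d <- dim(data)
  if (length(d) != 4L || d[4] < 20L) stopf("need a 4D series with >= 20 timepoints")
  if (TR <= 0 || TE <= 0) stopf("TR and TE must be positive")
  t_axis <- (seq_len(d[4]) - 1) * TR
  if (is.null(baseline_window)) {
    nz <- matrix(data, prod(d[1:3]), d[4])
    keep <- rowSums(nz) > 0
    curve <- colMeans(nz[keep, , drop = FALSE])
    n0 <- min(10L, d[4] %/% 4L)
    mu <- mean(curve[seq_len(n0)]); s <- sd(curve[seq_len(n0)])
    thr <- max(5 * s, 1e-9 * abs(mu))
    dev <- which(abs(curve - mu) > thr)
    first <- if (length(dev)) min(dev) else d[4]
    baseline_window <- seq_len(max(3L, first - 1L))
  }
  if (!length(baseline_window)) stopf("empty baseline window")
  structure(list(data = data, TR = TR, TE = TE, t = t_axis,
                 baseline_window = baseline_window, dim = d),
            class = "dsc_series")
}

#' Convert DSC signal to contrast-agent concentration
#'
#' Applies the gradient-echo relation C(t) = -ln(S(t)/S0)/TE per voxel,
#' with S0 the mean signal over the baseline window.  Voxels whose
#' baseline is at or below the noise floor are flagged invalid;
#' non-positive samples are clipped to the voxel's smallest positive
#' value and the voxel flagged.
#'
#' @param s a [dsc_series()].
#' @param noise_floor baseline signals at or below this are invalid.
#' @return list with `conc` (4D), `s0` (3D), `valid` and `clipped` (3D
#'   logical), time axis `t` and the baseline SD of the concentration.
#' @export
signal_to_concentration <- function(s, noise_floor = 0) {
  stopifnot(inherits(s, "dsc_series"))
  d <- s$dim
  S <- matrix(s$data, prod(d[1:3]), d[4])
  s0 <- rowMeans(S[, s$baseline_window, drop = FALSE])
  valid <- s0 > noise_floor
  clipped <- rep(FALSE, length(s0))
  bad <- which(valid & apply(S <= 0, 1, any))
  for (v in bad) {
    pos <- S[v, ] > 0
    if (!any(pos)) { valid[v] <- FALSE; next }
    S[v, !pos] <- min(S[v, pos])
    clipped[v] <- TRUE
  }
  conc <- matrix(0, nrow(S), ncol(S))
  conc[valid, ] <- -log(S[valid, , drop = FALSE] / s0[valid]) / s$TE
  base_sd <- apply(conc[, s$baseline_window, drop = FALSE], 1, sd)
  list(conc = array(conc, d), s0 = array(s0, d[1:3]),
       valid = array(valid, d[1:3]), clipped = array(clipped, d[1:3]),
       t = s$t, baseline_window = s$baseline_window,
       baseline_sd = array(base_sd, d[1:3]))
}

## first index, per row, where cond matrix is TRUE; Inf if none
row_first_true <- function(cond) {
  score <- col(cond)
  score[!cond] <- Inf
  do.call(pmin, c(as.data.frame(score), na.rm = TRUE))
}

#' Fit gamma-variate bolus curves
#'
#' Nonlinear least-squares fit of C(t) = K (t - t0)^alpha exp(-(t - t0)/beta)
#' (zero before arrival) per voxel, initialised from a log-linearisation
#' and refined by Levenberg-Marquardt on (log K, log alpha, log beta, t0),
#' batched across voxels.  Recirculation is suppressed by fitting only
#' samples up to the first post-peak time where the concentration falls
#' below `tail_frac` of the peak.  Voxels whose peak is below
#' `peak_snr` baseline-noise SDs, or that fail to converge, are invalid.
#'
#' @param conc concentration series: a numeric vector, or a matrix
#'   (voxels x time), or a 4D array.
#' @param t time axis (s).
#' @param baseline_sd per-voxel baseline concentration SD (0 when absent).
#' @param peak_snr peak-detection threshold in baseline SDs.
#' @param tail_frac post-peak cutoff as a fraction of the peak.
#' @param mask optional logical selector of voxels to fit.
#' @param max_iter Levenberg-Marquardt iteration cap.
#' @return an object of class `gamma_fit` with per-voxel `K`, `alpha`,
#'   `beta`, `t0`, goodness-of-fit `r2` and `valid` flag (all shaped like
#'   the input grid).
#' @export
fit_gamma_variate <- function(conc, t, baseline_sd = NULL, peak_snr = 3,
                              tail_frac = 0.30, mask = NULL, max_iter = 60L) {
  grid_dim <- NULL
  if (is.array(conc) && length(dim(conc)) == 4L) {
    grid_dim <- dim(conc)[1:3]
    conc <- matrix(conc, prod(grid_dim), dim(conc)[4])
  } else if (is.null(dim(conc))) conc <- matrix(conc, 1L)
  nvox <- nrow(conc); nt <- ncol(conc)
  if (length(t) != nt) stopf("time axis length mismatch")
  if (is.null(baseline_sd)) baseline_sd <- rep(0, nvox)
  baseline_sd <- as.vector(baseline_sd)
  sel <- if (is.null(mask)) rep(TRUE, nvox) else as.vector(mask)

  K <- alpha <- beta <- t0 <- r2 <- rep(NA_real_, nvox)
  valid <- rep(FALSE, nvox)

  C <- conc[sel, , drop = FALSE]
  n <- nrow(C)
  if (n > 0) {
    pk_idx <- max.col(C, ties.method = "first")
    pk <- C[cbind(seq_len(n), pk_idx)]
    fit_ok <- pk > pmax(peak_snr * baseline_sd[sel], 1e-12)

    ## recirculation cutoff: last sample before C dips under tail_frac*peak
    post <- col(C) > pk_idx & C < tail_frac * pk
    cut_idx <- row_first_true(post) - 1
    cut_idx[!is.finite(cut_idx)] <- nt
    W <- col(C) <= cut_idx                     # fit-sample mask

    ## onset: first sample clearly above both 10% of peak and the noise
    on_thr <- pmax(0.10 * pk, peak_snr * baseline_sd[sel])
    on_idx <- row_first_true(C > on_thr & col(C) <= pk_idx)
    on_idx[!is.finite(on_idx)] <- 2
    t0_init <- t[pmax(1, on_idx - 1)]

    ## log-linear init: log C = log K + alpha log(tau) - tau/beta
    theta <- matrix(NA_real_, n, 4)             # logK, logA, logB, t0
    for (v in which(fit_ok)) {
      tau <- t - t0_init[v]
      use <- which(W[v, ] & tau > 1e-6 & C[v, ] > 1e-6 * pk[v])
      if (length(use) < 4L) { fit_ok[v] <- FALSE; next }
      X <- cbind(1, log(tau[use]), -tau[use])
      cf <- tryCatch(qr.solve(X, log(C[v, use])), error = function(e) NULL)
      if (is.null(cf) || cf[2] <= 0 || cf[3] <= 0) {
        cf <- c(log(pk[v]), log(3), 1 / max(diff(range(t)) / 20, 1e-3))
      }
      theta[v, ] <- c(cf[1], log(max(cf[2], 1e-3)),
                      log(1 / max(cf[3], 1e-6)), t0_init[v])
    }

    act <- which(fit_ok)
    if (length(act)) {
      keep_t <- seq.int(max(1L, min(on_idx[act]) - 10L),
                        min(nt, max(cut_idx[act]) + 2L))  # active bolus window
      fitted <- lm_gamma_batch(C[act, keep_t, drop = FALSE], t[keep_t],
                               theta[act, , drop = FALSE],
                               W[act, keep_t, drop = FALSE], max_iter,
                               t0_max = t[pk_idx[act]] - 1e-6)
      idx_all <- which(sel)[act]
      K[idx_all] <- fitted$K
      alpha[idx_all] <- fitted$alpha
      beta[idx_all] <- fitted$beta
      t0[idx_all] <- fitted$t0
      r2[idx_all] <- fitted$r2
      valid[idx_all] <- fitted$converged & fitted$alpha > 0 &
        fitted$beta > 0 & fitted$t0 >= 0 & fitted$t0 <= max(t)
    }
  }
  shape <- function(x) if (is.null(grid_dim)) x else array(x, grid_dim)
  structure(list(K = shape(K), alpha = shape(alpha), beta = shape(beta),
                 t0 = shape(t0), r2 = shape(r2), valid = shape(valid),
                 t = t, grid_dim = grid_dim),
            class = "gamma_fit")
}

## batched Levenberg-Marquardt on theta = (log K, log alpha, log beta, t0).
## C: n x T concentration, W: n x T fit-sample mask.  Converged voxels are
## dropped from the working set, so late iterations touch few rows.
lm_gamma_batch <- function(C, t, theta, W, max_iter = 60L, tol = 1e-4,
                           t0_max = NULL) {
  n <- nrow(C); nt <- ncol(C)
  model_rows <- function(th, rows) {
    tau <- matrix(t, length(rows), nt, byrow = TRUE) - th[, 4]
    tau[tau < 0] <- 0
    a <- exp(th[, 2]); b <- exp(th[, 3]); Kv <- exp(th[, 1])
    M <- Kv * tau^a * exp(-tau / b)
    M[tau == 0] <- 0
    list(M = M, tau = tau, a = a, b = b)
  }
  tss <- rowSums((C - rowSums(C * W) / pmax(rowSums(W), 1))^2 * W)
  tss <- pmax(tss, 1e-300)
  md0 <- model_rows(theta, seq_len(n))
  f <- rowSums((C - md0$M)^2 * W)
  mu <- rep(1e-3, n)
  converged <- rep(FALSE, n)
  act <- which(f / tss >= 1e-12)
  converged[f / tss < 1e-12] <- TRUE
  for (it in seq_len(max_iter)) {
    if (!length(act)) break
    Ca <- C[act, , drop = FALSE]; Wa <- W[act, , drop = FALSE]
    md <- model_rows(theta[act, , drop = FALSE], act)
    tau <- md$tau; M <- md$M
    safe_tau <- pmax(tau, 1e-10)
    J1 <- M
    J2 <- M * log(safe_tau) * md$a
    J2[tau <= 0] <- 0
    J3 <- M * tau / md$b
    J4 <- M * (1 / md$b - md$a / safe_tau)
    J4[tau <= 1e-8] <- 0
    R <- (Ca - M) * Wa
    g <- cbind(rowSums(J1 * R), rowSums(J2 * R),
               rowSums(J3 * R), rowSums(J4 * R))
    H <- cbind(rowSums(J1 * J1 * Wa), rowSums(J1 * J2 * Wa),
               rowSums(J1 * J3 * Wa), rowSums(J1 * J4 * Wa),
               rowSums(J2 * J2 * Wa), rowSums(J2 * J3 * Wa),
               rowSums(J2 * J4 * Wa), rowSums(J3 * J3 * Wa),
               rowSums(J3 * J4 * Wa), rowSums(J4 * J4 * Wa))
    th_new <- theta[act, , drop = FALSE]
    stepmax <- rep(Inf, length(act))
    for (r in seq_along(act)) {
      Hv <- matrix(c(H[r, 1], H[r, 2], H[r, 3], H[r, 4],
                     H[r, 2], H[r, 5], H[r, 6], H[r, 7],
                     H[r, 3], H[r, 6], H[r, 8], H[r, 9],
                     H[r, 4], H[r, 7], H[r, 9], H[r, 10]), 4, 4)
      A <- Hv + mu[act[r]] * diag(pmax(diag(Hv), 1e-12))
      step <- tryCatch(solve(A, g[r, ]), error = function(e) rep(0, 4))
      th_new[r, ] <- theta[act[r], ] + step
      stepmax[r] <- max(abs(step))
    }
    ## physiological clamps keep the bolus shape sane under noise
    th_new[, 2] <- pmin(pmax(th_new[, 2], log(0.05)), log(30))
    th_new[, 3] <- pmin(pmax(th_new[, 3], log(0.01)), log(60))
    up <- if (is.null(t0_max)) max(t) - 1e-6 else t0_max[act]
    th_new[, 4] <- pmin(pmax(th_new[, 4], 0), up)
    md_new <- model_rows(th_new, act)
    f_new <- rowSums((Ca - md_new$M)^2 * Wa)
    better <- f_new < f[act] & is.finite(f_new)
    rel <- abs(f[act] - f_new) / pmax(f[act], 1e-300)
    theta[act[better], ] <- th_new[better, , drop = FALSE]
    f[act[better]] <- f_new[better]
    mu[act[better]] <- pmax(mu[act[better]] * 0.3, 1e-12)
    mu[act[!better]] <- pmin(mu[act[!better]] * 5, 1e10)
    done <- (better & (rel < tol | stepmax < 1e-4)) |  # converged
      f[act] / tss[act] < 1e-12 |                # essentially perfect fit
      mu[act] >= 1e8                             # stalled: accept current
    converged[act[done]] <- TRUE
    act <- act[!done]
  }
  list(K = exp(theta[, 1]), alpha = exp(theta[, 2]), beta = exp(theta[, 3]),
       t0 = theta[, 4], r2 = 1 - f / tss,
       converged = converged | f / tss < 1e-6)
}

#' Perfusion maps from fitted gamma-variate parameters
#'
#' rCBV is the bolus-curve integral K beta^(alpha+1) Gamma(alpha+1), rMTT
#' the normalised first moment measured from the arrival time,
#' beta (alpha + 1), and rCBF their ratio by the central volume principle.
#'
#' @param fit a `gamma_fit` from [fit_gamma_variate()].
#' @return an object of class `perfusion_maps` with `rcbv`, `rmtt`,
#'   `rcbf` and a `valid` mask.
#' @export
compute_perfusion_maps <- function(fit) {
  stopifnot(inherits(fit, "gamma_fit"))
  rcbv <- fit$K * fit$beta^(fit$alpha + 1) * gamma(fit$alpha + 1)
  rmtt <- fit$beta * (fit$alpha + 1)
  valid <- fit$valid & is.finite(rcbv) & is.finite(rmtt) & rmtt > 0
  rcbf <- rcbv / rmtt
  rcbv[!valid] <- NA_real_; rmtt[!valid] <- NA_real_; rcbf[!valid] <- NA_real_
  structure(list(rcbv = rcbv, rmtt = rmtt, rcbf = rcbf, valid = valid),
            class = "perfusion_maps")
}
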