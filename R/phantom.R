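#' Specification of the synthetic rat-brain cohort
#'
#' Defines the geometry, tissue contrasts, perfusion parameters, noise and
#' between-animal variability of the phantom generator.  Defaults emulate a
#' permanent middle-cerebral-artery-occlusion rat imaged at 0.5 h and 1.5 h
#' after occlusion: an ischemic core with a 35% diffusivity reduction
#' (below the 30%-reduction core rule), a penumbral rim with a 17%
#' reduction in MD/p/L, and a hypoperfused territory (core + rim) at 40%
#' of contralateral cerebral blood flow (below the 46%-reduction perfusion
#' deficit rule).  The core grows into the rim between the two timepoints,
#' so the penumbra shrinks.
#'
#' @param grid_shape voxels per axis.
#' @param voxel_size mm per axis (in-plane 0.2 mm, 1 mm slices).
#' @param n_rats number of animals.
#' @param timepoints imaging times in hours after occlusion; perfusion is
#'   acquired only at the first timepoint.
#' @param tissue_tensors list with `NT` (eigenvalue triple, mm^2/s, of
#'   normal parenchyma) and `CSF` (isotropic diffusivity, mm^2/s).
#' @param penumbra_scale multiplicative diffusivity factor of the rim.
#' @param core_scale multiplicative diffusivity factor of the core; must
#'   stay below 0.70 so that the core satisfies the MD-reduction rule.
#' @param cbf_deficit CBF in the hypoperfused territory as a fraction of
#'   normal; must stay below 0.54.
#' @param noise_sigma Rician noise SD relative to the mean b = 0 brain
#'   signal of the diffusion acquisition.
#' @param dsc_noise_sigma Rician noise SD relative to the DSC baseline.
#' @param rat_variability lognormal SD of per-rat global diffusivity and
#'   CBF multipliers.
#' @param rim_mm outward dilation (mm, in-plane) of the core ellipsoid that
#'   delimits the hypoperfused territory.
#' @param growth_mm core growth (mm, in-plane) between consecutive
#'   timepoints.
#' @param mtt_nt,mtt_lesion mean transit time (s) in normal and
#'   hypoperfused tissue.
#' @param bolus_alpha gamma-variate shape of the simulated bolus.
#' @param arrival_s nominal bolus arrival time (s) after acquisition start.
#' @param dsc list of DSC acquisition metadata: `TR` (s), `TE` (s),
#'   `n_rep` repetitions, baseline signal `s0`, concentration `gain`.
#' @param s0 b = 0 signal level of the diffusion acquisition.
#' @param seed master RNG seed of the cohort.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 16L),
                         voxel_size = c(0.2, 0.2, 1.0),
                         n_rats = 8L,
                         timepoints = c(0.5, 1.5),
                         tissue_tensors = list(NT = c(1.05, 0.55, 0.45) * 1e-3,
                                               CSF = 2.5e-3),
                         penumbra_scale = 0.83,
                         core_scale = 0.65,
                         cbf_deficit = 0.40,
                         noise_sigma = 0.03,
                         dsc_noise_sigma = 0.02,
                         rat_variability = 0.05,
                         rim_mm = 1.0,
                         growth_mm = 0.5,
                         mtt_nt = 6, mtt_lesion = 9,
                         bolus_alpha = 3,
                         arrival_s = 30,
                         dsc = list(TR = 0.6, TE = 0.02, n_rep = 200L,
                                    s0 = 500, gain = 20),
                         s0 = 1000,
                         seed = 1L) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (length(grid_shape) != 3L || any(grid_shape <= 0))
      stopf("grid_shape must be three positive integers")
    if (length(timepoints) < 1L) stopf("timepoints must be non-empty")
    if (penumbra_scale <= core_scale)
      stopf("penumbra_scale (%g) must exceed core_scale (%g)",
            penumbra_scale, core_scale)
    for (s in c(penumbra_scale, core_scale, cbf_deficit))
      if (s <= 0 || s >= 1) stopf("tissue scales must lie in (0, 1)")
    if (core_scale >= 0.70)
      stopf("core_scale %.2f does not satisfy the 30%% MD-reduction rule",
            core_scale)
    if (cbf_deficit >= 0.54)
      stopf("cbf_deficit %.2f does not satisfy the 46%% CBF-reduction rule",
            cbf_deficit)
    if (noise_sigma < 0 || dsc_noise_sigma < 0) stopf("noise must be >= 0")
    if (n_rats < 1L) stopf("n_rats must be >= 1")
  })
  invisible(spec)
}

## Rician-distorted magnitude signal: sqrt((S + n1)^2 + n2^2)
rician <- function(s, sigma) {
  if (sigma <= 0) return(s)
  n <- length(s)
  sqrt((s + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

## inside-ellipsoid test on voxel-grid coordinates
in_ellipsoid <- function(coords, center, semi) {
  u <- sweep(coords, 2, center)
  u <- sweep(u, 2, semi, "/")
  rowSums(u^2) <= 1
}

## gamma-variate bolus concentration K (t-t0)^a exp(-(t-t0)/b), 0 for t<=t0
gamma_variate <- function(t, K, alpha, beta, t0) {
  tau <- t - t0
  out <- numeric(length(t))
  pos <- tau > 0
  out[pos] <- K * tau[pos]^alpha * exp(-tau[pos] / beta)
  out
}

#' Simulate the DSC signal of one voxel
#'
#' Inverse of the perfusion quantification: given relative flow, mean
#' transit time and arrival time, generates the gamma-variate bolus
#' concentration (central volume principle: rCBV = gain * cbf * mtt) and
#' converts it to a gradient-echo signal S(t) = s0 exp(-TE C(t)).
#'
#' @param cbf relative cerebral blood flow (> 0).
#' @param mtt mean transit time in seconds (> 0).
#' @param arrival bolus arrival time t0 in seconds; must precede the end of
#'   the acquisition window.
#' @param dsc acquisition metadata (`TR`, `TE`, `n_rep`, `s0`, `gain`), as
#'   in [phantom_spec()].
#' @param alpha gamma-variate shape parameter.
#' @return numeric signal series of length `n_rep`, with the generating
#'   parameters attached as attribute `params`.
#' @export
simulate_dsc_voxel <- function(cbf, mtt, arrival, dsc = phantom_spec()$dsc,
                               alpha = 3) {
  if (cbf <= 0 || mtt <= 0) stopf("cbf and mtt must be positive")
  t <- (seq_len(dsc$n_rep) - 1) * dsc$TR
  if (arrival < 0 || arrival >= max(t))
    stopf("arrival %.1f s outside acquisition window [0, %.1f) s",
          arrival, max(t))
  beta <- mtt / (alpha + 1)
  K <- dsc$gain * cbf * mtt / (beta^(alpha + 1) * gamma(alpha + 1))
  conc <- gamma_variate(t, K, alpha, beta, arrival)
  s <- dsc$s0 * exp(-dsc$TE * conc)
  attr(s, "params") <- list(K = K, alpha = alpha, beta = beta, t0 = arrival,
                            rcbv = dsc$gain * cbf * mtt, rmtt = mtt,
                            rcbf = dsc$gain * cbf)
  s
}

## random orthonormal triads (n x 3 each), vectorised
random_frames <- function(n) {
  e1 <- matrix(rnorm(3 * n), n, 3)
  e1 <- e1 / sqrt(rowSums(e1^2))
  v <- matrix(rnorm(3 * n), n, 3)
  v <- v - e1 * rowSums(v * e1)
  e2 <- v / sqrt(rowSums(v^2))
  e3 <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  list(e1 = e1, e2 = e2, e3 = e3)
}

## 6 unique tensor components from eigenvalues (n x 3) and frames
tensor_components <- function(lam, fr) {
  comp <- function(a, b)
    lam[, 1] * fr$e1[, a] * fr$e1[, b] +
    lam[, 2] * fr$e2[, a] * fr$e2[, b] +
    lam[, 3] * fr$e3[, a] * fr$e3[, b]
  cbind(xx = comp(1, 1), yy = comp(2, 2), zz = comp(3, 3),
        xy = comp(1, 2), xz = comp(1, 3), yz = comp(2, 3))
}

#' Simulate one phantom rat
#'
#' Builds the per-animal anatomy (ellipsoidal two-hemisphere brain with
#' ventricular CSF and a one-hemisphere lesion: core ellipsoid plus
#' penumbral rim), assigns per-class diffusion tensors with random voxel
#' orientations, synthesises the diffusion-weighted volumes
#' S = S0 exp(-b g'Dg) with Rician noise and the DSC series at the first
#' timepoint, and records ground-truth labels before noise is added.
#'
#' @param spec a [phantom_spec()].
#' @param rat_index integer in `1:spec$n_rats`; determines the rat's
#'   independent RNG stream.
#' @return an object of class `phantom_rat`; see Details.
#' @details The returned list carries `rat_id`, the acquisition `scheme`,
#'   `dsc_meta`, the `midline` plane (point + normal), per-timepoint `dwi`
#'   4D arrays, the `dsc` 4D series, per-timepoint `truth` label volumes
#'   (coded 0 excluded, 1 core, 2 penumbra, 3 normal tissue,
#'   4 contralateral), `truth_pv` (mm^3), and noiseless `truth_md` /
#'   `truth_cbf` maps.
#' @export
simulate_rat <- function(spec, rat_index) {
  validate_phantom_spec(spec)
  seed <- child_seed(spec$seed, "phantom", rat_index)
  with_seed(seed, {
    d <- as.integer(spec$grid_shape)
    nvox <- prod(d)
    coords <- vox_coords(seq_len(nvox), d)
    vs <- spec$voxel_size
    ctr <- (d + 1) / 2

    jit <- function(s) runif(1, -s, s)
    brain_semi <- c(0.40 * d[1], 0.33 * d[2], 0.44 * d[3]) *
      (1 + c(jit(0.04), jit(0.04), jit(0.04)))
    brain <- in_ellipsoid(coords, ctr, brain_semi)

    midline_x <- ctr[1]
    midline <- list(point = c(midline_x, 0, 0), normal = c(1, 0, 0))
    ipsi_side <- coords[, 1] < midline_x        # lesion in the left hemisphere

    vent_semi <- c(0.04 * d[1], 0.08 * d[2], 0.15 * d[3])
    csf <- (in_ellipsoid(coords, ctr + c(-0.10 * d[1], 0, 0), vent_semi) |
            in_ellipsoid(coords, ctr + c(+0.10 * d[1], 0, 0), vent_semi)) & brain

    core_ctr <- ctr + c(-0.22 * d[1] + jit(0.02 * d[1]),
                        jit(0.04 * d[2]), jit(0.5))
    core_semi0 <- c(0.115 * d[1], 0.10 * d[2], 0.15 * d[3]) * (1 + jit(0.08))
    rim_vox <- spec$rim_mm / vs[1]              # in-plane voxels
    grow_vox <- spec$growth_mm / vs[1]
    hypo_semi <- core_semi0 + c(rim_vox, rim_vox, spec$rim_mm / vs[3])
    hypo <- in_ellipsoid(coords, core_ctr, hypo_semi) & brain & !csf & ipsi_side

    m_diff <- exp(rnorm(1, 0, spec$rat_variability))
    m_cbf <- exp(rnorm(1, 0, spec$rat_variability))
    arrival <- spec$arrival_s + runif(1, -2, 2)

    nt_ev <- spec$tissue_tensors$NT
    csf_d <- spec$tissue_tensors$CSF[1]

    scheme <- default_scheme()
    n_b0_brain <- spec$s0

    timepoint_data <- lapply(seq_along(spec$timepoints), function(ti) {
      core_semi <- core_semi0 +
        (ti - 1) * c(grow_vox, grow_vox, spec$growth_mm / vs[3])
      core <- in_ellipsoid(coords, core_ctr, core_semi) & brain & !csf &
        ipsi_side
      core <- core & hypo                        # growth stays inside territory
      pen <- hypo & !core

      labels <- integer(nvox)                    # 0 = excluded
      labels[brain & !csf & !ipsi_side] <- 4L    # contralateral
      labels[brain & !csf & ipsi_side] <- 3L     # normal tissue
      labels[pen] <- 2L
      labels[core] <- 1L

      scale <- rep(1, nvox)
      scale[pen] <- spec$penumbra_scale
      scale[core] <- spec$core_scale
      lam <- matrix(0, nvox, 3)
      par_idx <- which(brain & !csf)
      lam[par_idx, ] <- m_diff *
        outer(scale[par_idx], nt_ev)
      csf_idx <- which(csf)
      lam[csf_idx, ] <- csf_d

      tissue <- c(par_idx, csf_idx)
      fr <- random_frames(length(tissue))
      Dc <- tensor_components(lam[tissue, , drop = FALSE], fr)

      gsq <- cbind(scheme$g[, 1]^2, scheme$g[, 2]^2, scheme$g[, 3]^2,
                   2 * scheme$g[, 1] * scheme$g[, 2],
                   2 * scheme$g[, 1] * scheme$g[, 3],
                   2 * scheme$g[, 2] * scheme$g[, 3])
      ## signal: nvox_tissue x nvol
      expo <- Dc %*% t(gsq * scheme$b)
      S <- matrix(0, nvox, length(scheme$b))
      S[tissue, ] <- n_b0_brain * exp(-expo)
      sigma <- spec$noise_sigma * n_b0_brain
      if (sigma > 0) S[] <- rician(as.vector(S), sigma)
      dwi <- array(S, c(d, length(scheme$b)))
      attr(dwi, "voxel_size") <- vs

      lab_vol <- label_volume(array(labels, d), split_hemispheres(
        array(brain & !csf, d), midline), vs)

      truth_md <- array(rowMeans(lam), d)
      truth_md[!brain] <- NA_real_

      list(dwi = dwi, truth = lab_vol, truth_pv = compute_pv(lab_vol),
           truth_md = truth_md)
    })
    names(timepoint_data) <- paste0("t", spec$timepoints)

    ## DSC at the first timepoint only
    cbf_rel <- rep(NA_real_, nvox)
    tissue <- brain
    cbf_rel[brain] <- m_cbf
    cbf_rel[hypo] <- m_cbf * spec$cbf_deficit
    mtt <- rep(NA_real_, nvox)
    mtt[brain] <- spec$mtt_nt
    mtt[hypo] <- spec$mtt_lesion
    t_axis <- (seq_len(spec$dsc$n_rep) - 1) * spec$dsc$TR
    alpha <- spec$bolus_alpha
    beta <- mtt / (alpha + 1)
    K <- spec$dsc$gain * cbf_rel * mtt / (beta^(alpha + 1) * gamma(alpha + 1))
    tau <- outer(rep(1, nvox), t_axis) - arrival
    tau[tau < 0] <- 0
    conc <- K * tau^alpha * exp(-tau / ifelse(is.na(beta), 1, beta))
    conc[!brain, ] <- 0
    conc[is.na(conc)] <- 0
    Sdsc <- spec$dsc$s0 * exp(-spec$dsc$TE * conc)
    Sdsc[!brain, ] <- 0
    sig_dsc <- spec$dsc_noise_sigma * spec$dsc$s0
    if (sig_dsc > 0) Sdsc[brain, ] <- rician(as.vector(Sdsc[brain, ]), sig_dsc)
    dsc <- array(Sdsc, c(d, spec$dsc$n_rep))

    truth_cbf <- array(spec$dsc$gain * cbf_rel, d)

    structure(list(rat_id = sprintf("rat%02d", rat_index),
                   seed = seed, scheme = scheme,
                   dsc_meta = spec$dsc, voxel_size = vs,
                   midline = midline,
                   timepoints = spec$timepoints,
                   data = timepoint_data,
                   dsc = dsc,
                   truth_cbf = truth_cbf,
                   arrival = arrival,
                   multipliers = c(diffusivity = m_diff, cbf = m_cbf)),
              class = "phantom_rat")
  })
}

#' Simulate a full cohort
#'
#' Generates `spec$n_rats` animals, each from an independent RNG stream
#' derived from the cohort seed, so the cohort is bit-reproducible and any
#' single rat can be regenerated in isolation.
#'
#' @param spec a [phantom_spec()].
#' @return list of [simulate_rat()] objects.
#' @export
simulate_cohort <- function(spec) {
  validate_phantom_spec(spec)
  lapply(seq_len(spec$n_rats), function(i) simulate_rat(spec, i))
}

#' Write a phantom rat to disk
#'
#' Emits NIfTI volumes (4D DWI per timepoint, 4D DSC, uint8 label volumes),
#' FSL-style `bvals`/`bvecs`, and a JSON manifest with seeds, acquisition
#' metadata and truth penumbral volumes.
#'
#' @param rat a `phantom_rat`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_phantom_rat <- function(rat, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pv <- list()
  for (tp in names(rat$data)) {
    dwi_img <- RNifti::asNifti(rat$data[[tp]]$dwi)
    RNifti::pixdim(dwi_img) <- rat$voxel_size
    RNifti::writeNifti(dwi_img,
                       file.path(dir, sprintf("%s_%s_dwi.nii.gz", rat$rat_id, tp)))
    lab <- rat$data[[tp]]$truth$labels
    storage.mode(lab) <- "integer"
    lab_img <- RNifti::asNifti(lab)
    RNifti::pixdim(lab_img) <- rat$voxel_size
    lab_img <- RNifti::asNifti(lab_img, datatype = "uint8")
    RNifti::writeNifti(lab_img,
                       file.path(dir, sprintf("%s_%s_labels.nii.gz",
                                              rat$rat_id, tp)))
    pv[[tp]] <- rat$data[[tp]]$truth_pv
  }
  RNifti::writeNifti(RNifti::asNifti(rat$dsc),
                     file.path(dir, sprintf("%s_dsc.nii.gz", rat$rat_id)))
  write_scheme(rat$scheme, file.path(dir, sprintf("%s.bvals", rat$rat_id)),
               file.path(dir, sprintf("%s.bvecs", rat$rat_id)))
  manifest <- list(rat_id = rat$rat_id, seed = rat$seed,
                   voxel_size = rat$voxel_size, timepoints = rat$timepoints,
                   dsc_meta = rat$dsc_meta, midline = rat$midline,
                   truth_pv_mm3 = pv)
  path <- file.path(dir, sprintf("%s_manifest.json", rat$rat_id))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
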