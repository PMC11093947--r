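## Small phantom fixtures, built once per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

small_spec <- function(...) {
  args <- utils::modifyList(list(grid_shape = c(32L, 32L, 8L), n_rats = 2L,
                                 seed = 42L), list(...))
  do.call(phantom_spec, args)
}

## one noiseless rat plus its fitted maps and labels
noiseless_case <- function() fixture("noiseless", function() {
  spec <- small_spec(noise_sigma = 0, dsc_noise_sigma = 0)
  rat <- simulate_rat(spec, 1)
  tf <- fit_tensor(rat$data[[1]]$dwi, rat$scheme,
                   mask = brain_mask_from_b0(rat$data[[1]]$dwi, rat$scheme),
                   voxel_size = rat$voxel_size)
  mm <- exclude_csf(compute_metrics(tf))
  list(spec = spec, rat = rat, tensor = tf, metrics = mm)
})

## one noisy rat with full maps, labels and features
noisy_case <- function() fixture("noisy", function() {
  spec <- small_spec()
  rat <- simulate_rat(spec, 1)
  tf <- fit_tensor(rat$data[[1]]$dwi, rat$scheme,
                   mask = brain_mask_from_b0(rat$data[[1]]$dwi, rat$scheme),
                   voxel_size = rat$voxel_size)
  mm <- exclude_csf(compute_metrics(tf))
  cc <- signal_to_concentration(dsc_series(rat$dsc, rat$dsc_meta$TR,
                                           rat$dsc_meta$TE))
  gf <- fit_gamma_variate(cc$conc, cc$t, baseline_sd = cc$baseline_sd,
                          mask = mm$brain_mask & cc$valid)
  pm <- compute_perfusion_maps(gf)
  hemis <- split_hemispheres(mm$brain_mask, rat$midline)
  labels <- delineate(mm, pm$rcbf, hemis)
  ref <- build_ic_reference(mm, labels)
  feats <- extract_features(mm, labels, ref, rat_id = rat$rat_id,
                            timepoint = 0.5)
  list(spec = spec, rat = rat, metrics = mm, perfusion = pm,
       labels = labels, ref = ref, features = feats)
})

## toy multi-rat feature table with two informative columns among noise
toy_table <- function(n_rats = 4L, n_per_class = 60L, shift = 3,
                      seed = 99L, n_features = 4L) {
  set.seed(seed)
  rows <- lapply(seq_len(n_rats), function(r) {
    n <- 2L * n_per_class
    lab <- rep(c("NT", "penumbra"), each = n_per_class)
    X <- matrix(rnorm(n * n_features), n, n_features,
                dimnames = list(NULL, paste0("x", seq_len(n_features))))
    X[lab == "penumbra", 1] <- X[lab == "penumbra", 1] + shift
    df <- as.data.frame(X)
    df$label <- factor(lab, levels = c("NT", "penumbra"))
    df$rat_id <- sprintf("rat%02d", r)
    df$timepoint <- 0.5
    df$voxel <- seq_len(n)
    df
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

random_tensor_eigs <- function(n, seed = 1) {
  set.seed(seed)
  lam <- matrix(stats::rexp(3 * n, rate = 1e3), n, 3)
  t(apply(lam, 1, sort, decreasing = TRUE))
}

## metrics straight from an eigenvalue matrix via a 1-voxel-per-row field
metrics_from_eigs <- function(lam) {
  n <- nrow(lam)
  tf <- structure(list(
    evals = array(lam, c(n, 1, 1, 3)),
    log_s0 = array(0, c(n, 1, 1)),
    rss = array(0, c(n, 1, 1)),
    valid = array(TRUE, c(n, 1, 1)),
    clamped = array(FALSE, c(n, 1, 1)),
    dim = c(n, 1L, 1L), voxel_size = c(1, 1, 1)), class = "tensor_field")
  compute_metrics(tf)
}
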