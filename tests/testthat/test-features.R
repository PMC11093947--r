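## hand-made metric maps + labels holding given observation matrices
maps_from_matrix <- function(vals) {
  n <- nrow(vals)
  d <- c(n, 1L, 1L)
  maps <- setNames(lapply(seq_len(11), function(j) array(vals[, j], d)),
                   penumbraDTI:::metric_names())
  structure(c(maps, list(brain_mask = array(TRUE, d),
                         csf_mask = array(FALSE, d),
                         zero_trace = array(FALSE, d), dim = d,
                         voxel_size = c(1, 1, 1))), class = "metric_maps")
}

labels_vec <- function(codes) {
  label_volume(array(codes, c(length(codes), 1L, 1L)), NULL, c(1, 1, 1))
}

test_that("reference statistics match hand arithmetic on a 3-voxel core", {
  vals <- matrix(0, 5, 11)
  vals[1, ] <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11)
  vals[2, ] <- c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  vals[3, ] <- c(6, 1, 2, 9, 4, 5, 3, 7, 8, 2, 1)
  vals[4:5, ] <- 1
  ref <- build_ic_reference(maps_from_matrix(vals),
                            labels_vec(c(1L, 1L, 1L, 3L, 3L)))
  expect_equal(unname(ref$mu), unname(colMeans(vals[1:3, ])))
  expect_equal(unname(ref$s), unname(apply(vals[1:3, ], 2, sd)))
  expect_true(ref$small_core)
  expect_error(build_ic_reference(maps_from_matrix(vals),
                                  labels_vec(rep(3L, 5))), "core")
})

test_that("degenerate cores engage regularisation and SD floors", {
  vals <- matrix(rep(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11), each = 4),
                 4, 11)
  ref <- build_ic_reference(maps_from_matrix(vals),
                            labels_vec(c(1L, 1L, 1L, 1L)))
  expect_true(ref$regularized)
  expect_true(all(ref$zero_var))
  expect_equal(unname(ref$s), rep(1e-12, 11))
})

test_that("all 25 features match a brute-force pairwise oracle", {
  set.seed(17)
  n_ic <- 5; n_q <- 2
  vals <- matrix(rexp(11 * (n_ic + n_q), rate = 1), n_ic + n_q, 11)
  labels <- labels_vec(c(rep(1L, n_ic), 2L, 3L))
  mm <- maps_from_matrix(vals)
  ref <- build_ic_reference(mm, labels)
  ft <- extract_features(mm, labels, ref)
  expect_equal(nrow(ft), n_q)
  expect_length(intersect(names(ft), penumbraDTI:::feature_names()), 25L)

  Y <- vals[1:n_ic, ]
  for (qi in seq_len(n_q)) {
    x <- vals[n_ic + qi, ]
    expect_equal(ft$mahalanobis[qi],
                 sqrt(mahalanobis(matrix(x, 1), ref$mu, ref$S_reg)),
                 tolerance = 1e-10)
    cos_bf <- mean(apply(Y, 1, function(y)
      1 - sum(x * y) / sqrt(sum(x^2) * sum(y^2))))
    cor_bf <- mean(apply(Y, 1, function(y) 1 - cor(x, y)))
    expect_equal(ft$cosine_dist[qi], cos_bf, tolerance = 1e-10)
    expect_equal(ft$correlation_dist[qi], cor_bf, tolerance = 1e-10)
    for (j in seq_len(11)) {
      nm <- penumbraDTI:::metric_names()[j]
      expect_equal(ft[[paste0(nm, "_sed")]][qi],
                   unname(mean(abs(x[j] - Y[, j])) / ref$s[j]),
                   tolerance = 1e-10)
    }
  }
})

test_that("distance features agree with brute force on a 100-voxel instance", {
  set.seed(23)
  n_ic <- 40; n_q <- 60
  vals <- matrix(rnorm(11 * (n_ic + n_q), mean = 5), n_ic + n_q, 11)
  labels <- labels_vec(c(rep(1L, n_ic), rep(2L, 30), rep(3L, 30)))
  mm <- maps_from_matrix(vals)
  ref <- build_ic_reference(mm, labels)
  ft <- extract_features(mm, labels, ref)
  Y <- vals[seq_len(n_ic), ]
  sed_bf <- vapply(seq_len(n_q), function(qi)
    unname(mean(abs(vals[n_ic + qi, 5] - Y[, 5])) / ref$s[5]),
    numeric(1))
  expect_equal(ft$MD_sed, sed_bf, tolerance = 1e-10)
  cos_bf <- vapply(seq_len(n_q), function(qi) {
    x <- vals[n_ic + qi, ]
    mean(apply(Y, 1, function(y) 1 - sum(x * y) /
                 sqrt(sum(x^2) * sum(y^2))))
  }, numeric(1))
  expect_equal(ft$cosine_dist, cos_bf, tolerance = 1e-10)
})

test_that("Mahalanobis distance is affine invariant; sed is scale free", {
  set.seed(29)
  vals <- matrix(rnorm(11 * 40, 10), 40, 11)
  labels <- labels_vec(c(rep(1L, 25), rep(2L, 15)))
  mm <- maps_from_matrix(vals)
  ref <- build_ic_reference(mm, labels)
  ft <- extract_features(mm, labels, ref)
  ## joint invertible affine map on all metric vectors
  A <- matrix(rnorm(121), 11)
  A <- A + 11 * diag(11)
  b <- rnorm(11)
  vals2 <- sweep(vals %*% t(A), 2, b, "+")
  mm2 <- maps_from_matrix(vals2)
  ref2 <- build_ic_reference(mm2, labels)
  ft2 <- extract_features(mm2, labels, ref2)
  expect_equal(ft2$mahalanobis, ft$mahalanobis, tolerance = 1e-8)
  ## per-metric rescaling cancels in the standardized distances
  vals3 <- sweep(vals, 2, c(3, 0.5, 7, 2, 10, 1, 1, 4, 2, 9, 0.1), "*")
  mm3 <- maps_from_matrix(vals3)
  ref3 <- build_ic_reference(mm3, labels)
  ft3 <- extract_features(mm3, labels, ref3)
  for (nm in paste0(penumbraDTI:::metric_names(), "_sed"))
    expect_equal(ft3[[nm]], ft[[nm]], tolerance = 1e-10)
})

test_that("p_sed equals MD_sed on fitted phantom data", {
  ft <- noisy_case()$features
  expect_equal(ft$p_sed, ft$MD_sed, tolerance = 1e-12)
  expect_length(intersect(names(ft), penumbraDTI:::feature_names()), 25L)
})

test_that("zero-norm voxels are dropped with an accounting flag", {
  vals <- matrix(rnorm(11 * 10, 5), 10, 11)
  vals[8, ] <- 0                                # zero norm: cosine undefined
  vals[9, ] <- 2                                # zero spread: correlation undefined
  labels <- labels_vec(c(rep(1L, 6), rep(2L, 4)))
  mm <- maps_from_matrix(vals)
  ref <- build_ic_reference(mm, labels)
  ft <- extract_features(mm, labels, ref)
  expect_equal(nrow(ft), 2L)
  expect_equal(attr(ft, "n_dropped"), 2L)
})

test_that("NCA finds the separating feature and honours the 2% rule", {
  tab <- toy_table(n_rats = 1L, n_per_class = 100L, shift = 4, seed = 55L,
                   n_features = 2L)
  ## embed the two toy columns among the named 25 (others pure noise)
  full <- tab
  for (nm in penumbraDTI:::feature_names()) full[[nm]] <- rnorm(nrow(tab))
  full$FA <- tab$x1                              # separating
  full$RA <- tab$x2                              # noise
  res <- select_features(full, lambda_grid = 0.5 / 200, k_folds = 3,
                         seed = 5, max_rows = 200, max_iter = 40)
  w <- res$weights
  expect_gt(w["FA"], 50 * w["RA"])
  expect_false(res$bypassed)
  expect_true("FA" %in% res$selected)
  expect_false("RA" %in% res$selected)
})

test_that("a dominating penalty drives all weights to zero and bypasses", {
  tab <- toy_table(n_rats = 1L, n_per_class = 40L, shift = 3, seed = 6L)
  full <- tab
  for (nm in penumbraDTI:::feature_names()) full[[nm]] <- rnorm(nrow(tab))
  full$FA <- tab$x1
  res <- select_features(full, lambda_grid = 1e3, k_folds = 3, seed = 2,
                         max_rows = 80, max_iter = 20)
  ## selection under penalty dominance cannot beat using everything
  expect_true(res$bypassed)
  expect_length(res$selected, 25L)
  expect_error(select_features(full[full$label == "NT", ]), "two classes")
  expect_error(select_features(full, lambda_grid = numeric(0)), "empty")
})
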