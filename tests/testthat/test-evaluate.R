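test_that("classification metrics match hand arithmetic", {
  ## confusion counts TP=40, FN=10, TN=45, FP=5
  y <- c(rep("penumbra", 50), rep("NT", 50))
  p <- c(rep(0.9, 40), rep(0.1, 10), rep(0.1, 45), rep(0.9, 5))
  m <- classification_metrics(y, p)
  expect_equal(unname(m["sensitivity"]), 0.8)
  expect_equal(unname(m["specificity"]), 0.9)
  expect_equal(unname(m["precision"]), 40 / 45)
  expect_equal(unname(m["accuracy"]), 0.85)
  expect_equal(unname(m["f1"]), 2 * (40 / 45) * 0.8 / ((40 / 45) + 0.8))
  ## perfect predictions
  mp <- classification_metrics(y, as.numeric(y == "penumbra"))
  expect_equal(unname(mp), rep(1, 6))
  ## all-tied probabilities: AUROC 1/2 by the midrank convention
  mt <- classification_metrics(y, rep(0.4, 100))
  expect_equal(unname(mt["auroc"]), 0.5)
  ## one-class stratum: undefined quantities are NA, not zero
  m1 <- classification_metrics(rep("NT", 10), rep(0.1, 10))
  expect_true(is.na(m1["sensitivity"]))
  expect_true(is.na(m1["auroc"]))
  expect_equal(unname(m1["accuracy"]), 1)
  expect_error(classification_metrics(y, p[1:10]), "mismatch")
})

test_that("rank-statistic AUROC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(14)
  y <- sample(c("NT", "penumbra"), 300, replace = TRUE)
  p <- runif(300) + 0.3 * (y == "penumbra")
  ours <- classification_metrics(y, p)[["auroc"]]
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = factor(y, levels = c("NT", "penumbra")), predictor = p,
    quiet = TRUE, direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("McNemar exact branch reproduces the binomial tail sum", {
  y <- rep("penumbra", 20)
  ## b = 5 (A right, B wrong), c = 15
  pa <- c(rep("penumbra", 5), rep("NT", 15))
  pb <- c(rep("NT", 5), rep("penumbra", 15))
  res <- mcnemar_compare(pa, pb, y)
  expect_equal(res$b, 5); expect_equal(res$c, 15)
  expect_equal(res$method, "exact")
  expect_equal(res$p_value, 2 * sum(dbinom(0:5, 20, 0.5)), tolerance = 1e-12)
  expect_equal(round(res$p_value, 4), 0.0414)
  ## identical predictions
  same <- mcnemar_compare(pa, pa, y)
  expect_equal(same$p_value, 1.0)
  expect_true(same$degenerate)
})

test_that("McNemar exact test agrees with full enumeration for b + c <= 12", {
  for (b in 0:12) for (cc in 0:(12 - b)) {
    if (b + cc == 0) next
    n <- b + cc
    y <- rep("penumbra", n)
    pa <- c(rep("penumbra", b), rep("NT", cc))
    pb <- c(rep("NT", b), rep("penumbra", cc))
    res <- mcnemar_compare(pa, pb, y)
    ## oracle: enumerate all 2^n discordance splits under H0
    k <- 0:n
    prob_k <- choose(n, k) / 2^n
    p_oracle <- min(1, 2 * sum(prob_k[k <= min(b, cc)]))
    expect_equal(res$p_value, p_oracle, tolerance = 1e-12)
  }
})

test_that("McNemar large-sample branch matches the corrected chi-square", {
  y <- rep("penumbra", 60)
  pa <- c(rep("penumbra", 20), rep("NT", 40))
  pb <- c(rep("NT", 20), rep("penumbra", 10), rep("NT", 30))
  res <- mcnemar_compare(pa, pb, y)
  expect_equal(res$method, "chisq")
  oracle <- stats::mcnemar.test(table(factor(pa == y, c(FALSE, TRUE)),
                                      factor(pb == y, c(FALSE, TRUE))),
                                correct = TRUE)
  expect_equal(res$p_value, oracle$p.value, tolerance = 1e-12)
})

test_that("Dice and volume similarity capture overlap and volume", {
  d <- c(10, 10, 2)
  a <- array(FALSE, d); a[1:5, 1:10, 1] <- TRUE           # 50 voxels
  ident <- segmentation_agreement(a, a, c(1, 1, 1))
  expect_equal(ident$dsc, 1); expect_equal(ident$vs, 1)
  ## equal volumes, half overlap
  b <- array(FALSE, d); b[3:7, 1:10, 1] <- TRUE
  half <- segmentation_agreement(a, b, c(1, 1, 1))
  expect_equal(half$dsc, 30 / 50)
  expect_equal(half$vs, 1)
  ## disjoint equal-size masks: no overlap, same volume
  c2 <- array(FALSE, d); c2[6:10, 1:10, 2] <- TRUE
  disj <- segmentation_agreement(a, c2, c(1, 1, 1))
  expect_equal(disj$dsc, 0)
  expect_equal(disj$vs, 1)
  ## symmetry and the empty convention
  expect_equal(segmentation_agreement(b, a, c(1, 1, 1))$dsc, half$dsc)
  e <- array(FALSE, d)
  conv <- segmentation_agreement(e, e, c(1, 1, 1))
  expect_true(conv$empty)
  expect_equal(conv$dsc, 1); expect_equal(conv$vs, 1)
  expect_error(segmentation_agreement(a, array(FALSE, c(2, 2, 2)),
                                      c(1, 1, 1)), "mismatch")
})

test_that("volume agreement reports Pearson and Bland-Altman statistics", {
  pdm <- c(10, 20, 30, 40, 50)
  exact <- pv_agreement(pdm, pdm)
  expect_equal(exact$r, 1)
  expect_equal(exact$bias, 0)
  expect_equal(unname(exact$loa), c(0, 0))
  ## differences 1..5: bias 3, SD sqrt(2.5)
  ba <- pv_agreement(pdm + 1:5, pdm)
  expect_equal(ba$bias, 3)
  expect_equal(ba$sd, sqrt(2.5))
  expect_equal(unname(ba$loa),
               c(3 - 1.96 * sqrt(2.5), 3 + 1.96 * sqrt(2.5)))
  expect_equal(ba$bias_pct, 100 * 3 / 30)
  ## seeded sampling property: n = 16, recovered bias within 2 sigma/sqrt(n)
  set.seed(77)
  sigma <- 4
  pdm16 <- runif(16, 50, 150)
  ml16 <- pdm16 + rnorm(16, 0, sigma)
  samp <- pv_agreement(ml16, pdm16)
  expect_lt(abs(samp$bias), 2 * sigma / sqrt(16))
  expect_gt(samp$r, 0.9)
  expect_error(pv_agreement(1:2, 1:2), "at least 3")
  expect_true(pv_agreement(rep(1, 5), pdm)$degenerate)
})

test_that("permutation importance isolates the informative feature", {
  set.seed(101)
  n <- 600
  x1 <- ifelse(rep(c(TRUE, FALSE), each = n / 2), 1, -1) +
    rnorm(n, 0, 0.2)
  tab <- data.frame(x1 = x1, x2 = rnorm(n), x3 = rnorm(n),
                    label = factor(rep(c("penumbra", "NT"), each = n / 2),
                                   levels = c("NT", "penumbra")))
  fold <- list(test_rat = "r", train_idx = 1:n,
               inner_train_idx = seq(1, n, by = 2),
               inner_val_idx = seq(2, n, by = 2))
  m <- tune_and_fit_base("rf", tab, fold, c("x1", "x2", "x3"), budget = 1,
                         seed = 3)
  imp <- permutation_importance(m, tab, tab$label, n_repeats = 3, seed = 5)
  ## x1 drops to chance when permuted; x2/x3 carry no information
  expect_gt(imp[["x1"]], 0.4)
  expect_lt(abs(imp[["x2"]]), 0.05)
  expect_lt(abs(imp[["x3"]]), 0.05)
  expect_error(permutation_importance(m, tab, tab$label, n_repeats = 0),
               "n_repeats")
})

test_that("feature contrast reports class medians and paired tests", {
  tab <- toy_table(n_rats = 6L, n_per_class = 40L, shift = 2, seed = 19L)
  fc <- feature_contrast(tab, c("x1", "x2"))
  expect_equal(fc$feature, c("x1", "x2"))
  ## x1 is shifted upward in the penumbra class
  expect_gt(fc$penumbra_median[1], fc$nt_median[1])
  expect_equal(fc$pct_difference[1],
               100 * (fc$penumbra_median[1] - fc$nt_median[1]) /
                 fc$nt_median[1])
  expect_lt(fc$p_value[1], 0.01)
  expect_gt(fc$p_value[2], 0.05)
  ## median/IQR aggregation helper
  df <- data.frame(accuracy = c(0.7, 0.8, 0.9), sensitivity = c(NA, 1, 0.5),
                   specificity = 1, precision = 1, f1 = 1, auroc = 1)
  sm <- summarize_metrics(df)
  expect_equal(sm$median[sm$metric == "accuracy"], 0.8)
  expect_equal(sm$median[sm$metric == "sensitivity"], 0.75)
})
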