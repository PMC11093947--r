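## toy tables are cheap; models are fitted on two informative features
toy_features <- c("x1", "x2", "x3", "x4")

test_that("fold plan implements leave-one-rat-out with 1:1 balancing", {
  tab <- toy_table(n_rats = 4L, n_per_class = 50L)
  ## unbalance rat 2: drop penumbra rows so NT must be downsampled
  drop <- which(tab$rat_id == "rat02" & tab$label == "penumbra")[1:20]
  tab <- tab[-drop, ]
  plan <- make_folds(tab, seed = 3)
  expect_length(plan$folds, 4L)
  for (fold in plan$folds) {
    ## leakage guard: held-out rat contributes no training rows
    expect_length(intersect(tab$rat_id[fold$train_idx],
                            tab$rat_id[fold$test_idx]), 0L)
    expect_setequal(unique(tab$rat_id[fold$train_idx]),
                    setdiff(unique(tab$rat_id), fold$test_rat))
    ## 1:1 class balance per training rat
    for (r in names(fold$balance))
      expect_equal(fold$balance[[r]][["penumbra"]],
                   fold$balance[[r]][["NT"]])
    ## inner split is 70/30 of the balanced rows
    expect_equal(length(fold$inner_val_idx) / length(fold$train_idx), 0.3,
                 tolerance = 0.02)
    expect_length(intersect(fold$inner_train_idx, fold$inner_val_idx), 0L)
  }
  ## rat02 NT rows downsampled to its penumbra count in training folds
  expect_equal(unname(plan$folds$rat01$balance$rat02),
               unname(c(penumbra = 30L, NT = 30L)))
  ## same membership, different subsample under a different seed
  plan2 <- make_folds(tab, seed = 4)
  expect_identical(plan$folds$rat01$test_idx, plan2$folds$rat01$test_idx)
  expect_false(identical(plan$folds$rat01$train_idx,
                         plan2$folds$rat01$train_idx))
  expect_error(make_folds(tab[tab$rat_id %in% c("rat01", "rat02"), ]),
               "3 rats")
})

test_that("a rat without penumbra rows is capped at the median count", {
  tab <- toy_table(n_rats = 4L, n_per_class = 50L)
  tab <- tab[!(tab$rat_id == "rat03" & tab$label == "penumbra"), ]
  expect_warning(plan <- make_folds(tab, seed = 1), "no penumbra")
  expect_equal(plan$folds$rat01$balance$rat03[["NT"]], 50L)
  expect_equal(plan$folds$rat01$balance$rat03[["penumbra"]], 0L)
})

test_that("every base family learns a linearly separable problem", {
  tab <- toy_table(n_rats = 3L, n_per_class = 60L, shift = 6, seed = 13L)
  plan <- make_folds(tab, seed = 13)
  fold <- plan$folds[[1]]
  yva <- tab$label[fold$inner_val_idx]
  for (fam in penumbraDTI:::BASE_FAMILIES) {
    m <- tune_and_fit_base(fam, tab, fold, features = toy_features,
                           budget = 1, seed = 5)
    acc <- mean((predict_prob(m, tab[fold$inner_val_idx, ]) >= 0.5) ==
                  (yva == "penumbra"))
    expect_gte(acc, 0.97)
    ## probabilities stay in range and the class matches the threshold rule
    pr <- predict_penumbra(m, tab[fold$test_idx, ])
    expect_true(all(pr$prob >= 0 & pr$prob <= 1))
    expect_identical(pr$class == "penumbra", pr$prob >= 0.5)
  }
})

test_that("tuning is deterministic and improves with budget on hard data", {
  tab <- toy_table(n_rats = 3L, n_per_class = 40L, shift = 1, seed = 23L)
  plan <- make_folds(tab, seed = 23)
  fold <- plan$folds[[1]]
  m1 <- tune_and_fit_base("tree", tab, fold, toy_features, budget = 4,
                          seed = 9)
  m2 <- tune_and_fit_base("tree", tab, fold, toy_features, budget = 4,
                          seed = 9)
  expect_identical(attr(m1, "tuning")$accuracy, attr(m2, "tuning")$accuracy)
  expect_identical(m1$config, m2$config)
  tr <- attr(m1, "tuning")
  expect_length(tr$accuracy, 4L)
  expect_equal(tr$best, tr$configs[[which.max(tr$accuracy)]])
  expect_error(tune_and_fit_base("tree", tab, fold, toy_features,
                                 budget = 0), "budget")
  expect_error(tune_and_fit_base("ridge", tab, fold, toy_features),
               "family")
})

test_that("random forest outperforms a single tree in ensemble terms", {
  tab <- toy_table(n_rats = 3L, n_per_class = 80L, shift = 1.2, seed = 31L,
                   n_features = 4L)
  plan <- make_folds(tab, seed = 31)
  fold <- plan$folds[[1]]
  y <- tab$label[fold$train_idx]
  auc <- function(m) classification_metrics(
    y, predict_prob(m, tab[fold$train_idx, ]))[["auroc"]]
  rf <- tune_and_fit_base("rf", tab, fold, toy_features, budget = 1,
                          seed = 2)
  tree <- tune_and_fit_base("tree", tab, fold, toy_features, budget = 1,
                            seed = 2)
  expect_gte(auc(rf), auc(tree))
})

test_that("stacking reduces to its bases in degenerate settings", {
  tab <- toy_table(n_rats = 3L, n_per_class = 60L, shift = 6, seed = 41L)
  plan <- make_folds(tab, seed = 41)
  fold <- plan$folds[[1]]
  bases <- lapply(setNames(penumbraDTI:::BASE_FAMILIES,
                           penumbraDTI:::BASE_FAMILIES), function(fam)
    tune_and_fit_base(fam, tab, fold, toy_features, budget = 1, seed = 5))
  stack <- fit_stacking(bases, tab, fold, seed = 5)
  expect_false(stack$fallback)
  p <- predict_prob(stack, tab[fold$test_idx, ])
  expect_true(all(p >= 0 & p <= 1))
  ## all bases agree on separable data; the stack must agree with them
  pb <- predict_prob(bases$rf, tab[fold$test_idx, ])
  expect_gt(mean((p >= 0.5) == (pb >= 0.5)), 0.97)
})

test_that("stacking tracks a single perfect base among random ones", {
  set.seed(71)
  tab <- toy_table(n_rats = 3L, n_per_class = 80L, shift = 0, seed = 71L)
  ## x1 separates perfectly; x2..x4 are pure noise
  tab$x1 <- ifelse(tab$label == "penumbra", 1, -1) + rnorm(nrow(tab), 0, .1)
  plan <- make_folds(tab, seed = 71)
  fold <- plan$folds[[1]]
  perfect <- tune_and_fit_base("tree", tab, fold, "x1", budget = 1, seed = 1)
  noisy <- lapply(1:4, function(i)
    tune_and_fit_base("tree", tab, fold, c("x2", "x3", "x4"), budget = 1,
                      seed = i))
  ## schema note: stack predicts with each base's own feature subset
  bases <- c(list(perfect = perfect), setNames(noisy, paste0("n", 1:4)))
  stack <- fit_stacking(bases, tab, fold, seed = 3)
  y <- tab$label[fold$test_idx]
  acc_stack <- mean((predict_prob(stack, tab[fold$test_idx, ]) >= 0.5) ==
                      (y == "penumbra"))
  acc_perf <- mean((predict_prob(perfect, tab[fold$test_idx, ]) >= 0.5) ==
                     (y == "penumbra"))
  expect_gte(acc_stack, acc_perf - 0.02)
})

test_that("constant bases trigger the majority-vote fallback", {
  tab <- toy_table(n_rats = 3L, n_per_class = 30L, seed = 81L)
  plan <- make_folds(tab, seed = 81)
  fold <- plan$folds[[1]]
  ## trees on a constant feature never split: constant probabilities
  tab$xc <- 1
  const_base <- tune_and_fit_base("tree", tab, fold, "xc", budget = 1,
                                  seed = 1)
  p0 <- predict_prob(const_base, tab[1:5, ])
  expect_equal(diff(range(p0)), 0)
  bases <- list(a = const_base, b = const_base, c = const_base)
  stack <- fit_stacking(bases, tab, fold, seed = 1)
  expect_true(stack$fallback)
  expect_true(all(predict_prob(stack, tab[1:3, ]) %in% c(0, 1)))
})

test_that("prediction validates the feature schema", {
  tab <- toy_table(n_rats = 3L, n_per_class = 30L, seed = 91L)
  plan <- make_folds(tab, seed = 91)
  m <- tune_and_fit_base("tree", tab, plan$folds[[1]], toy_features,
                         budget = 1, seed = 1)
  bad <- tab[1:5, setdiff(names(tab), "x2")]
  expect_error(predict_prob(m, bad), "x2")
})

test_that("the full training loop is deterministic given the master seed", {
  tab <- toy_table(n_rats = 3L, n_per_class = 40L, shift = 2, seed = 97L)
  plan <- make_folds(tab, seed = 97)
  r1 <- train_cohort(tab, plan, features = toy_features, budget = 1,
                     seed = 55)
  r2 <- train_cohort(tab, plan, features = toy_features, budget = 1,
                     seed = 55)
  expect_identical(r1$predictions, r2$predictions)
  expect_setequal(names(r1$models[[1]]),
                  c(penumbraDTI:::BASE_FAMILIES, "stack"))
  ## training rows through their own model beat chance on balanced data
  fold <- plan$folds[[1]]
  y <- tab$label[fold$train_idx]
  p <- predict_prob(r1$models[[fold$test_rat]]$stack,
                    tab[fold$train_idx, ])
  expect_gt(mean((p >= 0.5) == (y == "penumbra")), 0.5)
})
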