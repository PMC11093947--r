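#' Leave-one-rat-out fold plan with class balancing
#'
#' One outer fold per rat: the held-out rat's voxels (both timepoints,
#' unbalanced) form the test set and every other rat contributes training
#' rows after its normal-tissue voxels are randomly downsampled to a 1:1
#' ratio with its penumbra voxels.  The pooled balanced training rows are
#' split 70/30 (stratified by class) into an inner training and validation
#' set for hyperparameter tuning.  Test rows are never balanced.
#'
#' @param table feature table from [extract_features()] (rows from all
#'   rats bound together).
#' @param seed RNG seed; fold membership is seed-independent, subsampling
#'   is not.
#' @param holdout inner validation fraction.
#' @param max_rows_per_rat optional cap on balanced rows contributed by
#'   each training rat (downsampled preserving the 1:1 ratio).
#' @return an object of class `fold_plan`.
#' @export
make_folds <- function(table, seed = 1L, holdout = 0.3,
                       max_rows_per_rat = Inf) {
  rats <- unique(table$rat_id)
  if (length(rats) < 3L) stopf("need at least 3 rats for leave-one-rat-out")
  pen_counts <- vapply(rats, function(r)
    sum(table$rat_id == r & table$label == "penumbra"), numeric(1))
  med_pen <- stats::median(pen_counts[pen_counts > 0])
  folds <- lapply(rats, function(test_rat) {
    fs <- child_seed(seed, "fold", test_rat)
    with_seed(fs, {
      train_rats <- setdiff(rats, test_rat)
      balance <- list()
      train_idx <- integer(0)
      for (r in train_rats) {
        ip <- which(table$rat_id == r & table$label == "penumbra")
        im <- which(table$rat_id == r & table$label == "NT")
        if (!length(ip)) {
          warning(sprintf("rat %s has no penumbra rows; capping its NT rows",
                          r), call. = FALSE)
          keep_n <- if (length(im)) sample(im, min(length(im), med_pen))
            else integer(0)
          keep_p <- integer(0)
        } else {
          m <- min(length(ip), length(im))
          keep_p <- if (length(ip) > m) sample(ip, m) else ip
          keep_n <- if (length(im) > m) sample(im, m) else im
          if (is.finite(max_rows_per_rat) &&
              length(keep_p) + length(keep_n) > max_rows_per_rat) {
            m2 <- max(1L, floor(max_rows_per_rat / 2))
            keep_p <- sample(keep_p, min(m2, length(keep_p)))
            keep_n <- sample(keep_n, min(m2, length(keep_n)))
          }
        }
        balance[[r]] <- c(penumbra = length(keep_p), NT = length(keep_n))
        train_idx <- c(train_idx, keep_p, keep_n)
      }
      train_idx <- sort(train_idx)
      val_idx <- sort(unlist(lapply(
        split(train_idx, as.character(table$label[train_idx])),
        function(ix) sample(ix, round(holdout * length(ix))))))
      list(test_rat = test_rat,
           test_idx = which(table$rat_id == test_rat),
           train_idx = train_idx,
           inner_train_idx = setdiff(train_idx, val_idx),
           inner_val_idx = val_idx,
           balance = balance, seed = fs)
    })
  })
  names(folds) <- rats
  structure(list(folds = folds, rats = rats, seed = seed,
                 holdout = holdout), class = "fold_plan")
}

BASE_FAMILIES <- c("mlp", "gam", "tree", "rf", "boost")

## hyperparameter search spaces (log-scaled where noted)
base_search_space <- function(family) {
  switch(family,
    mlp = list(size = list(lo = 8, hi = 64, int = TRUE, log = TRUE),
               decay = list(lo = 1e-4, hi = 1e-1, log = TRUE)),
    gam = list(k = list(lo = 4, hi = 12, int = TRUE)),
    tree = list(maxdepth = list(lo = 3, hi = 20, int = TRUE),
                minbucket = list(lo = 5, hi = 100, int = TRUE, log = TRUE)),
    rf = list(num_trees = list(lo = 100, hi = 500, int = TRUE),
              mtry_frac = list(lo = 0.1, hi = 0.8)),
    boost = list(nrounds = list(lo = 100, hi = 500, int = TRUE),
                 eta = list(lo = 0.01, hi = 0.3, log = TRUE),
                 max_depth = list(lo = 1, hi = 4, int = TRUE)),
    stopf("unknown base-model family '%s'", family))
}

space_default <- function(space) {
  lapply(space, function(p) {
    v <- if (isTRUE(p$log)) sqrt(p$lo * p$hi) else (p$lo + p$hi) / 2
    if (isTRUE(p$int)) round(v) else v
  })
}

space_sample <- function(space, n) {
  lapply(seq_len(n), function(i) lapply(space, function(p) {
    v <- if (isTRUE(p$log)) exp(runif(1, log(p$lo), log(p$hi)))
      else runif(1, p$lo, p$hi)
    if (isTRUE(p$int)) round(v) else v
  }))
}

fit_base_model <- function(family, config, X, y, seed) {
  set.seed(seed)
  ybin <- as.integer(y == "penumbra")
  model <- switch(family,
    mlp = {
      mu <- colMeans(X); sg <- apply(X, 2, sd); sg[sg <= 0] <- 1
      Z <- sweep(sweep(X, 2, mu), 2, sg, "/")
      fit <- nnet::nnet(x = Z, y = ybin, size = config$size,
                        decay = config$decay, maxit = 200, trace = FALSE,
                        MaxNWts = 20000)
      list(fit = fit, mu = mu, sg = sg)
    },
    gam = {
      df <- as.data.frame(X)
      df$.y <- ybin
      terms <- vapply(colnames(X), function(nm) {
        nu <- length(unique(X[, nm]))
        if (nu >= 4) sprintf("s(%s, k = %d)", nm, min(config$k, nu - 1L))
        else nm
      }, character(1))
      f <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
      fit <- mgcv::bam(f, family = stats::binomial(), data = df,
                       method = "fREML", discrete = TRUE)
      list(fit = fit)
    },
    tree = {
      df <- as.data.frame(X)
      df$.y <- factor(y, levels = c("NT", "penumbra"))
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = config$maxdepth,
                            minbucket = config$minbucket, cp = 1e-4))
      list(fit = fit)
    },
    rf = {
      df <- as.data.frame(X)
      df$.y <- factor(y, levels = c("NT", "penumbra"))
      fit <- ranger::ranger(.y ~ ., data = df, probability = TRUE,
                            num.trees = config$num_trees,
                            mtry = max(1L, round(config$mtry_frac * ncol(X))),
                            seed = seed, num.threads = 1)
      list(fit = fit)
    },
    boost = {
      dtrain <- xgboost::xgb.DMatrix(X, label = ybin, nthread = 1)
      fit <- xgboost::xgb.train(params = list(objective = "binary:logistic",
                                              eta = config$eta,
                                              max_depth = config$max_depth,
                                              nthread = 1),
                                data = dtrain, nrounds = config$nrounds,
                                verbose = 0)
      list(fit = fit)
    })
  structure(list(family = family, config = config, model = model,
                 features = colnames(X), seed = seed),
            class = "base_model")
}

#' Penumbra probability from a fitted model
#'
#' @param object a `base_model` or `stacked_model`.
#' @param newdata data.frame or matrix carrying the features used at fit
#'   time; column schema is validated.
#' @param ... unused.
#' @return numeric vector of penumbra probabilities in [0, 1].
#' @export
predict_prob <- function(object, newdata, ...) UseMethod("predict_prob")

check_schema <- function(features, newdata) {
  miss <- setdiff(features, colnames(newdata))
  if (length(miss)) stopf("newdata lacks fit-time features: %s",
                          paste(miss, collapse = ", "))
  as.matrix(as.data.frame(newdata)[, features, drop = FALSE])
}

#' @export
predict_prob.base_model <- function(object, newdata, ...) {
  X <- check_schema(object$features, newdata)
  m <- object$model
  p <- switch(object$family,
    mlp = {
      Z <- sweep(sweep(X, 2, m$mu), 2, m$sg, "/")
      as.vector(predict(m$fit, Z))
    },
    gam = as.vector(predict(m$fit, as.data.frame(X), type = "response")),
    tree = predict(m$fit, as.data.frame(X), type = "prob")[, "penumbra"],
    rf = predict(m$fit, as.data.frame(X),
                 num.threads = 1)$predictions[, "penumbra"],
    boost = predict(m$fit, xgboost::xgb.DMatrix(X, nthread = 1)))
  pmin(pmax(as.numeric(p), 0), 1)
}

#' Tune and fit one base model on a fold
#'
#' Hyperparameters are chosen to maximise inner-validation accuracy by
#' sequential model-based optimisation within the declared search space:
#' the default configuration and a few random ones are evaluated first,
#' then a random-forest surrogate proposes the remaining candidates by
#' upper-confidence-bound ranking (`method = "random"` gives a seeded
#' random search with the same budget).  The winning configuration is
#' refit on the full balanced outer-training set.
#'
#' @param family one of `r paste(BASE_FAMILIES, collapse = ", ")`.
#' @param table the feature table.
#' @param fold one element of `make_folds()$folds`.
#' @param features feature columns to use.
#' @param budget number of configurations evaluated (>= 1).
#' @param seed RNG seed.
#' @param method `"bayes"` or `"random"`.
#' @return a `base_model` with a `tuning` attribute (configurations and
#'   validation accuracies).
#' @export
tune_and_fit_base <- function(family, table, fold,
                              features = feature_names(), budget = 15L,
                              seed = 1L, method = c("bayes", "random")) {
  method <- match.arg(method)
  if (budget < 1L) stopf("tuning budget must be >= 1")
  space <- base_search_space(family)
  ytr <- as.character(table$label[fold$inner_train_idx])
  yva <- as.character(table$label[fold$inner_val_idx])
  if (length(unique(ytr)) < 2L || length(unique(yva)) < 2L)
    stopf("degenerate inner split: both classes required")
  Xtr <- as.matrix(table[fold$inner_train_idx, features, drop = FALSE])
  Xva <- table[fold$inner_val_idx, features, drop = FALSE]

  fseed <- child_seed(seed, "tune", family, fold$test_rat)
  with_seed(fseed, {
    configs <- list(space_default(space))
    if (budget > 1L) {
      n_init <- min(budget - 1L, 3L)
      configs <- c(configs, space_sample(space, n_init))
    }
    acc <- numeric(0)
    evaluate <- function(cfg, i) {
      m <- fit_base_model(family, cfg, Xtr, ytr,
                          seed = child_seed(fseed, "eval", i))
      mean((predict_prob(m, Xva) >= 0.5) == (yva == "penumbra"))
    }
    for (i in seq_along(configs)) acc[i] <- evaluate(configs[[i]], i)
    while (length(configs) < budget) {
      i <- length(configs) + 1L
      cand <- space_sample(space, 64L)
      cfg <- if (method == "bayes" && length(configs) >= 4L) {
        enc <- function(cfgs) do.call(rbind, lapply(cfgs, function(cc)
          unlist(cc)))
        sur_df <- data.frame(enc(configs), .acc = acc)
        sur <- ranger::ranger(.acc ~ ., data = sur_df, num.trees = 100,
                              seed = i, num.threads = 1)
        pr <- predict(sur, data.frame(enc(cand)), predict.all = TRUE,
                      num.threads = 1)$predictions
        ucb <- rowMeans(pr) + apply(pr, 1, sd)
        cand[[which.max(ucb)]]
      } else cand[[1L]]
      configs[[i]] <- cfg
      acc[i] <- evaluate(cfg, i)
    }
    best <- configs[[which.max(acc)]]
    ytrain <- as.character(table$label[fold$train_idx])
    Xtrain <- as.matrix(table[fold$train_idx, features, drop = FALSE])
    final <- fit_base_model(family, best, Xtrain, ytrain,
                            seed = child_seed(fseed, "final"))
    attr(final, "tuning") <- list(configs = configs, accuracy = acc,
                                  best = best)
    final
  })
}

#' Stack five base models with a regularised logistic meta-learner
#'
#' Meta-features are the base models' penumbra probabilities on the inner
#' validation rows (rows none of the bases saw when originally fitted for
#' tuning; the refit on the full balanced set does see them, a standard
#' stacked-generalisation compromise recorded in the package vignette).
#' The meta-learner is a ridge logistic regression; if all base
#' probabilities are constant it falls back to a flagged majority vote.
#'
#' @param bases named list of 5 fitted `base_model`s.
#' @param table feature table.
#' @param fold the fold the bases were fitted on.
#' @param seed RNG seed (meta cross-validation folds).
#' @return an object of class `stacked_model`.
#' @export
fit_stacking <- function(bases, table, fold, seed = 1L) {
  if (length(bases) < 2L) stopf("stacking needs several base models")
  rows <- table[fold$inner_val_idx, , drop = FALSE]
  meta_X <- vapply(bases, function(b) predict_prob(b, rows),
                   numeric(nrow(rows)))
  y <- factor(as.character(rows$label), levels = c("NT", "penumbra"))
  fallback <- all(apply(meta_X, 2, function(x) diff(range(x)) < 1e-12))
  meta <- if (fallback) NULL else
    with_seed(child_seed(seed, "stack", fold$test_rat), {
      cv <- glmnet::cv.glmnet(meta_X, y, family = "binomial", alpha = 0,
                              nfolds = 5, standardize = FALSE)
      list(fit = cv$glmnet.fit, lambda = cv$lambda.min)
    })
  structure(list(bases = bases, meta = meta, fallback = fallback,
                 features = bases[[1]]$features, seed = seed),
            class = "stacked_model")
}

#' @export
predict_prob.stacked_model <- function(object, newdata, ...) {
  meta_X <- vapply(object$bases, function(b) predict_prob(b, newdata),
                   numeric(nrow(newdata)))
  if (is.null(dim(meta_X))) meta_X <- matrix(meta_X, nrow = 1)
  if (object$fallback) return(rowMeans(meta_X >= 0.5))
  as.numeric(predict(object$meta$fit, meta_X, s = object$meta$lambda,
                     type = "response"))
}

#' Class + probability prediction
#'
#' @param model a fitted `base_model` or `stacked_model`.
#' @param newdata feature rows.
#' @param threshold probability cutoff for the penumbra class.
#' @return data.frame with `prob` and `class` columns.
#' @export
predict_penumbra <- function(model, newdata, threshold = 0.5) {
  p <- predict_prob(model, newdata)
  data.frame(prob = p,
             class = factor(ifelse(p >= threshold, "penumbra", "NT"),
                            levels = c("NT", "penumbra")))
}

#' Train all models across the leave-one-rat-out folds
#'
#' For every fold, tunes and fits the five base families, stacks them, and
#' predicts on the held-out rat.  Returns per-fold fitted models and a
#' long prediction table.
#'
#' @param table feature table.
#' @param plan a [make_folds()] plan.
#' @param features feature columns used for modelling.
#' @param budget tuning budget per model per fold.
#' @param seed master seed.
#' @param method tuning method, see [tune_and_fit_base()].
#' @return an object of class `loro_run`: `models` (per fold: five bases +
#'   `stack`), `predictions` (rat, timepoint, voxel, label, one
#'   probability column per model), `plan`.
#' @export
train_cohort <- function(table, plan, features = feature_names(),
                         budget = 15L, seed = 1L,
                         method = c("bayes", "random")) {
  method <- match.arg(method)
  models <- list()
  preds <- list()
  for (fold in plan$folds) {
    stopifnot(length(intersect(table$rat_id[fold$train_idx],
                               table$rat_id[fold$test_idx])) == 0L)
    bases <- lapply(setNames(BASE_FAMILIES, BASE_FAMILIES), function(fam)
      tune_and_fit_base(fam, table, fold, features, budget, seed, method))
    stack <- fit_stacking(bases, table, fold, seed)
    models[[fold$test_rat]] <- c(bases, list(stack = stack))
    test <- table[fold$test_idx, , drop = FALSE]
    pr <- data.frame(rat_id = test$rat_id, timepoint = test$timepoint,
                     voxel = test$voxel, label = test$label)
    for (nm in names(models[[fold$test_rat]]))
      pr[[paste0("prob_", nm)]] <-
        predict_prob(models[[fold$test_rat]][[nm]], test)
    preds[[fold$test_rat]] <- pr
  }
  structure(list(models = models,
                 predictions = do.call(rbind, c(preds, make.row.names = FALSE)),
                 plan = plan, features = features, budget = budget,
                 seed = seed),
            class = "loro_run")
}
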