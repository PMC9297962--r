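# Supervised-learning layer: feature selection, hyperparameter tuning,
# assembly-model classification, parameter regression with quantile
# prediction intervals, cross-validation, posterior predictive checks.

.param_cols <- c("model", "J", "alpha", "m", "nu", "s_E", "Lambda")

# statistic columns usable as features: present in the table and finite in
# every row (axis-masked columns are all-NA and sporadically undefined
# statistics are excluded rather than imputed)
.feature_cols <- function(table) {
  cand <- intersect(summary_stat_names(), names(table))
  cand[vapply(cand, function(cn) all(is.finite(table[[cn]])), logical(1))]
}

.check_obs <- function(obs, features) {
  v <- as.numeric(obs[features])
  if (anyNA(v) || any(!is.finite(v)))
    stop("observation is missing (masked) values for trained features: ",
         paste(features[!is.finite(v)], collapse = ", "),
         "; train and predict masks must match", call. = FALSE)
  setNames(v, features)
}

#' Boruta-style feature selection
#'
#' Every feature gets a shadow copy (its values permuted across rows); a
#' random forest is fit on features plus shadows, and a feature scores a
#' "hit" in an iteration when its importance exceeds the maximum shadow
#' importance. After each iteration the hit count is compared against a
#' Binomial(iterations, 0.5) null with a two-sided test at `alpha`:
#' significantly-many hits confirms the feature, significantly-few rejects
#' it. Undecided features at the iteration cap are kept (conservative).
#' Constant features are always dropped.
#'
#' @param table Training table (parameter columns + statistic columns).
#' @param target Column to predict (`"model"` for classification, or a
#'   parameter name for regression).
#' @param seed Integer seed.
#' @param max_iter Iteration cap (<= 100 recommended).
#' @param alpha Significance level of the binomial test.
#' @param num_trees Trees per forest iteration.
#' @return Character vector of retained feature names.
#' @export
boruta_select <- function(table, target, seed = 1, max_iter = 50,
                          alpha = 0.05, num_trees = 200) {
  feats <- .feature_cols(table)
  # constant features are uninformative by definition
  feats <- feats[vapply(feats, function(cn) var(table[[cn]]) > 0,
                        logical(1))]
  if (length(feats) == 0L)
    stop("no usable (non-constant) features in the table", call. = FALSE)
  if (nrow(table) < 10L)
    stop("too few rows for feature selection", call. = FALSE)
  set.seed(seed)
  y <- table[[target]]
  classification <- is.character(y) || is.factor(y)
  if (classification) y <- factor(y)
  X <- as.data.frame(table[feats])
  undecided <- feats
  confirmed <- character(0)
  hits <- setNames(integer(length(feats)), feats)
  iters <- setNames(integer(length(feats)), feats)
  for (it in seq_len(max_iter)) {
    if (length(undecided) == 0L) break
    active <- union(confirmed, undecided)
    Xa <- X[active]
    shadow <- as.data.frame(lapply(Xa, sample))
    names(shadow) <- paste0(".shadow_", names(Xa))
    d <- cbind(Xa, shadow, .y = y)
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = d,
      num.trees = num_trees, importance = "impurity",
      probability = FALSE, num.threads = 1,
      seed = sample.int(.Machine$integer.max, 1))
    imp <- fit$variable.importance
    shadow_max <- max(imp[grepl("^\\.shadow_", names(imp))])
    hit_now <- names(Xa)[imp[names(Xa)] > shadow_max]
    hits[intersect(hit_now, names(hits))] <-
      hits[intersect(hit_now, names(hits))] + 1L
    iters[active] <- iters[active] + 1L
    if (it >= 5L) {
      for (f in undecided) {
        pv <- binom.test(hits[[f]], iters[[f]], 0.5)$p.value
        if (pv < alpha) {
          if (hits[[f]] > iters[[f]] / 2) {
            confirmed <- c(confirmed, f)
          }
          undecided <- setdiff(undecided, f)
        }
      }
    }
  }
  retained <- union(confirmed, undecided)  # undecided kept, conservative
  if (length(retained) == 0L)
    stop("all features rejected; review the prior ranges and the summary ",
         "statistics supplied", call. = FALSE)
  feats[feats %in% retained]
}

# random draw from the documented hyperparameter priors
.draw_hyper <- function() {
  list(num.trees = sample(100:1000, 1L),
       max.depth = sample(2:32, 1L),
       mtry_frac = sample(seq(0.1, 1, by = 0.1), 1L))
}

.fit_ranger <- function(X, y, hyper, task, quantreg = FALSE, seed = 1) {
  d <- cbind(X, .y = y)
  ranger::ranger(
    dependent.variable.name = ".y", data = d,
    num.trees = hyper$num.trees,
    max.depth = hyper$max.depth,
    mtry = max(1L, floor(hyper$mtry_frac * ncol(X))),
    probability = (task == "classify"),
    quantreg = quantreg,
    keep.inbag = quantreg,
    num.threads = 1, seed = seed)
}

.fit_xgboost <- function(X, y, hyper, task, seed = 1) {
  if (!requireNamespace("xgboost", quietly = TRUE))
    stop("xgboost is not installed", call. = FALSE)
  if (task == "classify") {
    lev <- levels(y)
    xgboost::xgboost(
      data = as.matrix(X), label = as.integer(y) - 1L,
      objective = "multi:softprob", num_class = length(lev),
      nrounds = min(200L, hyper$num.trees),
      max_depth = min(10L, hyper$max.depth),
      colsample_bytree = hyper$mtry_frac,
      verbose = 0, nthread = 1)
  } else {
    xgboost::xgboost(
      data = as.matrix(X), label = y,
      objective = "reg:squarederror",
      nrounds = min(200L, hyper$num.trees),
      max_depth = min(10L, hyper$max.depth),
      colsample_bytree = hyper$mtry_frac,
      verbose = 0, nthread = 1)
  }
}

.algo_check <- function(algorithm) {
  algorithm <- match.arg(algorithm,
                         c("random_forest", "gradient_boosting", "adaboost"))
  if (algorithm == "adaboost")
    stop("adaboost is not available in this build; use random_forest or ",
         "gradient_boosting", call. = FALSE)
  algorithm
}

# K folds, stratified by class when y is a factor
.make_folds <- function(y, K) {
  n <- length(y)
  if (K > n) stop("K exceeds the number of rows", call. = FALSE)
  fold <- integer(n)
  if (is.factor(y)) {
    for (lv in levels(y)) {
      idx <- which(y == lv)
      fold[idx] <- sample(rep_len(seq_len(K), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(K), n))
  }
  fold
}

#' Random-search hyperparameter tuning
#'
#' Draws `n_draws` hyperparameter configurations (trees 100-1000, depth
#' 2-32, features-per-split fraction 0.1-1) and scores each by K-fold
#' cross-validation (classification accuracy or regression R^2); the best
#' draw is returned.
#'
#' @param table Training table.
#' @param target Target column (`"model"` or a parameter).
#' @param n_draws Number of random configurations.
#' @param K CV folds.
#' @param algorithm `"random_forest"` or `"gradient_boosting"`.
#' @param features Optional retained feature list (default: all usable).
#' @param seed Integer seed.
#' @return List with `best` (hyperparameter list), `score`, and the full
#'   `draws` data.frame.
#' @export
tune_hyperparameters <- function(table, target = "model", n_draws = 10,
                                 K = 5, algorithm = "random_forest",
                                 features = NULL, seed = 1) {
  algorithm <- .algo_check(algorithm)
  set.seed(seed)
  if (is.null(features)) features <- .feature_cols(table)
  y <- table[[target]]
  task <- if (is.character(y) || is.factor(y)) "classify" else "regress"
  if (task == "classify") y <- factor(y)
  X <- as.data.frame(table[features])
  draws <- vector("list", n_draws)
  scores <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    h <- .draw_hyper()
    fold <- .make_folds(y, K)
    sc <- numeric(K)
    for (k in seq_len(K)) {
      tr <- fold != k
      fit <- if (algorithm == "random_forest")
        .fit_ranger(X[tr, , drop = FALSE], y[tr], h, task,
                    seed = sample.int(.Machine$integer.max, 1))
      else .fit_xgboost(X[tr, , drop = FALSE], y[tr], h, task)
      pred <- .predict_any(fit, algorithm, X[!tr, , drop = FALSE], task,
                           levels(y))
      sc[k] <- if (task == "classify") {
        mean(pred$class == y[!tr])
      } else {
        1 - sum((y[!tr] - pred$value)^2) / sum((y[!tr] - mean(y[tr]))^2)
      }
    }
    draws[[i]] <- h
    scores[i] <- mean(sc)
  }
  best <- which.max(scores)
  list(best = draws[[best]], score = scores[best],
       draws = cbind(do.call(rbind.data.frame, draws), score = scores))
}

.predict_any <- function(fit, algorithm, X, task, class_levels = NULL) {
  if (algorithm == "random_forest") {
    p <- predict(fit, data = X, num.threads = 1)$predictions
    if (task == "classify") {
      cls <- class_levels[max.col(p[, class_levels, drop = FALSE])]
      list(prob = p[, class_levels, drop = FALSE], class = cls)
    } else {
      list(value = p)
    }
  } else {
    p <- predict(fit, as.matrix(X))
    if (task == "classify") {
      pm <- matrix(p, ncol = length(class_levels), byrow = TRUE)
      colnames(pm) <- class_levels
      list(prob = pm, class = class_levels[max.col(pm)])
    } else {
      list(value = p)
    }
  }
}

#' Train an assembly-model classifier
#'
#' Fits an ensemble classifier with the summary statistics as features and
#' the community assembly model class (neutral / filtering / competition)
#' as the target.
#'
#' @param table Training table with a `model` column and statistic columns.
#' @param seed Integer seed.
#' @param algorithm `"random_forest"` (default) or `"gradient_boosting"`.
#' @param features Optional retained feature list (e.g. from
#'   [boruta_select()]).
#' @param hyper Optional hyperparameter list (from
#'   [tune_hyperparameters()]); defaults to 500 trees, unlimited depth,
#'   sqrt-mtry.
#' @return An object of class `assemblage_fit`.
#' @export
train_classifier <- function(table, seed = 1, algorithm = "random_forest",
                             features = NULL, hyper = NULL) {
  algorithm <- .algo_check(algorithm)
  set.seed(seed)
  if (is.null(features)) features <- .feature_cols(table)
  if (length(features) == 0L) stop("no usable features", call. = FALSE)
  y <- factor(table$model)
  if (nlevels(y) < 2L)
    stop("need at least two model classes to classify", call. = FALSE)
  if (is.null(hyper))
    hyper <- list(num.trees = 500L, max.depth = 0L,
                  mtry_frac = sqrt(length(features)) / length(features))
  X <- as.data.frame(table[features])
  fit <- if (algorithm == "random_forest")
    .fit_ranger(X, y, hyper, "classify", seed = seed)
  else .fit_xgboost(X, y, hyper, "classify", seed = seed)
  structure(list(task = "classify", algorithm = algorithm, model = fit,
                 features = features, hyper = hyper, classes = levels(y),
                 mask = features, seed = seed),
            class = "assemblage_fit")
}

#' @export
print.assemblage_fit <- function(x, ...) {
  cat("assemblage", x$task, "fit (", x$algorithm, "),",
      length(x$features), "features\n")
  if (x$task == "classify") cat("  classes:",
                                paste(x$classes, collapse = ", "), "\n")
  else cat("  targets:", paste(x$targets, collapse = ", "), "\n")
  invisible(x)
}

#' Predict the assembly model for an observed community
#'
#' @param fit A classifier from [train_classifier()].
#' @param obs A `summary_vector` (or named numeric) whose availability mask
#'   covers the trained features; masked features raise an error.
#' @return List of class `assemblage_prediction` with `class_probs`
#'   (summing to 1) and `best_class`.
#' @export
predict_assembly_model <- function(fit, obs) {
  stopifnot(inherits(fit, "assemblage_fit"), fit$task == "classify")
  v <- .check_obs(obs, fit$features)
  X <- as.data.frame(as.list(v))
  names(X) <- fit$features
  pr <- .predict_any(fit$model, fit$algorithm, X, "classify", fit$classes)
  probs <- drop(pr$prob)
  probs <- probs / sum(probs)
  structure(list(class_probs = probs,
                 best_class = names(probs)[which.max(probs)]),
            class = "assemblage_prediction")
}

#' Train a parameter regressor with quantile prediction intervals
#'
#' Fits one quantile-regression forest per target parameter on a training
#' table restricted to a single assembly-model class (the best class from
#' classification). Point estimates are the ensemble mean; prediction
#' intervals come from the per-tree conditional quantiles.
#'
#' @param table Training table restricted to one model class.
#' @param targets Character vector of parameter columns to regress.
#' @param seed Integer seed.
#' @param algorithm `"random_forest"` (default; the only algorithm with
#'   quantile intervals) or `"gradient_boosting"` (point estimates only).
#' @param features,hyper As in [train_classifier()].
#' @return An `assemblage_fit` with one sub-model per target.
#' @export
train_regressor <- function(table, targets, seed = 1,
                            algorithm = "random_forest", features = NULL,
                            hyper = NULL) {
  algorithm <- .algo_check(algorithm)
  set.seed(seed)
  if (length(unique(table$model)) > 1L)
    warning("training table contains multiple model classes; ",
            "regression is normally run on the best class only")
  missing_t <- setdiff(targets, names(table))
  if (length(missing_t) > 0L)
    stop("target(s) absent from table: ",
         paste(missing_t, collapse = ", "), call. = FALSE)
  if (is.null(features)) features <- .feature_cols(table)
  if (is.null(hyper))
    hyper <- list(num.trees = 500L, max.depth = 0L,
                  mtry_frac = max(1 / length(features), 1 / 3))
  X <- as.data.frame(table[features])
  fits <- lapply(targets, function(tg) {
    y <- as.numeric(table[[tg]])
    if (algorithm == "random_forest")
      .fit_ranger(X, y, hyper, "regress", quantreg = TRUE, seed = seed)
    else .fit_xgboost(X, y, hyper, "regress", seed = seed)
  })
  names(fits) <- targets
  structure(list(task = "regress", algorithm = algorithm, model = fits,
                 features = features, hyper = hyper, targets = targets,
                 seed = seed),
            class = "assemblage_fit")
}

#' Estimate parameters for an observed community
#'
#' @param fit A regressor from [train_regressor()].
#' @param obs A `summary_vector` covering the trained features.
#' @param level Prediction-interval coverage (default 0.95, i.e. the
#'   2.5 and 97.5 percent conditional quantiles).
#' @return data.frame `parameter, estimate, lower, upper` (PI bounds are
#'   `NA` for gradient boosting).
#' @export
estimate_parameters <- function(fit, obs, level = 0.95) {
  stopifnot(inherits(fit, "assemblage_fit"), fit$task == "regress")
  v <- .check_obs(obs, fit$features)
  X <- as.data.frame(as.list(v))
  names(X) <- fit$features
  a <- (1 - level) / 2
  rows <- lapply(fit$targets, function(tg) {
    mod <- fit$model[[tg]]
    if (fit$algorithm == "random_forest") {
      pt <- predict(mod, data = X, type = "response",
                    num.threads = 1)$predictions
      qs <- predict(mod, data = X, type = "quantiles",
                    quantiles = c(a, 1 - a), num.threads = 1)$predictions
      lo <- min(qs[1], pt); hi <- max(qs[2], pt)
    } else {
      pt <- predict(mod, as.matrix(X))
      lo <- NA_real_; hi <- NA_real_
    }
    data.frame(parameter = tg, estimate = as.numeric(pt),
               lower = as.numeric(lo), upper = as.numeric(hi))
  })
  do.call(rbind, rows)
}

#' K-fold cross-validation report
#'
#' Classification: row-normalized confusion matrix, per-class precision and
#' recall, and the mean misclassification rate over held-out folds.
#' Regression: per-target R^2 (coefficient of determination) and explained
#' variance on pooled held-out predictions.
#'
#' @param table Training table.
#' @param task `"classify"` or `"regress"`.
#' @param targets Parameter columns (regression only).
#' @param K Number of folds (default 5).
#' @param seed Integer seed.
#' @param algorithm,features,hyper As elsewhere.
#' @return A list report (class `assemblage_cv`).
#' @export
cross_validate <- function(table, task = c("classify", "regress"),
                           targets = NULL, K = 5, seed = 1,
                           algorithm = "random_forest", features = NULL,
                           hyper = NULL) {
  task <- match.arg(task)
  algorithm <- .algo_check(algorithm)
  set.seed(seed)
  if (is.null(features)) features <- .feature_cols(table)
  X <- as.data.frame(table[features])
  if (task == "classify") {
    y <- factor(table$model)
    if (is.null(hyper))
      hyper <- list(num.trees = 500L, max.depth = 0L,
                    mtry_frac = sqrt(length(features)) / length(features))
    fold <- .make_folds(y, K)
    pred <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
    for (k in seq_len(K)) {
      tr <- fold != k
      fit <- if (algorithm == "random_forest")
        .fit_ranger(X[tr, , drop = FALSE], y[tr], hyper, "classify",
                    seed = sample.int(.Machine$integer.max, 1))
      else .fit_xgboost(X[tr, , drop = FALSE], y[tr], hyper, "classify")
      pred[!tr] <- .predict_any(fit, algorithm, X[!tr, , drop = FALSE],
                                "classify", levels(y))$class
    }
    cm <- table(truth = y, predicted = pred)
    cm_norm <- sweep(cm, 1, pmax(rowSums(cm), 1), "/")
    precision <- diag(cm) / pmax(colSums(cm), 1)
    recall <- diag(cm) / pmax(rowSums(cm), 1)
    structure(list(task = "classify", confusion = cm_norm,
                   counts = cm, precision = precision, recall = recall,
                   error_rate = mean(pred != y),
                   per_class_error = 1 - recall),
              class = "assemblage_cv")
  } else {
    if (is.null(targets)) stop("targets required for regression",
                               call. = FALSE)
    if (is.null(hyper))
      hyper <- list(num.trees = 500L, max.depth = 0L,
                    mtry_frac = max(1 / length(features), 1 / 3))
    fold <- .make_folds(numeric(nrow(table)), K)
    r2 <- ev <- setNames(numeric(length(targets)), targets)
    for (tg in targets) {
      y <- as.numeric(table[[tg]])
      pred <- numeric(length(y))
      for (k in seq_len(K)) {
        tr <- fold != k
        fit <- if (algorithm == "random_forest")
          .fit_ranger(X[tr, , drop = FALSE], y[tr], hyper, "regress",
                      seed = sample.int(.Machine$integer.max, 1))
        else .fit_xgboost(X[tr, , drop = FALSE], y[tr], hyper, "regress")
        pred[!tr] <- .predict_any(fit, algorithm,
                                  X[!tr, , drop = FALSE], "regress")$value
      }
      r2[tg] <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
      ev[tg] <- 1 - var(y - pred) / var(y)
    }
    structure(list(task = "regress", r2 = r2, explained_variance = ev),
              class = "assemblage_cv")
  }
}

#' @export
print.assemblage_cv <- function(x, ...) {
  if (x$task == "classify") {
    cat("CV misclassification rate:", round(x$error_rate, 3), "\n")
    print(round(x$confusion, 3))
  } else {
    cat("CV R^2:\n"); print(round(x$r2, 3))
  }
  invisible(x)
}

#' Posterior predictive check
#'
#' Simulates `n_sims` communities at the point estimates, fits a
#' centered+scaled PCA to the simulated summary statistics, projects the
#' observation, and reports its coordinates in the first two components
#' plus the percentile of its Euclidean distance (in the PC1-PC2 plane)
#' from the simulated centroid relative to the simulated points: values
#' near 1 flag an observation the fitted model does not reproduce.
#'
#' @param obs Observed `summary_vector`.
#' @param best_params Named list of parameter point estimates (must include
#'   `model`; other entries override [pipeline_priors()] defaults as fixed
#'   values).
#' @param n_sims Number of posterior predictive simulations.
#' @param seed Integer seed.
#' @param simulator Function `(theta, seed) -> summary_vector` (defaults to
#'   the package pipeline simulator); simulation failures are counted and
#'   more than 50 percent failures aborts.
#' @param ... Passed to the default simulator (e.g. `sampling`,
#'   `meta_params`).
#' @return List of class `assemblage_pps`: `pc_obs`, `percentile`,
#'   `n_failed`, `scores` (simulated PC coordinates).
#' @export
posterior_predictive_check <- function(obs, best_params, n_sims = 100,
                                       seed = 1, simulator = NULL, ...) {
  set.seed(seed)
  if (is.null(simulator))
    simulator <- function(theta, seed) .pps_default_sim(theta, seed, ...)
  sims <- vector("list", n_sims)
  nfail <- 0L
  for (i in seq_len(n_sims)) {
    s <- tryCatch(simulator(best_params,
                            seed = sample.int(2^31 - 2, 1)),
                  error = function(e) NULL)
    if (is.null(s)) nfail <- nfail + 1L else sims[[i]] <- s
  }
  if (nfail > n_sims / 2)
    stop("more than half of the posterior predictive simulations failed (",
         nfail, "/", n_sims, ")", call. = FALSE)
  sims <- sims[!vapply(sims, is.null, logical(1))]
  M <- do.call(rbind, lapply(sims, function(s) as.numeric(s)))
  colnames(M) <- summary_stat_names()
  keep <- colnames(M)[apply(M, 2, function(cc)
    all(is.finite(cc)) && var(cc) > 0)]
  keep <- keep[is.finite(as.numeric(obs[keep]))]
  if (length(keep) < 2L)
    stop("not enough informative statistics for the PPS projection",
         call. = FALSE)
  pca <- prcomp(M[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  sc <- pca$x[, 1:2, drop = FALSE]
  nd <- as.data.frame(as.list(setNames(as.numeric(obs[keep]), keep)))
  obs_sc <- predict(pca, newdata = nd)[, 1:2]
  d_sims <- sqrt(rowSums(sc^2))
  d_obs <- sqrt(sum(obs_sc^2))
  structure(list(pc_obs = obs_sc,
                 percentile = mean(d_sims <= d_obs),
                 n_failed = nfail,
                 scores = sc),
            class = "assemblage_pps")
}

#' @export
print.assemblage_pps <- function(x, ...) {
  cat("Posterior predictive check: observation at PC (",
      round(x$pc_obs[1], 2), ",", round(x$pc_obs[2], 2),
      "), distance percentile", round(x$percentile, 3),
      "(", x$n_failed, "failed sims )\n")
  invisible(x)
}
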