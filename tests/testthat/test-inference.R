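# synthetic regression/classification problems with known structure; the
# simulator never enters these tests

make_reg_table <- function(n = 300, seed = 1, noise = 0.5) {
  set.seed(seed)
  x1 <- runif(n, -2, 2)
  tab <- data.frame(model = "neutral", J = 1000, alpha = 100, m = 0.01,
                    nu = 0, s_E = 1, Lambda = runif(n))
  stats <- matrix(rnorm(n * length(summary_stat_names())), nrow = n)
  colnames(stats) <- summary_stat_names()
  stats[, "S"] <- x1
  tab <- cbind(tab, as.data.frame(stats))
  tab$Lambda <- sin(x1) + rnorm(n, 0, noise)
  tab
}

test_that("Boruta keeps the informative feature and drops noise", {
  set.seed(51)
  n <- 300
  tab <- data.frame(model = rep(c("neutral", "filtering"), each = n / 2))
  stats <- matrix(rnorm(n * length(summary_stat_names())), nrow = n)
  colnames(stats) <- summary_stat_names()
  stats[, "S"] <- ifelse(tab$model == "neutral", 1, -1) + rnorm(n, 0, 0.3)
  stats[, "GD1"] <- 3  # invariant statistic
  tab <- cbind(tab, as.data.frame(stats))
  kept <- boruta_select(tab, "model", seed = 52)
  expect_true("S" %in% kept)
  expect_false("GD1" %in% kept)
  noise_feats <- setdiff(summary_stat_names(), c("S", "GD1"))
  expect_lte(length(intersect(kept, noise_feats)),
             ceiling(length(noise_feats) * 0.2))
  expect_identical(kept, boruta_select(tab, "model", seed = 52))
})

test_that("Boruta rejects degenerate inputs loudly", {
  tab <- data.frame(model = rep(c("a", "b"), 3))
  stats <- matrix(1, nrow = 6, ncol = length(summary_stat_names()))
  colnames(stats) <- summary_stat_names()
  tab <- cbind(tab, as.data.frame(stats))
  expect_error(boruta_select(tab, "model"), "non-constant|few rows")
})

test_that("random search tuning returns reproducible, sane configurations", {
  tab <- synthetic_table(n_per_class = 40)
  t1 <- tune_hyperparameters(tab, "model", n_draws = 1, seed = 53)
  expect_true(t1$best$num.trees >= 100 && t1$best$num.trees <= 1000)
  expect_true(t1$best$max.depth >= 2 && t1$best$max.depth <= 32)
  expect_identical(nrow(t1$draws), 1L)
  t2 <- tune_hyperparameters(tab, "model", n_draws = 1, seed = 53)
  expect_identical(t1$best, t2$best)
  expect_error(tune_hyperparameters(tab, "model", algorithm = "adaboost"),
               "adaboost")
})

test_that("classification reaches zero error under separability and chance under permutation", {
  tab <- synthetic_table(n_per_class = 60, noise = 0.1, seed = 54)
  cv <- cross_validate(tab, "classify", seed = 55)
  expect_lt(cv$error_rate, 0.05)
  expect_equal(unname(rowSums(cv$confusion)), rep(1, 3))

  perm <- tab
  set.seed(56)
  perm$model <- sample(perm$model)
  cvp <- cross_validate(perm, "classify", seed = 57)
  expect_equal(cvp$error_rate, 2 / 3, tolerance = 0.12)

  fit <- train_classifier(tab, seed = 58)
  pred <- predict_assembly_model(fit, tab[1, , drop = FALSE][, -(1:7)])
  expect_equal(sum(pred$class_probs), 1, tolerance = 1e-9)
  expect_true(pred$best_class %in% c("neutral", "filtering", "competition"))
})

test_that("prediction honours the training mask", {
  tab <- synthetic_table(n_per_class = 40, seed = 59)
  fit <- train_classifier(tab, seed = 60)
  obs <- setNames(rep(NA_real_, length(summary_stat_names())),
                  summary_stat_names())
  expect_error(predict_assembly_model(fit, obs), "mask")
})

test_that("regression recovers a duplicated target and orders PI bounds", {
  tab <- make_reg_table(seed = 61, noise = 0)
  tab$S <- tab$Lambda  # feature == target, noiseless
  # every split may use the duplicated feature: the forest should localize
  # the target almost perfectly and its conditional quantiles collapse
  hyper <- list(num.trees = 500L, max.depth = 0L, mtry_frac = 1)
  fit <- train_regressor(tab, targets = "Lambda", seed = 62,
                         features = "S", hyper = hyper)
  i_mid <- order(abs(tab$Lambda - median(tab$Lambda)))[1]
  est <- estimate_parameters(fit, tab[i_mid, , drop = FALSE])
  expect_equal(est$estimate, tab$Lambda[i_mid], tolerance = 0.05)
  expect_lt(est$upper - est$lower, 0.3)
  expect_true(est$lower <= est$estimate && est$estimate <= est$upper)
  cv <- cross_validate(tab, "regress", targets = "Lambda", seed = 63,
                       features = "S", hyper = hyper)
  expect_gt(cv$r2[["Lambda"]], 0.95)
  expect_error(train_regressor(tab, targets = "not_a_param"), "absent")
})

test_that("quantile prediction intervals are approximately calibrated", {
  tab <- make_reg_table(n = 500, seed = 64, noise = 0.4)
  test_rows <- 401:500
  fit <- train_regressor(tab[-test_rows, ], targets = "Lambda", seed = 65)
  covered <- ordered_ok <- logical(length(test_rows))
  for (i in seq_along(test_rows)) {
    est <- estimate_parameters(fit, tab[test_rows[i], , drop = FALSE])
    covered[i] <- est$lower <= tab$Lambda[test_rows[i]] &&
      tab$Lambda[test_rows[i]] <= est$upper
    ordered_ok[i] <- est$lower <= est$estimate &&
      est$estimate <= est$upper
  }
  expect_true(all(ordered_ok))
  expect_gte(mean(covered), 0.88)
  expect_lte(mean(covered), 1.0)
})

test_that("regression on pure noise explains nothing", {
  tab <- make_reg_table(n = 200, seed = 66)
  tab$Lambda <- rnorm(200)  # target unrelated to any feature
  cv <- cross_validate(tab, "regress", targets = "Lambda", seed = 67)
  expect_lt(cv$r2[["Lambda"]], 0.15)
})

test_that("posterior predictive checks localize the observation", {
  set.seed(68)
  fake_sim <- function(theta, seed) {
    set.seed(seed)
    ab <- as.numeric(rmultinom(1, 200, prob = runif(12)))
    ab <- ab[ab > 0]
    assemble_summary_vector(abundances = ab, traits = rnorm(length(ab)),
                            meta_traits = rnorm(20))
  }
  obs <- fake_sim(list(), seed = 999)
  pps <- posterior_predictive_check(obs, list(), n_sims = 60, seed = 69,
                                    simulator = fake_sim)
  expect_lte(pps$percentile, 1)
  expect_identical(pps$n_failed, 0L)
  pps2 <- posterior_predictive_check(obs, list(), n_sims = 60, seed = 69,
                                     simulator = fake_sim)
  expect_identical(pps$percentile, pps2$percentile)
  expect_equal(pps$pc_obs, pps2$pc_obs)

  # a gross outlier lands at the far edge of the simulated cloud
  out_obs <- obs
  out_obs[is.finite(out_obs)] <- out_obs[is.finite(out_obs)] + 10 *
    pmax(1, abs(out_obs[is.finite(out_obs)]))
  pps_out <- posterior_predictive_check(out_obs, list(), n_sims = 60,
                                        seed = 70, simulator = fake_sim)
  expect_identical(pps_out$percentile, 1)

  # failure accounting
  bad_sim <- function(theta, seed) stop("boom")
  expect_error(posterior_predictive_check(obs, list(), n_sims = 10,
                                          seed = 71, simulator = bad_sim),
               "failed")
})
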