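test_that("Hill numbers satisfy the standard identities", {
  for (q in c(0, 0.5, 1, 2, 3, 4))
    expect_equal(hill_number(rep(1 / 8, 8), q), 8, tolerance = 1e-10)
  expect_equal(hill_number(c(0.75, 0.25), 2), 1.6)
  p <- c(0.5, 0.3, 0.2)
  expect_equal(hill_number(p, 1), exp(-sum(p * log(p))), tolerance = 1e-10)
  # numerical q -> 1 limit agrees with the exponential-entropy form
  expect_equal(hill_number(p, 1 + 1e-7), hill_number(p, 1),
               tolerance = 1e-5)
  expect_error(hill_number(c(0.5, 0.4), 2), "sum to 1")
  expect_error(hill_number(c(1.2, -0.2), 2), "non-negative")
  # monotone non-increasing in q; bounded by 1 and S, equal to S iff even
  set.seed(41)
  for (i in 1:20) {
    S <- sample(2:40, 1)
    p <- as.numeric(rmultinom(1, 500, runif(S)))
    p <- p[p > 0] / sum(p)
    hs <- vapply(c(0.5, 1, 2, 3, 4), function(q) hill_number(p, q),
                 numeric(1))
    expect_true(all(diff(hs) <= 1e-9))
    expect_true(all(hs >= 1 - 1e-9 & hs <= length(p) + 1e-9))
  }
  expect_lt(hill_number(c(0.9, 0.1), 2), 2)
})

test_that("genetic Hill numbers are compositions on normalized pi", {
  for (q in 1:4) expect_equal(genetic_hill(rep(0.02, 5), q), 5,
                              tolerance = 1e-9)
  expect_equal(genetic_hill(c(0.5, 0, 0, 0), 2), 1)
  set.seed(42)
  v <- runif(12)
  for (q in 1:4)
    expect_equal(genetic_hill(v, q), hill_number(v / sum(v), q))
  expect_error(genetic_hill(rep(0, 4), 2), "zero")
})

test_that("functional Hill numbers count effectively distinct species", {
  # two equally abundant, equally distinct species at any separation
  for (d in c(0.1, 1, 50))
    expect_equal(functional_hill(c(0, d), c(1, 1), 2), 2, tolerance = 1e-9)
  # scale invariance: d_ij / Q cancels any common trait rescaling
  set.seed(43)
  tr <- rnorm(8); ab <- runif(8)
  for (q in c(1, 2, 3))
    expect_equal(functional_hill(tr, ab, q),
                 functional_hill(tr * 37.5, ab, q), tolerance = 1e-9)
  expect_error(functional_hill(rep(1, 4), runif(4), 2), "identical")
  expect_error(functional_hill(1, 1, 2), "2 species")
})

test_that("moments match brute-force central-moment formulas", {
  expect_equal(dist_moments(c(5, 5, 5)),
               c(mean = 5, sd = 0, skew = 0, kurt = 0))
  expect_equal(dist_moments(c(1, 2, 3))[["skew"]], 0)
  set.seed(44)
  for (i in 1:10) {
    x <- rnorm(50, sd = runif(1, 0.5, 4))
    m <- dist_moments(x)
    mu <- mean(x)
    m2 <- mean((x - mu)^2); m3 <- mean((x - mu)^3); m4 <- mean((x - mu)^4)
    expect_equal(unname(m), c(mu, sqrt(m2), m3 / m2^1.5, m4 / m2^2 - 3),
                 tolerance = 1e-12)
  }
  expect_error(dist_moments(numeric(0)), "empty")
})

test_that("trait deltas carry the filtering / competition signatures", {
  expect_equal(trait_deltas(c(1, 2, 3), c(1, 2, 3)),
               c(delta_mu_trait = 0, delta_sigma_trait = 0))
  d <- trait_deltas(c(1, 2, 3) + 2, c(1, 2, 3))
  expect_equal(unname(d), c(-2, 0))
  # a local subset clustered near one value: less variation locally
  meta_tr <- c(-4, -2, 0, 2, 4)
  local_tr <- c(-0.2, 0, 0.1)
  expect_gt(trait_deltas(local_tr, meta_tr)[["delta_sigma_trait"]], 0)
  expect_error(trait_deltas(numeric(0), 1), "empty")
})

test_that("Spearman correlations use average ranks and handle ties", {
  r <- rank_correlations(abundance = 1:5, pi = c(2, 4, 6, 8, 10))
  expect_equal(r[["rho_abundance_pi"]], 1)
  r2 <- rank_correlations(abundance = 1:5, pi = 5:1)
  expect_equal(r2[["rho_abundance_pi"]], -1)
  # ties: brute-force Pearson on average ranks
  x <- c(1, 2, 2, 3, 7); y <- c(5, 5, 2, 9, 1)
  brute <- cor(rank(x), rank(y))
  expect_equal(rank_correlations(abundance = x, pi = y)[["rho_abundance_pi"]],
               brute, tolerance = 1e-12)
  # trait axis enters as |t - mean(t)|
  tr <- c(-3, 0.5, 1, 4)
  ab <- c(4, 3, 2, 1)
  expect_equal(
    rank_correlations(abundance = ab, traits = tr)[["rho_abundance_trait"]],
    cor(rank(ab), rank(abs(tr - mean(tr)))), tolerance = 1e-12)
  # fewer than 3 complete pairs -> missing marker
  expect_true(is.na(rank_correlations(abundance = 1:2,
                                      pi = 2:1)[["rho_abundance_pi"]]))
})

test_that("summary vectors have canonical order and honest masking", {
  sv <- assemble_summary_vector(abundances = c(20, 6, 3),
                                pis = c(0.01, 0.02, 0.004),
                                traits = c(0, 1, -1),
                                meta_traits = c(-2, 0, 1, 2))
  expect_identical(names(sv), summary_stat_names())
  expect_identical(attr(sv, "mask"),
                   c(abundance = TRUE, pi = TRUE, trait = TRUE))
  expect_false(anyNA(sv))
  expect_identical(sv[["S"]], 3)

  ab_only <- assemble_summary_vector(abundances = c(20, 6, 3))
  expect_identical(attr(ab_only, "mask"),
                   c(abundance = TRUE, pi = FALSE, trait = FALSE))
  expect_false(anyNA(ab_only[c("S", paste0("abundance_",
                                           c("mean", "sd", "skew", "kurt")),
                               paste0("D", 1:4))]))
  expect_true(all(is.na(ab_only[c(paste0("GD", 1:4), paste0("FD", 1:4),
                                  "pi_mean", "trait_mean",
                                  "rho_abundance_pi")])))
  expect_error(assemble_summary_vector(), "absent")

  # the log-moment flag transforms only the abundance / pi moments
  svl <- assemble_summary_vector(abundances = c(20, 6, 3),
                                 pis = c(0.01, 0.02, 0.004),
                                 traits = c(0, 1, -1),
                                 meta_traits = c(-2, 0, 1, 2),
                                 log_moments = TRUE)
  expect_equal(svl[["abundance_mean"]], mean(log1p(c(20, 6, 3))))
  expect_identical(svl[["D2"]], sv[["D2"]])
  expect_identical(svl[["trait_sd"]], sv[["trait_sd"]])

  # argument content, not call pattern, determines the vector
  sv2 <- assemble_summary_vector(traits = c(0, 1, -1),
                                 pis = c(0.01, 0.02, 0.004),
                                 abundances = c(20, 6, 3),
                                 meta_traits = c(-2, 0, 1, 2))
  expect_identical(sv, sv2)
})

test_that("simulated communities summarize consistently", {
  out <- tiny_assembled(seed = 45)
  pt <- community_genetic_diversities(out$state, out$meta, out$params,
                                      seed = 46)
  sv <- summarize_community(out$state, out$meta, pt)
  expect_identical(sv[["S"]], as.numeric(sum(out$state$count > 0)))
  expect_true(sv[["D1"]] >= 1 && sv[["D1"]] <= sv[["S"]])
  expect_true(all(attr(sv, "mask")))
  sv_ab <- summarize_community(out$state, out$meta, NULL,
                               axes = "abundance")
  expect_true(all(is.na(sv_ab[paste0("GD", 1:4)])))
})
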