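# Shared builders for small test communities. Everything is generated in
# code under fixed seeds; nothing is read from disk.

tiny_meta <- function(S_M = 50, J_M = 20000, seed = 11, sigma2_M = 2) {
  build_metacommunity(metacommunity_params(S_M = S_M, J_M = J_M,
                                           sigma2_M = sigma2_M,
                                           seed = seed))
}

tiny_assembled <- function(meta = tiny_meta(), model = "neutral",
                           J = 300, m = 0.01, nu = 0, Lambda = 0.75,
                           s_E = 10, alpha = 200, seed = 21,
                           init_mode = "metacommunity_sample") {
  p <- assembly_params(J = J, m = m, nu = nu, model = model, s_E = s_E,
                       Lambda_target = Lambda, alpha = alpha, seed = seed,
                       init_mode = init_mode)
  list(state = run_assembly(meta, p), params = p, meta = meta)
}

# quick training-table surrogate: informative synthetic features, no
# simulator in the loop (for inference-layer unit tests)
synthetic_table <- function(n_per_class = 60, noise = 0.3, seed = 5) {
  set.seed(seed)
  classes <- c("neutral", "filtering", "competition")
  model <- rep(classes, each = n_per_class)
  mu <- c(neutral = 0, filtering = 2, competition = -2)
  n <- length(model)
  tab <- data.frame(model = model, J = sample(500:2000, n, TRUE),
                    alpha = runif(n, 10, 100), m = runif(n, 1e-4, 0.1),
                    nu = 0, s_E = runif(n, 0.1, 10),
                    Lambda = runif(n))
  stats <- matrix(rnorm(n * length(summary_stat_names())), nrow = n)
  colnames(stats) <- summary_stat_names()
  stats[, "delta_sigma_trait"] <- mu[model] + rnorm(n, 0, noise)
  stats[, "S"] <- 40 + 5 * (model == "neutral") + rnorm(n)
  cbind(tab, as.data.frame(stats))
}
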