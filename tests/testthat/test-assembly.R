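test_that("initialization modes set up the community as specified", {
  meta <- tiny_meta()
  p_mono <- assembly_params(J = 100, init_mode = "monodominance")
  set.seed(1)
  st <- initialize_local(meta, p_mono)
  expect_identical(sum(st$count > 0), 1L)
  expect_identical(max(st$count), 100L)
  expect_identical(st$labels[which.max(st$count)],
                   names(which.max(meta$abundance)))
  expect_true(all(st$founder))
  expect_identical(progress_lambda(st), 0)

  # metacommunity_sample matches multinomial sampling of the pool
  p_samp <- assembly_params(J = 200, init_mode = "metacommunity_sample")
  set.seed(2)
  freq <- Reduce(`+`, replicate(40, {
    initialize_local(meta, p_samp)$count
  }, simplify = FALSE))
  expected <- 40 * 200 * as.numeric(meta$abundance) / sum(meta$abundance)
  keep <- expected >= 5
  chi <- sum((freq[keep] - expected[keep])^2 / expected[keep]) +
    (sum(freq[!keep]) - sum(expected[!keep]))^2 / sum(expected[!keep])
  df <- sum(keep)  # conservative
  expect_gt(pchisq(chi, df, lower.tail = FALSE), 1e-4)

  # a species holding almost the whole pool dominates the sample
  meta2 <- tiny_meta(S_M = 5, J_M = 10000, seed = 3)
  meta2$abundance[] <- c(9996L, 1L, 1L, 1L, 1L)
  set.seed(3)
  rich <- replicate(20, sum(initialize_local(meta2, p_samp)$count > 0))
  expect_gte(mean(rich == 1), 0.8)
})

test_that("death weights implement the three kernels exactly", {
  meta <- tiny_meta()
  p <- assembly_params(J = 500, model = "neutral")
  set.seed(4)
  st <- initialize_local(meta, p)
  expect_equal(death_weights(st, meta, p), rep(1 / 500, 500))

  # filtering with every trait at the optimum collapses to uniform
  stf <- st
  stf$trait[] <- 1.5
  pf <- assembly_params(J = 500, model = "filtering", s_E = 1, z_E = 1.5)
  expect_equal(death_weights(stf, meta, pf), rep(1 / 500, 500))

  # competition: three species z = (0, 0, 5), equal abundance, s_E = 1;
  # direct evaluation of the kernel
  meta3 <- tiny_meta(S_M = 3, J_M = 300, seed = 5)
  meta3$trait[] <- c(0, 0, 5)
  pc <- assembly_params(J = 9, model = "competition", s_E = 1)
  st3 <- initialize_local(meta3, pc)
  st3$demes <- rep(0:2, each = 3L)
  st3$count <- rep(3L, 3)
  st3$trait <- c(0, 0, 5)
  w <- death_weights(st3, meta3, pc)
  zbar <- 5 / 3
  raw <- exp(-c(0 - zbar, 0 - zbar, 5 - zbar)^2 / 1)[st3$demes + 1L]
  expect_equal(w, raw / sum(raw), tolerance = 1e-12)
  expect_lt(w[9], w[1])  # distant species dies least
  expect_equal(sum(w), 1)
})

test_that("single steps conserve J and respect the boundary dynamics", {
  meta <- tiny_meta()
  # m = 1: every replacement is an immigrant; all species stay in the pool
  p1 <- assembly_params(J = 50, m = 1, nu = 0)
  set.seed(6)
  st <- initialize_local(meta, p1)
  st2 <- assembly_step(st, meta, p1, n = 200)
  expect_identical(length(st2$demes), 50L)
  expect_identical(sum(st2$count), 50L)
  expect_identical(st2$step_count, 200)
  expect_true(all(st2$demes < st2$n_meta))
  expect_true(all(st2$col_count[unique(st2$demes) + 1L] >= 1L))

  # m = 0, nu = 0, monodominant start: absorbing state
  p0 <- assembly_params(J = 40, m = 0, nu = 0,
                        init_mode = "monodominance")
  set.seed(7)
  st0 <- initialize_local(meta, p0)
  st0b <- assembly_step(st0, meta, p0, n = 500)
  expect_identical(st0b$count, st0$count)
  # every deme has turned over, but the monoculture's ancestry (hence all
  # information about the initial state) is fully intact
  expect_identical(turnover(st0b), 1)
  expect_identical(progress_lambda(st0b), 0)

  # drift-only: richness can only decrease without immigration/speciation
  pd <- assembly_params(J = 100, m = 0, nu = 0,
                        init_mode = "metacommunity_sample")
  set.seed(8)
  std <- initialize_local(meta, pd)
  r0 <- sum(std$count > 0)
  std2 <- assembly_step(std, meta, pd, n = 2000)
  expect_lte(sum(std2$count > 0), r0)
})

test_that("Lambda tracks founding-ancestry erasure up to its target", {
  meta <- tiny_meta()
  p <- assembly_params(J = 120, m = 0.05, Lambda_target = 0.6)
  set.seed(9)
  st <- initialize_local(meta, p)
  expect_identical(progress_lambda(st), 0)
  expect_identical(turnover(st), 0)
  tv <- 0
  for (i in 1:20) {
    st <- assembly_step(st, meta, p, n = 25)
    lam <- progress_lambda(st)
    expect_gte(lam, 0)
    expect_lte(lam, 1)
    # the never-replaced fraction is the strictly monotone clock
    expect_gte(turnover(st), tv)
    tv <- turnover(st)
    # ancestry erasure can never outrun raw turnover
    expect_lte(lam, turnover(st) + 1e-12)
  }
  # Lambda_target = 0 returns the initial state untouched
  p0 <- assembly_params(J = 120, Lambda_target = 0)
  set.seed(10)
  init <- initialize_local(meta, p0)
  fin <- run_assembly(meta, p0, state = init)
  expect_identical(fin$step_count, 0)
  expect_identical(fin$count, init$count)
  # sustained immigration eventually erases all founding ancestry
  p1 <- assembly_params(J = 60, m = 0.1, Lambda_target = 1)
  set.seed(11)
  fin1 <- run_assembly(meta, p1)
  expect_identical(progress_lambda(fin1), 1)
  expect_false(any(fin1$founder_derived))
})

test_that("immigration-only equilibrium matches multinomial sampling", {
  # with m = 1 and full turnover every deme is an independent draw from
  # the metacommunity abundance distribution
  meta <- tiny_meta(S_M = 6, J_M = 6000, seed = 12)
  p <- assembly_params(J = 150, m = 1, nu = 0, Lambda_target = 1)
  set.seed(13)
  counts <- Reduce(`+`, replicate(30, run_assembly(meta, p)$count,
                                  simplify = FALSE))
  expected <- 30 * 150 * as.numeric(meta$abundance) / sum(meta$abundance)
  keep <- expected >= 5
  chi <- sum((counts[keep] - expected[keep])^2 / expected[keep])
  expect_gt(pchisq(chi, sum(keep), lower.tail = FALSE), 1e-4)
})

test_that("assembly runs are reproducible and guard against nonconvergence", {
  meta <- tiny_meta()
  p <- assembly_params(J = 200, m = 0.02, nu = 1e-3, seed = 99)
  a <- run_assembly(meta, p)
  b <- run_assembly(meta, p)
  expect_identical(a$count, b$count)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$step_count, b$step_count)

  pg <- assembly_params(J = 200, m = 0.02, Lambda_target = 0.9,
                        max_steps = 10, seed = 1)
  expect_error(run_assembly(meta, pg), "Lambda")
})

test_that("point-mutation speciation founds singleton species with jittered traits", {
  meta <- tiny_meta(S_M = 30, J_M = 30000, seed = 14, sigma2_M = 2)
  p <- assembly_params(J = 400, m = 0.05, nu = 0.05, Lambda_target = 0.9,
                       seed = 15)
  st <- run_assembly(meta, p)
  h <- species_histories(st, present_only = FALSE)
  sp <- h[h$origin == "local_speciation", ]
  expect_gt(nrow(sp), 30)
  expect_true(all(!is.na(sp$parent)))
  expect_true(all(sp$colonization_count == 0L))
  expect_true(all(sp$first_colonization_step == -1))
  # trait jump variance ~ sigma2_M / (lambda (1 + epsilon)) = 2
  parent_trait <- st$trait[match(sp$parent, st$labels)]
  jumps <- sp$trait - parent_trait
  expect_equal(var(jumps), 2, tolerance = 0.35)
})

test_that("histories and exports round-trip", {
  out <- tiny_assembled(nu = 5e-3, seed = 16)
  h <- species_histories(out$state)
  expect_true(all(h$abundance > 0))
  expect_true(all(vapply(h$trajectory, length, integer(1)) >= 1L))
  expect_true(all(unlist(h$trajectory) >= 1L))
  expect_true(all(h$colonization_count[h$origin == "immigrant"] >= 1L))
  path <- tempfile(fileext = ".tsv")
  write_species_histories(out$state, path)
  back <- read.delim(path)
  expect_true(all(c("species_id", "origin", "first_colonization_step",
                    "colonization_count", "trajectory") %in% names(back)))
  # in-situ radiations export as parseable newick
  meta <- out$meta
  p <- assembly_params(J = 300, m = 0.05, nu = 0.02, Lambda_target = 0.9,
                       seed = 17)
  st <- run_assembly(meta, p)
  nwk <- local_phylo_newick(st)
  if (length(nwk) > 0) {
    tr <- ape::read.tree(text = nwk[[1]])
    expect_s3_class(tr, "phylo")
  }
})
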