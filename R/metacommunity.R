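#' Metacommunity parameters
#'
#' Bundle and validate the parameters of the regional species pool: the
#' number of species `S_M`, the total number of individuals `J_M`, the
#' per-lineage speciation rate `lambda`, the extinction fraction `epsilon`
#' (so that the extinction rate is `lambda * epsilon`), and the Brownian
#' trait-evolution rate `sigma2_M` (trait variance accumulated per unit
#' branch length).
#'
#' @param S_M Integer >= 2, number of species in the metacommunity.
#' @param J_M Integer >= `S_M`, total number of individuals in the pool.
#' @param lambda Speciation rate (> 0). Time units are arbitrary; only
#'   `sigma2_M` per unit time and the speciation trait-variance ratio
#'   `sigma2_M / (lambda + lambda * epsilon)` consume them.
#' @param epsilon Extinction fraction in `[0, 1)`.
#' @param sigma2_M Brownian motion rate (>= 0).
#' @param seed Optional integer seed used by [build_metacommunity()].
#' @return An object of class `meta_params` (a validated list).
#' @export
#' @examples
#' metacommunity_params(S_M = 20, J_M = 10000)
metacommunity_params <- function(S_M = 500, J_M = 500000, lambda = 1,
                                 epsilon = 0, sigma2_M = 2, seed = NULL) {
  S_M <- as.integer(S_M)
  J_M <- as.integer(J_M)
  if (is.na(S_M) || S_M < 2L)
    stop("S_M must be an integer >= 2", call. = FALSE)
  if (is.na(J_M) || J_M < S_M)
    stop("J_M must be an integer >= S_M", call. = FALSE)
  if (!is.numeric(lambda) || lambda <= 0)
    stop("lambda must be > 0", call. = FALSE)
  if (!is.numeric(epsilon) || epsilon < 0 || epsilon >= 1)
    stop("epsilon must be in [0, 1)", call. = FALSE)
  if (!is.numeric(sigma2_M) || sigma2_M < 0)
    stop("sigma2_M must be >= 0", call. = FALSE)
  structure(list(S_M = S_M, J_M = J_M, lambda = lambda, epsilon = epsilon,
                 sigma2_M = sigma2_M, seed = seed),
            class = "meta_params")
}

#' Simulate a constant-rate birth-death phylogeny with a fixed tip count
#'
#' Forward-time simulation of a homogeneous diversification process with
#' speciation rate `lambda` and extinction rate `lambda * epsilon`, starting
#' from a single lineage and run until `S_M` lineages are simultaneously
#' extant. Runs that go fully extinct before reaching `S_M` tips are
#' discarded and resimulated, so the returned tree is conditioned on
#' survival. Extinct side branches are pruned; the result is ultrametric
#' with exactly `S_M` extant tips labelled `t0 .. t{S_M-1}` in tip-visit
#' order. The root edge (time from process origin to the first surviving
#' split) is kept in `$root.edge`, so the total process age is
#' `max(node.depth.edgelength) + root.edge`.
#'
#' @param params A [metacommunity_params()] object.
#' @return An [ape::read.tree()]-style `phylo` object.
#' @export
simulate_phylogeny <- function(params) {
  stopifnot(inherits(params, "meta_params"))
  n <- params$S_M
  lambda <- params$lambda
  mu <- params$lambda * params$epsilon
  repeat {
    tr <- .sim_bd_once(n, lambda, mu)
    if (!is.null(tr)) return(tr)
  }
}

# One forward pass of the birth-death process; NULL on full extinction.
# Bookkeeping is on "alive" lineage records (parent pointer + birth time).
.sim_bd_once <- function(n, lambda, mu, max_events = 1e6L) {
  # columns: parent id, birth time, death time (NA = extant), left child id,
  # right child id -- grown as flat vectors
  parent <- c(NA_integer_)
  btime <- c(0)
  dtime <- c(NA_real_)
  child1 <- c(NA_integer_)
  child2 <- c(NA_integer_)
  alive <- 1L
  t_now <- 0
  n_events <- 0L
  while (length(alive) < n) {
    k <- length(alive)
    if (k == 0L) return(NULL)
    rate <- k * (lambda + mu)
    t_now <- t_now + rexp(1L, rate)
    i <- alive[sample.int(k, 1L)]
    n_events <- n_events + 1L
    if (n_events > max_events)
      stop("birth-death simulation exceeded event budget", call. = FALSE)
    if (runif(1L) < lambda / (lambda + mu)) {
      # speciation: lineage i is replaced by two daughters
      id1 <- length(parent) + 1L
      id2 <- id1 + 1L
      parent <- c(parent, i, i)
      btime <- c(btime, t_now, t_now)
      dtime[i] <- t_now
      dtime <- c(dtime, NA_real_, NA_real_)
      child1[i] <- id1
      child2[i] <- id2
      child1 <- c(child1, NA_integer_, NA_integer_)
      child2 <- c(child2, NA_integer_, NA_integer_)
      alive <- c(alive[alive != i], id1, id2)
    } else {
      dtime[i] <- t_now
      alive <- alive[alive != i]
    }
  }
  .bd_to_phylo(parent, btime, dtime, child1, child2, alive, t_now)
}

# Collapse the event records to a pruned, ultrametric ape::phylo object.
.bd_to_phylo <- function(parent, btime, dtime, child1, child2, alive, t_end) {
  n_rec <- length(parent)
  surv <- logical(n_rec)
  surv[alive] <- TRUE
  # propagate survival rootward
  ord <- order(btime[seq_len(n_rec)], decreasing = TRUE)
  for (i in ord) {
    if (!is.na(child1[i]) && (surv[child1[i]] || surv[child2[i]]))
      surv[i] <- TRUE
  }
  # each surviving record maps to a path; collapse chains where only one
  # child survives
  tip_count <- length(alive)
  # assign ids: walk from root, emitting tips and bifurcating nodes
  edges <- matrix(0L, 0L, 2L)
  elen <- numeric(0)
  tipn <- 0L
  noden <- tip_count
  labels <- character(tip_count)
  root_edge_len <- NA_real_
  # recursion via explicit stack: (record, accumulated length, parent node id)
  # find first surviving bifurcation from the root record
  descend <- function(i) {
    # follow single-survivor chains; return c(record_at_split_or_tip, length)
    len <- 0
    repeat {
      end_t <- if (is.na(dtime[i])) t_end else dtime[i]
      len <- len + (end_t - btime[i])
      if (is.na(child1[i])) return(list(rec = i, len = len, tip = TRUE))
      c1 <- child1[i]; c2 <- child2[i]
      s1 <- surv[c1]; s2 <- surv[c2]
      if (s1 && s2) return(list(rec = i, len = len, tip = FALSE))
      i <- if (s1) c1 else c2
    }
  }
  if (tip_count == 1L)
    stop("cannot build a one-tip tree", call. = FALSE)
  env <- new.env()
  env$edges <- list()
  env$elen <- numeric(0)
  env$tipn <- 0L
  env$noden <- tip_count + 1L  # ape convention: root = ntip + 1
  build <- function(rec, parent_node) {
    # rec is a surviving bifurcation record whose split children get walked
    for (ch in c(child1[rec], child2[rec])) {
      d <- descend(ch)
      if (d$tip) {
        env$tipn <- env$tipn + 1L
        node <- env$tipn
        env$edges[[length(env$edges) + 1L]] <- c(parent_node, node)
        env$elen <- c(env$elen, d$len)
      } else {
        env$noden <- env$noden + 1L
        node <- env$noden
        env$edges[[length(env$edges) + 1L]] <- c(parent_node, node)
        env$elen <- c(env$elen, d$len)
        build(d$rec, node)
      }
    }
  }
  top <- descend(1L)
  root_node <- tip_count + 1L
  build(top$rec, root_node)
  phy <- list(edge = do.call(rbind, env$edges),
              edge.length = env$elen,
              tip.label = paste0("t", seq_len(tip_count) - 1L),
              Nnode = tip_count - 1L,
              root.edge = top$len)
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  ape::reorder.phylo(phy, "cladewise")
}

#' Evolve a continuous trait by Brownian motion on a phylogeny
#'
#' Each branch contributes an independent Gaussian increment with mean zero
#' and variance `sigma2_M` times the branch length; the root state is
#' `root_value` (0 by default). A root edge, if present, contributes its own
#' increment so the process starts at the origin of the clade.
#'
#' @param phylogeny A `phylo` object.
#' @param sigma2_M Brownian rate (variance per unit branch length, >= 0).
#' @param root_value Trait value at the root (default 0).
#' @return Named numeric vector of tip trait values.
#' @export
evolve_traits <- function(phylogeny, sigma2_M, root_value = 0) {
  stopifnot(inherits(phylogeny, "phylo"))
  if (!is.numeric(sigma2_M) || sigma2_M < 0)
    stop("sigma2_M must be >= 0", call. = FALSE)
  base <- root_value
  if (!is.null(phylogeny$root.edge) && phylogeny$root.edge > 0)
    base <- base + rnorm(1L, 0, sqrt(sigma2_M * phylogeny$root.edge))
  z <- ape::rTraitCont(phylogeny, model = "BM", sigma = sqrt(sigma2_M),
                       root.value = base)
  z <- z[phylogeny$tip.label]
  z
}

#' Solve Fisher's alpha from species count and community size
#'
#' Solves `S = alpha * log(1 + J / alpha)` for `alpha` by root finding.
#'
#' @param S Number of species (>= 1).
#' @param J Number of individuals (>= S).
#' @return Fisher's alpha (positive real).
#' @export
fishers_alpha <- function(S, J) {
  stopifnot(S >= 1, J >= S)
  if (S == J) return(Inf)
  f <- function(a) a * log1p(J / a) - S
  uniroot(f, lower = 1e-10, upper = S * 10 + 10, tol = 1e-10,
          extendInt = "upX")$root
}

# One log-series variate with parameter p (Devroye 1986, ch. X.5.3)
.rlogseries <- function(n, p) {
  out <- integer(n)
  lq <- log1p(-p)
  for (i in seq_len(n)) {
    u <- runif(1L)
    if (u > p) {
      out[i] <- 1L
    } else {
      v <- runif(1L)
      q <- -expm1(v * lq)      # 1 - (1-p)^v
      if (u < q * q) {
        out[i] <- as.integer(max(1, floor(1 + log(u) / log(q))))
      } else if (u > q) {
        out[i] <- 1L
      } else {
        out[i] <- 2L
      }
    }
  }
  out
}

#' Draw metacommunity abundances from a log-series distribution
#'
#' Fisher's alpha is solved from `S = alpha log(1 + J_M/alpha)`, the
#' log-series parameter is `x = J_M / (J_M + alpha)`, `S_M` variates are
#' drawn, and the draw is rescaled by largest-remainder rounding (with a
#' floor of one individual per species) so the abundances sum exactly to
#' `J_M`.
#'
#' @param S_M Number of species (>= 1).
#' @param J_M Total number of individuals (>= `S_M`).
#' @return Integer vector of length `S_M` summing to `J_M`.
#' @export
draw_logseries_abundances <- function(S_M, J_M) {
  S_M <- as.integer(S_M); J_M <- as.integer(J_M)
  if (is.na(S_M) || S_M < 1L) stop("S_M must be >= 1", call. = FALSE)
  if (is.na(J_M) || J_M < S_M) stop("J_M must be >= S_M", call. = FALSE)
  if (S_M == 1L) return(J_M)
  alpha <- fishers_alpha(S_M, J_M)
  x <- J_M / (J_M + alpha)
  k <- .rlogseries(S_M, x)
  .rescale_to_sum(k, J_M)
}

# Rescale positive counts to an exact total with a floor of 1 per entry.
# The leftover after proportional flooring is pushed onto the most abundant
# species (proportionally to abundance, then unit top-ups to the largest):
# spreading it over all fractional parts would inflate rare-species counts
# and visibly distort the log-series tail (e.g. halve the singleton count),
# whereas the abundant species absorb it without changing the shape.
.rescale_to_sum <- function(k, total) {
  n <- length(k)
  stopifnot(total >= n)
  raw <- k * (total / sum(k))
  fl <- pmax(1L, as.integer(round(raw)))
  rem <- total - sum(fl)
  if (rem > 0) {
    share <- as.integer(floor(rem * (k / sum(k))))
    fl <- fl + share
    rem <- rem - sum(share)
    if (rem > 0) {
      ord <- order(k, decreasing = TRUE)
      idx <- rep(ord, length.out = rem)
      fl <- fl + tabulate(idx, nbins = n)
    }
  } else if (rem < 0) {
    # remove from the largest entries, never below 1
    while (rem < 0) {
      i <- which.max(fl)
      take <- min(fl[i] - 1L, -rem)
      if (take == 0L) {
        ord <- order(fl, decreasing = TRUE)
        for (j in ord) {
          t2 <- min(fl[j] - 1L, -rem)
          fl[j] <- fl[j] - t2
          rem <- rem + t2
          if (rem == 0L) break
        }
        break
      }
      fl[i] <- fl[i] - take
      rem <- rem + take
    }
  }
  stopifnot(sum(fl) == total, all(fl >= 1L))
  as.integer(fl)
}

#' Build a complete metacommunity
#'
#' Composes [simulate_phylogeny()], [evolve_traits()] and
#' [draw_logseries_abundances()] into a static regional pool: an ultrametric
#' phylogeny over `S_M` species, one Brownian trait value per species (root
#' state 0), and integer abundances summing exactly to `J_M`. Abundances and
#' traits are keyed by tip label.
#'
#' @param params A [metacommunity_params()] object.
#' @return An object of class `metacommunity` with elements `phylogeny`
#'   (a `phylo`), `abundance` and `trait` (named vectors over tip labels),
#'   and `params`.
#' @export
#' @examples
#' m <- build_metacommunity(metacommunity_params(S_M = 10, J_M = 1000, seed = 1))
#' sum(m$abundance)  # 1000
build_metacommunity <- function(params) {
  stopifnot(inherits(params, "meta_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  phy <- simulate_phylogeny(params)
  traits <- evolve_traits(phy, params$sigma2_M)
  ab <- draw_logseries_abundances(params$S_M, params$J_M)
  # heavier species-abundance tail assigned in random order (log-series draw
  # is exchangeable, so any assignment is valid; keep draw order)
  ab <- setNames(ab, phy$tip.label)
  structure(list(phylogeny = phy, abundance = ab,
                 trait = traits[phy$tip.label], params = params),
            class = "metacommunity")
}

#' @export
print.metacommunity <- function(x, ...) {
  cat("Metacommunity:", x$params$S_M, "species,",
      format(x$params$J_M, big.mark = ","), "individuals\n")
  cat("  trait range: [", round(min(x$trait), 3), ",",
      round(max(x$trait), 3), "]  sigma2_M =", x$params$sigma2_M, "\n")
  invisible(x)
}

#' Write / read a metacommunity as newick + TSV
#'
#' `write_metacommunity` writes `<stem>.nwk` (phylogeny with branch lengths)
#' and `<stem>.tsv` (columns `species_id`, `abundance`, `trait`);
#' `read_metacommunity` reads them back.
#'
#' @param meta A `metacommunity` object.
#' @param stem Path stem (without extension).
#' @return `read_metacommunity` returns a `metacommunity`; the writer
#'   returns `stem` invisibly.
#' @export
write_metacommunity <- function(meta, stem) {
  stopifnot(inherits(meta, "metacommunity"))
  ape::write.tree(meta$phylogeny, file = paste0(stem, ".nwk"))
  df <- data.frame(species_id = names(meta$abundance),
                   abundance = as.integer(meta$abundance),
                   trait = as.numeric(meta$trait))
  write.table(df, paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(stem)
}

#' @rdname write_metacommunity
#' @export
read_metacommunity <- function(stem) {
  phy <- ape::read.tree(paste0(stem, ".nwk"))
  df <- read.delim(paste0(stem, ".tsv"), stringsAsFactors = FALSE)
  stopifnot(all(c("species_id", "abundance", "trait") %in% names(df)))
  ab <- setNames(as.integer(df$abundance), df$species_id)[phy$tip.label]
  tr <- setNames(as.numeric(df$trait), df$species_id)[phy$tip.label]
  params <- metacommunity_params(S_M = length(phy$tip.label),
                                 J_M = sum(ab))
  structure(list(phylogeny = phy, abundance = ab, trait = tr,
                 params = params),
            class = "metacommunity")
}
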