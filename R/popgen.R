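#' Harmonic mean of a population-size trajectory
#'
#' `n / sum(1/x)` over the recorded abundances; the classic approximation of
#' the effective population size of a fluctuating population.
#'
#' @param trajectory Positive numeric vector (zeros are excluded by
#'   construction upstream: abundances are only recorded while the species
#'   is present).
#' @return The harmonic mean.
#' @export
#' @examples
#' harmonic_mean_abundance(c(1, 4, 4, 2))  # 2
harmonic_mean_abundance <- function(trajectory) {
  if (length(trajectory) == 0L)
    stop("empty trajectory", call. = FALSE)
  if (any(trajectory <= 0))
    stop("trajectory must be positive", call. = FALSE)
  length(trajectory) / sum(1 / trajectory)
}

#' Coalescent setup for one species
#'
#' Container for the demographic model handed to [simulate_species_pi()]:
#' a local population of size `Ne_local` that diverged from a metacommunity
#' source of size `Ne_source` at `tau` generations ago, with ongoing
#' backward migration at probability `mig_rate` per lineage per generation,
#' sampled with `n_samples` gene copies at a locus of `L` sites mutating at
#' `mu` per site per generation.
#'
#' @param Ne_local,Ne_source Effective sizes in individuals (>= 1).
#' @param tau Divergence time in generations (>= 0; `Inf` = never joined).
#' @param mig_rate Backward migration probability per lineage per
#'   generation (>= 0).
#' @param n_samples Gene copies sampled (>= 2 for pi to be defined).
#' @param L Locus length in bp.
#' @param mu Per-site per-generation mutation rate.
#' @return An object of class `coalescent_setup`.
#' @export
coalescent_setup <- function(Ne_local, Ne_source, tau, mig_rate,
                             n_samples = 10, L = 570, mu = 5e-7) {
  if (Ne_local < 1) stop("Ne_local must be >= 1", call. = FALSE)
  if (Ne_source < 1) stop("Ne_source must be >= 1", call. = FALSE)
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (mig_rate < 0) stop("mig_rate must be >= 0", call. = FALSE)
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  structure(list(Ne_local = Ne_local, Ne_source = Ne_source, tau = tau,
                 mig_rate = mig_rate, n_samples = as.integer(n_samples),
                 L = as.integer(L), mu = mu),
            class = "coalescent_setup")
}

#' Rescale a forward-time species history to coalescent units
#'
#' Forward-time Moran steps are converted to backward-time Wright-Fisher
#' generations by the factor `2/J`, and both effective sizes and times are
#' scaled by `alpha` (individuals per deme), so rates per generation are
#' consistent with a local census of `J * alpha` organisms:
#' * `Ne_local = alpha * harmonic_mean(trajectory)`
#' * `tau = (elapsed_steps - first_colonization_step) * (2/J) * alpha`
#' * `mig_rate = colonization_count / (elapsed_steps * (2/J) * alpha)`
#' * `Ne_source = alpha * metacommunity abundance`
#'
#' In-situ species (`origin = "local_speciation"`) get `mig_rate = 0` and
#' `tau` measured from their speciation step.
#'
#' @param history One row of [species_histories()] (a list or single-row
#'   data.frame with `trajectory`, `first_colonization_step`,
#'   `colonization_count`, `origin`, `speciation_step`).
#' @param J Local community size in demes.
#' @param alpha Individuals per deme.
#' @param meta_abundance Metacommunity abundance of the species (or of its
#'   ultimate metacommunity ancestor for in-situ species).
#' @param elapsed_steps Total Moran steps elapsed in the run.
#' @param n_samples,L,mu Sampling specification (see [coalescent_setup()]).
#' @return A `coalescent_setup`.
#' @export
rescale_history <- function(history, J, alpha, meta_abundance,
                            elapsed_steps, n_samples = 10, L = 570,
                            mu = 5e-7) {
  traj <- history$trajectory
  if (is.list(traj)) traj <- traj[[1]]
  step_to_gen <- (2 / J) * alpha
  total_gens <- elapsed_steps * step_to_gen
  Ne_local <- max(1, alpha * harmonic_mean_abundance(traj))
  if (identical(as.character(history$origin), "local_speciation")) {
    tau <- (elapsed_steps - history$speciation_step) * step_to_gen
    mig <- 0
  } else {
    tau <- (elapsed_steps - history$first_colonization_step) * step_to_gen
    mig <- history$colonization_count / total_gens
  }
  coalescent_setup(Ne_local = Ne_local,
                   Ne_source = max(1, alpha * meta_abundance),
                   tau = tau, mig_rate = mig,
                   n_samples = n_samples, L = L, mu = mu)
}

#' Simulate nucleotide diversity under a two-deme structured coalescent
#'
#' Backward in time, `n_samples` lineages start in the local deme. Within
#' each deme pairs coalesce at rate `choose(k, 2) / Ne` per generation
#' (haploid scaling); local lineages additionally migrate to the source at
#' rate `mig_rate` each. At `tau` generations all remaining local lineages
#' join the source, where coalescence continues to the MRCA. Mutations are
#' dropped on the genealogy under an infinite-sites model with expectation
#' `mu * L` per generation of branch length, and per-site pi of the sample
#' is computed from the branch mutation counts.
#'
#' @param setup A [coalescent_setup()].
#' @param seed Optional integer seed.
#' @return List of class `genetic_diversity` with `pi`, `segsites`,
#'   `n_samples`, and the total tree length in generations.
#' @export
simulate_species_pi <- function(setup, seed = NULL) {
  stopifnot(inherits(setup, "coalescent_setup"))
  if (!is.null(seed)) set.seed(seed)
  n <- setup$n_samples
  # lineages: deme membership (1 local, 2 source), number of sample tips
  # below, birth time of the lineage (time of the coalescence creating it)
  deme <- rep(1L, n)
  tips <- rep(1L, n)
  born <- rep(0, n)
  t_now <- 0
  # accumulated branch segments: (#tips below, length in generations)
  seg_tips <- integer(0)
  seg_len <- numeric(0)
  moved <- FALSE
  repeat {
    k_l <- sum(deme == 1L)
    k_s <- sum(deme == 2L)
    if (k_l + k_s <= 1L) break
    rate_cl <- if (k_l >= 2) k_l * (k_l - 1) / 2 / setup$Ne_local else 0
    rate_cs <- if (k_s >= 2) k_s * (k_s - 1) / 2 / setup$Ne_source else 0
    rate_m <- if (!moved) k_l * setup$mig_rate else 0
    tot <- rate_cl + rate_cs + rate_m
    t_ev <- if (tot > 0) t_now + rexp(1L, tot) else Inf
    if (!moved && is.finite(setup$tau) && t_ev >= setup$tau) {
      # divergence reached: everyone joins the source
      deme[deme == 1L] <- 2L
      t_now <- setup$tau
      moved <- TRUE
      next
    }
    if (is.infinite(t_ev))
      stop("coalescent stalled (no events possible)", call. = FALSE)
    t_now <- t_ev
    u <- runif(1L) * tot
    if (u <= rate_cl || (u <= rate_cl + rate_cs)) {
      which_deme <- if (u <= rate_cl) 1L else 2L
      idx <- which(deme == which_deme)
      pair <- idx[sample.int(length(idx), 2L)]
      # close the two child branches
      seg_tips <- c(seg_tips, tips[pair])
      seg_len <- c(seg_len, t_now - born[pair])
      new_tips <- sum(tips[pair])
      deme <- deme[-pair]; tips <- tips[-pair]; born <- born[-pair]
      deme <- c(deme, which_deme)
      tips <- c(tips, new_tips)
      born <- c(born, t_now)
    } else {
      idx <- which(deme == 1L)
      i <- idx[sample.int(length(idx), 1L)]
      deme[i] <- 2L
    }
  }
  # mutations: Poisson(mu * L * branch length) per branch; each mutation a
  # new site; pairwise difference contribution of a branch with b tips
  # below is 2 b (n - b) / (n (n - 1))
  internal <- seg_tips < n          # branches above the MRCA carry no info
  muts <- rpois(length(seg_len), setup$mu * setup$L * seg_len)
  muts[!internal] <- 0L
  pi_sum <- sum(muts * 2 * seg_tips * (n - seg_tips)) / (n * (n - 1))
  structure(list(pi = pi_sum / setup$L,
                 segsites = sum(muts),
                 n_samples = n,
                 tree_length = sum(seg_len[internal])),
            class = "genetic_diversity")
}

#' Nucleotide diversity of an alignment
#'
#' Average number of pairwise differences per site among equal-length
#' sequences: `sum_{i<j} hamming(i, j) / choose(n, 2) / L`. Sites where
#' either sequence has a gap or ambiguity (anything outside ACGTacgt) are
#' still compared literally; supply clean alignments.
#'
#' @param alignment Character vector of sequences, a list of single
#'   sequences, or a `DNAbin` object from [ape::read.FASTA()].
#' @return Per-site nucleotide diversity (>= 0).
#' @export
#' @examples
#' nucleotide_diversity(c("ACGTACGTAA", "ACGTACGTAT"))  # 0.1
nucleotide_diversity <- function(alignment) {
  if (inherits(alignment, "DNAbin"))
    alignment <- vapply(as.character(as.list(alignment)),
                        paste, character(1), collapse = "")
  if (is.list(alignment)) alignment <- unlist(alignment)
  alignment <- toupper(as.character(alignment))
  n <- length(alignment)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  L <- unique(nchar(alignment))
  if (length(L) != 1L)
    stop("sequences must have equal length", call. = FALSE)
  mat <- do.call(rbind, strsplit(alignment, ""))
  total <- 0
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n))
      total <- total + sum(mat[i, ] != mat[j, ])
  total / choose(n, 2) / L
}

#' Per-species genetic diversities for a whole community
#'
#' Rescales every present species' forward-time history to a coalescent
#' model and simulates per-site nucleotide diversity. Species whose local
#' census (`abundance * alpha`) is below 2 are skipped; others are sampled
#' at `min(abundance * alpha, n_samples)` gene copies. In-situ species use
#' the metacommunity abundance of their ultimate metacommunity ancestor as
#' the source size.
#'
#' @param state A `local_state` after [run_assembly()].
#' @param meta The `metacommunity`.
#' @param params The [assembly_params()] used (supplies `J` and `alpha`).
#' @param n_samples,L,mu Sampling specification (defaults 10 gene copies,
#'   570 bp, 5e-7 per site per generation).
#' @param seed Optional seed.
#' @return A data.frame `species_id, pi, n_samples, segsites`.
#' @export
community_genetic_diversities <- function(state, meta, params,
                                          n_samples = 10, L = 570,
                                          mu = 5e-7, seed = NULL) {
  stopifnot(inherits(state, "local_state"))
  if (!is.null(seed)) set.seed(seed)
  h <- species_histories(state, present_only = TRUE)
  if (nrow(h) == 0L)
    return(data.frame(species_id = character(0), pi = numeric(0),
                      n_samples = integer(0), segsites = integer(0)))
  meta_ab <- .ancestral_meta_abundance(state, meta)
  out <- vector("list", nrow(h))
  for (i in seq_len(nrow(h))) {
    avail <- h$abundance[i] * params$alpha
    ns <- min(n_samples, avail)
    if (ns < 2) next
    setup <- tryCatch(
      rescale_history(h[i, ], J = params$J, alpha = params$alpha,
                      meta_abundance = meta_ab[[h$species_id[i]]],
                      elapsed_steps = state$step_count,
                      n_samples = ns, L = L, mu = mu),
      error = function(e)
        stop(sprintf("species %s: %s", h$species_id[i],
                     conditionMessage(e)), call. = FALSE))
    g <- simulate_species_pi(setup)
    out[[i]] <- data.frame(species_id = h$species_id[i], pi = g$pi,
                           n_samples = ns, segsites = g$segsites)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

# metacommunity abundance of each species' ultimate metacommunity ancestor
.ancestral_meta_abundance <- function(state, meta) {
  n <- length(state$labels)
  res <- numeric(n)
  for (i in seq_len(n)) {
    j <- i
    while (j > state$n_meta) j <- state$parent[j] + 1L
    res[i] <- as.numeric(meta$abundance[[j]])
  }
  setNames(as.list(res), state$labels)
}

#' Read per-species FASTA alignments and compute pi
#'
#' Each file `<dir>/<species_id>.fasta` (or `.fa`) is read with
#' [ape::read.FASTA()] and summarized by [nucleotide_diversity()].
#'
#' @param fasta_dir Directory of per-species FASTA files.
#' @return data.frame `species_id, pi, n_samples`.
#' @export
read_species_fasta_pi <- function(fasta_dir) {
  files <- list.files(fasta_dir, pattern = "\\.(fa|fasta)$",
                      full.names = TRUE)
  if (length(files) == 0L)
    stop("no FASTA files found in ", fasta_dir, call. = FALSE)
  res <- lapply(files, function(f) {
    aln <- tryCatch(ape::read.FASTA(f), error = function(e)
      stop(sprintf("malformed FASTA '%s': %s", f, conditionMessage(e)),
           call. = FALSE))
    data.frame(species_id = sub("\\.(fa|fasta)$", "", basename(f)),
               pi = nucleotide_diversity(aln),
               n_samples = length(aln))
  })
  do.call(rbind, res)
}
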