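#' Local community assembly parameters
#'
#' Parameters of the forward-time Moran process in the local community:
#' `J` demes, immigration probability `m` per replacement, point-mutation
#' speciation probability `nu` per birth, an assembly model (`neutral`,
#' `filtering`, or `competition`) with ecological strength `s_E` and (for
#' filtering) local trait optimum `z_E`, and the target proportional
#' approach to equilibrium `Lambda_target`.
#'
#' @param J Local community size in demes (integer >= 2).
#' @param m Immigration probability per replacement, in `[0, 1]`.
#' @param nu Speciation probability per birth, in `[0, 1]`.
#' @param model One of `"neutral"`, `"filtering"`, `"competition"`.
#' @param s_E Ecological strength (> 0); ignored when neutral. Scale of the
#'   Gaussian kernel converting squared trait distance into death weight.
#' @param z_E Local trait optimum (filtering only).
#' @param Lambda_target Target proportional equilibrium in `[0, 1]`.
#' @param init_mode `"monodominance"` (default: the community assembles
#'   from a founding population of the most abundant metacommunity
#'   species, so Lambda tracks genuine assembly progress) or
#'   `"metacommunity_sample"` (start at the neutral immigration
#'   equilibrium).
#' @param speciation_mode `"point_mutation"` or `"none"` (forces `nu = 0`).
#' @param alpha Individuals per deme (integer >= 1); consumed by the
#'   population-genetics rescaling, not by the forward process itself.
#' @param max_steps Guard on total Moran steps; exceeding it raises a
#'   nonconvergence error naming the Lambda reached.
#' @param seed Optional seed applied by [run_assembly()].
#' @return An object of class `assembly_params`.
#' @export
assembly_params <- function(J = 1000, m = 0.005, nu = 0,
                            model = c("neutral", "filtering", "competition"),
                            s_E = 10, z_E = 0, Lambda_target = 0.75,
                            init_mode = c("monodominance",
                                          "metacommunity_sample"),
                            speciation_mode = c("point_mutation", "none"),
                            alpha = 1000, max_steps = 1e8, seed = NULL) {
  model <- match.arg(model)
  init_mode <- match.arg(init_mode)
  speciation_mode <- match.arg(speciation_mode)
  J <- as.integer(J)
  if (is.na(J) || J < 2L) stop("J must be an integer >= 2", call. = FALSE)
  if (m < 0 || m > 1) stop("m must be in [0, 1]", call. = FALSE)
  if (nu < 0 || nu > 1) stop("nu must be in [0, 1]", call. = FALSE)
  if (Lambda_target < 0 || Lambda_target > 1)
    stop("Lambda_target must be in [0, 1]", call. = FALSE)
  if (model != "neutral" && (!is.numeric(s_E) || s_E <= 0))
    stop("s_E must be > 0 for non-neutral models", call. = FALSE)
  if (speciation_mode == "none") nu <- 0
  alpha <- as.integer(alpha)
  if (is.na(alpha) || alpha < 1L)
    stop("alpha must be an integer >= 1", call. = FALSE)
  structure(list(J = J, m = m, nu = nu, model = model, s_E = s_E, z_E = z_E,
                 Lambda_target = Lambda_target, init_mode = init_mode,
                 speciation_mode = speciation_mode, alpha = alpha,
                 max_steps = max_steps, seed = seed),
            class = "assembly_params")
}

.model_code <- function(model) {
  match(model, c("neutral", "filtering", "competition")) - 1L
}

#' Initialize the local community
#'
#' `monodominance` fills all `J` demes with the single most abundant
#' metacommunity species; `metacommunity_sample` draws `J` demes with
#' replacement with probability proportional to metacommunity abundance.
#' All founder flags start `TRUE`, so `Lambda = 0`. Initialization counts as
#' one colonization event per founding species (`first_colonization_step =
#' 0`, `colonization_count = 1`), and the initial abundances are recorded as
#' the first trajectory tick.
#'
#' @param meta A `metacommunity` object.
#' @param params An [assembly_params()] object.
#' @return An object of class `local_state`.
#' @export
initialize_local <- function(meta, params) {
  stopifnot(inherits(meta, "metacommunity"),
            inherits(params, "assembly_params"))
  S <- length(meta$abundance)
  J <- params$J
  if (params$init_mode == "monodominance") {
    top <- which.max(meta$abundance)
    demes <- rep.int(top - 1L, J)            # 0-based species index
  } else {
    demes <- sample.int(S, J, replace = TRUE,
                        prob = as.numeric(meta$abundance)) - 1L
  }
  count <- tabulate(demes + 1L, nbins = S)
  present <- count > 0L
  first_col <- ifelse(present, 0L, -1L)
  col_count <- ifelse(present, 1L, 0L)
  traj <- lapply(seq_len(S), function(i)
    if (present[i]) count[i] else integer(0))
  state <- list(
    labels = names(meta$abundance),
    demes = demes,
    founder = rep(TRUE, J),
    founder_derived = rep(TRUE, J),
    trait = as.numeric(meta$trait),
    count = count,
    origin = rep.int(0L, S),                  # 0 = immigrant pool species
    parent = rep.int(-1L, S),
    first_col = as.integer(first_col),
    col_count = as.integer(col_count),
    spec_step = rep.int(-1L, S),
    trajectories = traj,
    step_count = 0,
    replaced = 0L,
    J = J,
    n_meta = S)
  class(state) <- "local_state"
  state
}

#' @export
print.local_state <- function(x, ...) {
  cat("Local community: J =", x$J, "demes,",
      sum(x$count > 0), "species present\n")
  cat("  steps:", x$step_count, " Lambda:",
      round(progress_lambda(x), 4), "\n")
  invisible(x)
}

#' Proportional approach to equilibrium
#'
#' The fraction of information about the initial state of the community
#' that has been erased by assembly: one minus the fraction of demes whose
#' occupant still descends, through local births, from the founding
#' population. Immigration and in-situ speciation erase the founding
#' ancestry of a deme; local births propagate the parent deme's ancestry
#' tag (so a founder lineage can transiently re-expand). Lambda is 0 in a
#' fresh community, drifts upward on the immigration timescale
#' (`J * log(1 / (1 - Lambda)) / m` Moran steps in expectation under
#' neutrality), and 1 is absorbing once no deme traces to the founders.
#'
#' The raw never-replaced deme fraction (the fast turnover clock) remains
#' available as `turnover(state)`.
#'
#' @param state A `local_state`.
#' @return Numeric in `[0, 1]`.
#' @export
progress_lambda <- function(state) {
  stopifnot(inherits(state, "local_state"))
  1 - sum(state$founder_derived) / state$J
}

#' @rdname progress_lambda
#' @export
turnover <- function(state) {
  stopifnot(inherits(state, "local_state"))
  state$replaced / state$J
}

#' Per-deme death probabilities
#'
#' Neutral dynamics give every individual the same probability `1/J`.
#' Under environmental filtering the raw weight of an individual with trait
#' `z` is `1 - exp(-(z - z_E)^2 / s_E)` (death more likely far from the
#' optimum); under competition it is `exp(-(z - zbar)^2 / s_E)` where `zbar`
#' is the abundance-weighted local mean trait (death more likely near the
#' crowd). Raw weights are floored at `1e-12` and normalized to sum to one.
#'
#' @param state A `local_state`.
#' @param meta The `metacommunity` (unused under neutrality; traits are
#'   carried on the state).
#' @param params An [assembly_params()] object.
#' @return Numeric vector of length `J` summing to 1.
#' @export
death_weights <- function(state, meta, params) {
  stopifnot(inherits(state, "local_state"),
            inherits(params, "assembly_params"))
  J <- state$J
  if (params$model == "neutral") return(rep(1 / J, J))
  if (params$s_E <= 0)
    stop("s_E must be > 0 for non-neutral models", call. = FALSE)
  z <- state$trait[state$demes + 1L]
  if (params$model == "filtering") {
    w <- 1 - exp(-(z - params$z_E)^2 / params$s_E)
  } else {
    zbar <- sum(state$trait * state$count) / J
    w <- exp(-(z - zbar)^2 / params$s_E)
  }
  w <- pmax(w, 1e-12)
  w / sum(w)
}

# shared driver around the compiled engine
.run_engine <- function(state, meta, params, lambda_target, step_budget,
                        record_final) {
  sd_spec <- sqrt(meta$params$sigma2_M /
                    (meta$params$lambda * (1 + meta$params$epsilon)))
  cum <- cumsum(as.numeric(meta$abundance))
  cum <- cum / cum[length(cum)]
  res <- .assembly_run_cpp(
    state$demes, state$founder, state$trait, state$count, state$origin,
    state$parent, as.integer(state$first_col), state$col_count,
    as.integer(state$spec_step), state$trajectories, cum,
    .model_code(params$model), params$s_E, params$z_E,
    params$m, params$nu, sd_spec, lambda_target,
    params$max_steps, step_budget, max(1L, state$J %/% 2L),
    state$step_count, state$replaced, state$founder_derived, record_final)
  n_new <- length(res$count) - length(state$count)
  labels <- state$labels
  if (n_new > 0) {
    start <- length(state$count)
    labels <- c(labels, paste0("s", seq.int(start, length.out = n_new) -
                                 state$n_meta + 1L))
  }
  out <- state
  out$labels <- labels
  out$demes <- res$demes
  out$founder <- res$founder
  out$founder_derived <- res$founder_derived
  out$trait <- res$trait
  out$count <- res$count
  out$origin <- res$origin
  out$parent <- res$parent
  out$first_col <- res$first_col
  out$col_count <- res$col_count
  out$spec_step <- res$spec_step
  out$trajectories <- res$trajectories
  out$step_count <- res$step_count
  out$replaced <- res$replaced
  attr(out, "converged") <- res$converged
  out
}

#' Advance the local community by Moran steps
#'
#' Runs exactly `n` birth/death/colonization/speciation steps, ignoring the
#' Lambda target. Each step removes one individual (sampled by
#' [death_weights()]) and replaces it with an immigrant (probability `m`,
#' species sampled proportional to metacommunity abundance) or the offspring
#' of a uniformly chosen surviving local individual; each birth triggers
#' point-mutation speciation with probability `nu`.
#'
#' @param state A `local_state`.
#' @param meta The `metacommunity`.
#' @param params An [assembly_params()] object.
#' @param n Number of steps to take (default 1).
#' @return The updated `local_state`.
#' @export
assembly_step <- function(state, meta, params, n = 1) {
  stopifnot(inherits(state, "local_state"))
  .run_engine(state, meta, params, lambda_target = 2, step_budget = n,
              record_final = FALSE)
}

#' Run local assembly to a target Lambda
#'
#' Iterates the Moran process until `Lambda >= Lambda_target` or the
#' `max_steps` guard is exceeded (which raises an error naming the Lambda
#' reached). Abundance trajectories are recorded once per generation
#' (`J/2` steps), plus a final snapshot at termination.
#'
#' @param meta A `metacommunity`.
#' @param params An [assembly_params()] object.
#' @param state Optional pre-initialized `local_state` (defaults to
#'   [initialize_local()] under `params$init_mode`).
#' @return The final `local_state`; per-species forward-time histories are
#'   available through [species_histories()].
#' @export
run_assembly <- function(meta, params, state = NULL) {
  stopifnot(inherits(meta, "metacommunity"),
            inherits(params, "assembly_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  if (is.null(state)) state <- initialize_local(meta, params)
  out <- .run_engine(state, meta, params,
                     lambda_target = params$Lambda_target,
                     step_budget = -1, record_final = TRUE)
  if (!isTRUE(attr(out, "converged")))
    stop(sprintf(
      "assembly did not reach Lambda_target = %g within %g steps (Lambda = %g)",
      params$Lambda_target, params$max_steps, progress_lambda(out)),
      call. = FALSE)
  out
}

#' Per-species forward-time histories
#'
#' One row per species that was ever present locally: origin (immigrant from
#' the metacommunity vs in-situ point-mutation speciation), first
#' colonization step, number of distinct immigration arrivals, speciation
#' step and parent (for in-situ species), final local abundance, and the
#' recorded abundance trajectory.
#'
#' @param state A `local_state` after [run_assembly()].
#' @param present_only Keep only species with final abundance > 0
#'   (default TRUE).
#' @return A data.frame with a `trajectory` list-column.
#' @export
species_histories <- function(state, present_only = TRUE) {
  stopifnot(inherits(state, "local_state"))
  ever <- state$first_col >= 0 | state$origin == 1L
  keep <- if (present_only) ever & state$count > 0L else ever
  idx <- which(keep)
  par_lab <- rep(NA_character_, length(idx))
  has_par <- state$parent[idx] >= 0
  par_lab[has_par] <- state$labels[state$parent[idx][has_par] + 1L]
  data.frame(
    species_id = state$labels[idx],
    origin = ifelse(state$origin[idx] == 1L, "local_speciation",
                    "immigrant"),
    parent = par_lab,
    first_colonization_step = state$first_col[idx],
    speciation_step = state$spec_step[idx],
    colonization_count = state$col_count[idx],
    abundance = state$count[idx],
    trait = state$trait[idx],
    trajectory = I(state$trajectories[idx]),
    stringsAsFactors = FALSE)
}

#' Export per-species histories as TSV
#'
#' Writes `species_id  origin  first_colonization_step  colonization_count
#' trajectory...` with the trajectory comma-separated in one column.
#'
#' @param state A `local_state`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_species_histories <- function(state, path) {
  h <- species_histories(state, present_only = FALSE)
  h$trajectory <- vapply(h$trajectory, paste, character(1), collapse = ",")
  write.table(h, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Local phylogeny of in-situ radiations as newick
#'
#' Species born by point-mutation speciation bud off their parent lineage.
#' For every metacommunity species with in-situ descendants this returns a
#' newick string for the budding tree, with branch lengths in Moran steps
#' from the speciation event to the end of the run (or the next budding
#' event along the parent lineage).
#'
#' @param state A `local_state`.
#' @return Named character vector of newick strings (possibly empty).
#' @export
local_phylo_newick <- function(state) {
  stopifnot(inherits(state, "local_state"))
  kids <- split(which(state$origin == 1L) - 1L,
                state$parent[state$origin == 1L] + 1L)
  t_end <- state$step_count
  # recursive budding-tree construction for species s from time t0
  build <- function(s, t0) {
    ch <- kids[[as.character(s + 1L)]]
    ch <- ch[order(state$spec_step[ch + 1L])]
    lab <- state$labels[s + 1L]
    if (length(ch) == 0L)
      return(sprintf("%s:%g", lab, t_end - t0))
    t1 <- state$spec_step[ch[1] + 1L]
    rest <- .budding_rest(s, ch, 1L, state, t_end, kids)
    sprintf("(%s,%s):%g", rest, build(ch[1], t1), t1 - t0)
  }
  roots <- sort(unique(state$parent[state$origin == 1L]))
  roots <- roots[roots < state$n_meta & roots >= 0]
  # only metacommunity ancestors that themselves are not in-situ species
  out <- vapply(roots, function(r) paste0(build(r, 0), ";"), character(1))
  names(out) <- state$labels[roots + 1L]
  out
}

.budding_rest <- function(s, ch, i, state, t_end, kids) {
  lab <- state$labels[s + 1L]
  t_i <- state$spec_step[ch[i] + 1L]
  if (i == length(ch))
    return(sprintf("%s:%g", lab, t_end - t_i))
  t_next <- state$spec_step[ch[i + 1L] + 1L]
  inner <- .budding_rest(s, ch, i + 1L, state, t_end, kids)
  sub <- .local_build_child(ch[i + 1L], t_next, state, t_end, kids)
  sprintf("(%s,%s):%g", inner, sub, t_next - t_i)
}

.local_build_child <- function(s, t0, state, t_end, kids) {
  ch <- kids[[as.character(s + 1L)]]
  ch <- ch[order(state$spec_step[ch + 1L])]
  lab <- state$labels[s + 1L]
  if (length(ch) == 0L)
    return(sprintf("%s:%g", lab, t_end - t0))
  t1 <- state$spec_step[ch[1] + 1L]
  rest <- .budding_rest(s, ch, 1L, state, t_end, kids)
  sprintf("(%s,%s):%g", rest, .local_build_child(ch[1], t1, state, t_end,
                                                 kids), t1 - t0)
}
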