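# Configuration, simulation pipeline, empirical input and fixture
# generation: the plumbing between the simulator and the inference layer.

#' Prior specification
#'
#' @param kind One of `"uniform"`, `"uniform_int"`, `"loguniform"`,
#'   `"fixed"`, `"categorical"`.
#' @param lo,hi Bounds (finite; positive for log-uniform).
#' @param values Fixed value or category set.
#' @return An object of class `prior`.
#' @export
prior <- function(kind = c("uniform", "uniform_int", "loguniform", "fixed",
                           "categorical"), lo = NULL, hi = NULL,
                  values = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("uniform", "uniform_int", "loguniform")) {
    if (is.null(lo) || is.null(hi) || !is.finite(lo) || !is.finite(hi) ||
        hi < lo)
      stop("prior bounds must be finite with hi >= lo", call. = FALSE)
    if (kind == "loguniform" && lo <= 0)
      stop("log-uniform bounds must be > 0", call. = FALSE)
  } else if (is.null(values)) {
    stop("fixed/categorical priors need values", call. = FALSE)
  }
  structure(list(kind = kind, lo = lo, hi = hi, values = values),
            class = "prior")
}

#' @rdname prior
#' @param p A `prior` object.
#' @export
prior_draw <- function(p) {
  stopifnot(inherits(p, "prior"))
  switch(p$kind,
         uniform = runif(1, p$lo, p$hi),
         uniform_int = sample(seq.int(p$lo, p$hi), 1L),
         loguniform = exp(runif(1, log(p$lo), log(p$hi))),
         fixed = p$values,
         categorical = p$values[[sample.int(length(p$values), 1L)]])
}

#' Default pipeline priors
#'
#' The default prior set over the free model parameters: integer-uniform
#' `J` in 500-10000 demes, log-uniform `alpha` in 10-10000 individuals per
#' deme, log-uniform `m` in 1e-4 to 1e-1, uniform `nu` in 0 to 5e-3,
#' log-uniform `s_E` in 0.01-100, uniform `Lambda` in 0-1, and a uniform
#' categorical assembly model. All overridable via `...`.
#'
#' @param ... Named `prior` objects (or scalars, treated as fixed)
#'   overriding the defaults.
#' @return Named list of priors.
#' @export
pipeline_priors <- function(...) {
  pr <- list(
    model = prior("categorical",
                  values = c("neutral", "filtering", "competition")),
    J = prior("uniform_int", 500, 10000),
    alpha = prior("loguniform", 10, 10000),
    m = prior("loguniform", 1e-4, 1e-1),
    nu = prior("uniform", 0, 5e-3),
    s_E = prior("loguniform", 0.01, 100),
    Lambda = prior("uniform", 0, 1))
  over <- list(...)
  for (nm in names(over)) {
    v <- over[[nm]]
    pr[[nm]] <- if (inherits(v, "prior")) v else prior("fixed", values = v)
  }
  pr
}

#' Pipeline run configuration
#'
#' Bundles priors over the free parameters, the fixed metacommunity
#' parameters, the genetic sampling specification, the simulation count and
#' the master seed.
#'
#' @param n_sims Number of simulations to perform.
#' @param priors Named list from [pipeline_priors()].
#' @param S_M,J_M,lambda,epsilon,sigma2_M Metacommunity parameters (see
#'   [metacommunity_params()]).
#' @param z_E Local trait optimum for filtering.
#' @param mu,L,n_samples Genetic sampling spec (per-site mutation rate,
#'   locus length, gene copies per species).
#' @param init_mode Local initialization mode.
#' @param axes Data axes to include in the summary vectors.
#' @param max_steps Per-simulation Moran step guard.
#' @param seed Master seed; row `i` runs under seed `(seed + i) mod 2^31`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_sims = 100, priors = pipeline_priors(),
                       S_M = 500, J_M = 500000, lambda = 1, epsilon = 0,
                       sigma2_M = 2, z_E = 0, mu = 5e-7, L = 570,
                       n_samples = 10,
                       init_mode = "monodominance",
                       axes = c("abundance", "pi", "trait"),
                       max_steps = 2e7, seed = 1) {
  stopifnot(all(vapply(priors, inherits, logical(1), "prior")))
  needed <- c("model", "J", "alpha", "m", "nu", "s_E", "Lambda")
  miss <- setdiff(needed, names(priors))
  if (length(miss) > 0)
    stop("missing prior(s): ", paste(miss, collapse = ", "), call. = FALSE)
  structure(list(n_sims = as.integer(n_sims), priors = priors, S_M = S_M,
                 J_M = J_M, lambda = lambda, epsilon = epsilon,
                 sigma2_M = sigma2_M, z_E = z_E, mu = mu, L = L,
                 n_samples = n_samples, init_mode = init_mode, axes = axes,
                 max_steps = max_steps, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a flat key = value file
#'
#' Lines are `key = value`; `#` starts a comment. Values may be numbers,
#' bare strings, or prior specifications written as `uniform(a, b)`,
#' `uniform_int(a, b)`, `loguniform(a, b)`, `fixed(x)`, or
#' `categorical(a, b, c)`. Keys matching free parameters set priors; all
#' other keys set the matching [run_config()] field.
#'
#' @param path Config file path.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (i in seq_along(lines)) {
    parts <- regmatches(lines[i], regexpr("=", lines[i]), invert = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("config parse error at line %d: '%s'", i, lines[i]),
           call. = FALSE)
    kv[[trimws(parts[1])]] <- .parse_config_value(trimws(parts[2]))
  }
  free <- c("model", "J", "alpha", "m", "nu", "s_E", "Lambda")
  pr_over <- kv[names(kv) %in% free]
  pr_over <- lapply(pr_over, function(v)
    if (inherits(v, "prior")) v else prior("fixed", values = v))
  priors <- do.call(pipeline_priors, pr_over)
  rest <- kv[!(names(kv) %in% free)]
  allowed <- setdiff(names(formals(run_config)), "priors")
  bad <- setdiff(names(rest), allowed)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(run_config, c(rest, list(priors = priors)))
}

.parse_config_value <- function(s) {
  m <- regmatches(s, regexec(
    "^(uniform_int|uniform|loguniform|fixed|categorical)\\((.*)\\)$", s))[[1]]
  if (length(m) == 3L) {
    kind <- m[2]
    args <- trimws(strsplit(m[3], ",")[[1]])
    if (kind == "categorical") return(prior("categorical", values = args))
    nums <- suppressWarnings(as.numeric(args))
    if (kind == "fixed") {
      return(prior("fixed",
                   values = if (anyNA(nums)) args[1] else nums[1]))
    }
    if (anyNA(nums) || length(nums) != 2L)
      stop("bad prior bounds in '", s, "'", call. = FALSE)
    return(prior(kind, nums[1], nums[2]))
  }
  n <- suppressWarnings(as.numeric(s))
  if (!is.na(n)) return(n)
  s
}

#' Draw one parameter vector from the priors
#'
#' @param config A `run_config`.
#' @return Named list theta.
#' @export
draw_theta <- function(config) {
  th <- lapply(config$priors, prior_draw)
  th$J <- max(2L, as.integer(round(th$J)))
  th
}

#' Simulate one community and summarize it
#'
#' Builds a metacommunity, assembles the local community to the target
#' Lambda, simulates per-species genetic diversity, and assembles the
#' summary vector. Uses the current RNG state (seed upstream).
#'
#' @param theta Named list with `model`, `J`, `alpha`, `m`, `nu`, `s_E`,
#'   `Lambda`.
#' @param config A `run_config` supplying the fixed parameters.
#' @param keep_community Also return the state / pi table (for fixtures).
#' @return List with `theta`, `stats` (a `summary_vector`), and optionally
#'   `meta`, `state`, `pi_table`.
#' @export
simulate_one <- function(theta, config, keep_community = FALSE) {
  meta <- build_metacommunity(metacommunity_params(
    S_M = config$S_M, J_M = config$J_M, lambda = config$lambda,
    epsilon = config$epsilon, sigma2_M = config$sigma2_M))
  ap <- assembly_params(
    J = theta$J, m = theta$m, nu = theta$nu, model = theta$model,
    s_E = theta$s_E, z_E = config$z_E, Lambda_target = theta$Lambda,
    init_mode = config$init_mode, alpha = max(1L, round(theta$alpha)),
    max_steps = config$max_steps)
  state <- run_assembly(meta, ap)
  pi_tab <- NULL
  if ("pi" %in% config$axes)
    pi_tab <- community_genetic_diversities(
      state, meta, ap, n_samples = config$n_samples, L = config$L,
      mu = config$mu)
  stats <- summarize_community(state, meta, pi_tab, axes = config$axes)
  out <- list(theta = theta, stats = stats)
  if (keep_community) {
    out$meta <- meta
    out$state <- state
    out$pi_table <- pi_tab
  }
  out
}

# default simulator used by posterior_predictive_check: theta at point
# estimates, everything else from the config
.pps_default_sim <- function(theta, seed, config = run_config()) {
  set.seed(seed)
  th <- list(model = theta$model,
             J = max(2L, as.integer(round(theta$J))),
             alpha = theta$alpha, m = min(1, max(0, theta$m)),
             nu = min(1, max(0, theta$nu)),
             s_E = max(1e-6, theta$s_E),
             Lambda = min(1, max(0, theta$Lambda)))
  simulate_one(th, config)$stats
}

.theta_cols <- c("model", "J", "alpha", "m", "nu", "s_E", "Lambda")

#' Run the simulation pipeline
#'
#' For each of `n_sims` draws: sample theta from the priors, simulate, and
#' append one row (parameter columns then statistic columns) to the
#' training table. Per-row seeds derive from the master seed plus the row
#' index, so a fixed master seed gives an identical table and an
#' interrupted run can resume: with `path` given and `append = TRUE`,
#' already-present rows are skipped.
#'
#' @param config A `run_config`.
#' @param path Optional TSV output (written incrementally, append-safe).
#' @param quiet Suppress the progress line.
#' @return The training table (data.frame); the number of failed
#'   simulations is in `attr(, "n_failed")`.
#' @export
run_simulations <- function(config, path = NULL, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  header <- c("row", .theta_cols, summary_stat_names())
  done <- integer(0)
  if (!is.null(path) && file.exists(path)) {
    prev <- read.delim(path, stringsAsFactors = FALSE)
    done <- prev$row
  } else if (!is.null(path)) {
    writeLines(paste(header, collapse = "\t"), path)
  }
  rows <- vector("list", config$n_sims)
  n_failed <- 0L
  for (i in seq_len(config$n_sims)) {
    if (i %in% done) next
    set.seed((config$seed + i) %% (2^31 - 1))
    th <- draw_theta(config)
    if (!quiet)
      message(sprintf(
        "sim %d: model=%s J=%d alpha=%.3g m=%.3g nu=%.3g s_E=%.3g Lambda=%.3g",
        i, th$model, th$J, th$alpha, th$m, th$nu, th$s_E, th$Lambda))
    res <- tryCatch(simulate_one(th, config), error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1L
      if (!quiet)
        message(sprintf("sim %d failed: %s", i, conditionMessage(res)))
      next
    }
    row <- data.frame(row = i, as.data.frame(th[.theta_cols]),
                      as.data.frame(as.list(res$stats)))
    names(row) <- header
    rows[[i]] <- row
    if (!is.null(path))
      write.table(row, path, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE, append = TRUE)
    if (!quiet && i %% 50 == 0)
      message(sprintf("  %d / %d simulations", i, config$n_sims))
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (!is.null(path)) {
    tab <- read.delim(path, stringsAsFactors = FALSE)
  } else if (is.null(tab)) {
    tab <- as.data.frame(setNames(rep(list(numeric(0)), length(header)),
                                  header))
  }
  attr(tab, "n_failed") <- n_failed
  tab
}

#' Read a training table written by [run_simulations()]
#'
#' @param path TSV path.
#' @return data.frame with parameter and statistic columns.
#' @export
read_training_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c(.theta_cols, summary_stat_names())
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("training table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  tab
}

#' Read an empirical community table
#'
#' The table is TSV with a `species_id` column and any of `abundance`,
#' `trait`, `pi`; per-species nucleotide diversity can instead be computed
#' from single-locus FASTA alignments named `<species_id>.fasta` in
#' `fasta_dir`. Multivariate traits must be reduced to one column by the
#' user beforehand (e.g. the species score on the first principal
#' component).
#'
#' @param table_path Path to the TSV.
#' @param fasta_dir Optional directory of per-species FASTA files.
#' @param meta_traits Optional regional trait values (enables the
#'   regional-vs-local trait deltas).
#' @return List with `stats` (a `summary_vector`), `mask`, and the parsed
#'   per-species `table`.
#' @export
read_empirical <- function(table_path, fasta_dir = NULL,
                           meta_traits = NULL) {
  if (!file.exists(table_path))
    stop("empirical table not found: ", table_path, call. = FALSE)
  raw <- readLines(table_path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  nf <- lengths(strsplit(raw, "\t", fixed = TRUE))
  if (length(unique(nf)) != 1L)
    stop(sprintf("malformed TSV at line %d: expected %d fields, got %d",
                 which(nf != nf[1])[1], nf[1],
                 nf[which(nf != nf[1])[1]]), call. = FALSE)
  tab <- read.delim(table_path, stringsAsFactors = FALSE)
  if (!"species_id" %in% names(tab))
    stop("empirical table needs a species_id column", call. = FALSE)
  if (anyDuplicated(tab$species_id))
    stop("species_id values must be unique", call. = FALSE)
  if (!is.null(fasta_dir) && !"pi" %in% names(tab)) {
    pi_tab <- read_species_fasta_pi(fasta_dir)
    tab$pi <- pi_tab$pi[match(tab$species_id, pi_tab$species_id)]
  }
  axes_present <- intersect(c("abundance", "trait", "pi"), names(tab))
  if (length(axes_present) == 0L)
    stop("empirical table has no data axis (abundance / trait / pi)",
         call. = FALSE)
  stats <- assemble_summary_vector(
    abundances = if ("abundance" %in% names(tab)) tab$abundance,
    pis = if ("pi" %in% names(tab)) tab$pi,
    traits = if ("trait" %in% names(tab)) tab$trait,
    meta_traits = meta_traits)
  list(stats = stats, mask = attr(stats, "mask"), table = tab)
}

#' Generate a self-contained empirical-format fixture
#'
#' Simulates one community with a known parameter vector, exports it in the
#' empirical TSV format (`community.tsv`), and writes the generating
#' parameters alongside (`truth.tsv`) for recovery tests.
#'
#' @param scenario Assembly model of the generating run.
#' @param size `"tiny"` (fast smoke tests) or `"small"`.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @param config Optional `run_config` template; scenario and size
#'   override its model and problem sizes.
#' @return Invisible list with `community` and `truth` file paths, plus
#'   the `theta` used.
#' @export
generate_fixture <- function(scenario = c("neutral", "filtering",
                                          "competition"),
                             size = c("tiny", "small"), seed = 1,
                             dir = tempfile("fixture"), config = NULL) {
  scenario <- match.arg(scenario)
  size <- match.arg(size)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  if (is.null(config)) {
    dims <- switch(size,
                   tiny = list(S_M = 80, J_M = 20000, J = 300),
                   small = list(S_M = 200, J_M = 100000, J = 1000))
    config <- run_config(S_M = dims$S_M, J_M = dims$J_M, seed = seed)
    Jfix <- dims$J
  } else {
    Jfix <- prior_draw(config$priors$J)
  }
  theta <- list(model = scenario, J = as.integer(Jfix), alpha = 500,
                m = 0.005, nu = 5e-4, s_E = 10, Lambda = 0.75)
  res <- simulate_one(theta, config, keep_community = TRUE)
  present <- which(res$state$count > 0L)
  tab <- data.frame(species_id = res$state$labels[present],
                    abundance = res$state$count[present],
                    trait = res$state$trait[present])
  if (!is.null(res$pi_table)) {
    tab$pi <- res$pi_table$pi[match(tab$species_id,
                                    res$pi_table$species_id)]
    tab <- tab[is.finite(tab$pi), , drop = FALSE]
  }
  community <- file.path(dir, "community.tsv")
  truth <- file.path(dir, "truth.tsv")
  write.table(tab, community, sep = "\t", quote = FALSE, row.names = FALSE)
  tdf <- as.data.frame(theta)
  write.table(tdf, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(community = community, truth = truth, theta = theta,
                 meta = res$meta))
}
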