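#' Hill number of a proportion vector
#'
#' The effective number of equally abundant categories of order `q`:
#' `(sum p_i^q)^(1/(1-q))` for `q != 1`, and `exp(-sum p_i log p_i)`
#' (the exponential of Shannon entropy) in the `q -> 1` limit.
#' Zero-probability entries are dropped.
#'
#' @param proportions Non-negative vector summing to 1 (tolerance 1e-9).
#' @param q Order (>= 0).
#' @return The Hill number (between 1 and the number of positive entries).
#' @export
#' @examples
#' hill_number(rep(1/8, 8), 2)       # 8
#' hill_number(c(0.75, 0.25), 2)     # 1.6
hill_number <- function(proportions, q) {
  p <- proportions[proportions > 0]
  if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must be non-negative and sum to 1", call. = FALSE)
  if (q < 0) stop("q must be >= 0", call. = FALSE)
  if (abs(q - 1) < 1e-9) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

#' Hill number of a genetic-diversity distribution
#'
#' Applies [hill_number()] to per-species nucleotide diversities normalized
#' to proportions (`p_i = pi_i / sum(pi)`), quantifying the effective number
#' of equally genetically diverse species.
#'
#' @param pi_values Non-negative vector with at least one positive entry.
#' @param q Order.
#' @return The genetic Hill number, or an error when all pi are zero (the
#'   caller maps this to the missing marker).
#' @export
genetic_hill <- function(pi_values, q) {
  if (any(pi_values < 0)) stop("pi must be >= 0", call. = FALSE)
  s <- sum(pi_values)
  if (s <= 0)
    stop("all pi values are zero; genetic Hill number undefined",
         call. = FALSE)
  hill_number(pi_values / s, q)
}

#' Functional (trait) Hill number
#'
#' Attribute-diversity Hill number over pairwise trait distances
#' `d_ij = |t_i - t_j|` with abundance proportions `p`: with
#' `Q = sum_ij d_ij p_i p_j`,
#' `qFD = (sum_ij (d_ij / Q) (p_i p_j)^q)^(1 / (2 (1 - q)))` for `q != 1`,
#' and the continuous limit at `q = 1`. Invariant to rescaling all traits by
#' a common factor. Undefined (error) when all traits are identical
#' (`Q = 0`).
#'
#' @param traits Numeric trait values, one per species.
#' @param abundances Non-negative abundances (converted to proportions).
#' @param q Order.
#' @return The functional Hill number.
#' @export
functional_hill <- function(traits, abundances, q) {
  stopifnot(length(traits) == length(abundances))
  if (length(traits) < 2L)
    stop("need at least 2 species", call. = FALSE)
  keep <- abundances > 0
  traits <- traits[keep]; abundances <- abundances[keep]
  p <- abundances / sum(abundances)
  d <- abs(outer(traits, traits, "-"))
  pp <- outer(p, p)
  Q <- sum(d * pp)
  if (Q <= 0)
    stop("all trait values identical; functional Hill number undefined",
         call. = FALSE)
  if (abs(q - 1) < 1e-9) {
    nz <- pp > 0
    return(exp(-0.5 * sum((d[nz] / Q) * pp[nz] * log(pp[nz]))))
  }
  sum((d / Q) * pp^q)^(1 / (2 * (1 - q)))
}

#' First four moments of a distribution
#'
#' Mean, population standard deviation (`sqrt(m2)`), Fisher skewness
#' (`m3 / m2^1.5`) and excess kurtosis (`m4 / m2^2 - 3`), with the
#' convention that skewness and kurtosis of a constant vector are 0.
#'
#' @param values Nonempty numeric vector.
#' @return Named vector `mean, sd, skew, kurt`.
#' @export
dist_moments <- function(values) {
  if (length(values) == 0L) stop("empty vector", call. = FALSE)
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 <= 0)
    return(c(mean = m, sd = 0, skew = 0, kurt = 0))
  c(mean = m,
    sd = sqrt(m2),
    skew = e1071::skewness(values, type = 1),
    kurt = e1071::kurtosis(values, type = 1))
}

#' Regional-vs-local trait deltas
#'
#' `delta_mu = mean(meta) - mean(local)` and
#' `delta_sigma = sd(meta) - sd(local)`, both unweighted across species
#' (species-level trait lists), with population standard deviations.
#' Positive `delta_sigma` means less trait variation locally than
#' regionally (the environmental-filtering signature); negative means more
#' (the competition signature).
#'
#' @param local_traits Trait values of locally present species.
#' @param meta_traits Trait values of all metacommunity species.
#' @return Named vector `delta_mu_trait, delta_sigma_trait`.
#' @export
trait_deltas <- function(local_traits, meta_traits) {
  if (length(local_traits) == 0L || length(meta_traits) == 0L)
    stop("empty trait set", call. = FALSE)
  psd <- function(x) sqrt(mean((x - mean(x))^2))
  c(delta_mu_trait = mean(meta_traits) - mean(local_traits),
    delta_sigma_trait = psd(meta_traits) - psd(local_traits))
}

#' Spearman correlations among the data axes
#'
#' Pairwise Spearman rank correlations (average-rank tie handling) among
#' abundance, pi, and the trait variable `|t_i - tbar_local|` (absolute
#' deviation from the local mean trait). Needs at least 3 species with both
#' axes observed; otherwise the corresponding entry is `NA`.
#'
#' @param abundance,pi,traits Per-species vectors, aligned; any may be NULL.
#' @param local_trait_mean Mean trait used to center the trait variable
#'   (defaults to `mean(traits)`).
#' @return Named vector `rho_abundance_pi, rho_abundance_trait,
#'   rho_pi_trait`.
#' @export
rank_correlations <- function(abundance = NULL, pi = NULL, traits = NULL,
                              local_trait_mean = NULL) {
  tdev <- NULL
  if (!is.null(traits)) {
    if (is.null(local_trait_mean)) local_trait_mean <- mean(traits)
    tdev <- abs(traits - local_trait_mean)
  }
  rho <- function(x, y) {
    if (is.null(x) || is.null(y) || length(x) != length(y))
      return(NA_real_)
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) return(NA_real_)
    suppressWarnings(cor(x[ok], y[ok], method = "spearman"))
  }
  c(rho_abundance_pi = rho(abundance, pi),
    rho_abundance_trait = rho(abundance, tdev),
    rho_pi_trait = rho(pi, tdev))
}

#' Canonical summary-statistic names
#'
#' The fixed field order of the community summary vector: richness, then
#' four moments and four Hill numbers per axis (abundance, pi, trait), the
#' three cross-axis Spearman correlations, and the two regional-vs-local
#' trait deltas.
#'
#' @return Character vector of statistic names.
#' @export
summary_stat_names <- function() {
  c("S",
    paste0("abundance_", c("mean", "sd", "skew", "kurt")),
    paste0("D", 1:4),
    paste0("pi_", c("mean", "sd", "skew", "kurt")),
    paste0("GD", 1:4),
    paste0("trait_", c("mean", "sd", "skew", "kurt")),
    paste0("FD", 1:4),
    "rho_abundance_pi", "rho_abundance_trait", "rho_pi_trait",
    "delta_mu_trait", "delta_sigma_trait")
}

#' Assemble the community summary vector
#'
#' Computes the full fixed-order statistic vector across the available data
#' axes. Statistics that touch an absent axis (or that are undefined, e.g.
#' Hill numbers of an all-zero pi distribution) carry `NA`, the explicit
#' missing marker; the availability mask is recorded as an attribute and
#' must match between training and prediction.
#'
#' @param abundances Per-species local abundances (or NULL).
#' @param pis Per-species nucleotide diversities (or NULL), aligned with
#'   `abundances` where both are given.
#' @param traits Per-species local trait values (or NULL).
#' @param meta_traits Metacommunity trait values (needed for the deltas).
#' @param log_moments Compute the abundance and pi moments on
#'   `log1p`-transformed values instead of raw values (off by default;
#'   Hill numbers, correlations and deltas are unaffected).
#' @return Named numeric vector of class `summary_vector` with attribute
#'   `mask` (named logical: axis available?).
#' @export
assemble_summary_vector <- function(abundances = NULL, pis = NULL,
                                    traits = NULL, meta_traits = NULL,
                                    log_moments = FALSE) {
  have <- c(abundance = !is.null(abundances) && length(abundances) > 0,
            pi = !is.null(pis) && length(pis) > 0,
            trait = !is.null(traits) && length(traits) > 0)
  if (!any(have)) stop("all data axes absent", call. = FALSE)
  S <- max(length(abundances), length(pis), length(traits))
  out <- setNames(rep(NA_real_, length(summary_stat_names())),
                  summary_stat_names())
  out["S"] <- S
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  mom_in <- function(x) if (log_moments) log1p(x) else x
  if (have["abundance"]) {
    out[paste0("abundance_", c("mean", "sd", "skew", "kurt"))] <-
      dist_moments(mom_in(abundances))
    p <- abundances / sum(abundances)
    for (q in 1:4) out[paste0("D", q)] <- safe(hill_number(p, q))
  }
  if (have["pi"]) {
    pi_ok <- pis[is.finite(pis)]
    if (length(pi_ok) > 0) {
      out[paste0("pi_", c("mean", "sd", "skew", "kurt"))] <-
        dist_moments(mom_in(pi_ok))
      for (q in 1:4) out[paste0("GD", q)] <- safe(genetic_hill(pi_ok, q))
    }
  }
  if (have["trait"]) {
    out[paste0("trait_", c("mean", "sd", "skew", "kurt"))] <-
      dist_moments(traits)
    ab_w <- if (have["abundance"]) abundances else rep(1, length(traits))
    for (q in 1:4)
      out[paste0("FD", q)] <- safe(functional_hill(traits, ab_w, q))
    if (!is.null(meta_traits))
      out[c("delta_mu_trait", "delta_sigma_trait")] <-
        trait_deltas(traits, meta_traits)
  }
  # correlations need per-species alignment across axes; pairs with
  # mismatched lengths or missing axes come back NA from rank_correlations
  out[c("rho_abundance_pi", "rho_abundance_trait", "rho_pi_trait")] <-
    rank_correlations(
      abundance = if (have["abundance"]) abundances,
      pi = if (have["pi"]) pis,
      traits = if (have["trait"]) traits)
  structure(out, mask = have, class = c("summary_vector", "numeric"))
}

#' Summarize a simulated community
#'
#' Convenience wrapper: pulls local abundances and traits from a
#' `local_state`, joins per-species pi values, and calls
#' [assemble_summary_vector()].
#'
#' @param state A `local_state` after [run_assembly()].
#' @param meta The `metacommunity`.
#' @param pi_table Output of [community_genetic_diversities()] (or NULL to
#'   skip the genetic axis).
#' @param axes Character subset of `c("abundance", "pi", "trait")` to keep.
#' @return A `summary_vector`.
#' @export
summarize_community <- function(state, meta, pi_table = NULL,
                                axes = c("abundance", "pi", "trait")) {
  stopifnot(inherits(state, "local_state"))
  present <- which(state$count > 0L)
  ab <- state$count[present]
  tr <- state$trait[present]
  ids <- state$labels[present]
  pis <- NULL
  if (!is.null(pi_table) && nrow(pi_table) > 0) {
    # aligned with `ids`; species too rare to sample stay NA and are
    # dropped inside the moment/Hill computations and correlations
    pis <- setNames(rep(NA_real_, length(ids)), ids)
    pis[pi_table$species_id] <- pi_table$pi
    pis <- unname(pis)
  }
  assemble_summary_vector(
    abundances = if ("abundance" %in% axes) ab,
    pis = if ("pi" %in% axes) pis,
    traits = if ("trait" %in% axes) tr,
    meta_traits = if ("trait" %in% axes) as.numeric(meta$trait))
}
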