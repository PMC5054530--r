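#' X-chromosome mutation rate from the autosomal rate
#'
#' The autosomal per-site per-year mutation rate divided by the
#' autosome-to-X rate ratio.
#'
#' @param mu_autosome_per_year Autosomal mutation rate, per site per year.
#' @param autosome_to_x_ratio How much faster autosomes mutate than the X.
#' @return The X-linked rate, per site per year.
#' @examples
#' x_mutation_rate(2.2e-9, 1.3) # 1.692e-9
#' @export
x_mutation_rate <- function(mu_autosome_per_year, autosome_to_x_ratio) {
  if (!is.finite(autosome_to_x_ratio) || autosome_to_x_ratio <= 0) {
    abort("autosome_to_x_ratio must be positive")
  }
  if (!is.finite(mu_autosome_per_year) || mu_autosome_per_year <= 0) {
    abort("mu_autosome_per_year must be positive")
  }
  mu_autosome_per_year / autosome_to_x_ratio
}

#' Demography for the two-population split model
#'
#' Parameters of the neutral null model used by the drift test: two extant
#' populations that split from a common ancestor, each with its own
#' effective (chromosome-count) population size.  The defaults are the
#' high/low-altitude dog demography used throughout the package: split
#' 3,400 years ago, ancestral Ne 37,800, extant Ne 4,058 (high-altitude
#' population) and 8,681 (low-altitude), X-linked mutation rate
#' `x_mutation_rate(2.2e-9, 1.3)` per site per year, and a 3-year dog
#' generation time (per-year rates must be converted to generations; the
#' generation time is a modelling choice, exposed here).
#'
#' @param ne_pop1,ne_pop2,ne_anc Effective population sizes (chromosomes).
#' @param split_time_years Split time, years before present.
#' @param mu_per_site_year Mutation rate per site per year.
#' @param generation_time_years Generation time in years.
#' @param locus_length_bp Locus length L in bp.
#' @param n_sample_pop1,n_sample_pop2 Chromosomes sampled per population.
#' @param mode `"fixed_s"` (exactly `s_sites` segregating sites placed
#'   multinomially on branches, infinite-sites) or `"theta"` (Poisson with
#'   the mutation rate).
#' @param s_sites Number of segregating sites in `fixed_s` mode.
#' @return A list of class `demography_params` with the derived
#'   `split_time_generations` and per-generation mutation rate.
#' @export
demography_params <- function(ne_pop1 = 4058, ne_pop2 = 8681,
                              ne_anc = 37800, split_time_years = 3400,
                              mu_per_site_year = x_mutation_rate(2.2e-9, 1.3),
                              generation_time_years = 3,
                              locus_length_bp = 47544,
                              n_sample_pop1 = 15, n_sample_pop2 = 15,
                              mode = c("fixed_s", "theta"), s_sites = 108) {
  mode <- match.arg(mode)
  num <- c(ne_pop1 = ne_pop1, ne_pop2 = ne_pop2, ne_anc = ne_anc,
           mu = mu_per_site_year, gen = generation_time_years,
           L = locus_length_bp)
  if (any(!is.finite(num)) || any(num <= 0)) {
    abort("all demography parameters must be positive and finite")
  }
  if (split_time_years < 0) abort("split_time_years must be non-negative")
  if (mode == "fixed_s" && s_sites < 1) abort("fixed_s mode needs s_sites >= 1")
  if (n_sample_pop1 < 0 || n_sample_pop2 < 0 ||
      n_sample_pop1 + n_sample_pop2 < 2) {
    abort("need at least 2 sampled chromosomes in total")
  }
  structure(list(
    ne_pop1 = ne_pop1, ne_pop2 = ne_pop2, ne_anc = ne_anc,
    split_time_years = split_time_years,
    mu_per_site_year = mu_per_site_year,
    generation_time_years = generation_time_years,
    split_time_generations = split_time_years / generation_time_years,
    mu_per_site_generation = mu_per_site_year * generation_time_years,
    locus_length_bp = locus_length_bp,
    n_sample_pop1 = n_sample_pop1, n_sample_pop2 = n_sample_pop2,
    mode = mode, s_sites = if (mode == "fixed_s") s_sites else NA_integer_),
    class = "demography_params")
}

#' @exportS3Method base::print
print.demography_params <- function(x, ...) {
  cat(sprintf(
    paste0("<demography_params> split %g y (%g gen, %g y/gen); Ne %g/%g, ",
           "anc %g; mu %.4g /site/y; L %g bp; samples %d + %d; mode %s"),
    x$split_time_years, x$split_time_generations, x$generation_time_years,
    x$ne_pop1, x$ne_pop2, x$ne_anc, x$mu_per_site_year, x$locus_length_bp,
    x$n_sample_pop1, x$n_sample_pop2, x$mode),
    if (x$mode == "fixed_s") sprintf(" (S = %d)\n", x$s_sites) else "\n")
  invisible(x)
}

#' Simulate one replicate of the two-population split coalescent
#'
#' Standard neutral coalescent for an X-linked locus: within each extant
#' population, lineage pairs coalesce at rate \eqn{k(k-1)/2} per
#' \eqn{2 N_e} generations; at the split time (backwards) both lineage sets
#' merge into the ancestral population.  Mutations follow the infinite-sites
#' model, either exactly `s_sites` placed multinomially on branches
#' proportional to length (`fixed_s`) or Poisson with mean
#' total branch length x mu per generation x L (`theta`).  Every mutation
#' falls on a branch with between 1 and n-1 descendant tips, so every
#' segregating site is polymorphic in the pooled sample.
#'
#' @param params A [demography_params()] object.
#' @param seed Integer seed (required; a run is bit-reproducible given seed
#'   and parameters).
#' @return An object of class `sim_replicate`: list with `genotypes`
#'   (0/1 matrix, chromosomes x sites; first `n_sample_pop1` rows are
#'   population 1), `freq` (tibble of per-site derived-allele frequencies
#'   per population), `fst` (per-site Hudson Fst), `n_sites`,
#'   `total_branch_length` and `tmrca` (generations).
#' @export
simulate_split <- function(params, seed) {
  stopifnot(inherits(params, "demography_params"))
  if (missing(seed)) abort("an explicit seed is required")
  set.seed(seed)
  res <- .sim_split_cpp(
    params$n_sample_pop1, params$n_sample_pop2,
    params$ne_pop1, params$ne_pop2, params$ne_anc,
    params$split_time_generations,
    if (params$mode == "fixed_s") params$s_sites else -1L,
    params$mu_per_site_generation, params$locus_length_bp,
    TRUE)
  n1 <- params$n_sample_pop1
  n2 <- params$n_sample_pop2
  p1 <- res$derived1 / n1
  p2 <- if (n2 > 0) res$derived2 / n2 else rep(NA_real_, res$n_sites)
  geno <- t(res$genotypes)  # chromosomes x sites
  fst <- if (n2 >= 2 && n1 >= 2) {
    hudson_from_freq(p1, p2, n1, n2)
  } else {
    rep(NA_real_, res$n_sites)
  }
  structure(list(
    genotypes = geno,
    freq = tibble::tibble(site = seq_len(res$n_sites), p_pop1 = p1,
                          p_pop2 = p2),
    fst = fst,
    n_sites = res$n_sites,
    total_branch_length = res$total_branch_length,
    tmrca = res$tmrca,
    params = params, seed = seed),
    class = "sim_replicate")
}

hudson_from_freq <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ifelse(den > 0, num / den, NA_real_)
}

#' Drift-versus-selection test for a candidate region
#'
#' Simulates the neutral two-population split model `n_reps` times; per
#' replicate it computes the per-site Hudson Fst vector of the simulated
#' sample and (a) its mean and (b) a two-sided Welch t-test against the
#' observed Fst vector.  The headline empirical probability that drift alone
#' produces differentiation at least as strong as observed is
#' \deqn{P = \frac{1 + \#\{\bar F_{sim} \ge \bar F_{obs}\}}{n_{reps} + 1}}
#' (small-sample corrected so it is never exactly 0); the distribution of
#' per-replicate t-test p-values is returned alongside.
#'
#' @param observed_fst Observed per-SNP Fst for the region (NA dropped).
#' @param params A [demography_params()] object.
#' @param n_reps Number of neutral replicates (>= 100).
#' @param alpha Reference level used when summarising the t-test p's.
#' @param seed Integer seed.
#' @return An object of class `drift_test`: `empirical_probability`,
#'   `observed_mean_fst`, `mean_fst` (per-replicate), `t_p` (per-replicate),
#'   `frac_t_below_alpha`, `n_reps`, `n_redraws`, `alpha`, `params`, `seed`.
#' @export
drift_test <- function(observed_fst, params, n_reps = 10000, alpha = 0.05,
                       seed) {
  stopifnot(inherits(params, "demography_params"))
  if (missing(seed)) abort("an explicit seed is required")
  observed_fst <- observed_fst[is.finite(observed_fst)]
  if (length(observed_fst) == 0) abort("observed_fst has no finite values")
  if (n_reps < 100) abort("n_reps must be at least 100")
  if (params$n_sample_pop1 < 2 || params$n_sample_pop2 < 2) {
    abort("the drift test needs at least 2 chromosomes per population")
  }
  set.seed(seed)
  res <- .drift_reps_cpp(
    as.integer(n_reps),
    params$n_sample_pop1, params$n_sample_pop2,
    params$ne_pop1, params$ne_pop2, params$ne_anc,
    params$split_time_generations,
    if (params$mode == "fixed_s") params$s_sites else -1L,
    params$mu_per_site_generation, params$locus_length_bp,
    mean(observed_fst), stats::var(observed_fst), length(observed_fst))
  if (res$redraws > 0) {
    inform(paste0(res$redraws, " replicate(s) redrawn (no polymorphic site)"))
  }
  obs_mean <- mean(observed_fst)
  k <- sum(res$mean_fst >= obs_mean)
  structure(list(
    empirical_probability = (1 + k) / (n_reps + 1),
    observed_mean_fst = obs_mean,
    mean_fst = res$mean_fst,
    t_p = res$t_p,
    frac_t_below_alpha = mean(res$t_p < alpha, na.rm = TRUE),
    n_reps = as.integer(n_reps),
    n_redraws = res$redraws,
    alpha = alpha, params = params, seed = seed),
    class = "drift_test")
}

#' @exportS3Method base::print
print.drift_test <- function(x, ...) {
  cat(sprintf(
    paste0("<drift_test> observed mean Fst %.4f vs %d neutral replicates\n",
           "  P(drift gives mean Fst >= observed) = %.4g\n",
           "  per-replicate Welch t-test: %.1f%% of p-values < %g\n"),
    x$observed_mean_fst, x$n_reps, x$empirical_probability,
    100 * x$frac_t_below_alpha, x$alpha))
  invisible(x)
}

#' @export
tidy.drift_test <- function(x, ...) {
  tibble::tibble(
    empirical_probability = x$empirical_probability,
    observed_mean_fst = x$observed_mean_fst,
    mean_sim_fst = mean(x$mean_fst),
    frac_t_below_alpha = x$frac_t_below_alpha,
    n_reps = x$n_reps)
}

#' @export
glance.drift_test <- function(x, ...) tidy(x)
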