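test_that("X mutation rate arithmetic", {
  expect_equal(signif(x_mutation_rate(2.2e-9, 1.3), 4), 1.692e-9)
  expect_equal(x_mutation_rate(5e-9, 1), 5e-9)
  expect_equal(x_mutation_rate(4.4e-9, 2), 2.2e-9)
  expect_error(x_mutation_rate(2.2e-9, 0), "positive")
  expect_error(x_mutation_rate(-1, 1.3), "positive")
})

test_that("demography parameters derive generations and validate", {
  p <- demography_params()
  expect_equal(p$split_time_generations, 3400 / 3)
  expect_equal(p$mu_per_site_generation, x_mutation_rate(2.2e-9, 1.3) * 3)
  expect_error(demography_params(ne_pop1 = -1), "positive")
  expect_error(demography_params(n_sample_pop1 = 1, n_sample_pop2 = 0),
               "at least 2")
  expect_error(demography_params(mode = "fixed_s", s_sites = 0), "s_sites")
})

test_that("fixed-S replicates have exactly S sites, all polymorphic,
           and are bit-identical under the same seed", {
  p <- demography_params(n_sample_pop1 = 8, n_sample_pop2 = 7, s_sites = 50)
  r1 <- simulate_split(p, seed = 99)
  r2 <- simulate_split(p, seed = 99)
  expect_equal(r1$n_sites, 50)
  expect_identical(r1$genotypes, r2$genotypes)
  expect_identical(r1$fst, r2$fst)
  cs <- colSums(r1$genotypes)
  expect_true(all(cs >= 1 & cs <= 14)) # polymorphic in the pooled sample
  expect_equal(dim(r1$genotypes), c(15L, 50L))
  # frequencies in the replicate agree with the genotype matrix
  expect_equal(r1$freq$p_pop1, colMeans(r1$genotypes[1:8, ]))
  expect_equal(r1$freq$p_pop2, colMeans(r1$genotypes[9:15, ]))
})

test_that("no population structure at split time zero: mean Fst near 0", {
  p <- demography_params(ne_pop1 = 5000, ne_pop2 = 5000, ne_anc = 5000,
                         split_time_years = 0, s_sites = 50)
  set.seed(5)
  means <- vapply(1:500, function(i) {
    r <- simulate_split(p, seed = i)
    mean(r$fst, na.rm = TRUE)
  }, numeric(1))
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se + 0.01)
})

test_that("theta-mode segregating sites match Watterson's expectation", {
  # single population, constant size: E[S] = theta * L * a_{n-1}
  ne <- 1000; mu_gen <- 1e-8; L <- 5e4; n <- 15
  p <- demography_params(ne_pop1 = ne, ne_pop2 = ne, ne_anc = ne,
                         split_time_years = 0, mu_per_site_year = mu_gen,
                         generation_time_years = 1, locus_length_bp = L,
                         n_sample_pop1 = n, n_sample_pop2 = 0,
                         mode = "theta")
  S <- vapply(1:2000, function(i) simulate_split(p, seed = i)$n_sites,
              numeric(1))
  expected <- 4 * ne * mu_gen * L * sum(1 / seq_len(n - 1))
  se <- stats::sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("tree length matches the single-population closed form", {
  # E[total length] = 4 Ne a_{n-1} in the panmictic limit
  ne <- 2000; n <- 10
  p <- demography_params(ne_pop1 = ne, ne_pop2 = ne, ne_anc = ne,
                         split_time_years = 0, n_sample_pop1 = n,
                         n_sample_pop2 = 0, mode = "theta",
                         mu_per_site_year = 1e-9,
                         generation_time_years = 1)
  tl <- vapply(1:1500, function(i) {
    simulate_split(p, seed = i)$total_branch_length
  }, numeric(1))
  expected <- 4 * ne * sum(1 / seq_len(n - 1))
  se <- stats::sd(tl) / sqrt(length(tl))
  expect_lt(abs(mean(tl) - expected), 3 * se)
})

test_that("mean Fst increases strictly with split time", {
  p0 <- demography_params()
  gens <- c(0, 1e3, 5e3, 2e4)
  mean_fst <- vapply(gens, function(g) {
    p <- demography_params(split_time_years = g * p0$generation_time_years)
    set.seed(77)
    r <- xselscan:::.drift_reps_cpp(
      500L, p$n_sample_pop1, p$n_sample_pop2, p$ne_pop1, p$ne_pop2,
      p$ne_anc, p$split_time_generations, p$s_sites,
      p$mu_per_site_generation, p$locus_length_bp, 0.5, 0.01, 108L)
    mean(r$mean_fst)
  }, numeric(1))
  expect_true(all(diff(mean_fst) > 0))
})

test_that("simulated mean Fst agrees with an independent coalescent engine", {
  # cross-simulator oracle: msprime with the identical split demography
  p <- demography_params()
  script <- '
import msprime, numpy as np
dem = msprime.Demography()
dem.add_population(name="P1", initial_size=4058)
dem.add_population(name="P2", initial_size=8681)
dem.add_population(name="ANC", initial_size=37800)
dem.add_population_split(time=3400/3, derived=["P1", "P2"], ancestral="ANC")
reps = msprime.sim_ancestry(
    samples=[msprime.SampleSet(15, population="P1", ploidy=1),
             msprime.SampleSet(15, population="P2", ploidy=1)],
    demography=dem, sequence_length=47544, ploidy=2,
    num_replicates=400, random_seed=12345)
vals = []
for i, ts in enumerate(reps):
    mts = msprime.sim_mutations(ts, rate=1.692e-9*3, random_seed=i + 1,
                                discrete_genome=False)
    g = mts.genotype_matrix()
    if g.shape[0] == 0:
        continue
    p1 = g[:, :15].mean(axis=1); p2 = g[:, 15:].mean(axis=1)
    num = (p1-p2)**2 - p1*(1-p1)/14 - p2*(1-p2)/14
    den = p1*(1-p2) + p2*(1-p1)
    ok = den > 0
    if ok.sum() == 0:
        continue
    vals.append(np.mean(num[ok]/den[ok]))
print(np.mean(vals), np.std(vals)/np.sqrt(len(vals)))
'
  f <- file.path(tempdir(), "msprime_oracle.py")
  writeLines(script, f)
  out <- system2("python", f, stdout = TRUE, stderr = TRUE)
  nums <- as.numeric(strsplit(tail(out, 1), " ")[[1]])
  expect_false(anyNA(nums))
  p_theta <- demography_params(mode = "theta")
  set.seed(88)
  mine <- vapply(1:1000, function(i) {
    r <- simulate_split(p_theta, seed = i)
    if (r$n_sites == 0) return(NA_real_)
    mean(r$fst, na.rm = TRUE)
  }, numeric(1))
  mine <- mine[is.finite(mine)]
  se_mine <- stats::sd(mine) / sqrt(length(mine))
  tol <- 3 * sqrt(se_mine^2 + nums[2]^2)
  expect_lt(abs(mean(mine) - nums[1]), tol)
})

# a neutral draw carrying representative differentiation: because all sites
# of a replicate share one genealogy, single draws have very variable mean
# Fst, and amplifying a flat or negative draw plants no signal.  The rule --
# first seed from 1 upward whose mean Fst is within 20% of the null
# expectation -- is fixed and data-independent.
representative_neutral_draw <- function(p, e0) {
  for (s in 1:1000) {
    fst <- simulate_split(p, seed = s)$fst
    fst <- fst[is.finite(fst)]
    if (abs(mean(fst) - e0) < 0.2 * e0) return(fst)
  }
  stop("no representative draw found")
}

test_that("drift test: boundary, planted signal, and null behaviour", {
  p <- demography_params()
  neutral <- simulate_split(p, seed = 123)$fst
  neutral <- neutral[is.finite(neutral)]

  # observed smaller than every simulated mean -> probability ~ 1
  tiny <- rep(-0.5, 20)
  res_b <- drift_test(tiny, p, n_reps = 100, seed = 1)
  expect_equal(res_b$empirical_probability, 1, tolerance = 0.011)

  # a five-fold amplified (clipped to [0, 1]) representative neutral draw
  # gives differentiation that drift essentially never reaches
  e0 <- mean(drift_test(c(0.5, 0.5), p, n_reps = 2000, seed = 999)$mean_fst)
  inflated <- pmax(pmin(representative_neutral_draw(p, e0) * 5, 1), 0)
  res_i <- drift_test(inflated, p, n_reps = 10000, seed = 2)
  expect_lt(res_i$empirical_probability, 0.01)

  # neutral observed data give an unremarkable probability in a typical run
  res_n <- drift_test(neutral, p, n_reps = 1000, seed = 3)
  expect_gt(res_n$empirical_probability, 0.05)

  expect_error(drift_test(numeric(0), p, seed = 1), "no finite")
  expect_error(drift_test(neutral, p, n_reps = 10, seed = 1), "at least 100")
  expect_equal(res_n$n_reps, 1000L)
})
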