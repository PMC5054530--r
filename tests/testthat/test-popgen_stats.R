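test_that("sex-aware counts: females contribute 2 observations, males 1", {
  set.seed(11)
  sheet <- toy_sheet(5, 5)
  geno <- rand_geno(8, 15)
  vt <- make_vt(seq(100, 800, by = 100), geno, sheet)
  counts <- sex_aware_counts(vt, sheet, "P1")
  expect_true(all(counts$n_chr == 15)) # 5*2 + 5*1

  # all-female population, one sample missing at one site -> 2n - 2
  sheet_f <- toy_sheet(6, 0)
  geno_f <- rand_geno(3, 12)
  vt_f <- make_vt(c(10, 20, 30), geno_f, sheet_f)
  vt_f$hap1[2, 4] <- NA_integer_
  vt_f$hap2[2, 4] <- NA_integer_
  counts_f <- sex_aware_counts(vt_f, sheet_f, "P1")
  expect_equal(counts_f$n_chr, c(12L, 10L, 12L))

  expect_error(sex_aware_counts(vt, sheet, "nope"), "no samples")
})

test_that("sex-aware counts equal naive per-allele enumeration", {
  set.seed(12)
  for (rep in 1:5) {
    n_f <- sample(2:6, 1); n_m <- sample(0:5, 1)
    sheet <- toy_sheet(n_f, n_m)
    n_sites <- 20
    geno <- rand_geno(n_sites, 2 * n_f + n_m)
    vt <- make_vt(seq_len(n_sites) * 50, geno, sheet)
    # sprinkle missingness
    vt$hap1[sample(length(vt$hap1), 5)] <- NA_integer_
    counts <- sex_aware_counts(vt, sheet, "P1")
    for (s in seq_len(n_sites)) {
      obs <- c(vt$hap1[s, ], vt$hap2[s, sheet$sex == "female"])
      obs <- obs[!is.na(obs)]
      expect_equal(counts$n_chr[s], length(obs))
      expect_equal(counts$alt_count[s], sum(obs == 1))
    }
  }
})

test_that("windowed pi: monomorphic and single-pair cases", {
  sheet <- toy_sheet(1, 0) # one female = 2 chromosomes
  geno <- matrix(c(0L, 1L), nrow = 1) # one SNP, 1 ref / 1 alt
  vt <- make_vt(500, geno, sheet)
  track <- windowed_pi(vt, sheet, "P1", window_bp = 1000, chrom_length = 1000)
  expect_equal(track$pi, 1 / 1000)
  expect_equal(track$n_snps, 1L)

  geno0 <- matrix(c(0L, 0L), nrow = 1) # monomorphic
  vt0 <- make_vt(500, geno0, sheet)
  expect_equal(
    windowed_pi(vt0, sheet, "P1", 1000, chrom_length = 1000)$pi, 0)
})

test_that("windowed pi equals brute-force mean pairwise differences", {
  set.seed(13)
  for (rep in 1:50) {
    n_f <- sample(2:5, 1); n_m <- sample(0:4, 1)
    sheet <- toy_sheet(n_f, n_m)
    n_sites <- sample(3:12, 1)
    chrom_length <- 3000
    pos <- sort(sample.int(chrom_length, n_sites))
    geno <- rand_geno(n_sites, 2 * n_f + n_m)
    vt <- make_vt(pos, geno, sheet)
    vt$hap1[sample(length(vt$hap1), 3)] <- NA_integer_
    track <- windowed_pi(vt, sheet, "P1", window_bp = 1000,
                         chrom_length = chrom_length)
    oracle <- pi_bruteforce(vt, sheet, "P1", 1000, chrom_length)
    expect_equal(track$pi, oracle, tolerance = 1e-12)
  }
})

test_that("trailing partial window is flagged and uses its true length", {
  sheet <- toy_sheet(2, 0)
  vt <- make_vt(c(100, 1200), rand_geno(2, 4, p = c(0.5, 0.5)), sheet)
  track <- windowed_pi(vt, sheet, "P1", 1000, chrom_length = 1500)
  expect_equal(track$partial, c(FALSE, TRUE))
  expect_equal(track$window_end[2] - track$window_start[2] + 1, 500)
})

test_that("Hudson Fst: fixed difference gives 1, identical frequencies ~0", {
  big <- tibble::tibble(n_chr = 1000L, p_hat = 0.5,
                        ref_count = 500L, alt_count = 500L)
  expect_lt(abs(fst_per_snp(big, big)), 0.005)

  c1 <- tibble::tibble(n_chr = 20L, p_hat = 0, ref_count = 20L, alt_count = 0L)
  c2 <- tibble::tibble(n_chr = 20L, p_hat = 1, ref_count = 0L, alt_count = 20L)
  expect_equal(fst_per_snp(c1, c2), 1)

  # jointly monomorphic -> undefined
  expect_true(is.na(fst_per_snp(c1, c1)))
})

test_that("Hudson Fst matches an independently coded moments formula and is
           invariant under allele-label swap", {
  set.seed(14)
  n1 <- 17L; n2 <- 23L
  a1 <- rbinom(500, n1, runif(500, 0.05, 0.95))
  a2 <- rbinom(500, n2, runif(500, 0.05, 0.95))
  c1 <- tibble::tibble(n_chr = n1, alt_count = a1, ref_count = n1 - a1,
                       p_hat = a1 / n1)
  c2 <- tibble::tibble(n_chr = n2, alt_count = a2, ref_count = n2 - a2,
                       p_hat = a2 / n2)
  fst <- fst_per_snp(c1, c2)
  # oracle, written scalar-wise from the ratio-of-moments definition
  oracle <- vapply(seq_len(500), function(i) {
    x1 <- a1[i] / n1; x2 <- a2[i] / n2
    num <- (x1 - x2)^2 - x1 * (1 - x1) / (n1 - 1) - x2 * (1 - x2) / (n2 - 1)
    den <- x1 * (1 - x2) + x2 * (1 - x1)
    if (den == 0) NA_real_ else num / den
  }, numeric(1))
  expect_equal(fst, oracle, tolerance = 1e-12)

  # label swap p -> 1 - p in both populations
  c1s <- tibble::tibble(n_chr = n1, alt_count = n1 - a1, ref_count = a1,
                        p_hat = 1 - a1 / n1)
  c2s <- tibble::tibble(n_chr = n2, alt_count = n2 - a2, ref_count = a2,
                        p_hat = 1 - a2 / n2)
  expect_equal(fst_per_snp(c1s, c2s), fst, tolerance = 1e-12)

  # Weir-Cockerham variant runs and is also label-swap invariant
  wc <- fst_per_snp(c1, c2, estimator = "weir_cockerham")
  expect_equal(fst_per_snp(c1s, c2s, estimator = "weir_cockerham"), wc,
               tolerance = 1e-12)
})

test_that("Fisher exact p matches enumeration and the stats oracle", {
  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5))), 1)
  # symmetric table: two-sided = 2 x upper hypergeometric tail
  p <- fisher_exact_2x2(rbind(c(13, 2), c(2, 13)))
  expect_equal(p, 2 * sum(stats::dhyper(13:15, 15, 15, 15)),
               tolerance = 1e-12)
  expect_equal(p, 1.4506e-4, tolerance = 1e-4)

  set.seed(15)
  for (i in 1:200) {
    m1 <- sample(1:40, 1); m2 <- sample(1:40, 1)
    a <- sample(0:m1, 1); c_ <- sample(0:m2, 1)
    tab <- rbind(c(a, m1 - a), c(c_, m2 - c_))
    mine <- fisher_exact_2x2(tab)
    expect_equal(mine, fisher_enum_oracle(a, m1 - a, c_, m2 - c_),
                 tolerance = 1e-10)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      expect_equal(mine, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
    }
  }
})

test_that("Fisher p is invariant under transpose and row/column swap", {
  set.seed(16)
  for (i in 1:25) {
    tab <- matrix(sample(0:20, 4, replace = TRUE), 2)
    p <- fisher_exact_2x2(tab)
    expect_equal(fisher_exact_2x2(t(tab)), p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1]), p, tolerance = 1e-12)
  }
})

test_that("zero-margin tables give p = 1 by convention", {
  expect_equal(fisher_exact_2x2(rbind(c(0, 0), c(3, 4))), 1)
  expect_equal(fisher_exact_2x2(rbind(c(0, 3), c(0, 4))), 1)
})

test_that("BH q-values follow the step-up rule and its properties", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(numeric(0)), numeric(0))
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))

  set.seed(17)
  p <- runif(200)
  q <- fdr_bh(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
  # hand-coded step-up oracle
  m <- length(p)
  qo <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(q[o], pmin(qo, 1), tolerance = 1e-12)
})

test_that("BH on uniform p-values rejects at the nominal global rate", {
  # under the complete null, P(any BH rejection at level alpha) = alpha
  set.seed(18)
  n_mc <- 2000
  any_rej <- replicate(n_mc, any(fdr_bh(runif(50)) < 0.05))
  se <- sqrt(0.05 * 0.95 / n_mc)
  expect_lt(abs(mean(any_rej) - 0.05), 3 * se)
})

test_that("Ts/Tv tally and SNP density match a direct count", {
  sheet <- toy_sheet(1, 0)
  vt <- make_vt(c(100, 200, 300, 400),
                rand_geno(4, 2, p = rep(0.5, 4)), sheet,
                ref = c("A", "C", "A", "G"), alt = c("G", "T", "C", "T"))
  s <- tstv_and_density(vt, window_bp = 400, chrom_length = 400)
  expect_equal(s$ts_count, 2L)
  expect_equal(s$tv_count, 2L)
  expect_equal(s$tstv, 1)
  expect_equal(s$snp_density, 4)

  set.seed(19)
  n <- 60
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  vt2 <- make_vt(sort(sample.int(50000, n)), rand_geno(n, 2), sheet,
                 ref = ref, alt = alt)
  s2 <- tstv_and_density(vt2, window_bp = 50000, chrom_length = 50000)
  direct <- sum(paste0(ref, alt) %in% c("AG", "GA", "CT", "TC"))
  expect_equal(s2$ts_count, direct)
  expect_equal(s2$snp_density, n)
})
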