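# fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir()

toy_sheet <- function(n_f, n_m, population = "P1", altitude = 1000,
                      prefix = "s") {
  n <- n_f + n_m
  sample_sheet(data.frame(
    sample_id = sprintf("%s%02d", prefix, seq_len(n)),
    population = population,
    sex = rep(c("female", "male"), c(n_f, n_m)),
    altitude = altitude))
}

# build a variant_table directly from per-chromosome allele codes
# geno: sites x chromosomes 0/1 matrix (column order: all copies of sample 1,
# then sample 2, ...; females two consecutive columns, males one)
make_vt <- function(pos, geno, sheet, ref = NULL, alt = NULL, qual = 90,
                    dp = 30, phased = TRUE, chrom = "chrX") {
  n_sites <- length(pos)
  stopifnot(nrow(geno) == n_sites)
  copies <- ifelse(sheet$sex == "female", 2L, 1L)
  stopifnot(ncol(geno) == sum(copies))
  first <- cumsum(c(1L, copies))[seq_len(nrow(sheet))]
  hap1 <- geno[, first, drop = FALSE]
  hap2 <- matrix(NA_integer_, n_sites, nrow(sheet))
  fem <- which(sheet$sex == "female")
  hap2[, fem] <- geno[, first[fem] + 1L, drop = FALSE]
  colnames(hap1) <- colnames(hap2) <- sheet$sample_id
  if (is.null(ref)) ref <- rep("A", n_sites)
  if (is.null(alt)) alt <- rep("G", n_sites)
  sites <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    n_alt = 1L,
    qual = rep_len(as.numeric(qual), n_sites),
    dp = rep_len(as.numeric(dp), n_sites))
  phase <- matrix(rep_len(phased, n_sites * nrow(sheet)), n_sites,
                  dimnames = list(NULL, sheet$sample_id))
  xselscan:::new_variant_table(sites, hap1, hap2, phase, sheet)
}

rand_geno <- function(n_sites, n_chrom, p = NULL) {
  if (is.null(p)) p <- runif(n_sites, 0.05, 0.95)
  matrix(rbinom(n_sites * n_chrom, 1L, rep(p, n_chrom)), n_sites, n_chrom)
}

# independent oracle: per-site mean pairwise difference over non-missing
# chromosome pairs, summed over sites in the window, over window length
pi_bruteforce <- function(vt, sheet, population, window_bp, chrom_length) {
  samples <- sheet$sample_id[sheet$population == population]
  cm <- xselscan:::chromosome_matrix(vt, samples)
  pos <- vt$sites$pos
  n_win <- (chrom_length - 1) %/% window_bp + 1
  vapply(seq_len(n_win), function(w) {
    lo <- (w - 1) * window_bp + 1
    hi <- min(w * window_bp, chrom_length)
    rows <- which(pos >= lo & pos <= hi)
    tot <- 0
    for (s in rows) {
      x <- cm[s, ]
      x <- x[!is.na(x)]
      n <- length(x)
      if (n < 2) next
      k <- sum(x == 1)
      tot <- tot + k * (n - k) / choose(n, 2)
    }
    tot / (hi - lo + 1)
  }, numeric(1))
}

# independent oracle: two-sided Fisher p by direct enumeration with choose()
fisher_enum_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; N <- m1 + m2
  if (m1 == 0 || m2 == 0 || k == 0 || (b + d) == 0) return(1)
  xs <- max(0, k - m2):min(k, m1)
  pr <- choose(m1, xs) * choose(m2, k - xs) / choose(N, k)
  p_obs <- pr[xs == a]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}
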