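#' Sex-aware allele counts for one population
#'
#' On the X chromosome every female contributes up to two allele observations
#' per site and every male one, so chromosome counts -- not individual counts
#' -- are the denominator of all frequencies ("gender-corrected" allele
#' frequencies).
#'
#' @param vt A `variant_table` (bi-allelic sites expected downstream).
#' @param sheet A [sample_sheet()]; defaults to the one embedded in `vt`.
#' @param population Population name to count.
#' @return A tibble with one row per site: `chrom`, `pos`, `n_chr` (non-
#'   missing allele observations), `ref_count`, `alt_count`, `p_hat`
#'   (`alt_count / n_chr`, `NaN` when no chromosome is called).
#' @export
sex_aware_counts <- function(vt, sheet = vt$sheet, population) {
  sheet <- sample_sheet(sheet)
  samples <- sheet$sample_id[sheet$population == population]
  if (length(samples) == 0) {
    abort(paste0("no samples in population '", population, "'"))
  }
  cm <- chromosome_matrix(vt, samples)
  n_chr <- rowSums(!is.na(cm))
  alt <- rowSums(cm == 1L, na.rm = TRUE)
  tibble::tibble(
    chrom = vt$sites$chrom, pos = vt$sites$pos,
    n_chr = as.integer(n_chr),
    ref_count = as.integer(n_chr - alt),
    alt_count = as.integer(alt),
    p_hat = alt / n_chr)
}

#' Windowed nucleotide diversity
#'
#' Per non-overlapping window anchored at coordinate 1, the per-site pairwise
#' nucleotide diversity
#' \deqn{\pi = \sum_s \frac{n_s}{n_s - 1}\, 2 \hat p_s (1 - \hat p_s) \big/ w}
#' summed over callable SNPs in the window and divided by the window length
#' `w` in bp.  This equals the mean proportion of differing sites over all
#' pairs of sampled chromosomes.  Sites with fewer than two called
#' chromosomes are skipped; a trailing partial window uses its true length
#' as denominator and is flagged.
#'
#' @inheritParams sex_aware_counts
#' @param window_bp Window width in bp.
#' @param chrom_length Chromosome length; defaults to the last SNP position.
#' @return A tibble of class `diversity_track`: `window_start`, `window_end`,
#'   `n_snps`, `pi`, `partial`.
#' @export
windowed_pi <- function(vt, sheet = vt$sheet, population, window_bp,
                        chrom_length = NULL) {
  if (window_bp <= 0) abort("window_bp must be positive")
  ac <- sex_aware_counts(vt, sheet, population)
  chrom_length <- chrom_length %||% max(ac$pos, window_bp)
  usable <- ac$n_chr >= 2L
  contrib <- ifelse(usable,
                    ac$n_chr / (ac$n_chr - 1) * 2 * ac$p_hat * (1 - ac$p_hat),
                    0)
  win <- (ac$pos - 1L) %/% window_bp
  n_win <- as.integer((chrom_length - 1) %/% window_bp) + 1L
  starts <- (seq_len(n_win) - 1L) * window_bp + 1L
  ends <- pmin(starts + window_bp - 1L, chrom_length)
  f <- factor(win, levels = 0:(n_win - 1L))
  sums <- as.vector(tapply(contrib, f, sum))
  cnts <- as.vector(tapply(usable, f, sum))
  sums[is.na(sums)] <- 0
  cnts[is.na(cnts)] <- 0L
  out <- tibble::tibble(
    window_start = starts, window_end = ends,
    n_snps = cnts,
    pi = sums / (ends - starts + 1),
    partial = (ends - starts + 1L) < window_bp)
  class(out) <- c("diversity_track", class(out))
  out
}

#' Per-SNP Fst between two populations
#'
#' Hudson's ratio-of-moments estimator (default)
#' \deqn{F = \frac{(p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} -
#'   \frac{p_2(1-p_2)}{n_2-1}}{p_1(1-p_2) + p_2(1-p_1)}}
#' computed from chromosome counts, which is agnostic to the mixed
#' male/female ploidy of X data.  The Weir--Cockerham variance-components
#' estimator on allele observations is available for comparison.  Sites where
#' the denominator vanishes (jointly monomorphic) or where either population
#' has fewer than two called chromosomes are `NA` and are excluded from any
#' downstream ranking, never imputed as 0.  Negative estimates are retained.
#'
#' @param counts1,counts2 Outputs of [sex_aware_counts()] for the two
#'   populations (same sites, same order).
#' @param estimator `"hudson"` or `"weir_cockerham"`.
#' @return Numeric vector of per-site Fst (with `NA` for undefined sites).
#' @export
fst_per_snp <- function(counts1, counts2,
                        estimator = c("hudson", "weir_cockerham")) {
  estimator <- match.arg(estimator)
  stopifnot(nrow(counts1) == nrow(counts2))
  n1 <- counts1$n_chr; n2 <- counts2$n_chr
  p1 <- counts1$p_hat; p2 <- counts2$p_hat
  ok <- n1 >= 2L & n2 >= 2L
  if (estimator == "hudson") {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    fst <- ifelse(ok & den > 0, num / den, NA_real_)
  } else {
    # Weir & Cockerham (1984) theta on allele observations (haploid form,
    # appropriate when each X chromosome is one sampled allele)
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2)
    fst <- ifelse(ok & (a + b) != 0, a / (a + b), NA_real_)
  }
  fst
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration with the minimum-likelihood two-sided
#' rule: with margins fixed, the p-value is the sum of probabilities of all
#' tables whose point probability does not exceed that of the observed table
#' (relative tolerance `1e-12` on the comparison, which makes ties
#' deterministic).  A zero margin gives p = 1 by convention.
#'
#' @param tab A 2x2 matrix of non-negative integer counts
#'   `rbind(c(a, b), c(c, d))`.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(rbind(c(5, 5), c(5, 5)))   # 1
#' fisher_exact_2x2(rbind(c(13, 2), c(2, 13))) # ~1.45e-4
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) ||
      any(tab != round(tab))) {
    abort("tab must be a 2x2 matrix of non-negative integers")
  }
  a <- tab[1, 1]
  m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); k <- sum(tab[, 1])
  if (m1 == 0 || m2 == 0 || k == 0 || sum(tab[, 2]) == 0) {
    return(1)
  }
  support <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Benjamini--Hochberg FDR correction
#'
#' Step-up q-values: \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at
#' 1, returned in the original order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
fdr_bh <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Transition/transversion ratio and SNP density
#'
#' Transitions are the purine--purine and pyrimidine--pyrimidine changes
#' (A<->G, C<->T); everything else is a transversion.  Density is the mean
#' number of SNPs per full window of `window_bp` anchored at coordinate 1.
#'
#' @inheritParams windowed_pi
#' @param window_bp Window width for the density summary (bp).
#' @return A one-row tibble: `ts_count`, `tv_count`, `tstv`, `snp_density`.
#' @export
tstv_and_density <- function(vt, window_bp = 50000, chrom_length = NULL) {
  if (any(vt$sites$n_alt != 1L)) {
    abort("tstv_and_density expects bi-allelic sites; run filter_variants")
  }
  pair <- paste0(vt$sites$ref, vt$sites$alt)
  ts <- sum(pair %in% c("AG", "GA", "CT", "TC"))
  tv <- length(pair) - ts
  chrom_length <- chrom_length %||% max(vt$sites$pos)
  n_full <- max(1L, as.integer(chrom_length %/% window_bp))
  in_full <- sum(vt$sites$pos <= n_full * window_bp)
  tibble::tibble(
    ts_count = ts, tv_count = tv,
    tstv = if (tv > 0) ts / tv else NA_real_,
    snp_density = in_full / n_full)
}
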