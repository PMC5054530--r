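#' Extract per-chromosome haplotypes over a SNP panel
#'
#' Builds one allele string per sampled chromosome (two per female, one per
#' hemizygous male) over the given panel positions, using the phase carried
#' in the variant table.  A chromosome with any missing panel call is dropped
#' (whole chromosomes, never single sites, so strings stay aligned) and
#' counted; an unphased heterozygous female genotype at a panel site drops
#' both of that individual's chromosomes with a warning.
#'
#' @param vt A phased `variant_table`.
#' @param sheet A [sample_sheet()]; defaults to the sheet embedded in `vt`.
#' @param panel_positions Positions (1-based) of the panel SNPs; all must be
#'   present in `vt`.
#' @return A tibble of class `haplotype_panel` with one row per surviving
#'   chromosome: `sample_id`, `copy` (1/2), `population`, `haplotype`
#'   (nucleotide string).  Attributes `panel_positions` and `n_dropped`.
#' @export
extract_haplotypes <- function(vt, sheet = vt$sheet, panel_positions) {
  sheet <- sample_sheet(sheet)
  idx <- match(panel_positions, vt$sites$pos)
  if (anyNA(idx)) {
    abort(paste0("panel position(s) absent from variants: ",
                 paste(panel_positions[is.na(idx)], collapse = ", ")))
  }
  ref <- vt$sites$ref[idx]
  alt <- vt$sites$alt[idx]
  allele_char <- function(code) {
    out <- ifelse(is.na(code), NA_character_, ifelse(code == 0L, ref, alt))
    out
  }
  h1 <- vt$hap1[idx, , drop = FALSE]
  h2 <- vt$hap2[idx, , drop = FALSE]
  ph <- vt$phase[idx, , drop = FALSE]

  rows <- list()
  n_dropped <- 0L
  n_unphased <- 0L
  for (j in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[j]
    if (sheet$sex[j] == "male") {
      a <- h1[, j]
      if (anyNA(a)) {
        n_dropped <- n_dropped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sid, copy = 1L, population = sheet$population[j],
        haplotype = paste(allele_char(a), collapse = ""))
    } else {
      a <- h1[, j]; b <- h2[, j]
      if (anyNA(a) || anyNA(b)) {
        n_dropped <- n_dropped + 2L
        next
      }
      het_unphased <- a != b & !ph[, j]
      if (any(het_unphased)) {
        n_unphased <- n_unphased + 1L
        n_dropped <- n_dropped + 2L
        next
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sid, copy = c(1L, 2L),
        population = sheet$population[j],
        haplotype = c(paste(allele_char(a), collapse = ""),
                      paste(allele_char(b), collapse = "")))
    }
  }
  if (n_unphased > 0) {
    warn(paste0(n_unphased, " female(s) with unphased heterozygous panel ",
                "genotypes dropped"))
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(sample_id = character(), copy = integer(),
                   population = character(), haplotype = character())
  attr(out, "panel_positions") <- panel_positions
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("haplotype_panel", class(out))
  out
}

#' Haplotype frequency records from per-population counts
#'
#' Builds the per-population frequency records used by the altitude
#' correlation directly from chromosome and major-haplotype counts, the
#' arithmetic behind every frequency this package reports:
#' `frequency = major_count / n_chromosomes`, with a half-up 2-decimal
#' display column.
#'
#' @param population,altitude,n_chromosomes,major_count Parallel vectors.
#' @return A tibble with `population`, `altitude`, `n_chromosomes`,
#'   `major_count`, `frequency`, `frequency_2dp`.
#' @export
freq_records <- function(population, altitude, n_chromosomes, major_count) {
  tibble::tibble(
    population = population,
    altitude = altitude,
    n_chromosomes = as.integer(n_chromosomes),
    major_count = as.integer(major_count),
    frequency = major_count / n_chromosomes,
    frequency_2dp = round_half_up(major_count / n_chromosomes, 2))
}

#' Gender-corrected major-haplotype frequency per population
#'
#' Counts exact matches of the target haplotype over each population's
#' surviving chromosomes (2 per female, 1 per male).  Frequencies are kept at
#' full precision; `frequency_2dp` is the half-up 2-decimal display value
#' used in published tables.
#'
#' @param panel A [extract_haplotypes()] result, or any tibble with
#'   `population` and `haplotype` columns (one row per chromosome).
#' @param target_haplotype The haplotype string to count.
#' @param sheet Optional [sample_sheet()] supplying one altitude per
#'   population; populations absent from the panel get zero chromosomes and
#'   are flagged.
#' @return A tibble: `population`, `altitude`, `n_chromosomes`,
#'   `major_count`, `frequency`, `frequency_2dp`, `usable` (FALSE when no
#'   chromosome survived).
#' @export
major_haplotype_frequency <- function(panel, target_haplotype, sheet = NULL) {
  sizes <- nchar(panel$haplotype)
  if (length(sizes) > 0 && any(sizes != nchar(target_haplotype))) {
    abort("target haplotype length differs from panel haplotype length")
  }
  pops <- unique(panel$population)
  alt_of <- NULL
  if (!is.null(sheet)) {
    sheet <- sample_sheet(sheet)
    alt_of <- vapply(split(sheet$altitude, sheet$population), function(a) {
      if (length(unique(a)) != 1) {
        abort("population with more than one altitude in the sheet")
      }
      a[1]
    }, numeric(1))
    pops <- union(pops, names(alt_of))
  }
  out <- purrr::map_dfr(pops, function(p) {
    h <- panel$haplotype[panel$population == p]
    freq_records(p, if (is.null(alt_of)) NA_real_ else unname(alt_of[p]),
                 length(h), sum(h == target_haplotype))
  })
  out$usable <- out$n_chromosomes > 0
  if (any(!out$usable)) {
    warn(paste0("population(s) with no surviving chromosomes: ",
                paste(out$population[!out$usable], collapse = ", ")))
  }
  out
}

#' Correlation between haplotype frequency and altitude
#'
#' Tests whether the major-haplotype frequency rises with altitude across
#' populations.  The default is an unweighted Pearson correlation with the
#' usual two-sided t test on \eqn{t = r\sqrt{(n-2)/(1-r^2)}}; Spearman and a
#' chromosome-count-weighted Pearson variant are available.
#'
#' @param records Output of [major_haplotype_frequency()] (rows flagged
#'   `usable = FALSE` or with missing altitude are excluded).
#' @param method `"pearson"` or `"spearman"`.
#' @param weighted Weight populations by chromosome count (Pearson only).
#' @return An object of class `altitude_cor`: a list with `r`, `p_value`,
#'   `n`, `method`, `weighted` and the records used.
#' @export
altitude_correlation <- function(records, method = c("pearson", "spearman"),
                                 weighted = FALSE) {
  method <- match.arg(method)
  use <- records
  if ("usable" %in% names(use)) use <- use[use$usable, , drop = FALSE]
  use <- use[is.finite(use$altitude), , drop = FALSE]
  n <- nrow(use)
  if (n < 3) abort("need at least 3 populations with data")
  if (stats::sd(use$frequency) == 0 || stats::sd(use$altitude) == 0) {
    abort("zero variance in frequency or altitude")
  }
  if (weighted && method == "pearson") {
    w <- use$n_chromosomes / sum(use$n_chromosomes)
    mx <- sum(w * use$altitude); my <- sum(w * use$frequency)
    r <- sum(w * (use$altitude - mx) * (use$frequency - my)) /
      sqrt(sum(w * (use$altitude - mx)^2) * sum(w * (use$frequency - my)^2))
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  } else {
    ct <- suppressWarnings(
      cor.test(use$frequency, use$altitude, method = method))
    r <- unname(ct$estimate)
    p <- ct$p.value
  }
  structure(
    list(r = r, p_value = p, n = n, method = method, weighted = weighted,
         records = use),
    class = "altitude_cor")
}

#' @exportS3Method base::print
print.altitude_cor <- function(x, ...) {
  cat(sprintf(
    "<altitude_cor> %s%s r = %.4f, two-sided p = %.3g (n = %d populations)\n",
    x$method, if (x$weighted) " (weighted)" else "", x$r, x$p_value, x$n))
  invisible(x)
}

#' @export
tidy.altitude_cor <- function(x, ...) {
  tibble::tibble(estimate = x$r, p.value = x$p_value, n = x$n,
                 method = x$method, weighted = x$weighted)
}

#' @export
glance.altitude_cor <- function(x, ...) tidy(x)

#' Pairwise linkage disequilibrium over a haplotype panel
#'
#' Gamete-frequency LD between every pair of panel loci:
#' \eqn{D = p_{AB} - p_A p_B}, \eqn{r^2 = D^2 / (p_A q_A p_B q_B)} and
#' \eqn{D' = D / D_{max}} with the usual sign-dependent
#' \eqn{D_{max} = \min(p_A q_B, q_A p_B)} for \eqn{D > 0} and
#' \eqn{\min(p_A p_B, q_A q_B)} for \eqn{D < 0}.  Allele A at each locus is
#' the first allele observed.  Pairs involving a monomorphic locus are `NA`.
#'
#' @param panel A [extract_haplotypes()] result (or tibble with a
#'   `haplotype` column), one row per chromosome; at least two chromosomes.
#' @return A list with matrices `r2` and `dprime` (loci x loci).
#' @export
pairwise_ld <- function(panel) {
  haps <- panel$haplotype
  if (length(haps) < 2) abort("need at least two chromosomes")
  m <- do.call(rbind, strsplit(haps, ""))
  L <- ncol(m)
  r2 <- dp <- matrix(NA_real_, L, L)
  diag(r2) <- diag(dp) <- 1
  # binary coding: allele "A" = first allele seen at the locus
  bin <- matrix(0L, nrow(m), L)
  poly <- logical(L)
  for (l in seq_len(L)) {
    alleles <- unique(m[, l])
    if (length(alleles) > 2) abort("panel locus with more than two alleles")
    poly[l] <- length(alleles) == 2
    bin[, l] <- as.integer(m[, l] == alleles[1])
  }
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      if (!poly[i] || !poly[j]) next
      pa <- mean(bin[, i]); pb <- mean(bin[, j])
      pab <- mean(bin[, i] == 1 & bin[, j] == 1)
      D <- pab - pa * pb
      qa <- 1 - pa; qb <- 1 - pb
      r2[i, j] <- r2[j, i] <- D^2 / (pa * qa * pb * qb)
      dmax <- if (D >= 0) min(pa * qb, qa * pb) else min(pa * pb, qa * qb)
      dp[i, j] <- dp[j, i] <- if (dmax == 0) NA_real_ else D / dmax
    }
  }
  diag(r2)[!poly] <- NA_real_
  diag(dp)[!poly] <- NA_real_
  list(r2 = r2, dprime = dp)
}
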