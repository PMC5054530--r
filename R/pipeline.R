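#' Run the two-test selection scan for one population contrast
#'
#' Computes per-SNP Hudson (or Weir--Cockerham) Fst and a per-SNP two-sided
#' Fisher exact test on the ref/alt chromosome counts of the two (possibly
#' pooled) population groups, applies FDR correction, flags the top
#' `top_fraction` of each statistic as outliers, maps outliers to genes and
#' ranks genes by outlier-SNP density.  Sites with undefined Fst are
#' excluded from the Fst ranking; a non-discriminating cutoff (Fst cutoff
#' <= 0, or q cutoff = 1, as happens when the groups coincide) yields zero
#' outliers for that test rather than flagging noise.
#'
#' @param vt A filtered, bi-allelic `variant_table`.
#' @param annotation Tibble from [read_annotation()].
#' @param pop_a,pop_b Character vectors of population names forming the two
#'   groups (e.g. `"TM"` vs `"YJ"`, or `c("TM", "DQ")` vs `"YJ"`).
#' @param sheet A [sample_sheet()]; defaults to the one in `vt`.
#' @param top_fraction Outlier fraction per test.
#' @param estimator Fst estimator, see [fst_per_snp()].
#' @param out_dir If non-NULL, write `scan.tsv`, `gene_density.tsv` and
#'   `manifest.json` there.
#' @return A list of class `scan_result`: `snps` (per-SNP tibble with
#'   `fst`, `fisher_p`, `fisher_q`, outlier flags), `genes` (density table),
#'   `gene_sets`, `thresholds` and `manifest`.
#' @export
run_scan <- function(vt, annotation, pop_a, pop_b, sheet = vt$sheet,
                     top_fraction = 0.01,
                     estimator = c("hudson", "weir_cockerham"),
                     out_dir = NULL) {
  estimator <- match.arg(estimator)
  sheet <- sample_sheet(sheet)
  for (p in c(pop_a, pop_b)) {
    if (!p %in% sheet$population) {
      abort(paste0("contrast population '", p, "' not in sample sheet"))
    }
  }
  counts_group <- function(pops) {
    sub <- sheet[sheet$population %in% pops, , drop = FALSE]
    sub$population <- "group"
    sex_aware_counts(vt, sub, "group")
  }
  ca <- counts_group(pop_a)
  cb <- counts_group(pop_b)
  fst <- fst_per_snp(ca, cb, estimator)
  fisher_p <- vapply(seq_len(nrow(ca)), function(i) {
    fisher_exact_2x2(rbind(c(ca$ref_count[i], ca$alt_count[i]),
                           c(cb$ref_count[i], cb$alt_count[i])))
  }, numeric(1))
  fisher_q <- fdr_bh(fisher_p)

  snps <- tibble::tibble(
    chrom = vt$sites$chrom, pos = vt$sites$pos,
    p_a = ca$p_hat, p_b = cb$p_hat,
    fst = fst, fisher_p = fisher_p, fisher_q = fisher_q,
    is_fst_outlier = FALSE, is_fisher_outlier = FALSE)

  ok_fst <- which(is.finite(fst))
  fst_cut <- NA_real_
  if (length(ok_fst) > 0) {
    co <- call_outliers(fst[ok_fst], top_fraction, "high")
    fst_cut <- co$cutoff
    if (fst_cut > 0) snps$is_fst_outlier[ok_fst] <- co$is_outlier
  }
  ok_q <- which(is.finite(fisher_q))
  q_cut <- NA_real_
  if (length(ok_q) > 0) {
    co <- call_outliers(fisher_q[ok_q], top_fraction, "low")
    q_cut <- co$cutoff
    if (q_cut < 1) snps$is_fisher_outlier[ok_q] <- co$is_outlier
  }

  gene_sets <- genes_with_outliers(snps, annotation)
  genes <- rank_genes_by_density(snps, annotation)
  thresholds <- list(
    top_fraction = top_fraction, estimator = estimator,
    fst_cutoff = fst_cut, q_cutoff = q_cut,
    neg_log10_q_cutoff = if (is.finite(q_cut) && q_cut > 0) -log10(q_cut)
                         else NA_real_)
  manifest <- list(
    tool = "xselscan", version = as.character(utils::packageVersion("xselscan")),
    pop_a = pop_a, pop_b = pop_b, estimator = estimator,
    top_fraction = top_fraction,
    n_snps = nrow(snps), n_fst_defined = length(ok_fst),
    n_fst_outliers = sum(snps$is_fst_outlier),
    n_fisher_outliers = sum(snps$is_fisher_outlier),
    fst_cutoff = fst_cut, q_cutoff = q_cut,
    n_genes_fst = length(gene_sets$fst_genes),
    n_genes_fisher = length(gene_sets$fisher_genes))

  out <- structure(list(snps = snps, genes = genes, gene_sets = gene_sets,
                        thresholds = thresholds, manifest = manifest),
                   class = "scan_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_plain(snps, file.path(out_dir, "scan.tsv"))
    write_tsv_plain(genes, file.path(out_dir, "gene_density.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @exportS3Method base::print
print.scan_result <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    paste0("<scan_result> %d SNPs (%d with defined Fst)\n",
           "  Fst outliers: %d (cutoff %.4f); Fisher outliers: %d ",
           "(q cutoff %.3g)\n  genes with outliers: %d (Fst), %d (Fisher)\n"),
    m$n_snps, m$n_fst_defined, m$n_fst_outliers, m$fst_cutoff,
    m$n_fisher_outliers, m$q_cutoff, m$n_genes_fst, m$n_genes_fisher))
  invisible(x)
}

#' @export
tidy.scan_result <- function(x, ...) x$snps

#' @export
glance.scan_result <- function(x, ...) {
  m <- x$manifest
  tibble::tibble(
    n_snps = m$n_snps, n_fst_outliers = m$n_fst_outliers,
    n_fisher_outliers = m$n_fisher_outliers, fst_cutoff = m$fst_cutoff,
    q_cutoff = m$q_cutoff, n_genes_fst = m$n_genes_fst,
    n_genes_fisher = m$n_genes_fisher)
}

#' Drift-versus-selection test for a region of a scan
#'
#' Extracts the observed per-SNP Fst values inside a region from a
#' [run_scan()] result and runs [drift_test()] against the neutral split
#' model.
#'
#' @param scan A `scan_result`.
#' @param region Length-2 numeric `c(start, end)` (1-based inclusive).
#' @param params A [demography_params()].
#' @param n_reps Neutral replicates.
#' @param alpha Reference level for the t-test p summary.
#' @param seed Integer seed.
#' @param out_file If non-NULL, write the JSON summary there.
#' @return A [drift_test()] result.
#' @export
run_drift_test <- function(scan, region, params = demography_params(),
                           n_reps = 10000, alpha = 0.05, seed,
                           out_file = NULL) {
  stopifnot(inherits(scan, "scan_result"), length(region) == 2)
  obs <- scan$snps$fst[scan$snps$pos >= region[1] &
                         scan$snps$pos <= region[2]]
  obs <- obs[is.finite(obs)]
  if (length(obs) == 0) {
    abort("no defined Fst values in the requested region")
  }
  res <- drift_test(obs, params, n_reps = n_reps, alpha = alpha, seed = seed)
  if (!is.null(out_file)) {
    jsonlite::write_json(list(
      empirical_probability = res$empirical_probability,
      observed_mean_fst = res$observed_mean_fst,
      frac_t_below_alpha = res$frac_t_below_alpha,
      n_reps = res$n_reps, n_observed_snps = length(obs),
      alpha = res$alpha, seed = seed,
      params = unclass(res$params)),
      out_file, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

#' Haplotype-frequency versus altitude test
#'
#' Extracts phased haplotypes over a SNP panel, computes gender-corrected
#' major-haplotype frequencies per population and tests their correlation
#' with altitude.
#'
#' @param vt A phased `variant_table`.
#' @param panel_positions Panel SNP positions.
#' @param target_haplotype Haplotype string to track.
#' @param sheet A [sample_sheet()]; defaults to the one in `vt`.
#' @param method,weighted Passed to [altitude_correlation()].
#' @param out_dir If non-NULL, write `haplotype_frequencies.tsv` and
#'   `altitude_correlation.json` there.
#' @return A list of class `altitude_test`: `records`, `correlation`
#'   (an `altitude_cor`), `panel`.
#' @export
run_altitude_test <- function(vt, panel_positions, target_haplotype,
                              sheet = vt$sheet, method = "pearson",
                              weighted = FALSE, out_dir = NULL) {
  panel <- extract_haplotypes(vt, sheet, panel_positions)
  records <- major_haplotype_frequency(panel, target_haplotype, sheet)
  usable <- sum(records$usable & is.finite(records$altitude))
  if (usable < 3) abort("fewer than 3 populations with usable haplotype data")
  corr <- altitude_correlation(records, method = method, weighted = weighted)
  out <- structure(list(records = records, correlation = corr, panel = panel),
                   class = "altitude_test")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_plain(records,
                    file.path(out_dir, "haplotype_frequencies.tsv"))
    jsonlite::write_json(
      list(r = corr$r, p_value = corr$p_value, n = corr$n,
           method = corr$method, weighted = corr$weighted,
           target_haplotype = target_haplotype,
           panel_positions = panel_positions),
      file.path(out_dir, "altitude_correlation.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  out
}

#' @exportS3Method base::print
print.altitude_test <- function(x, ...) {
  print(x$correlation)
  print(x$records[order(x$records$altitude),
                  c("population", "altitude", "n_chromosomes",
                    "major_count", "frequency_2dp")])
  invisible(x)
}

#' @export
tidy.altitude_test <- function(x, ...) x$records

#' @export
glance.altitude_test <- function(x, ...) tidy(x$correlation)

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), "NA", format(v, trim = TRUE, scientific = FALSE,
                                  digits = 15))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
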