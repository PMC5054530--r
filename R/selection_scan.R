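#' Flag top-quantile outliers
#'
#' Nearest-rank top-fraction rule: with `k = ceiling(top_fraction * n)`, the
#' cutoff is the k-th most extreme value in the requested direction and every
#' value at least as extreme -- including all ties at the cutoff -- is
#' flagged.  Flags are independent of input order.
#'
#' @param values Finite numeric vector (drop undefined values upstream).
#' @param top_fraction Fraction of values to flag (default 1\%).
#' @param direction `"high"` (large values extreme, e.g. Fst) or `"low"`
#'   (small values extreme, e.g. q-values).
#' @return A list with `is_outlier` (logical vector), `cutoff` and `k`.
#' @export
call_outliers <- function(values, top_fraction = 0.01,
                          direction = c("high", "low")) {
  direction <- match.arg(direction)
  if (any(!is.finite(values))) {
    abort("values must be finite; exclude undefined sites first")
  }
  n <- length(values)
  if (n * top_fraction < 1) {
    warn(sprintf(
      "only %d values for top fraction %g; cutoff is the most extreme value",
      n, top_fraction))
  }
  k <- max(1L, as.integer(ceiling(top_fraction * n)))
  if (direction == "high") {
    cutoff <- sort(values, decreasing = TRUE)[k]
    flags <- values >= cutoff
  } else {
    cutoff <- sort(values)[k]
    flags <- values <= cutoff
  }
  list(is_outlier = flags, cutoff = cutoff, k = k)
}

#' Map outlier SNPs to genes
#'
#' A gene is included when at least one outlier SNP falls inside its
#' `[start, end]` span (introns included); overlapping genes may share SNPs.
#'
#' @param scan A scan tibble with `pos`, `is_fst_outlier`, `is_fisher_outlier`
#'   (as produced by [run_scan()]).
#' @param annotation Tibble from [read_annotation()].
#' @return A list with character vectors `fst_genes` and `fisher_genes`.
#' @export
genes_with_outliers <- function(scan, annotation) {
  hit <- function(pos) {
    if (length(pos) == 0) return(character())
    in_gene <- vapply(seq_len(nrow(annotation)), function(i) {
      any(pos >= annotation$start[i] & pos <= annotation$end[i])
    }, logical(1))
    annotation$gene_name[in_gene]
  }
  list(
    fst_genes = hit(scan$pos[which(scan$is_fst_outlier)]),
    fisher_genes = hit(scan$pos[which(scan$is_fisher_outlier)]))
}

#' Rank genes by outlier-SNP density
#'
#' Density is the number of outlier SNPs (union of the Fst and Fisher outlier
#' sets) inside the gene span per kb of span.  Genes are sorted by density,
#' descending, with ties broken by start coordinate (stable).
#'
#' @inheritParams genes_with_outliers
#' @return A tibble: `gene_name`, `span_bp`, `n_fst`, `n_fisher`,
#'   `n_outliers` (union), `n_snps` (all scanned SNPs in span), `density`
#'   per kb.
#' @export
rank_genes_by_density <- function(scan, annotation) {
  if (any(annotation$end <= annotation$start)) {
    abort("gene with non-positive span")
  }
  fst_pos <- scan$pos[which(scan$is_fst_outlier)]
  fis_pos <- scan$pos[which(scan$is_fisher_outlier)]
  uni_pos <- union(fst_pos, fis_pos)
  count_in <- function(pos, s, e) sum(pos >= s & pos <= e)
  out <- purrr::pmap_dfr(
    list(annotation$gene_name, annotation$start, annotation$end),
    function(g, s, e) {
      span <- e - s + 1L
      tibble::tibble(
        gene_name = g, start = s, span_bp = span,
        n_fst = count_in(fst_pos, s, e),
        n_fisher = count_in(fis_pos, s, e),
        n_outliers = count_in(uni_pos, s, e),
        n_snps = count_in(scan$pos, s, e),
        density = count_in(uni_pos, s, e) / (span / 1000))
    })
  out <- out[order(-out$density, out$start), , drop = FALSE]
  out$start <- NULL
  out
}

#' Intersect candidate gene sets from two scans
#'
#' @param genes_a,genes_b Character vectors of gene names called in two scans
#'   run against the same annotation.
#' @return A list with `shared` (the intersection) and `presence` (a tibble
#'   with one row per gene in either set and logical membership columns).
#' @export
intersect_scans <- function(genes_a, genes_b) {
  shared <- intersect(genes_a, genes_b)
  if (length(shared) == 0) {
    warn("no genes shared between the two scans")
  }
  all_genes <- union(genes_a, genes_b)
  list(
    shared = shared,
    presence = tibble::tibble(
      gene_name = all_genes,
      in_scan_a = all_genes %in% genes_a,
      in_scan_b = all_genes %in% genes_b))
}
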