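#' Build and validate a sample sheet
#'
#' The sample sheet drives every sex-aware computation in the package: on the
#' X chromosome a female carries two chromosome copies and a male one, so
#' allele and haplotype frequencies are always counted over chromosomes, not
#' individuals.
#'
#' @param x A data frame with columns `sample_id`, `population`, `sex`
#'   (`"male"`/`"female"`, abbreviations `"M"`/`"F"` accepted) and `altitude`
#'   in metres.
#' @return A tibble of class `sample_sheet` with normalised `sex` values.
#' @examples
#' sample_sheet(data.frame(
#'   sample_id = c("s1", "s2"), population = "TM",
#'   sex = c("F", "M"), altitude = 4380
#' ))
#' @export
sample_sheet <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("sample_id", "population", "sex", "altitude")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("sample sheet is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  x$sample_id <- as.character(x$sample_id)
  if (anyDuplicated(x$sample_id)) {
    abort("sample ids must be unique")
  }
  sex <- tolower(as.character(x$sex))
  sex[sex %in% c("f", "female", "2")] <- "female"
  sex[sex %in% c("m", "male", "1")] <- "male"
  if (!all(sex %in% c("female", "male"))) {
    abort("sex must be coded male/female (or M/F)")
  }
  x$sex <- sex
  if (!is.numeric(x$altitude) || any(!is.finite(x$altitude)) ||
      any(x$altitude < 0)) {
    abort("altitude must be finite, non-negative metres")
  }
  class(x) <- c("sample_sheet", class(x))
  x
}

#' Read a sample sheet from a delimited text file
#'
#' @param path Path to a tab- or comma-separated file with a header row.
#' @return A [sample_sheet()] tibble.
#' @export
read_sample_sheet <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  sample_sheet(utils::read.table(path, header = TRUE, sep = sep,
                                 stringsAsFactors = FALSE))
}

# ---- VariantTable ----------------------------------------------------------

# Internal representation: per-site metadata tibble plus two integer allele
# matrices (sites x samples; allele 0 = REF, k = k-th ALT; NA = missing).
# Males use hap1 only, hap2 is structurally NA (hemizygosity).  `phase` is a
# per-genotype logical ("|" in the VCF, or trivially TRUE for haploid and
# homozygous calls).
new_variant_table <- function(sites, hap1, hap2, phase, sheet) {
  stopifnot(nrow(sites) == nrow(hap1), ncol(hap1) == nrow(sheet))
  o <- order(sites$pos)
  structure(
    list(sites = sites[o, , drop = FALSE],
         hap1 = hap1[o, , drop = FALSE],
         hap2 = hap2[o, , drop = FALSE],
         phase = phase[o, , drop = FALSE],
         sheet = sheet),
    class = "variant_table")
}

#' @exportS3Method base::print
print.variant_table <- function(x, ...) {
  cat("<variant_table> ", nrow(x$sites), " sites x ", nrow(x$sheet),
      " samples (", sum(x$sheet$sex == "female"), " F / ",
      sum(x$sheet$sex == "male"), " M; ",
      sum(2L * (x$sheet$sex == "female") + (x$sheet$sex == "male")),
      " chromosomes)\n", sep = "")
  print(head(x$sites, 5))
  invisible(x)
}

n_sites <- function(vt) nrow(vt$sites)

# chromosome-copy matrix for a set of samples: one column per female copy
# plus one per male; values are allele codes with NA for missing
chromosome_matrix <- function(vt, samples) {
  idx <- match(samples, vt$sheet$sample_id)
  if (anyNA(idx)) abort("unknown sample id in chromosome_matrix")
  f <- idx[vt$sheet$sex[idx] == "female"]
  m <- idx[vt$sheet$sex[idx] == "male"]
  cbind(vt$hap1[, f, drop = FALSE], vt$hap2[, f, drop = FALSE],
        vt$hap1[, m, drop = FALSE])
}

#' Read X-chromosome SNPs from a VCF file
#'
#' Parses a VCF 4.x file with `vcfR`, resolves per-sample ploidy from the
#' sample sheet (two allele slots per female, one per male) and preserves
#' per-genotype phase flags.  Records whose ALT contains anything other than
#' single-nucleotide alleles (indels, symbolic alleles) are dropped and
#' counted.  A heterozygous diploid call in a male -- an artifact under
#' hemizygosity -- is set to missing for that sample with a warning.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param sheet A [sample_sheet()]; every VCF sample must appear in it.
#' @return A `variant_table`.
#' @export
read_vcf <- function(path, sheet) {
  sheet <- sample_sheet(sheet)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  vcf_samples <- colnames(vcf@gt)[-1]
  unknown <- setdiff(vcf_samples, sheet$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("VCF sample(s) not in sample sheet: ",
                 paste(unknown, collapse = ", ")))
  }

  ref <- fix$REF
  alt <- fix$ALT
  alt_alleles <- strsplit(ifelse(is.na(alt), "", alt), ",", fixed = TRUE)
  is_snp <- nchar(ref) == 1L & ref %in% c("A", "C", "G", "T") &
    vapply(alt_alleles, function(a) {
      length(a) >= 1L && all(nchar(a) == 1L & a %in% c("A", "C", "G", "T"))
    }, logical(1))
  n_dropped <- sum(!is_snp)
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " non-SNP record(s) dropped on read"))
  }

  gt_raw <- vcf@gt[, -1, drop = FALSE][is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  alt_alleles <- alt_alleles[is_snp]
  gt <- sub(":.*$", "", gt_raw)
  gt[gt %in% c(".", "./.", ".|.")] <- NA_character_

  a1 <- suppressWarnings(as.integer(sub("^([0-9.]+).*$", "\\1", gt)))
  two <- !is.na(gt) & grepl("[/|]", gt)
  a2 <- rep(NA_integer_, length(gt))
  a2[two] <- suppressWarnings(
    as.integer(sub("^[0-9.]+[/|]([0-9.]+).*$", "\\1", gt[two])))
  dim(a1) <- dim(a2) <- dim(gt)
  phase <- !is.na(gt) & (grepl("|", gt, fixed = TRUE) | !two)
  dim(phase) <- dim(gt)

  # align columns to sheet order
  ord <- match(sheet$sample_id, vcf_samples)
  if (anyNA(ord)) {
    abort(paste0("sample sheet sample(s) absent from VCF: ",
                 paste(sheet$sample_id[is.na(ord)], collapse = ", ")))
  }
  a1 <- a1[, ord, drop = FALSE]
  a2 <- a2[, ord, drop = FALSE]
  phase <- phase[, ord, drop = FALSE]

  male <- sheet$sex == "male"
  if (any(male)) {
    m2 <- a2[, male, drop = FALSE]
    m1 <- a1[, male, drop = FALSE]
    het <- !is.na(m1) & !is.na(m2) & m1 != m2
    if (any(het)) {
      warn(paste0(sum(het),
                  " heterozygous male X genotype(s) set to missing"))
      m1[het] <- NA_integer_
    }
    # homozygous diploid male call collapses to one chromosome
    a1[, male] <- m1
    a2[, male] <- NA_integer_
    ph <- phase[, male, drop = FALSE]
    ph[het] <- FALSE
    phase[, male] <- ph | !is.na(m1)
  }
  # homozygous females are trivially phased
  hom <- !is.na(a1) & !is.na(a2) & a1 == a2
  phase[hom] <- TRUE

  qual <- suppressWarnings(as.numeric(fix$QUAL))
  dp <- suppressWarnings(as.numeric(sub("^.*?DP=([0-9.]+).*$", "\\1",
                                        ifelse(is.na(fix$INFO), "", fix$INFO))))
  dp[!grepl("DP=", ifelse(is.na(fix$INFO), "", fix$INFO))] <- NA_real_

  sites <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = ref[is_snp],
    alt = vapply(alt_alleles, paste, character(1), collapse = ","),
    n_alt = lengths(alt_alleles),
    qual = qual,
    dp = dp)
  colnames(a1) <- colnames(a2) <- colnames(phase) <- sheet$sample_id
  vt <- new_variant_table(sites, a1, a2, phase, sheet)
  attr(vt, "n_dropped_non_snp") <- n_dropped
  vt
}

#' Write a variant table to a VCF file
#'
#' Emits a minimal VCF 4.2 file with QUAL, `DP` in INFO and GT genotypes.
#' Females are written as two alleles with `|` where the genotype is phased
#' (`/` otherwise); males as a single haploid allele.
#'
#' @param vt A `variant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path) {
  sheet <- vt$sheet
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sheet$sample_id), collapse = "\t"))
  fmt_allele <- function(a) ifelse(is.na(a), ".", as.character(a))
  male <- sheet$sex == "male"
  sep <- ifelse(vt$phase, "|", "/")
  gt <- matrix("", nrow = n_sites(vt), ncol = nrow(sheet))
  gt[, male] <- fmt_allele(vt$hap1[, male, drop = FALSE])
  if (any(!male)) {
    gt[, !male] <- paste0(fmt_allele(vt$hap1[, !male, drop = FALSE]),
                          sep[, !male, drop = FALSE],
                          fmt_allele(vt$hap2[, !male, drop = FALSE]))
  }
  qual <- ifelse(is.na(vt$sites$qual), ".",
                 format(vt$sites$qual, trim = TRUE, scientific = FALSE))
  info <- ifelse(is.na(vt$sites$dp), ".",
                 paste0("DP=", format(vt$sites$dp, trim = TRUE,
                                      scientific = FALSE)))
  body <- paste(vt$sites$chrom, vt$sites$pos, ".", vt$sites$ref,
                vt$sites$alt, qual, "PASS", info, "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

# ---- Post-calling filters --------------------------------------------------

#' Apply the five post-calling SNP filters
#'
#' Filters are applied in a fixed order, each counting its removals from the
#' set that survived the previous rules:
#' 1. SNPs within `indel_radius` bp of a supplied indel position;
#' 2. sites with genotypes missing in more than `missing_frac_max` of all
#'    sheet samples (a sample counts as missing when any of its expected
#'    allele slots is uncalled);
#' 3. non-bi-allelic sites;
#' 4. site depth outside the `depth_pct` percentiles, computed over the sites
#'    remaining after rules 1--3;
#' 5. site QUAL not greater than `qual_min`.
#'
#' When every site lacks DP or QUAL the corresponding rule is skipped and the
#' report says so.
#'
#' @param vt A `variant_table`.
#' @param indel_positions Integer positions of indels on the same chromosome.
#' @param missing_frac_max Maximum tolerated missing-sample fraction.
#' @param qual_min Minimum QUAL (exclusive).
#' @param depth_pct Length-2 percentage vector of retained depth percentiles.
#' @param indel_radius Exclusion radius around indels, in bp.
#' @return A list with `variants` (the surviving `variant_table`) and
#'   `report` (a tibble of per-rule removal counts, class `filter_report`).
#' @export
filter_variants <- function(vt, indel_positions = integer(),
                            missing_frac_max = 0.20, qual_min = 40,
                            depth_pct = c(2.5, 97.5), indel_radius = 5) {
  rules <- character()
  removed <- integer()
  notes <- character()
  raw_n <- n_sites(vt)
  keep_tbl <- function(keep) {
    vt$sites <<- vt$sites[keep, , drop = FALSE]
    vt$hap1 <<- vt$hap1[keep, , drop = FALSE]
    vt$hap2 <<- vt$hap2[keep, , drop = FALSE]
    vt$phase <<- vt$phase[keep, , drop = FALSE]
  }

  # 1: proximity to indels
  if (length(indel_positions) > 0) {
    ip <- sort(as.numeric(indel_positions))
    near <- vapply(vt$sites$pos, function(p) {
      i <- findInterval(p, ip)
      lo <- if (i >= 1) p - ip[i] else Inf
      hi <- if (i < length(ip)) ip[i + 1] - p else Inf
      min(lo, hi) <= indel_radius
    }, logical(1))
  } else {
    near <- rep(FALSE, n_sites(vt))
  }
  rules <- c(rules, "indel_proximity")
  removed <- c(removed, sum(near))
  notes <- c(notes, sprintf("within %d bp of an indel", indel_radius))
  keep_tbl(!near)

  # 2: missingness over all sheet samples
  male <- vt$sheet$sex == "male"
  miss1 <- is.na(vt$hap1)
  miss2 <- is.na(vt$hap2)
  sample_missing <- miss1
  sample_missing[, !male] <- miss1[, !male, drop = FALSE] |
    miss2[, !male, drop = FALSE]
  frac <- rowMeans(sample_missing)
  bad <- frac > missing_frac_max
  rules <- c(rules, "missingness")
  removed <- c(removed, sum(bad))
  notes <- c(notes, sprintf("missing in > %d%% of all samples",
                            round(100 * missing_frac_max)))
  keep_tbl(!bad)

  # 3: bi-allelic only
  multi <- vt$sites$n_alt != 1L
  rules <- c(rules, "biallelic")
  removed <- c(removed, sum(multi))
  notes <- c(notes, "more than one ALT allele")
  keep_tbl(!multi)

  # 4: depth percentiles on the set surviving rules 1-3
  dp <- vt$sites$dp
  if (all(is.na(dp))) {
    rules <- c(rules, "depth")
    removed <- c(removed, 0L)
    notes <- c(notes, "skipped: no DP available")
    warn("depth filter skipped: no DP field in any record")
  } else {
    bounds <- quantile(dp, probs = depth_pct / 100, na.rm = TRUE, names = FALSE)
    bad <- !is.na(dp) & (dp < bounds[1] | dp > bounds[2])
    rules <- c(rules, "depth")
    removed <- c(removed, sum(bad))
    notes <- c(notes, sprintf("DP outside [%g, %g] (%g-%g percentiles)",
                              bounds[1], bounds[2], depth_pct[1], depth_pct[2]))
    keep_tbl(!bad)
  }

  # 5: QUAL
  qual <- vt$sites$qual
  if (all(is.na(qual))) {
    rules <- c(rules, "qual")
    removed <- c(removed, 0L)
    notes <- c(notes, "skipped: no QUAL available")
    warn("QUAL filter skipped: no QUAL in any record")
  } else {
    bad <- !is.na(qual) & qual <= qual_min
    rules <- c(rules, "qual")
    removed <- c(removed, sum(bad))
    notes <- c(notes, sprintf("QUAL <= %g", qual_min))
    keep_tbl(!bad)
  }

  report <- tibble::tibble(rule = rules, n_removed = removed, note = notes)
  attr(report, "n_input") <- raw_n
  attr(report, "n_surviving") <- n_sites(vt)
  class(report) <- c("filter_report", class(report))
  if (n_sites(vt) == 0) {
    warn("no sites survive the filters; see the filter report")
  }
  list(variants = vt, report = report)
}

#' @exportS3Method base::print
print.filter_report <- function(x, ...) {
  cat("<filter_report> ", attr(x, "n_input"), " sites in, ",
      attr(x, "n_surviving"), " surviving\n", sep = "")
  NextMethod()
}

# ---- Gene annotation -------------------------------------------------------

#' Read gene annotations from BED or GFF3
#'
#' Coordinates are normalised to 1-based inclusive intervals (the VCF
#' convention): BED's 0-based half-open start is shifted on read, GFF3 is
#' taken as is.  For GFF3, features of type `gene` are used when present,
#' otherwise all features.
#'
#' @param path Path to a `.bed`, `.gff` or `.gff3` file.
#' @param format Force `"bed"` or `"gff3"`; default guesses from extension.
#' @return A tibble with `gene_name`, `chrom`, `start`, `end`, `biotype`.
#' @export
read_annotation <- function(path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3")
  check_annotation_lines(path, format)
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  if (format == "gff3" && "type" %in% names(df) &&
      any(df$type == "gene")) {
    df <- df[df$type == "gene", , drop = FALSE]
  }
  name <- df[["Name"]] %||% NULL
  if (is.null(name) || all(is.na(name))) name <- df[["name"]]
  if (is.null(name) || all(is.na(name))) name <- df[["gene_id"]]
  if (is.null(name) || all(is.na(name))) name <- df[["ID"]]
  if (is.null(name)) name <- paste0("feature_", seq_len(nrow(df)))
  biotype <- df[["biotype"]] %||% df[["gene_biotype"]] %||%
    as.character(df[["type"]] %||% NA_character_)
  out <- tibble::tibble(
    gene_name = as.character(name),
    chrom = as.character(df$seqnames),
    start = as.integer(df$start),
    end = as.integer(df$end),
    biotype = as.character(biotype))
  if (any(out$start >= out$end)) {
    abort("annotation contains an interval with start >= end")
  }
  out
}

# quick structural validation so malformed lines are reported by number
check_annotation_lines <- function(path, format) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || grepl("^#", ln)) next
    if (format == "bed" && grepl("^(track|browser)", ln)) next
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) == 1) f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    ok <- if (format == "bed") {
      length(f) >= 3 && !anyNA(suppressWarnings(as.numeric(f[2:3])))
    } else {
      length(f) >= 9 && !anyNA(suppressWarnings(as.numeric(f[4:5])))
    }
    if (!ok) {
      abort(sprintf("malformed %s line %d in %s", toupper(format), i, path))
    }
  }
  invisible(TRUE)
}
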