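#' Configuration for a synthetic altitude-gradient study
#'
#' Describes a complete synthetic study: populations along an altitude
#' gradient with mixed sexes, a neutral SNP background simulated from the
#' two-population split coalescent, and one selected region whose major
#' haplotype frequency follows a logistic cline in altitude,
#' \deqn{f(a) = f_{low} + \frac{f_{high} - f_{low}}{1 + e^{-k (a - a_0)}}.}
#'
#' Defaults emulate the study structure the package targets: 15 dog
#' populations from 300 m to 4,380 m (the published chromosome counts split
#' into females and males), a 47,544 bp candidate region carrying 108 SNPs
#' whose major haplotype rises steeply with altitude, and a neutral
#' background from the high/low-altitude split demography.
#'
#' @param populations Tibble with `name`, `altitude`, `n_females`, `n_males`.
#' @param chrom_length_bp Chromosome length.
#' @param neutral_snp_count Neutral background SNPs.
#' @param region_start,region_length_bp,region_snp_count The selected region.
#' @param f_low,f_high,midpoint_altitude,steepness Cline parameters (`f` in
#'   `[0,1]`, altitude in m, steepness per m).
#' @param demography [demography_params()] for the neutral background (the
#'   sampled populations are pooled into a high- and a low-altitude deme at
#'   `midpoint_altitude`).
#' @param n_decoy_genes Decoy gene annotations over the neutral background.
#' @param panel_size Number of region SNPs used as the haplotype panel.
#' @param seed Integer seed.
#' @return A list of class `study_config`.
#' @export
study_config <- function(populations = default_populations(),
                         chrom_length_bp = 3e6,
                         neutral_snp_count = 1200,
                         region_start = 1500001,
                         region_length_bp = 47544,
                         region_snp_count = 108,
                         f_low = 0.10, f_high = 0.95,
                         midpoint_altitude = 2500, steepness = 0.0015,
                         demography = demography_params(),
                         n_decoy_genes = 6,
                         panel_size = 11,
                         seed = 1) {
  populations <- tibble::as_tibble(populations)
  stopifnot(all(c("name", "altitude", "n_females", "n_males") %in%
                  names(populations)))
  if (anyDuplicated(populations$name)) abort("population names must be unique")
  if (!(f_low >= 0 && f_low <= f_high && f_high <= 1)) {
    abort("need 0 <= f_low <= f_high <= 1")
  }
  region_end <- region_start + region_length_bp - 1
  if (region_end > chrom_length_bp) abort("selected region exceeds chromosome")
  if (region_snp_count > region_length_bp) {
    abort("more region SNPs than region positions")
  }
  structure(list(
    populations = populations, chrom_length_bp = chrom_length_bp,
    neutral_snp_count = neutral_snp_count,
    region_start = region_start, region_end = region_end,
    region_length_bp = region_length_bp,
    region_snp_count = region_snp_count,
    f_low = f_low, f_high = f_high,
    midpoint_altitude = midpoint_altitude, steepness = steepness,
    demography = demography, n_decoy_genes = n_decoy_genes,
    panel_size = panel_size, seed = seed),
    class = "study_config")
}

#' The published 15-population sampling design
#'
#' Population names, altitudes and chromosome counts of the 15-population
#' altitude gradient (300--4,380 m), with each chromosome count split into
#' females and males (2F + M = chromosomes).
#'
#' @return A tibble with `name`, `altitude`, `n_females`, `n_males`.
#' @export
default_populations <- function() {
  t1 <- table1_fixture()
  f <- round(t1$n_chromosomes / 3)
  tibble::tibble(
    name = t1$population, altitude = t1$altitude,
    n_females = as.integer(f),
    n_males = as.integer(t1$n_chromosomes - 2L * f))
}

# expected major-haplotype frequency from the logistic cline
cline_frequency <- function(altitude, config) {
  config$f_low + (config$f_high - config$f_low) /
    (1 + exp(-config$steepness * (altitude - config$midpoint_altitude)))
}

#' Generate a complete synthetic study
#'
#' Produces a phased variant table, sample sheet, gene annotation and the
#' generating truth.  The neutral background comes from one draw of the
#' split coalescent with the populations pooled into a high- and a
#' low-altitude deme; neutral SNP positions are uniform outside the selected
#' region.  Within the selected region each chromosome carries either the
#' distinct major haplotype (probability given by the cline at its
#' population's altitude) or one of three background haplotypes, as a whole
#' unit -- no recombination inside the region, reproducing a strong LD
#' block.  Annotation holds one gene spanning the region (`selgene`) plus
#' decoy genes over the background.
#'
#' @param config A [study_config()].
#' @param out_dir If non-NULL, write `study.vcf`, `samples.tsv` and
#'   `genes.bed` there.
#' @return A list with `variants` (`variant_table`), `sheet`, `annotation`,
#'   `truth` (per-chromosome haplotype assignment, expected per-population
#'   frequencies, panel positions, major haplotype string, selected gene
#'   name) and `config`.
#' @export
generate_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  pops <- config$populations

  sheet <- purrr::pmap_dfr(pops, function(name, altitude, n_females, n_males) {
    tibble::tibble(
      sample_id = sprintf("%s_%02d", name, seq_len(n_females + n_males)),
      population = name,
      sex = rep(c("female", "male"), c(n_females, n_males)),
      altitude = altitude)
  })
  sheet <- sample_sheet(sheet)

  # chromosome bookkeeping: per sample, 2 copies (F) or 1 (M)
  copies <- ifelse(sheet$sex == "female", 2L, 1L)
  chrom_of <- rep(seq_len(nrow(sheet)), copies)   # sample index per chromosome
  n_chrom <- length(chrom_of)
  chrom_pop <- sheet$population[chrom_of]
  chrom_alt <- sheet$altitude[chrom_of]

  # ---- neutral background from the split coalescent ----
  high <- chrom_alt >= config$midpoint_altitude
  n1 <- sum(high); n2 <- sum(!high)
  dem <- config$demography
  bg <- .sim_split_cpp(n1, n2, dem$ne_pop1, dem$ne_pop2, dem$ne_anc,
                       dem$split_time_generations,
                       as.integer(config$neutral_snp_count),
                       dem$mu_per_site_generation, dem$locus_length_bp, TRUE)
  # rows of bg$genotypes are sites, columns tips (deme 1 first)
  neutral_geno <- matrix(0L, nrow = bg$n_sites, ncol = n_chrom)
  neutral_geno[, high] <- bg$genotypes[, seq_len(n1), drop = FALSE]
  neutral_geno[, !high] <- bg$genotypes[, n1 + seq_len(n2), drop = FALSE]

  region_pos_all <- config$region_start:config$region_end
  neutral_candidates <- setdiff(seq_len(config$chrom_length_bp),
                                region_pos_all)
  neutral_pos <- sort(sample(neutral_candidates, config$neutral_snp_count))

  # ---- selected region: whole-unit haplotypes on a cline ----
  region_pos <- sort(sample(region_pos_all, config$region_snp_count))
  n_bg_haps <- 3L
  repeat {
    major_hap <- rep(1L, config$region_snp_count)
    bg_haps <- matrix(rbinom(n_bg_haps * config$region_snp_count, 1L, 0.3),
                      nrow = n_bg_haps)
    if (all(rowSums(bg_haps != matrix(major_hap, n_bg_haps,
                                      config$region_snp_count,
                                      byrow = TRUE)) > 0)) break
  }
  f_exp <- cline_frequency(chrom_alt, config)
  is_major <- rbinom(n_chrom, 1L, f_exp) == 1L
  bg_choice <- sample.int(n_bg_haps, n_chrom, replace = TRUE)
  region_geno <- matrix(0L, nrow = config$region_snp_count, ncol = n_chrom)
  region_geno[, is_major] <- major_hap
  if (any(!is_major)) {
    region_geno[, !is_major] <- t(bg_haps[bg_choice[!is_major], , drop = FALSE])
  }

  # ---- assemble sites and per-sample allele matrices ----
  pos <- c(neutral_pos, region_pos)
  geno <- rbind(neutral_geno, region_geno)
  o <- order(pos)
  pos <- pos[o]
  geno <- geno[o, , drop = FALSE]
  n_sites <- length(pos)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))

  hap1 <- matrix(NA_integer_, n_sites, nrow(sheet))
  hap2 <- matrix(NA_integer_, n_sites, nrow(sheet))
  first_copy <- match(seq_len(nrow(sheet)), chrom_of)
  hap1[, ] <- geno[, first_copy]
  fem <- which(sheet$sex == "female")
  hap2[, fem] <- geno[, first_copy[fem] + 1L]
  colnames(hap1) <- colnames(hap2) <- sheet$sample_id
  phase <- matrix(TRUE, n_sites, nrow(sheet),
                  dimnames = list(NULL, sheet$sample_id))

  sites <- tibble::tibble(
    chrom = "chrX", pos = as.integer(pos), ref = unname(ref),
    alt = unname(alt), n_alt = 1L,
    qual = round(runif(n_sites, 50, 99), 1),
    dp = as.integer(stats::rpois(n_sites, 30) + 2L))
  vt <- new_variant_table(sites, hap1, hap2, phase, sheet)

  # ---- annotation: selected gene + decoys over the background ----
  decoy_len <- 40000
  gap <- (config$chrom_length_bp - decoy_len) / (config$n_decoy_genes + 1)
  decoy_start <- round(gap * seq_len(config$n_decoy_genes))
  # push decoys off the selected region
  clash <- decoy_start + decoy_len >= config$region_start &
    decoy_start <= config$region_end
  decoy_start[clash] <- config$region_end + 10000 +
    seq_len(sum(clash)) * (decoy_len + 10000)
  annotation <- tibble::tibble(
    gene_name = c("selgene", sprintf("decoy%d", seq_len(config$n_decoy_genes))),
    chrom = "chrX",
    start = as.integer(c(config$region_start, decoy_start)),
    end = as.integer(c(config$region_end, decoy_start + decoy_len - 1)),
    biotype = "protein_coding")
  annotation <- annotation[annotation$end <= config$chrom_length_bp, ]

  # ---- truth ----
  panel_idx <- unique(round(seq(1, config$region_snp_count,
                                length.out = config$panel_size)))
  panel_positions <- region_pos[panel_idx]
  site_of <- match(panel_positions, pos)
  major_string <- paste(ifelse(major_hap[panel_idx] == 1L, alt[site_of],
                               ref[site_of]), collapse = "")
  truth <- list(
    chromosome_assignment = tibble::tibble(
      sample_id = sheet$sample_id[chrom_of],
      copy = unlist(lapply(copies, seq_len)),
      population = chrom_pop,
      carries_major = is_major,
      background_haplotype = ifelse(is_major, NA_integer_, bg_choice)),
    region_haplotypes = list(major = major_hap, background = bg_haps),
    region_positions = region_pos,
    expected_frequency = tibble::tibble(
      population = pops$name, altitude = pops$altitude,
      expected_frequency = cline_frequency(pops$altitude, config)),
    panel_positions = panel_positions,
    major_haplotype = major_string,
    selected_gene = "selgene")

  out <- list(variants = vt, sheet = sheet, annotation = annotation,
              truth = truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_vcf(vt, file.path(out_dir, "study.vcf"))
    utils::write.table(sheet, file.path(out_dir, "samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bed <- annotation
    writeLines(paste(bed$chrom, bed$start - 1L, bed$end, bed$gene_name,
                     sep = "\t"),
               file.path(out_dir, "genes.bed"))
    out$files <- file.path(out_dir, c("study.vcf", "samples.tsv", "genes.bed"))
  }
  out
}

#' Published major-haplotype frequencies along the altitude gradient
#'
#' The 15-population table of gender-corrected chromosome counts and
#' major-haplotype ('CGTTCGCTTTG') counts across altitudes 300--4,380 m,
#' packaged as frequency records for the correlation test.
#'
#' @return A tibble of frequency records (see
#'   [major_haplotype_frequency()]), with the major haplotype string as
#'   attribute `target_haplotype`.
#' @export
table1_fixture <- function() {
  rec <- freq_records(
    population = c("HEB", "PZ", "YA", "YJ", "XA", "CD", "SM", "YX",
                   "LJ1", "LJ2", "DQ", "HY", "MQ", "YS", "TM"),
    altitude = c(300, 300, 600, 800, 1000, 1000, 1300, 1600,
                 2400, 2500, 3300, 3700, 3600, 4000, 4380),
    n_chromosomes = c(27, 21, 27, 15, 26, 36, 30, 16,
                      15, 16, 15, 19, 17, 27, 15),
    major_count = c(9, 5, 7, 2, 13, 15, 5, 4, 4, 5, 6, 11, 10, 27, 13))
  rec$usable <- TRUE
  attr(rec, "target_haplotype") <- "CGTTCGCTTTG"
  rec
}
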