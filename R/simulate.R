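#' Simulation settings for a synthetic pigmentation cohort
#'
#' Bundles every knob of the cohort generator: regional structure, genome size,
#' the causal architecture of the two liability traits, LD-block geometry,
#' genotype missingness and the RNG seed. The defaults describe a structured
#' cohort of 3 regions x 100 samples per trait with 5 strong-effect causal
#' SNPs: one dominant lead locus (HERC2-like, roughly twice the effect of the
#' rest) plus four medium loci, together contributing about 90\% of the
#' liability variance -- the near-Mendelian architecture of human eye colour.
#'
#' @param n_samples_per_region samples drawn from each region.
#' @param regions character vector of region labels; each region is treated as
#'   one sampled population.
#' @param n_snps total number of simulated biallelic SNPs.
#' @param n_causal number of causal SNPs per trait (each placed in its own LD
#'   block).
#' @param causal_effects additive liability effect per eye-colour causal SNP
#'   (liability units per alternate allele); length `n_causal`.
#' @param hair_causal_effects same for the hair darkness axis; defaults to
#'   `causal_effects` (acting on a disjoint SNP set).
#' @param noise_sd standard deviation of the Gaussian environmental liability
#'   noise.
#' @param divergence Balding-Nichols drift parameter in \[0, 1); 0 means all
#'   regions share the ancestral allele frequencies.
#' @param ld_block_size number of SNPs per correlated LD block.
#' @param ld_flip_prob probability that a block SNP allele differs from the
#'   shared latent haplotype allele; smaller values give tighter LD.
#' @param grade_thresholds 4 strictly increasing liability cutpoints for the
#'   eye 0-4 grades, or `NULL` to place them at the empirical liability
#'   quantiles implied by `grade_props`.
#' @param hair_grade_thresholds 3 strictly increasing cutpoints for hair
#'   darkness grades 1-4 (grade 0 is red, driven by the recessive red locus),
#'   or `NULL` for the quantiles implied by `hair_grade_props`.
#' @param grade_props target proportions of eye grades 0-4 used when
#'   `grade_thresholds` is `NULL`. The default (16/16/2/33/33\%) mirrors the
#'   class composition typical of phenotyped North Eurasian cohorts: about a
#'   third light eyes, two thirds dark, and a thin intermediate class.
#' @param hair_grade_props target proportions of hair darkness grades 1-4
#'   (given not red) when `hair_grade_thresholds` is `NULL`; default
#'   15/13/13/59\%.
#' @param red_locus_freq ancestral allele frequency of the dedicated red-hair
#'   locus; homozygous carriers (code 2) get hair grade 0.
#' @param missing_rate per-cell genotype missingness probability in \[0, 1).
#' @param maf_range range of ancestral allele frequencies for non-causal
#'   blocks.
#' @param causal_maf_range range of ancestral allele frequencies for causal
#'   blocks (kept intermediate so the causal variance is realised).
#' @param seed integer seed; all randomness in the generator flows from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_samples_per_region = 100,
                       regions = c("RegionA", "RegionB", "RegionC"),
                       n_snps = 5000,
                       n_causal = 5,
                       causal_effects = c(1.6, 1.0, 0.9, 0.8, 0.7),
                       hair_causal_effects = causal_effects,
                       noise_sd = 0.5,
                       divergence = 0.1,
                       ld_block_size = 5,
                       ld_flip_prob = 0.1,
                       grade_thresholds = NULL,
                       hair_grade_thresholds = NULL,
                       grade_props = c(0.16, 0.16, 0.02, 0.33, 0.33),
                       hair_grade_props = c(0.15, 0.13, 0.13, 0.59),
                       red_locus_freq = 0.25,
                       missing_rate = 0.02,
                       maf_range = c(0.05, 0.95),
                       causal_maf_range = c(0.3, 0.7),
                       seed = 1L) {
  stopifnot(n_samples_per_region >= 1, n_snps >= 1, ld_block_size >= 1,
            length(regions) >= 1, !anyDuplicated(regions))
  if (divergence < 0 || divergence >= 1)
    stop("divergence must lie in [0, 1)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (n_causal > n_snps) stop("n_causal cannot exceed n_snps")
  if (length(causal_effects) != n_causal)
    stop("causal_effects must have length n_causal")
  if (length(hair_causal_effects) != n_causal)
    stop("hair_causal_effects must have length n_causal")
  if (!is.null(grade_thresholds)) {
    if (length(grade_thresholds) != 4 || is.unsorted(grade_thresholds, strictly = TRUE))
      stop("grade_thresholds must be 4 strictly increasing cutpoints")
  }
  if (!is.null(hair_grade_thresholds)) {
    if (length(hair_grade_thresholds) != 3 ||
        is.unsorted(hair_grade_thresholds, strictly = TRUE))
      stop("hair_grade_thresholds must be 3 strictly increasing cutpoints")
  }
  if (length(grade_props) != 5 || any(grade_props <= 0) ||
      abs(sum(grade_props) - 1) > 1e-8)
    stop("grade_props must be 5 positive proportions summing to 1")
  if (length(hair_grade_props) != 4 || any(hair_grade_props <= 0) ||
      abs(sum(hair_grade_props) - 1) > 1e-8)
    stop("hair_grade_props must be 4 positive proportions summing to 1")
  cfg <- list(n_samples_per_region = as.integer(n_samples_per_region),
              regions = as.character(regions),
              n_snps = as.integer(n_snps),
              n_causal = as.integer(n_causal),
              causal_effects = as.numeric(causal_effects),
              hair_causal_effects = as.numeric(hair_causal_effects),
              noise_sd = noise_sd,
              divergence = divergence,
              ld_block_size = as.integer(ld_block_size),
              ld_flip_prob = ld_flip_prob,
              grade_thresholds = grade_thresholds,
              hair_grade_thresholds = hair_grade_thresholds,
              grade_props = as.numeric(grade_props),
              hair_grade_props = as.numeric(hair_grade_props),
              red_locus_freq = red_locus_freq,
              missing_rate = missing_rate,
              maf_range = maf_range,
              causal_maf_range = causal_maf_range,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Balding-Nichols regional allele frequencies
#'
#' Draws per-region allele frequencies from a Beta distribution with mean
#' `base_freq` and variance `base_freq * (1 - base_freq) * divergence`,
#' the standard model for allele-frequency drift in structured populations.
#' `divergence = 0` returns the ancestral frequency exactly. Draws are clipped
#' into `[1e-4, 1 - 1e-4]` so no region fixes an allele.
#'
#' @param base_freq ancestral allele frequency (or a vector of them), each in
#'   (0, 1).
#' @param divergence drift parameter in \[0, 1).
#' @param n_regions number of regions.
#' @return A matrix of frequencies, `n_regions` rows x `length(base_freq)`
#'   columns.
#' @export
simulate_regional_frequencies <- function(base_freq, divergence, n_regions) {
  if (any(base_freq <= 0 | base_freq >= 1))
    stop("base_freq must lie strictly in (0, 1)")
  if (divergence < 0 || divergence >= 1)
    stop("divergence must lie in [0, 1)")
  p <- length(base_freq)
  if (divergence == 0) {
    return(matrix(rep(base_freq, each = n_regions), nrow = n_regions))
  }
  ratio <- (1 - divergence) / divergence
  a <- rep(base_freq, each = n_regions) * ratio
  b <- rep(1 - base_freq, each = n_regions) * ratio
  f <- stats::rbeta(n_regions * p, a, b)
  f <- pmin(pmax(f, 1e-4), 1 - 1e-4)
  matrix(f, nrow = n_regions)
}

block_structure <- function(cfg) {
  block <- ((seq_len(cfg$n_snps) - 1L) %/% cfg$ld_block_size) + 1L
  n_blocks <- max(block)
  if (n_blocks < 2L * cfg$n_causal + 1L)
    stop("too few LD blocks to host disjoint eye/hair causal SNPs and a red locus")
  block
}

#' Simulate genotypes for a structured cohort
#'
#' Within each region, genotypes at a SNP are Binomial(2, regional frequency).
#' SNPs are organised into consecutive LD blocks: all SNPs of a block copy two
#' shared latent haplotype alleles, each flipped independently with probability
#' `ld_flip_prob`, which induces positive genotype correlation within the
#' block. Eye and hair causal SNPs occupy disjoint blocks (one causal SNP at
#' the centre of its block); a dedicated red-hair locus sits in a further
#' block. Missing calls are inserted uniformly at `missing_rate`.
#'
#' @param cfg a [sim_config()].
#' @param freqs optional matrix of per-region, per-block ancestral frequencies
#'   (regions x blocks); drawn internally when `NULL`.
#' @return A list with elements
#'   \describe{
#'     \item{genotypes}{samples x SNPs additive-code matrix (0/1/2, `NA` for
#'       missing calls).}
#'     \item{variants}{per-SNP table: `snp_id`, `chrom`, `pos`, `ref`, `alt`,
#'       `qual`, `dp`, `block`, causal flags.}
#'     \item{manifest}{ground truth: causal SNP ids and effects per trait, the
#'       red locus, per-region block frequencies, and the complete (pre-mask)
#'       causal genotypes used to build liabilities.}
#'   }
#' @export
simulate_genotypes <- function(cfg, freqs = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  block <- block_structure(cfg)
  n_blocks <- max(block)
  n_regions <- length(cfg$regions)
  n <- cfg$n_samples_per_region * n_regions

  # reserve blocks: eye causal, hair causal, red locus, all disjoint
  eye_blocks <- seq_len(cfg$n_causal)
  hair_blocks <- cfg$n_causal + seq_len(cfg$n_causal)
  red_block <- 2L * cfg$n_causal + 1L
  spread <- function(b) { # spread reserved blocks across the genome
    round(seq(1, n_blocks, length.out = 2L * cfg$n_causal + 1L))[b]
  }
  eye_blocks <- spread(eye_blocks)
  hair_blocks <- spread(cfg$n_causal + seq_len(cfg$n_causal))
  red_block <- spread(2L * cfg$n_causal + 1L)

  base <- runif(n_blocks, cfg$maf_range[1], cfg$maf_range[2])
  base[c(eye_blocks, hair_blocks)] <-
    runif(2L * cfg$n_causal, cfg$causal_maf_range[1], cfg$causal_maf_range[2])
  base[red_block] <- cfg$red_locus_freq
  if (is.null(freqs)) {
    freqs <- simulate_regional_frequencies(base, cfg$divergence, n_regions)
  }
  stopifnot(nrow(freqs) == n_regions, ncol(freqs) == n_blocks)

  region_of <- rep(cfg$regions, each = cfg$n_samples_per_region)
  region_idx <- rep(seq_len(n_regions), each = cfg$n_samples_per_region)
  sample_ids <- sprintf("S%03d", seq_len(n))

  geno <- matrix(0L, nrow = n, ncol = cfg$n_snps)
  flip <- cfg$ld_flip_prob
  for (b in seq_len(n_blocks)) {
    cols <- which(block == b)
    pb <- freqs[region_idx, b]
    h1 <- rbinom(n, 1L, pb)
    h2 <- rbinom(n, 1L, pb)
    for (j in cols) {
      a1 <- ifelse(runif(n) < flip, 1L - h1, h1)
      a2 <- ifelse(runif(n) < flip, 1L - h2, h2)
      geno[, j] <- a1 + a2
    }
  }

  # causal SNP = centre SNP of its reserved block
  centre <- function(b) {
    cols <- which(block == b)
    cols[ceiling(length(cols) / 2)]
  }
  eye_idx <- vapply(eye_blocks, centre, integer(1))
  hair_idx <- vapply(hair_blocks, centre, integer(1))
  red_idx <- centre(red_block)

  # variant annotations (synthetic QUAL/DP so the QC filters have work to do)
  bases <- c("A", "C", "G", "T")
  chrom <- paste0("chr", ((seq_len(cfg$n_snps) - 1L) %% 22L) + 1L)
  pos <- 10000L + 50L * seq_len(cfg$n_snps)
  ref <- sample(bases, cfg$n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  qual <- round(runif(cfg$n_snps, 20, 100), 1)
  dp <- rpois(cfg$n_snps, 30)
  snp_id <- paste0(chrom, ":", pos, "_", ref, "_", alt)
  variants <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                         ref = ref, alt = alt, qual = qual, dp = dp,
                         block = block,
                         eye_causal = seq_len(cfg$n_snps) %in% eye_idx,
                         hair_causal = seq_len(cfg$n_snps) %in% hair_idx,
                         red_locus = seq_len(cfg$n_snps) == red_idx,
                         stringsAsFactors = FALSE)

  manifest <- list(
    causal_snp_ids = snp_id[eye_idx],
    hair_causal_snp_ids = snp_id[hair_idx],
    red_locus_snp_id = snp_id[red_idx],
    causal_effects = cfg$causal_effects,
    hair_causal_effects = cfg$hair_causal_effects,
    causal_blocks = eye_blocks,
    hair_causal_blocks = hair_blocks,
    block = stats::setNames(block, snp_id),
    ancestral_freq = base,
    regional_freq = freqs,
    causal_genotypes = geno[, eye_idx, drop = FALSE],
    hair_causal_genotypes = geno[, hair_idx, drop = FALSE],
    red_genotypes = geno[, red_idx]
  )

  if (cfg$missing_rate > 0) {
    mask <- matrix(runif(n * cfg$n_snps) < cfg$missing_rate, nrow = n)
    geno[mask] <- NA_integer_
  }
  dimnames(geno) <- list(sample_ids, snp_id)

  manifest$region <- region_of
  list(genotypes = geno, variants = variants, manifest = manifest)
}

#' Simulate ordinal phenotypes under a liability-threshold model
#'
#' Eye liability is the additive causal genetic score plus Gaussian noise; the
#' eye grade (0-4) counts how many of the 4 ordered cutpoints lie below the
#' liability. Hair darkness grades 1-4 are produced the same way from the hair
#' causal set with 3 cutpoints; samples homozygous for the red-locus alternate
#' allele are overridden to hair grade 0 (red), mirroring the recessive
#' behaviour of red hair. When cutpoints are not supplied they are placed at
#' the empirical liability quantiles (quintiles for eyes, quartiles for hair).
#'
#' @param sim result of [simulate_genotypes()].
#' @param cfg the matching [sim_config()].
#' @return A phenotype data frame (`sample_id`, `population`, `region`,
#'   `eye_grade`, `hair_grade`) with the per-sample liabilities attached as
#'   attribute `"liability"`.
#' @export
simulate_phenotypes <- function(sim, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  man <- sim$manifest
  n <- nrow(sim$genotypes)
  eye_liab <- drop(man$causal_genotypes %*% cfg$causal_effects) +
    rnorm(n, 0, cfg$noise_sd)
  hair_liab <- drop(man$hair_causal_genotypes %*% cfg$hair_causal_effects) +
    rnorm(n, 0, cfg$noise_sd)

  eye_thr <- cfg$grade_thresholds
  if (is.null(eye_thr)) {
    eye_thr <- quantile(eye_liab, cumsum(cfg$grade_props)[1:4], names = FALSE)
  }
  hair_thr <- cfg$hair_grade_thresholds
  if (is.null(hair_thr)) {
    hair_thr <- quantile(hair_liab, cumsum(cfg$hair_grade_props)[1:3],
                         names = FALSE)
  }

  eye_grade <- rowSums(outer(eye_liab, eye_thr, ">"))
  hair_grade <- 1L + rowSums(outer(hair_liab, hair_thr, ">"))
  hair_grade[man$red_genotypes == 2L] <- 0L

  ph <- data.frame(sample_id = rownames(sim$genotypes),
                   population = man$region,
                   region = man$region,
                   eye_grade = as.integer(eye_grade),
                   hair_grade = as.integer(hair_grade),
                   stringsAsFactors = FALSE)
  attr(ph, "liability") <- data.frame(eye = eye_liab, hair = hair_liab)
  attr(ph, "thresholds") <- list(eye = eye_thr, hair = hair_thr)
  ph
}

#' Generate a complete synthetic cohort
#'
#' Seeds the RNG from `cfg$seed` and runs [simulate_genotypes()] and
#' [simulate_phenotypes()]; identical configurations produce identical
#' cohorts.
#'
#' @param cfg a [sim_config()].
#' @return An object of class `snp_cohort`: list with `genotypes`,
#'   `phenotypes`, `variants`, `manifest`, `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(sim, cfg)
  sim$manifest$liability <- attr(ph, "liability")
  out <- list(genotypes = sim$genotypes, phenotypes = ph,
              variants = sim$variants, manifest = sim$manifest, config = cfg)
  class(out) <- "snp_cohort"
  out
}

#' @export
print.snp_cohort <- function(x, ...) {
  cat("Synthetic pigmentation cohort\n")
  cat(sprintf("  %d samples (%d regions x %d), %d SNPs, %d causal per trait\n",
              nrow(x$genotypes), length(x$config$regions),
              x$config$n_samples_per_region, ncol(x$genotypes),
              x$config$n_causal))
  cat(sprintf("  missingness %.1f%%, divergence %.2f, seed %d\n",
              100 * mean(is.na(x$genotypes)), x$config$divergence,
              x$config$seed))
  invisible(x)
}

format_gt <- function(code) {
  out <- rep("./.", length(code))
  out[!is.na(code) & code == 0L] <- "0/0"
  out[!is.na(code) & code == 1L] <- "0/1"
  out[!is.na(code) & code == 2L] <- "1/1"
  out
}

#' Write a synthetic cohort to disk
#'
#' Emits a VCF 4.2 file (GT genotypes, QUAL column, `DP` in INFO), a
#' tab-separated phenotype table and a JSON truth manifest. Output is a pure
#' function of the cohort, so a fixed simulation seed yields byte-identical
#' files.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a named list of the three file paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "snp_cohort"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vcf_path <- file.path(out_dir, "cohort.vcf")
  pheno_path <- file.path(out_dir, "phenotypes.tsv")
  manifest_path <- file.path(out_dir, "manifest.json")

  v <- cohort$variants
  tg <- t(cohort$genotypes)  # snps x samples
  gt <- matrix(format_gt(tg), nrow = nrow(tg))
  body <- paste(v$chrom, v$pos, v$snp_id, v$ref, v$alt,
                formatC(v$qual, format = "f", digits = 1), "PASS",
                paste0("DP=", v$dp), "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##source=pigsnp-synthetic-cohort",
              "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(cohort$genotypes)),
                    collapse = "\t"))
  writeLines(c(header, body), vcf_path)

  write.table(cohort$phenotypes, pheno_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  man <- cohort$manifest
  json <- list(causal_snp_ids = man$causal_snp_ids,
               hair_causal_snp_ids = man$hair_causal_snp_ids,
               red_locus_snp_id = man$red_locus_snp_id,
               causal_effects = man$causal_effects,
               hair_causal_effects = man$hair_causal_effects,
               ancestral_freq = man$ancestral_freq,
               regional_freq = as.data.frame(man$regional_freq),
               regions = cohort$config$regions,
               liability = man$liability,
               seed = cohort$config$seed)
  jsonlite::write_json(json, manifest_path, digits = NA, pretty = TRUE)

  invisible(list(vcf = vcf_path, phenotypes = pheno_path,
                 manifest = manifest_path))
}
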