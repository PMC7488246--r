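#' Read biallelic SNP calls from a VCF file
#'
#' Parses a VCF 4.2 file (via \pkg{vcfR}) into a per-variant table plus a raw
#' genotype-call matrix. SNP ids follow the `chrom:pos_ref_alt` convention
#' (1-based positions, kept verbatim from the file). Multiallelic lines are
#' skipped with a warning, since that id format implies a single alternate
#' allele. Variant depth is taken from the INFO `DP` field; when absent it
#' falls back to the mean per-sample FORMAT `DP`.
#'
#' @param path VCF file path.
#' @return A list of class `variant_calls`:
#'   \describe{
#'     \item{variants}{data frame `snp_id`, `chrom`, `pos`, `ref`, `alt`,
#'       `qual`, `dp`.}
#'     \item{gt}{character matrix of genotype tokens, variants x samples.}
#'     \item{sample_ids}{sample names in file order.}
#'   }
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no variant records in ", path)

  multi <- grepl(",", fix$ALT, fixed = TRUE) | is.na(fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " multiallelic or ALT-less line(s) skipped")
  }
  keep <- !multi

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  dp <- suppressWarnings(as.numeric(sub(".*?DP=([0-9.]+).*", "\\1", fix$INFO)))
  no_info_dp <- !grepl("(^|;)DP=", fix$INFO)
  dp[no_info_dp] <- NA_real_
  if (any(is.na(dp))) {
    fmt_dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                       error = function(e) NULL)
    if (!is.null(fmt_dp)) {
      fmt_dp <- fmt_dp[keep, , drop = FALSE]
      fill <- rowMeans(fmt_dp, na.rm = TRUE)
      dp[is.na(dp)] <- fill[is.na(dp)]
    }
  }

  pos <- as.integer(fix$POS)
  if (any(is.na(pos) | pos <= 0)) {
    stop("non-positive or unparseable POS at line(s): ",
         paste(which(is.na(pos) | pos <= 0), collapse = ", "))
  }
  variants <- data.frame(
    snp_id = paste0(fix$CHROM, ":", pos, "_", fix$REF, "_", fix$ALT),
    chrom = fix$CHROM, pos = pos, ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)), dp = dp,
    stringsAsFactors = FALSE)
  if (anyDuplicated(variants$snp_id))
    stop("duplicate snp_id in call set: ",
         variants$snp_id[duplicated(variants$snp_id)][1])
  rownames(gt) <- variants$snp_id

  out <- list(variants = variants, gt = gt, sample_ids = colnames(gt))
  class(out) <- "variant_calls"
  out
}

#' @export
print.variant_calls <- function(x, ...) {
  cat(sprintf("variant_calls: %d biallelic SNPs x %d samples\n",
              nrow(x$variants), length(x$sample_ids)))
  invisible(x)
}

#' Variant-level quality control
#'
#' Keeps variants with `QUAL` strictly greater than `qual_min` and read depth
#' strictly greater than `dp_min` (the upstream hard filter applied to the
#' sequencing calls). Variants with missing QUAL or DP fail the filter.
#'
#' @param calls a [read_vcf()] result.
#' @param qual_min minimum (exclusive) variant quality; default 40.
#' @param dp_min minimum (exclusive) read depth; default 5.
#' @return A filtered `variant_calls` object with attribute
#'   `"removed_variants"`.
#' @export
filter_variants <- function(calls, qual_min = 40, dp_min = 5) {
  stopifnot(inherits(calls, "variant_calls"))
  keep <- !is.na(calls$variants$qual) & !is.na(calls$variants$dp) &
    calls$variants$qual > qual_min & calls$variants$dp > dp_min
  out <- list(variants = calls$variants[keep, , drop = FALSE],
              gt = calls$gt[keep, , drop = FALSE],
              sample_ids = calls$sample_ids)
  class(out) <- "variant_calls"
  attr(out, "removed_variants") <- calls$variants$snp_id[!keep]
  out
}

#' Encode genotype calls additively
#'
#' Converts diploid genotype tokens into alternate-allele counts: `0/0` -> 0,
#' `0/1` or `1/0` -> 1, `1/1` -> 2. Phased separators (`|`) are treated as
#' unphased; `./.` (or `.`) becomes `NA`. Any other token is an error.
#'
#' @param calls a `variant_calls` object (after any variant filtering).
#' @return Numeric matrix of additive codes, samples x SNPs, with `NA` marking
#'   missing calls; rownames are sample ids, colnames SNP ids.
#' @export
encode_genotypes <- function(calls) {
  stopifnot(inherits(calls, "variant_calls"))
  tok <- sub(":.*$", "", calls$gt)         # keep GT field only
  tok <- gsub("|", "/", tok, fixed = TRUE) # phase-agnostic
  code <- matrix(NA_real_, nrow = nrow(tok), ncol = ncol(tok))
  code[tok == "0/0"] <- 0
  code[tok %in% c("0/1", "1/0")] <- 1
  code[tok == "1/1"] <- 2
  missing_tok <- is.na(tok) | tok %in% c("./.", ".", "./", ".|.")
  bad <- !missing_tok & is.na(code)
  if (any(bad)) {
    stop("unrecognised genotype token(s): ",
         paste(unique(tok[bad])[seq_len(min(5, length(unique(tok[bad]))))],
               collapse = ", "))
  }
  dimnames(code) <- dimnames(calls$gt)
  t(code)
}

#' Sample-level call-rate filter
#'
#' Drops samples whose fraction of non-missing genotype calls falls below
#' `min_rate` (the minimal genotyping rate used to admit a sample into the
#' analysis, default 90\%).
#'
#' @param genotypes samples x SNPs additive-code matrix (`NA` = missing).
#' @param min_rate minimum genotyping rate in \[0, 1\]; samples with a rate
#'   `>= min_rate` are kept.
#' @return The filtered matrix with attribute `"dropped_samples"`.
#' @export
filter_samples_by_call_rate <- function(genotypes, min_rate = 0.90) {
  rate <- rowMeans(!is.na(genotypes))
  keep <- rate >= min_rate
  if (!any(keep)) stop("call-rate filter removed every sample")
  out <- genotypes[keep, , drop = FALSE]
  attr(out, "dropped_samples") <- rownames(genotypes)[!keep]
  out
}

#' Mean-impute residual missing genotypes
#'
#' Replaces missing codes with the per-SNP mean computed on the training
#' samples only, so no test-set information leaks into downstream scorers.
#' SNPs entirely missing in the training samples cannot be imputed and are
#' dropped (with a warning).
#'
#' @param genotypes samples x SNPs additive-code matrix.
#' @param training_sample_ids ids of the samples whose observed codes define
#'   the imputation means; defaults to all samples.
#' @return A continuous-valued genotype matrix without missing entries, with
#'   attribute `"dropped_snps"`.
#' @export
impute_missing <- function(genotypes, training_sample_ids = rownames(genotypes)) {
  stopifnot(all(training_sample_ids %in% rownames(genotypes)))
  tr <- genotypes[training_sample_ids, , drop = FALSE]
  means <- colMeans(tr, na.rm = TRUE)
  dead <- !is.finite(means)
  if (any(dead)) {
    warning(sum(dead), " SNP(s) entirely missing in training samples dropped")
    genotypes <- genotypes[, !dead, drop = FALSE]
    means <- means[!dead]
  }
  na_idx <- which(is.na(genotypes), arr.ind = TRUE)
  if (nrow(na_idx)) genotypes[na_idx] <- means[na_idx[, 2]]
  attr(genotypes, "dropped_snps") <- names(dead)[dead]
  genotypes
}

#' Read and validate a phenotype table
#'
#' Expects a tab-separated file with columns `sample_id`, `population`,
#' `region`, `eye_grade`, `hair_grade`; grades must be integers 0-4 (darkness
#' scales: eye 0 = lightest, 4 = darkest; hair 0 = red, 1 = blond, 4 = dark)
#' and region labels non-empty.
#'
#' @param path TSV file path.
#' @param genotypes optional genotype matrix; samples present in the table but
#'   absent from the matrix are reported via a message.
#' @return Validated phenotype data frame.
#' @export
read_phenotypes <- function(path, genotypes = NULL) {
  ph <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "population", "region", "eye_grade", "hair_grade")
  miss <- setdiff(required, names(ph))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  check_grade <- function(g, nm) {
    bad <- which(is.na(g) | g != as.integer(g) | g < 0 | g > 4)
    if (length(bad)) stop(nm, " out of range 0-4 at row(s): ",
                          paste(head(bad, 5), collapse = ", "))
  }
  check_grade(ph$eye_grade, "eye_grade")
  check_grade(ph$hair_grade, "hair_grade")
  bad_region <- which(is.na(ph$region) | !nzchar(trimws(ph$region)))
  if (length(bad_region)) stop("empty region label at row(s): ",
                               paste(head(bad_region, 5), collapse = ", "))
  if (anyDuplicated(ph$sample_id))
    stop("duplicate sample_id: ", ph$sample_id[duplicated(ph$sample_id)][1])
  if (!is.null(genotypes)) {
    absent <- setdiff(ph$sample_id, rownames(genotypes))
    if (length(absent)) {
      message(length(absent), " phenotyped sample(s) absent from genotypes: ",
              paste(head(absent, 5), collapse = ", "))
    }
  }
  ph
}
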