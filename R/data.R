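#' Reference score matrix for 36 candidate eye-colour SNPs
#'
#' A published per-dataset selection-score matrix for 36 candidate
#' eye-colour-predictive SNPs in North Eurasian populations: integer scores
#' for three regional datasets (Caucasus, European Russia, West Siberia) and
#' the pooled dataset, plus rs identifiers and nearest-gene annotations. SNP
#' ids use the `chromosome:position_allele1_allele2` convention (GRCh37).
#' Useful as a worked example for [merge_and_rank()] and
#' [select_snp_sets()]: five SNPs carry the maximal pooled score 3 and the
#' top seven SNPs by total score form the minimal predictive set.
#'
#' Where the printed source leaves the regional placement of a score
#' ambiguous, scores were assigned to regions in column order; totals and
#' pooled scores are unaffected.
#'
#' @param as_ledgers return a named list of per-dataset `snp_id`/`score`
#'   tables ready for [merge_and_rank()] instead of the raw table.
#' @return A data frame (`snp_id`, `caucasus`, `european_russia`,
#'   `west_siberia`, `pooled`, `rsid`, `gene`), or a list of ledgers.
#' @export
#' @examples
#' ledger <- merge_and_rank(eye_reference_scores(as_ledgers = TRUE))
#' sum(ledger$pooled == 3)            # 5 top-tier SNPs
#' sum(ledger$total_score >= 3)       # the 7-SNP minimal set
eye_reference_scores <- function(as_ledgers = FALSE) {
  path <- system.file("extdata", "eye_best_snps_scores.tsv",
                      package = "pigsnp", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!as_ledgers) return(tab)
  ds <- c("caucasus", "european_russia", "west_siberia", "pooled")
  stats::setNames(lapply(ds, function(d) {
    data.frame(snp_id = tab$snp_id, score = tab[[d]],
               stringsAsFactors = FALSE)
  }), ds)
}
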