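#' Declarative scoring rule sets
#'
#' SNP selection evidence is condensed into an integer score 0-3 per dataset
#' by small declarative rule sets. Each rule carries a score value and a list
#' of clauses; a SNP attains the score if *any* clause holds, and receives the
#' *maximum* score over all matching rules. Clause types:
#' \describe{
#'   \item{`top_f(k)` / `top_mi(k)`}{F (p-gated) or MI rank at most k.}
#'   \item{`top_f_or_mi(k)` / `top_f_and_mi(k)`}{disjunction / conjunction of
#'     the two rank conditions.}
#'   \item{`nonzero(alpha)`}{lasso coefficient nonzero (|coef| > 1e-8) at that
#'     alpha.}
#'   \item{`nonzero_all(alphas)`}{nonzero at every listed alpha.}
#'   \item{`abs_coef_ge(alpha, value)` / `abs_coef_gt(alpha, value)`}{absolute
#'     coefficient at least / strictly above `value` at that alpha (raw 0/1/2
#'     genotype scale).}
#'   \item{`in_best_list`}{membership in a separately supplied best-SNPs
#'     list.}
#' }
#'
#' `scoring_rules()` returns the default rule sets. Score 3 exists only for
#' pooled rule sets (the pooled dataset being the most robust); regional
#' scores top out at 2. Defaults:
#' \itemize{
#'   \item eye, pooled — 3: top-5 F, or |coef| >= 0.1 at alpha 0.2, or nonzero
#'     at 0.5; 2: top-10 F or MI, or nonzero at 0.2; 1: |coef| >= 0.1 at
#'     0.005.
#'   \item eye, regional — 2: top-5 by F *and* MI, or |coef| >= 0.1 at 0.5, or
#'     nonzero at 0.7; 1: top-6 by F and MI, or nonzero at both 0.7 and 0.5.
#'   \item hair, pooled — 3: top-5 F or MI, or |coef| > 0.05 at 0.2, or
#'     nonzero at 0.5; 2: top-10 F or MI; 1: remaining members of the
#'     best-SNPs list.
#'   \item hair, regional — same as eye regional.
#' }
#' The regional "top-k by F and MI" conjunction follows the regional rule
#' wording; set `regional_rank_combine = "or"` for the disjunctive reading.
#'
#' @param trait `"eye"` or `"hair"`.
#' @param kind `"pooled"` or `"regional"`.
#' @param regional_rank_combine combine regional rank clauses with `"and"`
#'   (default) or `"or"`.
#' @return Object of class `scoring_rules` (list of rules).
#' @export
scoring_rules <- function(trait = c("eye", "hair"),
                          kind = c("pooled", "regional"),
                          regional_rank_combine = c("and", "or")) {
  trait <- match.arg(trait)
  kind <- match.arg(kind)
  regional_rank_combine <- match.arg(regional_rank_combine)
  cl <- function(type, ...) c(list(type = type), list(...))
  rule <- function(score, ...) list(score = score, clauses = list(...))
  rtop <- if (regional_rank_combine == "and") "top_f_and_mi" else "top_f_or_mi"

  rules <- if (kind == "regional") {
    list(rule(2L, cl(rtop, k = 5), cl("abs_coef_ge", alpha = 0.5, value = 0.1),
              cl("nonzero", alpha = 0.7)),
         rule(1L, cl(rtop, k = 6), cl("nonzero_all", alphas = c(0.7, 0.5))))
  } else if (trait == "eye") {
    list(rule(3L, cl("top_f", k = 5), cl("abs_coef_ge", alpha = 0.2, value = 0.1),
              cl("nonzero", alpha = 0.5)),
         rule(2L, cl("top_f_or_mi", k = 10), cl("nonzero", alpha = 0.2)),
         rule(1L, cl("abs_coef_ge", alpha = 0.005, value = 0.1)))
  } else {
    list(rule(3L, cl("top_f_or_mi", k = 5),
              cl("abs_coef_gt", alpha = 0.2, value = 0.05),
              cl("nonzero", alpha = 0.5)),
         rule(2L, cl("top_f_or_mi", k = 10)),
         rule(1L, cl("in_best_list")))
  }
  structure(list(trait = trait, kind = kind, rules = rules),
            class = "scoring_rules")
}

clause_holds <- function(clause, scores, best_list) {
  rank_le <- function(r, k) !is.na(r) & r <= k
  coef_at <- function(a) {
    col <- paste0("coef_", a)
    if (!col %in% names(scores)) stop("no lasso coefficients at alpha ", a)
    scores[[col]]
  }
  switch(clause$type,
    top_f = rank_le(scores$f_rank, clause$k),
    top_mi = rank_le(scores$mi_rank, clause$k),
    top_f_or_mi = rank_le(scores$f_rank, clause$k) |
                  rank_le(scores$mi_rank, clause$k),
    top_f_and_mi = rank_le(scores$f_rank, clause$k) &
                   rank_le(scores$mi_rank, clause$k),
    nonzero = abs(coef_at(clause$alpha)) > 1e-8,
    nonzero_all = Reduce(`&`, lapply(clause$alphas,
                                     function(a) abs(coef_at(a)) > 1e-8)),
    abs_coef_ge = abs(coef_at(clause$alpha)) >= clause$value,
    abs_coef_gt = abs(coef_at(clause$alpha)) > clause$value,
    in_best_list = scores$snp_id %in% best_list,
    stop("unknown clause type: ", clause$type)
  )
}

#' Assign per-dataset SNP scores from a rule set
#'
#' Evaluates every rule of the set on a [score_features()] table and assigns
#' each SNP the maximum score among matching rules (0 if none match).
#'
#' @param scores a `feature_scores` table.
#' @param rules a [scoring_rules()] object.
#' @param best_list optional character vector of best-SNP ids (needed by rule
#'   sets with an `in_best_list` clause).
#' @return Data frame `snp_id`, `score`.
#' @export
assign_snp_scores <- function(scores, rules, best_list = NULL) {
  stopifnot(inherits(rules, "scoring_rules"))
  needs_best <- any(vapply(rules$rules, function(r) {
    any(vapply(r$clauses, function(cl) cl$type == "in_best_list", logical(1)))
  }, logical(1)))
  if (needs_best && is.null(best_list))
    stop("this rule set needs a best_list")
  score <- integer(nrow(scores))
  for (r in rules$rules) {
    hit <- Reduce(`|`, lapply(r$clauses, clause_holds, scores = scores,
                              best_list = best_list))
    score <- pmax(score, ifelse(hit, r$score, 0L))
  }
  data.frame(snp_id = scores$snp_id, score = as.integer(score),
             stringsAsFactors = FALSE)
}

#' @rdname assign_snp_scores
#' @export
assign_pooled_eye_scores <- function(scores) {
  assign_snp_scores(scores, scoring_rules("eye", "pooled"))
}

#' @rdname assign_snp_scores
#' @param regional_rank_combine see [scoring_rules()].
#' @export
assign_regional_eye_scores <- function(scores,
                                       regional_rank_combine = "and") {
  assign_snp_scores(scores, scoring_rules("eye", "regional",
                                          regional_rank_combine))
}

#' @rdname assign_snp_scores
#' @export
assign_hair_scores <- function(scores, best_list) {
  assign_snp_scores(scores, scoring_rules("hair", "pooled"),
                    best_list = best_list)
}

#' Narrow a top list to the best SNPs
#'
#' Membership in the best-SNPs list: top-10 by F, top-10 by MI, nonzero lasso
#' coefficients at alphas 0.5 or 0.2, or |coef| >= 0.1 at alpha 0.005.
#'
#' @param scores a `feature_scores` table.
#' @param top_k rank depth (default 10).
#' @param nonzero_alphas alphas whose nonzero sets qualify (default 0.5, 0.2).
#' @param coef_alpha,coef_min absolute-coefficient qualification (default
#'   |coef| >= 0.1 at alpha 0.005).
#' @return Character vector of best SNP ids.
#' @export
best_snp_list <- function(scores, top_k = 10, nonzero_alphas = c(0.5, 0.2),
                          coef_alpha = 0.005, coef_min = 0.1) {
  hit <- (!is.na(scores$f_rank) & scores$f_rank <= top_k) |
    (!is.na(scores$mi_rank) & scores$mi_rank <= top_k)
  for (a in nonzero_alphas) {
    hit <- hit | abs(scores[[paste0("coef_", a)]]) > 1e-8
  }
  hit <- hit | abs(scores[[paste0("coef_", coef_alpha)]]) >= coef_min
  sort(scores$snp_id[hit])
}

#' Merge per-dataset score ledgers and rank by total score
#'
#' Joins the per-dataset score tables over the union of SNPs (a SNP missing
#' from a dataset contributes 0), sums the per-dataset scores into the total
#' score, drops all-zero SNPs, and ranks by descending total; ties break by
#' the number of datasets with a nonzero score, then by `snp_id`.
#'
#' @param ledgers named list of `snp_id`/`score` data frames, one per dataset
#'   (regions plus pooled).
#' @return Object of class `score_ledger`: data frame `snp_id`, one score
#'   column per dataset, `n_datasets` (nonzero count), `total_score`.
#' @export
merge_and_rank <- function(ledgers) {
  stopifnot(length(ledgers) >= 1, !is.null(names(ledgers)),
            all(nzchar(names(ledgers))))
  ids <- sort(unique(unlist(lapply(ledgers, `[[`, "snp_id"))))
  mat <- sapply(ledgers, function(l) {
    s <- l$score[match(ids, l$snp_id)]
    ifelse(is.na(s), 0L, as.integer(s))
  })
  mat <- matrix(mat, nrow = length(ids),
                dimnames = list(NULL, names(ledgers)))
  total <- rowSums(mat)
  keep <- total > 0
  out <- data.frame(snp_id = ids[keep], stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(mat[keep, , drop = FALSE]))
  out$n_datasets <- rowSums(mat[keep, , drop = FALSE] > 0)
  out$total_score <- as.integer(total[keep])
  out <- out[order(-out$total_score, -out$n_datasets, out$snp_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("score_ledger", "data.frame")
  out
}

#' Select the minimal and optimal SNP sets from a ledger
#'
#' The optimal set contains every SNP with a nonzero pooled-dataset score (the
#' best-SNPs list used for the full classifier). The minimal set is the top
#' scoring tier: for eye colour, SNPs whose total score reaches `min_total`
#' (default 3) with support from at least `min_datasets` datasets (default 2);
#' for hair colour, SNPs carrying the maximal pooled score 3.
#'
#' @param ledger a [merge_and_rank()] result.
#' @param trait `"eye"` or `"hair"`.
#' @param pooled name of the pooled score column (default `"pooled"`).
#' @param min_total,min_datasets eye minimal-set thresholds.
#' @param allow_empty return empty sets with a warning instead of an error.
#' @return List with character vectors `minimal` and `optimal`.
#' @export
select_snp_sets <- function(ledger, trait = c("eye", "hair"),
                            pooled = "pooled", min_total = 3,
                            min_datasets = 2, allow_empty = FALSE) {
  trait <- match.arg(trait)
  if (!pooled %in% names(ledger))
    stop("ledger has no pooled column named '", pooled, "'")
  optimal <- ledger$snp_id[ledger[[pooled]] > 0]
  minimal <- if (trait == "eye") {
    ledger$snp_id[ledger$total_score >= min_total &
                    ledger$n_datasets >= min_datasets]
  } else {
    ledger$snp_id[ledger[[pooled]] == 3L]
  }
  complain <- function(what) {
    msg <- paste0(what, " SNP set is empty (no SNP met the selection rules)")
    if (allow_empty) warning(msg) else stop(msg)
  }
  if (!length(optimal)) complain("optimal")
  if (!length(minimal)) complain("minimal")
  list(minimal = minimal, optimal = optimal)
}
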