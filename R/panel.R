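#' Analysis settings for SNP-panel discovery
#'
#' Collects the tunable parameters of the discovery pipeline. Defaults encode
#' the reference workflow: QUAL > 40 and DP > 5 variant QC, 90\% sample call
#' rate, populations needing at least 4 of the 5 grades, a 60:40 stratified
#' split, the F-test p < 0.01 gate, k = 3 MI neighbours, the 9-alpha lasso
#' grid, top-30 top lists, top-10 best-list narrowing, and the eye/hair
#' pooled/regional scoring rule sets.
#'
#' @param qual_min,dp_min variant QC thresholds (exclusive), see
#'   [filter_variants()].
#' @param call_rate_min sample call-rate threshold, see
#'   [filter_samples_by_call_rate()].
#' @param min_distinct_grades population grade-diversity threshold, see
#'   [filter_populations_by_grade_diversity()].
#' @param split_ratio training fraction of the stratified split.
#' @param p_threshold F-test p-value gate.
#' @param k_mi MI neighbour count.
#' @param alphas lasso penalty grid.
#' @param top_k depth of the F/MI top lists (default 30).
#' @param top_list_alphas alphas whose nonzero sets enter the top list.
#' @param best_top_k,best_nonzero_alphas,best_coef_alpha,best_coef_min
#'   best-list narrowing thresholds, see [best_snp_list()].
#' @param regional_rank_combine `"and"` or `"or"` for regional rank clauses,
#'   see [scoring_rules()].
#' @param min_total,min_datasets eye minimal-set selection thresholds, see
#'   [select_snp_sets()].
#' @param min_class_n minimum test-class size for reporting metrics.
#' @param regions optional character vector restricting the analysis to these
#'   regional datasets (default: every region present after filtering).
#' @param eye_mapping,hair_mapping optional custom grade-to-class mappings
#'   (length-5 character vectors, see [class_scale()]).
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(qual_min = 40, dp_min = 5, call_rate_min = 0.90,
                         min_distinct_grades = 4, split_ratio = 0.6,
                         p_threshold = 0.01, k_mi = 3,
                         alphas = c(0.7, 0.5, 0.2, 0.1, 0.05, 0.01,
                                    0.005, 0.001, 0.0005),
                         top_k = 30,
                         top_list_alphas = c(0.5, 0.2, 0.1, 0.01, 0.005),
                         best_top_k = 10, best_nonzero_alphas = c(0.5, 0.2),
                         best_coef_alpha = 0.005, best_coef_min = 0.1,
                         regional_rank_combine = "and",
                         min_total = 3, min_datasets = 2, min_class_n = 10,
                         regions = NULL,
                         eye_mapping = NULL, hair_mapping = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "panel_config"
  cfg
}

panel_scales <- function(trait, config) {
  if (trait == "eye") {
    list(primary = class_scale("eye3", config$eye_mapping))
  } else {
    list(primary = class_scale("hair4", config$hair_mapping),
         merged = class_scale("hair3"))
  }
}

#' Fit a pigmentation SNP panel
#'
#' The central fitting function: given additive-coded genotypes and ordinal
#' phenotypes it (1) drops populations without grade diversity, (2) draws one
#' seeded stratified 60:40 train/test split (strata = class x region, so each
#' region is split in the same proportion inside the pooled dataset), (3) runs
#' the three feature-selection scorers (univariate F test, kNN mutual
#' information, lasso path) on the training samples of the pooled dataset and
#' of each regional dataset, (4) condenses the evidence into 0-3 scores per
#' dataset with the trait's rule sets and ranks SNPs by total score, (5)
#' selects the minimal and optimal SNP sets, and (6) fits a least-squares
#' linear classifier per set on the pooled training samples and evaluates it
#' per class on the held-out test samples. Test-set labels are never touched
#' before step (6).
#'
#' @param genotypes samples x SNPs additive-code matrix (`NA` = missing), as
#'   from [encode_genotypes()] or [simulate_cohort()].
#' @param phenotypes phenotype data frame (`sample_id`, `population`,
#'   `region`, `eye_grade`, `hair_grade`).
#' @param trait `"eye"` or `"hair"`.
#' @param config a [panel_config()].
#' @param seed integer seed controlling the split and the MI jitter.
#' @param split optional pre-computed logical `in_train` vector named by
#'   sample id (overrides the seeded split; used e.g. for paired panel
#'   comparisons).
#' @return An object of class `snp_panel`; see [summary.snp_panel()],
#'   [coef.snp_panel()], [predict.snp_panel()], [plot.snp_panel()].
#' @export
snp_panel <- function(genotypes, phenotypes, trait = c("eye", "hair"),
                      config = panel_config(), seed = 1L, split = NULL) {
  trait <- match.arg(trait)
  stopifnot(inherits(config, "panel_config"))
  grade_col <- paste0(trait, "_grade")

  common <- intersect(phenotypes$sample_id, rownames(genotypes))
  if (!length(common)) stop("no samples shared between genotypes and phenotypes")
  ph <- phenotypes[match(common, phenotypes$sample_id), , drop = FALSE]

  ph <- filter_populations_by_grade_diversity(ph, trait,
                                              config$min_distinct_grades)
  if (!is.null(config$regions)) {
    ph <- ph[ph$region %in% config$regions, , drop = FALSE]
    if (!nrow(ph)) stop("no samples left after region restriction")
  }
  regions <- sort(unique(ph$region))
  G <- genotypes[ph$sample_id, , drop = FALSE]
  y <- ph[[grade_col]]
  scales <- panel_scales(trait, config)
  cls <- apply_scale(y, scales$primary)

  if (is.null(split)) {
    in_train <- stratified_split(paste(cls, ph$region, sep = "|"),
                                 ratio = config$split_ratio, seed = seed)
  } else {
    if (is.null(names(split)) || !all(ph$sample_id %in% names(split)))
      stop("supplied split must be a logical vector named by sample id")
    in_train <- unname(split[ph$sample_id])
  }
  split_df <- data.frame(sample_id = ph$sample_id, region = ph$region,
                         class = as.character(cls), in_train = in_train,
                         stringsAsFactors = FALSE)

  # --- feature selection + scoring per dataset (training samples only) ---
  set.seed(seed)  # MI jitter stream, fixed dataset order
  datasets <- c(list(pooled = rep(TRUE, nrow(ph))),
                stats::setNames(lapply(regions, function(r) ph$region == r),
                                regions))
  features <- list()
  scores <- list()
  best_list <- NULL
  for (ds in names(datasets)) {
    sel <- datasets[[ds]] & in_train
    if (sum(sel) < 3) {
      warning("dataset '", ds, "' has fewer than 3 training samples; skipped")
      next
    }
    Xtr <- impute_missing(G[sel, , drop = FALSE])
    fs <- score_features(Xtr, y[sel], alphas = config$alphas,
                         p_threshold = config$p_threshold, k_mi = config$k_mi)
    features[[ds]] <- fs
    if (ds == "pooled") {
      if (trait == "eye") {
        scores[[ds]] <- assign_snp_scores(fs, scoring_rules("eye", "pooled"))
      } else {
        best_list <- best_snp_list(fs, top_k = config$best_top_k,
                                   nonzero_alphas = config$best_nonzero_alphas,
                                   coef_alpha = config$best_coef_alpha,
                                   coef_min = config$best_coef_min)
        scores[[ds]] <- assign_snp_scores(fs, scoring_rules("hair", "pooled"),
                                          best_list = best_list)
      }
    } else {
      scores[[ds]] <- assign_snp_scores(
        fs, scoring_rules(trait, "regional", config$regional_rank_combine))
    }
  }
  if (is.null(features$pooled)) stop("pooled dataset could not be analysed")

  ledger <- merge_and_rank(scores)
  sets <- select_snp_sets(ledger, trait, pooled = "pooled",
                          min_total = config$min_total,
                          min_datasets = config$min_datasets,
                          allow_empty = TRUE)

  # --- classifier fit on pooled training samples, evaluation on test ---
  train_ids <- ph$sample_id[in_train]
  Ximp <- impute_missing(G, training_sample_ids = train_ids)
  train_means <- colMeans(G[train_ids, , drop = FALSE], na.rm = TRUE)

  models <- list()
  predictions <- list()
  reports <- list()
  for (set_name in c("minimal", "optimal")) {
    snp_set <- intersect(sets[[set_name]], colnames(Ximp))
    if (!length(snp_set)) next
    model <- fit_linear_classifier(Ximp[in_train, , drop = FALSE],
                                   y[in_train], snp_set)
    models[[set_name]] <- model
    pred <- predict_and_classify(model, Ximp[!in_train, , drop = FALSE],
                                 scales$primary)
    predictions[[set_name]] <- pred
    truth <- cls[!in_train]
    rep1 <- evaluate_predictions(pred$score, pred$class, truth,
                                 scales$primary, true_grades = y[!in_train],
                                 min_class_n = config$min_class_n)
    if (trait == "hair") {
      rep3 <- evaluate_predictions(pred$score, merge_blond_brown(pred$class),
                                   merge_blond_brown(truth), scales$merged,
                                   true_grades = y[!in_train],
                                   min_class_n = config$min_class_n)
      reports[[set_name]] <- list(hair4 = rep1, hair3 = rep3)
    } else {
      reports[[set_name]] <- rep1
    }
  }

  out <- list(trait = trait, config = config, seed = seed, scales = scales,
              phenotypes = ph, split = split_df, features = features,
              scores = scores, best_list = best_list, ledger = ledger,
              sets = sets, models = models, predictions = predictions,
              reports = reports, train_means = train_means,
              grades = stats::setNames(y, ph$sample_id),
              genotypes_imputed = Ximp,
              removed_populations = attr(ph, "removed_populations"),
              call = match.call())
  class(out) <- "snp_panel"
  out
}

default_set <- function(object) {
  if (!is.null(object$models$optimal)) "optimal" else "minimal"
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("snp_panel (%s colour), %d samples, %d SNPs, seed %d\n",
              x$trait, nrow(x$split), ncol(x$genotypes_imputed), x$seed))
  cat(sprintf("  datasets: %s\n", paste(names(x$scores), collapse = ", ")))
  cat(sprintf("  minimal set: %d SNPs; optimal set: %d SNPs\n",
              length(x$sets$minimal), length(x$sets$optimal)))
  invisible(x)
}

#' Summarise a fitted SNP panel
#'
#' @param object a [snp_panel()] fit.
#' @param ... unused.
#' @return A `summary.snp_panel` object: the top of the score ledger, the
#'   selected sets and the per-class evaluation reports.
#' @export
summary.snp_panel <- function(object, ...) {
  out <- list(trait = object$trait,
              n_train = sum(object$split$in_train),
              n_test = sum(!object$split$in_train),
              ledger_top = head(as.data.frame(object$ledger), 10),
              sets = object$sets, reports = object$reports)
  class(out) <- "summary.snp_panel"
  out
}

#' @export
print.summary.snp_panel <- function(x, ...) {
  cat(sprintf("SNP panel summary (%s colour): %d train / %d test samples\n\n",
              x$trait, x$n_train, x$n_test))
  cat("Top of the total-score ledger:\n")
  print(x$ledger_top, row.names = FALSE)
  cat(sprintf("\nminimal set (%d): %s\n", length(x$sets$minimal),
              paste(head(x$sets$minimal, 8), collapse = ", ")))
  cat(sprintf("optimal set (%d SNPs)\n", length(x$sets$optimal)))
  for (nm in names(x$reports)) {
    cat("\nEvaluation,", nm, "set:\n")
    r <- x$reports[[nm]]
    if (inherits(r, "evaluation_report")) print(r) else for (s in names(r)) {
      cat(" scale", s, "\n"); print(r[[s]])
    }
  }
  invisible(x)
}

#' @describeIn snp_panel classifier coefficients for one SNP set.
#' @param object,x a fitted `snp_panel`.
#' @param set `"optimal"` or `"minimal"`.
#' @param ... further arguments (unused).
#' @export
coef.snp_panel <- function(object, set = default_set(object), ...) {
  model <- object$models[[set]]
  if (is.null(model)) stop("no fitted model for set '", set, "'")
  coef(model)
}

#' @describeIn snp_panel continuous scores / grades / classes for new
#'   genotypes (missing calls imputed with the training means); with
#'   `newdata = NULL`, the stored held-out test predictions.
#' @param newdata samples x SNPs genotype matrix, or `NULL`.
#' @param type `"score"`, `"grade"` or `"class"`.
#' @export
predict.snp_panel <- function(object, newdata = NULL,
                              set = default_set(object),
                              type = c("score", "grade", "class"), ...) {
  type <- match.arg(type)
  model <- object$models[[set]]
  if (is.null(model)) stop("no fitted model for set '", set, "'")
  if (is.null(newdata)) {
    pred <- object$predictions[[set]]
  } else {
    miss <- setdiff(model$snp_ids, colnames(newdata))
    if (length(miss)) stop("newdata lacks SNP(s): ",
                           paste(head(miss, 5), collapse = ", "))
    X <- newdata[, model$snp_ids, drop = FALSE]
    for (j in seq_len(ncol(X))) {
      na <- is.na(X[, j])
      if (any(na)) X[na, j] <- object$train_means[[model$snp_ids[j]]]
    }
    pred <- predict_and_classify(model, X, object$scales$primary)
  }
  switch(type, score = stats::setNames(pred$score, pred$sample_id),
         grade = stats::setNames(pred$grade, pred$sample_id),
         class = stats::setNames(pred$class, pred$sample_id))
}

#' @describeIn snp_panel training residuals (grade minus linear score).
#' @export
residuals.snp_panel <- function(object, set = default_set(object), ...) {
  model <- object$models[[set]]
  if (is.null(model)) stop("no fitted model for set '", set, "'")
  tr <- object$split$in_train
  X <- object$genotypes_imputed[tr, , drop = FALSE]
  score <- drop(X[, model$snp_ids, drop = FALSE] %*% model$weights) +
    model$intercept
  stats::setNames(object$grades[tr] - score, object$split$sample_id[tr])
}

#' @describeIn snp_panel simulate ordinal grades from the fitted linear
#'   model (linear score plus Gaussian residual noise, cut at the grade
#'   midpoints).
#' @param nsim number of simulated grade vectors.
#' @param seed optional seed for the simulation.
#' @export
simulate.snp_panel <- function(object, nsim = 1, seed = NULL,
                               set = default_set(object), ...) {
  model <- object$models[[set]]
  if (is.null(model)) stop("no fitted model for set '", set, "'")
  if (!is.null(seed)) set.seed(seed)
  tr <- object$split$in_train
  X <- object$genotypes_imputed[tr, , drop = FALSE]
  mu <- drop(X[, model$snp_ids, drop = FALSE] %*% model$weights) +
    model$intercept
  out <- as.data.frame(replicate(nsim, {
    g <- floor(mu + rnorm(length(mu), 0, model$sigma) + 0.5)
    as.integer(pmin(pmax(g, 0), 4))
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  rownames(out) <- object$split$sample_id[tr]
  out
}

roc_points <- function(score, positive) {
  ord <- order(score, decreasing = TRUE)
  tp <- cumsum(positive[ord]) / sum(positive)
  fp <- cumsum(!positive[ord]) / sum(!positive)
  list(fpr = c(0, fp), tpr = c(0, tp))
}

#' @describeIn snp_panel one-vs-rest ROC curves on the held-out test samples.
#' @export
plot.snp_panel <- function(x, set = default_set(x), ...) {
  pred <- x$predictions[[set]]
  if (is.null(pred)) stop("no predictions for set '", set, "'")
  scale <- x$scales$primary
  truth <- factor(x$split$class[!x$split$in_train], levels = scale$levels)
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("One-vs-rest ROC, %s set (%s colour)",
                                set, x$trait), ...)
  cols <- seq_along(scale$levels) + 1L
  shown <- character(0)
  for (i in seq_along(scale$levels)) {
    lv <- scale$levels[i]
    pos <- truth == lv
    if (sum(pos) == 0 || all(pos)) next
    rp <- roc_points(orient_score(pred$score, lv, scale), pos)
    graphics::lines(rp$fpr, rp$tpr, col = cols[i], lwd = 2)
    auc <- auc_mann_whitney(orient_score(pred$score, lv, scale), pos)
    shown <- c(shown, sprintf("%s (AUC %.2f, n=%d)", lv, auc, sum(pos)))
  }
  graphics::legend("bottomright", legend = shown,
                   col = cols[seq_along(shown)], lwd = 2, bty = "n")
  invisible(x)
}

#' Run the full discovery pipeline from files
#'
#' File-based front end: reads a VCF and a phenotype TSV, applies variant QC
#' (QUAL/DP), additive encoding and the sample call-rate filter, fits
#' [snp_panel()], and optionally writes the ledger, the SNP sets, the
#' per-class metrics and a provenance manifest (seed and configuration) to an
#' output directory.
#'
#' @param vcf_path,pheno_path input files.
#' @param trait `"eye"` or `"hair"`.
#' @param config a [panel_config()].
#' @param seed integer seed.
#' @param out_dir optional directory for result artifacts.
#' @return The fitted `snp_panel` (invisibly when `out_dir` is given).
#' @export
snp_panel_from_files <- function(vcf_path, pheno_path,
                                 trait = c("eye", "hair"),
                                 config = panel_config(), seed = 1L,
                                 out_dir = NULL) {
  trait <- match.arg(trait)
  calls <- read_vcf(vcf_path)
  calls <- filter_variants(calls, config$qual_min, config$dp_min)
  G <- encode_genotypes(calls)
  G <- filter_samples_by_call_rate(G, config$call_rate_min)
  ph <- read_phenotypes(pheno_path, G)
  fit <- snp_panel(G, ph, trait, config = config, seed = seed)
  if (is.null(out_dir)) return(fit)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(as.data.frame(fit$ledger), file.path(out_dir, "score_ledger.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(fit$sets$minimal, file.path(out_dir, "minimal_set.txt"))
  writeLines(fit$sets$optimal, file.path(out_dir, "optimal_set.txt"))
  for (nm in names(fit$reports)) {
    r <- fit$reports[[nm]]
    reps <- if (inherits(r, "evaluation_report")) list(primary = r) else r
    for (s in names(reps)) {
      df <- as.data.frame(reps[[s]])
      df$accuracy <- attr(reps[[s]], "accuracy")
      df$r_squared <- attr(reps[[s]], "r_squared")
      write.table(df, file.path(out_dir, sprintf("metrics_%s_%s.tsv", nm, s)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(
    list(trait = trait, seed = seed,
         config = config[!vapply(config, is.null, logical(1))],
         n_samples = nrow(fit$split), removed_variants =
           length(attr(calls, "removed_variants"))),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(fit)
}
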