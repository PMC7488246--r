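#' Stratified train/test split
#'
#' Randomly assigns samples to the training set within each stratum so that
#' each stratum's training fraction matches `ratio` up to integer rounding
#' (within one sample). Strata of size 1 go to training with a warning.
#' Deterministic given `seed`.
#'
#' @param strata vector (factor/character) of stratum labels, one per sample
#'   (typically class, or class x region for a pooled dataset).
#' @param ratio training fraction (default 0.6).
#' @param seed integer seed.
#' @return Logical vector `in_train`, named when `strata` has names.
#' @export
stratified_split <- function(strata, ratio = 0.6, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  strata <- as.character(strata)
  set.seed(seed)
  in_train <- logical(length(strata))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n <- length(idx)
    if (n == 1L) {
      warning("stratum '", s, "' has a single sample; assigned to training")
      in_train[idx] <- TRUE
      next
    }
    n_train <- round(ratio * n)
    n_train <- min(max(n_train, 1L), n - 1L)  # keep both sides non-empty
    in_train[sample(idx, n_train)] <- TRUE
  }
  names(in_train) <- names(strata)
  in_train
}

#' Least-squares linear classifier on a SNP set
#'
#' Ordinary least squares of the ordinal grade on the additive 0/1/2 genotype
#' codes of the selected SNPs. Rank-deficient designs (e.g. SNP sets in
#' perfect LD, or more SNPs than training samples) fall back to a
#' minimally-regularised ridge solve (penalty 1e-6 on the SNP weights, the
#' intercept unpenalised) with a warning.
#'
#' @param X samples x SNPs genotype matrix (imputed).
#' @param y numeric grade target.
#' @param snp_set character vector of SNP ids to use.
#' @return Object of class `snp_classifier`: `snp_ids`, `weights` (named),
#'   `intercept`, `ridge` flag, `sigma` (residual sd on the training data).
#' @export
fit_linear_classifier <- function(X, y, snp_set) {
  if (!length(snp_set)) stop("snp_set is empty")
  missing_snps <- setdiff(snp_set, colnames(X))
  if (length(missing_snps))
    stop("SNP(s) absent from genotypes: ",
         paste(head(missing_snps, 5), collapse = ", "))
  Z <- cbind(`(Intercept)` = 1, X[, snp_set, drop = FALSE])
  n <- nrow(Z)
  qz <- qr(Z)
  ridge <- qz$rank < ncol(Z) || n < ncol(Z)
  if (!ridge) {
    beta <- qr.coef(qz, y)
  } else {
    warning("rank-deficient design; applying ridge fallback (1e-6)")
    ZtZ <- crossprod(Z)
    diag(ZtZ)[-1] <- diag(ZtZ)[-1] + 1e-6
    beta <- drop(solve(ZtZ, crossprod(Z, y)))
  }
  pred <- drop(Z %*% beta)
  out <- list(snp_ids = snp_set,
              weights = stats::setNames(beta[-1], snp_set),
              intercept = unname(beta[1]), ridge = ridge,
              sigma = sqrt(sum((y - pred)^2) / max(n - qz$rank, 1)))
  class(out) <- "snp_classifier"
  out
}

#' @export
print.snp_classifier <- function(x, ...) {
  cat(sprintf("snp_classifier: %d SNPs%s, intercept %.3f\n",
              length(x$snp_ids), if (x$ridge) " (ridge fallback)" else "",
              x$intercept))
  invisible(x)
}

#' @export
coef.snp_classifier <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$weights)
}

#' Continuous scores and hard classes from a fitted classifier
#'
#' The continuous prediction is the linear score; the hard class is the class
#' of the nearest integer grade on the trait's scale (midpoint thresholds,
#' exact midpoints resolving to the darker grade).
#'
#' @param model a [fit_linear_classifier()] result.
#' @param X genotype matrix covering the model's SNPs (imputed).
#' @param scale a [class_scale()] for the trait.
#' @return Data frame `sample_id`, `score`, `grade` (nearest 0-4), `class`.
#' @export
predict_and_classify <- function(model, X, scale) {
  stopifnot(inherits(model, "snp_classifier"), inherits(scale, "class_scale"))
  score <- drop(X[, model$snp_ids, drop = FALSE] %*% model$weights) +
    model$intercept
  grade <- pmin(pmax(floor(score + 0.5), 0), 4)  # x.5 rounds up (darker)
  data.frame(sample_id = rownames(X), score = score, grade = as.integer(grade),
             class = apply_scale(grade, scale), stringsAsFactors = FALSE)
}

#' One-vs-rest AUC by rank statistic
#'
#' Mann-Whitney formulation: probability (ties counted half) that a positive
#' sample scores above a negative one.
#'
#' @param score continuous score oriented towards the positive class.
#' @param positive logical vector marking the positive class.
#' @return AUC in \[0, 1\], or `NA` if either group is empty.
#' @export
auc_mann_whitney <- function(score, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

orient_score <- function(score, level, scale) {
  centers <- scale$centers
  ctr <- centers[[level]]
  if (ctr == min(centers)) -score
  else if (ctr == max(centers)) score
  else -abs(score - ctr)
}

#' Per-class evaluation of an ordinal classifier
#'
#' Computes one-vs-rest AUC from the continuous score (for the extreme classes
#' the score itself, sign-oriented; for middle classes the negative absolute
#' distance to the class's representative grade), precision and recall from
#' the hard classes, overall accuracy, and the r-squared of the continuous
#' prediction against the ordinal grade. Classes with fewer than `min_class_n`
#' test samples are reported `NA` (the "N/A (n)" convention).
#'
#' @param scores continuous predictions.
#' @param hard_classes predicted classes (factor on the scale's levels).
#' @param true_classes true classes (same levels).
#' @param scale the [class_scale()] in use.
#' @param true_grades optional true 0-4 grades for the r-squared (defaults to
#'   the class centers of `true_classes`).
#' @param min_class_n minimum class size for reporting metrics (default 10).
#' @return Object of class `evaluation_report`: data frame `class`, `n`,
#'   `auc`, `precision`, `recall`, with attributes `accuracy`, `r_squared`,
#'   `n_test`.
#' @export
evaluate_predictions <- function(scores, hard_classes, true_classes, scale,
                                 true_grades = NULL, min_class_n = 10) {
  stopifnot(inherits(scale, "class_scale"))
  true_classes <- factor(true_classes, levels = scale$levels)
  hard_classes <- factor(hard_classes, levels = scale$levels)
  if (!length(true_classes)) stop("empty test set")
  rows <- lapply(scale$levels, function(lv) {
    pos <- true_classes == lv
    n <- sum(pos)
    if (n < min_class_n) {
      return(data.frame(class = lv, n = n, auc = NA_real_,
                        precision = NA_real_, recall = NA_real_))
    }
    auc <- auc_mann_whitney(orient_score(scores, lv, scale), pos)
    pred_pos <- hard_classes == lv
    precision <- if (sum(pred_pos) > 0) sum(pred_pos & pos) / sum(pred_pos)
                 else NA_real_
    recall <- sum(pred_pos & pos) / n
    data.frame(class = lv, n = n, auc = auc, precision = precision,
               recall = recall)
  })
  out <- do.call(rbind, rows)
  attr(out, "accuracy") <- mean(hard_classes == true_classes)
  if (is.null(true_grades)) true_grades <- scale$centers[as.character(true_classes)]
  sst <- sum((true_grades - mean(true_grades))^2)
  attr(out, "r_squared") <- if (sst > 0) 1 - sum((true_grades - scores)^2) / sst
                            else NA_real_
  attr(out, "n_test") <- length(true_classes)
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  for (cl in c("auc", "precision", "recall")) y[[cl]] <- round(y[[cl]], digits)
  print(y, row.names = FALSE)
  cat(sprintf("accuracy %.3f, r^2 %.3f on %d test samples (classes with n < min reported NA)\n",
              attr(x, "accuracy"), attr(x, "r_squared"), attr(x, "n_test")))
  invisible(x)
}

#' Read externally produced panel predictions
#'
#' Ingests a CSV of per-sample predictions from an external prediction tool:
#' columns `sample_id`, `predicted_class`, and optionally one probability
#' column per class (named `p_<class>`).
#'
#' @param path CSV path.
#' @param scale the [class_scale()] the predictions use.
#' @return Data frame with validated columns.
#' @export
read_external_predictions <- function(path, scale) {
  pred <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "predicted_class") %in% names(pred)))
    stop("external predictions need sample_id and predicted_class columns")
  bad <- setdiff(unique(pred$predicted_class), scale$levels)
  if (length(bad)) stop("predicted_class outside scale levels: ",
                        paste(bad, collapse = ", "))
  pred
}

#' Evaluate external predictions with the package's own metric path
#'
#' Runs externally supplied per-sample predictions through
#' [evaluate_predictions()] so external panels and the package's classifiers
#' are measured identically (same AUC, N/A and accuracy conventions). When
#' per-class probability columns are present the one-vs-rest AUC for a class
#' uses that class's probability directly; otherwise AUC is computed from the
#' hard labels' implied grades.
#'
#' @param pred external predictions (see [read_external_predictions()]).
#' @param truth phenotype table restricted to the evaluated samples.
#' @param trait `"eye"` or `"hair"`.
#' @param scale the [class_scale()] shared with the comparison.
#' @param min_class_n as in [evaluate_predictions()].
#' @return An `evaluation_report`.
#' @export
evaluate_external <- function(pred, truth, trait = c("eye", "hair"), scale,
                              min_class_n = 10) {
  trait <- match.arg(trait)
  grade_col <- paste0(trait, "_grade")
  missing_s <- setdiff(truth$sample_id, pred$sample_id)
  extra_s <- setdiff(pred$sample_id, truth$sample_id)
  if (length(missing_s) || length(extra_s)) {
    stop("sample mismatch between predictions and truth; missing: ",
         paste(head(missing_s, 5), collapse = ", "), "; extra: ",
         paste(head(extra_s, 5), collapse = ", "))
  }
  pred <- pred[match(truth$sample_id, pred$sample_id), , drop = FALSE]
  hard <- factor(pred$predicted_class, levels = scale$levels)
  true_cls <- apply_scale(truth[[grade_col]], scale)

  prob_cols <- paste0("p_", scale$levels)
  have_probs <- all(prob_cols %in% names(pred))
  if (have_probs) {
    # per-class AUC straight from that class's probability
    rows <- lapply(scale$levels, function(lv) {
      pos <- true_cls == lv
      n <- sum(pos)
      if (n < min_class_n) {
        return(data.frame(class = lv, n = n, auc = NA_real_,
                          precision = NA_real_, recall = NA_real_))
      }
      auc <- auc_mann_whitney(pred[[paste0("p_", lv)]], pos)
      pred_pos <- hard == lv
      data.frame(class = lv, n = n, auc = auc,
                 precision = if (sum(pred_pos) > 0)
                   sum(pred_pos & pos) / sum(pred_pos) else NA_real_,
                 recall = sum(pred_pos & pos) / n)
    })
    out <- do.call(rbind, rows)
    attr(out, "accuracy") <- mean(hard == true_cls, na.rm = FALSE)
    attr(out, "r_squared") <- NA_real_
    attr(out, "n_test") <- length(true_cls)
    class(out) <- c("evaluation_report", "data.frame")
    out
  } else {
    score <- scale$centers[as.character(hard)]
    evaluate_predictions(score, hard, true_cls, scale,
                         true_grades = truth[[grade_col]],
                         min_class_n = min_class_n)
  }
}

#' Side-by-side comparison of two evaluation reports
#'
#' Both reports must cover the same classes (and are expected to come from
#' the same test samples and class scale, e.g. the package's panel versus an
#' external reference panel on one shared split).
#'
#' @param report_a,report_b `evaluation_report` objects.
#' @param labels length-2 character labels for the two panels.
#' @return Data frame with per-class metrics of both reports and their deltas
#'   (b - a), plus an `accuracy` attribute with the two accuracies.
#' @export
compare_panels <- function(report_a, report_b, labels = c("a", "b")) {
  stopifnot(inherits(report_a, "evaluation_report"),
            inherits(report_b, "evaluation_report"))
  if (!identical(report_a$class, report_b$class))
    stop("reports cover different classes: ",
         paste(report_a$class, collapse = "/"), " vs ",
         paste(report_b$class, collapse = "/"))
  if (!identical(report_a$n, report_b$n))
    stop("reports computed on different test compositions")
  out <- data.frame(class = report_a$class, n = report_a$n,
                    stringsAsFactors = FALSE)
  for (m in c("auc", "precision", "recall")) {
    out[[paste0(m, "_", labels[1])]] <- report_a[[m]]
    out[[paste0(m, "_", labels[2])]] <- report_b[[m]]
    out[[paste0(m, "_delta")]] <- report_b[[m]] - report_a[[m]]
  }
  attr(out, "accuracy") <- stats::setNames(
    c(attr(report_a, "accuracy"), attr(report_b, "accuracy")), labels)
  out
}
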