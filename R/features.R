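#' Univariate F-test association scores
#'
#' For each SNP, computes the Pearson correlation r between the additive
#' genotype code and the ordinal grade target (treated as continuous), the
#' corresponding regression F statistic `F = r^2 / (1 - r^2) * (n - 2)` and
#' its upper-tail p-value on (1, n - 2) degrees of freedom. Constant SNPs
#' (zero genotype variance) have undefined correlation; their rows carry `NA`
#' and are excluded from any ranking.
#'
#' @param X samples x SNPs genotype matrix (continuous regressors allowed,
#'   e.g. after mean imputation).
#' @param y numeric grade target; must not be constant.
#' @return Data frame `snp_id`, `r`, `f_score`, `p_value` (one row per SNP).
#' @export
univariate_f_scores <- function(X, y) {
  n <- nrow(X)
  if (n < 3) stop("need at least 3 samples")
  if (length(y) != n) stop("length(y) must match nrow(X)")
  if (var(y) == 0) stop("target y is constant")
  xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm)
  yc <- y - mean(y)
  sxx <- colSums(Xc^2)
  sxy <- colSums(Xc * yc)
  syy <- sum(yc^2)
  r <- ifelse(sxx > 0, sxy / sqrt(sxx * syy), NA_real_)
  # guard |r| = 1 numerical overflow
  r2 <- pmin(r^2, 1 - 1e-15)
  f <- r2 / (1 - r2) * (n - 2)
  p <- pf(f, 1, n - 2, lower.tail = FALSE)
  if (anyNA(r)) {
    message(sum(is.na(r)), " constant SNP(s) excluded from F scoring")
  }
  data.frame(snp_id = colnames(X), r = r, f_score = f, p_value = p,
             stringsAsFactors = FALSE)
}

#' Gate and rank SNPs by F score
#'
#' Keeps SNPs with p-value strictly below `p_threshold` and sorts them by
#' descending F score (ties broken lexicographically by `snp_id` so rankings
#' are deterministic).
#'
#' @param scores output of [univariate_f_scores()].
#' @param p_threshold p-value gate applied before ranking (default 0.01).
#' @return The gated rows, ranked, with a `rank` column.
#' @export
select_by_f <- function(scores, p_threshold = 0.01) {
  keep <- !is.na(scores$p_value) & scores$p_value < p_threshold
  out <- scores[keep, , drop = FALSE]
  out <- out[order(-out$f_score, out$snp_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' k-nearest-neighbour mutual information for one variable pair
#'
#' Nonparametric MI estimate in nats. For a continuous pair the
#' Kraskov-Stoegbauer-Grassberger estimator (variant 1, max-norm) is used;
#' when `x_discrete = TRUE` the mixed discrete/continuous variant (within-class
#' kNN radii) is used instead. Continuous inputs are standardised and a tiny
#' jitter (1e-10 relative) breaks ties, so results depend (negligibly) on the
#' RNG state. Estimates are clipped at zero.
#'
#' @param x,y numeric vectors of equal length.
#' @param k number of neighbours (default 3).
#' @param x_discrete treat `x` as a discrete variable (e.g. genotype codes).
#' @return Non-negative MI estimate in nats.
#' @export
knn_mi <- function(x, y, k = 3, x_discrete = FALSE) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (k >= n) stop("k must be smaller than the number of samples")
  jitter_of <- function(v) {
    s <- sd(v)
    v / ifelse(s > 0, s, 1) + 1e-10 * rnorm(length(v))
  }
  yj <- jitter_of(as.numeric(y))
  if (x_discrete) {
    g <- match(x, sort(unique(x)))
    est <- mi_knn_dc_cpp(as.integer(g), yj, as.integer(k))
  } else {
    xj <- jitter_of(as.numeric(x))
    est <- mi_knn_cc_cpp(xj, yj, as.integer(k))
  }
  max(est, 0)
}

#' Mutual information scores for every SNP
#'
#' Estimates MI between each genotype column (treated as discrete via its
#' distinct values) and the continuous-coded grade target, using the mixed
#' discrete/continuous kNN estimator. The target is standardised and jittered
#' once, shared across SNPs.
#'
#' @param X samples x SNPs genotype matrix.
#' @param y numeric grade target.
#' @param k number of neighbours (default 3).
#' @return Data frame `snp_id`, `mi` (nats, clipped at 0).
#' @export
mutual_info_scores <- function(X, y, k = 3) {
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the number of samples")
  s <- sd(y)
  yj <- y / ifelse(s > 0, s, 1) + 1e-10 * rnorm(n)
  Xg <- matrix(0L, nrow = n, ncol = ncol(X))
  for (j in seq_len(ncol(X))) {
    Xg[, j] <- match(X[, j], sort(unique(X[, j])))
  }
  mi <- mi_knn_dc_matrix_cpp(Xg, yj, as.integer(k))
  data.frame(snp_id = colnames(X), mi = mi, stringsAsFactors = FALSE)
}

#' Lasso linear model by coordinate descent
#'
#' Minimises `(1 / (2 n)) * ||X w - y||^2 + alpha * ||w||_1` with an
#' unpenalised intercept (handled by centring X and y). Regressors are *not*
#' standardised: the absolute-coefficient selection thresholds used downstream
#' (0.1, 0.05) are meaningful on the raw 0/1/2 genotype scale only. Cyclic
#' coordinate descent with active-set sweeps; converged when the largest
#' coefficient update falls below `tol`.
#'
#' @param X samples x SNPs numeric matrix (no missing values).
#' @param y numeric target.
#' @param alpha L1 penalty constant (>= 0).
#' @param w0 optional warm-start coefficient vector.
#' @param tol convergence tolerance on the max coefficient update
#'   (default 1e-6, well below the 0.05/0.1 decision thresholds).
#' @param max_iter sweep budget (default 1e4); non-convergence raises a
#'   warning and flags the result.
#' @return Object of class `lasso_fit`: `coefficients` (named), `intercept`,
#'   `alpha`, `n`, `objective`, `iterations`, `converged`.
#' @export
lasso_fit <- function(X, y, alpha, w0 = NULL, tol = 1e-6, max_iter = 10000L) {
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples")
  if (anyNA(X) || anyNA(y)) stop("X and y must be finite (impute first)")
  if (alpha < 0) stop("alpha must be non-negative")
  if (is.null(w0)) w0 <- numeric(ncol(X))
  xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm)
  ym <- mean(y)
  fit <- lasso_cd_cpp(Xc, y - ym, alpha, w0, tol, as.integer(max_iter))
  if (!fit$converged) {
    warning("lasso coordinate descent did not converge at alpha = ", alpha)
  }
  w <- stats::setNames(as.numeric(fit$w), colnames(X))
  out <- list(coefficients = w, intercept = ym - sum(xm * w), alpha = alpha,
              n = n, objective = fit$objective,
              iterations = fit$iterations, converged = fit$converged)
  class(out) <- "lasso_fit"
  out
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("lasso_fit: alpha = %g, %d / %d nonzero, objective %.6g%s\n",
              x$alpha, sum(abs(x$coefficients) > 1e-8),
              length(x$coefficients), x$objective,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' @export
coef.lasso_fit <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' Lasso regularization path over an alpha grid
#'
#' Fits [lasso_fit()] at each alpha of the grid, warm-starting each fit from
#' the solution at the next larger alpha. Reports per-alpha nonzero counts
#' (|coef| > 1e-8, absorbing solver noise) and the training r-squared of the
#' fitted linear predictor.
#'
#' @param X,y as in [lasso_fit()].
#' @param alphas penalty grid; default is the 9-value grid
#'   0.7, 0.5, 0.2, 0.1, 0.05, 0.01, 0.005, 0.001, 0.0005.
#' @param tol,max_iter passed to [lasso_fit()].
#' @return Object of class `lasso_path`: `coefficients` (SNPs x alphas
#'   matrix), `intercepts`, `alphas` (descending), `n_nonzero`, `r_squared`.
#' @export
lasso_path <- function(X, y,
                       alphas = c(0.7, 0.5, 0.2, 0.1, 0.05, 0.01,
                                  0.005, 0.001, 0.0005),
                       tol = 1e-6, max_iter = 10000L) {
  if (!length(alphas)) stop("alpha grid is empty")
  alphas <- sort(unique(alphas), decreasing = TRUE)
  p <- ncol(X)
  coefs <- matrix(0, nrow = p, ncol = length(alphas),
                  dimnames = list(colnames(X), paste0("alpha_", alphas)))
  intercepts <- numeric(length(alphas))
  r2 <- numeric(length(alphas))
  w <- numeric(p)
  ybar <- mean(y)
  sst <- sum((y - ybar)^2)
  for (i in seq_along(alphas)) {
    fit <- lasso_fit(X, y, alphas[i], w0 = w, tol = tol, max_iter = max_iter)
    w <- unname(fit$coefficients)
    coefs[, i] <- w
    intercepts[i] <- fit$intercept
    pred <- drop(X %*% w) + fit$intercept
    r2[i] <- 1 - sum((y - pred)^2) / sst
  }
  out <- list(coefficients = coefs, intercepts = intercepts, alphas = alphas,
              n_nonzero = colSums(abs(coefs) > 1e-8), r_squared = r2)
  class(out) <- "lasso_path"
  out
}

#' @export
print.lasso_path <- function(x, ...) {
  cat("lasso_path over", length(x$alphas), "alphas\n")
  print(data.frame(alpha = x$alphas, nonzero = unname(x$n_nonzero),
                   train_r2 = round(x$r_squared, 4)), row.names = FALSE)
  invisible(x)
}

path_coef <- function(path, alpha) {
  i <- which(abs(path$alphas - alpha) < 1e-12)
  if (!length(i)) stop("alpha ", alpha, " not on the fitted path")
  path$coefficients[, i]
}

#' Per-SNP feature score table for one dataset
#'
#' Runs the three scorers on one training dataset and assembles the per-SNP
#' table downstream scoring rules consume: Pearson r, F statistic and p-value,
#' the F rank among p-gated SNPs, the MI estimate and rank, and the lasso
#' coefficient at every alpha of the grid. Ranks break ties by higher score
#' then lexicographic `snp_id`.
#'
#' @param X imputed samples x SNPs training genotype matrix.
#' @param y training grade target.
#' @param alphas lasso grid (see [lasso_path()]).
#' @param p_threshold F-test p-value gate preceding the F ranking.
#' @param k_mi MI neighbour count.
#' @return Object of class `feature_scores`: data frame with one row per SNP
#'   and attributes `path` (the `lasso_path`) and `dataset` label.
#' @export
score_features <- function(X, y,
                           alphas = c(0.7, 0.5, 0.2, 0.1, 0.05, 0.01,
                                      0.005, 0.001, 0.0005),
                           p_threshold = 0.01, k_mi = 3) {
  fs <- univariate_f_scores(X, y)
  gated <- select_by_f(fs, p_threshold)
  fs$f_rank <- NA_integer_
  fs$f_rank[match(gated$snp_id, fs$snp_id)] <- gated$rank

  mi <- mutual_info_scores(X, y, k = k_mi)
  fs$mi <- mi$mi[match(fs$snp_id, mi$snp_id)]
  ord <- order(-fs$mi, fs$snp_id)
  fs$mi_rank <- NA_integer_
  fs$mi_rank[ord] <- seq_len(nrow(fs))

  path <- lasso_path(X, y, alphas = alphas)
  cf <- path$coefficients[match(fs$snp_id, rownames(path$coefficients)), ,
                          drop = FALSE]
  colnames(cf) <- paste0("coef_", path$alphas)
  out <- cbind(fs, as.data.frame(cf))
  rownames(out) <- NULL
  attr(out, "path") <- path
  class(out) <- c("feature_scores", "data.frame")
  out
}

#' Assemble the top-SNPs list for a dataset
#'
#' Union of the top-k SNPs by F score (after the p-value gate), the top-k by
#' MI, and the SNPs with nonzero lasso coefficients at the configured alphas;
#' each SNP is annotated with every provenance flag it satisfies and
#' duplicates are collapsed.
#'
#' @param scores a [score_features()] table.
#' @param dataset_label label recorded on the list (e.g. `"pooled"`).
#' @param top_k top-list depth for F and MI (default 30).
#' @param nonzero_alphas alphas whose nonzero sets enter the union
#'   (default 0.5, 0.2, 0.1, 0.01, 0.005).
#' @return Object of class `top_snp_list`: data frame `snp_id`, `in_top_f`,
#'   `in_top_mi`, one `nonzero_<alpha>` column per alpha; attribute
#'   `"dataset"`.
#' @export
build_top_snp_list <- function(scores, dataset_label = "pooled", top_k = 30,
                               nonzero_alphas = c(0.5, 0.2, 0.1, 0.01, 0.005)) {
  in_top_f <- !is.na(scores$f_rank) & scores$f_rank <= top_k
  in_top_mi <- !is.na(scores$mi_rank) & scores$mi_rank <= top_k
  nz <- sapply(nonzero_alphas, function(a) {
    abs(scores[[paste0("coef_", a)]]) > 1e-8
  })
  nz <- matrix(nz, nrow = nrow(scores))
  colnames(nz) <- paste0("nonzero_", nonzero_alphas)
  keep <- in_top_f | in_top_mi | rowSums(nz) > 0
  out <- data.frame(snp_id = scores$snp_id[keep],
                    in_top_f = in_top_f[keep],
                    in_top_mi = in_top_mi[keep],
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(nz[keep, , drop = FALSE]))
  rownames(out) <- NULL
  attr(out, "dataset") <- dataset_label
  class(out) <- c("top_snp_list", "data.frame")
  out
}
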