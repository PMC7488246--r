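test_that("univariate F scores match the closed form and the t-test", {
  # hand-computed example: r = 6/sqrt(40), F = r2/(1-r2)*(n-2) = 27
  fs <- univariate_f_scores(matrix(c(0, 0, 1, 2, 2), ncol = 1,
                                   dimnames = list(NULL, "s1")),
                            c(0, 1, 2, 3, 4))
  expect_equal(fs$r, 6 / sqrt(40), tolerance = 1e-12)
  expect_equal(fs$f_score, 27, tolerance = 1e-9)
  expect_equal(fs$p_value, pf(27, 1, 3, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(fs$p_value, 0.0138, tolerance = 1e-2)

  # F equals the squared slope t statistic of the univariate regression
  set.seed(1)
  for (i in 1:5) {
    n <- sample(20:60, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    fs <- univariate_f_scores(matrix(x, dimnames = list(NULL, "s")), y)
    lmfit <- summary(lm(y ~ x))
    expect_equal(fs$f_score, lmfit$coefficients["x", "t value"]^2,
                 tolerance = 1e-8)
    expect_equal(fs$p_value, lmfit$coefficients["x", "Pr(>|t|)"],
                 tolerance = 1e-8)
  }
})

test_that("p-values are calibrated under the null", {
  set.seed(2)
  n <- 100
  X <- matrix(rnorm(n * 2000), n, dimnames = list(NULL, sprintf("s%04d", 1:2000)))
  y <- rnorm(n)  # independent of every column
  fs <- univariate_f_scores(X, y)
  frac <- mean(fs$p_value < 0.01)
  expect_gt(frac, 0.002)
  expect_lt(frac, 0.02)
  # Kolmogorov distance of p-values from uniform is small
  expect_lt(max(abs(sort(fs$p_value) - (1:2000) / 2000)), 0.05)
})

test_that("constant SNPs are excluded and the F gate precedes ranking", {
  X <- cbind(s_var = c(0, 1, 2, 1, 0, 2), s_const = rep(1, 6))
  expect_message(fs <- univariate_f_scores(X, c(0, 1, 2, 2, 0, 1)), "constant")
  expect_true(is.na(fs$r[fs$snp_id == "s_const"]))
  expect_equal(nrow(select_by_f(fs, p_threshold = 1)), 1)

  # gate precedes ranking: high-F SNP with p >= threshold is dropped
  tab <- data.frame(snp_id = c("a", "b"), r = c(0.9, 0.8),
                    f_score = c(10, 50), p_value = c(0.005, 0.02))
  sel <- select_by_f(tab, 0.01)
  expect_equal(sel$snp_id, "a")
  expect_equal(select_by_f(tab[0, ], 0.01)$snp_id, character(0))

  # deterministic lexicographic tie-break at equal F
  tab2 <- data.frame(snp_id = c("z", "y"), r = 0.5,
                     f_score = c(5, 5), p_value = 0.001)
  expect_equal(select_by_f(tab2, 0.01)$snp_id, c("y", "z"))
})

test_that("kNN mutual information is calibrated on known cases", {
  set.seed(3)
  n <- 1500
  x <- rnorm(n)
  y <- 0.8 * x + sqrt(1 - 0.8^2) * rnorm(n)
  expect_lt(abs(knn_mi(x, y) - (-0.5 * log(1 - 0.64))), 0.1)
  expect_lt(knn_mi(rnorm(n), rnorm(n)), 0.05)

  # deterministic dependence: MI approaches the entropy of the discrete input
  set.seed(4)
  xd <- sample(0:2, 600, replace = TRUE)
  mi_self <- knn_mi(xd, xd, x_discrete = TRUE)
  expect_lt(abs(mi_self - log(3)), 0.2)

  # non-negativity and permutation invariance over random cases
  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(150); y <- rnorm(150)
    p <- sample(150)
    set.seed(100 + i); m1 <- knn_mi(x, y)
    set.seed(100 + i); m2 <- knn_mi(x[p], y[p])
    expect_gte(m1, 0)
    expect_lt(abs(m1 - m2), 0.02)
  }
  expect_error(knn_mi(1:3, 1:3, k = 3), "k must be smaller")
})

test_that("per-SNP MI scores rank deterministic dependence highest", {
  set.seed(6)
  n <- 300
  X <- cbind(signal = sample(0:2, n, replace = TRUE),
             junk1 = sample(0:2, n, replace = TRUE),
             junk2 = sample(0:2, n, replace = TRUE))
  y <- X[, "signal"] + rnorm(n, 0, 0.3)
  mi <- mutual_info_scores(X, y)
  expect_true(all(mi$mi >= 0))
  expect_equal(mi$snp_id[which.max(mi$mi)], "signal")
})

test_that("lasso solutions satisfy closed forms and KKT conditions", {
  set.seed(7)
  n <- 120
  # orthonormalised design (columns orthogonal, each with x'x = n)
  X <- qr.Q(qr(scale(matrix(rnorm(n * 6), n), scale = FALSE))) * sqrt(n)
  colnames(X) <- paste0("s", 1:6)
  y <- drop(X %*% c(1, -0.5, 0.3, 0, 0, 0)) + rnorm(n)
  b <- drop(crossprod(X, y - mean(y))) / n
  for (alpha in c(0.05, 0.2, 0.6)) {
    fit <- lasso_fit(X, y, alpha)
    oracle <- sign(b) * pmax(abs(b) - alpha, 0)
    expect_lt(max(abs(fit$coefficients - oracle)), 1e-6)
  }

  # null-model condition: alpha at or above max correlation kills every weight
  alpha_max <- max(abs(b))
  expect_true(all(lasso_fit(X, y, alpha_max * 1.0001)$coefficients == 0))

  # unpenalised limit recovers OLS
  set.seed(8)
  X2 <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y2 <- drop(X2 %*% c(1, 2, -1, 0)) + rnorm(50)
  f0 <- lasso_fit(X2, y2, 0)
  ols <- coef(lm(y2 ~ X2))
  expect_equal(unname(f0$coefficients), unname(ols[-1]), tolerance = 1e-5)
  expect_equal(f0$intercept, unname(ols[1]), tolerance = 1e-5)

  # KKT: |x'r|/n <= alpha at zeros, = alpha * sign(w) at nonzeros
  set.seed(9)
  X3 <- matrix(rnorm(80 * 30), 80, dimnames = list(NULL, paste0("k", 1:30)))
  y3 <- drop(X3[, 1:3] %*% c(1, -1, 0.5)) + rnorm(80)
  fit3 <- lasso_fit(X3, y3, 0.1)
  Xc <- scale(X3, scale = FALSE)
  r <- (y3 - mean(y3)) - drop(Xc %*% fit3$coefficients)
  grad <- drop(crossprod(Xc, r)) / nrow(X3)
  nz <- abs(fit3$coefficients) > 1e-8
  expect_true(all(abs(grad[!nz]) <= 0.1 + 1e-6))
  expect_true(all(abs(grad[nz] - 0.1 * sign(fit3$coefficients[nz])) < 1e-5))

  # objective never exceeds the all-zero or OLS objectives
  obj <- function(w) sum(((y3 - mean(y3)) - Xc %*% w)^2) / (2 * 80) +
    0.1 * sum(abs(w))
  expect_lte(fit3$objective, obj(numeric(30)) + 1e-10)
  expect_lte(fit3$objective, obj(unname(coef(lm(y3 ~ X3))[-1])) + 1e-10)
})

test_that("lasso matches brute-force grid search on a 2-parameter problem", {
  set.seed(10)
  X <- matrix(rnorm(60 * 2), 60, 2, dimnames = list(NULL, c("a", "b")))
  y <- drop(X %*% c(0.8, -0.4)) + rnorm(60, 0, 0.5)
  alpha <- 0.1
  fit <- lasso_fit(X, y, alpha)
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  grid <- seq(-1.5, 1.5, by = 5e-4)
  obj_w1 <- function(w1) {
    # for fixed w1 the optimal w2 is the soft-thresholded partial residual
    r1 <- yc - Xc[, 1] * w1
    w2 <- sign(crossprod(Xc[, 2], r1)) *
      pmax(abs(crossprod(Xc[, 2], r1)) / 60 - alpha, 0) / (sum(Xc[, 2]^2) / 60)
    sum((r1 - Xc[, 2] %*% w2)^2) / 120 + alpha * (abs(w1) + abs(w2))
  }
  objs <- vapply(grid, obj_w1, numeric(1))
  expect_lt(abs(grid[which.min(objs)] - fit$coefficients["a"]), 1e-3)
  expect_lte(fit$objective, min(objs) + 1e-6)
})

test_that("lasso agrees with an independent solver", {
  set.seed(11)
  X <- matrix(rnorm(100 * 20), 100, dimnames = list(NULL, paste0("g", 1:20)))
  y <- drop(X[, 1:4] %*% c(1, -0.7, 0.5, 0.3)) + rnorm(100)
  for (alpha in c(0.3, 0.05)) {
    fit <- lasso_fit(X, y, alpha)
    ref <- glmnet::glmnet(X, y, lambda = alpha, standardize = FALSE,
                          thresh = 1e-12)
    expect_lt(max(abs(fit$coefficients - as.numeric(ref$beta))), 1e-4)
  }
})

test_that("the regularization path is sparse-monotone and warm-start safe", {
  grid9 <- c(0.7, 0.5, 0.2, 0.1, 0.05, 0.01, 0.005, 0.001, 0.0005)

  set.seed(12)
  X <- matrix(rnorm(90 * 50), 90, dimnames = list(NULL, sprintf("r%02d", 1:50)))
  y <- drop(X[, 1:5] %*% seq(1, 0.2, length.out = 5)) + rnorm(90)
  path <- lasso_path(X, y, alphas = grid9)
  expect_equal(path$alphas, sort(grid9, decreasing = TRUE))
  # fewer features at higher alpha
  expect_true(all(diff(unname(path$n_nonzero)) >= 0))  # stored descending
  # training r2 grows as the penalty relaxes
  expect_true(all(diff(path$r_squared) >= -1e-8))

  # one-alpha grid equals a single fit
  single <- lasso_path(X, y, alphas = 0.1)
  expect_equal(single$coefficients[, 1], lasso_fit(X, y, 0.1)$coefficients)

  # warm-started path solutions match cold starts
  for (i in c(3, 6)) {
    cold <- lasso_fit(X, y, path$alphas[i])
    expect_lt(max(abs(path$coefficients[, i] - cold$coefficients)), 1e-5)
  }
  expect_error(lasso_path(X, y, alphas = numeric(0)), "empty")
})

test_that("top-SNP lists reproduce a brute-force union of provenance flags", {
  set.seed(13)
  n_snp <- 40
  tab <- toy_scores(n_snp)
  tab$f_rank[sample(n_snp, 25)] <- sample(25)
  tab$mi_rank <- sample(n_snp)
  tab$coef_0.5 <- ifelse(runif(n_snp) < 0.1, rnorm(n_snp), 0)
  tab$coef_0.2 <- ifelse(runif(n_snp) < 0.2, rnorm(n_snp), 0)
  tab$coef_0.005 <- ifelse(runif(n_snp) < 0.5, rnorm(n_snp), 0)
  top <- build_top_snp_list(tab, "pooled", top_k = 10,
                            nonzero_alphas = c(0.5, 0.2, 0.005))

  # independent brute-force recomputation, SNP by SNP
  for (i in seq_len(n_snp)) {
    in_f <- !is.na(tab$f_rank[i]) && tab$f_rank[i] <= 10
    in_mi <- tab$mi_rank[i] <= 10
    nz <- abs(c(tab$coef_0.5[i], tab$coef_0.2[i], tab$coef_0.005[i])) > 1e-8
    should_appear <- in_f || in_mi || any(nz)
    appears <- tab$snp_id[i] %in% top$snp_id
    expect_equal(appears, should_appear)
    if (appears) {
      row <- top[top$snp_id == tab$snp_id[i], ]
      expect_equal(row$in_top_f, in_f)
      expect_equal(row$in_top_mi, in_mi)
      expect_equal(unname(unlist(row[paste0("nonzero_",
                                            c(0.5, 0.2, 0.005))])), nz)
    }
  }
  # duplicates collapsed: one row per SNP
  expect_equal(anyDuplicated(top$snp_id), 0)
})
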