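test_that("stratified splitting hits the 60:40 ratio inside every stratum", {
  strata <- rep(c("A", "B"), c(60, 40))
  tr <- stratified_split(strata, 0.6, seed = 1)
  expect_equal(sum(tr), 60)
  expect_equal(sum(tr[strata == "A"]), 36)
  expect_equal(sum(tr[strata == "B"]), 24)

  # one class only: plain 60:40
  tr1 <- stratified_split(rep("only", 50), 0.6, seed = 2)
  expect_equal(sum(tr1), 30)

  # every stratum size 2..50: train fraction within one sample of 60%
  sizes <- 2:50
  strata2 <- rep(sprintf("s%02d", sizes), sizes)
  tr2 <- stratified_split(strata2, 0.6, seed = 3)
  for (s in unique(strata2)) {
    n <- sum(strata2 == s)
    expect_lte(abs(sum(tr2[strata2 == s]) - 0.6 * n), 1)
  }

  # singleton stratum goes to training, with a warning
  expect_warning(tr3 <- stratified_split(c("a", "a", "lone"), 0.6, seed = 4),
                 "single sample")
  expect_true(tr3[3])

  # deterministic given the seed
  expect_identical(stratified_split(strata, 0.6, seed = 9),
                   stratified_split(strata, 0.6, seed = 9))
})

test_that("the linear classifier solves the normal equations", {
  # single SNP, exactly linear: slope recovered, zero residual
  X <- matrix(c(0, 1, 2, 0, 1, 2), ncol = 1, dimnames = list(NULL, "s1"))
  rownames(X) <- paste0("i", 1:6)
  y <- 2 * X[, 1] + 0.5
  m <- fit_linear_classifier(X, y, "s1")
  expect_equal(unname(m$weights), 2, tolerance = 1e-10)
  expect_equal(m$intercept, 0.5, tolerance = 1e-10)
  expect_equal(m$sigma, 0, tolerance = 1e-8)

  # random instances match lm
  set.seed(30)
  for (i in 1:5) {
    Xr <- matrix(sample(0:2, 40 * 4, replace = TRUE), 40,
                 dimnames = list(paste0("n", 1:40), paste0("g", 1:4)))
    yr <- rnorm(40)
    mr <- fit_linear_classifier(Xr, yr, colnames(Xr))
    ref <- coef(lm(yr ~ Xr))
    expect_equal(unname(mr$weights), unname(ref[-1]), tolerance = 1e-8)
  }

  # collinear SNP set triggers the ridge fallback but stays finite
  Xc <- cbind(a = c(0, 1, 2, 1), b = c(0, 1, 2, 1), c = c(1, 0, 1, 2))
  rownames(Xc) <- paste0("r", 1:4)
  expect_warning(mc <- fit_linear_classifier(Xc, c(0, 1, 2, 1),
                                             colnames(Xc)), "rank-deficient")
  expect_true(all(is.finite(mc$weights)))
  expect_true(mc$ridge)
  expect_error(fit_linear_classifier(Xc, 1:4, character(0)), "empty")
})

test_that("continuous scores map to classes at grade midpoints", {
  m <- structure(list(snp_ids = "s", weights = c(s = 1), intercept = 0,
                      ridge = FALSE, sigma = 0), class = "snp_classifier")
  sc <- class_scale("eye3")
  X <- matrix(c(3.9, 2.5, 0.2, -1, 9), ncol = 1,
              dimnames = list(paste0("p", 1:5), "s"))
  pred <- predict_and_classify(m, X, sc)
  expect_equal(pred$grade, c(4L, 3L, 0L, 0L, 4L))  # 2.5 rounds darker; clipped
  expect_equal(as.character(pred$class),
               c("brown", "brown", "blue", "blue", "brown"))

  # constant model: one class for everybody
  m0 <- structure(list(snp_ids = "s", weights = c(s = 0), intercept = 2,
                       ridge = FALSE, sigma = 0), class = "snp_classifier")
  pred0 <- predict_and_classify(m0, X, sc)
  expect_equal(unique(as.character(pred0$class)), "intermediate")
})

test_that("AUC equals brute-force pairwise concordance", {
  # perfectly separating scores
  expect_equal(auc_mann_whitney(c(1, 2, 3, 10, 11), c(F, F, F, T, T)), 1)
  # constant score is chance level
  expect_equal(auc_mann_whitney(rep(1, 10), rep(c(T, F), 5)), 0.5)
  expect_true(is.na(auc_mann_whitney(1:3, c(TRUE, TRUE, TRUE))))

  brute_auc <- function(score, pos) {
    s1 <- score[pos]; s0 <- score[!pos]
    cmp <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(31)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    score <- sample(1:8, n, replace = TRUE)  # ties included
    pos <- runif(n) < 0.4
    if (!any(pos) || all(pos)) next
    expect_equal(auc_mann_whitney(score, pos), brute_auc(score, pos))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(32)
  score <- rnorm(200)
  pos <- runif(200) < plogis(score)
  expect_equal(auc_mann_whitney(score, pos),
               as.numeric(pROC::auc(pROC::roc(pos, score, quiet = TRUE,
                                              direction = "<"))))
})

test_that("evaluation reports respect the N/A convention and count bookkeeping", {
  sc <- class_scale("eye3")
  set.seed(33)
  grades <- c(rep(0, 30), rep(2, 4), rep(4, 30))  # tiny intermediate class
  truth <- eye_grade_to_class(grades)
  score <- grades + rnorm(64, 0, 0.8)
  hard <- eye_grade_to_class(pmin(pmax(round(score), 0), 4))
  rep1 <- evaluate_predictions(score, hard, truth, sc, true_grades = grades)
  expect_equal(rep1$n, c(30, 4, 30))
  expect_true(is.na(rep1$auc[rep1$class == "intermediate"]))
  expect_true(all(rep1$auc[!is.na(rep1$auc)] >= 0 &
                    rep1$auc[!is.na(rep1$auc)] <= 1))
  expect_equal(sum(rep1$n), attr(rep1, "n_test"))

  # perfectly separating scores give AUC 1 for the extreme classes
  rep2 <- evaluate_predictions(grades, truth, truth, sc, true_grades = grades)
  expect_equal(rep2$auc[rep2$class == "blue"], 1)
  expect_equal(rep2$auc[rep2$class == "brown"], 1)
  expect_equal(attr(rep2, "accuracy"), 1)

  # extreme-class AUC is invariant under strictly monotone score transforms
  mono <- exp(score / 2)
  rep3 <- evaluate_predictions(mono, hard, truth, sc, true_grades = grades)
  expect_equal(rep3$auc[rep3$class == "blue"], rep1$auc[rep1$class == "blue"])
  expect_equal(rep3$auc[rep3$class == "brown"], rep1$auc[rep1$class == "brown"])
})

test_that("external predictions run through the shared evaluation path", {
  sc <- class_scale("eye3")
  truth <- data.frame(sample_id = sprintf("s%02d", 1:40),
                      eye_grade = rep(c(0L, 4L), 20))
  pred <- data.frame(sample_id = truth$sample_id,
                     predicted_class = ifelse(truth$eye_grade == 0,
                                              "blue", "brown"))
  path <- tempfile(fileext = ".csv")
  write.csv(pred, path, row.names = FALSE)
  ext <- read_external_predictions(path, sc)
  repx <- evaluate_external(ext, truth, "eye", sc)
  expect_equal(attr(repx, "accuracy"), 1)
  expect_true(is.na(repx$auc[repx$class == "intermediate"]))  # n = 0 -> N/A

  # identical reports compare with zero deltas
  cmp <- compare_panels(repx, repx)
  expect_true(all(cmp$auc_delta[!is.na(cmp$auc_delta)] == 0))

  # a missing sample is a hard error listing the discrepancy
  expect_error(evaluate_external(ext[-1, ], truth, "eye", sc),
               "sample mismatch")

  # probability columns drive the per-class AUC when present
  pred$p_blue <- ifelse(truth$eye_grade == 0, 0.9, 0.1)
  pred$p_intermediate <- 0.05
  pred$p_brown <- 1 - pred$p_blue - pred$p_intermediate
  write.csv(pred, path, row.names = FALSE)
  repp <- evaluate_external(read_external_predictions(path, sc), truth,
                            "eye", sc)
  expect_equal(repp$auc[repp$class == "blue"], 1)
})
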