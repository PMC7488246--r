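test_that("pooled eye scoring rules assign the quoted scores", {
  tab <- toy_scores(6)
  tab$f_rank[1] <- 1                 # top-5 F            -> 3
  tab$mi_rank[2] <- 8                # top-10 MI only     -> 2
  tab$coef_0.005[3] <- 0.12          # |coef|>=0.1 @0.005 -> 1
  tab$coef_0.2[4] <- 0.12            # |coef|>=0.1 @0.2   -> 3
  tab$coef_0.5[5] <- 0.01            # nonzero @0.5       -> 3
  # snp 6 matches nothing            -> 0
  sc <- assign_pooled_eye_scores(tab)
  expect_equal(sc$score, c(3L, 2L, 1L, 3L, 3L, 0L))

  # nonzero (but small) coefficient at alpha 0.2 gives 2, not 3
  tab2 <- toy_scores(1); tab2$coef_0.2[1] <- 0.05
  expect_equal(assign_pooled_eye_scores(tab2)$score, 2L)

  # boundary: exactly 0.1 at alpha 0.2 satisfies the >= rule
  tab3 <- toy_scores(1); tab3$coef_0.2[1] <- 0.1
  expect_equal(assign_pooled_eye_scores(tab3)$score, 3L)
})

test_that("regional scoring rules use the rank conjunction and alpha 0.7", {
  tab <- toy_scores(5)
  tab$f_rank[1] <- 3; tab$mi_rank[1] <- 4    # top-5 by F AND MI -> 2
  tab$coef_0.7[2] <- 0.02                    # nonzero @0.7      -> 2
  tab$f_rank[3] <- 6; tab$mi_rank[3] <- 6    # top-6 both        -> 1
  tab$f_rank[4] <- 2                         # top-5 F only (AND) -> 0
  sc <- assign_regional_eye_scores(tab)
  expect_equal(sc$score, c(2L, 2L, 1L, 0L, 0L))
  expect_true(all(sc$score <= 2L))  # score 3 is pooled-only

  # disjunctive reading is available as a configuration
  sc_or <- assign_regional_eye_scores(tab, regional_rank_combine = "or")
  expect_equal(sc_or$score[4], 2L)
})

test_that("hair scoring uses the strict 0.05 threshold and the best list", {
  tab <- toy_scores(5)
  tab$coef_0.2[1] <- 0.06             # |coef| > 0.05 @0.2 -> 3
  tab$coef_0.2[2] <- 0.05             # not strictly above -> needs other rule
  tab$f_rank[3] <- 9                  # top-10 F           -> 2
  best <- c("snp002", "snp004")       # rest of best list  -> 1
  sc <- assign_hair_scores(tab, best)
  expect_equal(sc$score, c(3L, 1L, 2L, 1L, 0L))
  expect_error(assign_hair_scores(tab, NULL), "best_list")
})

test_that("a SNP takes the maximum score over all matching rules", {
  tab <- toy_scores(1)
  tab$f_rank[1] <- 1          # score-3 rule
  tab$coef_0.005[1] <- 0.5    # score-1 rule
  expect_equal(assign_pooled_eye_scores(tab)$score, 3L)
})

test_that("scores match an independent brute-force rule evaluator", {
  # plain-transcription evaluators, written independently of the rule engine
  brute_pooled_eye <- function(row) {
    s3 <- (!is.na(row$f_rank) && row$f_rank <= 5) ||
      abs(row$coef_0.2) >= 0.1 || abs(row$coef_0.5) > 1e-8
    s2 <- (!is.na(row$f_rank) && row$f_rank <= 10) ||
      (!is.na(row$mi_rank) && row$mi_rank <= 10) || abs(row$coef_0.2) > 1e-8
    s1 <- abs(row$coef_0.005) >= 0.1
    if (s3) 3L else if (s2) 2L else if (s1) 1L else 0L
  }
  brute_regional <- function(row) {
    top <- function(k) (!is.na(row$f_rank) && row$f_rank <= k) &&
      (!is.na(row$mi_rank) && row$mi_rank <= k)
    s2 <- top(5) || abs(row$coef_0.5) >= 0.1 || abs(row$coef_0.7) > 1e-8
    s1 <- top(6) || (abs(row$coef_0.7) > 1e-8 && abs(row$coef_0.5) > 1e-8)
    if (s2) 2L else if (s1) 1L else 0L
  }
  brute_hair <- function(row, best) {
    s3 <- (!is.na(row$f_rank) && row$f_rank <= 5) ||
      (!is.na(row$mi_rank) && row$mi_rank <= 5) ||
      abs(row$coef_0.2) > 0.05 || abs(row$coef_0.5) > 1e-8
    s2 <- (!is.na(row$f_rank) && row$f_rank <= 10) ||
      (!is.na(row$mi_rank) && row$mi_rank <= 10)
    s1 <- row$snp_id %in% best
    if (s3) 3L else if (s2) 2L else if (s1) 1L else 0L
  }

  set.seed(20)
  for (rep in 1:5) {
    n <- 30
    tab <- toy_scores(n)
    tab$f_rank[sample(n, 15)] <- sample(15)
    tab$mi_rank <- sample(n)
    for (a in c(0.7, 0.5, 0.2, 0.005)) {
      tab[[paste0("coef_", a)]] <-
        ifelse(runif(n) < 0.3, round(rnorm(n, 0, 0.15), 3), 0)
    }
    best <- sample(tab$snp_id, 8)
    expect_equal(assign_pooled_eye_scores(tab)$score,
                 vapply(seq_len(n), function(i) brute_pooled_eye(tab[i, ]),
                        integer(1)))
    expect_equal(assign_regional_eye_scores(tab)$score,
                 vapply(seq_len(n), function(i) brute_regional(tab[i, ]),
                        integer(1)))
    expect_equal(assign_hair_scores(tab, best)$score,
                 vapply(seq_len(n), function(i) brute_hair(tab[i, ], best),
                        integer(1)))
  }
})

test_that("improving a SNP's evidence never lowers its score", {
  set.seed(21)
  for (rep in 1:10) {
    tab <- toy_scores(10)
    tab$f_rank[sample(10, 5)] <- sample(5)
    tab$mi_rank <- sample(10)
    tab$coef_0.2 <- ifelse(runif(10) < 0.4, rnorm(10, 0, 0.1), 0)
    tab$coef_0.005 <- ifelse(runif(10) < 0.5, rnorm(10, 0, 0.1), 0)
    before <- assign_pooled_eye_scores(tab)$score
    i <- sample(10, 1)
    tab$f_rank[i] <- 1L                      # best possible F rank
    tab$coef_0.2[i] <- sign(tab$coef_0.2[i] + 0.01) *
      (abs(tab$coef_0.2[i]) + 0.2)           # larger |coef|
    after <- assign_pooled_eye_scores(tab)$score
    expect_gte(after[i], before[i])
    expect_equal(after[-i], before[-i])
  }
})

test_that("ledger merging sums scores, drops zeros and ranks deterministically", {
  ledgers <- list(
    caucasus = data.frame(snp_id = c("a", "b", "zero"), score = c(2L, 1L, 0L)),
    west_siberia = data.frame(snp_id = c("a", "c"), score = c(2L, 1L)),
    european_russia = data.frame(snp_id = "a", score = 2L),
    pooled = data.frame(snp_id = c("a", "b"), score = c(3L, 2L)))
  led <- merge_and_rank(ledgers)
  # (2,2,2,3) across four datasets sums to 9, missing entries count 0
  expect_equal(led$total_score[led$snp_id == "a"], 9L)
  expect_equal(led$total_score[led$snp_id == "b"], 3L)
  expect_equal(led$total_score[led$snp_id == "c"], 1L)
  expect_false("zero" %in% led$snp_id)   # all-zero SNPs excluded
  expect_equal(led$snp_id, c("a", "b", "c"))  # ranked by total

  # dataset order never changes totals
  led2 <- merge_and_rank(rev(ledgers))
  expect_equal(led2$total_score[match(led$snp_id, led2$snp_id)],
               led$total_score)

  # ties break by multi-dataset support, then snp_id
  tie <- merge_and_rank(list(
    r1 = data.frame(snp_id = c("x", "y"), score = c(2L, 1L)),
    pooled = data.frame(snp_id = c("y", "z"), score = c(1L, 2L))))
  expect_equal(tie$snp_id, c("y", "x", "z"))  # y: 2 datasets beats x, z
})

test_that("SNP set selection follows the trait rules", {
  ledgers <- eye_reference_scores(as_ledgers = TRUE)
  led <- merge_and_rank(ledgers)
  sets <- select_snp_sets(led, "eye")
  expect_length(sets$minimal, 7)
  expect_length(sets$optimal, 36)
  expect_true(all(sets$minimal %in% sets$optimal))

  # hair minimal = pooled score 3
  hl <- merge_and_rank(list(pooled = data.frame(
    snp_id = c("a", "b", "c"), score = c(3L, 2L, 1L))))
  hs <- select_snp_sets(hl, "hair")
  expect_equal(hs$minimal, "a")
  expect_length(hs$optimal, 3)

  # degenerate single-dataset ledger: relaxed thresholds make the tiers merge
  one <- merge_and_rank(list(pooled = data.frame(
    snp_id = c("a", "b"), score = c(2L, 2L))))
  s1 <- select_snp_sets(one, "eye", min_total = 2, min_datasets = 1)
  expect_equal(s1$minimal, s1$optimal)

  # adding a zero-score SNP changes nothing
  led_plus <- merge_and_rank(c(ledgers, list(extra = data.frame(
    snp_id = "novel", score = 0L))))
  expect_equal(select_snp_sets(led_plus, "eye")$minimal, sets$minimal)

  # empty selection is an explicit error (or a warning when tolerated)
  null_led <- merge_and_rank(list(pooled = data.frame(snp_id = "a", score = 1L),
                                  r1 = data.frame(snp_id = "b", score = 1L)))
  expect_error(select_snp_sets(null_led, "hair"), "empty")
  expect_warning(select_snp_sets(null_led, "hair", allow_empty = TRUE),
                 "empty")
})
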