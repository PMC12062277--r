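test_that("the empirical FDR matches direct count arithmetic", {
  observed <- c(5, 4, 1)
  nulls <- c(2, 0, 0, 4, 0, 0)    # two permutations pooled
  expect_equal(empirical_fdr(observed, nulls, B = 2, pi0 = 0.97, d = 3),
               0.2425)
  # one-line brute-force recount on random pools
  set.seed(3)
  for (i in 1:20) {
    obs <- rpois(30, 3); np <- rpois(60, 3); d <- sample(0:5, 1)
    if (sum(obs > d) == 0) next
    brute <- 0.9 * (sum(np > d) / 4) / sum(obs > d)
    expect_equal(empirical_fdr(obs, np, B = 4, pi0 = 0.9, d = d), brute)
  }
  # null pool entirely below the observed scores: FDR 0
  expect_equal(empirical_fdr(c(5, 4), c(0.1, 0.2), B = 1, d = 1), 0)
  expect_error(empirical_fdr(c(1, 2), c(3), B = 1, d = 5),
               class = "graphomix_undefined_threshold")
})

test_that("pi0 = 1 with exchangeable scores gives FDR near one at the median", {
  set.seed(8)
  scores <- rnorm(2000)
  obs <- scores[1:1000]
  np <- scores[1001:2000]
  d <- median(scores)
  expect_lt(abs(empirical_fdr(obs, np, B = 1, pi0 = 1, d = d) - 1), 0.15)
})

test_that("threshold selection scans count-change points", {
  # worked example: d* = 3 at target 0.25 with FDR 0.2425
  dec <- select_threshold(c(5, 4, 1), c(2, 0, 0, 4, 0, 0), B = 2,
                          pi0 = 0.97, target = 0.25)
  expect_true(dec$achieved)
  expect_equal(dec$threshold, 3)
  expect_equal(dec$fdr, 0.2425)
  expect_equal(sum(dec$informative), 2)    # scores 5 and 4

  # null pool all zeros: every observed score is informative at FDR 0
  dec0 <- select_threshold(c(5, 4, 1), rep(0, 6), B = 2, target = 0.05)
  expect_true(dec0$achieved)
  expect_equal(dec0$fdr, 0)
  expect_equal(sum(dec0$informative), 3)

  # unattainable target: no threshold, minimum attainable FDR reported
  dec1 <- select_threshold(c(1, 2), c(1, 2, 1.5, 2.5), B = 1, pi0 = 1,
                           target = 1e-6)
  expect_false(dec1$achieved)
  expect_true(is.na(dec1$threshold))
  expect_gt(dec1$min_fdr, 1e-6)
  expect_false(any(dec1$informative))
  expect_s3_class(tidy(dec), "tbl_df")
  expect_s3_class(autoplot(dec), "ggplot")
})

test_that("informative calls require correct prediction and a passed threshold", {
  attr <- tibble::tibble(
    sample_id = rep(c("s1", "s2", "s3"), each = 2),
    feature = rep(c("GA", "GB"), 3),
    phi = c(5, 0.1, 3, 4, 9, 9)
  )
  preds <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                          predicted = c(1, 0, 0), label = c(1, 0, 1))
  calls <- call_informative(attr, d_star = 2, preds)
  # s3 is misclassified: excluded no matter the scores
  expect_false("s3" %in% calls$sample_id)
  expect_setequal(paste(calls$sample_id, calls$feature),
                  c("s1 GA", "s2 GA", "s2 GB"))
  # all scores below the threshold: no calls
  expect_equal(nrow(call_informative(attr, d_star = 100, preds)), 0)
})

test_that("marker ranking follows mean fraction with documented tie-breaks", {
  sets <- list(
    A = tibble::tibble(sample_id = c(paste0("a", 1:8), paste0("a", 1:2)),
                       feature = c(rep("GX", 8), rep("GY", 2))),
    B = tibble::tibble(sample_id = paste0("b", 1:6), feature = rep("GX", 6))
  )
  rk <- rank_markers(sets, c(A = 10, B = 10))
  gx <- rk[rk$feature == "GX", ]
  expect_equal(gx$mean_fraction, mean(c(0.8, 0.6)))   # 8/10 and 6/10
  expect_equal(rk$feature[1], "GX")

  # the same sample counted once even if called in both modalities
  dup <- list(A = tibble::tibble(sample_id = c("a1", "a1"),
                                 feature = c("GZ", "GZ")))
  rkd <- rank_markers(dup, c(A = 4))
  expect_equal(rkd$mean_fraction[rkd$feature == "GZ"], 0.25)

  # never-informative markers are absent; zero-correct studies excluded
  expect_warning(rk2 <- rank_markers(c(sets, list(C = sets$A[0, ])),
                                     c(A = 10, B = 10, C = 0)),
                 "excluded")
  expect_equal(rk2$mean_fraction[rk2$feature == "GX"], mean(c(0.8, 0.6)))
})

test_that("null-model pools permute labels reproducibly", {
  co <- tiny_cohort(n_complete = 10L, n1 = 0L, n2 = 0L, d = c(8L, 8L))
  seen <- list()
  factory <- function(cohort, seed) {
    seen[[length(seen) + 1L]] <<- cohort$labels
    rep(0.5, length(cohort$labels) * 8)   # one score per sample x node
  }
  pool <- train_null_models(co, factory, B = 1, seed = 4)
  expect_equal(length(pool$pool), 10 * 8)
  # permutation preserves the label multiset
  expect_equal(sort(seen[[1]]), sort(co$labels))
  # fixed seed: identical permutation sequence
  seen2 <- list()
  factory2 <- function(cohort, seed) { seen2[[length(seen2) + 1L]] <<- cohort$labels; 0 }
  train_null_models(co, factory2, B = 3, seed = 4)
  train_null_models(co, factory2, B = 3, seed = 4)
  expect_identical(seen2[1:3], seen2[4:6])
})

test_that("repeat aggregation retains and ranks interactions by the 3-of-10 rule", {
  pairs <- c("lip:apo", "lip:mit", "cel:mit", "syn:end")
  counts <- lapply(1:10, function(r) {
    setNames(c(100, 80, 60, 40) + r, pairs)
  })
  tops <- c(rep(list("lip:apo"), 5), rep(list(c("lip:mit", "cel:mit")), 3),
            rep(list("syn:end"), 2))
  rk <- aggregate_interaction_repeats(tops, counts, min_appearances = 3)
  # appearing twice is dropped; three or more retained
  expect_false("syn:end" %in% rk$pair)
  expect_setequal(rk$pair, c("lip:apo", "lip:mit", "cel:mit"))
  # rank by appearances first, then by total samples
  expect_equal(rk$pair[1], "lip:apo")        # 5 appearances
  expect_equal(rk$pair[2], "lip:mit")        # tie at 3, more samples
  expect_equal(rk$pair[3], "cel:mit")
})

test_that("the interaction analysis pipeline runs end to end on a toy set", {
  set.seed(12)
  n <- 24; m <- 4
  y <- rep(c(0, 1), each = n / 2)
  toks <- list(
    bd1 = matrix(rnorm(n * m) + y, n, m),
    bd2 = matrix(rnorm(n * m) - y, n, m),
    bd3 = matrix(rnorm(n * m), n, m)
  )
  res <- biodomain_interaction_analysis(toks, y, n_repeats = 2,
                                        min_appearances = 1, B = 1,
                                        epochs = 4, n_steps = 2, seed = 3)
  expect_s3_class(res$ranking, "tbl_df")
  expect_length(res$per_repeat, 2)
  expect_true(all(res$ranking$appearances <= 2))
  # mismatched sample counts are rejected
  bad <- toks; bad$bd3 <- bad$bd3[1:10, ]
  expect_error(biodomain_interaction_analysis(bad, y, n_repeats = 1),
               class = "graphomix_invalid_argument")
})
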