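test_that("complete-sample alignment loss matches its closed forms", {
  set.seed(1)
  z <- matrix(rnorm(200 * 16), 200, 16)
  expect_equal(alignment_loss_complete(z, z), -1, tolerance = 1e-12)
  # |Pearson| is invariant to affine maps
  expect_equal(alignment_loss_complete(z, -3 * z + 7), -1, tolerance = 1e-9)
  # independent embeddings: near zero (null-correlation bound at n = 200)
  z2 <- matrix(rnorm(200 * 16), 200, 16)
  expect_lt(abs(alignment_loss_complete(z, z2)), 0.15)
  # bounded in [-1, 0]
  for (s in 1:5) {
    za <- matrix(rnorm(30 * 4), 30, 4); zb <- matrix(rnorm(30 * 4), 30, 4)
    l <- alignment_loss_complete(za, zb)
    expect_gte(l, -1); expect_lte(l, 0)
  }
  # zero-variance dimensions contribute zero, not NaN
  zc <- z; zc[, 1] <- 5
  expect_true(is.finite(alignment_loss_complete(zc, z2)))
  expect_warning(alignment_loss_complete(z[1:2, ], z2[1:2, ]), "fewer than 3")
})

test_that("cross-pair alignment loss averages same-label pairs only", {
  # one perfectly matching pair
  v <- matrix(rnorm(3), 1, 3)
  expect_equal(alignment_loss_crosspair(v, v, 1, 1), -1, tolerance = 1e-12)

  # hand-computed 2x2 pairing with m = 3 against a direct correlation oracle
  set.seed(4)
  z1 <- matrix(rnorm(6), 2, 3); z2 <- matrix(rnorm(6), 2, 3)
  l1 <- c(1, 0); l2 <- c(1, 0)
  oracle <- -mean(c(abs(cor(z1[1, ], z2[1, ])), abs(cor(z1[2, ], z2[2, ]))))
  expect_equal(alignment_loss_crosspair(z1, z2, l1, l2), oracle,
               tolerance = 1e-10)

  # mixed-label pairs never enter the mean
  z2b <- rbind(z2, rnorm(3))
  l2b <- c(1, 0, 1)
  oracle2 <- -mean(c(abs(cor(z1[1, ], z2b[1, ])), abs(cor(z1[1, ], z2b[3, ])),
                     abs(cor(z1[2, ], z2b[2, ]))))
  expect_equal(alignment_loss_crosspair(z1, z2b, l1, l2b), oracle2,
               tolerance = 1e-10)

  expect_warning(out <- alignment_loss_crosspair(z1, z2, c(1, 1), c(0, 0)),
                 "no same-label")
  expect_equal(out, 0)
})

test_that("the composite loss combines components per the objective", {
  co <- tiny_cohort()
  specs <- lapply(co$graphs, as_graph_spec)
  mdl <- model_new(specs, encoder_config(channels = 2), seed = 2)
  ids <- co$sample_ids[1:12]   # complete samples
  x <- graphomix:::batch_features(co, mdl$modalities, ids)
  y <- co$labels[1:12]

  # all lambdas zero: total = sum of per-modality losses
  l0 <- total_loss(mdl, x, y, loss_config(lambda1 = 0, lambda2 = 0, lambda3 = 0))
  expect_equal(l0$total,
               l0$components$loss_transcriptomics + l0$components$loss_proteomics,
               tolerance = 1e-10)

  # with lambdas: every component contributes
  l1 <- total_loss(mdl, x, y, loss_config(lambda1 = 2, lambda2 = 0.5, lambda3 = 1e-3))
  expect_equal(l1$total,
               l1$components$loss_transcriptomics + l1$components$loss_proteomics +
                 2 * l1$components$loss_int + 0.5 * l1$components$loss_align +
                 1e-3 * l1$components$loss_reg,
               tolerance = 1e-8)

  # single-modality batch: integration and alignment terms exactly zero
  ids1 <- co$sample_ids[41:50]
  x1 <- graphomix:::batch_features(co, "transcriptomics", ids1)
  ls <- total_loss(mdl, x1, co$labels[41:50], loss_config())
  expect_identical(ls$components$loss_int, 0)
  expect_identical(ls$components$loss_align, 0)
})

test_that("cross entropy vanishes for confident correct logits", {
  logits <- graphomix:::ad_const(rbind(c(10, -10), c(-10, 10)))
  l <- graphomix:::ce_loss_fw(logits, c(0L, 1L), c(1, 1))
  expect_lt(as.numeric(l$value), 1e-3)
})

test_that("single-modality batches leave the integrator untouched", {
  co <- tiny_cohort()
  specs <- lapply(co$graphs, as_graph_spec)
  mdl <- model_new(specs, encoder_config(channels = 2), seed = 11)
  ids1 <- co$sample_ids[41:50]  # transcriptomics only
  x1 <- graphomix:::batch_features(co, "transcriptomics", ids1)
  fw <- graphomix:::model_forward(mdl, x1, training = TRUE)
  res <- graphomix:::total_loss_fw(mdl, fw, co$labels[41:50], loss_config(),
                                   c(1, 1))
  graphomix:::ad_backward(res$loss)
  int_grads <- vapply(mdl$integrator$flat, function(p) {
    if (is.null(p$grad)) 0 else max(abs(p$grad))
  }, numeric(1))
  expect_identical(max(int_grads), 0)
  # the exercised encoder did receive gradient
  enc_grads <- vapply(mdl$encoders$transcriptomics$flat, function(p) {
    if (is.null(p$grad)) 0 else max(abs(p$grad))
  }, numeric(1))
  expect_gt(max(enc_grads), 0)
})

test_that("stratified folds preserve class balance and reproduce", {
  y <- c(rep(1, 6), rep(0, 3))
  plan <- stratified_kfold(y, k = 3, seed = 2)
  for (f in 1:3) {
    expect_equal(sum(y[plan$fold == f] == 1), 2)
    expect_equal(sum(y[plan$fold == f] == 0), 1)
  }
  expect_identical(plan$fold, stratified_kfold(y, k = 3, seed = 2)$fold)
  expect_false(identical(plan$fold, stratified_kfold(y, k = 3, seed = 5)$fold))
  # k = 1: a single fold holding every sample
  expect_true(all(stratified_kfold(y, k = 1, seed = 1)$fold == 1))
  expect_error(stratified_kfold(c(1, 1, 1, 0), k = 3), "at least k")
})

test_that("an incomplete epoch makes one pass per availability subset", {
  co <- tiny_cohort(n_complete = 8L, n1 = 4L, n2 = 4L, d = c(15L, 12L))
  specs <- lapply(co$graphs, as_graph_spec)
  mdl <- model_new(specs, encoder_config(channels = 2), seed = 1)
  opt <- optimizer_adam(mdl, lr = 1e-3)
  log <- train_epoch_incomplete(mdl, co, opt, loss_config(), batch_size = 4,
                                seed = 7)
  # subsets of sizes (8, 4, 4) with batch 4: exactly 4 optimizer steps
  expect_equal(nrow(log), 4)
  expect_equal(opt$t, 4L)
  expect_setequal(unique(log$subset),
                  c("complete", "transcriptomics_only", "proteomics_only"))
  # fixed seed: identical subset order on a fresh model
  mdl2 <- model_new(specs, encoder_config(channels = 2), seed = 1)
  log2 <- train_epoch_incomplete(mdl2, co, optimizer_adam(mdl2), loss_config(),
                                 batch_size = 4, seed = 7)
  expect_identical(log$subset, log2$subset)
})

test_that("training reduces the loss on a planted-signal cohort", {
  co <- tiny_cohort(seed = 13L, n_complete = 60L, n1 = 0L, n2 = 0L,
                    d = c(25L, 20L), effect = 2)
  mdl <- train_multiomics(co, encoder_cfg = encoder_config(channels = 2),
                          epochs = 12, batch_size = 16, lr = 3e-3, seed = 2)
  lg <- tidy(mdl)
  per_epoch <- tapply(lg$loss_total, lg$epoch, mean)
  expect_lt(mean(tail(per_epoch, 3)), mean(head(per_epoch, 3)))
  expect_s3_class(glance(mdl), "tbl_df")
  expect_s3_class(autoplot(mdl), "ggplot")
})

test_that("grid search runs folds x seeds trials and picks the better config", {
  co <- tiny_cohort(seed = 17L, n_complete = 36L, n1 = 0L, n2 = 0L,
                    d = c(15L, 12L), effect = 3)
  plan <- stratified_kfold(co$labels, k = 3, seed = 1, n_seeds_per_split = 3)
  # singleton grid: that config wins with 9 trial rows
  g1 <- grid_search(list(list(lr = 3e-3)), co, plan, epochs = 3)
  expect_equal(nrow(g1$trials), 9)
  expect_equal(g1$best_index, 1L)
  # a sabotaged config (zero learning rate) loses to a working one
  g2 <- grid_search(list(list(lr = 0), list(lr = 3e-3)), co, plan, epochs = 4)
  expect_equal(nrow(g2$trials), 18)
  expect_equal(g2$best_index, 2L)
  expect_error(grid_search(list(), co, plan), "empty")
})
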