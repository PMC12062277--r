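test_that("control-mean baselines use controls only", {
  X <- rbind(c(0, 10), c(2, 20), c(9, 9), c(7, 7))
  y <- c(0, 0, 1, 1)
  expect_equal(control_mean_baseline(X, y), c(1, 15))
  # changing case values leaves the baseline unchanged
  X2 <- X; X2[3:4, ] <- 100
  expect_equal(control_mean_baseline(X2, y), c(1, 15))
  # identical controls: the baseline is that vector
  X3 <- rbind(c(5, 5), c(5, 5), c(0, 0))
  expect_equal(control_mean_baseline(X3, c(0, 0, 1)), c(5, 5))
  expect_error(control_mean_baseline(X, c(1, 1, 1, 1)), "no control")
})

test_that("integrated gradients reproduce closed-form attributions", {
  w <- c(1.5, -2, 0.5)
  lin <- ig_model(function(x) sum(w * x) + 3, grad = function(x, cls) w)
  x <- c(2, 1, -1); b <- c(0.5, 0, 1)
  # zero path: x = baseline
  expect_equal(as.numeric(integrated_gradients(lin, b, b, 0L, 10)), c(0, 0, 0))
  # linear model: exact at any number of steps
  for (steps in c(1, 7, 100)) {
    phi <- as.numeric(integrated_gradients(lin, x, b, 0L, steps))
    expect_equal(phi, (x - b) * w, tolerance = 1e-12)
  }
  # bilinear f = x1 * x2 from a zero baseline: phi = (3, 3)
  bil <- ig_model(function(x) x[1] * x[2],
                  grad = function(x, cls) c(x[2], x[1]))
  phi2 <- as.numeric(integrated_gradients(bil, c(2, 3), c(0, 0), 0L, 500))
  expect_equal(phi2, c(3, 3), tolerance = 1e-2)
  # finite-difference fallback agrees with the analytic gradient
  bil_fd <- ig_model(function(x) x[1] * x[2])
  phi3 <- as.numeric(integrated_gradients(bil_fd, c(2, 3), c(0, 0), 0L, 100))
  expect_equal(phi3, as.numeric(integrated_gradients(bil, c(2, 3), c(0, 0), 0L, 100)),
               tolerance = 1e-6)
  # non-finite model output is reported with the interpolation point
  bad <- ig_model(function(x) log(x[1]), grad = function(x, cls) c(NaN, 0))
  expect_error(integrated_gradients(bad, c(1, 1), c(0, 0), 0L, 5),
               class = "graphomix_numeric_error")
})

test_that("integrated Hessians satisfy the closed forms and the row-sum identity", {
  w <- c(1, 2)
  lin <- ig_model(function(x) sum(w * x), grad = function(x, cls) w,
                  hess = function(x, cls) matrix(0, 2, 2))
  ih <- integrated_hessians(lin, c(3, 4), c(0, 0), 0L, 20)
  expect_lt(max(abs(ih$Gamma[row(ih$Gamma) != col(ih$Gamma)])), 1e-6)
  expect_equal(diag(ih$Gamma), ih$phi, tolerance = 1e-10)

  bil <- ig_model(function(x) x[1] * x[2],
                  grad = function(x, cls) c(x[2], x[1]),
                  hess = function(x, cls) matrix(c(0, 1, 1, 0), 2, 2))
  ih2 <- integrated_hessians(bil, c(2, 3), c(0, 0), 0L, 50)
  expect_equal(ih2$Gamma[1, 2], 1.5, tolerance = 1e-2)
  expect_equal(ih2$Gamma[1, 1], ih2$phi[1] - ih2$Gamma[1, 2], tolerance = 1e-10)
  # symmetrized interaction matches the analytic 2 * x1 * x2 / 4
  expect_equal(ih2$Gamma[1, 2] + ih2$Gamma[2, 1], 2 * 2 * 3 / 4,
               tolerance = 1e-2)
  # row sums reproduce phi exactly by construction
  expect_equal(rowSums(ih2$Gamma), ih2$phi, tolerance = 1e-12)
})

test_that("model attributions are complete and batch consistently", {
  fx <- small_trained_model()
  co <- fx$cohort; mdl <- fx$model
  tr <- co$sample_ids
  bl <- list(transcriptomics = control_mean_baseline(
    co$features$transcriptomics, co$labels))
  x <- co$features$transcriptomics[3, ]
  phi <- integrated_gradients(mdl, list(transcriptomics = x), bl,
                              class_label = 1L, n_steps = 200,
                              source = "transcriptomics")
  f_at <- function(v) {
    fw <- graphomix:::model_forward(mdl, list(transcriptomics = matrix(v, 1)),
                                    training = FALSE)
    fw$uni$transcriptomics$value[1, 2]
  }
  gap <- abs(sum(phi$phi) - (f_at(x) - f_at(bl$transcriptomics)))
  expect_lt(gap, 1e-3)

  # batched cohort attribution equals the single-sample path
  at <- attribute_cohort(mdl, co, co$sample_ids[3], bl,
                         source = "transcriptomics", n_steps = 200)
  expect_equal(at$phi, phi$phi, tolerance = 1e-10)
})

test_that("token interactions aggregate with the attribution identity intact", {
  set.seed(6)
  K <- 3; m <- 4
  tt <- token_transformer(K, m, integrator_config(n_blocks = 1, n_heads = 2),
                          seed = 2)
  X <- matrix(rnorm(30 * K * m), 30, K * m)
  y <- rbinom(30, 1, 0.5)
  tt <- train_token_transformer(tt, X, y, epochs = 5, seed = 1)
  tok <- matrix(X[1, ], K, m, byrow = TRUE)
  base <- matrix(0, K, m)
  ti <- token_interactions(tt, tok, base, n_steps = 5)
  # token-level row sums equal token-level integrated gradients
  expect_equal(rowSums(ti$token_matrix), ti$token_phi, tolerance = 1e-3)
  expect_equal(dim(ti$token_matrix), c(K, K))

  # single-dimension tokens reduce exactly to integrated_hessians on the
  # same function (finite differences of the same analytic gradient)
  tt1 <- token_transformer(4, 1, integrator_config(n_blocks = 1, n_heads = 1),
                           seed = 3)
  f1 <- function(x) {
    as.vector(graphomix:::token_logits_fw(tt1$int,
                                          graphomix:::ad_const(matrix(x, 1)),
                                          4, 1)$logits$value)
  }
  x0 <- rnorm(4)
  ih <- integrated_hessians(ig_model(f1), x0, rep(0, 4), 1L, 6)
  ti1 <- token_interactions(tt1, matrix(x0, 4, 1), matrix(0, 4, 1), n_steps = 6)
  expect_equal(ti1$token_matrix, ih$Gamma, tolerance = 1e-2)

  # zero-displacement tokens: all interactions vanish
  ti0 <- token_interactions(tt, base, base, n_steps = 3)
  expect_lt(max(abs(ti0$token_matrix)), 1e-10)
})
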