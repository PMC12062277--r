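test_that("community transform matches blockwise oracles", {
  # c = 1 degenerates to a plain linear map
  h <- matrix(rnorm(12), 4, 3)
  W <- matrix(rnorm(6), 3, 2)
  p1 <- matrix(1, 4, 1)
  expect_equal(community_transform(h, p1, W), h %*% W, tolerance = 1e-12)

  # one-hot memberships: every node uses exactly its community's block
  p <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  W2 <- cbind(matrix(rnorm(6), 3, 2), matrix(rnorm(6), 3, 2))
  out <- community_transform(h, p, W2)
  oracle <- rbind(h[1, ] %*% W2[, 1:2], h[2, ] %*% W2[, 3:4],
                  h[3, ] %*% W2[, 1:2], h[4, ] %*% W2[, 3:4])
  expect_equal(out, oracle, tolerance = 1e-12)

  # hand-computed scalar case: mixing weights 0.5/0.5 and 1/0 over blocks 2, 4
  hh <- community_transform(matrix(c(1, 1), 2, 1),
                            rbind(c(.5, .5), c(1, 0)),
                            matrix(c(2, 4), 1, 2))
  expect_equal(as.vector(hh), c(3, 2))

  expect_error(community_transform(h, p[1:2, ], W2), "matching rows")
  expect_error(community_transform(h, p * 2, W2), "row-stochastic")
})

test_that("message passing equals the dense normalized-adjacency product", {
  # single isolated node: degree 1 self-loop leaves features unchanged
  expect_equal(message_pass(matrix(2), matrix(nrow = 0, ncol = 2)), matrix(2))

  # two connected nodes, unit weights: both outputs are 1 for input (2, 0)
  expect_equal(as.vector(message_pass(matrix(c(2, 0), 2, 1), rbind(c(1, 2)))),
               c(1, 1))

  # random graphs vs dense oracle
  for (s in 1:5) {
    g <- generate_prior_graph(sample(5:30, 1), "scale_free", seed = s)
    spec <- as_graph_spec(g)
    d <- length(spec$feature_ids)
    h <- matrix(rnorm(d * 3), d, 3)
    b <- rnorm(3)
    oracle <- dense_norm_adjacency(g) %*% h + matrix(b, d, 3, byrow = TRUE)
    expect_lt(max(abs(message_pass(h, spec$edges, bias = b) - oracle)), 1e-6)
  }

  expect_error(message_pass(matrix(1, 2, 1), rbind(c(1, 2)), edge_weights = -1),
               "negative")
})

test_that("message passing is equivariant to node relabeling", {
  g <- generate_prior_graph(15, "scale_free", seed = 3)
  spec <- as_graph_spec(g)
  h <- matrix(rnorm(15 * 2), 15, 2)
  out <- message_pass(h, spec$edges)
  perm <- sample(15)
  inv <- order(perm)
  pedges <- matrix(match(spec$edges, perm), ncol = 2)  # relabeled edges
  out_perm <- message_pass(h[perm, ], pedges)
  expect_lt(max(abs(out_perm[inv, ] - out)), 1e-6)
})

test_that("conv block masking keeps the top-scoring nodes", {
  d <- 10
  g <- generate_prior_graph(d, "scale_free", seed = 2)
  spec <- as_graph_spec(g)
  params <- list(p = matrix(1, d, 1), Wc = matrix(rnorm(4), 2, 2),
                 b = c(0, 0), bn_gain = c(1, 1), bn_bias = c(0, 0),
                 topk_s = c(1, -0.5))
  h <- matrix(rnorm(d * 2), d, 2)
  # no masking: node set unchanged
  res <- conv_block(h, spec$edges, params, apply_topk = FALSE)
  expect_true(all(res$active))
  # ratio 1 keeps all nodes
  res1 <- conv_block(h, spec$edges, params, apply_topk = TRUE, ratio = 1)
  expect_true(all(res1$active))
  # ratio 0.5 keeps exactly the argmax-5 of the scores
  res5 <- conv_block(h, spec$edges, params, apply_topk = TRUE, ratio = 0.5)
  expect_equal(sum(res5$active), 5)
  s <- params$topk_s / sqrt(sum(params$topk_s^2))
  # recompute the pre-gate features to identify the expected top nodes
  hhat <- community_transform(h, params$p, params$Wc)
  mp <- message_pass(hhat, spec$edges, bias = params$b)
  resid <- h + pmax(mp, 0)
  mu <- colMeans(resid); v <- colMeans(sweep(resid, 2, mu)^2)
  bn <- sweep(sweep(resid, 2, mu), 2, sqrt(v + 1e-5), "/")
  score <- as.vector(bn %*% s)
  expect_setequal(which(res5$active), order(score, decreasing = TRUE)[1:5])
})

test_that("memory pooling produces row-stochastic assignments and fixed shapes", {
  C <- 3; dc <- 4; dip <- 2
  mu <- matrix(rnorm(dc * C), dc, C)
  W <- matrix(rnorm(C * dip), C, dip)
  x <- matrix(rnorm(7 * C), 7, C)
  res <- memory_pool(x, mu, W)
  expect_equal(dim(res$z_prime), c(dip, dc))
  expect_true(all(abs(rowSums(res$assignment) - 1) < 1e-6))
  expect_true(all(res$assignment >= 0))

  # two identical nodes get identical assignment rows
  x2 <- rbind(x[1, ], x[1, ], x[3:5, ])
  res2 <- memory_pool(x2, mu, W)
  expect_equal(res2$assignment[1, ], res2$assignment[2, ], tolerance = 1e-12)

  # output shape is independent of the number of active nodes
  res3 <- memory_pool(x[1:2, ], mu, W)
  expect_equal(dim(res3$z_prime), c(dip, dc))

  # single cluster: z' is a linear map of the (uniformly) pooled features
  res4 <- memory_pool(x, matrix(0, 1, C), W)
  expect_equal(as.vector(res4$z_prime), as.vector(t(colSums(x) %*% W)),
               tolerance = 1e-10)

  expect_error(memory_pool(x[0, , drop = FALSE], mu, W),
               class = "graphomix_empty_graph")
})

test_that("the full encoder is deterministic with the documented output size", {
  g <- generate_prior_graph(40, "scale_free", seed = 6)
  spec <- as_graph_spec(g)
  x <- rnorm(40)
  cfg <- encoder_config(embedding_dim = 16, channels = 2)
  enc <- graphomix:::encoder_new(spec, cfg, seed = 4)
  z1 <- encode(x, spec, cfg, encoder = enc)
  z2 <- encode(x, spec, cfg, encoder = enc)
  expect_identical(z1, z2)
  expect_length(z1, 16)
  # batched input: one embedding row per sample
  Z <- encode(matrix(rnorm(3 * 40), 3, 40), spec, cfg, encoder = enc)
  expect_equal(dim(Z), c(3, 16))
  expect_error(encode(rnorm(10), spec, cfg), "node count")
})

test_that("top-k masking enforces the active-node cap before pooling", {
  g <- generate_prior_graph(500, "scale_free", seed = 9)
  spec <- as_graph_spec(g)
  cfg <- encoder_config(channels = 2, node_cap = 120, n_conv_blocks = 2)
  enc <- graphomix:::encoder_new(spec, cfg, seed = 2)
  out <- graphomix:::encoder_forward(enc, matrix(rnorm(2 * 500), 2, 500),
                                     training = TRUE)
  expect_true(all(out$n_active <= 120))
  expect_true(all(is.finite(out$z$value)))
})

test_that("every encoder parameter receives gradient on a random batch", {
  g <- generate_prior_graph(25, "scale_free", seed = 5)
  spec <- as_graph_spec(g)
  enc <- graphomix:::encoder_new(spec, encoder_config(channels = 2), seed = 1)
  out <- graphomix:::encoder_forward(enc, matrix(rnorm(4 * 25), 4, 25),
                                     training = TRUE)
  graphomix:::ad_backward(graphomix:::ad_sum(graphomix:::ad_sq(out$z)))
  grads <- vapply(enc$flat, function(p) {
    !is.null(p$grad) && any(p$grad != 0)
  }, logical(1))
  expect_true(all(grads))
})
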