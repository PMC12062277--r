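test_that("prior graph generators produce simple deterministic graphs", {
  # path on 2 nodes has exactly one edge
  g2 <- generate_prior_graph(2, "path", seed = 7)
  expect_equal(igraph::ecount(g2), 1)
  expect_equal(igraph::V(g2)$name, c("G0001", "G0002"))

  # identical edge sets under a fixed seed
  ga <- generate_prior_graph(45, "scale_free", seed = 1)
  gb <- generate_prior_graph(45, "scale_free", seed = 1)
  expect_identical(igraph::as_edgelist(ga), igraph::as_edgelist(gb))

  # block-model graph is simple: no self-loops, each edge once
  g <- generate_prior_graph(100, "community_sbm", seed = 3)
  el <- igraph::as_edgelist(g, names = FALSE)
  expect_true(all(el[, 1] != el[, 2]))
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  expect_equal(anyDuplicated(key), 0L)
  expect_equal(igraph::vcount(g), 100)
  expect_equal(igraph::components(g)$no, 1L)

  expect_error(generate_prior_graph(1, "path"), "n_nodes")
})

test_that("null effect size yields null t-statistics at the nominal rate", {
  cfg <- simulation_config(n_samples_complete = 400, n_samples_mod1_only = 0,
                           n_samples_mod2_only = 0,
                           n_nodes_per_modality = c(500, 10),
                           n_informative = 0, effect_size = 0, seed = 42)
  co <- generate_cohort(cfg)
  X <- co$features[[1]]
  y <- co$labels
  tstat <- apply(X, 2, function(v) t.test(v[y == 1], v[y == 0])$statistic)
  frac <- mean(abs(tstat) > 1.96)
  expect_lt(abs(frac - 0.05), 0.03)
})

test_that("planted nodes carry the strongest signal across seeds", {
  hits <- vapply(1:10, function(s) {
    cfg <- simulation_config(n_samples_complete = 400, n_samples_mod1_only = 0,
                             n_samples_mod2_only = 0,
                             n_nodes_per_modality = c(100, 10),
                             n_informative = 10, effect_size = 2, seed = s)
    co <- generate_cohort(cfg)
    X <- co$features[[1]]; y <- co$labels
    tstat <- apply(X, 2, function(v) {
      (mean(v[y == 1]) - mean(v[y == 0])) /
        sqrt(var(v[y == 1]) / sum(y == 1) + var(v[y == 0]) / sum(y == 0))
    })
    top10 <- names(sort(abs(tstat), decreasing = TRUE))[1:10]
    setequal(top10, co$informative)
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("modality masks track the three availability groups", {
  co <- tiny_cohort(n2 = 0L)
  # no sample carries only the second modality
  expect_equal(sum(co$masks$proteomics & !co$masks$transcriptomics), 0L)
  co2 <- tiny_cohort()
  expect_equal(sum(co2$masks$transcriptomics & co2$masks$proteomics), 40L)
  expect_equal(sum(co2$masks$transcriptomics & !co2$masks$proteomics), 10L)
  expect_equal(sum(!co2$masks$transcriptomics & co2$masks$proteomics), 5L)
  # feature matrices only cover carriers
  expect_setequal(rownames(co2$features$proteomics),
                  co2$masks$sample_id[co2$masks$proteomics])
})

test_that("generators are deterministic and the null cohort is label-free", {
  cfg <- simulation_config(n_samples_complete = 200, n_samples_mod1_only = 0,
                           n_samples_mod2_only = 0,
                           n_nodes_per_modality = c(100, 10),
                           n_informative = 10, effect_size = 3,
                           case_fraction = 0.66, seed = 9)
  a <- generate_null_cohort(cfg)
  b <- generate_null_cohort(cfg)
  expect_identical(a$features, b$features)
  expect_identical(a$labels, b$labels)

  # observed case fraction within the binomial bound
  n <- length(a$labels)
  expect_lt(abs(mean(a$labels) - 0.66), 2 / sqrt(n))

  # labels carry no information: two-sample test p-values are null-like
  X <- a$features[[1]]; y <- a$labels
  pvals <- apply(X, 2, function(v) t.test(v[y == 1], v[y == 0])$p.value)
  expect_gte(mean(pvals > 0.05), 0.90)
})

test_that("graph-diffused noise correlates adjacent nodes above non-adjacent", {
  g <- generate_prior_graph(100, "scale_free", seed = 5)
  cfg <- simulation_config(n_samples_complete = 400, n_samples_mod1_only = 0,
                           n_samples_mod2_only = 0,
                           n_nodes_per_modality = c(100, 10),
                           n_informative = 0, effect_size = 0,
                           within_graph_corr = 0.5, seed = 6)
  co <- generate_cohort(cfg, list(
    transcriptomics = g,
    proteomics = generate_prior_graph(10, "path", seed = 1)
  ))
  C <- cor(co$features$transcriptomics)
  A <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  diag(A) <- NA
  adj_corr <- mean(C[which(A)], na.rm = TRUE)
  nonadj_corr <- mean(C[which(!A)], na.rm = TRUE)
  expect_gt(adj_corr, nonadj_corr)
  expect_gt(adj_corr, 0.1)
})

test_that("config invariants are enforced", {
  expect_error(simulation_config(n_informative = 50,
                                 n_nodes_per_modality = c(40, 30)),
               "n_informative")
  expect_error(simulation_config(within_graph_corr = 1), "within_graph_corr")
  expect_error(simulation_config(case_fraction = 0), "case_fraction")
  expect_error(simulation_config(n_samples_complete = -1), "n_samples_complete")
  # graph/node-count mismatch
  cfg <- simulation_config(n_nodes_per_modality = c(30, 25))
  expect_error(generate_cohort(cfg, list(
    a = generate_prior_graph(10, "path", seed = 1),
    b = generate_prior_graph(25, "path", seed = 1)
  )), "node counts")
})
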