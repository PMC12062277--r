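#' Simulation settings for synthetic multi-omics cohorts
#'
#' Bundles everything that defines a synthetic two-modality cohort: sample
#' counts for the three disjoint availability groups (complete,
#' first-modality-only, second-modality-only), per-modality node counts, the
#' number of planted predictive nodes, the standardized case/control mean
#' shift applied to them, the strength of correlation between features of
#' adjacent graph nodes, the correlation between paired measurements of
#' shared planted nodes in complete samples, the case fraction, and the seed.
#'
#' The defaults emulate a two-modality disease cohort with unequal feature
#' and sample counts and partial sample overlap, with roughly a 2:1
#' case:control ratio.
#'
#' @param n_samples_complete,n_samples_mod1_only,n_samples_mod2_only sample
#'   counts for the three availability groups.
#' @param n_nodes_per_modality integer vector of length 2; graph sizes.
#' @param n_informative number of planted predictive nodes (chosen among the
#'   feature symbols shared by both modalities).
#' @param effect_size standardized mean shift added to planted nodes in cases.
#' @param within_graph_corr mixing weight in `[0, 1)` of the one-step
#'   graph-diffused noise component; larger values correlate adjacent nodes
#'   more strongly.
#' @param cross_modality_corr correlation in `[0, 1)` between the two
#'   modalities' values of shared planted nodes in complete samples.
#' @param case_fraction proportion of cases in `(0, 1)`.
#' @param seed integer seed; all randomness in the generators flows from it.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(n_samples_complete = 228L,
                              n_samples_mod1_only = 336L,
                              n_samples_mod2_only = 59L,
                              n_nodes_per_modality = c(100L, 80L),
                              n_informative = 10L,
                              effect_size = 1,
                              within_graph_corr = 0.4,
                              cross_modality_corr = 0.5,
                              case_fraction = 0.65,
                              seed = 1L) {
  cfg <- list(
    n_samples_complete = check_count(n_samples_complete, "n_samples_complete"),
    n_samples_mod1_only = check_count(n_samples_mod1_only, "n_samples_mod1_only"),
    n_samples_mod2_only = check_count(n_samples_mod2_only, "n_samples_mod2_only"),
    n_nodes_per_modality = vapply(seq_along(n_nodes_per_modality), function(i) {
      check_count(n_nodes_per_modality[i], "n_nodes_per_modality", min = 2L)
    }, integer(1)),
    n_informative = check_count(n_informative, "n_informative"),
    effect_size = effect_size,
    within_graph_corr = within_graph_corr,
    cross_modality_corr = cross_modality_corr,
    case_fraction = case_fraction,
    seed = check_count(seed, "seed")
  )
  if (length(cfg$n_nodes_per_modality) != 2L) {
    abort("`n_nodes_per_modality` must have length 2.")
  }
  if (cfg$n_informative > min(cfg$n_nodes_per_modality)) {
    abort("`n_informative` must not exceed the smaller modality's node count.")
  }
  for (nm in c("within_graph_corr", "cross_modality_corr")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v >= 1) {
      abort(sprintf("`%s` must lie in [0, 1).", nm))
    }
  }
  if (cfg$case_fraction <= 0 || cfg$case_fraction >= 1) {
    abort("`case_fraction` must lie in (0, 1).")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic prior-knowledge graph
#'
#' Produces a simple undirected connected graph over synthetic feature
#' symbols `"G0001"`, `"G0002"`, ... that stands in for a curated
#' prior-knowledge topology. Three generative models are available: a
#' preferential-attachment graph (`scale_free`, heavy-tailed degrees as in
#' protein-interaction networks), a stochastic block model
#' (`community_sbm`, modular structure), and a path graph (`path`,
#' deterministic chain useful in tests). Disconnected draws are reconnected
#' by adding random bridging edges so that node count is preserved.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param model one of `"scale_free"`, `"community_sbm"`, `"path"`.
#' @param seed integer seed; the same arguments always return the same graph.
#' @return an `igraph` object with a `name` vertex attribute.
#' @export
generate_prior_graph <- function(n_nodes, model = c("scale_free", "community_sbm", "path"),
                                 seed = 1L) {
  n_nodes <- check_count(n_nodes, "n_nodes", min = 2L)
  model <- match.arg(model)
  g <- with_seed(seed, {
    g <- switch(model,
      path = igraph::make_ring(n_nodes, circular = FALSE),
      scale_free = igraph::sample_pa(n_nodes, m = 2, directed = FALSE),
      community_sbm = {
        k <- max(2L, min(5L, n_nodes %/% 10L))
        sizes <- rep(n_nodes %/% k, k)
        sizes[seq_len(n_nodes - sum(sizes))] <- sizes[seq_len(n_nodes - sum(sizes))] + 1L
        pm <- matrix(0.02, k, k)
        diag(pm) <- min(1, 8 / max(sizes, 2))
        igraph::sample_sbm(n_nodes, pref.matrix = pm, block.sizes = sizes)
      }
    )
    g <- igraph::simplify(g)
    # reconnect fragmented draws without changing the node count
    comp <- igraph::components(g)
    while (comp$no > 1L) {
      anchors <- vapply(seq_len(comp$no), function(cc) {
        members <- which(comp$membership == cc)
        members[sample.int(length(members), 1L)]
      }, integer(1))
      ord <- sample(anchors)
      g <- igraph::add_edges(g, as.vector(rbind(ord[-length(ord)], ord[-1L])))
      g <- igraph::simplify(g)
      comp <- igraph::components(g)
    }
    g
  })
  igraph::V(g)$name <- sprintf("G%04d", seq_len(n_nodes))
  g
}

# internal: symmetric-normalized adjacency with self-loops, as dense matrix
normalized_adjacency <- function(graph, weights = NULL) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph, sparse = TRUE))
  if (!is.null(weights)) {
    A[A > 0] <- 0
    el <- igraph::as_edgelist(graph, names = FALSE)
    for (e in seq_len(nrow(el))) {
      A[el[e, 1], el[e, 2]] <- weights[e]
      A[el[e, 2], el[e, 1]] <- weights[e]
    }
  }
  Ahat <- A + diag(nrow(A))
  d <- rowSums(Ahat)
  Dm <- 1 / sqrt(d)
  Ahat * outer(Dm, Dm)
}

#' Generate a synthetic multi-omics cohort with planted signal
#'
#' Draws binary labels, then builds per-modality feature matrices with a
#' graph-linked noise model: i.i.d. Gaussian noise is diffused one step over
#' the symmetric-normalized adjacency of the prior graph and mixed with the
#' i.i.d. component at weight `within_graph_corr`, so features of adjacent
#' nodes are positively correlated. Columns are standardized so that
#' `effect_size` is a standardized mean shift, which is then added to the
#' planted nodes of case samples. Planted nodes are drawn from the feature
#' symbols shared by both modalities; in complete samples their pre-diffusion
#' noise is shared across modalities at `cross_modality_corr`. The three
#' availability groups (complete, first-modality-only, second-modality-only)
#' are disjoint and recorded in the modality masks.
#'
#' @param cfg a [simulation_config()].
#' @param graphs named list of two `igraph` prior graphs whose node counts
#'   match `cfg$n_nodes_per_modality`.
#' @return an object of class `omics_cohort`: a list with `sample_ids`,
#'   `labels` (named 0/1 integer vector), `features` (per-modality matrices
#'   over the samples that carry the modality), `feature_ids`, `masks`
#'   (tibble of sample availability), `informative` (planted symbols), and
#'   the generating `config`.
#' @export
generate_cohort <- function(cfg, graphs = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(graphs)) {
    graphs <- list(
      transcriptomics = generate_prior_graph(cfg$n_nodes_per_modality[1], "scale_free",
                                             seed = child_seed(cfg$seed, 101L)),
      proteomics = generate_prior_graph(cfg$n_nodes_per_modality[2], "scale_free",
                                        seed = child_seed(cfg$seed, 102L))
    )
  }
  if (length(graphs) != 2L) abort("`graphs` must list exactly two modalities.")
  if (is.null(names(graphs)) || any(!nzchar(names(graphs)))) {
    names(graphs) <- c("modality1", "modality2")
  }
  d <- vapply(graphs, igraph::vcount, numeric(1))
  if (!all(d == cfg$n_nodes_per_modality)) {
    abort("graph node counts do not match `cfg$n_nodes_per_modality`.")
  }
  feature_ids <- lapply(graphs, function(g) igraph::V(g)$name)
  shared <- intersect(feature_ids[[1]], feature_ids[[2]])
  if (cfg$n_informative > 0L && length(shared) < cfg$n_informative) {
    abort("not enough shared feature symbols for the requested planted nodes.")
  }

  n_total <- cfg$n_samples_complete + cfg$n_samples_mod1_only + cfg$n_samples_mod2_only
  if (n_total < 1L) abort("cohort has no samples.")
  out <- with_seed(cfg$seed, {
    labels <- rbinom(n_total, 1L, cfg$case_fraction)
    informative <- if (cfg$n_informative > 0L) {
      sort(sample(shared, cfg$n_informative))
    } else character(0)
    eps <- lapply(d, function(di) matrix(rnorm(n_total * di), n_total, di))
    # share pre-diffusion noise of planted nodes across modalities for
    # complete samples
    if (cfg$cross_modality_corr > 0 && length(informative) &&
        cfg$n_samples_complete > 0L) {
      rows <- seq_len(cfg$n_samples_complete)
      i1 <- match(informative, feature_ids[[1]])
      i2 <- match(informative, feature_ids[[2]])
      rho <- cfg$cross_modality_corr
      eps[[2]][rows, i2] <- rho * eps[[1]][rows, i1] +
        sqrt(1 - rho^2) * eps[[2]][rows, i2]
    }
    w <- cfg$within_graph_corr
    X <- lapply(seq_along(graphs), function(i) {
      S <- normalized_adjacency(graphs[[i]])
      Xi <- (1 - w) * eps[[i]] + w * (eps[[i]] %*% S)
      # standardize columns using the exact variance of the mixing model
      v <- (1 - w)^2 + 2 * (1 - w) * w * diag(S) + w^2 * colSums(S^2)
      Xi <- sweep(Xi, 2L, sqrt(v), "/")
      colnames(Xi) <- feature_ids[[i]]
      Xi
    })
    if (cfg$effect_size != 0 && length(informative)) {
      for (i in seq_along(X)) {
        idx <- match(informative, feature_ids[[i]])
        X[[i]][labels == 1L, idx] <- X[[i]][labels == 1L, idx] + cfg$effect_size
      }
    }
    list(labels = labels, informative = informative, X = X)
  })

  sample_ids <- sprintf("S%04d", seq_len(n_total))
  names(out$labels) <- sample_ids
  grp <- rep(c("complete", "mod1_only", "mod2_only"),
             c(cfg$n_samples_complete, cfg$n_samples_mod1_only, cfg$n_samples_mod2_only))
  has1 <- grp %in% c("complete", "mod1_only")
  has2 <- grp %in% c("complete", "mod2_only")
  masks <- tibble(sample_id = sample_ids)
  masks[[names(graphs)[1]]] <- has1
  masks[[names(graphs)[2]]] <- has2
  features <- list(
    out$X[[1]][has1, , drop = FALSE],
    out$X[[2]][has2, , drop = FALSE]
  )
  rownames(features[[1]]) <- sample_ids[has1]
  rownames(features[[2]]) <- sample_ids[has2]
  names(features) <- names(graphs)
  names(feature_ids) <- names(graphs)
  structure(list(
    sample_ids = sample_ids,
    labels = as.integer(out$labels),
    features = features,
    feature_ids = feature_ids,
    masks = masks,
    informative = out$informative,
    graphs = graphs,
    config = cfg
  ), class = "omics_cohort")
}

#' Generate a label-independent (null) cohort
#'
#' Identical to [generate_cohort()] with the planted effect forced to zero,
#' so labels carry no information about the features. Used to calibrate the
#' permutation-based false-discovery procedure.
#'
#' @inheritParams generate_cohort
#' @return an `omics_cohort`.
#' @export
generate_null_cohort <- function(cfg, graphs = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  cfg$effect_size <- 0
  generate_cohort(cfg, graphs)
}

#' @method print omics_cohort
#' @export
print.omics_cohort <- function(x, ...) {
  cat("<omics_cohort> ", length(x$sample_ids), " samples (",
      sum(x$labels), " cases)\n", sep = "")
  for (nm in names(x$features)) {
    cat("  ", nm, ": ", nrow(x$features[[nm]]), " samples x ",
        ncol(x$features[[nm]]), " features\n", sep = "")
  }
  invisible(x)
}

# labels restricted to the samples carrying a given modality
modality_labels <- function(cohort, modality) {
  ids <- rownames(cohort$features[[modality]])
  setNames(cohort$labels[match(ids, cohort$sample_ids)], ids)
}
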