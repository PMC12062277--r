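#' Encoder hyperparameters
#'
#' Architecture settings for the per-modality graph neural network feature
#' extractor: `n_communities` soft communities for the positional encoding
#' (each with its own convolution weights), `n_conv_blocks` stacked graph
#' convolution blocks of width `channels`, a memory-pooling layer with
#' `n_clusters` learnable centroids mapped to `features_per_cluster` features
#' each, a final embedding of `embedding_dim` dimensions, and a `node_cap` on
#' the number of non-masked nodes entering memory pooling (enforced, when the
#' graph is larger, by per-block top-k masking at ratio
#' `(node_cap / d)^(1/N)`).
#'
#' @param n_communities number of soft communities (c >= 1).
#' @param n_conv_blocks number of graph convolution blocks (N >= 1).
#' @param channels node feature channels within the blocks.
#' @param n_clusters memory-pooling centroids (d_c).
#' @param features_per_cluster width of the per-cluster output map.
#' @param embedding_dim embedding size m (16 throughout the reference
#'   experiments).
#' @param node_cap maximum number of active nodes entering memory pooling.
#' @param use_batchnorm apply batch normalization inside each block.
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(n_communities = 4L, n_conv_blocks = 2L, channels = 4L,
                           n_clusters = 4L, features_per_cluster = 4L,
                           embedding_dim = 16L, node_cap = 300L,
                           use_batchnorm = TRUE) {
  cfg <- list(
    n_communities = check_count(n_communities, "n_communities", 1L),
    n_conv_blocks = check_count(n_conv_blocks, "n_conv_blocks", 1L),
    channels = check_count(channels, "channels", 1L),
    n_clusters = check_count(n_clusters, "n_clusters", 1L),
    features_per_cluster = check_count(features_per_cluster, "features_per_cluster", 1L),
    embedding_dim = check_count(embedding_dim, "embedding_dim", 1L),
    node_cap = check_count(node_cap, "node_cap", 1L),
    use_batchnorm = isTRUE(use_batchnorm)
  )
  structure(cfg, class = "encoder_config")
}

# edge triplets (i, j, w) of the graph including unit self-loops; undirected
# edges appear in both orientations
edge_triplets <- function(spec) {
  d <- length(spec$feature_ids)
  w <- spec$edge_weights %||% rep(1, max(nrow(spec$edges), 0L))
  if (any(w < 0)) abort("negative edge weights are not allowed.")
  i <- c(spec$edges[, 1], spec$edges[, 2], seq_len(d))
  j <- c(spec$edges[, 2], spec$edges[, 1], seq_len(d))
  ww <- c(w, w, rep(1, d))
  cbind(i = i, j = j, w = ww)
}

# symmetric-normalized adjacency (with self-loops) as a sparse d x d matrix
normalized_adjacency_sparse <- function(spec) {
  tr <- edge_triplets(spec)
  d <- length(spec$feature_ids)
  deg <- as.vector(rowsum(tr[, "w"], tr[, "i"], reorder = TRUE))
  vals <- tr[, "w"] / sqrt(deg[tr[, "i"]] * deg[tr[, "j"]])
  Matrix::sparseMatrix(i = tr[, "i"], j = tr[, "j"], x = vals, dims = c(d, d))
}

# block-diagonal batched operator; `keep` is an (n*d) logical vector of
# active nodes (sample-major); degrees are recomputed over the kept induced
# subgraph of each sample
batched_operator <- function(tr, d, n, keep = NULL) {
  if (is.null(keep)) {
    deg <- as.vector(rowsum(tr[, "w"], tr[, "i"], reorder = TRUE))
    vals <- tr[, "w"] / sqrt(deg[tr[, "i"]] * deg[tr[, "j"]])
    A <- Matrix::sparseMatrix(i = tr[, "i"], j = tr[, "j"], x = vals, dims = c(d, d))
    return(Matrix::bdiag(rep(list(A), n)))
  }
  ii <- jj <- xx <- vector("list", n)
  for (s in seq_len(n)) {
    off <- (s - 1L) * d
    ks <- keep[off + seq_len(d)]
    sel <- ks[tr[, "i"]] & ks[tr[, "j"]]
    trs <- tr[sel, , drop = FALSE]
    deg <- rep(0, d)
    agg <- rowsum(trs[, "w"], trs[, "i"])
    deg[as.integer(rownames(agg))] <- agg
    ii[[s]] <- trs[, "i"] + off
    jj[[s]] <- trs[, "j"] + off
    xx[[s]] <- trs[, "w"] / sqrt(deg[trs[, "i"]] * deg[trs[, "j"]])
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n * d, n * d))
}

# initialize encoder parameters for a graph with d nodes
encoder_new <- function(spec, cfg, seed = 1L) {
  stopifnot(inherits(spec, "graph_spec"), inherits(cfg, "encoder_config"))
  d <- length(spec$feature_ids)
  c_ <- cfg$n_communities; C <- cfg$channels
  dc <- cfg$n_clusters; dip <- cfg$features_per_cluster
  m <- cfg$embedding_dim
  needs_topk <- d > cfg$node_cap
  params <- with_seed(seed, {
    blocks <- lapply(seq_len(cfg$n_conv_blocks), function(b) {
      blk <- list(
        Wc = new_param(glorot(C, c_ * C)),
        b = new_param(rep(0, C)),
        bn_gain = new_param(rep(1, C)),
        bn_bias = new_param(rep(0, C))
      )
      # the node-scoring vector only exists where masking is active
      if (needs_topk) blk$topk_s <- new_param(rnorm(C, sd = 0.5))
      blk
    })
    list(
      comm_logits = new_param(matrix(rnorm(d * c_, sd = 0.3), d, c_)),
      lift_W = new_param(glorot(1L, c_ * C)),
      blocks = blocks,
      pool_mu = new_param(matrix(rnorm(dc * C, sd = 0.5), dc, C)),
      pool_W = new_param(glorot(C, dip)),
      pool_b = new_param(rep(0, dip)),
      res_W = new_param(glorot(d, dc * dip)),
      out_W = new_param(glorot(dc * dip, m)),
      out_b = new_param(rep(0, m))
    )
  })
  apply_topk <- d > cfg$node_cap
  ratio <- if (apply_topk) min(1, (cfg$node_cap / d)^(1 / cfg$n_conv_blocks)) else 1
  structure(list(
    cfg = cfg, spec = spec, d = d,
    params = params,
    flat = collect_params(params, prefix = spec$name),
    triplets = edge_triplets(spec),
    states = replicate(cfg$n_conv_blocks, new.env(parent = emptyenv())),
    op_cache = new.env(parent = emptyenv()),
    apply_topk = apply_topk,
    topk_ratio = ratio
  ), class = "gnn_encoder")
}

# community-weighted linear transform (batched rows; pfull: rows x c node)
community_transform_fw <- function(h, pfull, W, n_comm, C_out) {
  terms <- lapply(seq_len(n_comm), function(k) {
    Wk <- ad_cols(W, ((k - 1L) * C_out + 1L):(k * C_out))
    ad_rowscale(ad_mm(h, Wk), ad_cols(pfull, k))
  })
  Reduce(ad_add, terms)
}

message_pass_fw <- function(hhat, M, b) {
  ad_addrow(ad_spmm(M, hhat), b)
}

# full batched encoder forward pass.
# x: numeric n x d matrix or an adnode leaf; returns list(z, x_node, keep).
encoder_forward <- function(enc, x, training = TRUE) {
  cfg <- enc$cfg
  d <- enc$d; C <- cfg$channels; c_ <- cfg$n_communities
  x_node <- if (is_adnode(x)) x else ad_input(as_mat(x))
  n <- nrow(x_node$value)
  if (ncol(x_node$value) != d) abort("input width does not match graph node count.")
  node_idx <- rep(seq_len(d), times = n)
  group <- rep(seq_len(n), each = d)
  p_node <- ad_softmax_rows(enc$params$comm_logits)
  pfull <- ad_rows(p_node, node_idx)
  flat <- ad_flatten_rows(x_node)
  H <- community_transform_fw(flat, pfull, enc$params$lift_W, c_, C)
  keep <- rep(TRUE, n * d)
  key <- paste0("n", n)
  if (is.null(enc$op_cache[[key]])) {
    enc$op_cache[[key]] <- batched_operator(enc$triplets, d, n)
  }
  M <- enc$op_cache[[key]]
  for (bidx in seq_len(cfg$n_conv_blocks)) {
    blk <- enc$params$blocks[[bidx]]
    hhat <- community_transform_fw(H, pfull, blk$Wc, c_, C)
    mp <- message_pass_fw(hhat, M, blk$b)
    act <- ad_relu(mp)
    resid <- ad_add(H, act)
    Hb <- if (cfg$use_batchnorm) {
      batchnorm_fw(resid, blk$bn_gain, blk$bn_bias, enc$states[[bidx]],
                   training = training,
                   weights = if (enc$apply_topk) as.numeric(keep) else NULL)
    } else resid
    if (enc$apply_topk && enc$topk_ratio < 1) {
      s <- blk$topk_s
      s2 <- ad_sum(ad_sq(s))
      inv <- ad_powc(ad_sadd(s2, 1e-12), -0.5)
      t_raw <- ad_scale1(ad_mm(Hb, s), inv)
      tv <- as.vector(t_raw$value)
      new_keep <- rep(FALSE, n * d)
      for (smp in seq_len(n)) {
        off <- (smp - 1L) * d
        active <- which(keep[off + seq_len(d)])
        k_keep <- max(1L, ceiling(enc$topk_ratio * length(active)))
        # rounding guard: the cap binds on the nodes entering memory pooling
        if (bidx == cfg$n_conv_blocks) k_keep <- min(k_keep, cfg$node_cap)
        sel <- active[order(tv[off + active], decreasing = TRUE)[seq_len(k_keep)]]
        new_keep[off + sel] <- TRUE
      }
      keep <- new_keep
      gate <- ad_mul(ad_const(matrix(as.numeric(keep), ncol = 1L)), ad_sigmoid(t_raw))
      H <- ad_rowscale(Hb, gate)
      M <- batched_operator(enc$triplets, d, n, keep = keep)
    } else {
      H <- Hb
    }
  }
  n_active <- as.vector(rowsum(as.numeric(keep), group))
  if (any(n_active > cfg$node_cap)) {
    abort("active node count exceeds `node_cap` before memory pooling.")
  }
  if (any(n_active < 1L)) abort("no active nodes entering memory pooling.",
                                class = "graphomix_empty_graph")
  # memory pooling: soft assignment to learnable centroids
  mu <- enc$params$pool_mu
  Hsq <- ad_rowsums(ad_sq(H))
  cross <- ad_mm(H, ad_t(mu))
  musq <- ad_rowsums(ad_sq(mu))
  Dmat <- ad_addrow(ad_addcol(ad_smul(cross, -2), Hsq), ad_t(musq))
  S <- ad_softmax_rows(ad_neg(Dmat))
  pooled <- ad_cbind(lapply(seq_len(cfg$n_clusters), function(k) {
    Pk <- ad_rowsum_group(ad_rowscale(H, ad_cols(S, k)), group, n)
    linear_fw(Pk, enc$params$pool_W, enc$params$pool_b)
  }))
  res <- ad_mm(x_node, enc$params$res_W)
  z <- linear_fw(ad_add(pooled, res), enc$params$out_W, enc$params$out_b)
  list(z = z, x_node = x_node, keep = keep, n_active = n_active, S = S)
}

# ---- numeric single-graph operations (module surface) -----------------------

#' Community-weighted linear node transform
#'
#' Each node's feature vector is transformed by a mixture of per-community
#' weight blocks, mixed according to the node's soft community membership.
#'
#' @param h_in nodes x C_in matrix of node features.
#' @param p nodes x c row-stochastic community membership matrix.
#' @param W C_in x (c * C_out) weight matrix; column block k holds community
#'   k's C_in x C_out weights.
#' @return nodes x C_out matrix.
#' @export
community_transform <- function(h_in, p, W) {
  h_in <- as_mat(h_in); p <- as_mat(p); W <- as_mat(W)
  if (nrow(h_in) != nrow(p)) abort("`h_in` and `p` must have matching rows.")
  if (any(p < -1e-9) || any(abs(rowSums(p) - 1) > 1e-6)) {
    abort("`p` must be row-stochastic.")
  }
  n_comm <- ncol(p)
  if (ncol(W) %% n_comm != 0L) abort("`W` width must be a multiple of the community count.")
  C_out <- ncol(W) %/% n_comm
  out <- community_transform_fw(ad_const(h_in), ad_const(p), ad_const(W),
                                n_comm, C_out)
  out$value
}

#' Degree-normalized message passing over a graph
#'
#' Updates each node's features with the weighted sum of its own and its
#' neighbours' features, normalized by `1/sqrt(d_r * d_j)` where degrees
#' count a unit self-loop, plus a learnable intercept.
#'
#' @param h_hat nodes x C matrix of (already transformed) node features.
#' @param edges two-column index matrix of undirected edges.
#' @param edge_weights optional non-negative scalar weights (default 1).
#' @param bias intercept vector of length C (default zeros).
#' @return nodes x C matrix.
#' @export
message_pass <- function(h_hat, edges, edge_weights = NULL, bias = NULL) {
  h_hat <- as_mat(h_hat)
  d <- nrow(h_hat)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (!is.null(edge_weights) && any(edge_weights < 0)) {
    abort("negative edge weights: normalization undefined.")
  }
  spec <- graph_spec(sprintf("n%d", seq_len(d)), edges, edge_weights)
  A <- normalized_adjacency_sparse(spec)
  out <- as.matrix(A %*% h_hat)
  if (!is.null(bias)) out <- sweep(out, 2L, bias, "+")
  out
}

#' One graph convolution block
#'
#' Community transform, message passing, ReLU, residual add of the block
#' input, batch normalization (batch statistics over the supplied nodes),
#' and optional top-k node masking: nodes are scored by a learnable vector,
#' the top `ceiling(ratio * n)` kept, and kept features gated by the sigmoid
#' of their score.
#'
#' @param h nodes x C matrix (block input; C_in = C_out).
#' @param edges undirected edge index matrix.
#' @param params list with `p` (community membership), `Wc`, `b`, `bn_gain`,
#'   `bn_bias`, `topk_s`; see [encoder_config()].
#' @param apply_topk whether to mask low-scoring nodes.
#' @param ratio fraction of nodes kept when masking.
#' @param edge_weights optional edge weights.
#' @param batchnorm apply batch normalization.
#' @return list with `h` (output features), `active` (logical node mask),
#'   and `edges` (induced edge set over active nodes).
#' @export
conv_block <- function(h, edges, params, apply_topk = FALSE, ratio = 1,
                       edge_weights = NULL, batchnorm = TRUE) {
  h <- as_mat(h)
  C <- ncol(h)
  hhat <- community_transform(h, params$p, params$Wc)
  mp <- message_pass(hhat, edges, edge_weights, params$b)
  act <- pmax(mp, 0)
  resid <- h + act
  if (batchnorm) {
    mu <- colMeans(resid)
    v <- colMeans(sweep(resid, 2L, mu, "-")^2)
    resid <- sweep(sweep(resid, 2L, mu, "-"), 2L, sqrt(v + 1e-5), "/")
    resid <- sweep(sweep(resid, 2L, params$bn_gain, "*"), 2L, params$bn_bias, "+")
  }
  active <- rep(TRUE, nrow(h))
  out_edges <- edges
  if (apply_topk && ratio < 1) {
    s <- params$topk_s / sqrt(sum(params$topk_s^2) + 1e-12)
    score <- as.vector(resid %*% s)
    k_keep <- max(1L, ceiling(ratio * nrow(h)))
    kept <- order(score, decreasing = TRUE)[seq_len(k_keep)]
    active <- seq_len(nrow(h)) %in% kept
    gate <- active * (1 / (1 + exp(-score)))
    resid <- resid * gate
    e_keep <- active[edges[, 1]] & active[edges[, 2]]
    out_edges <- edges[e_keep, , drop = FALSE]
  }
  list(h = resid, active = active, edges = out_edges)
}

#' Memory pooling to a fixed-size coarse representation
#'
#' Soft-assigns nodes to learnable centroids (softmax over negative squared
#' Euclidean distance) and maps the cluster-aggregated features through a
#' shared linear layer, producing a fixed-shape output regardless of the
#' number of active nodes.
#'
#' @param x_tilde active-nodes x C matrix of latent node features.
#' @param centroids d_c x C matrix of cluster centroids.
#' @param W C x d_i' linear map applied per cluster.
#' @param b optional intercept of length d_i'.
#' @return list with `z_prime` (d_i' x d_c matrix) and `assignment`
#'   (active-nodes x d_c row-stochastic matrix).
#' @export
memory_pool <- function(x_tilde, centroids, W, b = NULL) {
  x_tilde <- as_mat(x_tilde)
  if (nrow(x_tilde) < 1L) abort("memory pooling requires at least one active node.",
                                class = "graphomix_empty_graph")
  D2 <- outer(rowSums(x_tilde^2), rowSums(centroids^2), "+") -
    2 * x_tilde %*% t(centroids)
  E <- exp(-sweep(D2, 1L, apply(D2, 1L, min), "-"))
  S <- E / rowSums(E)
  P <- t(S) %*% x_tilde            # d_c x C
  Z <- P %*% W                     # d_c x d_i'
  if (!is.null(b)) Z <- sweep(Z, 2L, b, "+")
  list(z_prime = t(Z), assignment = S)
}

#' Encode one or more samples with a GNN feature extractor
#'
#' Runs the full extractor stack (community positional encoding,
#' `n_conv_blocks` graph convolutions with residuals and optional top-k
#' masking, memory pooling, and the residual projection of the raw input)
#' and returns the m-dimensional embedding. Deterministic given the encoder
#' parameters (evaluation mode: frozen normalization statistics).
#'
#' @param x numeric vector (one sample) or samples x d matrix.
#' @param spec a `graph_spec` whose node count matches `length(x)`.
#' @param cfg an [encoder_config()].
#' @param encoder optionally a pre-built encoder (from prior training);
#'   when `NULL` a fresh one is initialized from `seed`.
#' @param seed initialization seed when `encoder` is `NULL`.
#' @return samples x m embedding matrix (a vector for a single sample).
#' @export
encode <- function(x, spec, cfg = encoder_config(), encoder = NULL, seed = 1L) {
  single <- is.null(dim(x))
  xm <- if (single) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(xm) != length(spec$feature_ids)) {
    abort("input length does not match the graph's node count.")
  }
  enc <- encoder %||% encoder_new(spec, cfg, seed = seed)
  out <- encoder_forward(enc, xm, training = FALSE)
  z <- out$z$value
  if (single) as.vector(z) else z
}
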