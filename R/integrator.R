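#' Integrator (set transformer) hyperparameters
#'
#' @param n_blocks number of transformer encoder blocks.
#' @param n_heads attention heads; must divide the embedding dimension.
#' @param ffn_hidden width of the tokenwise feedforward hidden layer
#'   (`NULL` = twice the embedding dimension).
#' @param mlp_head_hidden hidden width of the classifier heads
#'   (`NULL` = twice the embedding dimension).
#' @param n_classes number of target classes.
#' @return an object of class `integrator_config`.
#' @export
integrator_config <- function(n_blocks = 2L, n_heads = 4L, ffn_hidden = NULL,
                              mlp_head_hidden = NULL, n_classes = 2L) {
  structure(list(
    n_blocks = check_count(n_blocks, "n_blocks", 1L),
    n_heads = check_count(n_heads, "n_heads", 1L),
    ffn_hidden = if (!is.null(ffn_hidden)) check_count(ffn_hidden, "ffn_hidden", 1L),
    mlp_head_hidden = if (!is.null(mlp_head_hidden)) check_count(mlp_head_hidden, "mlp_head_hidden", 1L),
    n_classes = check_count(n_classes, "n_classes", 2L)
  ), class = "integrator_config")
}

integrator_new <- function(m, cfg, seed = 1L) {
  if (m %% cfg$n_heads != 0L) {
    abort("embedding dimension must be divisible by `n_heads`.",
          class = "graphomix_config_error")
  }
  dk <- m %/% cfg$n_heads
  f <- cfg$ffn_hidden %||% (2L * m)
  h <- cfg$mlp_head_hidden %||% (2L * m)
  C <- cfg$n_classes
  params <- with_seed(seed, {
    blocks <- lapply(seq_len(cfg$n_blocks), function(b) {
      heads <- lapply(seq_len(cfg$n_heads), function(hh) {
        list(Wq = new_param(glorot(m, dk)), Wk = new_param(glorot(m, dk)),
             Wv = new_param(glorot(m, dk)))
      })
      list(heads = heads,
           Wo = new_param(glorot(m, m)),
           ln1_g = new_param(rep(1, m)), ln1_b = new_param(rep(0, m)),
           ffn_W1 = new_param(glorot(m, f)), ffn_b1 = new_param(rep(0, f)),
           ffn_W2 = new_param(glorot(f, m)), ffn_b2 = new_param(rep(0, m)),
           ln2_g = new_param(rep(1, m)), ln2_b = new_param(rep(0, m)))
    })
    list(cls = new_param(matrix(rnorm(m, sd = 0.5), 1L, m)),
         blocks = blocks,
         head = list(W1 = new_param(glorot(m, h)), b1 = new_param(rep(0, h)),
                     W2 = new_param(glorot(h, C)), b2 = new_param(rep(0, C))))
  })
  structure(list(cfg = cfg, m = m, dk = dk, params = params,
                 flat = collect_params(params, "integrator")),
            class = "set_integrator")
}

mlp_head_new <- function(m, hidden, C, seed = 1L) {
  params <- with_seed(seed, {
    list(W1 = new_param(glorot(m, hidden)), b1 = new_param(rep(0, hidden)),
         W2 = new_param(glorot(hidden, C)), b2 = new_param(rep(0, C)))
  })
  params
}

mlp_forward <- function(head, z) {
  linear_fw(ad_relu(linear_fw(z, head$W1, head$b1)), head$W2, head$b2)
}

# one transformer encoder block applied to a token list (each n x m node)
transformer_block_fw <- function(blk, tokens, dk, keep_attention = FALSE) {
  K1 <- length(tokens)
  n_heads <- length(blk$heads)
  attn <- if (keep_attention) list() else NULL
  msa <- vector("list", K1)
  head_outs <- lapply(seq_len(n_heads), function(hh) {
    hd <- blk$heads[[hh]]
    Q <- lapply(tokens, function(tk) ad_mm(tk, hd$Wq))
    Kk <- lapply(tokens, function(tk) ad_mm(tk, hd$Wk))
    V <- lapply(tokens, function(tk) ad_mm(tk, hd$Wv))
    lapply(seq_len(K1), function(i) {
      scores <- ad_cbind(lapply(seq_len(K1), function(j) {
        ad_smul(ad_rowdot(Q[[i]], Kk[[j]]), 1 / sqrt(dk))
      }))
      A <- ad_softmax_rows(scores)
      if (keep_attention) attn[[length(attn) + 1L]] <<- A$value
      Reduce(ad_add, lapply(seq_len(K1), function(j) {
        ad_rowscale(V[[j]], ad_cols(A, j))
      }))
    })
  })
  out_tokens <- lapply(seq_len(K1), function(i) {
    concat <- ad_cbind(lapply(head_outs, function(ho) ho[[i]]))
    m_i <- ad_mm(concat, blk$Wo)
    zp <- layernorm_fw(ad_add(tokens[[i]], m_i), blk$ln1_g, blk$ln1_b)
    f_i <- linear_fw(ad_relu(linear_fw(zp, blk$ffn_W1, blk$ffn_b1)),
                     blk$ffn_W2, blk$ffn_b2)
    layernorm_fw(ad_add(zp, f_i), blk$ln2_g, blk$ln2_b)
  })
  list(tokens = out_tokens, attention = attn)
}

# full transformer over modality tokens; prepends the class token
transformer_forward <- function(int, tokens, keep_attention = FALSE,
                                prepend_class = TRUE) {
  n <- nrow(tokens[[1]]$value)
  full <- if (prepend_class) {
    cls_rep <- ad_rows(int$params$cls, rep(1L, n))
    c(list(cls_rep), tokens)
  } else tokens
  attention <- list()
  for (blk in int$params$blocks) {
    res <- transformer_block_fw(blk, full, int$dk, keep_attention)
    full <- res$tokens
    if (keep_attention) attention[[length(attention) + 1L]] <- res$attention
  }
  list(tokens = full, attention = attention)
}

integrator_logits_fw <- function(int, tokens, keep_attention = FALSE) {
  res <- transformer_forward(int, tokens, keep_attention)
  list(logits = mlp_forward(int$params$head, res$tokens[[1]]),
       class_token = res$tokens[[1]],
       attention = res$attention)
}

# ---- numeric module surface -------------------------------------------------

#' Apply one set-transformer encoder block to a token matrix
#'
#' Multi-head self-attention with residual connection and layer
#' normalization, followed by a tokenwise feedforward network with residual
#' connection and layer normalization. No positional encodings are used, so
#' the block is equivariant to permutations of the tokens.
#'
#' @param Z (K+1) x m token matrix (row 1 = class token).
#' @param integrator a `set_integrator` (from a model or [integrator_config()]
#'   via internal initialization).
#' @param block which encoder block's parameters to use.
#' @return list with `Z_out` ((K+1) x m) and `attention` (per head, a
#'   (K+1) x (K+1) row-stochastic matrix).
#' @export
encoder_block <- function(Z, integrator, block = 1L) {
  stopifnot(inherits(integrator, "set_integrator"))
  Z <- as_mat(Z)
  if (ncol(Z) != integrator$m) abort("token width does not match the integrator.")
  tokens <- lapply(seq_len(nrow(Z)), function(i) ad_const(Z[i, , drop = FALSE]))
  res <- transformer_block_fw(integrator$params$blocks[[block]], tokens,
                              integrator$dk, keep_attention = TRUE)
  Z_out <- do.call(rbind, lapply(res$tokens, function(tk) tk$value))
  # collect attention rows (stored per head x query) into per-head matrices
  K1 <- nrow(Z)
  n_heads <- length(integrator$params$blocks[[block]]$heads)
  attn <- lapply(seq_len(n_heads), function(hh) {
    rows <- res$attention[((hh - 1L) * K1 + 1L):(hh * K1)]
    do.call(rbind, rows)
  })
  list(Z_out = Z_out, attention = attn)
}

#' Integrate modality embeddings and score the sample
#'
#' Collects the modality embeddings into a token set with the learnable
#' class token, runs the transformer encoder, and maps the class token's
#' final representation through the classifier head. Invariant (up to
#' numerical precision) to the order of the modality tokens.
#'
#' @param tokens K x m matrix or list of m-vectors of modality embeddings.
#' @param integrator a `set_integrator`.
#' @return numeric score vector of length `n_classes` (pre-softmax logits).
#' @export
integrate_predict <- function(tokens, integrator) {
  stopifnot(inherits(integrator, "set_integrator"))
  if (is.list(tokens)) tokens <- do.call(rbind, lapply(tokens, rbind))
  tokens <- as_mat(tokens)
  if (nrow(tokens) < 1L) abort("at least one modality embedding is required.")
  tk <- lapply(seq_len(nrow(tokens)), function(i) ad_const(tokens[i, , drop = FALSE]))
  out <- integrator_logits_fw(integrator, tk)
  as.vector(out$logits$value)
}

#' Score a single-modality embedding with its MLP head
#'
#' @param z embedding vector of length m.
#' @param head an MLP head parameter list (from a fitted model's
#'   `uni_heads`).
#' @return numeric score vector of length `n_classes`.
#' @export
unimodal_predict <- function(z, head) {
  as.vector(mlp_forward(head, ad_const(matrix(z, nrow = 1L)))$value)
}
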