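#' Assemble an untrained multi-omics graph model
#'
#' Builds one GNN feature extractor per modality over its prior graph,
#' one unimodal MLP classifier head per modality, and the set-transformer
#' integrator with its learnable class token.
#'
#' @param specs named list of `graph_spec` objects, one per modality.
#' @param encoder_cfg an [encoder_config()] (shared across modalities).
#' @param integrator_cfg an [integrator_config()].
#' @param seed weight-initialization seed.
#' @return an object of class `omics_gnn`.
#' @export
model_new <- function(specs, encoder_cfg = encoder_config(),
                      integrator_cfg = integrator_config(), seed = 1L) {
  if (is.null(names(specs)) || any(!nzchar(names(specs)))) {
    abort("`specs` must be a named list of graph_spec objects.")
  }
  m <- encoder_cfg$embedding_dim
  h <- integrator_cfg$mlp_head_hidden %||% (2L * m)
  encoders <- list(); uni_heads <- list()
  for (k in seq_along(specs)) {
    nm <- names(specs)[k]
    sp <- specs[[k]]
    sp$name <- nm
    encoders[[nm]] <- encoder_new(sp, encoder_cfg, seed = child_seed(seed, k))
    uni_heads[[nm]] <- mlp_head_new(m, h, integrator_cfg$n_classes,
                                    seed = child_seed(seed, 50L + k))
  }
  integrator <- integrator_new(m, integrator_cfg, seed = child_seed(seed, 99L))
  flat <- c(do.call(c, unname(lapply(encoders, function(e) e$flat))),
            integrator$flat,
            collect_params(uni_heads, "uni"))
  names(flat) <- make.unique(names(flat))
  structure(list(
    modalities = names(specs),
    encoders = encoders,
    uni_heads = uni_heads,
    integrator = integrator,
    encoder_cfg = encoder_cfg,
    integrator_cfg = integrator_cfg,
    flat = flat,
    log = NULL,
    trained = FALSE
  ), class = "omics_gnn")
}

#' @method print omics_gnn
#' @export
print.omics_gnn <- function(x, ...) {
  np <- sum(vapply(x$flat, function(p) length(p$value), numeric(1)))
  cat("<omics_gnn> modalities:", paste(x$modalities, collapse = ", "),
      sprintf("| m=%d | %d parameters | %s\n", x$encoder_cfg$embedding_dim,
              np, if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# forward pass over a batch with uniform modality availability.
# x: named list of n x d_i matrices (subset of model$modalities).
# Returns adnodes for embeddings and logits.
model_forward <- function(model, x, training = TRUE, keep_attention = FALSE) {
  present <- names(x)
  bad <- setdiff(present, model$modalities)
  if (length(bad)) abort(sprintf("modality '%s' has no matching graph.", bad[1]),
                         class = "graphomix_config_error")
  if (!length(present)) abort("sample has no modalities.")
  enc_out <- lapply(present, function(nm) {
    encoder_forward(model$encoders[[nm]], x[[nm]], training = training)
  })
  names(enc_out) <- present
  z <- lapply(enc_out, function(e) e$z)
  uni <- lapply(present, function(nm) mlp_forward(model$uni_heads[[nm]], z[[nm]]))
  names(uni) <- present
  int_out <- NULL
  if (length(present) == length(model$modalities) && length(present) > 1L) {
    int_out <- integrator_logits_fw(model$integrator, unname(z),
                                    keep_attention = keep_attention)
  }
  list(z = z, uni = uni, int = int_out,
       x_nodes = lapply(enc_out, function(e) e$x_node),
       n_active = lapply(enc_out, function(e) e$n_active))
}

#' Forward pass for one sample through the full model
#'
#' Complete samples produce an integrated score (set transformer on the
#' aligned embeddings) plus one unimodal score per modality; samples missing
#' a modality are routed through the unimodal MLP heads of the modalities
#' they carry.
#'
#' @param sample named list of per-modality numeric feature vectors (only
#'   the modalities the sample carries).
#' @param model an `omics_gnn`.
#' @return tibble with columns `source` (`"integrated"` or the modality
#'   name), one score column per class, and `predicted` (0-based class).
#' @export
full_model_forward <- function(sample, model) {
  x <- lapply(sample, function(v) matrix(v, nrow = 1L))
  out <- model_forward(model, x, training = FALSE)
  rows <- list()
  if (!is.null(out$int)) {
    sc <- as.vector(out$int$logits$value)
    rows[[length(rows) + 1L]] <- tibble(source = "integrated",
                                        score_0 = sc[1], score_1 = sc[2],
                                        predicted = which.max(sc) - 1L)
  }
  for (nm in names(out$uni)) {
    sc <- as.vector(out$uni[[nm]]$value)
    rows[[length(rows) + 1L]] <- tibble(source = nm,
                                        score_0 = sc[1], score_1 = sc[2],
                                        predicted = which.max(sc) - 1L)
  }
  dplyr::bind_rows(rows)
}

#' Predict labels for a cohort
#'
#' Complete samples are scored by the integrated classifier; incomplete
#' samples by the unimodal head of the modality they carry.
#'
#' @param object a trained `omics_gnn`.
#' @param cohort an `omics_cohort`.
#' @param source `"auto"` (integrated where possible), `"integrated"`, or a
#'   modality name to force that route.
#' @param ... unused.
#' @return tibble: `sample_id`, `source`, per-class scores, `predicted`,
#'   and `label` when known.
#' @export
predict.omics_gnn <- function(object, cohort, source = "auto", ...) {
  model <- object
  mods <- model$modalities
  masks <- cohort$masks
  out <- vector("list", 0L)
  idx_of <- function(nm, ids) match(ids, rownames(cohort$features[[nm]]))
  complete_ids <- cohort$sample_ids[Reduce(`&`, lapply(mods, function(nm) masks[[nm]]))]
  score_batch <- function(ids, use_mods, src) {
    if (!length(ids)) return(NULL)
    x <- lapply(use_mods, function(nm) {
      cohort$features[[nm]][idx_of(nm, ids), , drop = FALSE]
    })
    names(x) <- use_mods
    fw <- model_forward(model, x, training = FALSE)
    sc <- if (src == "integrated") fw$int$logits$value else fw$uni[[src]]$value
    tibble(sample_id = ids, source = src,
           score_0 = sc[, 1], score_1 = sc[, 2],
           predicted = max.col(sc) - 1L)
  }
  if (source == "auto") {
    if (length(mods) > 1L) {
      if (length(complete_ids)) {
        out[[length(out) + 1L]] <- score_batch(complete_ids, mods, "integrated")
      }
      for (nm in mods) {
        only <- cohort$sample_ids[masks[[nm]] & !cohort$sample_ids %in% complete_ids]
        out[[length(out) + 1L]] <- score_batch(only, nm, nm)
      }
    } else {
      out[[length(out) + 1L]] <- score_batch(cohort$sample_ids[masks[[mods]]],
                                             mods, mods)
    }
  } else if (source == "integrated") {
    out[[length(out) + 1L]] <- score_batch(complete_ids, mods, "integrated")
  } else {
    ids <- cohort$sample_ids[masks[[source]]]
    out[[length(out) + 1L]] <- score_batch(ids, source, source)
  }
  res <- dplyr::bind_rows(out)
  res$label <- cohort$labels[match(res$sample_id, cohort$sample_ids)]
  res
}
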