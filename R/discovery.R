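#' Build a null attribution-score pool from label-permuted models
#'
#' For each of `B` permutations, the training labels are shuffled by the
#' seeded generator, a fresh model is trained on the permuted cohort by
#' `model_factory`, and its attribution scores are collected. The pooled
#' scores estimate the distribution of attributions under the null
#' hypothesis of no label/feature association, and can be reused by
#' different analyses of the same dataset.
#'
#' @param cohort an `omics_cohort` (its labels are permuted).
#' @param model_factory `function(cohort, seed)` returning a numeric vector
#'   of attribution scores (e.g. train + integrated gradients).
#' @param B number of permutations.
#' @param seed controls the permutation sequence and per-model seeds.
#' @return object of class `null_pool`: list with `pool` (all scores),
#'   `per_b` (per-permutation scores), `B`, `seed`.
#' @export
train_null_models <- function(cohort, model_factory, B, seed = 1L) {
  B <- check_count(B, "B", 1L)
  per_b <- vector("list", B)
  perms <- with_seed(seed, {
    lapply(seq_len(B), function(b) sample.int(length(cohort$labels)))
  })
  for (b in seq_len(B)) {
    perm_cohort <- cohort
    perm_cohort$labels <- cohort$labels[perms[[b]]]
    scores <- model_factory(perm_cohort, child_seed(seed, b))
    if (!is.numeric(scores)) abort("`model_factory` must return numeric scores.")
    per_b[[b]] <- scores   # names (if any) are kept for downstream grouping
  }
  structure(list(pool = unlist(per_b), per_b = per_b, B = B, seed = seed),
            class = "null_pool")
}

null_pool_values <- function(null_pool) {
  if (inherits(null_pool, "null_pool")) null_pool$pool else as.numeric(null_pool)
}

#' Permutation-based empirical false discovery rate at a threshold
#'
#' `FDR(d) = pi0 * (mean over permutations of the null count above d) /
#' (observed count above d)`, where `pi0` is the prior probability that a
#' marker (or interaction) is uninformative.
#'
#' @param observed observed attribution scores.
#' @param null_pool numeric vector of pooled null scores or a
#'   [train_null_models()] result.
#' @param B number of permutations that produced the pool.
#' @param pi0 prior null probability (0.97 in the reference analyses).
#' @param d score threshold; there must be at least one observed score
#'   above it.
#' @return estimated FDR at `d` (may exceed 1).
#' @export
empirical_fdr <- function(observed, null_pool, B, pi0 = 0.97, d) {
  nulls <- null_pool_values(null_pool)
  n_disc <- sum(observed > d)
  if (n_disc == 0L) {
    abort("no observed scores above `d`; FDR undefined.",
          class = "graphomix_undefined_threshold")
  }
  pi0 * (sum(nulls > d) / B) / n_disc
}

#' Choose the informative-score threshold at a target FDR
#'
#' Scans a grid of candidate thresholds (midpoints between adjacent
#' distinct values of the pooled observed and null scores, where the count
#' ratio actually changes) and returns the smallest threshold whose
#' estimated FDR is at or below `target`. If no threshold achieves the
#' target, the minimum attainable FDR is reported instead.
#'
#' @inheritParams empirical_fdr
#' @param target FDR target (0.05 in the reference analyses).
#' @return object of class `fdr_decision`: `threshold` (`NA` when
#'   unachievable), `fdr` (estimated FDR at the threshold), `achieved`,
#'   `min_fdr`, `table` (tibble of evaluated thresholds), `informative`
#'   (logical over `observed`), plus the inputs.
#' @export
select_threshold <- function(observed, null_pool, B, pi0 = 0.97, target = 0.05) {
  nulls <- null_pool_values(null_pool)
  vals <- sort(unique(c(observed, nulls)))
  grid <- if (length(vals) > 1L) (vals[-1] + vals[-length(vals)]) / 2 else vals
  obs_sorted <- sort(observed)
  null_sorted <- sort(nulls)
  # counts strictly above each grid point (grid points fall between values)
  n_disc <- length(obs_sorted) - findInterval(grid, obs_sorted)
  null_count <- length(null_sorted) - findInterval(grid, null_sorted)
  keep <- n_disc > 0L
  grid <- grid[keep]; n_disc <- n_disc[keep]; null_count <- null_count[keep]
  if (!length(grid)) abort("no threshold leaves any observed discovery.",
                           class = "graphomix_undefined_threshold")
  tab <- tibble(
    d = grid,
    n_discoveries = as.integer(n_disc),
    null_mean_count = null_count / B
  )
  tab$fdr <- pi0 * tab$null_mean_count / tab$n_discoveries
  ok <- which(tab$fdr <= target)
  if (length(ok)) {
    pick <- ok[1]
    threshold <- tab$d[pick]
    fdr <- tab$fdr[pick]
    achieved <- TRUE
  } else {
    threshold <- NA_real_
    fdr <- NA_real_
    achieved <- FALSE
  }
  structure(list(
    threshold = threshold, fdr = fdr, achieved = achieved,
    min_fdr = min(tab$fdr), target = target, pi0 = pi0, B = B,
    table = tab,
    informative = if (achieved) observed > threshold else rep(FALSE, length(observed)),
    observed = observed
  ), class = "fdr_decision")
}

#' @method print fdr_decision
#' @export
print.fdr_decision <- function(x, ...) {
  if (x$achieved) {
    cat(sprintf("<fdr_decision> threshold d*=%.4g, FDR(d*)=%.4g (target %.3g), %d informative\n",
                x$threshold, x$fdr, x$target, sum(x$informative)))
  } else {
    cat(sprintf("<fdr_decision> target %.3g unattainable; minimum FDR %.4g\n",
                x$target, x$min_fdr))
  }
  invisible(x)
}

#' Call informative features in correctly predicted validation samples
#'
#' A feature is informative for a sample when the sample is a correctly
#' predicted validation sample and the feature's attribution score exceeds
#' the threshold.
#'
#' @param attributions tibble with `sample_id`, `feature`, and a score
#'   column (`phi`); typically from [attribute_cohort()], with scores
#'   already on the scale the threshold was chosen on (e.g. magnitudes).
#' @param d_star score threshold (from [select_threshold()]).
#' @param predictions tibble with `sample_id`, `predicted`, `label` for the
#'   validation samples.
#' @param score column name holding the scores.
#' @return tibble of (sample_id, feature) informative calls.
#' @export
call_informative <- function(attributions, d_star, predictions, score = "phi") {
  correct_ids <- predictions$sample_id[predictions$predicted == predictions$label]
  out <- attributions[attributions$sample_id %in% correct_ids &
                        attributions[[score]] > d_star, , drop = FALSE]
  as_tibble(out)
}

#' Rank markers across studies by informative-sample fraction
#'
#' For each marker and study, counts the unique sample identifiers for
#' which the marker was called informative (across modalities and graphs),
#' divides by the study's number of correctly predicted validation samples,
#' and ranks markers by the mean fraction across studies (ties broken by
#' total sample count, then symbol).
#'
#' @param informative_sets named list (study -> tibble with `sample_id`,
#'   `feature` from [call_informative()]).
#' @param correct_counts named numeric: correctly predicted validation
#'   samples per study.
#' @return tibble: `rank`, `feature`, `mean_fraction`, and per-study
#'   `n_<study>` columns.
#' @export
rank_markers <- function(informative_sets, correct_counts) {
  studies <- names(informative_sets)
  if (is.null(studies) || !length(studies)) abort("at least one study is required.")
  keep <- vapply(studies, function(s) {
    ok <- isTRUE(correct_counts[[s]] > 0)
    if (!ok) warn(sprintf("study '%s' has no correctly predicted samples; excluded.", s))
    ok
  }, logical(1))
  studies <- studies[keep]
  if (!length(studies)) abort("no study with correctly predicted samples.")
  all_feats <- sort(unique(unlist(lapply(informative_sets[studies],
                                         function(x) x$feature))))
  per_study <- lapply(studies, function(s) {
    x <- informative_sets[[s]]
    cnt <- tapply(x$sample_id, x$feature, function(v) length(unique(v)))
    n <- setNames(rep(0L, length(all_feats)), all_feats)
    n[names(cnt)] <- as.integer(cnt)
    n
  })
  names(per_study) <- studies
  frac <- sapply(studies, function(s) per_study[[s]] / correct_counts[[s]])
  frac <- matrix(frac, ncol = length(studies),
                 dimnames = list(all_feats, studies))
  res <- tibble(feature = all_feats,
                mean_fraction = unname(rowMeans(frac)),
                total_samples = unname(Reduce(`+`, per_study)))
  for (s in studies) res[[paste0("n_", s)]] <- as.integer(per_study[[s]])
  ord <- order(-res$mean_fraction, -res$total_samples, res$feature)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  dplyr::relocate(res, rank)
}

# symmetrized interaction magnitude per unordered token pair
pair_scores_from_matrix <- function(tm, pair_idx) {
  vapply(seq_len(nrow(pair_idx)), function(r) {
    a <- pair_idx[r, 1]; b <- pair_idx[r, 2]
    abs(tm[a, b] + tm[b, a])
  }, numeric(1))
}

# interaction scores for every sample: returns samples x pairs matrix
sample_interaction_scores <- function(model, tokens, baseline, pair_idx,
                                      class_label = 1L, n_steps = 4L) {
  n <- nrow(tokens)
  out <- matrix(0, n, nrow(pair_idx))
  for (s in seq_len(n)) {
    ti <- token_interactions(model,
                             matrix(tokens[s, ], model$K, model$m, byrow = TRUE),
                             matrix(baseline, model$K, model$m, byrow = TRUE),
                             class_label = class_label, n_steps = n_steps)
    out[s, ] <- pair_scores_from_matrix(ti$token_matrix, pair_idx)
  }
  out
}

#' Rank cross-graph interactions from repeated interaction analyses
#'
#' Trains an auxiliary set transformer on per-graph class-token embeddings
#' of complete samples, derives pairwise token interactions with integrated
#' Hessians, calls informative interactions under the permutation FDR, and
#' repeats the whole procedure `n_repeats` times with different weight
#' initializations. Interactions appearing in the per-repeat top ten
#' percent (by number of informative samples) at least `min_appearances`
#' times are retained, ranked by appearance count and then by total
#' informative-sample count.
#'
#' @param tokens_by_graph named list (graph/biodomain -> n x m matrix of
#'   class-token representations over the same complete samples).
#' @param labels 0/1 labels for those samples.
#' @param n_repeats model-training repetitions (10 in the reference
#'   protocol).
#' @param min_appearances retention threshold (3 in the reference
#'   protocol).
#' @param top_fraction fraction of interactions marked per repeat (0.10).
#' @param B permutations for the null pool per repeat.
#' @param pi0,target FDR settings.
#' @param epochs,lr training settings for the auxiliary transformer.
#' @param n_steps quadrature steps per axis for integrated Hessians.
#' @param seed base seed.
#' @return object of class `interaction_ranking`: `ranking` tibble
#'   (`pair`, `appearances`, `total_samples`, `rank`), `per_repeat` lists,
#'   and the settings.
#' @export
biodomain_interaction_analysis <- function(tokens_by_graph, labels,
                                           n_repeats = 10L, min_appearances = 3L,
                                           top_fraction = 0.10, B = 3L,
                                           pi0 = 0.97, target = 0.05,
                                           epochs = 30L, lr = 5e-3,
                                           n_steps = 4L, seed = 1L) {
  Kg <- length(tokens_by_graph)
  if (Kg < 2L) abort("at least two graphs are required.")
  nms <- names(tokens_by_graph)
  ns <- vapply(tokens_by_graph, nrow, integer(1))
  if (length(unique(ns)) != 1L) {
    abort("all graphs must provide tokens for the same complete samples.",
          class = "graphomix_invalid_argument")
  }
  m <- ncol(tokens_by_graph[[1]])
  X <- do.call(cbind, tokens_by_graph)   # n x (K*m), token-major blocks
  n <- nrow(X)
  pair_idx <- t(utils::combn(Kg, 2L))
  pair_names <- apply(pair_idx, 1L, function(r) paste(nms[r[1]], nms[r[2]], sep = ":"))
  baseline <- colMeans(X[labels == 0, , drop = FALSE])
  cfg <- integrator_config(n_blocks = 1L, n_heads = max(1L, m %/% 4L))
  per_repeat <- vector("list", n_repeats)
  counts_list <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    rs <- child_seed(seed, 100L + r)
    tm <- token_transformer(Kg, m, cfg, seed = rs)
    tm <- train_token_transformer(tm, X, labels, epochs = epochs, lr = lr,
                                  seed = child_seed(rs, 1L))
    obs <- sample_interaction_scores(tm, X, baseline, pair_idx,
                                     n_steps = n_steps)
    # null pool: transformers trained on permuted labels
    perms <- with_seed(child_seed(rs, 2L),
                       lapply(seq_len(B), function(b) sample.int(n)))
    null_scores <- lapply(seq_len(B), function(b) {
      tmb <- token_transformer(Kg, m, cfg, seed = child_seed(rs, 10L + b))
      tmb <- train_token_transformer(tmb, X, labels[perms[[b]]], epochs = epochs,
                                     lr = lr, seed = child_seed(rs, 20L + b))
      as.vector(sample_interaction_scores(tmb, X, baseline, pair_idx,
                                          n_steps = n_steps))
    })
    dec <- select_threshold(as.vector(obs), unlist(null_scores), B = B,
                            pi0 = pi0, target = target)
    thr <- if (dec$achieved) dec$threshold else Inf
    informative <- obs > thr
    pair_counts <- colSums(informative)
    names(pair_counts) <- pair_names
    k_top <- max(1L, ceiling(top_fraction * length(pair_counts)))
    top <- names(sort(pair_counts, decreasing = TRUE))[seq_len(k_top)]
    top <- top[pair_counts[top] > 0]
    per_repeat[[r]] <- list(top = top, counts = pair_counts, decision = dec)
    counts_list[[r]] <- pair_counts
  }
  ranking <- aggregate_interaction_repeats(
    lapply(per_repeat, function(r) r$top), counts_list, min_appearances)
  structure(list(ranking = ranking, per_repeat = per_repeat,
                 n_repeats = n_repeats, min_appearances = min_appearances,
                 top_fraction = top_fraction),
            class = "interaction_ranking")
}

#' Aggregate per-repeat top interactions into a final ranking
#'
#' Interactions marked in the per-repeat top fraction at least
#' `min_appearances` times are retained and ranked first by the number of
#' appearances, then by the total number of informative samples across
#' repeats, then by name.
#'
#' @param tops list (one element per repeat) of character vectors naming
#'   the interactions in that repeat's top fraction.
#' @param counts_list list of named numeric vectors: informative-sample
#'   counts per interaction per repeat (all sharing the same names).
#' @param min_appearances retention threshold.
#' @return tibble: `pair`, `appearances`, `total_samples`, `rank`.
#' @export
aggregate_interaction_repeats <- function(tops, counts_list, min_appearances = 3L) {
  pair_names <- names(counts_list[[1]])
  appearances <- setNames(rep(0L, length(pair_names)), pair_names)
  for (top in tops) appearances[top] <- appearances[top] + 1L
  total_samples <- Reduce(`+`, counts_list)
  ranking <- tibble(pair = pair_names,
                    appearances = as.integer(appearances),
                    total_samples = as.numeric(total_samples))
  ranking <- ranking[ranking$appearances >= min_appearances, , drop = FALSE]
  ranking <- ranking[order(-ranking$appearances, -ranking$total_samples,
                           ranking$pair), , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  ranking
}
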