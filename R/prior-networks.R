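#' Per-modality prior graph specification
#'
#' A `graph_spec` pairs an ordered vector of feature symbols (defining node
#' index order, which must match the assay's feature columns) with an
#' undirected simple edge list over those indices and optional scalar edge
#' weights.
#'
#' @param feature_ids character vector of node symbols (unique, ordered).
#' @param edges two-column integer matrix of node index pairs (each
#'   unordered pair stored once, no self-loops).
#' @param edge_weights optional numeric vector, one weight per edge.
#' @param name label for the graph (e.g. a biodomain).
#' @return an object of class `graph_spec`.
#' @export
graph_spec <- function(feature_ids, edges, edge_weights = NULL, name = "graph") {
  feature_ids <- as.character(feature_ids)
  if (anyDuplicated(feature_ids)) abort("`feature_ids` must be unique.")
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges)) {
    if (any(edges < 1L | edges > length(feature_ids))) {
      abort("edge indices out of range.")
    }
    if (any(edges[, 1] == edges[, 2])) abort("self-loops are not allowed.")
    # canonical order and dedup
    edges <- t(apply(edges, 1L, sort))
    key <- paste(edges[, 1], edges[, 2])
    dup <- duplicated(key)
    if (any(dup)) {
      if (!is.null(edge_weights)) {
        agg <- tapply(edge_weights, key, function(w) {
          if (length(unique(w)) > 1L) NA_real_ else w[1]
        })
        if (anyNA(agg)) abort("duplicate edges with conflicting weights.",
                              class = "graphomix_format_error")
        edge_weights <- as.numeric(agg[key[!dup]])
      }
      edges <- edges[!dup, , drop = FALSE]
    }
  }
  if (!is.null(edge_weights) && length(edge_weights) != nrow(edges)) {
    abort("`edge_weights` must have one entry per edge.")
  }
  structure(list(name = name, feature_ids = feature_ids, edges = edges,
                 edge_weights = edge_weights), class = "graph_spec")
}

#' @method print graph_spec
#' @export
print.graph_spec <- function(x, ...) {
  cat("<graph_spec> '", x$name, "': ", length(x$feature_ids), " nodes, ",
      nrow(x$edges), " edges", if (!is.null(x$edge_weights)) " (weighted)",
      "\n", sep = "")
  invisible(x)
}

#' Convert an igraph to a graph_spec
#' @param graph an undirected `igraph` with a `name` vertex attribute.
#' @param name graph label.
#' @return a `graph_spec`.
#' @export
as_graph_spec <- function(graph, name = "graph") {
  g <- igraph::simplify(igraph::as_undirected(graph, mode = "collapse"))
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- sprintf("G%04d", seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight else NULL
  graph_spec(ids, el, w, name = name)
}

#' Convert a graph_spec to an igraph
#' @param spec a `graph_spec`.
#' @return an undirected simple `igraph`.
#' @export
graph_spec_to_igraph <- function(spec) {
  g <- igraph::make_empty_graph(n = length(spec$feature_ids), directed = FALSE)
  igraph::V(g)$name <- spec$feature_ids
  if (nrow(spec$edges)) {
    g <- igraph::add_edges(g, t(spec$edges))
    if (!is.null(spec$edge_weights)) igraph::E(g)$weight <- spec$edge_weights
  }
  g
}

#' Union of all shortest paths between seed genes in a background network
#'
#' Reconstructs a subnetwork from a background protein-protein interaction
#' graph by taking, for every unordered pair of seed nodes that lie in the
#' same connected component, all nodes and edges on at least one shortest
#' (unweighted) path between the pair. When several equal-length shortest
#' paths exist, all of them are included, which makes the result
#' deterministic and order-independent. Seeds missing from the background
#' are reported with a warning and skipped; isolated seeds are kept as
#' singleton nodes. Pairs in different components are skipped with a
#' warning.
#'
#' @param background undirected `igraph` (treated as unweighted).
#' @param seeds character vector of seed node names.
#' @return an `igraph` subnetwork.
#' @export
shortest_path_subnetwork <- function(background, seeds) {
  seeds <- unique(as.character(seeds))
  if (!length(seeds)) abort("`seeds` must not be empty.")
  all_names <- igraph::V(background)$name
  missing <- setdiff(seeds, all_names)
  if (length(missing)) {
    warn(sprintf("%d seed(s) not in background: %s", length(missing),
                 paste(missing, collapse = ", ")))
    seeds <- setdiff(seeds, missing)
  }
  if (!length(seeds)) abort("no seeds present in the background graph.")
  g <- igraph::as_undirected(igraph::simplify(background), mode = "collapse")
  dist_seed <- igraph::distances(g, v = seeds, weights = NA)
  comp <- igraph::components(g)$membership
  keep_nodes <- rep(FALSE, igraph::vcount(g))
  names(keep_nodes) <- all_names
  keep_nodes[seeds] <- TRUE
  el <- igraph::as_edgelist(g, names = FALSE)
  keep_edges <- rep(FALSE, nrow(el))
  cross_warned <- FALSE
  if (length(seeds) > 1L) {
    for (a in seq_len(length(seeds) - 1L)) {
      for (b in (a + 1L):length(seeds)) {
        s <- seeds[a]; t <- seeds[b]
        if (comp[s] != comp[t]) { cross_warned <- TRUE; next }
        ds <- dist_seed[a, ]; dt <- dist_seed[b, ]
        dst <- dist_seed[a, t]
        on_path <- is.finite(ds) & is.finite(dt) & (ds + dt == dst)
        keep_nodes <- keep_nodes | on_path
        if (nrow(el)) {
          u <- el[, 1]; v <- el[, 2]
          e_on <- (ds[u] + 1 + dt[v] == dst) | (ds[v] + 1 + dt[u] == dst)
          keep_edges <- keep_edges | (e_on & !is.na(e_on))
        }
      }
    }
  }
  if (cross_warned) warn("some seed pairs lie in different components; skipped.")
  sub <- igraph::subgraph_from_edges(g, which(keep_edges), delete.vertices = FALSE)
  igraph::induced_subgraph(sub, which(keep_nodes))
}

#' Restrict a prior graph to measured features
#'
#' Intersects the graph's node set with the measured feature symbols,
#' inducing the edges and preserving the original relative node order.
#'
#' @param spec a `graph_spec`.
#' @param measured character vector of measured feature symbols.
#' @return a `graph_spec` over the intersection.
#' @export
restrict_to_measured <- function(spec, measured) {
  stopifnot(inherits(spec, "graph_spec"))
  keep <- spec$feature_ids %in% measured
  if (!any(keep)) {
    abort("no graph nodes are measured.", class = "graphomix_empty_graph")
  }
  new_ids <- spec$feature_ids[keep]
  remap <- match(spec$feature_ids, new_ids)
  e_keep <- keep[spec$edges[, 1]] & keep[spec$edges[, 2]]
  edges <- cbind(remap[spec$edges[e_keep, 1]], remap[spec$edges[e_keep, 2]])
  w <- if (!is.null(spec$edge_weights)) spec$edge_weights[e_keep] else NULL
  message(sprintf("restrict_to_measured: kept %d/%d nodes, %d/%d edges",
                  length(new_ids), length(spec$feature_ids),
                  nrow(edges), nrow(spec$edges)))
  graph_spec(new_ids, edges, w, name = spec$name)
}

#' Load a prior graph from disk
#'
#' Supports three dialects: two/three-column edge-list TSV
#' (source, target, optional weight; a `#`-prefixed header is tolerated),
#' SIF (`source<TAB or space>interaction<TAB or space>target [target2 ...]`),
#' and GraphML. Duplicate edges are merged; conflicting duplicate weights
#' are an error. Node order is first-appearance order unless a sidecar file
#' (one symbol per line) is supplied.
#'
#' @param path file path.
#' @param format one of `"edge_list_tsv"`, `"sif"`, `"graphml"`.
#' @param node_order_path optional sidecar defining the node order.
#' @param name graph label (defaults to the file name).
#' @return a `graph_spec`.
#' @export
load_graph <- function(path, format = c("edge_list_tsv", "sif", "graphml"),
                       node_order_path = NULL, name = NULL) {
  format <- tryCatch(match.arg(format),
                     error = function(e) abort(sprintf("unknown graph format '%s'.", format[1]),
                                               class = "graphomix_format_error"))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(node_order_path) && file.exists(paste0(path, ".nodes"))) {
    node_order_path <- paste0(path, ".nodes")
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    spec <- as_graph_spec(g, name = name)
  } else {
    lines <- readLines(path)
    pairs <- list()
    weights <- c()
    for (li in seq_along(lines)) {
      line <- trimws(lines[li])
      if (!nzchar(line) || startsWith(line, "#")) next
      tok <- strsplit(line, "[\t ]+")[[1]]
      if (format == "edge_list_tsv") {
        if (length(tok) < 2L) {
          abort(sprintf("line %d: expected at least two columns.", li),
                class = "graphomix_format_error")
        }
        if (li == 1L && length(tok) >= 3L && is.na(suppressWarnings(as.numeric(tok[3])))) {
          next  # header row
        }
        if (li == 1L && identical(tolower(tok[1]), "source")) next
        pairs[[length(pairs) + 1L]] <- tok[1:2]
        weights <- c(weights, if (length(tok) >= 3L) {
          w <- suppressWarnings(as.numeric(tok[3]))
          if (is.na(w)) abort(sprintf("line %d: bad weight '%s'.", li, tok[3]),
                              class = "graphomix_format_error")
          w
        } else NA_real_)
      } else { # sif
        if (length(tok) == 1L) {
          pairs[[length(pairs) + 1L]] <- c(tok[1], NA)  # isolated node
        } else if (length(tok) >= 3L) {
          for (tgt in tok[3:length(tok)]) {
            pairs[[length(pairs) + 1L]] <- c(tok[1], tgt)
          }
        } else {
          abort(sprintf("line %d: malformed SIF record.", li),
                class = "graphomix_format_error")
        }
      }
    }
    em <- do.call(rbind, pairs)
    if (is.null(em)) abort("no edges found.", class = "graphomix_format_error")
    syms <- as.vector(t(em))
    syms <- unique(syms[!is.na(syms)])
    idx <- matrix(match(em, syms), ncol = 2L)
    real <- !is.na(idx[, 2]) & idx[, 1] != idx[, 2]
    w <- if (format == "edge_list_tsv" && any(!is.na(weights))) weights[real] else NULL
    spec <- graph_spec(syms, idx[real, , drop = FALSE], w, name = name)
  }
  if (!is.null(node_order_path)) {
    order_ids <- readLines(node_order_path)
    order_ids <- order_ids[nzchar(trimws(order_ids))]
    if (!setequal(order_ids, spec$feature_ids)) {
      abort("node-order sidecar does not match the graph's node set.",
            class = "graphomix_format_error")
    }
    perm <- match(spec$feature_ids, order_ids)
    spec <- graph_spec(order_ids, cbind(perm[spec$edges[, 1]], perm[spec$edges[, 2]]),
                       spec$edge_weights, name = spec$name)
  }
  spec
}

#' Write a prior graph to disk
#'
#' @param spec a `graph_spec`.
#' @param path destination.
#' @param format one of `"edge_list_tsv"`, `"sif"`, `"graphml"`.
#' @export
write_graph_spec <- function(spec, path, format = c("edge_list_tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph_spec_to_igraph(spec), path, format = "graphml")
  } else if (format == "edge_list_tsv") {
    src <- spec$feature_ids[spec$edges[, 1]]
    tgt <- spec$feature_ids[spec$edges[, 2]]
    lines <- if (!is.null(spec$edge_weights)) {
      paste(src, tgt, spec$edge_weights, sep = "\t")
    } else {
      paste(src, tgt, sep = "\t")
    }
    isolated <- setdiff(spec$feature_ids, unique(c(src, tgt)))
    writeLines(c(lines), path)
    # node order sidecar keeps isolated nodes and ordering reproducible
    writeLines(spec$feature_ids, paste0(path, ".nodes"))
  } else {
    src <- spec$feature_ids[spec$edges[, 1]]
    tgt <- spec$feature_ids[spec$edges[, 2]]
    writeLines(paste(src, "interacts", tgt, sep = "\t"), path)
  }
  invisible(path)
}
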