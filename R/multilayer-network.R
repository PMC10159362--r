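#' Construct a weighted multilayer network
#'
#' A multilayer network has the same ordered node set replicated in every
#' layer, and arbitrary weighted undirected edges both within layers
#' (intra-layer) and across layers (inter-layer).  The whole network is
#' stored as a single supra-adjacency matrix `M` of dimension
#' `N x N` with `N = n * L`, where `n` is the number of nodes per layer and
#' `L` the number of layers.  The supra-index of node `i` (1-based position
#' in `node_names`) in layer `alpha` (1-based position in `layer_names`) is
#' `(alpha - 1) * n + i`; layers are ordered as declared.
#'
#' @param M numeric `N x N` matrix of nonnegative edge weights; must be
#'   symmetric with a zero diagonal.
#' @param node_names character vector of `n` node identifiers (identical
#'   across layers).
#' @param layer_names character vector of `L` layer identifiers.
#' @return An object of class `multilayer_network`: a list with elements
#'   `M`, `node_names`, `layer_names`, `n`, `L`, `N`.  Rows/columns of `M`
#'   are labelled `"node@layer"`.
#' @seealso [read_multilayer_edgelist()], [decompose_supra()]
#' @export
multilayer_network <- function(M, node_names, layer_names) {
  node_names <- as.character(node_names)
  layer_names <- as.character(layer_names)
  n <- length(node_names)
  L <- length(layer_names)
  N <- n * L
  if (anyDuplicated(node_names)) stop("duplicate node names")
  if (anyDuplicated(layer_names)) stop("duplicate layer names")
  M <- as.matrix(M)
  if (!is.numeric(M) || nrow(M) != N || ncol(M) != N)
    stop(sprintf("M must be a %d x %d numeric matrix (n * L = %d * %d)", N, N, n, L))
  if (any(M < 0)) stop("all edge weights must be nonnegative")
  if (any(diag(M) != 0)) stop("diagonal of M must be zero (no self-edges)")
  if (!isTRUE(all.equal(M, t(M), tolerance = 1e-12, check.attributes = FALSE)))
    stop("M must be symmetric (undirected network)")
  supra <- supra_names(node_names, layer_names)
  dimnames(M) <- list(supra, supra)
  structure(list(M = M, node_names = node_names, layer_names = layer_names,
                 n = n, L = L, N = N),
            class = "multilayer_network")
}

supra_names <- function(node_names, layer_names) {
  as.vector(vapply(layer_names,
                   function(l) paste0(node_names, "@", l),
                   character(length(node_names))))
}

#' Supra-index of a (node, layer) pair
#'
#' @param net a `multilayer_network` or `supra_decomposition`.
#' @param node character vector of node identifiers.
#' @param layer single layer identifier.
#' @return Integer vector of 1-based supra-indices `(alpha - 1) * n + i`.
#' @export
supra_index <- function(net, node, layer) {
  alpha <- match(layer, net$layer_names)
  if (is.na(alpha)) stop(sprintf("unknown layer '%s'", layer))
  i <- match(node, net$node_names)
  if (anyNA(i))
    stop(sprintf("unknown node(s): %s", paste(node[is.na(i)], collapse = ", ")))
  (alpha - 1L) * net$n + i
}

layer_indices <- function(net, layer) {
  alpha <- match(layer, net$layer_names)
  if (is.na(alpha)) stop(sprintf("unknown layer '%s'", layer))
  seq.int((alpha - 1L) * net$n + 1L, alpha * net$n)
}

#' @export
print.multilayer_network <- function(x, ...) {
  cat(sprintf("multilayer_network: %d nodes x %d layers (N = %d supra-nodes)\n",
              x$n, x$L, x$N))
  cat(sprintf("  layers: %s\n", paste(x$layer_names, collapse = ", ")))
  cat(sprintf("  edges:  %d (weight > 0)\n", sum(x$M > 0) / 2))
  invisible(x)
}

#' Read a multilayer network from an edge-list file
#'
#' The file is a TSV with header `node_a  layer_a  node_b  layer_b  weight`;
#' lines starting with `#` are ignored.  Each undirected edge must be listed
#' exactly once (duplicate rows for the same unordered supra-node pair are
#' an error; weights must be pre-aggregated).
#'
#' @param path path to the edge-list TSV.
#' @param layer_names character vector declaring the layers in order.
#' @param node_names optional character vector declaring the nodes in order;
#'   if omitted the sorted union of observed node IDs is used and replicated
#'   in every layer.
#' @return A [multilayer_network()].
#' @export
read_multilayer_edgelist <- function(path, layer_names, node_names = NULL) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          colClasses = c("character", "character",
                                         "character", "character", "numeric"))
  required <- c("node_a", "layer_a", "node_b", "layer_b", "weight")
  if (!all(required %in% names(df)))
    stop("edge list must have columns node_a, layer_a, node_b, layer_b, weight")
  layer_names <- as.character(layer_names)
  if (is.null(node_names)) {
    node_names <- sort(unique(c(df$node_a, df$node_b)))
    if (length(node_names) == 0) stop("empty edge file and no node_names declared")
  }
  n <- length(node_names)
  L <- length(layer_names)
  M <- matrix(0, n * L, n * L)
  if (nrow(df) > 0) {
    bad_layer <- !(df$layer_a %in% layer_names) | !(df$layer_b %in% layer_names)
    if (any(bad_layer)) {
      r <- which(bad_layer)[1]
      stop(sprintf("row %d: unknown layer ('%s' or '%s')", r, df$layer_a[r], df$layer_b[r]))
    }
    if (any(is.na(df$weight) | df$weight < 0)) {
      r <- which(is.na(df$weight) | df$weight < 0)[1]
      stop(sprintf("row %d: weight must be a nonnegative number", r))
    }
    ia <- (match(df$layer_a, layer_names) - 1L) * n + match(df$node_a, node_names)
    ib <- (match(df$layer_b, layer_names) - 1L) * n + match(df$node_b, node_names)
    if (anyNA(ia) || anyNA(ib)) {
      r <- which(is.na(ia) | is.na(ib))[1]
      stop(sprintf("row %d: node not in declared node_names", r))
    }
    if (any(ia == ib)) {
      r <- which(ia == ib)[1]
      stop(sprintf("row %d: self-edge (same node and layer) not allowed", r))
    }
    key <- paste(pmin(ia, ib), pmax(ia, ib))
    if (anyDuplicated(key)) {
      r <- which(duplicated(key))[1]
      stop(sprintf("row %d: duplicate edge (weights must be pre-aggregated)", r))
    }
    M[cbind(ia, ib)] <- df$weight
    M[cbind(ib, ia)] <- df$weight
  }
  multilayer_network(M, node_names, layer_names)
}

#' Write a multilayer network to an edge-list file
#'
#' Inverse of [read_multilayer_edgelist()]: each undirected edge is written
#' once (lower supra-index first) with 12 significant digits, so a
#' read-write-read round trip is lossless at that precision.
#'
#' @param net a `multilayer_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multilayer_edgelist <- function(net, path) {
  up <- which(upper.tri(net$M) & net$M > 0, arr.ind = TRUE)
  alpha_a <- (up[, 1] - 1L) %/% net$n + 1L
  alpha_b <- (up[, 2] - 1L) %/% net$n + 1L
  df <- data.frame(
    node_a = net$node_names[(up[, 1] - 1L) %% net$n + 1L],
    layer_a = net$layer_names[alpha_a],
    node_b = net$node_names[(up[, 2] - 1L) %% net$n + 1L],
    layer_b = net$layer_names[alpha_b],
    weight = sprintf("%.12g", net$M[up]),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Define a query set of nodes in one target layer
#'
#' Query sets drive the set-focused centrality measures
#' ([local_set_centrality()], [query_set_centrality()]) and serve as the
#' seed set for [rwr_h()].  All query nodes must live in a single target
#' layer.
#'
#' @param nodes nonempty character vector of node identifiers.
#' @param layer the target layer identifier.
#' @return An object of class `query_set` with elements `nodes` and `layer`.
#' @export
query_set <- function(nodes, layer) {
  nodes <- unique(as.character(nodes))
  if (length(nodes) == 0) stop("query set must be nonempty")
  if (length(layer) != 1) stop("query set must target exactly one layer")
  structure(list(nodes = nodes, layer = as.character(layer)), class = "query_set")
}

validate_query <- function(net, q) {
  if (!inherits(q, "query_set")) stop("expected a query_set object")
  supra_index(net, q$nodes, q$layer)  # errors on unknown node/layer
}
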