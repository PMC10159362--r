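#' @name multicens-measures
#' @title The MultiCens family of multilayer centrality measures
#'
#' @description
#' Five hierarchically decomposable scores, all fixed points of damped
#' linear systems on the row-normalized supra-decomposition `(A, C)` with
#' restart probability `1 - p`:
#'
#' * **local centrality** `l = p A l + (1-p)/n 1` — within-layer influence
#'   only (`A` is block-diagonal, so nothing crosses layers);
#' * **local layer centrality** `l_i = p A^\[i\] l_i + (1-p)/n 1_\[i\]`,
#'   where `A^[i]` zeroes all column-blocks of `A` except layer `i`'s;
#' * **global centrality** `g = p[(A+C) g + C l] + (1-p)/N 1` — the
#'   cross-layer-aware remainder, with the inter-layer term weighted by the
#'   local centrality of the node being jumped to;
#' * **layer-specific centrality** `g_i = p[(A+C) g_i + C l_i] + (1-p)/N 1_[i]`
#'   — influence on one target layer;
#' * **local-set / query-set centrality** — the same pair of systems with
#'   the indicator restricted to a query set of nodes inside the target
#'   layer; query-set centrality is the measure used to rank candidate
#'   mediator genes.
#'
#' The family is exactly decomposable: summing local layer centralities over
#' layers gives local centrality; summing layer-specific centralities gives
#' global centrality; summing set centralities over a partition of a layer
#' gives the layer's centrality; and unit-normalized `l + g` equals
#' unit-normalized PageRank versatility (the raw vectors differ by the
#' scale factor `L + 1`).
#'
#' All systems are solved in the random-walk (transition) orientation: the
#' jointly row-normalized `A` and `C` of [row_normalize()] enter the
#' iteration transposed, i.e. as column-stochastic transition matrices of
#' the symmetric input network.  (In the smoothing orientation the uniform
#' vector would be the exact versatility fixed point and `l + g` would be
#' exactly constant; see the vignette.)  Solvers iterate from the forcing
#' vector with L-infinity tolerance `tol` (default `1e-10`, enforced as a
#' bound on the distance to the fixed point) and cap `max_iter` (default
#' 1000); convergence is guaranteed for `0 <= p < 1`.  `method = "direct"`
#' replaces the iteration with a dense linear solve of the same system.
#'
#' @param dec a row-normalized [decompose_supra()] decomposition.
#' @param p damping parameter in `[0, 1)`; default 0.85.
#' @param layer target layer identifier.
#' @param q a [query_set()] in the target layer.
#' @param l optional precomputed local centrality at the same `p`
#'   (recomputed when `NULL`); supplying one computed at a different `p` is
#'   an error.
#' @param tol,max_iter solver controls, see [solve_fixed_point()].
#' @param method `"iterative"` (power iteration) or `"direct"` (dense
#'   linear solve).
#' @return A `centrality_result`: list with `scores` (named numeric of
#'   length `N` over supra-nodes), `measure`, `p`, `target_layer`,
#'   `query_set`, `converged_in`, `residual`.
NULL

new_centrality_result <- function(scores, measure, dec, p = NA_real_,
                                  target_layer = NULL, query_set = NULL,
                                  converged_in = NA_integer_, residual = NA_real_) {
  names(scores) <- supra_names(dec$node_names, dec$layer_names)
  structure(list(scores = scores, measure = measure, p = p,
                 target_layer = target_layer, query_set = query_set,
                 converged_in = converged_in, residual = residual,
                 node_names = dec$node_names, layer_names = dec$layer_names,
                 n = dec$n, L = dec$L),
            class = "centrality_result")
}

#' @export
print.centrality_result <- function(x, ...) {
  cat(sprintf("centrality_result: measure = %s, N = %d", x$measure, length(x$scores)))
  if (!is.na(x$p)) cat(sprintf(", p = %g", x$p))
  if (!is.null(x$target_layer)) cat(sprintf(", target layer = %s", x$target_layer))
  cat("\n")
  if (!is.na(x$converged_in))
    cat(sprintf("  converged in %d iterations (residual %.2e)\n",
                x$converged_in, x$residual))
  top <- utils::head(sort(x$scores, decreasing = TRUE), 5)
  cat("  top scores:\n")
  for (i in seq_along(top)) cat(sprintf("    %s  %.6g\n", names(top)[i], top[i]))
  invisible(x)
}

# masked intra-layer matrix A^[i]: all but layer i's column-block set to 0
mask_columns <- function(A, idx) {
  Ai <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  Ai[, idx] <- A[, idx]
  Ai
}

#' Local centrality
#'
#' @rdname multicens-measures
#' @export
local_centrality <- function(dec, p = 0.85, tol = 1e-10, max_iter = 1000L,
                             method = c("iterative", "direct")) {
  dec <- require_normalized(dec)
  b <- rep((1 - p) / dec$n, dec$N)
  sol <- run_solver(t(dec$A), b, p, tol, max_iter, method)
  new_centrality_result(sol$x, "local", dec, p,
                        converged_in = sol$iterations, residual = sol$residual)
}

#' Local centrality restricted to one layer
#'
#' @rdname multicens-measures
#' @export
local_layer_centrality <- function(dec, layer, p = 0.85, tol = 1e-10,
                                   max_iter = 1000L,
                                   method = c("iterative", "direct")) {
  dec <- require_normalized(dec)
  idx <- layer_indices(dec, layer)
  b <- numeric(dec$N)
  b[idx] <- (1 - p) / dec$n
  sol <- run_solver(mask_columns(t(dec$A), idx), b, p, tol, max_iter, method)
  new_centrality_result(sol$x, "local_layer", dec, p, target_layer = layer,
                        converged_in = sol$iterations, residual = sol$residual)
}

#' Global centrality
#'
#' @rdname multicens-measures
#' @export
global_centrality <- function(dec, p = 0.85, l = NULL, tol = 1e-10,
                              max_iter = 1000L,
                              method = c("iterative", "direct")) {
  dec <- require_normalized(dec)
  if (is.null(l)) {
    # inner solve tighter than the outer one: its error enters the forcing
    # term and is amplified by up to p/(1-p) through the outer system
    l <- local_centrality(dec, p, tol = tol / 100, max_iter = max_iter,
                          method = method)
  } else {
    if (!inherits(l, "centrality_result") || l$measure != "local")
      stop("l must be a local centrality result")
    if (!isTRUE(all.equal(l$p, p)))
      stop(sprintf("p mismatch: local centrality was computed at p = %g, not %g", l$p, p))
  }
  Mt <- t(dec$A + dec$C)
  b <- p * as.vector(t(dec$C) %*% l$scores) + (1 - p) / dec$N
  sol <- run_solver(Mt, b, p, tol, max_iter, method)
  new_centrality_result(sol$x, "global", dec, p,
                        converged_in = sol$iterations, residual = sol$residual)
}

#' Layer-specific centrality
#'
#' @rdname multicens-measures
#' @export
layer_specific_centrality <- function(dec, layer, p = 0.85, tol = 1e-10,
                                      max_iter = 1000L,
                                      method = c("iterative", "direct")) {
  dec <- require_normalized(dec)
  idx <- layer_indices(dec, layer)
  li <- local_layer_centrality(dec, layer, p, tol = tol / 100,
                               max_iter = max_iter, method = method)
  b <- p * as.vector(t(dec$C) %*% li$scores)
  b[idx] <- b[idx] + (1 - p) / dec$N
  sol <- run_solver(t(dec$A + dec$C), b, p, tol, max_iter, method)
  new_centrality_result(sol$x, "layer_specific", dec, p, target_layer = layer,
                        converged_in = sol$iterations, residual = sol$residual)
}

#' Local-set centrality
#'
#' @rdname multicens-measures
#' @export
local_set_centrality <- function(dec, q, p = 0.85, tol = 1e-10,
                                 max_iter = 1000L,
                                 method = c("iterative", "direct")) {
  dec <- require_normalized(dec)
  q_idx <- validate_query(dec, q)
  idx <- layer_indices(dec, q$layer)
  b <- numeric(dec$N)
  b[q_idx] <- (1 - p) / dec$n
  sol <- run_solver(mask_columns(t(dec$A), idx), b, p, tol, max_iter, method)
  new_centrality_result(sol$x, "local_set", dec, p, target_layer = q$layer,
                        query_set = q, converged_in = sol$iterations,
                        residual = sol$residual)
}

#' Query-set centrality (the headline gene-ranking measure)
#'
#' @rdname multicens-measures
#' @export
query_set_centrality <- function(dec, q, p = 0.85, tol = 1e-10,
                                 max_iter = 1000L,
                                 method = c("iterative", "direct")) {
  dec <- require_normalized(dec)
  q_idx <- validate_query(dec, q)
  ls <- local_set_centrality(dec, q, p, tol = tol / 100, max_iter = max_iter,
                             method = method)
  b <- p * as.vector(t(dec$C) %*% ls$scores)
  b[q_idx] <- b[q_idx] + (1 - p) / dec$N
  sol <- run_solver(t(dec$A + dec$C), b, p, tol, max_iter, method)
  new_centrality_result(sol$x, "query_set", dec, p, target_layer = q$layer,
                        query_set = q, converged_in = sol$iterations,
                        residual = sol$residual)
}

#' Normalize a score vector to unit sum
#'
#' Centrality vectors are scale-agnostic; cross-measure identities (e.g.
#' local + global versus versatility) hold after normalizing each vector to
#' sum to 1.
#'
#' @param x a `centrality_result` or numeric vector.
#' @return Numeric vector summing to 1 (unchanged if the sum is 0).
#' @export
unit_normalize <- function(x) {
  v <- if (inherits(x, "centrality_result")) x$scores else x
  s <- sum(v)
  if (s > 0) v / s else v
}

#' Rank nodes by a centrality score
#'
#' Ranks supra-nodes (optionally restricted to given layers, optionally
#' excluding nodes such as the query set itself) in descending score order;
#' ties are broken by node identifier, lexicographically, so rankings are
#' stable and reproducible.
#'
#' @param res a `centrality_result`.
#' @param layers optional character vector of layers to rank within.
#' @param exclude_nodes optional node identifiers dropped from the ranking
#'   (in the ranked layers).
#' @return A `data.frame` with columns `node`, `layer`, `score`, `rank`.
#' @export
rank_nodes <- function(res, layers = NULL, exclude_nodes = NULL) {
  stopifnot(inherits(res, "centrality_result"))
  node <- rep(res$node_names, res$L)
  layer <- rep(res$layer_names, each = res$n)
  keep <- rep(TRUE, length(res$scores))
  if (!is.null(layers)) keep <- keep & layer %in% layers
  if (!is.null(exclude_nodes)) keep <- keep & !(node %in% exclude_nodes)
  df <- data.frame(node = node[keep], layer = layer[keep],
                   score = unname(res$scores[keep]), stringsAsFactors = FALSE)
  ord <- order(-df$score, df$node, df$layer)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
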