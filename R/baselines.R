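#' Intra-layer degree centrality
#'
#' Row sums of the raw (unnormalized) intra-layer matrix `A`: the weighted
#' within-layer degree of each supra-node.
#'
#' @param dec an unnormalized [decompose_supra()] decomposition.
#' @return A `centrality_result` with measure `"deg_intra"`.
#' @export
intra_layer_degree <- function(dec) {
  dec <- require_raw(dec)
  new_centrality_result(rowSums(dec$A), "deg_intra", dec)
}

#' Inter-layer degree centrality
#'
#' Row sums of the raw inter-layer matrix `C`: the weighted cross-layer
#' degree.  With `-ln(p-value)` edge weights this is the S_sec score of
#' prior endocrine-interaction work.  Optionally only the columns of a
#' query set are summed, i.e. only cross-layer connections *to the query
#' set* count — the restriction used when benchmarking against set-focused
#' measures.
#'
#' @param dec an unnormalized [decompose_supra()] decomposition.
#' @param query optional [query_set()]; when given, degree counts only
#'   edges incident to the query supra-nodes.
#' @return A `centrality_result` with measure `"deg_inter"`.
#' @export
inter_layer_degree <- function(dec, query = NULL) {
  dec <- require_raw(dec)
  if (is.null(query)) {
    s <- rowSums(dec$C)
  } else {
    q_idx <- validate_query(dec, query)
    s <- rowSums(dec$C[, q_idx, drop = FALSE])
  }
  new_centrality_result(s, "deg_inter", dec,
                        query_set = if (is.null(query)) NULL else query)
}

#' PageRank versatility
#'
#' PageRank on the full supra-adjacency `M = A + C`, ignoring the
#' intra/inter-layer distinction: `x = p M x + (1-p)/N 1`, iterated with the
#' transition operator (the transpose of the row-normalized `M`, i.e. the
#' column-stochastic random-walk matrix — see the package vignette for why
#' the smoothing orientation would degenerate to a constant vector).  Local
#' plus global centrality equals versatility up to the scale factor
#' `L + 1`.
#'
#' @inheritParams multicens-measures
#' @return A `centrality_result` with measure `"versatility"`.
#' @export
versatility <- function(dec, p = 0.85, tol = 1e-10, max_iter = 1000L,
                        method = c("iterative", "direct")) {
  dec <- require_normalized(dec)
  b <- rep((1 - p) / dec$N, dec$N)
  sol <- run_solver(t(dec$A + dec$C), b, p, tol, max_iter, method)
  new_centrality_result(sol$x, "versatility", dec, p,
                        converged_in = sol$iterations, residual = sol$residual)
}

#' Random walk with restart on a heterogeneous/multilayer network (RWR-H)
#'
#' Solves `x = p M~ x + (1-p) x0` with `M~ = (1-lambda) A~ + lambda C~`,
#' where `A~` and `C~` are the *column*-normalized raw `A` and `C` (the
#' walker's transition probabilities) and `x0` puts mass `1/|S|` on each
#' seed node.  At each step the walker restarts from the seeds with
#' probability `1 - p`, or walks on, jumping across layers with probability
#' `lambda`.  Zero columns (nodes with no intra- or no inter-layer edges)
#' are left zero, so a little probability mass can drain there; on networks
#' with no zero columns the scores sum to 1.
#'
#' @param dec an unnormalized [decompose_supra()] decomposition.
#' @param seeds a [query_set()] (or integer vector of supra-indices) of
#'   seed nodes; nonempty.
#' @param p continuation probability in `[0, 1)`.
#' @param lambda inter-layer jump probability in `[0, 1]`; default 0.5.
#' @param tol,max_iter,method solver controls, see [solve_fixed_point()].
#' @return A `centrality_result` with measure `"rwr_h"`.
#' @export
rwr_h <- function(dec, seeds, p = 0.85, lambda = 0.5, tol = 1e-10,
                  max_iter = 1000L, method = c("iterative", "direct")) {
  dec <- require_raw(dec)
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1)
    stop("lambda must be a single number in [0, 1]")
  if (inherits(seeds, "query_set")) {
    s_idx <- validate_query(dec, seeds)
  } else {
    s_idx <- as.integer(seeds)
    if (length(s_idx) == 0 || any(is.na(s_idx)) || any(s_idx < 1) || any(s_idx > dec$N))
      stop("seeds must be a nonempty query_set or valid supra-indices")
  }
  if (length(s_idx) == 0) stop("seed set must be nonempty")
  Mt <- (1 - lambda) * col_normalize(dec$A) + lambda * col_normalize(dec$C)
  x0 <- numeric(dec$N)
  x0[s_idx] <- 1 / length(s_idx)
  sol <- run_solver(Mt, (1 - p) * x0, p, tol, max_iter, match.arg(method))
  new_centrality_result(sol$x, "rwr_h", dec, p,
                        query_set = if (inherits(seeds, "query_set")) seeds else NULL,
                        converged_in = sol$iterations, residual = sol$residual)
}

col_normalize <- function(X) {
  s <- colSums(X)
  f <- ifelse(s > 0, 1 / s, 0)
  X * rep(f, each = nrow(X))
}
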