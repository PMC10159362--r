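#' Split a supra-adjacency matrix into intra- and inter-layer parts
#'
#' Writes the supra-adjacency matrix `M` as `M = A + C`, where `A` keeps
#' only the `L` diagonal `n x n` blocks (edges within a layer) and `C` keeps
#' only the off-diagonal blocks (edges across layers).  All centrality
#' measures in the package are defined on this decomposition.
#'
#' @param net a [multilayer_network()].
#' @return An object of class `supra_decomposition`: a list with the `N x N`
#'   matrices `A` and `C`, the node/layer metadata of `net`, and a
#'   `normalized` flag (`FALSE`; see [row_normalize()]).
#' @export
decompose_supra <- function(net) {
  if (!inherits(net, "multilayer_network")) stop("expected a multilayer_network")
  block <- (seq_len(net$N) - 1L) %/% net$n  # layer index of each supra-node
  same_layer <- outer(block, block, "==")
  A <- net$M * same_layer
  C <- net$M * !same_layer
  dimnames(A) <- dimnames(C) <- dimnames(net$M)
  structure(list(A = A, C = C, node_names = net$node_names,
                 layer_names = net$layer_names, n = net$n, L = net$L, N = net$N,
                 normalized = FALSE),
            class = "supra_decomposition")
}

#' Jointly row-normalize a supra-decomposition
#'
#' Divides each row of `A + C` with a positive sum by that sum; `A` and `C`
#' are scaled by the same per-row factor, so the block structure is
#' preserved and `A + C` becomes row-stochastic (rows of isolated
#' supra-nodes stay all-zero).  The fixed-point centrality solvers require
#' this normalization: with row-stochastic `A + C` and restart probability
#' `p < 1` every iteration is a convergent geometric series.  The operation
#' is idempotent in effect: re-normalizing changes nothing.
#'
#' @param dec a `supra_decomposition` from [decompose_supra()].
#' @return The decomposition with scaled `A`, `C` and `normalized = TRUE`.
#' @export
row_normalize <- function(dec) {
  stopifnot(inherits(dec, "supra_decomposition"))
  s <- rowSums(dec$A) + rowSums(dec$C)
  f <- ifelse(s > 0, 1 / s, 0)
  dec$A <- dec$A * f
  dec$C <- dec$C * f
  dec$normalized <- TRUE
  dec
}

#' @export
print.supra_decomposition <- function(x, ...) {
  cat(sprintf("supra_decomposition: N = %d (%d nodes x %d layers), %s\n",
              x$N, x$n, x$L,
              if (x$normalized) "row-normalized" else "raw weights"))
  invisible(x)
}

require_normalized <- function(dec) {
  if (!inherits(dec, "supra_decomposition")) stop("expected a supra_decomposition")
  if (!isTRUE(dec$normalized))
    stop("this measure requires a row-normalized decomposition; call row_normalize() first")
  dec
}

require_raw <- function(dec) {
  if (!inherits(dec, "supra_decomposition")) stop("expected a supra_decomposition")
  if (isTRUE(dec$normalized))
    stop("this measure uses raw edge weights; pass the unnormalized decomposition")
  dec
}
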