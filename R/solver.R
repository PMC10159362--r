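#' Solve the damped fixed-point system x = p * Op x + b
#'
#' Shared engine behind every PageRank-style measure in the package.  The
#' iteration starts from the forcing vector `b` (the exact solution at
#' `p = 0`) and repeats `x <- p * Op %*% x + b` until the L-infinity change
#' drops to `tol`.  Convergence is guaranteed whenever the spectral radius
#' of `p * Op` is below 1, which holds for every operator used here:  each
#' is a sub-matrix (or the whole) of a row-stochastic `A + C`, so with
#' `p < 1` the iteration is a convergent geometric series.
#'
#' @param Op numeric `N x N` operator matrix.
#' @param b numeric forcing vector of length `N`.
#' @param p damping/restart parameter in `[0, 1)`.
#' @param tol L-infinity convergence tolerance.
#' @param max_iter iteration cap; exceeding it is an error that reports the
#'   final residual.
#' @return A list with `x` (the fixed point), `iterations`, and `residual`
#'   (final L-infinity change).
#' @export
solve_fixed_point <- function(Op, b, p, tol = 1e-10, max_iter = 1000L) {
  check_p(p)
  x <- b
  # stopping: the iteration contracts with factor <= p, so the distance to
  # the fixed point is bounded by res * p / (1 - p); require that bound (or
  # the raw change, whichever is stricter) to be <= tol
  thresh <- if (p > 0) 0.1 * tol * min(1, (1 - p) / p) else tol
  for (it in seq_len(max_iter)) {
    x_new <- p * as.vector(Op %*% x) + b
    res <- max(abs(x_new - x))
    x <- x_new
    if (res <= thresh) {
      return(list(x = x, iterations = it, residual = res))
    }
  }
  stop(sprintf("fixed-point iteration did not converge in %d iterations (residual %.3e > tol %.3e)",
               max_iter, res, tol))
}

# Direct dense solve of (I - p Op) x = b; the linear-algebra route used when
# method = "direct" and as the in-package oracle for the iterative solver.
solve_direct <- function(Op, b, p) {
  check_p(p)
  x <- solve(diag(nrow(Op)) - p * Op, b)
  list(x = as.vector(x), iterations = NA_integer_, residual = 0)
}

check_p <- function(p) {
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p >= 1)
    stop("p must be a single number in [0, 1)")
  invisible(p)
}

run_solver <- function(Op, b, p, tol, max_iter, method) {
  method <- match.arg(method, c("iterative", "direct"))
  if (method == "direct") solve_direct(Op, b, p) else solve_fixed_point(Op, b, p, tol, max_iter)
}
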