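#' Read an expression matrix from TSV/CSV
#'
#' Expects genes in rows and samples in columns, with the first column
#' holding gene identifiers.  Sample identifiers should be subject-level so
#' that cross-tissue alignment can intersect them.
#'
#' @param path file path; tab- or comma-separated inferred from extension
#'   (`.csv` means comma).
#' @return Numeric matrix, genes x samples, with dimnames.
#' @export
read_expression_matrix <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, comment.char = "#")
  as.matrix(df)
}

#' Select the top-variance genes of a tissue
#'
#' Returns the `k` genes with the largest sample variance; ties are broken
#' by gene-identifier order.  Used to cap network size before coexpression
#' construction (take the per-tissue top lists and their union).
#'
#' @param xm numeric genes x samples matrix with gene rownames.
#' @param k number of genes to keep; must be in `[1, nrow(xm)]`.
#' @return Character vector of `k` gene identifiers.
#' @export
top_variance_genes <- function(xm, k) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0) stop("k must be a positive integer")
  if (k > nrow(xm)) stop("k exceeds the number of genes")
  v <- apply(xm, 1, stats::var)
  rownames(xm)[order(-v, rownames(xm))][seq_len(k)]
}

#' Build a multi-tissue coexpression multilayer network
#'
#' Every layer is a tissue; the node set is the sorted union of the
#' requested genes, replicated per layer.  Within-layer edge weights are
#' `|Spearman rho|` between the two genes over all of that tissue's
#' samples; cross-layer weights are `|Spearman rho|` over the subjects
#' shared by the two tissues.  The result is a complete weighted graph (no
#' pruning) unless `prune_below` is set.  Genes absent from a tissue's
#' matrix get all-zero rows in that layer; correlations with a constant
#' expression profile are undefined and recorded as weight 0 (a message
#' reports the count).
#'
#' @param xms named list of genes x samples matrices, one per tissue; list
#'   names are the layer names.
#' @param genes optional character vector of genes to use as the node set
#'   (default: union of all genes observed in `xms`).
#' @param prune_below optional threshold; weights strictly below it are set
#'   to 0 (default `NULL`, keep the complete weighted graph).
#' @return A [multilayer_network()].
#' @export
spearman_multilayer <- function(xms, genes = NULL, prune_below = NULL) {
  if (!is.list(xms) || length(xms) < 2 || is.null(names(xms)))
    stop("xms must be a named list of at least two expression matrices")
  layer_names <- names(xms)
  if (is.null(genes)) genes <- sort(unique(unlist(lapply(xms, rownames))))
  genes <- sort(unique(as.character(genes)))
  n <- length(genes)
  L <- length(xms)
  N <- n * L
  M <- matrix(0, N, N)
  n_undefined <- 0L
  fill <- function(block, rows_present, cols_present, ri, ci) {
    nas <- is.na(block)
    if (any(nas)) {
      n_undefined <<- n_undefined + sum(nas)
      block[nas] <- 0
    }
    out <- matrix(0, n, n)
    out[rows_present, cols_present] <- abs(block)
    M[ri, ci] <<- out
    invisible(NULL)
  }
  for (t in seq_len(L)) {
    Xt <- xms[[t]]
    present_t <- genes %in% rownames(Xt)
    Xt <- Xt[genes[present_t], , drop = FALSE]
    idx_t <- ((t - 1L) * n + 1L):(t * n)
    R <- suppressWarnings(stats::cor(t(Xt), method = "spearman"))
    diag(R) <- 0
    fill(R, present_t, present_t, idx_t, idx_t)
    if (t < L) for (u in (t + 1L):L) {
      Xu <- xms[[u]]
      present_u <- genes %in% rownames(Xu)
      Xu <- Xu[genes[present_u], , drop = FALSE]
      shared <- intersect(colnames(xms[[t]]), colnames(Xu))
      if (length(shared) < 3)
        stop(sprintf("tissues '%s' and '%s' share only %d samples (need >= 3)",
                     layer_names[t], layer_names[u], length(shared)))
      idx_u <- ((u - 1L) * n + 1L):(u * n)
      Rtu <- suppressWarnings(
        stats::cor(t(xms[[t]][genes[present_t], shared, drop = FALSE]),
                   t(Xu[, shared, drop = FALSE]), method = "spearman"))
      fill(Rtu, present_t, present_u, idx_t, idx_u)
      M[idx_u, idx_t] <- t(M[idx_t, idx_u])
    }
  }
  if (n_undefined > 0)
    message(sprintf("%d undefined correlation(s) (constant expression profile) set to weight 0",
                    n_undefined))
  if (!is.null(prune_below)) M[M < prune_below] <- 0
  multilayer_network(M, genes, layer_names)
}

#' Add protein-protein interaction support to coexpression weights
#'
#' For every PPI gene pair present in the network's node set, the
#' within-layer edge weight of the pair is increased by 1 unit in every
#' layer (coexpression evidence and physical-interaction evidence are
#' added).  Pairs referencing unknown genes are skipped; a message reports
#' how many.
#'
#' @param net a [multilayer_network()].
#' @param ppi_edges data frame whose first two columns are interacting gene
#'   identifiers.
#' @return The augmented `multilayer_network`.
#' @export
augment_with_ppi <- function(net, ppi_edges) {
  stopifnot(inherits(net, "multilayer_network"))
  if (nrow(ppi_edges) == 0) return(net)
  ga <- as.character(ppi_edges[[1]])
  gb <- as.character(ppi_edges[[2]])
  ia <- match(ga, net$node_names)
  ib <- match(gb, net$node_names)
  known <- !is.na(ia) & !is.na(ib) & ia != ib
  if (any(!known))
    message(sprintf("skipped %d PPI edge(s) with unknown or identical gene ids", sum(!known)))
  ia <- ia[known]; ib <- ib[known]
  M <- net$M
  for (alpha in seq_len(net$L)) {
    off <- (alpha - 1L) * net$n
    M[cbind(off + ia, off + ib)] <- M[cbind(off + ia, off + ib)] + 1
    M[cbind(off + ib, off + ia)] <- M[cbind(off + ib, off + ia)] + 1
  }
  multilayer_network(M, net$node_names, net$layer_names)
}

#' Linearly adjust expression for covariates
#'
#' Regresses each gene's profile on the covariate design (intercept
#' included; factors are one-hot encoded via `model.matrix`) and returns
#' the residuals with the gene means restored — the standard linear
#' correction for sex, age, batch and similar confounders before network
#' construction.
#'
#' @param xm numeric genes x samples matrix.
#' @param covariates data frame of covariates with one row per sample, in
#'   the same order as `colnames(xm)` (or with rownames matching them).
#' @return Adjusted matrix of the same shape.
#' @export
adjust_covariates <- function(xm, covariates) {
  if (!is.null(rownames(covariates)) &&
      all(colnames(xm) %in% rownames(covariates))) {
    covariates <- covariates[colnames(xm), , drop = FALSE]
  }
  if (nrow(covariates) != ncol(xm))
    stop("covariate rows must align to the samples (columns of xm)")
  X <- stats::model.matrix(~ ., data = covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient covariate design; collinear column(s): %s",
                 paste(dropped, collapse = ", ")))
  }
  fit <- stats::lm.fit(X, t(xm))
  res <- t(fit$residuals)
  res + rowMeans(xm)
}
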