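#' Restrict inter-layer edges to those incident to a query set
#'
#' Zeroes every entry of the inter-layer matrix `C` except rows/columns of
#' the query supra-nodes.  Used when benchmarking query-agnostic measures
#' (versatility, inter-layer degree) against set-focused ones: their
#' cross-layer information is limited to connections to the query set, so
#' all methods see the same signal.
#'
#' @param dec an unnormalized [decompose_supra()] decomposition.
#' @param query a [query_set()].
#' @return A new unnormalized decomposition with restricted `C`.
#' @export
restrict_interlayer <- function(dec, query) {
  dec <- require_raw(dec)
  q_idx <- validate_query(dec, query)
  keep <- matrix(FALSE, dec$N, dec$N)
  keep[q_idx, ] <- TRUE
  keep[, q_idx] <- TRUE
  dec$C <- dec$C * keep
  dec
}

#' Run the synthetic benchmark grid
#'
#' For every combination of connection strength, ground-truth mixing
#' fraction and seed, generates a benchmark network ([generate_synthetic()]),
#' ranks the source-layer (layer 1) nodes with each method, and scores the
#' ranking against the ground truth by recall-at-k and normalized AUC.
#' Following the benchmark protocol, inter-layer degree counts cross-layer
#' connections to the query set only and RWR-H seeds equal the query set;
#' versatility's inter-layer edges are likewise restricted to the query set
#' by default (via [restrict_interlayer()]); set
#' `restrict_versatility = FALSE` to score plain whole-network versatility.
#'
#' @param model benchmark model, 1 or 2.
#' @param strengths numeric grid of connection strengths (the full sweep is
#'   `seq(0.05, 1, by = 0.05)`).
#' @param xs numeric grid of source-set-2 fractions.
#' @param seeds integer vector of RNG seeds.
#' @param n_per_layer,community_size,base_p,background_strength generator
#'   knobs, see [synthetic_config()]; `background_strength = NULL` ties the
#'   background communities to the swept strength.
#' @param p,lambda centrality parameters.
#' @param k_eval the `k` for recall-at-k (100 in the full-size benchmark).
#' @param methods subset of
#'   `c("qc", "lc", "gc", "versatility", "deg_inter", "rwrh")`.
#' @param restrict_versatility logical; restrict versatility's inter-layer
#'   edges to the query set (default `TRUE`, the benchmark protocol).
#' @return A `data.frame` with one row per (model, strength, x, seed,
#'   method): columns `model`, `strength`, `x`, `method`, `seed`,
#'   `recall_at_k`, `auc`.
#' @export
run_benchmark <- function(model = 1, strengths = seq(0.05, 1, by = 0.05),
                          xs = 0, seeds = 1, n_per_layer = 500,
                          community_size = 50, base_p = 0.05,
                          background_strength = NULL, p = 0.85, lambda = 0.5,
                          k_eval = 100,
                          methods = c("qc", "lc", "gc", "versatility",
                                      "deg_inter", "rwrh"),
                          restrict_versatility = TRUE) {
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (s in strengths) for (x in xs) for (sd in seeds) {
    cfg <- synthetic_config(model = model, n_per_layer = n_per_layer,
                            base_p = base_p, community_size = community_size,
                            strength = s,
                            background_strength = if (is.null(background_strength)) s
                                                  else background_strength,
                            fraction_x = x, seed = sd)
    gen <- generate_synthetic(cfg)
    sc <- benchmark_scores(gen$network, gen$truth$query_set, p = p,
                           lambda = lambda, methods = methods,
                           restrict_versatility = restrict_versatility)
    for (m in methods) {
      ranked <- rank_layer(sc[[m]], gen$network, "L1")
      ev <- recall_at_k(ranked, gen$truth$ground_truth)
      rows[[length(rows) + 1L]] <- data.frame(
        model = model, strength = s, x = x, method = m, seed = sd,
        recall_at_k = ev$recall[min(k_eval, length(ranked))],
        auc = auc_recall(ev), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# per-method supra score vectors for a benchmark network
benchmark_scores <- function(net, query, p = 0.85, lambda = 0.5,
                             methods = c("qc", "lc", "gc", "versatility",
                                         "deg_inter", "rwrh"),
                             restrict_versatility = TRUE) {
  raw <- decompose_supra(net)
  dec <- row_normalize(raw)
  out <- list()
  if ("qc" %in% methods)
    out$qc <- query_set_centrality(dec, query, p)$scores
  if ("lc" %in% methods)
    out$lc <- local_centrality(dec, p)$scores
  if ("gc" %in% methods)
    out$gc <- global_centrality(dec, p)$scores
  if ("versatility" %in% methods) {
    vdec <- if (restrict_versatility) row_normalize(restrict_interlayer(raw, query)) else dec
    out$versatility <- versatility(vdec, p)$scores
  }
  if ("deg_inter" %in% methods)
    out$deg_inter <- inter_layer_degree(raw, query)$scores
  if ("rwrh" %in% methods)
    out$rwrh <- rwr_h(raw, query, p, lambda)$scores
  out
}

# rank the nodes of one layer by a supra score vector (ties: node id)
rank_layer <- function(scores, net, layer) {
  idx <- layer_indices(net, layer)
  v <- scores[idx]
  net$node_names[order(-v, net$node_names)]
}

#' Generate fixture expression matrices with a planted cross-tissue module
#'
#' Gaussian expression for `n_tissues` tissues over a shared subject panel,
#' with the first `module_size` genes sharing a per-subject latent factor
#' in every tissue, so module genes are correlated (about `rho`) both
#' within and across tissues while all other genes are independent noise.
#' A stand-in for real multi-tissue expression data when testing network
#' inference end to end.
#'
#' @param n_genes genes per tissue (>= 2).
#' @param n_samples shared subjects (>= 2).
#' @param n_tissues number of tissues (>= 2).
#' @param module_size planted module size (`0` for a pure null).
#' @param rho target correlation among module genes, in `[0, 1)`.
#' @param seed RNG seed.
#' @return List with `expression` (named list of genes x samples matrices)
#'   and `module_genes` (character vector).
#' @export
generate_fixture_expression <- function(n_genes = 100, n_samples = 100,
                                        n_tissues = 2, module_size = 10,
                                        rho = 0.9, seed = 1) {
  if (n_genes < 2 || n_samples < 2 || n_tissues < 2) stop("sizes must be >= 2")
  if (module_size > n_genes) stop("module_size exceeds n_genes")
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  genes <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))
  samples <- sprintf("s%0*d", nchar(n_samples), seq_len(n_samples))
  tissues <- paste0("tissue", seq_len(n_tissues))
  with_seed(seed, {
    z <- stats::rnorm(n_samples)  # shared latent factor of the planted module
    expr <- lapply(tissues, function(t) {
      X <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples,
                  dimnames = list(genes, samples))
      if (module_size > 0) {
        noise <- X[seq_len(module_size), , drop = FALSE]
        X[seq_len(module_size), ] <-
          sqrt(rho) * matrix(z, module_size, n_samples, byrow = TRUE) +
          sqrt(1 - rho) * noise
      }
      X
    })
    names(expr) <- tissues
    list(expression = expr, module_genes = genes[seq_len(module_size)])
  })
}
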