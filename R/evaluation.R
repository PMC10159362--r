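#' Recall-at-k curve of a ranking against a ground-truth set
#'
#' `recall(k)` is the fraction of ground-truth nodes among the top `k` of
#' the ranking, for every `k` from 1 to the size of the ranked universe.
#'
#' @param ranking character vector: the full ranked universe, best first.
#' @param truth nonempty character vector of ground-truth identifiers; must
#'   be a subset of `ranking`.
#' @return A `ranking_evaluation` list: `ks`, `recall`, `n_candidates`,
#'   `truth_size`.
#' @seealso [auc_recall()]
#' @export
recall_at_k <- function(ranking, truth) {
  truth <- unique(as.character(truth))
  if (length(truth) == 0) stop("ground-truth set must be nonempty")
  if (anyDuplicated(ranking)) stop("ranking contains duplicate identifiers")
  if (!all(truth %in% ranking))
    stop("ground truth must be a subset of the ranked universe")
  hits <- cumsum(ranking %in% truth)
  structure(list(ks = seq_along(ranking), recall = hits / length(truth),
                 n_candidates = length(ranking), truth_size = length(truth)),
            class = "ranking_evaluation")
}

#' Normalized area under the recall-at-k curve
#'
#' The mean of `recall(k)` over all `k`, divided by the same mean for the
#' ideal ranking (all ground-truth nodes first).  An ideal ranking scores
#' exactly 1; a uniformly random ranking scores about 0.5 for small truth
#' sets.
#'
#' @param ev a `ranking_evaluation` from [recall_at_k()].
#' @return Normalized area in `[0, 1]`.
#' @export
auc_recall <- function(ev) {
  stopifnot(inherits(ev, "ranking_evaluation"))
  n <- ev$n_candidates
  T_ <- ev$truth_size
  ideal <- pmin(ev$ks, T_) / T_
  mean(ev$recall) / mean(ideal)
}

#' Variance-matched random gene sets
#'
#' Draws random gene sets matching a target set's composition across three
#' variance strata (low / medium / high, split at the 33rd and 66th
#' percentiles of the variance distribution; boundary genes fall in the
#' lower stratum).  Used as a null model to assess the significance of a
#' gene set's centrality scores.
#'
#' @param variances named numeric vector: per-gene variance for the whole
#'   gene universe.
#' @param target character vector, the gene set whose stratum counts each
#'   draw must match; all target genes must appear in `variances`.
#' @param n_draws number of random sets.
#' @param seed RNG seed.
#' @return List of `n_draws` character vectors, each drawn without
#'   replacement with the target's per-stratum counts.
#' @export
stratified_random_sets <- function(variances, target, n_draws, seed = 1) {
  genes <- names(variances)
  if (is.null(genes)) stop("variances must be a named vector")
  target <- unique(as.character(target))
  if (!all(target %in% genes)) stop("all target genes must have a variance")
  cuts <- stats::quantile(variances, c(0.33, 0.66), names = FALSE)
  stratum <- ifelse(variances <= cuts[1], "low",
                    ifelse(variances <= cuts[2], "medium", "high"))
  names(stratum) <- genes
  target_counts <- table(factor(stratum[target], levels = c("low", "medium", "high")))
  pool <- split(genes, factor(stratum, levels = c("low", "medium", "high")))
  for (s in names(target_counts)) {
    if (target_counts[[s]] > length(pool[[s]]))
      stop(sprintf("stratum '%s' has only %d genes but the target needs %d",
                   s, length(pool[[s]]), target_counts[[s]]))
  }
  with_seed(seed, {
    lapply(seq_len(n_draws), function(i) {
      picked <- unlist(lapply(names(target_counts), function(s) {
        k <- target_counts[[s]]
        if (k == 0) character(0) else sample(pool[[s]], k)
      }), use.names = FALSE)
      sort(picked)
    })
  })
}

#' Signed rank differences between two rankings
#'
#' For every node, its position in `r1` minus its position in `r2`.
#' Comparing e.g. local-centrality against global-centrality rankings
#' highlights genes whose within-layer and cross-layer influence diverge.
#'
#' @param r1,r2 character vectors: two rankings over the same universe.
#' @return Named integer vector (names = nodes, ordered as in `r1`).
#' @export
delta_ranks <- function(r1, r2) {
  if (anyDuplicated(r1) || anyDuplicated(r2))
    stop("rankings must not contain duplicates")
  if (length(r1) != length(r2) || !setequal(r1, r2))
    stop("rankings must cover identical universes")
  d <- seq_along(r1) - match(r1, r2)
  names(d) <- r1
  d
}

#' Literature co-occurrence support score
#'
#' Observed-over-expected ratio of joint article counts under independence:
#' `support = joint / (h * g) * corpus_size`.  A hormone-gene (or
#' disease-gene) pair co-mentioned more often than expected by chance
#' scores above 1, the conventional evidence threshold.
#'
#' @param h_count number of articles mentioning the hormone/disease term.
#' @param g_count number of articles mentioning the gene.
#' @param joint_count number of articles mentioning both; must not exceed
#'   either marginal count.
#' @param corpus_size total articles in the corpus; default 27e6 (PubMed).
#' @return Nonnegative support score.
#' @export
cooccurrence_support <- function(h_count, g_count, joint_count,
                                 corpus_size = 27e6) {
  if (h_count <= 0 || g_count <= 0)
    stop("h_count and g_count must be positive (ratio undefined otherwise)")
  if (joint_count < 0 || corpus_size <= 0)
    stop("joint_count must be >= 0 and corpus_size > 0")
  if (joint_count > min(h_count, g_count))
    stop("joint_count cannot exceed either marginal count")
  joint_count / (h_count * g_count) * corpus_size
}

#' Cosine similarity between two embedding vectors
#'
#' Contextual-similarity support for a gene-hormone (or gene-disease) pair
#' from word embeddings of the two terms; positive values indicate support.
#'
#' @param v1,v2 numeric vectors of equal length and nonzero norm.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
embedding_cosine <- function(v1, v2) {
  if (length(v1) != length(v2)) stop("vectors must have equal dimension")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero vector has no direction")
  sum(v1 * v2) / (n1 * n2)
}
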