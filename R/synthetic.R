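#' Configuration for the two-layer planted-community benchmark
#'
#' The benchmark emulates hormonal signaling between two tissues.  A base
#' Erdos-Renyi multilayer network (every within- and cross-layer node pair
#' gets an edge of weight 1 with probability `base_p`) is overlaid with
#' denser planted communities: a *query set* in layer 2 (hormone-responsive
#' genes), *source set 1* in layer 1 directly connected to the query set
#' (hormone-producing genes), *source set 2* in layer 1 connected only to
#' source set 1 (two-hop mediators), and three background communities in
#' layer 1 standing in for unrelated gene clusters.  Model 2 additionally
#' plants a distractor community in layer 2 connected to the query set.
#' Extra edges are added independently with probability `strength` (the
#' *connection strength*) within each planted community and between the
#' designated community pairs; a pair hit by both the base and the extra
#' process gets weight 2.
#'
#' @param model 1 (single layer-2 community) or 2 (extra layer-2
#'   community connected to the query set).
#' @param n_per_layer nodes per layer; default 500.
#' @param base_p base edge probability; default 0.05.
#' @param community_size size of every planted community; default 50.
#' @param strength extra-edge probability for the query/source communities,
#'   in `[0, 1]`.
#' @param background_strength extra-edge probability within and across the
#'   three background communities; defaults to `strength`.
#' @param fraction_x fraction of the ground-truth set drawn from source set
#'   2 (the rest from source set 1).
#' @param seed RNG seed; the generator is deterministic given the seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(model = 1, n_per_layer = 500, base_p = 0.05,
                             community_size = 50, strength = 0.5,
                             background_strength = strength, fraction_x = 0,
                             seed = 1) {
  model <- as.integer(model)
  if (!model %in% c(1L, 2L)) stop("model must be 1 or 2")
  for (pr in c(base_p, strength, background_strength))
    if (!is.numeric(pr) || pr < 0 || pr > 1) stop("probabilities must lie in [0, 1]")
  if (fraction_x < 0 || fraction_x > 1) stop("fraction_x must lie in [0, 1]")
  # layer 1 holds source sets 1-2 plus three background communities;
  # layer 2 holds the query set (and in model 2 a distractor community)
  if (5L * community_size > n_per_layer)
    stop("layer 1 needs 5 communities: community_size * 5 must not exceed n_per_layer")
  if (model == 2L && 2L * community_size > n_per_layer)
    stop("layer 2 needs 2 communities in model 2")
  structure(list(model = model, n_per_layer = as.integer(n_per_layer),
                 base_p = base_p, community_size = as.integer(community_size),
                 strength = strength, background_strength = background_strength,
                 fraction_x = fraction_x, seed = as.integer(seed)),
            class = "synthetic_config")
}

# evaluate expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic two-layer benchmark network
#'
#' Builds the planted-community network described in [synthetic_config()].
#' Community membership is assigned as contiguous index blocks (source set 1
#' = the first `community_size` nodes of layer 1, source set 2 the next
#' block, then the three background communities; the query set is the first
#' block of layer 2, the model-2 distractor the next), which makes
#' membership reproducible without consuming RNG draws.  Random draws occur
#' in a fixed documented order (base network first, then extra edges for:
#' query set, source set 1, source set 2, source1-source2, source1-query,
#' model-2 distractor, distractor-query, the three background communities,
#' background pairs), so a fixed seed yields a bitwise-identical network.
#'
#' @param cfg a [synthetic_config()].
#' @return A list with `network` (a [multilayer_network()]) and `truth` (a
#'   `synthetic_truth` list: `query_set`, `source_set_1`, `source_set_2`,
#'   `background_sets`, `extra_layer2_community`, `ground_truth`).
#' @export
generate_synthetic <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_per_layer
  cs <- cfg$community_size
  N <- 2L * n
  node_names <- sprintf("g%0*d", nchar(n), seq_len(n))
  layer_names <- c("L1", "L2")

  blk <- function(k) ((k - 1L) * cs + 1L):(k * cs)  # within-layer node index block
  s1 <- blk(1); s2 <- blk(2); bg <- list(blk(3), blk(4), blk(5))
  qry <- blk(1) + n          # layer-2 supra-indices
  extra <- blk(2) + n

  W <- with_seed(cfg$seed, {
    W <- matrix(0, N, N)
    # base ER network over all within- and cross-layer pairs, weight 1
    up <- upper.tri(W)
    W[up] <- as.numeric(stats::runif(sum(up)) < cfg$base_p)
    add_pairs <- function(W, idx_a, idx_b = NULL, prob) {
      if (prob <= 0) return(W)
      if (is.null(idx_b)) {        # all unordered pairs within idx_a
        pr <- t(utils::combn(idx_a, 2L))
      } else {                     # all pairs across two disjoint sets
        pr <- as.matrix(expand.grid(a = idx_a, b = idx_b))
      }
      i <- pmin(pr[, 1], pr[, 2]); j <- pmax(pr[, 1], pr[, 2])
      hit <- stats::runif(length(i)) < prob
      W[cbind(i[hit], j[hit])] <- W[cbind(i[hit], j[hit])] + 1
      W
    }
    s <- cfg$strength
    W <- add_pairs(W, qry, prob = s)
    W <- add_pairs(W, s1, prob = s)
    W <- add_pairs(W, s2, prob = s)
    W <- add_pairs(W, s1, s2, prob = s)
    W <- add_pairs(W, s1, qry, prob = s)
    if (cfg$model == 2L) {
      W <- add_pairs(W, extra, prob = s)
      W <- add_pairs(W, extra, qry, prob = s)
    }
    bs <- cfg$background_strength
    for (b in bg) W <- add_pairs(W, b, prob = bs)
    W <- add_pairs(W, bg[[1]], bg[[2]], prob = bs)
    W <- add_pairs(W, bg[[1]], bg[[3]], prob = bs)
    W <- add_pairs(W, bg[[2]], bg[[3]], prob = bs)
    W + t(W)
  })

  net <- multilayer_network(W, node_names, layer_names)
  truth <- structure(list(
    query_set = query_set(node_names[blk(1)], "L2"),
    source_set_1 = node_names[s1],
    source_set_2 = node_names[s2],
    background_sets = lapply(bg, function(b) node_names[b]),
    extra_layer2_community = if (cfg$model == 2L) node_names[blk(2)] else NULL,
    community_size = cs), class = "synthetic_truth")
  truth$ground_truth <- make_ground_truth(truth, cfg$fraction_x, cfg$seed)
  list(network = net, truth = truth)
}

#' Sample a mixed ground-truth node set
#'
#' The ground truth starts as source set 1 (directly connected to the query
#' set) and a fraction `fraction_x` of its slots are replaced by nodes from
#' source set 2 (connected only through source set 1):
#' `floor(fraction_x * community_size)` nodes are sampled from source set 2
#' and the complement count from source set 1, deterministically under
#' `seed`.
#'
#' @param truth a `synthetic_truth` from [generate_synthetic()].
#' @param fraction_x fraction in `[0, 1]` of the set drawn from source set 2.
#' @param seed RNG seed for the subsampling.
#' @return Character vector of `community_size` layer-1 node identifiers.
#' @export
make_ground_truth <- function(truth, fraction_x, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (fraction_x < 0 || fraction_x > 1) stop("fraction_x must lie in [0, 1]")
  cs <- truth$community_size
  n2 <- floor(fraction_x * cs)
  with_seed(seed + 1L, {
    picked2 <- if (n2 > 0) sample(truth$source_set_2, n2) else character(0)
    picked1 <- if (cs - n2 > 0) sample(truth$source_set_1, cs - n2) else character(0)
    sort(c(picked1, picked2))
  })
}
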