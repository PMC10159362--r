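# direct dense solves written inline act as independent oracles for the
# iterative solvers throughout this file

test_that("edgeless and p = 0 degenerate cases give the forcing vector", {
  net <- multilayer_network(matrix(0, 6, 6), paste0("g", 1:3), c("T1", "T2"))
  dec <- norm_dec(net)
  l <- local_centrality(dec, p = 0.85)
  expect_equal(unname(l$scores), rep(0.05, 6))  # (1-p)/n = 0.15/3
  net2 <- random_net(4, 2, seed = 1)
  l0 <- local_centrality(norm_dec(net2), p = 0)
  expect_equal(unname(l0$scores), rep(1 / 4, 8))
  # layer-restricted: mass only on the target layer
  ll <- local_layer_centrality(dec, "T1", p = 0.5)
  expect_equal(unname(ll$scores), c(rep(0.5 / 3, 3), rep(0, 3)))
  # local-set on an edgeless network: mass only on query supra-nodes
  net10 <- multilayer_network(matrix(0, 20, 20), sprintf("g%02d", 1:10), c("T1", "T2"))
  ls <- local_set_centrality(norm_dec(net10), query_set(c("g01", "g02"), "T1"), p = 0.5)
  expect_equal(unname(ls$scores[1:2]), rep(0.05, 2))
  expect_true(all(ls$scores[3:20] == 0))
})

test_that("every measure matches its direct linear solve on random networks", {
  for (seed in 1:4) {
    net <- random_net(n = 7, L = sample(2:3, 1), density = 0.4, seed = seed)
    dec <- norm_dec(net)
    for (p in c(0.3, 0.85)) {
      for (fn in list(
        function(m) local_centrality(dec, p, method = m),
        function(m) local_layer_centrality(dec, "T2", p, method = m),
        function(m) global_centrality(dec, p, method = m),
        function(m) layer_specific_centrality(dec, "T1", p, method = m),
        function(m) local_set_centrality(dec, query_set(c("g01", "g03"), "T1"), p, method = m),
        function(m) query_set_centrality(dec, query_set(c("g01", "g03"), "T1"), p, method = m),
        function(m) versatility(dec, p, method = m))) {
        it <- fn("iterative")
        dr <- fn("direct")
        expect_lt(max(abs(it$scores - dr$scores)) / max(dr$scores), 1e-8)
      }
    }
  }
})

test_that("local centrality decomposes into per-layer local centralities", {
  net <- random_net(6, 3, density = 0.5, seed = 9)
  dec <- norm_dec(net)
  for (p in c(0, 0.3, 0.85)) {
    l <- local_centrality(dec, p)
    lsum <- Reduce(`+`, lapply(net$layer_names, function(ly)
      local_layer_centrality(dec, ly, p)$scores))
    expect_equal(lsum, l$scores, tolerance = 1e-8)
    # each per-layer vector is l masked to that layer
    l2 <- local_layer_centrality(dec, "T2", p)
    idx <- 7:12
    expect_equal(l2$scores[idx], l$scores[idx], tolerance = 1e-8)
    expect_true(all(l2$scores[-idx] == 0))
  }
})

test_that("global centrality reduces to l / L when there are no inter-layer edges", {
  W <- matrix(0, 12, 12)
  set.seed(4)
  for (blk in list(1:6, 7:12)) {
    B <- matrix(runif(36), 6); B <- (B + t(B)) / 2; diag(B) <- 0
    W[blk, blk] <- B
  }
  net <- multilayer_network(W, paste0("g", 1:6), c("T1", "T2"))
  dec <- norm_dec(net)
  expect_true(all(dec$C == 0))
  l <- local_centrality(dec, 0.85)
  g <- global_centrality(dec, 0.85, l)
  expect_equal(g$scores, l$scores / 2, tolerance = 1e-8)
})

test_that("local + global centrality is versatility times (L + 1) and matches after unit normalization", {
  for (seed in c(3, 8)) {
    net <- random_net(6, 2, density = 0.5, seed = seed)
    dec <- norm_dec(net)
    l <- local_centrality(dec, 0.85)
    g <- global_centrality(dec, 0.85, l)
    x <- versatility(dec, 0.85)
    expect_equal(unit_normalize(l$scores + g$scores), unit_normalize(x),
                 tolerance = 1e-8)
    expect_equal(l$scores + g$scores, (net$L + 1) * x$scores, tolerance = 1e-7)
  }
})

test_that("layer-specific centralities sum to global centrality", {
  net <- random_net(5, 4, density = 0.4, seed = 6)
  dec <- norm_dec(net)
  g <- global_centrality(dec, 0.85)
  gsum <- Reduce(`+`, lapply(net$layer_names, function(ly)
    layer_specific_centrality(dec, ly, 0.85)$scores))
  expect_equal(gsum, g$scores, tolerance = 1e-8)
})

test_that("set centralities over a partition sum to the layer centralities", {
  net <- random_net(9, 2, density = 0.5, seed = 12)
  dec <- norm_dec(net)
  parts <- split(net$node_names, rep(1:3, each = 3))
  for (p in c(0.3, 0.85)) {
    ls_sum <- Reduce(`+`, lapply(parts, function(ns)
      local_set_centrality(dec, query_set(ns, "T1"), p)$scores))
    expect_equal(ls_sum, local_layer_centrality(dec, "T1", p)$scores,
                 tolerance = 1e-8)
    qs_sum <- Reduce(`+`, lapply(parts, function(ns)
      query_set_centrality(dec, query_set(ns, "T1"), p)$scores))
    expect_equal(qs_sum, layer_specific_centrality(dec, "T1", p)$scores,
                 tolerance = 1e-8)
  }
  # whole layer as a single query set equals the layer measures
  whole <- query_set(net$node_names, "T2")
  expect_equal(local_set_centrality(dec, whole, 0.85)$scores,
               local_layer_centrality(dec, "T2", 0.85)$scores, tolerance = 1e-8)
  expect_equal(query_set_centrality(dec, whole, 0.85)$scores,
               layer_specific_centrality(dec, "T2", 0.85)$scores, tolerance = 1e-8)
})

test_that("relabeling nodes permutes every score vector identically", {
  net <- random_net(6, 2, density = 0.5, seed = 21)
  perm <- c(4, 2, 6, 1, 3, 5)
  supra_perm <- c(perm, perm + 6)
  net_p <- multilayer_network(net$M[supra_perm, supra_perm],
                              net$node_names[perm], net$layer_names)
  dec <- norm_dec(net); dec_p <- norm_dec(net_p)
  q <- query_set(c("g02", "g04"), "T2")
  for (fn in list(function(d) local_centrality(d, 0.85)$scores,
                  function(d) global_centrality(d, 0.85)$scores,
                  function(d) query_set_centrality(d, q, 0.85)$scores,
                  function(d) versatility(d, 0.85)$scores)) {
    expect_equal(unname(fn(dec_p)), unname(fn(dec)[supra_perm]), tolerance = 1e-8)
  }
})

test_that("as p tends to 0 every measure tends to its forcing vector", {
  net <- random_net(5, 2, density = 0.5, seed = 30)
  dec <- norm_dec(net)
  p <- 1e-8
  expect_equal(unname(local_centrality(dec, p)$scores), rep(1 / 5, 10),
               tolerance = 1e-6)
  q <- query_set(c("g01", "g05"), "T1")
  qc <- query_set_centrality(dec, q, p)
  ind <- numeric(10); ind[c(1, 5)] <- (1 - p) / 10
  expect_equal(unname(qc$scores), ind, tolerance = 1e-6)
})

test_that("parameter and input validation errors are raised", {
  net <- random_net(4, 2, seed = 1)
  dec <- norm_dec(net)
  expect_error(local_centrality(dec, p = 1), "\\[0, 1\\)")
  expect_error(local_layer_centrality(dec, "nope", 0.85), "unknown layer")
  expect_error(query_set(character(0), "T1"), "nonempty")
  expect_error(local_set_centrality(dec, query_set("zz", "T1"), 0.85), "unknown node")
  expect_error(local_centrality(decompose_supra(net), 0.85), "row-normalized")
  l_wrong <- local_centrality(dec, 0.3)
  expect_error(global_centrality(dec, 0.85, l_wrong), "p mismatch")
})
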