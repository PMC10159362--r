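test_that("top-variance selection matches a brute-force variance sort", {
  set.seed(14)
  X <- matrix(rnorm(20 * 15), 20, 15,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:15)))
  X["g07", ] <- 5                         # constant gene
  got <- top_variance_genes(X, 8)
  v <- apply(X, 1, var)
  expect_setequal(got, names(sort(v, decreasing = TRUE))[1:8])
  expect_false("g07" %in% top_variance_genes(X, 19))
  expect_setequal(top_variance_genes(X, 20), rownames(X))
  expect_error(top_variance_genes(X, 0), "positive")
  expect_error(top_variance_genes(X, 21), "exceeds")
})

test_that("coexpression weights equal brute-force rank correlations", {
  set.seed(8)
  genes <- sprintf("g%d", 1:5)
  samples <- sprintf("s%02d", 1:10)
  X1 <- matrix(rnorm(50), 5, 10, dimnames = list(genes, samples))
  X2 <- matrix(rnorm(50), 5, 10, dimnames = list(genes, samples))
  net <- spearman_multilayer(list(A = X1, B = X2))
  # independent oracle: rank each profile, then Pearson on the ranks
  rho_rank <- function(u, v) {
    ru <- rank(u); rv <- rank(v)
    sum((ru - mean(ru)) * (rv - mean(rv))) /
      sqrt(sum((ru - mean(ru))^2) * sum((rv - mean(rv))^2))
  }
  for (g in genes) for (h in genes) {
    i <- supra_index(net, g, "A"); j <- supra_index(net, h, "A")
    expected <- if (g == h) 0 else abs(rho_rank(X1[g, ], X1[h, ]))
    expect_equal(net$M[i, j], expected, tolerance = 1e-12)
    jB <- supra_index(net, h, "B")
    expect_equal(net$M[i, jB], abs(rho_rank(X1[g, ], X2[h, ])), tolerance = 1e-12)
  }
  expect_true(all(net$M >= 0 & net$M <= 1))
  expect_equal(net$M, t(net$M))
})

test_that("monotone profiles give weight 1 and identical cross-layer profiles give 1", {
  samples <- sprintf("s%d", 1:8)
  X1 <- rbind(a = 1:8, b = (1:8)^3, c = rnorm(8))
  colnames(X1) <- samples
  X2 <- rbind(a = 1:8, b = rnorm(8), c = rnorm(8))
  colnames(X2) <- samples
  net <- spearman_multilayer(list(T1 = X1, T2 = X2))
  expect_equal(net$M[supra_index(net, "a", "T1"), supra_index(net, "b", "T1")], 1)
  expect_equal(net$M[supra_index(net, "a", "T1"), supra_index(net, "a", "T2")], 1)
})

test_that("rank-based weights are invariant to monotone transforms of expression", {
  set.seed(5)
  samples <- sprintf("s%d", 1:12)
  X <- matrix(rnorm(36), 3, 12, dimnames = list(c("a", "b", "c"), samples))
  net1 <- spearman_multilayer(list(T1 = X, T2 = X + 1))
  net2 <- spearman_multilayer(list(T1 = exp(X), T2 = (X + 1)^3))
  expect_equal(net1$M, net2$M, tolerance = 1e-12)
})

test_that("insufficient shared samples and constant profiles are handled as contracted", {
  genes <- c("a", "b", "c")
  X1 <- matrix(rnorm(18), 3, 6, dimnames = list(genes, sprintf("s%d", 1:6)))
  X2 <- matrix(rnorm(18), 3, 6, dimnames = list(genes, sprintf("s%d", 5:10)))
  expect_error(spearman_multilayer(list(T1 = X1, T2 = X2)), "share only 2")
  X3 <- X1; X3["b", ] <- 7   # constant profile -> undefined rho -> weight 0
  expect_message(net <- spearman_multilayer(list(T1 = X3, T2 = X1)),
                 "undefined correlation")
  expect_equal(net$M[supra_index(net, "b", "T1"), supra_index(net, "a", "T1")], 0)
})

test_that("genes absent from a tissue get zero rows in that layer", {
  samples <- sprintf("s%d", 1:6)
  X1 <- matrix(rnorm(18), 3, 6, dimnames = list(c("a", "b", "c"), samples))
  X2 <- matrix(rnorm(12), 2, 6, dimnames = list(c("a", "b"), samples))
  net <- spearman_multilayer(list(T1 = X1, T2 = X2))
  expect_equal(net$n, 3)
  c_t2 <- supra_index(net, "c", "T2")
  expect_true(all(net$M[c_t2, ] == 0))
})

test_that("PPI augmentation adds exactly the incidence matrix, once per layer", {
  set.seed(3)
  net <- spearman_multilayer(list(
    T1 = matrix(rnorm(24), 4, 6, dimnames = list(letters[1:4], sprintf("s%d", 1:6))),
    T2 = matrix(rnorm(24), 4, 6, dimnames = list(letters[1:4], sprintf("s%d", 1:6)))))
  ppi <- data.frame(a = c("a", "b"), b = c("c", "d"))
  aug <- augment_with_ppi(net, ppi)
  delta <- aug$M - net$M
  expected <- matrix(0, 8, 8)
  for (off in c(0, 4)) {
    expected[off + 1, off + 3] <- expected[off + 3, off + 1] <- 1  # a-c
    expected[off + 2, off + 4] <- expected[off + 4, off + 2] <- 1  # b-d
  }
  expect_equal(unname(delta), expected)
  # empty list leaves the network unchanged; unknown ids are skipped
  expect_identical(augment_with_ppi(net, ppi[0, ])$M, net$M)
  expect_message(aug2 <- augment_with_ppi(net, data.frame(a = "zz", b = "a")),
                 "skipped 1")
  expect_equal(aug2$M, net$M)
})

test_that("covariate adjustment removes linear effects and restores gene means", {
  set.seed(22)
  n_s <- 60
  age <- runif(n_s, 40, 90)
  sex <- factor(sample(c("F", "M"), n_s, replace = TRUE))
  cov <- data.frame(age = age, sex = sex)
  noise <- rnorm(n_s, sd = 1)
  X <- rbind(dep = 2 * age + noise + 10,       # gene driven by a covariate
             indep = rnorm(n_s),               # unrelated gene
             isage = age)                      # gene equal to a covariate
  colnames(X) <- sprintf("s%d", 1:n_s)
  adj <- adjust_covariates(X, cov)
  expect_equal(dim(adj), dim(X))
  expect_equal(rowMeans(adj), rowMeans(X), tolerance = 1e-9)
  # residual variance of the driven gene matches the noise variance (10%)
  expect_lt(abs(var(adj["dep", ]) / var(noise) - 1), 0.1)
  # gene equal to a covariate collapses to (almost) its mean
  expect_lt(var(adj["isage", ]), 1e-18)
  # profiles orthogonal to the design are unchanged beyond centering effects
  expect_gt(cor(adj["indep", ], X["indep", ]), 0.95)
  # rank-deficient design errors and names the collinear column
  cov_bad <- cbind(cov, age2 = 2 * age)
  expect_error(adjust_covariates(X, cov_bad), "collinear.*age2")
})

test_that("expression round-trips through TSV", {
  X <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3", "s4")))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(gene = rownames(X), X, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  X2 <- read_expression_matrix(path)
  expect_equal(X2, X, tolerance = 1e-12)
})
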