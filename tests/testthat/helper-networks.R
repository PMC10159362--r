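# fixtures built in code: random multilayer networks and tiny edge lists

# dense random symmetric weighted multilayer network
random_net <- function(n, L, density = 0.3, seed = 1) {
  set.seed(seed)
  N <- n * L
  W <- matrix(0, N, N)
  up <- upper.tri(W)
  w <- ifelse(stats::runif(sum(up)) < density, stats::runif(sum(up)), 0)
  W[up] <- w
  W <- W + t(W)
  multilayer_network(W, sprintf("g%02d", seq_len(n)),
                     paste0("T", seq_len(L)))
}

norm_dec <- function(net) row_normalize(decompose_supra(net))

# write an edge-list data.frame to a temp TSV
write_edge_tsv <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

edge_df <- function(...) {
  data.frame(..., stringsAsFactors = FALSE)
}
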