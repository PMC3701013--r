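# Shared fixtures and small independent oracles for the test suite.

# deterministic ultrametric balanced tree of depth `depth`
ultra_tree <- function(n = 8, depth = 10) {
  tr <- ape::compute.brlen(ape::stree(n, type = "balanced"), power = 1)
  d <- ape::node.depth.edgelength(tr)
  tr$edge.length <- tr$edge.length * depth / max(d)
  tr$tip.label <- paste0("sp", seq_len(n))
  tr
}

star_tree <- function(n = 8, depth = 1) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(depth, nrow(tr$edge))
  tr$tip.label <- paste0("sp", seq_len(n))
  tr
}

# brute-force Brownian covariance: shared root-to-MRCA path length for every
# tip pair, via ape's mrca() and independent accumulation of edge lengths
brute_covariance <- function(tree) {
  n <- length(tree$tip.label)
  depth <- numeric(n + tree$Nnode)
  # accumulate depths by walking edges in preorder
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    e <- ord$edge[k, ]
    depth[e[2]] <- depth[e[1]] + ord$edge.length[k]
  }
  M <- ape::mrca(tree)
  V <- matrix(depth[M], n, n, dimnames = list(tree$tip.label, tree$tip.label))
  diag(V) <- depth[seq_len(n)]
  V
}

# dense GLS oracle: (X' V^-1 X)^-1 X' V^-1 y via solve()
gls_oracle <- function(X, y, V) {
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
}

# dense multivariate normal log-density via solve() and determinant()
mvn_logpdf <- function(x, mu, S) {
  k <- length(x)
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  -0.5 * (k * log(2 * pi) + ld +
            drop(t(x - mu) %*% solve(S) %*% (x - mu)))
}

# Monte-Carlo standard error by batch means, taken at several batch sizes
# and combined conservatively (slowly mixing components inflate the
# long-batch estimate, which short batches miss)
mcse <- function(x, nbatches = c(10, 25, 50)) {
  one <- function(nb) {
    m <- floor(length(x) / nb)
    bm <- vapply(seq_len(nb), function(b)
      mean(x[((b - 1) * m + 1):(b * m)]), numeric(1))
    stats::sd(bm) / sqrt(nb)
  }
  max(vapply(nbatches, one, numeric(1)))
}

species_table <- function() calcelong::species_means()
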