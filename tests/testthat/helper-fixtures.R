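# Builders for small in-code fixtures shared across test files.

# Weighted undirected graph from a (u, v, w) edge table; extra isolated
# vertices can be appended.
make_network <- function(u, v, w, zcs = NULL, extra_vertices = character()) {
  d <- data.frame(from = u, to = v, weight = w,
                  zcs = if (is.null(zcs)) rep(NA_real_, length(u)) else zcs)
  verts <- sort(unique(c(u, v, extra_vertices)))
  igraph::graph_from_data_frame(d, directed = FALSE,
                                vertices = data.frame(name = verts))
}

# Two vertex-disjoint unit-weight triangles: abc and def.
two_triangles <- function() {
  make_network(c("a", "a", "b", "d", "d", "e"),
               c("b", "c", "c", "e", "f", "f"),
               rep(1, 6))
}

# Complete graph on n named vertices with constant edge weight.
make_clique <- function(n, weight = 1, prefix = "g") {
  pairs <- utils::combn(sprintf("%s%02d", prefix, seq_len(n)), 2L)
  make_network(pairs[1L, ], pairs[2L, ], rep(weight, ncol(pairs)))
}

# Planted-partition weighted graph: blocks of `sizes` genes, all
# within-block edges at w_in, all cross-block edges at w_out (omitted when
# w_out is 0).
planted_partition_graph <- function(sizes, w_in = 0.9, w_out = 0.05) {
  genes <- sprintf("g%03d", seq_len(sum(sizes)))
  block <- rep(seq_along(sizes), sizes)
  pairs <- utils::combn(seq_along(genes), 2L)
  same <- block[pairs[1L, ]] == block[pairs[2L, ]]
  w <- ifelse(same, w_in, w_out)
  keep <- w > 0
  net <- make_network(genes[pairs[1L, keep]], genes[pairs[2L, keep]], w[keep])
  attr(net, "truth") <- split(genes, block)
  net
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Best Jaccard match of each truth block among found clusters.
block_recovery <- function(truth_blocks, clusters) {
  vapply(truth_blocks, function(blk) {
    if (length(clusters) == 0L) return(0)
    max(vapply(clusters, jaccard, 0, a = blk))
  }, 0)
}

# Small expression matrix with named genes/samples.
toy_matrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}
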