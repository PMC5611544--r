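test_that("pairwise scores: Fisher z closed forms, clamping, and standardization", {
  set.seed(11)
  base <- matrix(rnorm(4 * 10), 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  m <- rbind(base, dup = base[1, , drop = FALSE])
  rownames(m)[5] <- "g1copy"
  sc <- pairwise_scores(m)
  dup_row <- sc[sc$gene_u == "g1" & sc$gene_v == "g1copy", ]
  expect_equal(dup_row$r, 1)
  expect_equal(dup_row$z_fisher, atanh(1 - 1e-15))  # clamped, finite
  expect_true(is.finite(dup_row$z_fisher))

  # arctanh identities
  expect_equal(atanh(0), 0)
  expect_equal(round(atanh(0.9), 4), 1.4722)

  # standardization contract over the pair population
  set.seed(5)
  big <- matrix(rnorm(50 * 45), 50, 45,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:45)))
  sc2 <- pairwise_scores(big)
  expect_equal(nrow(sc2), 50 * 49 / 2)
  expect_lt(abs(mean(sc2$z_cs)), 1e-6)
  expect_lt(abs(sd(sc2$z_cs) - 1), 1e-6)
})

test_that("pairwise scores reject zero-variance genes and too few samples", {
  m <- toy_matrix(c(1, 1, 1, 0, 2, 5), c("flat", "ok"), paste0("s", 1:3))
  expect_error(pairwise_scores(m), "zero-variance.*flat")
  m2 <- toy_matrix(c(1, 2, 3, 4), c("a", "b"), c("s1", "s2"))
  expect_error(pairwise_scores(m2), "3 samples")
})

test_that("blocked computation equals the direct full correlation matrix", {
  set.seed(13)
  m <- matrix(rnorm(37 * 12), 37, 12,
              dimnames = list(sprintf("g%02d", 1:37), sprintf("s%02d", 1:12)))
  blocked <- pairwise_scores(m, block_size = 5)
  whole <- pairwise_scores(m, block_size = 1000)
  cc <- cor(t(m))
  direct <- cc[upper.tri(cc)]
  # same multiset of correlations regardless of blocking
  expect_equal(sort(blocked$r), sort(direct))
  key <- function(s) paste(s$gene_u, s$gene_v)
  expect_equal(blocked$r[order(key(blocked))], whole$r[order(key(whole))])
})

test_that("thresholding keeps exactly the strict z_cs exceedances", {
  zcs <- c(3, 2.5, 2, 1.96, 1, 0, -1, -2, -2.5, -3)
  sc <- data.frame(gene_u = paste0("u", 1:10), gene_v = paste0("v", 1:10),
                   r = zcs / 10, z_fisher = zcs / 5, z_cs = zcs)
  attr(sc, "genes") <- c(paste0("u", 1:10), paste0("v", 1:10))
  class(sc) <- c("coexpression_scores", "data.frame")
  net <- threshold_network(sc, z_cutoff = 1.96)
  expect_equal(igraph::ecount(net), 3)          # 1.96 itself excluded
  expect_equal(igraph::vcount(net), 20)         # isolated genes retained
  expect_equal(igraph::graph_attr(net, "min_r"), 0.2)
  expect_equal(igraph::graph_attr(net, "edge_fraction"), 0.3)

  # cutoff below every score keeps the complete pair list
  all_net <- threshold_network(sc, z_cutoff = -Inf)
  expect_equal(igraph::ecount(all_net), 10)

  expect_warning(threshold_network(sc, z_cutoff = 10), "no edges")
})

test_that("edge sets are nested under increasing cutoffs and ranking matches r", {
  set.seed(3)
  m <- matrix(rnorm(30 * 20), 30, 20,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:20)))
  sc <- pairwise_scores(m)
  # affine standardization: z_cs ranking equals r ranking
  expect_identical(order(sc$z_cs), order(sc$r))
  expect_identical(order(sc$z_cs), order(sc$z_fisher))
  edge_key <- function(net) {
    ed <- igraph::as_data_frame(net)
    sort(paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to)))
  }
  cuts <- c(0.5, 1, 1.5, 2)
  nets <- lapply(cuts, function(z) suppressWarnings(threshold_network(sc, z)))
  for (i in seq_len(length(nets) - 1L)) {
    expect_true(all(edge_key(nets[[i + 1L]]) %in% edge_key(nets[[i]])))
  }
})

test_that("kept fraction at 1.96 is near 2.5% on independent genes", {
  set.seed(29)
  m <- matrix(rnorm(250 * 45), 250, 45,
              dimnames = list(sprintf("g%03d", 1:250), sprintf("s%02d", 1:45)))
  sc <- pairwise_scores(m)
  frac <- mean(sc$z_cs > 1.96)
  # 31125 pairs; binomial 3 sigma ~ 0.0027
  expect_lt(abs(frac - 0.025), 0.004)
})

test_that("first neighbors honors the strict weight cutoff and keeps the query", {
  hub <- make_network(rep("hub", 4), paste0("n", 1:4),
                      c(0.9, 0.85, 0.7, 0.5))
  nb <- first_neighbors(hub, "hub")              # default 0.80
  expect_setequal(igraph::V(nb)$name, c("hub", "n1", "n2"))
  star <- first_neighbors(hub, "hub", min_weight = 0)
  expect_setequal(igraph::V(nb0 <- star)$name, c("hub", paste0("n", 1:4)))
  # no neighbor above cutoff: only the query gene survives
  lonely <- first_neighbors(hub, "n4", min_weight = 0.95)
  expect_equal(igraph::V(lonely)$name, "n4")
  expect_error(first_neighbors(hub, "nope"), "unknown gene")
})

test_that("symmetric storage: each unordered pair appears exactly once", {
  set.seed(19)
  m <- matrix(rnorm(15 * 8), 15, 8,
              dimnames = list(sprintf("g%02d", 1:15), sprintf("s%d", 1:8)))
  sc <- pairwise_scores(m)
  expect_equal(nrow(sc), choose(15, 2))
  expect_true(all(sc$gene_u < sc$gene_v))
  expect_false(any(sc$gene_u == sc$gene_v))
  expect_true(all(sc$r >= -1 & sc$r <= 1))
})

test_that("pairwise-complete scoring drops pairs under the overlap floor", {
  set.seed(23)
  m <- matrix(rnorm(6 * 10), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  m[1, 1:6] <- NA  # g1 overlaps others in only 4 samples
  expect_warning(sc <- pairwise_scores(m, min_overlap = 10), "overlap")
  expect_false("g1" %in% c(sc$gene_u, sc$gene_v))
  sc2 <- pairwise_scores(m, min_overlap = 3)
  expect_equal(nrow(sc2), choose(6, 2))
})
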