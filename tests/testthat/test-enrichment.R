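test_that("hypergeometric tail matches closed cases", {
  expect_equal(hypergeom_overlap(10, 5, 4, 0), 1)    # P(X >= 0) = 1
  expect_equal(hypergeom_overlap(10, 5, 4, 4), 5 / 210)
  expect_equal(hypergeom_overlap(8, 8, 8, 8), 1)     # forced complete overlap
  expect_error(hypergeom_overlap(10, 5, 4, 5), "inconsistent")
  expect_error(hypergeom_overlap(10, 12, 4, 2), "inconsistent")
})

test_that("hypergeometric tail equals exhaustive subset enumeration (N <= 8)", {
  # oracle: enumerate every size-n_j subset of 1..N and count overlaps with
  # the fixed set 1..n_i of at least m
  enum_tail <- function(N, n_i, n_j, m) {
    if (n_j == 0) return(as.numeric(m == 0))
    subsets <- utils::combn(N, n_j)
    mean(colSums(subsets <= n_i) >= m)
  }
  for (N in c(4, 6, 8)) {
    for (n_i in 0:N) for (n_j in 0:N) {
      lo <- max(0, n_i + n_j - N)
      for (m in lo:min(n_i, n_j)) {
        expect_equal(hypergeom_overlap(N, n_i, n_j, m),
                     enum_tail(N, n_i, n_j, m),
                     tolerance = 1e-12,
                     info = sprintf("N=%d ni=%d nj=%d m=%d", N, n_i, n_j, m))
      }
    }
  }
})

test_that("hypergeometric tail agrees with phyper and is monotone in overlap", {
  cases <- expand.grid(N = c(50, 2000), n_i = c(10, 40), n_j = c(5, 25))
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      for (m in max(0, n_i + n_j - N):min(n_i, n_j)) {
        expect_equal(hypergeom_overlap(N, n_i, n_j, m),
                     phyper(m - 1, n_i, N - n_i, n_j, lower.tail = FALSE),
                     tolerance = 1e-12)
      }
      p_seq <- vapply(max(0, n_i + n_j - N):min(n_i, n_j),
                      function(m) hypergeom_overlap(N, n_i, n_j, m), 0)
      expect_true(all(diff(p_seq) <= 1e-15))  # larger overlap, smaller p
    })
  }
})

test_that("BH adjustment matches hand computation and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(numeric()), numeric())
  p <- c(0.04, 0.001, 0.9, 0.02)
  q <- bh_adjust(p)
  # hand step-up: q_i = min_{j: p_j >= p_i} p_j * n / rank_j
  hand <- sapply(seq_along(p), function(i) {
    r <- rank(p)
    min(1, min((p * length(p) / r)[p >= p[i]]))
  })
  expect_equal(q, hand)
  # order invariance up to the order-preservation contract
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_adjust(p[perm]), q[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("gene-set size filter applies inclusive bounds against the universe", {
  universe <- sprintf("g%04d", 1:2000)
  sets <- list(tiny = universe[1:9], small = universe[1:10],
               big = universe[1:1500], huge = universe[1:1501],
               offworld = c(universe[1:12], "alien1", "alien2"))
  gs <- geneset_collection(sets, universe = universe)
  kept <- filter_genesets(gs)
  expect_setequal(names(kept$sets), c("small", "big", "offworld"))
  # sizes measured against the universe: offworld counts 12, not 14
  sweep_preset <- filter_genesets(gs, min_size = 10, max_size = 499)
  expect_setequal(names(sweep_preset$sets), c("small", "offworld"))
  empty <- filter_genesets(geneset_collection(setNames(list(), character())))
  expect_length(empty$sets, 0)
})

test_that("GMT parsing keeps names, descriptions and members", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tfirst pathway\tg1\tg2\tg3",
               "setB\tsecond pathway\tg2\tg4"), f)
  gs <- read_gmt(f)
  expect_setequal(names(gs$sets), c("setA", "setB"))
  expect_equal(gs$sets$setA, c("g1", "g2", "g3"))
  expect_equal(unname(gs$descriptions["setB"]), "second pathway")
  if (requireNamespace("fgsea", quietly = TRUE)) {
    ref <- fgsea::gmtPathways(f)  # independent reader for the member lists
    expect_identical(gs$sets[names(ref)], lapply(ref, as.character))
  }
  writeLines("setC\tonly a description", f)
  expect_error(read_gmt(f), "malformed")
})

test_that("cluster annotation flags planted overlaps like a brute-force oracle", {
  universe <- sprintf("g%03d", 1:200)
  clusters <- list(c1 = universe[1:20], c2 = universe[21:50],
                   c3 = universe[51:60])
  sets <- list(sA = universe[1:18],                # strong overlap with c1
               sB = universe[c(21:35, 150:160)],   # partial overlap with c2
               sC = universe[100:140],             # no planted overlap
               sD = universe[c(51:60, 61:70)])     # strong overlap with c3
  gs <- geneset_collection(sets, universe = universe)
  res <- annotate_clusters(clusters, gs, universe = universe)
  expect_equal(nrow(res), 12)

  # independent oracle: phyper + p.adjust over the same family
  oracle <- expand.grid(cluster = names(clusters), set = names(sets),
                        stringsAsFactors = FALSE)
  oracle$m <- mapply(function(ci, si)
    length(intersect(clusters[[ci]], sets[[si]])), oracle$cluster, oracle$set)
  oracle$p <- mapply(function(ci, si, m)
    phyper(m - 1, length(sets[[si]]), 200 - length(sets[[si]]),
           length(clusters[[ci]]), lower.tail = FALSE),
    oracle$cluster, oracle$set, oracle$m)
  oracle$q <- p.adjust(oracle$p, "BH")
  key <- paste(res$cluster_id, res$set_id)
  okey <- paste(oracle$cluster, oracle$set)
  expect_equal(res$p, oracle$p[match(key, okey)], tolerance = 1e-12)
  expect_equal(res$q, oracle$q[match(key, okey)], tolerance = 1e-12)
  expect_equal(res$annotated, res$es > 1.3)
  expect_equal(res$es, -log10(res$q))

  # best term: lowest q within each cluster
  for (cid in names(clusters)) {
    sub <- res[res$cluster_id == cid, ]
    expect_equal(sub$set_id[sub$best_term], sub$set_id[which.min(sub$q)])
  }
})

test_that("a cluster identical to one set reports it as best term, zero overlap yields none", {
  universe <- sprintf("g%03d", 1:100)
  clusters <- list(cl = universe[1:10])
  gs <- geneset_collection(list(match = universe[1:10],
                                other = universe[50:80]),
                           universe = universe)
  res <- annotate_clusters(clusters, gs, universe = universe)
  expect_equal(res$set_id[res$best_term], "match")
  # zero overlap with every set: nothing annotated
  gs2 <- geneset_collection(list(far = universe[60:90]), universe = universe)
  res2 <- annotate_clusters(clusters, gs2, universe = universe)
  expect_false(any(res2$annotated))
  expect_error(
    annotate_clusters(list(cl = c("g001", "alien")), gs, universe = universe),
    "alien")
})

test_that("responsive-cluster scores are signed and zeroed below significance", {
  universe <- sprintf("g%05d", 1:20000)
  clusters <- list(hot = universe[1:20], cold = universe[101:130])
  up_list <- universe[c(1:20, 201:380)]  # all of 'hot' inside a 200-gene list
  res <- identify_responsive_clusters(
    clusters, list(seedling_up = up_list), universe = universe,
    q_cutoff = 0.01, directions = c(seedling_up = "up"))
  hot <- res[res$cluster_id == "hot", ]
  expect_lt(hot$q, 1e-10)
  expect_gt(hot$score, 0)
  expect_true("hot" %in% attr(res, "responsive"))
  # disjoint cluster: not significant, score exactly 0
  cold <- res[res$cluster_id == "cold", ]
  expect_equal(cold$score, 0)
  expect_false("cold" %in% attr(res, "responsive"))

  # same overlap labelled "down": same magnitude, negative sign
  res_dn <- identify_responsive_clusters(
    clusters, list(seedling_dn = up_list), universe = universe,
    q_cutoff = 0.01, directions = c(seedling_dn = "down"))
  expect_equal(res_dn$score[res_dn$cluster_id == "hot"], -hot$score)
  expect_equal(res_dn$q[res_dn$cluster_id == "hot"], hot$q)

  expect_error(identify_responsive_clusters(
    clusters, list(x = up_list), universe = universe,
    directions = c(x = "sideways")), "unknown direction")
})

test_that("motif presence uses a strict majority of cluster genes", {
  clusters <- list(c1 = paste0("g", 1:5), c2 = paste0("g", 6:9))
  hits <- data.frame(
    gene_id = c("g1", "g2", "g3",         # motifA in 3/5 of c1 (60%)
                "g1", "g2",               # motifB in 2/5 of c1 (40%)
                "g6", "g7",               # motifC in exactly half of c2
                "g6", "g7", "g8"),        # motifD in 3/4 of c2
    motif_id = c("motifA", "motifA", "motifA",
                 "motifB", "motifB",
                 "motifC", "motifC",
                 "motifD", "motifD", "motifD"))
  ann <- motif_presence_filter(clusters, hits)
  expect_equal(ann$c1, "motifA")
  expect_equal(ann$c2, "motifD")  # exactly 50% is dropped
  empty <- motif_presence_filter(clusters,
                                 data.frame(gene_id = character(),
                                            motif_id = character()))
  expect_equal(empty$c1, character())
})
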