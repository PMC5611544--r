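#' A named collection of gene sets over a background universe
#'
#' @param sets Named list of character vectors (members unique within a
#'   set; set names unique).
#' @param universe Optional character vector of background genes; when
#'   given, set sizes and overlaps are computed against it.  When absent,
#'   functions that need a universe require one explicitly.
#' @param descriptions Optional named character vector of set descriptions.
#' @return List of class \code{geneset_collection}.
#' @export
geneset_collection <- function(sets, universe = NULL, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene sets must have unique names")
  sets <- lapply(sets, unique)
  if (!is.null(universe)) universe <- unique(universe)
  structure(list(sets = sets, universe = universe,
                 descriptions = descriptions),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat("geneset_collection: ", length(x$sets), " set(s)",
      if (!is.null(x$universe)) paste0(", universe of ", length(x$universe),
                                       " gene(s)"), "\n", sep = "")
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Each tab-delimited line is: set name, description, then member genes.
#'
#' @param path Path to a GMT file.
#' @param universe Optional background gene vector for the collection.
#' @return A [geneset_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short))
    stop("malformed GMT line(s) (need name, description, >= 1 gene): line ",
         which(short)[1L])
  nm <- vapply(parts, `[`, "", 1L)
  desc <- stats::setNames(vapply(parts, `[`, "", 2L), nm)
  sets <- stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])), nm)
  geneset_collection(sets, universe = universe, descriptions = desc)
}

#' Upper cumulative hypergeometric overlap test
#'
#' The probability of observing an overlap of size m or greater between a
#' set of \code{n_i} genes and a set of \code{n_j} genes drawn from a
#' universe of N genes:
#' \deqn{P(X \ge m) = \sum_{x=m}^{\min(n_i, n_j)}
#'   \binom{n_i}{x} \binom{N - n_i}{n_j - x} / \binom{N}{n_j}}
#' computed with log-space binomial coefficients for numerical stability.
#'
#' @param N Universe size.
#' @param n_i,n_j Sizes of the two gene sets.
#' @param m Observed overlap.
#' @return p-value in [0, 1].
#' @export
hypergeom_overlap <- function(N, n_i, n_j, m) {
  if (any(c(N, n_i, n_j, m) < 0) || n_i > N || n_j > N ||
      m > min(n_i, n_j) || m < max(0, n_i + n_j - N))
    stop("inconsistent counts: need 0 <= m <= min(n_i, n_j) <= N and ",
         "m >= n_i + n_j - N")
  if (m == 0) return(1)
  x <- m:min(n_i, n_j)
  lp <- lchoose(n_i, x) + lchoose(N - n_i, n_j - x) - lchoose(N, n_j)
  min(1, sum(exp(lp)))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the
#' input.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Filter gene sets by size
#'
#' Keeps sets whose size lies in \code{[min_size, max_size]} (the default
#' bounds drop sets annotating fewer than 10 or more than 1500 genes;
#' pass \code{max_size = 499} to keep only sets annotating under 500
#' genes, the sweep-evaluation preset).  Sizes are computed against the
#' declared universe when the collection has one.
#'
#' @param collection A [geneset_collection()].
#' @param min_size,max_size Inclusive size bounds.
#' @return Filtered \code{geneset_collection}.
#' @export
filter_genesets <- function(collection, min_size = 10L, max_size = 1500L) {
  sets <- collection$sets
  eff <- if (is.null(collection$universe)) sets else
    lapply(sets, intersect, collection$universe)
  sizes <- lengths(eff)
  keep <- sizes >= min_size & sizes <= max_size
  geneset_collection(sets[keep], universe = collection$universe,
                     descriptions = collection$descriptions[names(sets)[keep]])
}

cluster_list <- function(clusters) {
  if (inherits(clusters, "cluster_set")) clusters$clusters else clusters
}

#' Annotate clusters by gene-set enrichment
#'
#' Tests every (cluster, set) pair with the cumulative hypergeometric test
#' and corrects across the full family with Benjamini-Hochberg.  The
#' enrichment score is ES = -log10(q); pairs with ES above
#' \code{es_cutoff} (default 1.3, i.e. q < 0.05) are flagged as
#' annotations, and each cluster's single best term (lowest q, ties by
#' set name) is marked.
#'
#' @param clusters A \code{cluster_set} or named list of gene vectors.
#' @param genesets A [geneset_collection()] (pre-filtered by size).
#' @param universe Background gene vector; defaults to the collection's
#'   universe, or, for a \code{cluster_set}, all its network genes
#'   (clustered plus unclustered).
#' @param es_cutoff Annotation threshold on ES.
#' @return Data frame with columns cluster_id, set_id, overlap, p, q, es,
#'   annotated, best_term.
#' @export
annotate_clusters <- function(clusters, genesets, universe = NULL,
                              es_cutoff = 1.3) {
  cl <- cluster_list(clusters)
  if (is.null(universe)) {
    universe <- if (inherits(clusters, "cluster_set"))
      c(unlist(cl, use.names = FALSE), clusters$unclustered)
    else genesets$universe
  }
  if (is.null(universe))
    stop("a background universe is required (none declared on the collection)")
  universe <- unique(universe)
  stray <- setdiff(unlist(cl, use.names = FALSE), universe)
  if (length(stray) > 0L)
    stop("cluster gene(s) absent from the universe: ",
         paste(utils::head(stray, 10L), collapse = ", "))
  N <- length(universe)
  sets <- lapply(genesets$sets, intersect, universe)
  if (length(cl) == 0L || length(sets) == 0L)
    return(data.frame(cluster_id = character(), set_id = character(),
                      overlap = integer(), p = numeric(), q = numeric(),
                      es = numeric(), annotated = logical(),
                      best_term = logical()))
  grid <- expand.grid(cluster_id = names(cl), set_id = names(sets),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- mapply(function(ci, si) {
    members <- cl[[ci]]
    m <- length(intersect(members, sets[[si]]))
    c(m, hypergeom_overlap(N, length(members), length(sets[[si]]), m))
  }, grid$cluster_id, grid$set_id)
  grid$overlap <- as.integer(res[1L, ])
  grid$p <- res[2L, ]
  grid$q <- bh_adjust(grid$p)
  grid$es <- -log10(grid$q)
  grid$annotated <- grid$es > es_cutoff
  grid <- grid[order(grid$cluster_id, grid$q, grid$set_id), , drop = FALSE]
  grid$best_term <- !duplicated(grid$cluster_id)
  rownames(grid) <- NULL
  grid
}

#' Identify clusters enriched in differential-expression gene lists
#'
#' Tests each (cluster, DE list) pair with the cumulative hypergeometric
#' test, corrects across all pairs with Benjamini-Hochberg, and reports a
#' signed score: +(-log10 q) for "up" lists, -(-log10 q) for "down"
#' lists, and 0 when the pair is not significant at \code{q_cutoff}.  A
#' cluster is responsive when it is significant for at least one list.
#'
#' @param clusters A \code{cluster_set} or named list of gene vectors.
#' @param de_lists Named list of gene vectors (subsets of the universe).
#' @param universe Background gene vector.
#' @param q_cutoff Significance cutoff on q (default 0.001).
#' @param directions Named character vector over \code{names(de_lists)}
#'   with values \code{"up"} or \code{"down"}.
#' @return Data frame with columns cluster_id, list_id, direction,
#'   overlap, p, q, score, significant; responsive cluster ids are in
#'   attribute \code{"responsive"}.
#' @export
identify_responsive_clusters <- function(clusters, de_lists, universe,
                                         q_cutoff = 0.001, directions) {
  cl <- cluster_list(clusters)
  if (is.null(names(de_lists))) stop("de_lists must be named")
  if (missing(directions) || !all(names(de_lists) %in% names(directions)))
    stop("directions must cover every DE list")
  bad <- setdiff(unique(directions[names(de_lists)]), c("up", "down"))
  if (length(bad) > 0L)
    stop("unknown direction label(s): ", paste(bad, collapse = ", "))
  universe <- unique(universe)
  outside <- setdiff(unlist(de_lists, use.names = FALSE), universe)
  if (length(outside) > 0L)
    stop("DE list gene(s) absent from the universe: ",
         paste(utils::head(outside, 10L), collapse = ", "))
  N <- length(universe)
  cl <- lapply(cl, intersect, universe)
  grid <- expand.grid(cluster_id = names(cl), list_id = names(de_lists),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- mapply(function(ci, li) {
    m <- length(intersect(cl[[ci]], de_lists[[li]]))
    c(m, hypergeom_overlap(N, length(cl[[ci]]), length(de_lists[[li]]), m))
  }, grid$cluster_id, grid$list_id)
  grid$direction <- unname(directions[grid$list_id])
  grid$overlap <- as.integer(res[1L, ])
  grid$p <- res[2L, ]
  grid$q <- bh_adjust(grid$p)
  grid$significant <- grid$q < q_cutoff
  sign <- ifelse(grid$direction == "up", 1, -1)
  grid$score <- ifelse(grid$significant, sign * -log10(grid$q), 0)
  attr(grid, "responsive") <-
    sort(unique(grid$cluster_id[grid$significant]))
  grid
}

#' Read a two-column motif hit table
#'
#' TSV with columns gene_id and motif_id, multiple rows per gene.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns gene_id, motif_id.
#' @export
read_motif_hits <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2) stop("motif hit file must have columns gene_id, motif_id")
  data.frame(gene_id = tab[[1L]], motif_id = tab[[2L]])
}

#' Annotate clusters with upstream motifs by presence fraction
#'
#' A motif annotates a cluster when it is present in strictly more than
#' \code{min_fraction} of the cluster's genes (default: more than half).
#'
#' @param clusters A \code{cluster_set} or named list of gene vectors.
#' @param hits Motif hit table from [read_motif_hits()] (columns gene_id,
#'   motif_id).
#' @param min_fraction Presence fraction a motif must exceed.
#' @return Named list mapping cluster id to a sorted character vector of
#'   motifs.
#' @export
motif_presence_filter <- function(clusters, hits, min_fraction = 0.5) {
  cl <- cluster_list(clusters)
  by_gene <- split(hits$motif_id, hits$gene_id)
  lapply(cl, function(members) {
    found <- unlist(lapply(unique(members), function(g) unique(by_gene[[g]])),
                    use.names = FALSE)
    if (length(found) == 0L) return(character())
    counts <- table(found)
    sort(names(counts)[counts / length(members) > min_fraction])
  })
}
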