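#' All-pairs coexpression scores
#'
#' For every unordered gene pair computes the Pearson correlation r across
#' samples, its Fisher z-transform \code{atanh(r)} (r clamped to
#' +/-(1 - 1e-15) so perfectly correlated pairs stay finite), and the
#' standardized coexpression score z_cs = (z - mean(z)) / sd(z), where the
#' mean and standard deviation are taken over the whole population of
#' unordered pairs.  z_cs is the number of standard deviations a pair lies
#' from the pair-population mean, so a cutoff of 1.96 keeps the top 2.5%
#' tail of an approximately normal score population.
#'
#' Correlations are computed block-by-block so memory stays bounded for
#' large gene counts.  With missing values present, correlations are
#' pairwise-complete and pairs whose sample overlap falls below
#' \code{min_overlap} are dropped with a warning (by default every sample
#' must be present).
#'
#' @param matrix Expression matrix with >= 2 genes and >= 3 samples; genes
#'   with zero variance are an error (remove them first).
#' @param block_size Number of genes per correlation block.
#' @param min_overlap Minimum number of mutually present samples for a pair
#'   to be scored; defaults to all samples.
#' @return A data frame of class \code{coexpression_scores} with one row
#'   per unordered pair (\code{gene_u < gene_v} in gene order) and columns
#'   \code{gene_u}, \code{gene_v}, \code{r}, \code{z_fisher}, \code{z_cs};
#'   the full gene vector is attached as attribute \code{"genes"}.
#' @export
pairwise_scores <- function(matrix, block_size = 1000L, min_overlap = ncol(matrix)) {
  genes <- rownames(matrix)
  n_genes <- length(genes)
  if (n_genes < 2L) stop("need at least 2 genes")
  if (ncol(matrix) < 3L) stop("need at least 3 samples to correlate")
  v <- apply(matrix, 1L, stats::var, na.rm = TRUE)
  if (any(!is.na(v) & v == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(genes[!is.na(v) & v == 0], 5L), collapse = ", "))
  has_na <- anyNA(matrix)
  x <- t(matrix)  # samples x genes, as cor() expects

  blocks <- split(seq_len(n_genes),
                  ceiling(seq_len(n_genes) / max(2L, block_size)))
  n_pairs <- n_genes * (n_genes - 1L) / 2
  iu <- integer(n_pairs); iv <- integer(n_pairs); rr <- numeric(n_pairs)
  pos <- 0L
  use <- if (has_na) "pairwise.complete.obs" else "everything"
  for (a in seq_along(blocks)) {
    for (b in a:length(blocks)) {
      bi <- blocks[[a]]; bj <- blocks[[b]]
      cc <- stats::cor(x[, bi, drop = FALSE], x[, bj, drop = FALSE], use = use)
      if (has_na && min_overlap > 0L) {
        ok <- crossprod(!is.na(x[, bi, drop = FALSE]) + 0,
                        !is.na(x[, bj, drop = FALSE]) + 0)
        cc[ok < min_overlap] <- NA_real_
      }
      idx <- which(if (a == b) upper.tri(cc) else matrix(TRUE, length(bi), length(bj)),
                   arr.ind = TRUE)
      k <- nrow(idx)
      if (k > 0L) {
        iu[pos + seq_len(k)] <- bi[idx[, 1L]]
        iv[pos + seq_len(k)] <- bj[idx[, 2L]]
        rr[pos + seq_len(k)] <- cc[idx]
        pos <- pos + k
      }
    }
  }
  length(iu) <- pos; length(iv) <- pos; length(rr) <- pos
  dropped <- is.na(rr)
  if (any(dropped)) {
    warning(sum(dropped), " pair(s) below the minimum sample overlap dropped")
    iu <- iu[!dropped]; iv <- iv[!dropped]; rr <- rr[!dropped]
  }
  eps <- 1e-15
  z <- atanh(pmin(pmax(rr, -(1 - eps)), 1 - eps))
  z_cs <- (z - mean(z)) / stats::sd(z)
  out <- data.frame(gene_u = genes[iu], gene_v = genes[iv],
                    r = rr, z_fisher = z, z_cs = z_cs,
                    stringsAsFactors = FALSE)
  attr(out, "genes") <- genes
  class(out) <- c("coexpression_scores", "data.frame")
  out
}

#' Threshold coexpression scores into a network
#'
#' Edges are exactly the pairs with \code{z_cs} strictly greater than
#' \code{z_cutoff}.  The resulting simple undirected igraph carries the
#' Pearson r as edge attribute \code{weight} (the quantity all downstream
#' density and segregation arithmetic uses) and \code{zcs} as metadata.
#' All scored genes are kept as vertices, including isolated ones.  Graph
#' attributes report the realized kept-edge fraction and the minimum r
#' among kept edges (the empirical r equivalent of the cutoff).
#'
#' @param scores A \code{coexpression_scores} data frame.
#' @param z_cutoff Standardized-score cutoff (default 1.96, the top 2.5%
#'   of a standard-normal score population).
#' @return An igraph network.
#' @export
threshold_network <- function(scores, z_cutoff = 1.96) {
  genes <- attr(scores, "genes")
  if (is.null(genes)) genes <- sort(unique(c(scores$gene_u, scores$gene_v)))
  keep <- scores$z_cs > z_cutoff
  edges <- data.frame(from = scores$gene_u[keep], to = scores$gene_v[keep],
                      weight = scores$r[keep], zcs = scores$z_cs[keep],
                      stringsAsFactors = FALSE)
  if (nrow(edges) == 0L)
    warning("no pair exceeds z_cs cutoff ", z_cutoff, "; network has no edges")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = genes))
  g <- igraph::set_graph_attr(g, "z_cutoff", z_cutoff)
  g <- igraph::set_graph_attr(g, "edge_fraction", mean(keep))
  g <- igraph::set_graph_attr(g, "min_r",
                              if (any(keep)) min(scores$r[keep]) else NA_real_)
  g
}

#' First-neighbor subnetwork of a query gene
#'
#' Returns the induced subgraph on the query gene plus every neighbor
#' connected to it by an edge of weight strictly above \code{min_weight}
#' (the default 0.80 is on the Pearson-r scale).  The query gene is kept
#' even when no neighbor passes.
#'
#' @param network igraph network from [threshold_network()].
#' @param gene Query gene identifier.
#' @param min_weight Minimum edge weight from the query gene.
#' @return igraph subgraph.
#' @export
first_neighbors <- function(network, gene, min_weight = 0.80) {
  if (!gene %in% igraph::V(network)$name)
    stop("unknown gene identifier: ", gene)
  inc <- igraph::incident(network, gene)
  w <- igraph::edge_attr(network, "weight", inc)
  strong <- inc[w > min_weight]
  nbrs <- setdiff(unique(c(igraph::ends(network, strong))), gene)
  igraph::induced_subgraph(network, c(gene, sort(nbrs)))
}

network_edge_table <- function(network) {
  ed <- igraph::as_data_frame(network, what = "edges")
  if (nrow(ed) == 0L)
    return(data.frame(gene_u = character(), gene_v = character(),
                      r = numeric(), z_cs = numeric()))
  swap <- ed$from > ed$to
  tmp <- ed$from[swap]; ed$from[swap] <- ed$to[swap]; ed$to[swap] <- tmp
  out <- data.frame(gene_u = ed$from, gene_v = ed$to, r = ed$weight,
                    z_cs = if ("zcs" %in% names(ed)) ed$zcs else NA_real_,
                    stringsAsFactors = FALSE)
  out[order(-out$z_cs, out$gene_u, out$gene_v), , drop = FALSE]
}

#' Export a network as a TSV edge list
#'
#' Columns gene_u, gene_v, r, z_cs, sorted by z_cs descending.  A node
#' table (one gene per line, isolated vertices included) is written
#' alongside when \code{nodes_path} is given.
#'
#' @param network igraph network.
#' @param path Edge-list output path.
#' @param nodes_path Optional node-list output path.
#' @export
write_edge_list <- function(network, path, nodes_path = NULL) {
  utils::write.table(network_edge_table(network), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(nodes_path))
    writeLines(c("gene_id", igraph::V(network)$name), nodes_path)
  invisible(path)
}

#' Read a network back from a TSV edge list
#'
#' @param path Edge-list TSV written by [write_edge_list()].
#' @param nodes_path Optional node list; when given, genes without edges
#'   are restored as isolated vertices.
#' @return igraph network with \code{weight} and \code{zcs} edge attributes.
#' @export
read_network_edges <- function(path, nodes_path = NULL) {
  ed <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene_u", "gene_v", "r") %in% names(ed)))
    stop("edge list must have columns gene_u, gene_v, r (and optionally z_cs)")
  verts <- if (!is.null(nodes_path)) {
    readLines(nodes_path)[-1L]
  } else sort(unique(c(ed$gene_u, ed$gene_v)))
  d <- data.frame(from = ed$gene_u, to = ed$gene_v, weight = ed$r,
                  zcs = if ("z_cs" %in% names(ed)) ed$z_cs else NA_real_)
  igraph::graph_from_data_frame(d, directed = FALSE,
                                vertices = data.frame(name = verts))
}

#' Export a network in SIF format
#'
#' One line per edge: \code{gene_u coexp gene_v}.
#'
#' @param network igraph network.
#' @param path Output path.
#' @export
write_sif <- function(network, path) {
  ed <- network_edge_table(network)
  writeLines(sprintf("%s\tcoexp\t%s", ed$gene_u, ed$gene_v), path)
  invisible(path)
}

#' Export a network in GraphML format
#'
#' @param network igraph network.
#' @param path Output path.
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
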