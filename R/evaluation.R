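#' Average segregation of a cluster
#'
#' The ratio of the mean weight of edges internal to the cluster to the
#' mean weight of all network edges incident on cluster members, each
#' distinct edge counted once (internal edges are themselves incident, so
#' an isolated clique scores exactly 1).  Values above 1 mean internal
#' edges outweigh the cluster's surroundings; a cluster with no internal
#' edge has no defined segregation and returns \code{NA}.
#'
#' @param network igraph network with a \code{weight} edge attribute.
#' @param cluster Character vector of member genes.
#' @return Non-negative real, or \code{NA} when undefined.
#' @export
average_segregation <- function(network, cluster) {
  eids <- igraph::E(network)
  ends <- igraph::ends(network, eids, names = TRUE)
  w <- eids$weight
  in_u <- ends[, 1L] %in% cluster
  in_v <- ends[, 2L] %in% cluster
  internal <- in_u & in_v
  incident <- in_u | in_v
  if (!any(internal)) return(NA_real_)
  mean(w[internal]) / mean(w[incident])
}

notch <- function(values) {
  # median +/- 1.58 * IQR / sqrt(n), the classic box-plot notch bounds
  n <- length(values)
  if (n == 0L) return(c(NA_real_, NA_real_))
  med <- stats::median(values)
  half <- 1.58 * stats::IQR(values, type = 7) / sqrt(n)
  c(med - half, med + half)
}

#' Evaluate a clustering sweep
#'
#' Scores each density threshold of a sweep by four criteria: the number
#' of clusters (of at least the minimum size), the fraction of network
#' genes falling in a cluster, the distribution of per-cluster average
#' segregation, and (when a gene-set collection is supplied) the
#' hypergeometric gene-set enrichment of the clusters at
#' \code{q < q_cutoff} -- how many clusters overlap at least one set, and
#' how many distinct sets are hit.  Pre-filter the collection (for
#' example to sets under 500 genes) with [filter_genesets()] before
#' calling.
#'
#' @param sweep Named list of \code{cluster_set} objects from
#'   [sweep_cluster()].
#' @param network The clustered igraph network.
#' @param genesets Optional [geneset_collection()].
#' @param q_cutoff BH q-value cutoff for counting enriched (cluster, set)
#'   pairs (default 0.1).
#' @return Data frame with one row per T_d: \code{T_d}, \code{n_clusters},
#'   \code{gene_fraction}, segregation quartiles and notch bounds, and the
#'   enrichment summary columns.  Per-cluster segregation and enrichment
#'   score vectors are attached as attributes \code{"segregation"} and
#'   \code{"es"}.
#' @export
evaluate_sweep <- function(sweep, network, genesets = NULL, q_cutoff = 0.1) {
  n_genes <- igraph::vcount(network)
  universe <- igraph::V(network)$name
  seg_list <- list(); es_list <- list()
  rows <- lapply(names(sweep), function(td) {
    cs <- sweep[[td]]
    sizes <- lengths(cs$clusters)
    seg <- vapply(cs$clusters, function(g) average_segregation(network, g),
                  0)
    seg <- seg[!is.na(seg)]
    seg_list[[td]] <<- seg
    nb <- notch(seg)
    enr <- c(n_enriched_clusters = NA_real_,
             n_distinct_enriched_sets = NA_real_, es_median = NA_real_)
    if (!is.null(genesets) && length(cs$clusters) > 0L) {
      res <- annotate_clusters(cs, genesets, universe = universe)
      sig <- res[res$q < q_cutoff, , drop = FALSE]
      es_list[[td]] <<- sig$es
      enr <- c(n_enriched_clusters = length(unique(sig$cluster_id)),
               n_distinct_enriched_sets = length(unique(sig$set_id)),
               es_median = if (nrow(sig) > 0L) stats::median(sig$es) else NA_real_)
    }
    data.frame(T_d = as.numeric(td),
               n_clusters = length(cs$clusters),
               gene_fraction = sum(sizes) / n_genes,
               seg_median = if (length(seg)) stats::median(seg) else NA_real_,
               seg_q1 = if (length(seg)) unname(stats::quantile(seg, 0.25, type = 7)) else NA_real_,
               seg_q3 = if (length(seg)) unname(stats::quantile(seg, 0.75, type = 7)) else NA_real_,
               seg_notch_lo = nb[1L], seg_notch_hi = nb[2L],
               n_enriched_clusters = enr[["n_enriched_clusters"]],
               n_distinct_enriched_sets = enr[["n_distinct_enriched_sets"]],
               es_median = enr[["es_median"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "segregation") <- seg_list
  attr(out, "es") <- es_list
  out
}

#' Write a sweep report as TSV
#'
#' @param report Data frame from [evaluate_sweep()].
#' @param path Output path.
#' @export
write_sweep_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
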