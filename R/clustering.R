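#' Parameters for density-based clustering
#'
#' @param T_d Density threshold in (0, 1]; every emitted cluster's internal
#'   weight density must be at least T_d.
#' @param T_s Support threshold in (0, 1]; a candidate gene joins a growing
#'   cluster only while its support (summed edge weight into the cluster)
#'   is at least \code{T_s * |S| * density(S)}.
#' @param min_cluster_size Minimum emitted cluster size (>= 2; default 3,
#'   i.e. clusters of three or more genes).
#' @return A list of class \code{clustering_params}.
#' @export
clustering_params <- function(T_d, T_s = 0.5, min_cluster_size = 3L) {
  if (!is.numeric(T_d) || length(T_d) != 1L || T_d <= 0 || T_d > 1)
    stop("T_d must be a single value in (0, 1]")
  if (T_s <= 0 || T_s > 1) stop("T_s must be in (0, 1]")
  if (min_cluster_size < 2L) stop("min_cluster_size must be >= 2")
  structure(list(T_d = T_d, T_s = T_s,
                 min_cluster_size = as.integer(min_cluster_size)),
            class = "clustering_params")
}

#' Weighted density of a gene set
#'
#' The sum of internal edge weights divided by the number of possible
#' internal pairs, \code{|S| * (|S| - 1) / 2}; lies in [0, 1] when weights
#' do.
#'
#' @param network igraph network with a \code{weight} edge attribute.
#' @param genes Character vector of >= 2 member genes.
#' @return Density in [0, 1].
#' @export
cluster_density <- function(network, genes) {
  k <- length(genes)
  if (k < 2L) stop("density is undefined for fewer than 2 genes")
  sub <- igraph::induced_subgraph(network, genes)
  w <- igraph::E(sub)$weight
  sum(w) / (k * (k - 1) / 2)
}

# Adjacency lists over lexicographically ranked vertices; index order IS the
# tie-break order used everywhere below.
build_adjacency <- function(network) {
  names_sorted <- sort(igraph::V(network)$name, method = "radix")
  idx <- stats::setNames(seq_along(names_sorted), names_sorted)
  ends <- igraph::ends(network, igraph::E(network), names = TRUE)
  w <- igraph::E(network)$weight
  if (length(w) > 0L && any(w < 0))
    stop("negative edge weights are not allowed in density clustering; ",
         "threshold the network at a positive score cutoff")
  if (length(w) > 0L && any(w > 1))
    stop("edge weights must lie in [0, 1]")
  a <- idx[ends[, 1L]]; b <- idx[ends[, 2L]]
  nbr <- vector("list", length(names_sorted))
  wts <- vector("list", length(names_sorted))
  ord <- order(c(a, b), c(b, a))
  from <- c(a, b)[ord]; to <- c(b, a)[ord]; ww <- c(w, w)[ord]
  split_to <- split(to, factor(from, levels = seq_along(names_sorted)))
  split_w <- split(ww, factor(from, levels = seq_along(names_sorted)))
  for (i in seq_along(names_sorted)) {
    nbr[[i]] <- as.integer(split_to[[i]])
    wts[[i]] <- as.numeric(split_w[[i]])
  }
  list(names = names_sorted, nbr = nbr, wts = wts)
}

#' Greedy density-based clustering (SPICi-style)
#'
#' Repeatedly seeds a cluster at the unclustered gene with the highest
#' weighted degree, pairs it with its best available neighbor (maximum
#' edge weight; ties broken by weighted degree, then lexicographic gene
#' order), and grows it by adding the unclustered gene with maximal
#' support into the cluster while (i) that support is at least
#' \code{T_s * |S| * density(S)} and (ii) the grown cluster's density
#' stays at least \code{T_d}.  Emitted clusters below
#' \code{min_cluster_size} genes are returned as unclustered instead.
#' All tie-breaks are lexicographic on gene identifier, so the result is
#' fully deterministic.
#'
#' Clusters are ordered by decreasing size, then by lexicographically
#' smallest member, and labelled \code{Cluster0001}, \code{Cluster0002},
#' ... in that order.
#'
#' @param network igraph network with edge weights in [0, 1] (negative
#'   weights are an error).
#' @param params A [clustering_params()] object.
#' @return A list of class \code{cluster_set}: \code{clusters} (named list
#'   of sorted gene vectors), \code{unclustered} (sorted gene vector),
#'   \code{T_d}, and \code{params}.
#' @export
spici_cluster <- function(network, params) {
  stopifnot(inherits(params, "clustering_params"))
  adj <- build_adjacency(network)
  n <- length(adj$names)
  active <- rep(TRUE, n)
  wdeg <- vapply(seq_len(n), function(i) sum(adj$wts[[i]]), 0)
  clusters <- list()
  unclustered <- integer()

  pick_max <- function(values, candidates) {
    # candidates with maximal value; smallest index wins ties
    m <- max(values)
    candidates[values >= m][1L]
  }

  while (any(active)) {
    act <- which(active)
    seed <- pick_max(wdeg[act], act)
    keep <- active[adj$nbr[[seed]]]
    nb <- adj$nbr[[seed]][keep]
    nw <- adj$wts[[seed]][keep]
    if (length(nb) == 0L) {
      unclustered <- c(unclustered, seed)
      active[seed] <- FALSE
      next
    }
    best_w <- max(nw)
    cand <- nb[nw >= best_w]
    mate <- if (length(cand) > 1L) pick_max(wdeg[cand], cand) else cand
    S <- c(seed, mate)
    W <- nw[match(mate, nb)]
    in_S <- rep(FALSE, n); in_S[S] <- TRUE
    # support of every active non-member adjacent to S
    sup <- numeric(n)
    touched <- rep(FALSE, n)
    for (s in S) {
      ns <- adj$nbr[[s]]; ws <- adj$wts[[s]]
      ok <- active[ns] & !in_S[ns]
      sup[ns[ok]] <- sup[ns[ok]] + ws[ok]
      touched[ns[ok]] <- TRUE
    }
    repeat {
      cands <- which(touched & !in_S & active)
      if (length(cands) == 0L) break
      u <- pick_max(sup[cands], cands)
      k <- length(S)
      dens <- W / (k * (k - 1) / 2)
      grown_dens <- (W + sup[u]) / ((k + 1) * k / 2)
      if (sup[u] >= params$T_s * k * dens && grown_dens >= params$T_d) {
        S <- c(S, u); in_S[u] <- TRUE; W <- W + sup[u]
        nu <- adj$nbr[[u]]; wu <- adj$wts[[u]]
        ok <- active[nu] & !in_S[nu]
        sup[nu[ok]] <- sup[nu[ok]] + wu[ok]
        touched[nu[ok]] <- TRUE
      } else break
    }
    kS <- length(S)
    if (kS >= params$min_cluster_size &&
        W / (kS * (kS - 1) / 2) >= params$T_d) {
      clusters[[length(clusters) + 1L]] <- sort(S)
    } else {
      unclustered <- c(unclustered, S)
    }
    active[S] <- FALSE
    for (s in S) {  # removing S lowers neighbors' weighted degree
      ns <- adj$nbr[[s]]; ws <- adj$wts[[s]]
      ok <- active[ns]
      wdeg[ns[ok]] <- wdeg[ns[ok]] - ws[ok]
    }
  }

  member_names <- lapply(clusters, function(ix) adj$names[ix])
  if (length(member_names) > 0L) {
    ord <- order(-lengths(member_names),
                 vapply(member_names, `[`, "", 1L), method = "radix")
    member_names <- member_names[ord]
    names(member_names) <- sprintf("Cluster%04d", seq_along(member_names))
  } else names(member_names) <- character()
  structure(list(clusters = member_names,
                 unclustered = sort(adj$names[unclustered], method = "radix"),
                 T_d = params$T_d, params = params),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set: ", length(x$clusters), " cluster(s) at T_d = ", x$T_d,
      "; ", sum(lengths(x$clusters)), " gene(s) clustered, ",
      length(x$unclustered), " unclustered\n", sep = "")
  invisible(x)
}

#' Cluster a network over a grid of density thresholds
#'
#' Runs [spici_cluster()] independently at each T_d value; results are
#' deterministic given identical inputs.
#'
#' @param network igraph network.
#' @param T_d_values Numeric vector of density thresholds (sorted
#'   ascending internally).
#' @param T_s,min_cluster_size Passed to [clustering_params()].
#' @return Named list mapping each T_d (formatted as given) to its
#'   \code{cluster_set}.
#' @export
sweep_cluster <- function(network, T_d_values, T_s = 0.5, min_cluster_size = 3L) {
  T_d_values <- sort(T_d_values)
  out <- lapply(T_d_values, function(td)
    spici_cluster(network, clustering_params(td, T_s, min_cluster_size)))
  names(out) <- format(T_d_values, trim = TRUE)
  out
}

#' Write cluster membership as TSV
#'
#' Columns cluster_id and gene_id; unclustered genes are listed under
#' cluster_id \code{"unclustered"}.
#'
#' @param clusters A \code{cluster_set}.
#' @param path Output path.
#' @export
write_clusters <- function(clusters, path) {
  tab <- data.frame(
    cluster_id = c(rep(names(clusters$clusters), lengths(clusters$clusters)),
                   rep("unclustered", length(clusters$unclustered))),
    gene_id = c(unlist(clusters$clusters, use.names = FALSE),
                clusters$unclustered))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cluster membership written by [write_clusters()]
#'
#' @param path TSV with columns cluster_id, gene_id.
#' @param T_d Density threshold to record on the result (optional).
#' @return A \code{cluster_set}.
#' @export
read_clusters <- function(path, T_d = NA_real_) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (!all(c("cluster_id", "gene_id") %in% names(tab)))
    stop("cluster file must have columns cluster_id and gene_id")
  uncl <- tab$gene_id[tab$cluster_id == "unclustered"]
  rest <- tab[tab$cluster_id != "unclustered", , drop = FALSE]
  cl <- lapply(split(rest$gene_id, rest$cluster_id), sort)
  cl <- cl[order(-lengths(cl), vapply(cl, `[`, "", 1L))]
  if (length(cl) == 0L) names(cl) <- character()
  structure(list(clusters = cl, unclustered = sort(uncl),
                 T_d = T_d, params = NULL),
            class = "cluster_set")
}
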