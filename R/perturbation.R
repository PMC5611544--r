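#' PAGE Z-scores for cluster perturbation
#'
#' Parametric gene-set enrichment: with mu and delta the mean and standard
#' deviation of all profiled fold changes, a cluster whose m profiled
#' genes have mean fold change S_m scores
#' \deqn{Z = (S_m - \mu) \sqrt{m} / \delta,}
#' approximately standard normal for random sets, so coordinated up- or
#' down-regulation of a module shows up as a large |Z|.  Two-sided normal
#' p-values are corrected across scored clusters with Benjamini-Hochberg.
#' Genes in a cluster but absent from the profile are ignored (m counts
#' profiled members only); clusters with fewer than \code{min_set_size}
#' profiled genes are skipped and listed in the \code{"skipped"}
#' attribute.
#'
#' @param profile Named numeric vector of log2 fold changes (see
#'   [read_fold_changes()]); should cover at least ~1000 genes for the
#'   population moments to be meaningful (a warning is raised below that).
#' @param clusters A \code{cluster_set} or named list of gene vectors.
#' @param min_set_size Minimum number of profiled genes per scored
#'   cluster (default 10).
#' @param annotations Optional annotation table from [annotate_clusters()]
#'   used to attach each cluster's best term.
#' @return Data frame with columns cluster_id, m, set_mean, z, p, q,
#'   direction (and best_term when annotations are given).
#' @export
page_zscores <- function(profile, clusters, min_set_size = 10L,
                         annotations = NULL) {
  if (is.null(names(profile))) stop("profile must be a named numeric vector")
  if (anyDuplicated(names(profile))) stop("duplicate genes in profile")
  if (length(profile) < 1000L)
    warning("profile covers ", length(profile),
            " genes; population moments may be unstable below ~1000")
  delta <- stats::sd(profile)
  if (!is.finite(delta) || delta == 0)
    stop("fold-change profile has zero spread; Z-scores are undefined")
  mu <- mean(profile)
  cl <- cluster_list(clusters)
  member_fc <- lapply(cl, function(g) profile[names(profile) %in% g])
  m <- lengths(member_fc)
  skip <- m < min_set_size
  scored <- names(cl)[!skip]
  set_mean <- vapply(member_fc[!skip], mean, 0)
  z <- (set_mean - mu) * sqrt(m[!skip]) / delta
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(cluster_id = scored, m = m[!skip],
                    set_mean = unname(set_mean), z = unname(z),
                    p = unname(p), q = bh_adjust(unname(p)),
                    direction = ifelse(z >= 0, "up", "down"),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    best <- annotations[annotations$best_term, c("cluster_id", "set_id")]
    out$best_term <- best$set_id[match(out$cluster_id, best$cluster_id)]
  }
  attr(out, "skipped") <- names(cl)[skip]
  out
}

#' Select significantly perturbed clusters
#'
#' Keeps results with q strictly below the cutoff, ranked by |Z|
#' descending (ties by cluster id).
#'
#' @param results Data frame from [page_zscores()].
#' @param q_cutoff q-value cutoff (default 0.01; use 0.001 for a stricter
#'   screen).
#' @return The selected rows, re-ranked.
#' @export
select_perturbed <- function(results, q_cutoff = 0.01) {
  sel <- results[results$q < q_cutoff, , drop = FALSE]
  sel <- sel[order(-abs(sel$z), sel$cluster_id), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

#' Write perturbation results as TSV
#'
#' @param results Data frame from [page_zscores()] or
#'   [select_perturbed()].
#' @param path Output path.
#' @export
write_perturbation <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
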