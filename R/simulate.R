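#' Design for a planted-module expression simulation
#'
#' Genes are laid out as coexpressed blocks followed by background genes.
#' Each block-b gene mixes a shared global factor, a block-specific latent
#' factor, and independent noise as
#' \code{sqrt(rho_out) * G + sqrt(rho_in - rho_out) * F_b +
#' sqrt(1 - rho_in) * eps}, so the expected Pearson correlation is
#' \code{rho_in} within a block and \code{rho_out} across blocks;
#' background genes share only the global factor.
#'
#' @param n_genes Total number of genes (block sizes must sum to at most
#'   this).
#' @param n_conditions Number of conditions/columns (default 45, a
#'   compendium-scale condition count).
#' @param block_sizes Integer vector of planted-module sizes.
#' @param rho_in Target within-block correlation (default 0.9).
#' @param rho_out Background/cross-block correlation (default 0).
#' @param seed Integer RNG seed; identical designs give identical
#'   matrices.
#' @return List of class \code{planted_design}.
#' @export
planted_design <- function(n_genes, n_conditions = 45L,
                           block_sizes = rep(30L, 5L),
                           rho_in = 0.9, rho_out = 0, seed = 1L) {
  if (sum(block_sizes) > n_genes)
    stop("block sizes sum to more than n_genes")
  if (!(rho_out >= 0 && rho_out < rho_in && rho_in <= 1))
    stop("need 0 <= rho_out < rho_in <= 1")
  if (n_conditions < 3L) stop("need at least 3 conditions")
  structure(list(n_genes = as.integer(n_genes),
                 n_conditions = as.integer(n_conditions),
                 block_sizes = as.integer(block_sizes),
                 rho_in = rho_in, rho_out = rho_out,
                 seed = as.integer(seed)),
            class = "planted_design")
}

#' Simulate an expression matrix with planted coexpressed modules
#'
#' @param design A [planted_design()].
#' @return List with \code{matrix} (genes x conditions expression matrix)
#'   and \code{truth} (named character vector of block labels,
#'   \code{"background"} for unplanted genes).
#' @export
simulate_expression <- function(design) {
  stopifnot(inherits(design, "planted_design"))
  set.seed(design$seed)
  n <- design$n_genes; p <- design$n_conditions
  genes <- sprintf("G%05d", seq_len(n))
  conditions <- sprintf("C%03d", seq_len(p))
  labels <- rep("background", n)
  global <- stats::rnorm(p)
  vals <- matrix(NA_real_, n, p, dimnames = list(genes, conditions))
  pos <- 0L
  for (b in seq_along(design$block_sizes)) {
    sz <- design$block_sizes[b]
    f <- stats::rnorm(p)
    rows <- pos + seq_len(sz)
    noise <- matrix(stats::rnorm(sz * p), sz, p)
    vals[rows, ] <- sqrt(design$rho_out) * rep(global, each = sz) +
      sqrt(design$rho_in - design$rho_out) * rep(f, each = sz) +
      sqrt(1 - design$rho_in) * noise
    labels[rows] <- sprintf("block%02d", b)
    pos <- pos + sz
  }
  n_bg <- n - pos
  if (n_bg > 0L) {
    rows <- pos + seq_len(n_bg)
    noise <- matrix(stats::rnorm(n_bg * p), n_bg, p)
    vals[rows, ] <- sqrt(design$rho_out) * rep(global, each = n_bg) +
      sqrt(1 - design$rho_out) * noise
  }
  list(matrix = expression_matrix(vals),
       truth = stats::setNames(labels, genes))
}

#' Simulate a fold-change profile with planted perturbed clusters
#'
#' Background log2 fold changes are i.i.d. standard normal over every
#' gene of the cluster set (clustered and unclustered); genes belonging
#' to the named perturbed clusters are shifted by \code{effect} (negative
#' for coordinated down-regulation).
#'
#' @param clusters A \code{cluster_set} or named list of gene vectors.
#' @param perturbed Character vector of cluster ids to perturb (must
#'   exist).
#' @param effect Per-gene log2 fold-change shift.
#' @param seed Integer RNG seed.
#' @return Named numeric vector of fold changes; the planted design is in
#'   attributes \code{"perturbed"} and \code{"effect"}.
#' @export
simulate_profile <- function(clusters, perturbed = character(), effect = 0,
                             seed = 1L) {
  cl <- cluster_list(clusters)
  missing <- setdiff(perturbed, names(cl))
  if (length(missing) > 0L)
    stop("unknown cluster id(s): ", paste(missing, collapse = ", "))
  genes <- unique(c(unlist(cl, use.names = FALSE),
                    if (inherits(clusters, "cluster_set")) clusters$unclustered))
  set.seed(seed)
  fc <- stats::setNames(stats::rnorm(length(genes)), genes)
  hit <- unique(unlist(cl[perturbed], use.names = FALSE))
  fc[hit] <- fc[hit] + effect
  attr(fc, "perturbed") <- perturbed
  attr(fc, "effect") <- effect
  fc
}
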