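#' Two-group differential expression
#'
#' Per-gene two-group linear-model (pooled-variance) t-test on log2-scale
#' expression, run on replicate samples (never on replicate-averaged
#' columns).  log2FC is mean(treatment) - mean(control); p-values are
#' two-sided and corrected across the tested genes with
#' Benjamini-Hochberg.  Genes with zero residual variance get a missing
#' p (and q).  No empirical-Bayes variance moderation is applied.
#'
#' @param matrix Expression matrix (IQR-filter it first with
#'   [iqr_filter()] if desired).
#' @param grouping Named character vector mapping sample id to group.
#' @param contrast Character vector of length 2: c(treatment, control)
#'   group labels, each with >= 2 replicate samples.
#' @return Data frame of class \code{de_profile} with columns gene_id,
#'   log2fc, t, p, q.
#' @export
de_test <- function(matrix, grouping, contrast) {
  check_grouping(matrix, grouping)
  if (length(contrast) != 2L) stop("contrast must be c(treatment, control)")
  trt <- names(grouping)[grouping == contrast[[1L]]]
  ctl <- names(grouping)[grouping == contrast[[2L]]]
  if (length(trt) < 2L || length(ctl) < 2L)
    stop("each contrast side needs at least 2 replicate samples")
  x1 <- matrix[, trt, drop = FALSE]
  x2 <- matrix[, ctl, drop = FALSE]
  n1 <- rowSums(!is.na(x1)); n2 <- rowSums(!is.na(x2))
  m1 <- rowMeans(x1, na.rm = TRUE); m2 <- rowMeans(x2, na.rm = TRUE)
  ss1 <- rowSums((x1 - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((x2 - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2L
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  lfc <- m1 - m2
  t <- lfc / se
  p <- 2 * stats::pt(-abs(t), df)
  p[!is.finite(t)] <- NA_real_  # zero residual variance
  t[se == 0 & lfc == 0] <- 0
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bh_adjust(p[!is.na(p)])
  out <- data.frame(gene_id = rownames(matrix), log2fc = lfc, t = t,
                    p = p, q = q, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("de_profile", "data.frame")
  out
}

#' Select significantly differentially expressed genes
#'
#' up = q strictly below the cutoff and log2FC > 0; down = q strictly
#' below the cutoff and log2FC < 0.
#'
#' @param profile A \code{de_profile} from [de_test()].
#' @param q_cutoff q-value cutoff (default 0.01).
#' @return List with character vectors \code{up} and \code{down}
#'   (disjoint).
#' @export
select_de <- function(profile, q_cutoff = 0.01) {
  sig <- !is.na(profile$q) & profile$q < q_cutoff
  list(up = profile$gene_id[sig & profile$log2fc > 0],
       down = profile$gene_id[sig & profile$log2fc < 0])
}

#' Write a DE profile as TSV
#'
#' Full profile: gene_id, log2fc, t, p, q.  With
#' \code{fold_change_only = TRUE} writes the two-column (gene_id, log2fc)
#' upload format consumed by the perturbation stage.
#'
#' @param profile A \code{de_profile}.
#' @param path Output path.
#' @param fold_change_only Write only gene_id and log2fc.
#' @export
write_de_profile <- function(profile, path, fold_change_only = FALSE) {
  tab <- if (fold_change_only) profile[, c("gene_id", "log2fc")] else profile
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column fold-change profile
#'
#' The upload format: a header row, gene identifiers in the first column
#' and log2 fold changes in the second.
#'
#' @param path Path to the TSV.
#' @return Named numeric vector of log2 fold changes.
#' @export
read_fold_changes <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2L)
    stop("fold-change profiles must have two columns: gene_id and log2 ",
         "fold change (with headers)")
  genes <- tab[[1L]]
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers in fold-change profile")
  fc <- suppressWarnings(as.numeric(tab[[2L]]))
  bad <- is.na(fc) & !(tab[[2L]] %in% c("NA", ""))
  if (any(bad))
    stop("non-numeric fold change for gene ", genes[which(bad)[1L]])
  keep <- !is.na(fc)
  stats::setNames(fc[keep], genes[keep])
}
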