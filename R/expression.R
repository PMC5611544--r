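#' Validate a gene-by-sample expression matrix
#'
#' An expression matrix is a plain numeric matrix of log2-scale values with
#' unique gene identifiers as row names and unique sample identifiers as
#' column names.  Missing values are represented as \code{NA}; all other
#' cells must be finite.
#'
#' @param values Numeric matrix with row names (genes) and column names
#'   (samples).
#' @return The validated matrix, invisibly unchanged.
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression values must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    stop("expression matrix must have gene row names and sample column names")
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (any(is.infinite(values)))
    stop("expression matrix contains non-finite values")
  values
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers.  Cells equal to \code{missing_token} are read as missing;
#' any other non-numeric cell is an error naming the offending gene and
#' sample.
#'
#' @param path Path to a TSV file.
#' @param missing_token String standing for a missing value (default
#'   \code{"NA"}).
#' @return A validated expression matrix.
#' @export
read_expression_matrix <- function(path, missing_token = "NA") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(tab) < 2) stop("expression file must have a gene column and at least one sample column")
  genes <- tab[[1L]]
  if (anyDuplicated(genes))
    stop("duplicate gene row(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  samples <- colnames(tab)[-1L]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  vals[vals == missing_token] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric cell at gene ", genes[bad[1L, 1L]],
         ", sample ", samples[bad[1L, 2L]], ": '", vals[bad[1L, , drop = FALSE]], "'")
  dimnames(num) <- list(genes, samples)
  expression_matrix(num)
}

#' Write an expression matrix as TSV
#'
#' Values are printed with \code{\%.17g} so that reading the file back
#' reproduces every double bit-identically.
#'
#' @param matrix Expression matrix.
#' @param path Output path.
#' @export
write_expression_matrix <- function(matrix, path) {
  out <- cbind(gene_id = rownames(matrix),
               array(sprintf("%.17g", matrix), dim = dim(matrix)))
  out[out == "NA"] <- "NA"
  colnames(out) <- c("gene_id", colnames(matrix))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-group mapping
#'
#' Two-column TSV (sample_id, group).  Returns a named character vector
#' mapping sample identifiers to group labels.
#'
#' @param path Path to a two-column TSV with a header row.
#' @export
read_sample_grouping <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2) stop("grouping file must have two columns (sample_id, group)")
  if (anyDuplicated(tab[[1L]]))
    stop("duplicate sample identifiers in grouping file")
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Read contrast pairs
#'
#' Two-column TSV (treatment_group, control_group), one contrast per row.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns \code{treatment} and \code{control}.
#' @export
read_contrasts <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2) stop("contrast file must have two columns (treatment_group, control_group)")
  data.frame(treatment = tab[[1L]], control = tab[[2L]])
}

check_grouping <- function(matrix, grouping) {
  if (is.null(names(grouping)))
    stop("grouping must be a named vector (names = sample ids)")
  missing <- setdiff(names(grouping), colnames(matrix))
  if (length(missing) > 0L)
    stop("grouping refers to samples absent from the matrix: ",
         paste(missing, collapse = ", "))
  invisible(grouping)
}

#' Average replicate samples into one column per group
#'
#' Each output column is the arithmetic mean of the group's replicate
#' columns, missing values excluded pairwise.  A (gene, group) cell whose
#' replicates are all missing is flagged missing.  Samples not named in the
#' grouping are dropped.  Output columns follow the order of first
#' appearance of each group.
#'
#' @param matrix Expression matrix.
#' @param grouping Named character vector mapping sample id to group label
#'   (see [read_sample_grouping()]).
#' @return Expression matrix with one column per group.
#' @export
average_replicates <- function(matrix, grouping) {
  check_grouping(matrix, grouping)
  groups <- unique(unname(grouping))
  out <- vapply(groups, function(g) {
    cols <- names(grouping)[grouping == g]
    m <- rowMeans(matrix[, cols, drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    m
  }, numeric(nrow(matrix)))
  dim(out) <- c(nrow(matrix), length(groups))  # vapply drops 1-gene matrices
  dimnames(out) <- list(rownames(matrix), groups)
  expression_matrix(out)
}

#' Remove lowly varying genes by interquartile range
#'
#' A gene is removed when its IQR across samples falls strictly below the
#' comparison value.  With \code{compare = "median_iqr"} (default) the
#' comparison value is the median of all genes' IQRs, the standard
#' variance-filter convention; with \code{compare = "median_expression"}
#' each gene's IQR is compared to that gene's own median expression.
#' Quartiles use linear interpolation between order statistics
#' (\code{type = 7}), fixed for reproducibility.  Genes missing in more
#' than \code{max_missing} of samples are removed with a warning.
#'
#' @param matrix Expression matrix with at least 2 (ideally >= 4) samples.
#' @param compare Either \code{"median_iqr"} or \code{"median_expression"}.
#' @param max_missing Maximum tolerated fraction of missing values per gene.
#' @return List with elements \code{matrix} (retained genes) and
#'   \code{removed} (character vector); retained and removed genes
#'   partition the input exactly.
#' @export
iqr_filter <- function(matrix, compare = c("median_iqr", "median_expression"),
                       max_missing = 0.5) {
  compare <- match.arg(compare)
  if (ncol(matrix) < 2L) stop("IQR filter needs at least 2 samples")
  miss_frac <- rowMeans(is.na(matrix))
  too_missing <- miss_frac > max_missing
  if (any(too_missing))
    warning(sum(too_missing), " gene(s) missing in more than ",
            round(100 * max_missing), "% of samples removed")
  considered <- matrix[!too_missing, , drop = FALSE]
  iqrs <- apply(considered, 1L, stats::IQR, na.rm = TRUE, type = 7)
  low <- if (compare == "median_iqr") {
    iqrs < stats::median(iqrs)
  } else {
    meds <- apply(considered, 1L, stats::median, na.rm = TRUE)
    iqrs < meds
  }
  removed <- c(rownames(matrix)[too_missing], rownames(considered)[low])
  kept <- considered[!low, , drop = FALSE]
  list(matrix = kept, removed = removed)
}
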