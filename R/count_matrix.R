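#' Construct a validated count matrix
#'
#' A `count_matrix` holds the observed data of the model: a genes x cells
#' matrix Y of nonnegative integer read counts with unique gene and cell
#' identifiers. All downstream steps (dispersion estimation, factorization,
#' diagnostics) operate on this container.
#'
#' @param counts numeric matrix, genes in rows and cells in columns; every
#'   entry must be a nonnegative integer value (stored as double is fine, the
#'   values must be whole numbers). Fractional or negative entries are
#'   rejected, never rounded: the model is count-native by design.
#' @param gene_ids optional character vector of unique gene identifiers;
#'   defaults to existing rownames or `gene_1..gene_p`.
#' @param cell_ids optional character vector of unique cell identifiers;
#'   defaults to existing colnames or `cell_1..cell_n`.
#' @return a `count_matrix`: the matrix with dimnames set and class attached.
#' @export
count_matrix <- function(counts, gene_ids = NULL, cell_ids = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix", call. = FALSE)
  p <- nrow(counts); n <- ncol(counts)
  if (p < 1L || n < 1L)
    stop("`counts` must have at least one gene and one cell", call. = FALSE)
  bad <- which(!is.finite(counts) | counts < 0 | counts != floor(counts))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(counts))
    stop(sprintf(
      "counts must be nonnegative integers; first offending entry %s at gene %d, cell %d",
      format(counts[bad[1L]]), ij[1L], ij[2L]), call. = FALSE)
  }
  if (is.null(gene_ids)) gene_ids <- rownames(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(p))
  if (is.null(cell_ids)) cell_ids <- colnames(counts)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  gene_ids <- as.character(gene_ids); cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != p || anyDuplicated(gene_ids))
    stop("`gene_ids` must be ", p, " unique strings", call. = FALSE)
  if (length(cell_ids) != n || anyDuplicated(cell_ids))
    stop("`cell_ids` must be ", n, " unique strings", call. = FALSE)
  dimnames(counts) <- list(gene_ids, cell_ids)
  storage.mode(counts) <- "double"
  structure(counts, class = c("count_matrix", "matrix", "array"))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells, %.1f%% zeros\n",
              nrow(x), ncol(x), 100 * mean(x == 0)))
  invisible(x)
}

as_count_matrix <- function(x) {
  if (inherits(x, "count_matrix")) x else count_matrix(as.matrix(x))
}

#' Per-cell sequencing depths (size factors)
#'
#' The total read count N_j of each cell enters the rate model as a fixed
#' offset log(N_j). Cells with zero total count have no defined depth and
#' must be removed before modelling (see [read_counts()]).
#'
#' @param counts a [count_matrix()] (or coercible matrix).
#' @return named numeric vector of positive column sums.
#' @export
size_factors <- function(counts) {
  counts <- as_count_matrix(counts)
  d <- colSums(counts)
  if (any(d <= 0))
    stop("cells with zero total count have undefined depth; drop them first (see read_counts)",
         call. = FALSE)
  d
}

#' Observed per-gene zero fraction
#'
#' For each gene, the number of cells in which it is unexpressed (count 0)
#' divided by the number of cells. This is the empirical dropout-rate curve
#' that the NB-expected zero fraction is compared against.
#'
#' @inheritParams size_factors
#' @return named numeric vector in \[0, 1\], one value per gene.
#' @seealso [expected_zero_fraction()], [dropout_diagnostic()]
#' @export
observed_zero_fraction <- function(counts) {
  counts <- as_count_matrix(counts)
  rowMeans(counts == 0)
}

#' Remove lowly expressed genes
#'
#' Drops genes expressed (count > 0) in fewer than `min_cells` cells. This is
#' the default pre-filter applied by the command-line interface before
#' dispersion estimation and fitting.
#'
#' @inheritParams size_factors
#' @param min_cells minimum number of cells with a nonzero count for a gene
#'   to be retained (default 2).
#' @return a filtered `count_matrix`.
#' @export
filter_low_genes <- function(counts, min_cells = 2L) {
  counts <- as_count_matrix(counts)
  keep <- rowSums(counts > 0) >= min_cells
  if (!any(keep)) stop("no genes pass the expression filter", call. = FALSE)
  count_matrix(unclass(counts)[keep, , drop = FALSE])
}
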