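#' Read a count matrix from MatrixMarket, CSV or TSV
#'
#' MatrixMarket (`.mtx`) coordinate files need gene and cell identifier
#' sidecars (one ID per line), by default `genes.txt` and `barcodes.txt`
#' next to the matrix file. Dense CSV/TSV files carry identifiers as row
#' names (first column) and header. Orientation is genes x cells unless
#' `cells_as_rows` is set. Entries must be nonnegative integers; fractional
#' or negative values are rejected with the offending coordinate named.
#' Cells with zero total count (no defined depth offset) are dropped with a
#' warning.
#'
#' @param path input file.
#' @param format `"mtx"`, `"csv"` or `"tsv"`; inferred from the extension
#'   when `NULL`.
#' @param genes_path,barcodes_path sidecar ID files for mtx input.
#' @param cells_as_rows transpose on read (default `FALSE`).
#' @param drop_zero_cells drop all-zero cell columns with a warning
#'   (default `TRUE`).
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, format = NULL, genes_path = NULL,
                        barcodes_path = NULL, cells_as_rows = FALSE,
                        drop_zero_cells = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- infer_format(path, format)
  if (format == "mtx") {
    m <- Matrix::readMM(path)
    m <- methods::as(m, "TsparseMatrix")
    bad <- which(m@x < 0 | m@x != floor(m@x))
    if (length(bad))
      stop(sprintf(
        "counts must be nonnegative integers; first offending entry %s at row %d, column %d",
        format(m@x[bad[1L]]), m@i[bad[1L]] + 1L, m@j[bad[1L]] + 1L),
        call. = FALSE)
    x <- as.matrix(m)
    if (is.null(genes_path))
      genes_path <- file.path(dirname(path), "genes.txt")
    if (is.null(barcodes_path))
      barcodes_path <- file.path(dirname(path), "barcodes.txt")
    if (!file.exists(genes_path) || !file.exists(barcodes_path))
      stop("mtx input needs ID sidecars: ", genes_path, ", ", barcodes_path,
           call. = FALSE)
    gid <- readLines(genes_path)
    cid <- readLines(barcodes_path)
    if (cells_as_rows) { x <- t(x); tmp <- gid; gid <- cid; cid <- tmp }
    if (length(gid) != nrow(x) || length(cid) != ncol(x))
      stop(sprintf(
        "sidecar lengths (%d genes, %d cells) do not match matrix %d x %d",
        length(gid), length(cid), nrow(x), ncol(x)), call. = FALSE)
    rownames(x) <- gid; colnames(x) <- cid
  } else {
    df <- utils::read.table(path, header = TRUE, sep = if (format == "csv")
      "," else "\t", row.names = 1L, check.names = FALSE)
    x <- as.matrix(df)
    if (cells_as_rows) x <- t(x)
  }
  out <- count_matrix(x)
  if (drop_zero_cells) {
    zero <- colSums(out) == 0
    if (any(zero)) {
      warning(sum(zero), " cell(s) with zero total count dropped")
      out <- count_matrix(unclass(out)[, !zero, drop = FALSE])
    }
  }
  out
}

#' Write a count matrix
#'
#' Inverse of [read_counts()]: `mtx` writes a MatrixMarket coordinate
#' integer file plus `genes.txt`/`barcodes.txt` sidecars next to it;
#' `csv`/`tsv` write a dense table with gene row names and a cell-ID header.
#'
#' @param counts a [count_matrix()].
#' @param path output file.
#' @inheritParams read_counts
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = NULL, genes_path = NULL,
                         barcodes_path = NULL) {
  counts <- as_count_matrix(counts)
  format <- infer_format(path, format)
  if (format == "mtx") {
    sp <- Matrix::Matrix(unclass(counts), sparse = TRUE)
    Matrix::writeMM(sp, path)
    if (is.null(genes_path))
      genes_path <- file.path(dirname(path), "genes.txt")
    if (is.null(barcodes_path))
      barcodes_path <- file.path(dirname(path), "barcodes.txt")
    writeLines(rownames(counts), genes_path)
    writeLines(colnames(counts), barcodes_path)
  } else {
    utils::write.table(unclass(counts), path, sep = if (format == "csv")
      "," else "\t", quote = FALSE, col.names = NA)
  }
  invisible(path)
}

infer_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("mtx", "csv", "tsv")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mtx", "csv", "tsv")) return(ext)
  if (ext %in% c("txt", "tab")) return("tsv")
  stop("cannot infer format from extension of ", path,
       "; pass `format` explicitly", call. = FALSE)
}

#' Write a fitted embedding (and optionally loadings) as TSV
#'
#' Cells as rows, factors as columns (`factor_1 .. factor_K`), first column
#' the cell IDs. Values are written with 17 significant digits so doubles
#' round-trip exactly and identical fits produce byte-identical files.
#'
#' @param model a [factor_model()].
#' @param path output TSV for the embedding (cells x factors).
#' @param cell_ids,gene_ids identifiers; defaults `cell_1..`/`gene_1..`.
#' @param loadings_path optional second TSV for the loadings (genes x K).
#' @param order apply [order_factors()] before writing (default `FALSE`).
#' @param top keep only the leading `top` factors after ordering.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(model, path, cell_ids = NULL, gene_ids = NULL,
                            loadings_path = NULL, order = FALSE, top = NULL) {
  stopifnot(inherits(model, "factor_model"))
  if (order) model <- order_factors(model)
  if (!is.null(top)) {
    top <- as.integer(top)
    if (top < 1L || top > model$K)
      stop("`top` must be in 1..K", call. = FALSE)
    model <- factor_model(model$W[, seq_len(top), drop = FALSE],
                          model$H[seq_len(top), , drop = FALSE])
  }
  n <- ncol(model$H); p <- nrow(model$W); K <- model$K
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  header <- paste(c("cell_id", paste0("factor_", seq_len(K))), collapse = "\t")
  body <- vapply(seq_len(n), function(j)
    paste(c(cell_ids[j], sprintf("%.17g", model$H[, j])), collapse = "\t"),
    character(1))
  writeLines(c(header, body), path)
  if (!is.null(loadings_path)) {
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(p))
    lheader <- paste(c("gene_id", paste0("factor_", seq_len(K))),
                     collapse = "\t")
    lbody <- vapply(seq_len(p), function(i)
      paste(c(gene_ids[i], sprintf("%.17g", model$W[i, ])), collapse = "\t"),
      character(1))
    writeLines(c(lheader, lbody), loadings_path)
  }
  invisible(path)
}

#' Read an embedding TSV back into a factor matrix
#'
#' @param path TSV written by [write_embedding()].
#' @return K x cells numeric matrix with cell IDs as column names.
#' @export
read_embedding <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  h <- t(as.matrix(df[, -1L, drop = FALSE]))
  colnames(h) <- as.character(df[[1L]])
  rownames(h) <- NULL
  h
}

# Serialize a run manifest (configuration echo, inputs with checksums,
# versions, seed, timings) next to the outputs of a CLI run.
write_manifest <- function(dir, command, params, inputs = character(),
                           seed = NA, elapsed = NA) {
  manifest <- list(
    tool = "scNBMF",
    version = as.character(utils::packageVersion("scNBMF")),
    r_version = as.character(getRversion()),
    command = command,
    params = params,
    inputs = if (length(inputs))
      lapply(stats::setNames(as.list(inputs), basename(inputs)), function(f)
        list(path = f, md5 = unname(tools::md5sum(f)))) else list(),
    seed = seed,
    elapsed_seconds = elapsed
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(file.path(dir, "manifest.json"))
}
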