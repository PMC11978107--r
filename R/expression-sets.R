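#' Single-cell reference expression container
#'
#' Bundles a non-negative integer gene-by-cell count matrix (dense or sparse)
#' with per-cell annotations and, once computed by [log_normalize()], a
#' matching matrix of log-normalized expression. This is the reference object
#' every marker-selection and deconvolution step consumes.
#'
#' @param counts Gene-by-cell matrix of non-negative integer counts; rownames
#'   are gene ids, colnames are cell barcodes. A `Matrix` sparse matrix is
#'   kept sparse.
#' @param cell_meta Data frame with one row per cell, containing at least
#'   `cell_type`; `donor` and `sample` are filled with `"unknown"` when
#'   absent. Row order must match the columns of `counts`, or a `barcode`
#'   column must identify them.
#' @param logexpr Optional log-expression matrix of identical shape.
#'
#' @return An object of class `cell_expr_set`: a list with elements `counts`,
#'   `logexpr` (possibly `NULL`), and `cell_meta` (a tibble).
#' @export
#' @examples
#' counts <- matrix(rpois(12, 2), 3, 4,
#'                  dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' meta <- data.frame(cell_type = c("A", "A", "B", "B"), donor = "d1")
#' ref <- cell_expression_set(counts, meta)
#' ref
cell_expression_set <- function(counts, cell_meta, logexpr = NULL) {
  if (is.null(rownames(counts))) {
    stop("`counts` must have gene ids as rownames", call. = FALSE)
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene ids in `counts` rownames", call. = FALSE)
  }
  if (min_value(counts) < 0) {
    stop("`counts` must be non-negative", call. = FALSE)
  }
  cell_meta <- as_tibble(cell_meta)
  if (!"barcode" %in% names(cell_meta)) {
    if (nrow(cell_meta) != ncol(counts)) {
      stop("`cell_meta` rows (", nrow(cell_meta), ") do not match cells (",
           ncol(counts), ") and no `barcode` column is present", call. = FALSE)
    }
    cell_meta$barcode <- colnames(counts)
  }
  missing_meta <- setdiff(colnames(counts), cell_meta$barcode)
  if (length(missing_meta) > 0) {
    message(length(missing_meta),
            " cell(s) lack metadata and were dropped from the reference")
    counts <- counts[, colnames(counts) %in% cell_meta$barcode, drop = FALSE]
    if (!is.null(logexpr)) {
      logexpr <- logexpr[, colnames(counts), drop = FALSE]
    }
  }
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$barcode), ]
  if (!"cell_type" %in% names(cell_meta)) {
    stop("`cell_meta` must contain a `cell_type` column", call. = FALSE)
  }
  if (anyNA(cell_meta$cell_type)) {
    stop("every cell must have a non-missing `cell_type`", call. = FALSE)
  }
  cell_meta$cell_type <- as.character(cell_meta$cell_type)
  for (col in c("donor", "sample")) {
    if (!col %in% names(cell_meta)) cell_meta[[col]] <- "unknown"
  }
  if (!is.null(logexpr) && !identical(dim(logexpr), dim(counts))) {
    stop("`logexpr` must have the same shape as `counts`", call. = FALSE)
  }
  structure(
    list(counts = counts, logexpr = logexpr, cell_meta = cell_meta),
    class = "cell_expr_set"
  )
}

# minimum that works for both base and Matrix classes without densifying
min_value <- function(m) {
  if (inherits(m, "sparseMatrix")) {
    x <- m@x
    if (length(x) < length(m)) min(0, x) else min(x)
  } else {
    min(m)
  }
}

#' @exportS3Method base::print
print.cell_expr_set <- function(x, ...) {
  cat("<cell_expr_set> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells\n", sep = "")
  tab <- sort(table(x$cell_meta$cell_type), decreasing = TRUE)
  cat("  cell types: ",
      paste0(names(tab), " (", tab, ")", collapse = ", "), "\n", sep = "")
  cat("  donors: ", length(unique(x$cell_meta$donor)),
      "; log-normalized: ", !is.null(x$logexpr), "\n", sep = "")
  invisible(x)
}

#' @export
dim.cell_expr_set <- function(x) dim(x$counts)

#' Bulk expression container
#'
#' A gene-by-sample count table together with sample annotations describing
#' the library preparation (`polyA` or `RiboZeroGold`), the RNA extraction
#' (`Cyto`, `Total`, `Nuc`), the tissue block and the donor. Values outside
#' the declared vocabularies are carried as `"other"` with a warning rather
#' than rejected, so foreign datasets still load.
#'
#' @param counts Gene-by-sample numeric matrix, non-negative.
#' @param sample_meta Data frame keyed by `sample_id` (or with rows in column
#'   order) with optional `library_type`, `rna_extraction`, `tissue_block`,
#'   `donor` columns.
#' @return An object of class `bulk_expr_set`: list with `counts` (matrix)
#'   and `sample_meta` (tibble).
#' @export
bulk_expression_set <- function(counts, sample_meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    stop("`counts` must have gene ids as rownames", call. = FALSE)
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample ids", call. = FALSE)
  }
  neg <- which(counts < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stop("negative count for gene '", rownames(counts)[neg[1, 1]],
         "' in sample '", colnames(counts)[neg[1, 2]], "'", call. = FALSE)
  }
  if (is.null(sample_meta)) {
    sample_meta <- tibble(sample_id = colnames(counts))
  }
  sample_meta <- as_tibble(sample_meta)
  if (!"sample_id" %in% names(sample_meta)) {
    if (nrow(sample_meta) != ncol(counts)) {
      stop("`sample_meta` has no `sample_id` and row count differs from samples",
           call. = FALSE)
    }
    sample_meta$sample_id <- colnames(counts)
  }
  absent <- setdiff(colnames(counts), sample_meta$sample_id)
  if (length(absent) > 0) {
    stop("sample(s) missing from metadata: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(sample_meta$sample_id, colnames(counts))
  if (length(extra) > 0) {
    warning(length(extra), " metadata sample(s) not in counts were ignored",
            call. = FALSE)
    sample_meta <- sample_meta[sample_meta$sample_id %in% colnames(counts), ]
  }
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample_id), ]
  sample_meta$library_type <-
    check_vocab(sample_meta, "library_type", .library_types)
  sample_meta$rna_extraction <-
    check_vocab(sample_meta, "rna_extraction", .rna_extractions)
  for (col in c("tissue_block", "donor")) {
    if (!col %in% names(sample_meta)) sample_meta[[col]] <- "unknown"
  }
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "bulk_expr_set")
}

check_vocab <- function(meta, col, vocab) {
  if (!col %in% names(meta)) return(rep("other", nrow(meta)))
  x <- as.character(meta[[col]])
  bad <- !is.na(x) & !x %in% vocab
  if (any(bad)) {
    warning(sum(bad), " value(s) of `", col,
            "` outside the declared vocabulary carried as \"other\"",
            call. = FALSE)
    x[bad] <- "other"
  }
  x
}

#' @exportS3Method base::print
print.bulk_expr_set <- function(x, ...) {
  cat("<bulk_expr_set> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  combos <- dplyr::count(x$sample_meta, .data$library_type,
                         .data$rna_extraction)
  cat("  library x extraction combinations: ", nrow(combos), "\n", sep = "")
  invisible(x)
}

#' @export
dim.bulk_expr_set <- function(x) dim(x$counts)

#' Read a single-cell reference from MTX + TSV files
#'
#' Loads a MatrixMarket sparse count matrix with its gene and barcode lists
#' and a cell-metadata TSV keyed by barcode, and validates the result. Cells
#' present in the matrix but absent from the metadata are dropped with a
#' message reporting the count.
#'
#' @param matrix_path Path to the `.mtx` count matrix (genes x cells).
#' @param genes_path Path to a headerless TSV whose first column is gene ids.
#' @param cells_path Path to a headerless TSV whose first column is barcodes.
#' @param meta_path Path to a TSV with header, containing `barcode` and
#'   `cell_type` columns (plus optional `donor`, `sample`).
#' @return A validated [cell_expression_set()].
#' @export
read_cell_expression <- function(matrix_path, genes_path, cells_path,
                                 meta_path) {
  m <- methods::as(Matrix::readMM(matrix_path), "CsparseMatrix")
  genes <- readr::read_tsv(genes_path, col_names = FALSE,
                           show_col_types = FALSE)[[1]]
  cells <- readr::read_tsv(cells_path, col_names = FALSE,
                           show_col_types = FALSE)[[1]]
  if (length(genes) != nrow(m)) {
    stop("gene list has ", length(genes), " entries but matrix has ",
         nrow(m), " rows", call. = FALSE)
  }
  if (length(cells) != ncol(m)) {
    stop("barcode list has ", length(cells), " entries but matrix has ",
         ncol(m), " columns", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    stop("duplicate gene ids in ", genes_path, call. = FALSE)
  }
  dimnames(m) <- list(genes, cells)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  cell_expression_set(m, meta)
}

#' Write a single-cell reference as MTX + TSV files
#'
#' Inverse of [read_cell_expression()]; emits `counts.mtx`, `genes.tsv`,
#' `barcodes.tsv` and `cell_meta.tsv` under `dir`.
#'
#' @param set A `cell_expr_set`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cell_expression <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- set$counts
  if (!inherits(m, "sparseMatrix")) m <- methods::as(m, "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "counts.mtx"))
  readr::write_tsv(tibble(gene = rownames(set$counts)),
                   file.path(dir, "genes.tsv"), col_names = FALSE)
  readr::write_tsv(tibble(barcode = colnames(set$counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  readr::write_tsv(set$cell_meta, file.path(dir, "cell_meta.tsv"))
  invisible(dir)
}

#' Read bulk expression counts and sample metadata from TSV
#'
#' @param counts_tsv TSV with genes as rows (first column = gene id) and
#'   samples as columns.
#' @param meta_tsv TSV with a `sample_id` column and optional annotation
#'   columns (`library_type`, `rna_extraction`, `tissue_block`, `donor`).
#' @return A validated [bulk_expression_set()].
#' @export
read_bulk_expression <- function(counts_tsv, meta_tsv = NULL) {
  tab <- readr::read_tsv(counts_tsv, show_col_types = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- as.character(tab[[1]])
  meta <- if (!is.null(meta_tsv)) {
    readr::read_tsv(meta_tsv, show_col_types = FALSE)
  }
  bulk_expression_set(counts, meta)
}

#' Write a bulk expression set to TSV
#'
#' @param set A `bulk_expr_set`.
#' @param counts_tsv,meta_tsv Output paths.
#' @return `counts_tsv`, invisibly.
#' @export
write_bulk_expression <- function(set, counts_tsv, meta_tsv) {
  tab <- as_tibble(set$counts, rownames = "gene")
  readr::write_tsv(tab, counts_tsv)
  readr::write_tsv(set$sample_meta, meta_tsv)
  invisible(counts_tsv)
}
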