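# Readers and writers for the supported file dialects: dense delimited
# text (genes as rows, header of cell ids), Matrix Market with id sidecar
# files, axis tables, and the TSV result tables.

mtx_sidecars <- function(path, genes, cells) {
  stem <- sub("\\.mtx$", "", path)
  list(genes = if (is.null(genes)) paste0(stem, ".genes.txt") else genes,
       cells = if (is.null(cells)) paste0(stem, ".cells.txt") else cells)
}

check_ids <- function(ids, what, file) {
  if (anyDuplicated(ids))
    stop("duplicate ", what, " ids in ", file)
  ids
}

#' Read a genes x cells expression matrix
#'
#' Two dialects are supported. Dense delimited text (`.csv`/`.tsv`/other):
#' genes as rows, first column gene ids, header row of cell ids; the
#' separator is sniffed. Matrix Market (`.mtx`): genes as rows, with
#' plain-text id sidecar files (defaults `<stem>.genes.txt` and
#' `<stem>.cells.txt`, one id per line).
#'
#' @param path Path to the matrix file.
#' @param genes,cells Optional sidecar paths (Matrix Market only).
#' @return A dense numeric matrix with gene rownames and cell colnames.
#' @export
read_expression <- function(path, genes = NULL, cells = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path)) {
    sc <- mtx_sidecars(path, genes, cells)
    M <- Matrix::readMM(path)
    gid <- check_ids(readLines(sc$genes), "gene", sc$genes)
    cid <- check_ids(readLines(sc$cells), "cell", sc$cells)
    if (length(gid) != nrow(M))
      stop("sidecar ", sc$genes, " has ", length(gid),
           " ids but the matrix has ", nrow(M), " rows")
    if (length(cid) != ncol(M))
      stop("sidecar ", sc$cells, " has ", length(cid),
           " ids but the matrix has ", ncol(M), " columns")
    Y <- as.matrix(M)
    dimnames(Y) <- list(gid, cid)
  } else {
    dt <- data.table::fread(path, header = TRUE, sep = "auto",
                            data.table = FALSE)
    if (nrow(dt) == 0) stop("no genes in ", path)
    gid <- check_ids(as.character(dt[[1]]), "gene", path)
    vals <- dt[, -1, drop = FALSE]
    if (!all(vapply(vals, is.numeric, logical(1))))
      stop("non-numeric expression entries in ", path)
    check_ids(colnames(vals), "cell", path)
    Y <- as.matrix(vals)
    rownames(Y) <- gid
  }
  if (any(!is.finite(Y)))
    stop("missing or non-finite expression values in ", path,
         " are not supported")
  Y
}

#' Write a genes x cells expression matrix
#'
#' Dense delimited output uses a `gene_id` first column and a header of
#' cell ids (comma-separated for `.csv`, tab otherwise); values are written
#' with full round-trip precision. A `.mtx` path writes Matrix Market plus
#' the two id sidecar files.
#'
#' @param Y Matrix with gene rownames and cell colnames.
#' @param path Output path; the extension selects the dialect.
#' @param genes,cells Optional sidecar paths (Matrix Market only).
#' @return The main output path, invisibly.
#' @export
write_expression <- function(Y, path, genes = NULL, cells = NULL) {
  Y <- as.matrix(Y)
  if (grepl("\\.mtx$", path)) {
    sc <- mtx_sidecars(path, genes, cells)
    Matrix::writeMM(Matrix::Matrix(Y, sparse = TRUE), path)
    writeLines(rownames(Y), sc$genes)
    writeLines(colnames(Y), sc$cells)
  } else {
    sep <- if (grepl("\\.csv$", path)) "," else "\t"
    # 17 significant digits guarantee a lossless double round trip
    ch <- formatC(Y, format = "g", digits = 17)
    dim(ch) <- dim(Y)
    writeLines(
      c(paste(c("gene_id", colnames(Y)), collapse = sep),
        paste(rownames(Y), apply(ch, 1, paste, collapse = sep), sep = sep)),
      path
    )
  }
  invisible(path)
}

#' Read a per-cell pseudotime table
#'
#' Expects a delimited file with a header and at least two columns: cell
#' id, then pseudotime.
#'
#' @param path Path to the table.
#' @return A named numeric vector of pseudotime values.
#' @export
read_pseudotime <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2) stop("pseudotime table needs columns: cell_id, pseudotime")
  ids <- check_ids(as.character(dt[[1]]), "cell", path)
  t <- dt[[2]]
  if (!is.numeric(t)) stop("non-numeric pseudotime values in ", path)
  stats::setNames(as.numeric(t), ids)
}

#' Read a per-spot coordinate table
#'
#' Expects a delimited file with a header and at least three columns: spot
#' id, then the two coordinates.
#'
#' @param path Path to the table.
#' @return An `n x 2` numeric matrix with spot rownames.
#' @export
read_coords <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 3) stop("coordinate table needs columns: id, x, y")
  ids <- check_ids(as.character(dt[[1]]), "spot", path)
  S <- as.matrix(dt[, 2:3])
  if (!is.numeric(S)) stop("non-numeric coordinates in ", path)
  rownames(S) <- ids
  colnames(S) <- c("x", "y")
  S
}

#' Align an expression matrix with its axis values by cell id
#'
#' Reorders both to the intersection of ids, in expression-column order;
#' cells present on only one side are dropped with a message.
#'
#' @param Y Expression matrix with cell colnames.
#' @param axis Named pseudotime vector or coordinate matrix with rownames.
#' @return A list with the aligned `Y` and `axis`.
#' @export
align_axis <- function(Y, axis) {
  ids_axis <- if (is.matrix(axis)) rownames(axis) else names(axis)
  if (is.null(colnames(Y)) || is.null(ids_axis))
    stop("both the expression matrix and the axis must carry cell ids")
  common <- intersect(colnames(Y), ids_axis)
  if (!length(common))
    stop("no shared cell ids between expression and axis")
  dropped <- (ncol(Y) - length(common)) + (length(ids_axis) - length(common))
  if (dropped > 0)
    message(dropped, " cell(s) lacking expression or axis values dropped")
  axis2 <- if (is.matrix(axis)) axis[common, , drop = FALSE]
           else axis[common]
  list(Y = Y[, common, drop = FALSE], axis = axis2)
}

#' Write a variable-gene result table
#'
#' Writes the TSV result table with its fixed column order, sorted by
#' ascending p-value with a stable tie-break on gene id (tables without a
#' p-value column are written in gene order). Missing values are written
#' as empty fields.
#'
#' @param res A result data.frame from [ftest_pvalues()],
#'   [permutation_test()] or [svg_test()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_results <- function(res, path) {
  if (!is.null(res$pvalue))
    res <- res[order(res$pvalue, res$gene_id), , drop = FALSE]
  data.table::fwrite(res, path, sep = "\t", na = "")
  invisible(path)
}
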