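#' Read a gene x cell count matrix with id files
#'
#' Accepts MatrixMarket sparse format (`.mtx`) or a dense CSV of numbers
#' (genes as rows, no header). Gene and cell identifiers come from
#' one-id-per-line files (first column used if multi-column, as in
#' 10x-style `genes.tsv`). Duplicate gene symbols are collapsed by summing
#' their rows, with a warning.
#'
#' @param path_matrix path to the matrix file (`.mtx` or `.csv`).
#' @param path_genes path to the gene id file (one per line).
#' @param path_cells path to the cell id file (one per line).
#' @param species `"mouse"` or `"human"`.
#' @return a [labeled_counts()] object.
#' @export
read_counts <- function(path_matrix, path_genes, path_cells, species) {
  genes <- read.delim(path_genes, header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  cells <- read.delim(path_cells, header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  genes <- trim_ws(as.character(genes))
  cells <- trim_ws(as.character(cells))
  if (grepl("\\.mtx$", path_matrix, ignore.case = TRUE)) {
    m <- Matrix::readMM(path_matrix)
    m <- as(m, "CsparseMatrix")
  } else {
    m <- as.matrix(utils::read.csv(path_matrix, header = FALSE))
    storage.mode(m) <- "double"
    m <- Matrix::Matrix(m, sparse = TRUE)
  }
  if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
    stop("matrix is ", nrow(m), " x ", ncol(m), " but id files list ",
         length(genes), " genes and ", length(cells), " cells",
         call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    warning("collapsing ", length(dups),
            " duplicated gene symbol(s) by summing rows (e.g. '",
            dups[1], "')", call. = FALSE)
    grp <- factor(genes, levels = unique(genes))
    agg <- Matrix::sparseMatrix(
      i = as.integer(grp), j = seq_along(genes), x = 1,
      dims = c(nlevels(grp), length(genes))
    )
    m <- agg %*% m
    genes <- levels(grp)
  }
  labeled_counts(m, genes, cells, species)
}

#' Write a labeled count matrix as MTX plus id files
#'
#' Inverse of [read_counts()]; the round trip preserves every nonzero
#' entry exactly.
#'
#' @param x a [labeled_counts()] object.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (default the species label).
#' @return invisibly, the three file paths.
#' @export
write_counts <- function(x, dir, prefix = x$species) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pm <- file.path(dir, paste0(prefix, "_matrix.mtx"))
  pg <- file.path(dir, paste0(prefix, "_genes.tsv"))
  pc <- file.path(dir, paste0(prefix, "_barcodes.tsv"))
  Matrix::writeMM(x$counts, pm)
  writeLines(x$gene_ids, pg)
  writeLines(x$cell_ids, pc)
  invisible(c(matrix = pm, genes = pg, cells = pc))
}

#' Column mappings for supported GRN edge-list dialects
#' @noRd
grn_dialect_columns <- function(dialect) {
  switch(dialect,
    biccn_like = c(tf = "TF", target = "target_gene"),
    psychencode_like = c(tf = "TF", target = "target"),
    generic = c(tf = "tf", target = "target")
  )
}

#' Read a TF-to-target edge list
#'
#' Parses tab- or comma-separated files with at least a TF column and a
#' target column; additional columns (e.g. scores) are ignored for
#' counting. Dialects select the expected column names:
#' `biccn_like` (`TF`, `target_gene`), `psychencode_like` (`TF`, `target`,
#' optional `score`; per-cell-type files conventionally named
#' `<celltype>_GRN.txt`), `generic` (`tf`, `target`, or the first two
#' columns when those names are absent).
#'
#' @param path path to the edge-list file.
#' @param dialect one of `"generic"`, `"biccn_like"`, `"psychencode_like"`.
#' @param cell_type cell type label; by default inferred from a
#'   `<celltype>_GRN.txt` file name, else the file base name.
#' @return a [grn_edge_set()].
#' @export
read_grn_edges <- function(path,
                           dialect = c("generic", "biccn_like",
                                       "psychencode_like"),
                           cell_type = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(cell_type)) {
    bn <- basename(path)
    cell_type <- if (grepl("_GRN\\.txt$", bn)) sub("_GRN\\.txt$", "", bn)
                 else sub("\\.[^.]*$", "", bn)
  }
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(trim_ws(first))) {
    warning("empty GRN file: ", path, call. = FALSE)
    return(grn_edge_set(cell_type, character(), character(), dialect))
  }
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.delim(path, sep = sep, header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  cols <- grn_dialect_columns(dialect)
  have <- names(df)
  if (!all(cols %in% have)) {
    if (dialect == "generic" && ncol(df) >= 2) {
      cols <- c(tf = have[1], target = have[2])
    } else {
      stop("GRN file lacks required columns ",
           paste(sprintf("'%s'", cols), collapse = ", "),
           "; found: ", paste(sprintf("'%s'", have), collapse = ", "),
           call. = FALSE)
    }
  }
  grn_edge_set(cell_type, df[[cols["tf"]]], df[[cols["target"]]], dialect)
}

#' Write a GRN edge set to disk
#'
#' @param grn a [grn_edge_set()].
#' @param path output file path.
#' @param dialect output format (see [read_grn_edges()]).
#' @return invisibly, `path`.
#' @export
write_grn_edges <- function(grn, path,
                            dialect = c("generic", "biccn_like",
                                        "psychencode_like")) {
  dialect <- match.arg(dialect)
  cols <- grn_dialect_columns(dialect)
  df <- data.frame(grn$edges$tf, grn$edges$target,
                   stringsAsFactors = FALSE)
  names(df) <- cols[c("tf", "target")]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mouse-human ortholog map
#'
#' TSV with mouse and human symbol columns (named `mouse`/`human`, or
#' `mouse_symbol`/`human_symbol`, or the first two columns). Only 1:1
#' pairs are retained; many-to-many entries are dropped and counted.
#'
#' @param path path to the TSV file.
#' @return an [ortholog_map()]; errors if no pair survives the 1:1 filter.
#' @export
read_ortholog_map <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  nm <- tolower(names(df))
  mcol <- which(nm %in% c("mouse", "mouse_symbol"))[1]
  hcol <- which(nm %in% c("human", "human_symbol"))[1]
  if (is.na(mcol) || is.na(hcol)) {
    if (ncol(df) >= 2) { mcol <- 1L; hcol <- 2L }
    else stop("ortholog map needs mouse and human symbol columns",
              call. = FALSE)
  }
  map <- ortholog_map(df[[mcol]], df[[hcol]])
  if (map$n_dropped > 0) {
    message(map$n_dropped, " ortholog pairs dropped by the 1:1 filter")
  }
  if (map$universe_size == 0) {
    stop("no 1:1 ortholog pairs retained from ", path, call. = FALSE)
  }
  map
}

#' Read a DEG table from CSV
#'
#' Expected columns: `gene`, `cell_type`, `log2fc` (or `log2_fold_change`
#' / `avg_log2FC`), `p_adjusted` (or `p_adj`/`padj`).
#'
#' @param path path to the CSV file.
#' @return a [deg_table()].
#' @export
read_deg_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- names(df)
  ren <- c(log2_fold_change = "log2fc", avg_log2FC = "log2fc",
           p_adj = "p_adjusted", padj = "p_adjusted")
  for (old in names(ren)) {
    if (old %in% nm && !(ren[[old]] %in% nm)) {
      names(df)[names(df) == old] <- ren[[old]]
    }
  }
  deg_table(df)
}

#' Write a data frame report as TSV (floats at 6 significant digits)
#'
#' @param df data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- fmt_num(out[[j]])
    }
    if (is.list(out[[j]])) {
      out[[j]] <- vapply(out[[j]], function(v) paste(v, collapse = ","), "")
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
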