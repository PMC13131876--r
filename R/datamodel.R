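#' Labeled count matrix for one species
#'
#' Bundles a gene x cell matrix of UMI counts with its gene and cell
#' identifiers and a species label. Counts must be non-negative integers;
#' gene symbols must be unique (duplicates are collapsed by summation in
#' [read_counts()]).
#'
#' @param counts gene x cell matrix (dense or `Matrix` sparse) of
#'   non-negative integer counts.
#' @param gene_ids character vector of gene symbols, one per row.
#' @param cell_ids character vector of cell barcodes, one per column.
#' @param species `"mouse"` or `"human"`.
#' @return an object of class `labeled_counts`.
#' @export
labeled_counts <- function(counts, gene_ids, cell_ids, species) {
  species <- match.arg(species, SPECIES_LEVELS)
  gene_ids <- trim_ws(as.character(gene_ids))
  cell_ids <- as.character(cell_ids)
  if (nrow(counts) != length(gene_ids)) {
    stop("counts has ", nrow(counts), " rows but ", length(gene_ids),
         " gene ids were supplied", call. = FALSE)
  }
  if (ncol(counts) != length(cell_ids)) {
    stop("counts has ", ncol(counts), " columns but ", length(cell_ids),
         " cell ids were supplied", call. = FALSE)
  }
  vals <- if (inherits(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (length(vals) && any(vals < 0)) {
    stop("counts contain negative entries", call. = FALSE)
  }
  bad <- which(vals != round(vals))
  if (length(bad)) {
    if (inherits(counts, "sparseMatrix")) {
      cm <- as(counts, "TsparseMatrix")
      stop("non-integer count for cell '", cell_ids[cm@j[bad[1]] + 1L],
           "' (gene '", gene_ids[cm@i[bad[1]] + 1L], "')", call. = FALSE)
    }
    idx <- arrayInd(bad[1], dim(counts))
    stop("non-integer count for cell '", cell_ids[idx[2]],
         "' (gene '", gene_ids[idx[1]], "')", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids; collapse them first (see read_counts)",
         call. = FALSE)
  }
  if (!inherits(counts, "sparseMatrix")) {
    counts <- Matrix::Matrix(as.matrix(counts), sparse = TRUE)
  }
  counts <- as(counts, "CsparseMatrix")
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(
    list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
         species = species),
    class = "labeled_counts"
  )
}

#' @export
print.labeled_counts <- function(x, ...) {
  cat("labeled_counts: ", length(x$gene_ids), " genes x ",
      length(x$cell_ids), " cells (", x$species, ")\n", sep = "")
  invisible(x)
}

#' @export
dim.labeled_counts <- function(x) dim(x$counts)

#' Per-cell metadata table
#'
#' Validates a metadata data frame against a set of cell ids. Every cell
#' must appear exactly once, species/condition must use the canonical
#' levels, and the four species x condition groups partition the cells.
#'
#' @param df data frame with columns `cell_id`, `species`, `condition`,
#'   `cell_type`, `sample_id`.
#' @param cell_ids optional character vector the metadata must cover
#'   exactly once each.
#' @return the validated data frame with class `cell_metadata` prepended.
#' @export
cell_metadata <- function(df, cell_ids = NULL) {
  need <- c("cell_id", "species", "condition", "cell_type", "sample_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("metadata missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$species <- as.character(df$species)
  df$condition <- as.character(df$condition)
  if (!all(df$species %in% SPECIES_LEVELS)) {
    stop("species must be one of: ", paste(SPECIES_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$condition %in% CONDITION_LEVELS)) {
    stop("condition must be one of: ",
         paste(CONDITION_LEVELS, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$cell_id)) {
    stop("duplicate cell_id rows in metadata", call. = FALSE)
  }
  if (!is.null(cell_ids)) {
    missing_cells <- setdiff(cell_ids, df$cell_id)
    if (length(missing_cells)) {
      stop(length(missing_cells), " cells have no metadata row (e.g. '",
           missing_cells[1], "')", call. = FALSE)
    }
    df <- df[match(cell_ids, df$cell_id), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- unique(c("cell_metadata", class(df)))
  df
}

#' One-to-one ortholog symbol map
#'
#' Holds retained 1:1 mouse-human symbol pairs. Construction enforces the
#' 1:1 filter: any mouse or human symbol participating in more than one
#' pair is dropped entirely (with all its pairs).
#'
#' @param mouse,human character vectors of equal length.
#' @return object of class `ortholog_map` with elements `pairs` (data frame
#'   with columns `mouse`, `human`), `universe_size`, and `n_dropped`.
#' @export
ortholog_map <- function(mouse, human) {
  mouse <- trim_ws(as.character(mouse))
  human <- trim_ws(as.character(human))
  stopifnot(length(mouse) == length(human))
  keep <- nzchar(mouse) & nzchar(human)
  pairs <- unique(data.frame(mouse = mouse[keep], human = human[keep],
                             stringsAsFactors = FALSE))
  dup_m <- pairs$mouse[duplicated(pairs$mouse)]
  dup_h <- pairs$human[duplicated(pairs$human)]
  bad <- pairs$mouse %in% dup_m | pairs$human %in% dup_h
  n_dropped <- sum(bad)
  pairs <- pairs[!bad, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(
    list(pairs = pairs, universe_size = nrow(pairs), n_dropped = n_dropped),
    class = "ortholog_map"
  )
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat("ortholog_map: ", x$universe_size, " retained 1:1 pairs (",
      x$n_dropped, " pairs dropped by the 1:1 filter)\n", sep = "")
  invisible(x)
}

#' Translate symbols across species through an ortholog map
#'
#' @param genes character vector of symbols in the `from` species.
#' @param map an [ortholog_map()].
#' @param from source species (`"mouse"` or `"human"`).
#' @param fallback_case if `TRUE`, symbols absent from the explicit map are
#'   translated by species case convention (mouse Title-case <-> human
#'   UPPER-case). Off by default; the explicit map is safer.
#' @return character vector of the same length; `NA` where untranslatable.
#' @export
map_orthologs <- function(genes, map, from = c("mouse", "human"),
                          fallback_case = FALSE) {
  from <- match.arg(from)
  to <- setdiff(SPECIES_LEVELS, from)
  out <- map$pairs[[to]][match(genes, map$pairs[[from]])]
  if (fallback_case) {
    miss <- is.na(out)
    if (any(miss)) {
      out[miss] <- if (to == "human") toupper(genes[miss]) else
        paste0(toupper(substr(genes[miss], 1, 1)),
               tolower(substr(genes[miss], 2, nchar(genes[miss]))))
    }
  }
  out
}

#' Differentially-expressed-gene table
#'
#' Normalizes and validates a DEG table: one row per (gene, cell_type) with
#' a signed log2 fold change and an adjusted p-value. The `direction`
#' column is derived from the sign of `log2fc` (up iff log2fc > 0).
#'
#' @param df data frame with columns `gene`, `cell_type`, `log2fc`,
#'   `p_adjusted`.
#' @return validated data frame with class `deg_table` and a `direction`
#'   column.
#' @export
deg_table <- function(df) {
  need <- c("gene", "cell_type", "log2fc", "p_adjusted")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("DEG table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$gene <- trim_ws(as.character(df$gene))
  df$cell_type <- as.character(df$cell_type)
  if (any(df$p_adjusted < 0 | df$p_adjusted > 1, na.rm = TRUE)) {
    stop("p_adjusted outside [0, 1]", call. = FALSE)
  }
  if (anyDuplicated(df[c("gene", "cell_type")])) {
    stop("duplicate (gene, cell_type) rows in DEG table", call. = FALSE)
  }
  df$direction <- ifelse(df$log2fc > 0, "up", "down")
  class(df) <- unique(c("deg_table", class(df)))
  df
}

#' Directed TF-to-target edge set for one cell type
#'
#' @param cell_type cell type label the network belongs to.
#' @param tf,target character vectors of equal length (one edge per entry).
#' @param dialect source file dialect the edges were parsed from.
#' @return object of class `grn_edge_set` with a deduplicated `edges` data
#'   frame (`tf`, `target`, `is_self_loop`).
#' @export
grn_edge_set <- function(cell_type, tf, target,
                         dialect = c("generic", "biccn_like",
                                     "psychencode_like")) {
  dialect <- match.arg(dialect)
  tf <- trim_ws(as.character(tf))
  target <- trim_ws(as.character(target))
  stopifnot(length(tf) == length(target))
  edges <- unique(data.frame(tf = tf, target = target,
                             stringsAsFactors = FALSE))
  keep <- nzchar(edges$tf) & nzchar(edges$target)
  edges <- edges[keep, , drop = FALSE]
  edges$is_self_loop <- edges$tf == edges$target
  rownames(edges) <- NULL
  structure(
    list(cell_type = as.character(cell_type), edges = edges,
         source_dialect = dialect),
    class = "grn_edge_set"
  )
}

#' @export
print.grn_edge_set <- function(x, ...) {
  cat("grn_edge_set [", x$cell_type, "]: ", nrow(x$edges), " edges, ",
      length(unique(x$edges$tf)), " TFs (", x$source_dialect, ")\n",
      sep = "")
  invisible(x)
}
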