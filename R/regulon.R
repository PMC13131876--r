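#' Per-TF summaries of downstream differentially expressed genes
#'
#' For each TF in a cell type's GRN, counts the DEGs of that cell type
#' among the TF's targets, split by direction, and records whether the
#' TF itself is differentially expressed. Self-loops (TF targeting
#' itself) are excluded from the downstream counts by default.
#'
#' @param grn a [grn_edge_set()] for the cell type.
#' @param degs a [deg_table()]; rows are filtered to `cell_type`.
#' @param cell_type cell type label (defaults to the GRN's own label).
#' @param species species label carried into the output.
#' @param exclude_self_loops drop TF->TF self edges from counting
#'   (default `TRUE`).
#' @return data frame of class `tf_deg_summary`, sorted by
#'   `n_downstream_degs` descending (ties lexicographic by TF), with a
#'   `deg_genes` list-column of the downstream DEG symbols.
#' @export
tf_deg_summaries <- function(grn, degs, cell_type = grn$cell_type,
                             species = NA_character_,
                             exclude_self_loops = TRUE) {
  d <- degs[degs$cell_type == cell_type, , drop = FALSE]
  deg_dir <- stats::setNames(d$direction, d$gene)
  edges <- grn$edges
  if (exclude_self_loops) {
    edges <- edges[!edges$is_self_loop, , drop = FALSE]
  }
  tfs <- sort(unique(grn$edges$tf))
  rows <- lapply(tfs, function(tf) {
    targets <- unique(edges$target[edges$tf == tf])
    hit <- intersect(targets, names(deg_dir))
    n_up <- sum(deg_dir[hit] == "up")
    n_down <- sum(deg_dir[hit] == "down")
    data.frame(tf = tf, cell_type = cell_type, species = species,
               n_downstream_degs = length(hit), n_up = n_up,
               n_down = n_down,
               frac_up = if (length(hit)) n_up / length(hit) else NA_real_,
               tf_is_deg = tf %in% names(deg_dir),
               tf_direction = if (tf %in% names(deg_dir))
                 deg_dir[[tf]] else "none",
               deg_genes = I(list(sort(hit))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tf = character(), cell_type = character(),
                      species = character(), n_downstream_degs = integer(),
                      n_up = integer(), n_down = integer(),
                      frac_up = numeric(), tf_is_deg = logical(),
                      tf_direction = character(),
                      deg_genes = I(list()))
  }
  out <- out[order(-out$n_downstream_degs, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- unique(c("tf_deg_summary", class(out)))
  out
}

#' Global TF ranking across cell types
#'
#' Aggregates per-cell-type TF summaries for one species: each TF's total
#' downstream DEG count is the sum over cell types (kept as a long
#' per-cell-type breakdown for stacked-bar export), and a secondary
#' ranking orders TFs by the number of cell types in which the TF itself
#' is differentially expressed.
#'
#' @param summaries list of `tf_deg_summary` data frames (one per cell
#'   type) or a single combined data frame.
#' @return list with `ranking` (tf, total_downstream_degs,
#'   n_celltypes_tf_deg, union of downstream DEG genes as a
#'   list-column; sorted by total descending, ties lexicographic),
#'   `by_cell_type` (long format), and `de_tf_ranking`.
#' @export
rank_tfs_global <- function(summaries) {
  df <- if (is.data.frame(summaries)) summaries else
    do.call(rbind, summaries)
  if (nrow(df) == 0) stop("no TF summaries supplied", call. = FALSE)
  tfs <- sort(unique(df$tf))
  rank_df <- do.call(rbind, lapply(tfs, function(tf) {
    sub <- df[df$tf == tf, , drop = FALSE]
    genes <- sort(unique(unlist(sub$deg_genes)))
    data.frame(tf = tf,
               total_downstream_degs = sum(sub$n_downstream_degs),
               n_celltypes = nrow(sub),
               n_celltypes_tf_deg = sum(sub$tf_is_deg),
               deg_genes_union = I(list(genes)),
               stringsAsFactors = FALSE)
  }))
  rank_df <- rank_df[order(-rank_df$total_downstream_degs, rank_df$tf), ]
  rownames(rank_df) <- NULL
  de_tf <- rank_df[order(-rank_df$n_celltypes_tf_deg,
                         -rank_df$total_downstream_degs, rank_df$tf), ]
  rownames(de_tf) <- NULL
  list(ranking = rank_df,
       by_cell_type = df[c("tf", "cell_type", "species",
                           "n_downstream_degs", "n_up", "n_down")],
       de_tf_ranking = de_tf)
}

#' Cross-species master-regulator table
#'
#' Pairs TFs appearing in both species' top-`top_n` global rankings
#' through the ortholog map and, for each pair, intersects the two
#' species' downstream-DEG sets (unioned over cell types, mouse genes
#' ortholog-mapped to human symbols). Rows are sorted by overlap count
#' descending and serialized in the column order of published
#' master-regulator tables: human TF, human count, mouse TF, mouse
#' count, overlap count, overlapping genes.
#'
#' @param mouse_ranking,human_ranking `ranking` element from
#'   [rank_tfs_global()] for each species.
#' @param map an [ortholog_map()].
#' @param top_n ranking depth considered in each species (default 20).
#' @param fallback_case map unlisted TF symbols by case convention (see
#'   [map_orthologs()]).
#' @return data frame of class `cross_species_tf_table` with columns
#'   `human_tf`, `n_human_downstream_degs`, `mouse_tf`,
#'   `n_mouse_downstream_degs`, `n_overlap`, `overlap_genes`
#'   (list-column of human symbols).
#' @export
cross_species_tf_table <- function(mouse_ranking, human_ranking, map,
                                   top_n = 20, fallback_case = FALSE) {
  m_top <- utils::head(mouse_ranking, top_n)
  h_top <- utils::head(human_ranking, top_n)
  m_top$human_tf <- map_orthologs(m_top$tf, map, "mouse",
                                  fallback_case = fallback_case)
  paired <- m_top[!is.na(m_top$human_tf) &
                    m_top$human_tf %in% h_top$tf, , drop = FALSE]
  if (nrow(paired) == 0) {
    warning("no TFs pairable across the two species' rankings",
            call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(paired)), function(i) {
    htf <- paired$human_tf[i]
    hrow <- h_top[h_top$tf == htf, , drop = FALSE]
    m_genes_h <- map_orthologs(paired$deg_genes_union[[i]], map, "mouse")
    ov <- sort(intersect(m_genes_h[!is.na(m_genes_h)],
                         hrow$deg_genes_union[[1]]))
    data.frame(human_tf = htf,
               n_human_downstream_degs = hrow$total_downstream_degs,
               mouse_tf = paired$tf[i],
               n_mouse_downstream_degs =
                 paired$total_downstream_degs[i],
               n_overlap = length(ov),
               overlap_genes = I(list(ov)),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(human_tf = character(),
               n_human_downstream_degs = integer(),
               mouse_tf = character(),
               n_mouse_downstream_degs = integer(),
               n_overlap = integer(), overlap_genes = I(list()))
  out <- out[order(-out$n_overlap, out$human_tf), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(out$n_overlap <= pmin(out$n_human_downstream_degs,
                                      out$n_mouse_downstream_degs)))
  class(out) <- unique(c("cross_species_tf_table", class(out)))
  out
}

#' Dot-plot-ready long table of TF-target DEG relations
#'
#' One row per (TF, downstream DEG) with the DEG's direction — the long
#' format behind TF-by-gene dot plots.
#'
#' @param summary a `tf_deg_summary`.
#' @param degs the [deg_table()] used to build it.
#' @return data frame with `tf`, `gene`, `direction`.
#' @export
tf_target_dotplot_table <- function(summary, degs) {
  rows <- lapply(seq_len(nrow(summary)), function(i) {
    genes <- summary$deg_genes[[i]]
    if (!length(genes)) return(NULL)
    d <- degs[degs$cell_type == summary$cell_type[i], ]
    data.frame(tf = summary$tf[i], gene = genes,
               direction = d$direction[match(genes, d$gene)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(tf = character(),
                                      gene = character(),
                                      direction = character())
  rownames(out) <- NULL
  out
}
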