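#' Cross-species module matching with the three-criterion caller
#'
#' Every mouse x human module pair is tested for gene-membership overlap
#' by the upper-tail hypergeometric test over the ortholog-mapped network
#' universe, with BH adjustment across all pairs. A pair is a *module of
#' interest* iff it (1) shares at least one hub gene (intersection of the
#' species' top-`top_k_hubs` hub lists after ortholog mapping), (2) shows
#' significant membership overlap (adjusted p < `alpha`), and (3) is
#' differentially expressed between conditions in both species.
#'
#' @param mouse_modules,human_modules `module_set` objects.
#' @param map an [ortholog_map()].
#' @param de a `module_de_result` covering both species (or a list of
#'   two).
#' @param alpha significance level for criterion (2) (default 0.05).
#' @param top_k_hubs hub list length for criterion (1) (default 10).
#' @param universe optional explicit gene universe (human symbols);
#'   default is the ortholog-mapped genes present in both species'
#'   network input.
#' @return data frame of class `module_pair_test`, one row per pair,
#'   sorted by adjusted p: overlap counts, hypergeometric p, shared hub
#'   genes, differential flags, and `is_module_of_interest`.
#' @export
match_modules <- function(mouse_modules, human_modules, map, de,
                          alpha = 0.05, top_k_hubs = 10,
                          universe = NULL) {
  if (is.list(de) && !is.data.frame(de)) de <- do.call(rbind, de)
  mouse_genes_h <- map_orthologs(names(mouse_modules$assignment), map,
                                 from = "mouse")
  keep <- !is.na(mouse_genes_h)
  n_unmapped <- sum(!keep)
  m_assign <- mouse_modules$assignment[keep]
  names(m_assign) <- mouse_genes_h[keep]
  h_assign <- human_modules$assignment
  if (is.null(universe)) {
    universe <- intersect(names(m_assign), names(h_assign))
  }
  if (!length(universe)) stop("empty ortholog universe", call. = FALSE)
  m_assign <- m_assign[names(m_assign) %in% universe]
  h_assign <- h_assign[names(h_assign) %in% universe]
  m_mods <- setdiff(unique(m_assign), "grey")
  h_mods <- setdiff(unique(h_assign), "grey")
  if (!length(m_mods) || !length(h_mods)) {
    stop("no non-grey modules to match", call. = FALSE)
  }
  de_flag <- function(sp, mod) {
    row <- de[de$species == sp & de$module == mod, , drop = FALSE]
    if (nrow(row) == 0) return(list(flag = FALSE, dir = "none"))
    list(flag = isTRUE(row$is_differential[1]), dir = row$direction[1])
  }
  rows <- list()
  for (mm in m_mods) {
    m_set <- names(m_assign)[m_assign == mm]
    m_hubs <- map_orthologs(mouse_modules$hub_genes[[mm]], map, "mouse")
    m_hubs <- m_hubs[!is.na(m_hubs)][seq_len(min(top_k_hubs,
                                                 sum(!is.na(m_hubs))))]
    m_de <- de_flag("mouse", mm)
    for (hm in h_mods) {
      h_set <- names(h_assign)[h_assign == hm]
      h_hubs <- utils::head(human_modules$hub_genes[[hm]], top_k_hubs)
      shared_hubs <- intersect(m_hubs, h_hubs)
      h_de <- de_flag("human", hm)
      ov <- intersect(m_set, h_set)
      rows[[length(rows) + 1L]] <- data.frame(
        mouse_module = mm, human_module = hm,
        n_universe = length(universe),
        n_mouse = length(m_set), n_human = length(h_set),
        n_overlap = length(ov),
        hypergeom_p = hypergeometric_overlap(m_set, h_set, universe),
        shared_hubs = I(list(shared_hubs)),
        both_differential = m_de$flag && h_de$flag,
        same_direction = m_de$dir != "none" && m_de$dir == h_de$dir,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- adjust_bh(out$hypergeom_p)
  out$is_module_of_interest <-
    vapply(out$shared_hubs, length, 0L) >= 1 &
    out$p_adjusted < alpha & out$both_differential
  out <- out[order(out$p_adjusted, out$mouse_module,
                   out$human_module), ]
  rownames(out) <- NULL
  attr(out, "n_unmapped_mouse_genes") <- n_unmapped
  class(out) <- unique(c("module_pair_test", class(out)))
  out
}

#' Module-pair overlap with both species' DEG sets
#'
#' For one module pair, reports the ortholog-mapped intersection of the
#' two modules' gene members, and its further intersection with both
#' species' DEG sets for the relevant cell type (the conserved
#' dysregulated core, as drawn in four-way Venn summaries).
#'
#' @param pair one row of a `module_pair_test` (or a list with
#'   `mouse_module` / `human_module`).
#' @param mouse_modules,human_modules `module_set` objects.
#' @param degs_mouse,degs_human [deg_table()] objects (already filtered
#'   to the relevant cell type, or filtered here via `cell_type`).
#' @param map an [ortholog_map()].
#' @param cell_type optional cell type to filter the DEG tables to.
#' @return list of class `overlap_report`: `overlap_genes_module_only`,
#'   `overlap_genes_with_degs` (data frame with both species' symbols
#'   and directions), and counts.
#' @export
overlap_with_degs <- function(pair, mouse_modules, human_modules,
                              degs_mouse, degs_human, map,
                              cell_type = NULL) {
  mm <- pair$mouse_module[1]; hm <- pair$human_module[1]
  m_genes <- names(mouse_modules$assignment)[
    mouse_modules$assignment == mm]
  h_genes <- names(human_modules$assignment)[
    human_modules$assignment == hm]
  m_mapped <- map_orthologs(m_genes, map, "mouse")
  ok <- !is.na(m_mapped)
  module_overlap <- intersect(m_mapped[ok], h_genes)
  filt <- function(d, ct) {
    if (!is.null(ct)) d <- d[d$cell_type == ct, , drop = FALSE]
    d
  }
  dm <- filt(degs_mouse, cell_type)
  dh <- filt(degs_human, cell_type)
  dm_h <- map_orthologs(dm$gene, map, "mouse")
  core <- intersect(module_overlap, intersect(dm_h[!is.na(dm_h)],
                                              dh$gene))
  inv <- map_orthologs(core, map, "human")
  df <- data.frame(
    human_symbol = core, mouse_symbol = inv,
    mouse_direction = dm$direction[match(inv, dm$gene)],
    human_direction = dh$direction[match(core, dh$gene)],
    stringsAsFactors = FALSE
  )
  df <- df[order(df$human_symbol), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(mouse_module = mm, human_module = hm,
                 overlap_genes_module_only = sort(module_overlap),
                 overlap_genes_with_degs = df,
                 n_module_overlap = length(module_overlap),
                 n_deg_overlap = nrow(df)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("overlap_report ", x$mouse_module, " x ", x$human_module, ": ",
      x$n_module_overlap, " shared module genes, ", x$n_deg_overlap,
      " also DE in both species\n", sep = "")
  invisible(x)
}
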