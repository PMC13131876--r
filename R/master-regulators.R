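#' Read a published master-regulator summary table
#'
#' Reads a TSV with one row per cross-species TF: human/mouse symbols,
#' per-species downstream-DEG counts, and the comma-separated list of
#' overlapping downstream DEGs (human symbols). A curated copy of such a
#' table ships with the package
#' (`system.file("extdata", "master_regulator_table.tsv", package =
#' "xnetconserve")`).
#'
#' @param path path to the TSV (default: the bundled table).
#' @return data frame with `overlap_genes` parsed into a list-column.
#' @export
read_master_regulator_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "master_regulator_table.tsv",
                        package = "xnetconserve")
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$overlap_genes <- lapply(strsplit(df$overlap_genes, ","), trim_ws)
  df
}

#' Expand a master-regulator summary into analysis-ready fixtures
#'
#' Reconstructs, for each TF row, per-species GRN edge sets and DEG
#' tables consistent with the printed counts: the listed overlapping
#' genes are downstream DEGs in both species (mouse symbols derived by
#' the Title-case convention), padded with species-private synthetic
#' filler genes up to the printed per-species totals. Filler genes are
#' absent from the ortholog map, so the only cross-species overlap the
#' regulon machinery can recover is the printed gene list. Useful for
#' validating the cross-species TF intersection on a published table.
#'
#' @param table data frame from [read_master_regulator_table()].
#' @param cell_type cell type label given to the reconstructed networks.
#' @return list with `grn_mouse`, `grn_human` ([grn_edge_set()]),
#'   `degs_mouse`, `degs_human` ([deg_table()]), and `map`
#'   ([ortholog_map()]).
#' @export
master_regulator_fixture <- function(table = read_master_regulator_table(),
                                     cell_type = "cortex") {
  title_case <- function(x) paste0(toupper(substr(x, 1, 1)),
                                   tolower(substr(x, 2, nchar(x))))
  map_h <- unique(unlist(table$overlap_genes))
  map_m <- title_case(map_h)
  map <- ortholog_map(c(map_m, table$mouse_tf),
                      c(map_h, table$human_tf))
  m_tf <- m_tg <- h_tf <- h_tg <- character(0)
  m_deg <- h_deg <- character(0)
  for (i in seq_len(nrow(table))) {
    ov_h <- table$overlap_genes[[i]]
    ov_m <- title_case(ov_h)
    n_fill_m <- table$n_mouse_degs[i] - length(ov_h)
    n_fill_h <- table$n_human_degs[i] - length(ov_h)
    fill_m <- sprintf("%s.priv%03d", table$mouse_tf[i],
                      seq_len(n_fill_m))
    fill_h <- sprintf("%s.PRIV%03d", table$human_tf[i],
                      seq_len(n_fill_h))
    tg_m <- c(ov_m, fill_m)
    tg_h <- c(ov_h, fill_h)
    m_tf <- c(m_tf, rep(table$mouse_tf[i], length(tg_m)))
    m_tg <- c(m_tg, tg_m)
    h_tf <- c(h_tf, rep(table$human_tf[i], length(tg_h)))
    h_tg <- c(h_tg, tg_h)
    m_deg <- union(m_deg, tg_m)
    h_deg <- union(h_deg, tg_h)
  }
  mk_deg <- function(genes) deg_table(data.frame(
    gene = genes, cell_type = cell_type, log2fc = 1,
    p_adjusted = 1e-3, stringsAsFactors = FALSE))
  list(
    grn_mouse = grn_edge_set(cell_type, m_tf, m_tg, "biccn_like"),
    grn_human = grn_edge_set(cell_type, h_tf, h_tg, "psychencode_like"),
    degs_mouse = mk_deg(m_deg),
    degs_human = mk_deg(h_deg),
    map = map
  )
}

#' Recompute the cross-species master-regulator table from fixtures
#'
#' Runs the full regulon overlay on the reconstructed fixtures: per-TF
#' downstream-DEG summaries per species, global ranking, and the
#' cross-species intersection table. With fixtures from
#' [master_regulator_fixture()], the recomputed overlap counts must
#' equal the printed ones.
#'
#' @param fixture output of [master_regulator_fixture()].
#' @param top_n ranking depth (default 20).
#' @return a `cross_species_tf_table`.
#' @export
master_regulator_overlap <- function(fixture, top_n = 20) {
  sm <- tf_deg_summaries(fixture$grn_mouse, fixture$degs_mouse,
                         species = "mouse")
  sh <- tf_deg_summaries(fixture$grn_human, fixture$degs_human,
                         species = "human")
  rm_ <- rank_tfs_global(sm)
  rh <- rank_tfs_global(sh)
  cross_species_tf_table(rm_$ranking, rh$ranking, fixture$map,
                         top_n = top_n)
}
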