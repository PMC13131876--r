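mk_degs <- function(genes, dirs, cell_type = "astro") {
  deg_table(data.frame(gene = genes, cell_type = cell_type,
                       log2fc = ifelse(dirs == "up", 1, -1),
                       p_adjusted = 0.001, stringsAsFactors = FALSE))
}

test_that("per-TF downstream DEG counting is plain set algebra", {
  grn <- grn_edge_set("astro",
                      tf = c("Tf1", "Tf1", "Tf1", "Tf2", "Tf3"),
                      target = c("A", "B", "C", "Z", "Tf3"))
  degs <- mk_degs(c("B", "C", "D", "Tf3"),
                  c("up", "down", "up", "up"))
  s <- tf_deg_summaries(grn, degs, species = "mouse")
  tf1 <- s[s$tf == "Tf1", ]
  expect_equal(tf1$n_downstream_degs, 2)
  expect_equal(tf1$n_up, 1)
  expect_equal(tf1$n_down, 1)
  expect_equal(tf1$frac_up, 0.5)
  # TF with no DEG targets is retained with zero counts
  tf2 <- s[s$tf == "Tf2", ]
  expect_equal(tf2$n_downstream_degs, 0)
  expect_false(tf2$tf_is_deg)
  # a DE-TF whose only (self-loop) target is excluded: flagged DE, n = 0
  tf3 <- s[s$tf == "Tf3", ]
  expect_true(tf3$tf_is_deg)
  expect_equal(tf3$n_downstream_degs, 0)
  # sorted by count descending, ties lexicographic
  expect_identical(s$tf, c("Tf1", "Tf2", "Tf3"))
})

test_that("edge-list row order never changes a summary", {
  set.seed(66)
  tfs <- sample(c("Tfa", "Tfb", "Tfc"), 60, replace = TRUE)
  targets <- sample(sprintf("G%02d", 1:25), 60, replace = TRUE)
  degs <- mk_degs(sprintf("G%02d", 1:12), rep("up", 12))
  g1 <- grn_edge_set("astro", tfs, targets)
  perm <- sample(length(g1$edges$tf))
  g2 <- grn_edge_set("astro", g1$edges$tf[perm], g1$edges$target[perm])
  expect_identical(tf_deg_summaries(g1, degs),
                   tf_deg_summaries(g2, degs))
})

test_that("global ranking sums across cell types with lexicographic ties", {
  g_astro <- grn_edge_set("astro", rep(c("Tfa", "Tfb"), each = 3),
                          c("A", "B", "C", "A", "B", "D"))
  g_micro <- grn_edge_set("micro", rep(c("Tfa", "Tfb"), each = 3),
                          c("E", "F", "G", "E", "F", "H"))
  degs <- deg_table(rbind(
    data.frame(gene = c("A", "B", "C"), cell_type = "astro",
               log2fc = 1, p_adjusted = 0.001),
    data.frame(gene = c("E", "F", "G", "H"), cell_type = "micro",
               log2fc = 1, p_adjusted = 0.001)))
  s <- rbind(tf_deg_summaries(g_astro, degs),
             tf_deg_summaries(g_micro, degs))
  rk <- rank_tfs_global(s)
  expect_equal(rk$ranking$total_downstream_degs[rk$ranking$tf == "Tfa"],
               3 + 3)
  expect_equal(rk$ranking$total_downstream_degs[rk$ranking$tf == "Tfb"],
               2 + 3)
  expect_identical(rk$ranking$tf, c("Tfa", "Tfb"))
  # exact tie: lexicographic order
  g_tie <- grn_edge_set("astro", c("Tfz", "Tfy"), c("A", "B"))
  rk2 <- rank_tfs_global(tf_deg_summaries(g_tie, degs))
  expect_identical(rk2$ranking$tf, c("Tfy", "Tfz"))
})

test_that("the cross-species table intersects ortholog-mapped DEG sets", {
  map <- ortholog_map(c("Apoe", "Cd86", "Mitf", "Grm3", "Tfa"),
                      c("APOE", "CD86", "MITF", "GRM3", "TFA"))
  m_rank <- data.frame(tf = "Tfa", total_downstream_degs = 3L,
                       n_celltypes = 1L, n_celltypes_tf_deg = 0L,
                       deg_genes_union =
                         I(list(c("Apoe", "Cd86", "Mitf"))))
  h_rank <- data.frame(tf = "TFA", total_downstream_degs = 3L,
                       n_celltypes = 1L, n_celltypes_tf_deg = 0L,
                       deg_genes_union =
                         I(list(c("APOE", "CD86", "GRM3"))))
  out <- cross_species_tf_table(m_rank, h_rank, map)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_overlap, 2)
  expect_setequal(out$overlap_genes[[1]], c("APOE", "CD86"))

  # a TF in only one species' top list yields no row
  h_other <- h_rank
  h_other$tf <- "TFB"
  expect_warning(out2 <- cross_species_tf_table(m_rank, h_other, map),
                 "pairable")
  expect_equal(nrow(out2), 0)
})

test_that("removing a DEG can only lower downstream counts", {
  set.seed(91)
  for (rep in 1:10) {
    tfs <- sample(c("Tfa", "Tfb", "Tfc", "Tfd"), 80, replace = TRUE)
    targets <- sample(sprintf("G%02d", 1:30), 80, replace = TRUE)
    grn <- grn_edge_set("astro", tfs, targets)
    genes <- sample(sprintf("G%02d", 1:30), 15)
    degs <- mk_degs(genes, sample(c("up", "down"), 15, replace = TRUE))
    full <- tf_deg_summaries(grn, degs)
    drop <- degs[degs$gene != sample(genes, 1), , drop = FALSE]
    reduced <- tf_deg_summaries(grn, drop)
    merged <- merge(full, reduced, by = "tf")
    expect_true(all(merged$n_downstream_degs.y <=
                      merged$n_downstream_degs.x))
  }
})

test_that("planted cross-species regulons pass through; private ones do not", {
  cfg <- synth_config(
    n_genes_shared = 120,
    cell_types = list(synth_cell_type("glia", 20),
                      synth_cell_type("neuron", 20)),
    regulons = list(
      planted_regulon("Tfmaster", 1:40, frac_targets_de = 0.9),
      planted_regulon("Tfminor", 41:60, frac_targets_de = 0.3,
                      cell_types = "glia"),
      planted_regulon("Tfmouse", 61:100, frac_targets_de = 0.9,
                      species_scope = "mouse_only")),
    seed = 13)
  ds <- generate_dataset(cfg)
  degs <- emit_truth_deg_table(ds$truth)
  map <- synth_ortholog_map(cfg)
  sm <- do.call(rbind, lapply(synth_grn_edge_sets(cfg, "mouse"),
                              tf_deg_summaries, degs = degs$mouse,
                              species = "mouse"))
  sh <- do.call(rbind, lapply(synth_grn_edge_sets(cfg, "human"),
                              tf_deg_summaries, degs = degs$human,
                              species = "human"))
  rk_m <- rank_tfs_global(sm)
  rk_h <- rank_tfs_global(sh)
  out <- cross_species_tf_table(rk_m$ranking, rk_h$ranking, map)
  expect_true("Tfmaster" %in% out$mouse_tf)
  expect_false("Tfmouse" %in% out$mouse_tf)
  expect_equal(out$mouse_tf[1], "Tfmaster")
  # overlap bound holds on every row
  expect_true(all(out$n_overlap <=
                    pmin(out$n_mouse_downstream_degs,
                         out$n_human_downstream_degs)))
})

test_that("dot-plot long table mirrors the summaries", {
  grn <- grn_edge_set("astro", c("Tf1", "Tf1"), c("A", "B"))
  degs <- mk_degs(c("A", "B"), c("up", "down"))
  s <- tf_deg_summaries(grn, degs)
  long <- tf_target_dotplot_table(s, degs)
  expect_equal(nrow(long), 2)
  expect_setequal(long$direction, c("up", "down"))
})
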