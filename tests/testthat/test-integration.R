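test_that("standardized variance ranks flat genes last, ties lexicographic", {
  counts <- rbind(
    Zflat = rep(3, 20),
    Bvar  = c(rep(0, 10), rep(6, 10)),
    Avar  = c(rep(0, 10), rep(6, 10))
  )
  sv <- standardized_variance(Matrix::Matrix(counts, sparse = TRUE))
  expect_equal(unname(sv["Zflat"]), 0)
  expect_equal(unname(sv["Avar"]), unname(sv["Bvar"]))

  map <- ortholog_map(c("Zflat", "Bvar", "Avar"),
                      c("ZFLAT", "BVAR", "AVAR"))
  lcm <- labeled_counts(counts, rownames(counts),
                        paste0("m", 1:20), "mouse")
  hc <- counts
  rownames(hc) <- c("ZFLAT", "BVAR", "AVAR")
  lch <- labeled_counts(hc, rownames(hc), paste0("h", 1:20), "human")
  expect_warning(
    vg <- select_variable_genes(lcm, lch, map,
                                integration_config(n_anchor_features = 5)),
    "returning all"
  )
  # ties broken lexicographically by (human) symbol; flat gene last
  expect_identical(vg, c("AVAR", "BVAR", "ZFLAT"))
})

test_that("planted high-loading module genes rank among the top variable genes", {
  cfg <- synth_config(
    n_genes_shared = 500, n_genes_private_per_species = 0,
    cell_types = list(synth_cell_type("glia", 150)),
    modules = list(planted_module("m", 1:25, "glia", loading_sd = 1.5)),
    seed = 21)
  ds <- generate_dataset(cfg)
  map <- synth_ortholog_map(cfg)
  vg <- select_variable_genes(ds$mouse, ds$human, map,
                              integration_config(n_anchor_features = 500))
  ranks <- match(toupper(sprintf("Shrg%04d", 1:25)), vg)
  expect_true(all(ranks <= 50))   # top 10% of 500
})

test_that("integrating a dataset with its own relabelled copy aligns pairs", {
  cfg <- synth_config(
    n_genes_shared = 80, n_genes_private_per_species = 0,
    cell_types = list(synth_cell_type("glia", 40),
                      synth_cell_type("neuron", 40)),
    seed = 31)
  ds <- generate_dataset(cfg)
  # human copy = mouse counts with human symbols/ids
  human <- labeled_counts(ds$mouse$counts,
                          toupper(ds$mouse$gene_ids),
                          sub("^mouse", "human", ds$mouse$cell_ids),
                          "human")
  map <- synth_ortholog_map(cfg)
  ic <- integration_config(n_anchor_features = 80, n_cca_dims = 10,
                           k_mnn = 1, subsample_to_match = FALSE)
  vg <- select_variable_genes(ds$mouse, human, map, ic)
  res <- integrate_datasets(ds$mouse, human, vg, map, ic)
  n <- length(ds$mouse$cell_ids)
  emb_m <- res$embedding[seq_len(n), ]
  emb_h <- res$embedding[n + seq_len(n), ]
  # every cell anchors to its own copy and correction leaves it in place
  expect_true(all(sqrt(rowSums((emb_m - emb_h)^2)) < 1e-6))
})

test_that("shared types mix across species while a private type stays apart", {
  cfg <- private_pop_config(1, ct_marker_frac = 0.1,
                            ct_marker_shift = 2.5)
  ds <- generate_dataset(cfg)
  map <- synth_ortholog_map(cfg)
  ic <- small_integration_config()
  vg <- select_variable_genes(ds$mouse, ds$human, map, ic)
  res <- integrate_datasets(ds$mouse, ds$human, vg, map, ic,
                            metadata = ds$metadata, seed = 1)
  labs <- cluster_sweep(res$embedding,
                        cluster_sweep_config(graph_k = 15), seed = 1)
  md <- ds$metadata
  best_purity <- 0
  glia_entropy <- 0
  for (rn in names(labs)) {
    lab <- labs[[rn]]
    m2 <- md[match(names(lab), md$cell_id), ]
    host <- names(which.max(table(lab[m2$cell_type ==
                                        "mouse_private"])))
    best_purity <- max(best_purity,
                       mean(m2$species[lab == host] == "mouse"))
    ghost <- names(which.max(table(lab[m2$cell_type == "glia"])))
    p <- mean(m2$species[lab == ghost] == "mouse")
    ent <- if (p %in% c(0, 1)) 0 else -p * log2(p) - (1 - p) * log2(1 - p)
    glia_entropy <- max(glia_entropy, ent)
  }
  expect_gt(glia_entropy, 0.5)     # shared type mixes
  expect_gt(best_purity, 0.9)      # private type stays mouse
})

test_that("cluster sweep finds exactly two well-separated blobs", {
  set.seed(5)
  emb <- rbind(matrix(rnorm(100 * 5), 100, 5),
               matrix(rnorm(100 * 5, mean = 10), 100, 5))
  rownames(emb) <- paste0("c", 1:200)
  labs <- cluster_sweep(emb, cluster_sweep_config(graph_k = 30),
                        seed = 1)
  for (lab in labs) {
    expect_equal(length(unique(lab)), 2)
    expect_equal(length(unique(lab[1:100])), 1)
  }
  # single-resolution list and determinism
  one <- cluster_sweep(emb, cluster_sweep_config(resolutions = 0.1,
                                                 graph_k = 10),
                       seed = 3)
  expect_length(one, 1)
  two <- cluster_sweep(emb, cluster_sweep_config(resolutions = 0.1,
                                                 graph_k = 10),
                       seed = 3)
  expect_identical(one, two)
  expect_error(cluster_sweep(matrix(c(1, NA), 2, 1)), "non-finite")
})

test_that("composition flags apply the strict >60% rule per marginal", {
  md <- cell_metadata(data.frame(
    cell_id = paste0("c", 1:200),
    species = rep(c("mouse", "human"), c(130, 70)),
    condition = rep(c("control", "alcohol", "control", "alcohol"),
                    c(65, 65, 35, 35)),
    cell_type = "glia",
    sample_id = "s1"))
  # cluster 1: 70 mouse + 30 human -> species_specific:mouse
  # cluster 2: 60 mouse + 40 human -> 0.60 is not > 0.60, no flag
  lab <- c(rep(1L, 70), rep(2L, 60), rep(1L, 30), rep(2L, 40))
  names(lab) <- c(paste0("c", 1:130), paste0("c", 131:200))
  comp <- composition_and_flags(list(res_0.1 = lab), md)
  expect_match(comp$flags[comp$cluster == 1], "species_specific:mouse")
  expect_false(grepl("species_specific",
                     comp$flags[comp$cluster == 2]))
  expect_equal(comp$frac_mouse[comp$cluster == 2], 0.6)
  # fractions sum to one per cluster
  expect_equal(comp$frac_mouse + comp$frac_human, c(1, 1))
  expect_equal(comp$frac_mouse_control + comp$frac_mouse_alcohol +
                 comp$frac_human_control + comp$frac_human_alcohol,
               c(1, 1), tolerance = 1e-9)
})

test_that("a nearly pure human-alcohol cluster gets both flags", {
  md <- cell_metadata(data.frame(
    cell_id = paste0("c", 1:100),
    species = rep(c("human", "mouse"), c(96, 4)),
    condition = rep(c("alcohol", "control"), c(96, 4)),
    cell_type = "microglia", sample_id = "s1"))
  lab <- stats::setNames(rep(1L, 100), paste0("c", 1:100))
  comp <- composition_and_flags(list(res_0.3 = lab), md)
  expect_match(comp$flags, "species_specific:human")
  expect_match(comp$flags, "condition_specific:alcohol")
})

test_that("marker detection applies both cutoffs strictly", {
  set.seed(8)
  n <- 60
  counts <- matrix(rpois(20 * n, 2), 20, n)
  counts[1, 1:30] <- rpois(30, 30)       # strong cluster-1 marker
  rownames(counts) <- paste0("g", 1:20)
  labels <- rep(c(1, 2), each = 30)
  all_rows <- find_cluster_markers(counts, labels, filter = FALSE)
  kept <- find_cluster_markers(counts, labels, filter = TRUE)
  manual <- all_rows[all_rows$log2fc > 0.25 &
                       all_rows$p_adjusted < 0.01, ]
  rownames(manual) <- NULL
  expect_identical(kept, manual)
  expect_true(any(kept$gene == "g1" & kept$cluster == 1))
  # tiny clusters are skipped with a warning
  expect_warning(
    find_cluster_markers(counts, c(rep(1, 58), 2, 2), filter = FALSE),
    "skipped")
})
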