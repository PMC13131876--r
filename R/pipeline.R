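#' Default pipeline configuration with provenance tags
#' @noRd
default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = "xnetconserve_out",
    paths = list(mouse_dir = NULL, human_dir = NULL, ortholog_map = NULL,
                 degs_mouse = NULL, degs_human = NULL,
                 grn_mouse_dir = NULL, grn_human_dir = NULL),
    integration = list(n_anchor_features = 2000L, n_cca_dims = 30L,
                       k_mnn = 5L, k_score = 30L,
                       subsample_to_match = TRUE),
    clustering = list(resolutions = seq(0.1, 0.8, by = 0.1),
                      graph_k = 20L, algorithm = "louvain"),
    composition = list(specificity_threshold = 0.60),
    markers = list(min_log2fc = 0.25, max_p_adjusted = 0.01),
    soft_power = list(target_r2 = 0.8, candidate_powers = 1:20,
                      network_type = "signed"),
    modules = list(metacell_k = 25L, max_overlap = 0, n_pcs = 20L,
                   min_module_size = 30L, merge_height = 0.25,
                   q_consensus = 0),
    conservation = list(alpha = 0.05, top_k_hubs = 10L),
    regulons = list(top_n = 20L, exclude_self_loops = TRUE)
  )
}

#' Provenance tags separating method-defined defaults from conventions
#' @noRd
config_provenance <- function() {
  c("integration.n_anchor_features" =
      "method (top 2,000 variable genes)",
    "clustering.resolutions" = "method (0.1-0.8 in increments of 0.1)",
    "clustering.algorithm" = "method (default Louvain)",
    "composition.specificity_threshold" = "method (more than 60%)",
    "markers.min_log2fc" = "method (log2 fold change > 0.25)",
    "markers.max_p_adjusted" = "method (adjusted p-value < 0.01)",
    "soft_power.target_r2" =
      "method (0.8 read as the scale-free fit target)",
    "conservation.alpha" =
      "convention (module eigengene test at adjusted p < 0.05)")
}

#' Validate and default-fill a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a list. Unknown keys are a hard
#' error; all range violations are collected and reported together. The
#' returned config is fully defaulted and carries a `provenance`
#' attribute tagging which defaults come from the published method
#' description versus field convention.
#'
#' @param config path to a YAML or JSON file, or a (possibly partial)
#'   config list; `NULL` gives the all-defaults config.
#' @return validated `pipeline_config` list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    if (is.null(config)) config <- list()
  }
  config <- config %||% list()
  defaults <- default_pipeline_config()
  errors <- character(0)
  unknown_top <- setdiff(names(config), names(defaults))
  if (length(unknown_top)) {
    errors <- c(errors, paste0("unknown top-level key(s): ",
                               paste(unknown_top, collapse = ", ")))
  }
  merged <- defaults
  for (k in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      unknown <- setdiff(names(config[[k]]), names(defaults[[k]]))
      if (length(unknown)) {
        errors <- c(errors, paste0("unknown key(s) under '", k, "': ",
                                   paste(unknown, collapse = ", ")))
      }
      for (kk in intersect(names(config[[k]]), names(defaults[[k]]))) {
        merged[[k]][[kk]] <- config[[k]][[kk]]
      }
    } else {
      merged[[k]] <- config[[k]]
    }
  }
  chk <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)
  ig <- merged$integration
  chk(all(c(ig$n_anchor_features, ig$n_cca_dims, ig$k_mnn,
            ig$k_score) > 0),
      "integration sizes must all be positive")
  cl <- merged$clustering
  chk(all(cl$resolutions > 0) &&
        !is.unsorted(cl$resolutions, strictly = TRUE),
      "clustering.resolutions must be strictly increasing and positive")
  chk(cl$algorithm %in% c("louvain", "leiden"),
      "clustering.algorithm must be 'louvain' or 'leiden'")
  sp_thr <- merged$composition$specificity_threshold
  chk(sp_thr > 0.5 && sp_thr <= 1,
      "composition.specificity_threshold must lie in (0.5, 1]")
  mk <- merged$markers
  chk(mk$min_log2fc >= 0, "markers.min_log2fc must be >= 0")
  chk(mk$max_p_adjusted > 0 && mk$max_p_adjusted < 1,
      "markers.max_p_adjusted must lie in (0, 1)")
  spw <- merged$soft_power
  chk(spw$target_r2 > 0 && spw$target_r2 <= 1,
      "soft_power.target_r2 must lie in (0, 1]")
  chk(spw$network_type %in% c("signed", "unsigned"),
      "soft_power.network_type must be 'signed' or 'unsigned'")
  md <- merged$modules
  chk(md$metacell_k >= 2, "modules.metacell_k must be >= 2")
  chk(md$max_overlap >= 0 && md$max_overlap <= 1,
      "modules.max_overlap must lie in [0, 1]")
  chk(md$min_module_size >= 2, "modules.min_module_size must be >= 2")
  cs <- merged$conservation
  chk(cs$alpha > 0 && cs$alpha < 1,
      "conservation.alpha must lie in (0, 1)")
  chk(cs$top_k_hubs >= 1, "conservation.top_k_hubs must be >= 1")
  chk(merged$regulons$top_n >= 1, "regulons.top_n must be >= 1")
  if (length(errors)) {
    stop("invalid pipeline configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  attr(merged, "provenance") <- config_provenance()
  class(merged) <- "pipeline_config"
  merged
}

#' Built-in demonstration dataset configuration
#'
#' A compact two-species design with two shared cell types plus a
#' mouse-private population, two planted conserved modules (one with a
#' condition shift), and three regulons including a cross-cell-type
#' master regulator and a mouse-only regulon.
#'
#' @param seed generator seed.
#' @return a [synth_config()].
#' @export
demo_synth_config <- function(seed = 1) {
  synth_config(
    n_genes_shared = 300, n_genes_private_per_species = 20,
    cell_types = list(synth_cell_type("glia", 120),
                      synth_cell_type("neuron", 60),
                      synth_cell_type("mouse_private", 40,
                                      species = "mouse")),
    n_samples_per_group = 2,
    modules = list(
      planted_module("shifted", 1:30, "glia", loading_sd = 0.6,
                     condition_shift = 2, conserved = TRUE),
      planted_module("stable", 31:60, "glia", loading_sd = 0.6,
                     condition_shift = 0, conserved = TRUE)
    ),
    regulons = list(
      planted_regulon("Tfmaster", 101:140, frac_targets_de = 0.8,
                      species_scope = "both",
                      cell_types = c("glia", "neuron")),
      planted_regulon("Tfshared", 141:160, frac_targets_de = 0.4,
                      species_scope = "both", cell_types = "glia"),
      planted_regulon("Tfmouse", 161:180, frac_targets_de = 0.8,
                      species_scope = "mouse_only", cell_types = "glia")
    ),
    nb_dispersion = 2, seed = seed
  )
}

#' Run the full cross-species pipeline
#'
#' Orchestrates the stages in dependency order — integrate (joint
#' embedding, resolution-sweep clustering, composition flags, markers),
#' modules (metacells, consensus modules, eigengene DE), conserve
#' (cross-species module matching and DEG overlap), regulons (TF
#' summaries, rankings, cross-species table) — writing every output as
#' TSV/JSON plus a run manifest with file hashes, seed, parameters, and
#' stage wall-times. With `demo = TRUE` the inputs are generated by
#' [demo_synth_config()] first.
#'
#' @param config a [validate_config()] result (or anything it accepts).
#' @param stages subset of `c("integrate", "modules", "conserve",
#'   "regulons")` or `"all"`.
#' @param demo generate and analyse the built-in synthetic demo dataset.
#' @param module_cell_type cell type used for module construction
#'   (default `"glia"` in demo mode).
#' @return the manifest (invisibly written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config = NULL, stages = "all", demo = FALSE,
                         module_cell_type = "glia") {
  config <- validate_config(config)
  if (identical(stages, "all")) {
    stages <- c("integrate", "modules", "conserve", "regulons")
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_times <- list()
  tick <- function(name, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    stage_times[[name]] <<- as.numeric(difftime(Sys.time(), t0,
                                                units = "secs"))
    res
  }
  if (demo) {
    sc <- demo_synth_config(seed = config$seed)
    ds <- tick("generate", generate_dataset(sc))
    mouse <- ds$mouse; human <- ds$human; metadata <- ds$metadata
    map <- synth_ortholog_map(sc)
    degs <- emit_truth_deg_table(ds$truth)
    grn_paths <- emit_grn_files(sc, file.path(out_dir, "inputs"))
    grn_mouse <- lapply(grn_paths$mouse, read_grn_edges,
                        dialect = "biccn_like")
    grn_human <- lapply(grn_paths$human, read_grn_edges,
                        dialect = "psychencode_like")
  } else {
    p <- config$paths
    need <- c("mouse_dir", "human_dir", "ortholog_map")
    if (any(c("conserve", "regulons") %in% stages)) {
      need <- c(need, "degs_mouse", "degs_human")
    }
    if ("regulons" %in% stages) {
      need <- c(need, "grn_mouse_dir", "grn_human_dir")
    }
    missing_paths <- need[vapply(need, function(k)
      is.null(p[[k]]) || !file.exists(p[[k]]), TRUE)]
    if (length(missing_paths)) {
      stop("missing or nonexistent input path(s): ",
           paste(missing_paths, collapse = ", "), call. = FALSE)
    }
    read_dir <- function(dir, species) {
      read_counts(list.files(dir, "matrix\\.mtx$", full.names = TRUE)[1],
                  list.files(dir, "genes\\.tsv$", full.names = TRUE)[1],
                  list.files(dir, "barcodes\\.tsv$",
                             full.names = TRUE)[1],
                  species)
    }
    mouse <- read_dir(p$mouse_dir, "mouse")
    human <- read_dir(p$human_dir, "human")
    md_path <- c(list.files(p$mouse_dir, "metadata\\.csv$",
                            full.names = TRUE),
                 list.files(p$human_dir, "metadata\\.csv$",
                            full.names = TRUE))
    if (!length(md_path)) {
      stop("no metadata.csv found next to the count matrices",
           call. = FALSE)
    }
    metadata <- cell_metadata(do.call(rbind,
                                      lapply(md_path, utils::read.csv)))
    map <- read_ortholog_map(p$ortholog_map)
    degs <- grn_mouse <- grn_human <- NULL
    if (any(c("conserve", "regulons") %in% stages)) {
      degs <- list(mouse = read_deg_table(p$degs_mouse),
                   human = read_deg_table(p$degs_human))
    }
    if ("regulons" %in% stages) {
      grn_mouse <- lapply(list.files(p$grn_mouse_dir, "_GRN\\.txt$",
                                     full.names = TRUE),
                          read_grn_edges, dialect = "biccn_like")
      grn_human <- lapply(list.files(p$grn_human_dir, "_GRN\\.txt$",
                                     full.names = TRUE),
                          read_grn_edges, dialect = "psychencode_like")
    }
  }
  if ("integrate" %in% stages) {
    tick("integrate", {
      ic <- do.call(integration_config, config$integration)
      vg <- select_variable_genes(mouse, human, map, ic)
      emb <- integrate_datasets(mouse, human, vg, map, ic,
                                metadata = metadata, seed = config$seed)
      cc <- do.call(cluster_sweep_config, config$clustering)
      labels <- cluster_sweep(emb$embedding, cc, seed = config$seed)
      comp <- composition_and_flags(
        labels, metadata,
        do.call(composition_flag_config, config$composition))
      utils::write.csv(data.frame(cell_id = rownames(emb$embedding),
                                  emb$embedding),
                       file.path(out_dir, "embedding.csv"),
                       row.names = FALSE)
      lab_df <- data.frame(cell_id = rownames(emb$embedding),
                           do.call(cbind, labels))
      write_report_tsv(lab_df, file.path(out_dir, "cluster_labels.tsv"))
      write_report_tsv(comp, file.path(out_dir, "composition.tsv"))
      NULL
    })
  }
  module_sets <- NULL; de_res <- NULL
  if ("modules" %in% stages) {
    tick("modules", {
      spc <- do.call(soft_power_config, config$soft_power)
      cmp <- consensus_module_pipeline(
        mouse, human, metadata, map, module_cell_type,
        metacell_k = if (demo) min(config$modules$metacell_k, 10)
                     else config$modules$metacell_k,
        max_overlap = config$modules$max_overlap,
        n_pcs = config$modules$n_pcs,
        soft_power = spc,
        min_module_size = if (demo)
          min(config$modules$min_module_size, 20)
          else config$modules$min_module_size,
        merge_height = config$modules$merge_height,
        q_consensus = config$modules$q_consensus,
        n_hubs = config$conservation$top_k_hubs)
      module_sets <- cmp$module_sets
      de_res <- cmp$de
      ms_m <- module_sets$mouse; ms_h <- module_sets$human
      write_report_tsv(
        data.frame(gene = names(cmp$assignment),
                   module = cmp$assignment),
        file.path(out_dir, "module_assignment.tsv"))
      utils::write.csv(data.frame(metacell = rownames(ms_m$eigengenes),
                                  ms_m$eigengenes),
                       file.path(out_dir, "eigengenes_mouse.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(metacell = rownames(ms_h$eigengenes),
                                  ms_h$eigengenes),
                       file.path(out_dir, "eigengenes_human.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(mouse = module_sets$mouse$hub_genes,
             human = module_sets$human$hub_genes),
        file.path(out_dir, "hub_genes.json"), auto_unbox = FALSE)
      write_report_tsv(de_res, file.path(out_dir, "module_de.tsv"))
      NULL
    })
  }
  if ("conserve" %in% stages && !is.null(module_sets)) {
    tick("conserve", {
      pairs <- match_modules(module_sets$mouse, module_sets$human, map,
                             de_res,
                             alpha = config$conservation$alpha,
                             top_k_hubs = config$conservation$top_k_hubs)
      write_report_tsv(pairs, file.path(out_dir, "module_pairs.tsv"))
      if (nrow(pairs)) {
        rep1 <- overlap_with_degs(pairs[1, ], module_sets$mouse,
                                  module_sets$human, degs$mouse,
                                  degs$human, map,
                                  cell_type = module_cell_type)
        jsonlite::write_json(
          list(mouse_module = rep1$mouse_module,
               human_module = rep1$human_module,
               overlap_genes_module_only =
                 rep1$overlap_genes_module_only,
               overlap_genes_with_degs = rep1$overlap_genes_with_degs),
          file.path(out_dir, "top_pair_overlap.json"),
          dataframe = "rows")
      }
      NULL
    })
  }
  if ("regulons" %in% stages) {
    tick("regulons", {
      sum_m <- do.call(rbind, lapply(grn_mouse, function(g)
        tf_deg_summaries(g, degs$mouse, species = "mouse",
                         exclude_self_loops =
                           config$regulons$exclude_self_loops)))
      sum_h <- do.call(rbind, lapply(grn_human, function(g)
        tf_deg_summaries(g, degs$human, species = "human",
                         exclude_self_loops =
                           config$regulons$exclude_self_loops)))
      rk_m <- rank_tfs_global(sum_m)
      rk_h <- rank_tfs_global(sum_h)
      cross <- cross_species_tf_table(rk_m$ranking, rk_h$ranking, map,
                                      top_n = config$regulons$top_n)
      write_report_tsv(sum_m[, setdiff(names(sum_m), "deg_genes")],
                       file.path(out_dir, "tf_summaries_mouse.tsv"))
      write_report_tsv(sum_h[, setdiff(names(sum_h), "deg_genes")],
                       file.path(out_dir, "tf_summaries_human.tsv"))
      write_report_tsv(rk_m$by_cell_type,
                       file.path(out_dir, "tf_ranking_mouse.tsv"))
      write_report_tsv(rk_h$by_cell_type,
                       file.path(out_dir, "tf_ranking_human.tsv"))
      write_report_tsv(cross,
                       file.path(out_dir, "cross_species_tfs.tsv"))
      jsonlite::write_json(
        lapply(seq_len(nrow(cross)), function(i)
          list(human_tf = cross$human_tf[i],
               mouse_tf = cross$mouse_tf[i],
               n_overlap = cross$n_overlap[i],
               overlap_genes = cross$overlap_genes[[i]])),
        file.path(out_dir, "cross_species_tfs.json"))
      NULL
    })
  }
  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   "manifest.json")
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    seed = config$seed,
    stages = stages,
    parameters = unclass(config),
    stage_wall_times_sec = stage_times,
    files = data.frame(
      path = files,
      md5 = unname(tools::md5sum(file.path(out_dir, files))),
      stringsAsFactors = FALSE
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
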