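#' Declare a synthetic cell type
#'
#' @param name cell type label.
#' @param n_cells_per_group cells per species x condition group.
#' @param species `"both"`, `"mouse"`, or `"human"` — which species carry
#'   this population (a single-species value plants a species-private
#'   subpopulation).
#' @return a `synth_cell_type` list.
#' @export
synth_cell_type <- function(name, n_cells_per_group,
                            species = c("both", "mouse", "human")) {
  species <- match.arg(species)
  structure(list(name = as.character(name),
                 n_cells_per_group = as.integer(n_cells_per_group),
                 species = species),
            class = "synth_cell_type")
}

#' Declare a planted co-expression module
#'
#' Module genes load on a shared per-cell latent factor (the planted
#' eigengene), which is mean-shifted in alcohol cells of the module's cell
#' type by `condition_shift` eigengene standard deviations.
#'
#' @param name module label in the truth record.
#' @param gene_indices indices into the shared gene set.
#' @param cell_type cell type in which the condition shift applies.
#' @param loading_sd scale of the per-gene log-space loadings (> 0).
#' @param condition_shift eigengene mean shift in the alcohol group, in
#'   eigengene SD units (0 = no condition effect).
#' @param conserved plant the module in both species (`TRUE`) or in mouse
#'   only (`FALSE`).
#' @return a `planted_module` list.
#' @export
planted_module <- function(name, gene_indices, cell_type,
                           loading_sd = 0.5, condition_shift = 0,
                           conserved = TRUE) {
  stopifnot(loading_sd > 0, length(gene_indices) >= 1)
  structure(list(name = as.character(name),
                 gene_indices = as.integer(gene_indices),
                 cell_type = as.character(cell_type),
                 loading_sd = loading_sd,
                 condition_shift = condition_shift,
                 conserved = isTRUE(conserved)),
            class = "planted_module")
}

#' Declare a planted TF regulon
#'
#' @param tf_symbol mouse-convention TF symbol (human symbol is its
#'   upper-case ortholog).
#' @param target_indices indices into the shared gene set.
#' @param frac_targets_de fraction of targets designated differentially
#'   expressed in the truth DEG tables (deterministic rounding:
#'   `floor(frac * n)` plus a seeded Bernoulli remainder).
#' @param species_scope `"both"`, `"mouse_only"`, or `"human_only"`.
#' @param cell_types cell types whose GRN files carry this regulon
#'   (default: all cell types in the config).
#' @return a `planted_regulon` list.
#' @export
planted_regulon <- function(tf_symbol, target_indices,
                            frac_targets_de = 0.5,
                            species_scope = c("both", "mouse_only",
                                              "human_only"),
                            cell_types = NULL) {
  species_scope <- match.arg(species_scope)
  stopifnot(frac_targets_de >= 0, frac_targets_de <= 1)
  structure(list(tf_symbol = as.character(tf_symbol),
                 target_indices = as.integer(target_indices),
                 frac_targets_de = frac_targets_de,
                 species_scope = species_scope,
                 cell_types = cell_types),
            class = "planted_regulon")
}

#' Configuration for the two-species synthetic dataset generator
#'
#' Counts follow a negative-binomial log-link latent factor model: for
#' gene g in cell c, counts ~ NB(mean = exp(b_g + t_{g,type(c)} +
#' sum_m l_{gm} e_{mc}), dispersion), where b_g is a gene base level
#' shared between species for orthologous genes, t is a cell-type marker
#' offset, l are module loadings and e per-cell module eigengenes.
#'
#' @param n_genes_shared number of orthologous genes shared by the species.
#' @param n_genes_private_per_species extra genes unique to each species
#'   (module-free noise).
#' @param cell_types list of [synth_cell_type()].
#' @param n_samples_per_group biological replicates per species x
#'   condition group.
#' @param modules list of [planted_module()]; gene sets must be disjoint.
#' @param regulons list of [planted_regulon()].
#' @param nb_dispersion negative-binomial size parameter (> 0; smaller =
#'   noisier).
#' @param base_mean_log_range range of per-gene base log-means, sampled
#'   uniformly.
#' @param ct_marker_frac fraction of shared genes up-shifted as markers of
#'   each cell type.
#' @param ct_marker_shift log-mean shift applied to cell type marker genes.
#' @param seed integer seed; fully determines the generated data.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_genes_shared = 300,
                         n_genes_private_per_species = 20,
                         cell_types = list(synth_cell_type("typeA", 100)),
                         n_samples_per_group = 2,
                         modules = list(),
                         regulons = list(),
                         nb_dispersion = 2,
                         base_mean_log_range = c(log(0.5), log(3)),
                         ct_marker_frac = 0.05,
                         ct_marker_shift = 1.5,
                         seed = 1) {
  stopifnot(n_genes_shared >= 1, n_genes_private_per_species >= 0,
            length(cell_types) >= 1, n_samples_per_group >= 1,
            nb_dispersion > 0, length(base_mean_log_range) == 2,
            base_mean_log_range[1] <= base_mean_log_range[2])
  all_idx <- unlist(lapply(modules, `[[`, "gene_indices"))
  if (anyDuplicated(all_idx)) {
    stop("planted module gene sets overlap", call. = FALSE)
  }
  if (length(all_idx) && max(all_idx) > n_genes_shared) {
    stop("module gene indices exceed the shared gene range", call. = FALSE)
  }
  reg_idx <- unlist(lapply(regulons, `[[`, "target_indices"))
  if (length(reg_idx) && max(reg_idx) > n_genes_shared) {
    stop("regulon target indices exceed the shared gene range",
         call. = FALSE)
  }
  ct_names <- vapply(cell_types, `[[`, "", "name")
  if (anyDuplicated(ct_names)) stop("duplicate cell type names",
                                    call. = FALSE)
  regulons <- lapply(regulons, function(r) {
    if (is.null(r$cell_types)) r$cell_types <- ct_names
    bad <- setdiff(r$cell_types, ct_names)
    if (length(bad)) stop("regulon '", r$tf_symbol,
                          "' references unknown cell type(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    r
  })
  for (m in modules) {
    if (!m$cell_type %in% ct_names) {
      stop("module '", m$name, "' references unknown cell type '",
           m$cell_type, "'", call. = FALSE)
    }
  }
  structure(list(n_genes_shared = as.integer(n_genes_shared),
                 n_genes_private_per_species =
                   as.integer(n_genes_private_per_species),
                 cell_types = cell_types,
                 n_samples_per_group = as.integer(n_samples_per_group),
                 modules = modules, regulons = regulons,
                 nb_dispersion = nb_dispersion,
                 base_mean_log_range = base_mean_log_range,
                 ct_marker_frac = ct_marker_frac,
                 ct_marker_shift = ct_marker_shift,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Gene symbols for the synthetic shared/private gene sets
#' @noRd
synth_gene_symbols <- function(config, species) {
  shared_mouse <- sprintf("Shrg%04d", seq_len(config$n_genes_shared))
  if (species == "mouse") {
    c(shared_mouse,
      sprintf("Mpriv%03d", seq_len(config$n_genes_private_per_species)))
  } else {
    c(toupper(shared_mouse),
      sprintf("HPRIV%03d", seq_len(config$n_genes_private_per_species)))
  }
}

#' Ortholog map covering the synthetic shared gene set
#'
#' Shared genes plus the planted regulon TF symbols are paired mouse to
#' human by the upper-case convention; species-private genes are
#' deliberately absent.
#'
#' @param config a [synth_config()].
#' @return an [ortholog_map()].
#' @export
synth_ortholog_map <- function(config) {
  m <- c(sprintf("Shrg%04d", seq_len(config$n_genes_shared)),
         vapply(config$regulons, `[[`, "", "tf_symbol"))
  ortholog_map(m, toupper(m))
}

#' Mouse-convention symbol for a synthetic TF in a given species
#' @noRd
synth_tf_symbol <- function(tf, species) {
  if (species == "human") toupper(tf) else tf
}

#' Generate a two-species synthetic dataset with planted structure
#'
#' Draws negative-binomial counts for both species under the latent factor
#' model described in [synth_config()], together with per-cell metadata and
#' a truth record storing every latent quantity (module eigengenes and
#' loadings, DE designations, regulon composition) for downstream
#' validation.
#'
#' @param config a [synth_config()].
#' @return list with elements `mouse`, `human` (both [labeled_counts()]),
#'   `metadata` (combined [cell_metadata()]), and `truth`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_rng(substream(config$seed, 1), {
    n_shared <- config$n_genes_shared
    n_priv <- config$n_genes_private_per_species
    base_shared <- runif(n_shared, config$base_mean_log_range[1],
                         config$base_mean_log_range[2])
    ct_names <- vapply(config$cell_types, `[[`, "", "name")
    n_marker <- max(1L, round(config$ct_marker_frac * n_shared))
    marker_sets <- lapply(ct_names, function(ct)
      sample.int(n_shared, n_marker))
    names(marker_sets) <- ct_names
    # per-gene module loadings (shared genes only), sorted so the first
    # listed gene of each module is the strongest-loading "driver"
    loadings <- matrix(0, n_shared, length(config$modules))
    if (length(config$modules)) {
      colnames(loadings) <- vapply(config$modules, `[[`, "", "name")
      for (j in seq_along(config$modules)) {
        m <- config$modules[[j]]
        l <- abs(rnorm(length(m$gene_indices), m$loading_sd,
                       m$loading_sd / 4))
        l <- pmax(l, m$loading_sd / 4)
        loadings[m$gene_indices, j] <- sort(l, decreasing = TRUE)
      }
    }
    species_data <- list()
    meta_list <- list()
    eig_list <- list()
    for (sp in SPECIES_LEVELS) {
      cts <- Filter(function(ct) ct$species %in% c("both", sp),
                    config$cell_types)
      n_cells <- sum(vapply(cts, `[[`, 0L, "n_cells_per_group")) *
        length(CONDITION_LEVELS)
      cell_type <- character(0); condition <- character(0)
      sample_id <- character(0)
      for (ct in cts) {
        for (cond in CONDITION_LEVELS) {
          nc <- ct$n_cells_per_group
          samp <- rep_len(seq_len(config$n_samples_per_group), nc)
          cell_type <- c(cell_type, rep(ct$name, nc))
          condition <- c(condition, rep(cond, nc))
          sample_id <- c(sample_id,
                         sprintf("%s_%s_s%d", sp, cond, sort(samp)))
        }
      }
      n_cells <- length(cell_type)
      cell_id <- sprintf("%s_c%05d", sp, seq_len(n_cells))
      # latent eigengenes: standard normal, shifted in alcohol cells of
      # the module's cell type; non-conserved modules are mouse-only
      eig <- matrix(0, n_cells, length(config$modules))
      logmu <- matrix(rep(base_shared, n_cells), n_shared, n_cells)
      for (ct in ct_names) {
        sel <- cell_type == ct
        if (any(sel)) {
          logmu[marker_sets[[ct]], sel] <-
            logmu[marker_sets[[ct]], sel] + config$ct_marker_shift
        }
      }
      if (length(config$modules)) {
        colnames(eig) <- colnames(loadings)
        for (j in seq_along(config$modules)) {
          m <- config$modules[[j]]
          if (!m$conserved && sp == "human") next
          e <- rnorm(n_cells)
          shift_cells <- condition == "alcohol" & cell_type == m$cell_type
          e[shift_cells] <- e[shift_cells] + m$condition_shift
          eig[, j] <- e
          idx <- m$gene_indices
          logmu[idx, ] <- logmu[idx, ] +
            loadings[idx, j, drop = FALSE] %*% t(e)
        }
      }
      if (n_priv > 0) {
        base_priv <- runif(n_priv, config$base_mean_log_range[1],
                           config$base_mean_log_range[2])
        logmu <- rbind(logmu, matrix(rep(base_priv, n_cells), n_priv,
                                     n_cells))
      }
      mu <- exp(pmin(logmu, 12))  # cap to avoid absurd library sizes
      counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                               size = config$nb_dispersion),
                       nrow(mu), ncol(mu))
      species_data[[sp]] <- labeled_counts(
        Matrix::Matrix(counts, sparse = TRUE),
        synth_gene_symbols(config, sp), cell_id, sp
      )
      meta_list[[sp]] <- data.frame(
        cell_id = cell_id, species = sp, condition = condition,
        cell_type = cell_type, sample_id = sample_id,
        stringsAsFactors = FALSE
      )
      eig_list[[sp]] <- eig
    }
    metadata <- cell_metadata(do.call(rbind, meta_list))
    rownames(metadata) <- NULL
    truth <- list(
      config = config,
      base_log_mean_shared = base_shared,
      loadings = loadings,
      eigengenes = eig_list,
      marker_sets = marker_sets,
      de_designation = designate_de(config)
    )
    list(mouse = species_data$mouse, human = species_data$human,
         metadata = metadata, truth = truth)
  })
}

#' Deterministic designation of DE genes for the truth DEG tables
#'
#' Module genes of condition-shifted modules are DE in the module's cell
#' type; for each regulon, floor(frac * n) + seeded-Bernoulli-remainder
#' targets are DE in the regulon's cell types. The same shared-gene
#' subset is designated in both species so cross-species overlaps are
#' exactly recoverable.
#' @noRd
designate_de <- function(config) {
  with_rng(substream(config$seed, 2), {
    module_de <- lapply(config$modules, function(m) {
      if (m$condition_shift == 0) return(NULL)
      data.frame(gene_index = m$gene_indices, cell_type = m$cell_type,
                 direction = ifelse(m$condition_shift > 0, "up", "down"),
                 source = paste0("module:", m$name),
                 conserved = m$conserved, stringsAsFactors = FALSE)
    })
    regulon_de <- lapply(config$regulons, function(r) {
      n <- length(r$target_indices)
      n_de <- floor(r$frac_targets_de * n)
      rem <- r$frac_targets_de * n - n_de
      if (rem > 0 && runif(1) < rem) n_de <- n_de + 1L
      if (n_de == 0) return(NULL)
      idx <- r$target_indices[seq_len(n_de)]
      dirs <- ifelse(runif(n_de) < 0.7, "up", "down")
      do.call(rbind, lapply(r$cell_types, function(ct)
        data.frame(gene_index = idx, cell_type = ct, direction = dirs,
                   source = paste0("regulon:", r$tf_symbol),
                   conserved = r$species_scope == "both",
                   species_scope = r$species_scope,
                   stringsAsFactors = FALSE)))
    })
    module_de <- do.call(rbind, module_de)
    if (!is.null(module_de) && nrow(module_de)) {
      module_de$species_scope <- ifelse(module_de$conserved, "both",
                                        "mouse_only")
    }
    regulon_de <- do.call(rbind, regulon_de)
    rbind(module_de, regulon_de)
  })
}

#' Emit ground-truth DEG tables for each species
#'
#' The pipeline consumes DEG lists rather than re-deriving differential
#' expression from counts, so the truth tables carry the planted
#' designations with placeholder adjusted p-values drawn below 0.01 and
#' signed fold changes matching the planted direction.
#'
#' @param truth the `truth` element returned by [generate_dataset()].
#' @return named list with a [deg_table()] per species (possibly empty).
#' @export
emit_truth_deg_table <- function(truth) {
  config <- truth$config
  des <- truth$de_designation
  out <- list()
  for (sp in SPECIES_LEVELS) {
    if (is.null(des) || nrow(des) == 0) {
      out[[sp]] <- deg_table(data.frame(gene = character(),
                                        cell_type = character(),
                                        log2fc = numeric(),
                                        p_adjusted = numeric()))
      next
    }
    scope_ok <- des$species_scope == "both" |
      des$species_scope == paste0(sp, "_only")
    d <- des[scope_ok, , drop = FALSE]
    if (nrow(d) == 0) {
      out[[sp]] <- deg_table(data.frame(gene = character(),
                                        cell_type = character(),
                                        log2fc = numeric(),
                                        p_adjusted = numeric()))
      next
    }
    syms <- synth_gene_symbols(config, sp)
    d$gene <- syms[d$gene_index]
    d <- d[!duplicated(d[c("gene", "cell_type")]), , drop = FALSE]
    d <- with_rng(substream(config$seed, 3 + match(sp, SPECIES_LEVELS)), {
      d$log2fc <- ifelse(d$direction == "up", 1, -1) *
        runif(nrow(d), 0.3, 2)
      d$p_adjusted <- runif(nrow(d), 0, 0.01)
      d
    })
    out[[sp]] <- deg_table(d[c("gene", "cell_type", "log2fc",
                               "p_adjusted")])
  }
  out
}

#' Planted GRN edge sets per cell type and species
#'
#' @param config a [synth_config()].
#' @param species which species' symbol convention to use.
#' @return named list of [grn_edge_set()] per cell type.
#' @export
synth_grn_edge_sets <- function(config, species = c("mouse", "human")) {
  species <- match.arg(species)
  keep_scope <- c("both", paste0(species, "_only"))
  syms <- synth_gene_symbols(config, species)
  cts <- unique(unlist(lapply(config$regulons, `[[`, "cell_types")))
  out <- list()
  for (ct in cts) {
    tf <- character(0); tg <- character(0)
    for (r in config$regulons) {
      if (!(r$species_scope %in% keep_scope) || !(ct %in% r$cell_types))
        next
      tf <- c(tf, rep(synth_tf_symbol(r$tf_symbol, species),
                      length(r$target_indices)))
      tg <- c(tg, syms[r$target_indices])
    }
    out[[ct]] <- grn_edge_set(ct, tf, tg,
                              dialect = if (species == "mouse")
                                "biccn_like" else "psychencode_like")
  }
  out
}

#' Write planted GRN edge lists in both external dialects
#'
#' Mouse networks are written in the BICCN-like layout
#' (`mouse_grn/<celltype>_GRN.txt`, columns `TF`/`target_gene`), human
#' networks in the PsychENCODE-like layout (`human_grn/<celltype>_GRN.txt`,
#' columns `TF`/`target`). Files parse back through [read_grn_edges()]
#' into exactly the planted edge sets.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory.
#' @return named list of written file paths by species.
#' @export
emit_grn_files <- function(config, out_dir) {
  paths <- list()
  for (sp in SPECIES_LEVELS) {
    dialect <- if (sp == "mouse") "biccn_like" else "psychencode_like"
    dir <- file.path(out_dir, paste0(sp, "_grn"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    sets <- synth_grn_edge_sets(config, sp)
    paths[[sp]] <- vapply(names(sets), function(ct) {
      p <- file.path(dir, paste0(ct, "_GRN.txt"))
      write_grn_edges(sets[[ct]], p, dialect = dialect)
      p
    }, "")
  }
  paths
}

#' Benchmark configuration for conserved-module recovery studies
#'
#' A single-cell-type, two-species design used throughout the package's
#' validation suite: 1,500 shared genes, four planted conserved modules
#' of 40 genes (the first carrying a 2-SD condition shift in the alcohol
#' group), 1,250 cells per species x condition group across two samples.
#' With the companion metacell settings (k = 25, disjoint membership, 25
#' metacells per stratum) this yields about 100 metacells per species
#' and a within-module metacell-level correlation near 0.6.
#'
#' @param seed generator seed.
#' @param condition_shift shift applied to the first module (default 2;
#'   set 0 for null-calibration runs).
#' @param loading_sd module loading scale (default 0.6, which yields the
#'   target within-module metacell correlation of about 0.6).
#' @return a [synth_config()].
#' @export
conservation_benchmark_config <- function(seed = 1, condition_shift = 2,
                                          loading_sd = 0.6) {
  synth_config(
    n_genes_shared = 1500, n_genes_private_per_species = 0,
    cell_types = list(synth_cell_type("glia", 1250)),
    n_samples_per_group = 2,
    modules = lapply(1:4, function(j)
      planted_module(paste0("mod", j), ((j - 1) * 40 + 1):(j * 40),
                     "glia", loading_sd = loading_sd,
                     condition_shift = if (j == 1) condition_shift else 0)),
    nb_dispersion = 2, seed = seed
  )
}
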