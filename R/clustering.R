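#' Clustering resolution sweep configuration
#'
#' @param resolutions strictly increasing positive resolutions (default
#'   0.1 to 0.8 in increments of 0.1).
#' @param graph_k neighbours for the shared-nearest-neighbour graph.
#' @param algorithm community detection algorithm.
#' @return a `cluster_sweep_config` list.
#' @export
cluster_sweep_config <- function(resolutions = seq(0.1, 0.8, by = 0.1),
                                 graph_k = 20,
                                 algorithm = c("louvain", "leiden")) {
  algorithm <- match.arg(algorithm)
  if (any(resolutions <= 0) || is.unsorted(resolutions, strictly = TRUE)) {
    stop("resolutions must be strictly increasing and positive",
         call. = FALSE)
  }
  stopifnot(graph_k > 0)
  structure(list(resolutions = resolutions, graph_k = as.integer(graph_k),
                 algorithm = algorithm),
            class = "cluster_sweep_config")
}

#' Shared-nearest-neighbour graph from an embedding
#'
#' k-nearest neighbours by Euclidean distance; edges between a cell and
#' each of its neighbours, weighted by the Jaccard similarity of the two
#' cells' neighbour sets.
#' @noRd
snn_graph <- function(embedding, k) {
  n <- nrow(embedding)
  k <- min(k, n - 1)
  nn <- knn_index(embedding, NULL, k)
  nn_sets <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  from <- rep(seq_len(n), each = k)
  to <- as.integer(t(nn))
  keep <- from < to
  pairs <- unique(data.frame(from = pmin(from, to), to = pmax(from, to)))
  w <- vapply(seq_len(nrow(pairs)), function(r) {
    a <- nn_sets[[pairs$from[r]]]; b <- nn_sets[[pairs$to[r]]]
    length(intersect(a, b)) / length(union(a, b))
  }, 0)
  keep <- w > 0
  igraph::graph_from_data_frame(
    cbind(pairs[keep, , drop = FALSE], weight = w[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
}

#' Community detection over a sweep of resolutions
#'
#' Builds one shared-nearest-neighbour graph (Jaccard-weighted) and runs
#' seeded Louvain (or Leiden) community detection at each resolution.
#' Cluster labels are integers ordered by decreasing cluster size.
#'
#' @param embedding numeric matrix (cells x dims), finite.
#' @param config a [cluster_sweep_config()].
#' @param seed seed fixing the community detection.
#' @return named list (one element per resolution) of integer label
#'   vectors named by the embedding row names.
#' @export
cluster_sweep <- function(embedding, config = cluster_sweep_config(),
                          seed = 1) {
  if (any(!is.finite(embedding))) {
    stop("embedding contains non-finite values", call. = FALSE)
  }
  g <- snn_graph(embedding, config$graph_k)
  out <- list()
  for (r in config$resolutions) {
    memb <- with_rng(substream(seed, round(1000 * r)), {
      if (config$algorithm == "louvain") {
        igraph::membership(igraph::cluster_louvain(g, resolution = r))
      } else {
        igraph::membership(igraph::cluster_leiden(
          g, objective_function = "modularity", resolution = r))
      }
    })
    sizes <- sort(table(memb), decreasing = TRUE)
    relabel <- stats::setNames(seq_along(sizes), names(sizes))
    lab <- unname(relabel[as.character(memb)])
    names(lab) <- rownames(embedding)
    out[[sprintf("res_%.1f", r)]] <- lab
  }
  out
}

#' Composition flagging configuration
#'
#' @param specificity_threshold a cluster is species- or
#'   condition-specific when the corresponding cell fraction strictly
#'   exceeds this value (default 0.60). Must lie in (0.5, 1].
#' @return a `composition_flag_config` list.
#' @export
composition_flag_config <- function(specificity_threshold = 0.60) {
  if (specificity_threshold <= 0.5 || specificity_threshold > 1) {
    stop("specificity_threshold must lie in (0.5, 1]", call. = FALSE)
  }
  structure(list(specificity_threshold = specificity_threshold),
            class = "composition_flag_config")
}

#' Cluster composition and species/condition specificity flags
#'
#' For every (resolution, cluster) the contribution of the four species x
#' condition groups is tabulated. A cluster is flagged
#' `species_specific:<sp>` or `condition_specific:<cond>` when strictly
#' more than `specificity_threshold` of its cells come from that species
#' or condition.
#'
#' @param labels_by_resolution output of [cluster_sweep()].
#' @param metadata [cell_metadata()] covering every labelled cell.
#' @param config a [composition_flag_config()].
#' @return data frame of class `composition_table` with one row per
#'   (resolution, cluster): group counts, marginal and four-way fractions,
#'   and a comma-separated `flags` column.
#' @export
composition_and_flags <- function(labels_by_resolution, metadata,
                                  config = composition_flag_config()) {
  thr <- config$specificity_threshold
  rows <- list()
  for (res in names(labels_by_resolution)) {
    lab <- labels_by_resolution[[res]]
    md <- metadata[match(names(lab), metadata$cell_id), ]
    if (anyNA(md$cell_id)) {
      stop("labels cover cells missing from metadata", call. = FALSE)
    }
    for (cl in sort(unique(lab))) {
      sel <- lab == cl
      n <- sum(sel)
      sp <- table(factor(md$species[sel], SPECIES_LEVELS))
      cond <- table(factor(md$condition[sel], CONDITION_LEVELS))
      grp <- table(factor(paste(md$species[sel], md$condition[sel],
                                sep = "_"),
                          levels = c("mouse_control", "mouse_alcohol",
                                     "human_control", "human_alcohol")))
      flags <- character(0)
      for (s in SPECIES_LEVELS) {
        if (sp[[s]] / n > thr) flags <- c(flags,
                                          paste0("species_specific:", s))
      }
      for (co in CONDITION_LEVELS) {
        if (cond[[co]] / n > thr) flags <- c(flags,
                                             paste0("condition_specific:",
                                                    co))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        resolution = res, cluster = cl, n_cells = n,
        n_mouse_control = grp[["mouse_control"]],
        n_mouse_alcohol = grp[["mouse_alcohol"]],
        n_human_control = grp[["human_control"]],
        n_human_alcohol = grp[["human_alcohol"]],
        frac_mouse = sp[["mouse"]] / n, frac_human = sp[["human"]] / n,
        frac_control = cond[["control"]] / n,
        frac_alcohol = cond[["alcohol"]] / n,
        frac_mouse_control = grp[["mouse_control"]] / n,
        frac_mouse_alcohol = grp[["mouse_alcohol"]] / n,
        frac_human_control = grp[["human_control"]] / n,
        frac_human_alcohol = grp[["human_alcohol"]] / n,
        flags = paste(flags, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- unique(c("composition_table", class(out)))
  out
}

#' Marker detection configuration
#'
#' @param min_log2fc markers must have log2 fold change strictly above
#'   this (default 0.25).
#' @param max_p_adjusted markers must have adjusted p-value strictly
#'   below this (default 0.01).
#' @return a `marker_config` list.
#' @export
marker_config <- function(min_log2fc = 0.25, max_p_adjusted = 0.01) {
  stopifnot(min_log2fc >= 0, max_p_adjusted > 0, max_p_adjusted < 1)
  structure(list(min_log2fc = min_log2fc,
                 max_p_adjusted = max_p_adjusted),
            class = "marker_config")
}

#' Per-cluster marker genes by one-vs-rest rank-sum testing
#'
#' For each cluster, every gene is tested in-cluster vs all other cells
#' with a Wilcoxon rank-sum test on log-normalized expression; log2 fold
#' change is `log2((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`;
#' p-values are BH-adjusted within each cluster's test family. With
#' `filter = TRUE` only rows passing `log2fc > min_log2fc` and
#' `p_adjusted < max_p_adjusted` are kept.
#'
#' @param counts a [labeled_counts()] object or a gene x cell matrix of
#'   raw counts.
#' @param labels integer cluster labels, one per cell.
#' @param config a [marker_config()].
#' @param filter apply the threshold filter (default `TRUE`).
#' @param min_cells clusters with fewer cells are skipped with a warning.
#' @return data frame with columns `cluster`, `gene`, `log2fc`,
#'   `p_value`, `p_adjusted`.
#' @export
find_cluster_markers <- function(counts, labels,
                                 config = marker_config(),
                                 filter = TRUE, min_cells = 3) {
  mat <- if (inherits(counts, "labeled_counts")) counts$counts else counts
  stopifnot(ncol(mat) == length(labels))
  logn <- as.matrix(log_normalize(mat))
  expm <- expm1(logn)
  rows <- list()
  for (cl in sort(unique(labels))) {
    sel <- labels == cl
    if (sum(sel) < min_cells) {
      warning("cluster ", cl, " has fewer than ", min_cells,
              " cells; skipped", call. = FALSE)
      next
    }
    mu_in <- rowMeans(expm[, sel, drop = FALSE])
    mu_out <- rowMeans(expm[, !sel, drop = FALSE])
    l2fc <- log2((mu_in + 1) / (mu_out + 1))
    test <- rank_sum_rows(logn, sel)
    padj <- adjust_bh(test$p_value)
    df <- data.frame(cluster = cl, gene = rownames(mat),
                     log2fc = l2fc, p_value = test$p_value,
                     p_adjusted = padj, stringsAsFactors = FALSE,
                     row.names = NULL)
    rows[[length(rows) + 1L]] <- df
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cluster = integer(), gene = character(),
                      log2fc = numeric(), p_value = numeric(),
                      p_adjusted = numeric())
  }
  if (filter) {
    out <- out[out$log2fc > config$min_log2fc &
                 out$p_adjusted < config$max_p_adjusted, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
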