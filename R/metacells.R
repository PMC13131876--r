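#' Construct metacells within one cell type
#'
#' Cells are stratified by (sample, species) within the requested cell
#' type. Within each stratum, cells are embedded by PCA of log-normalized
#' expression and each candidate metacell pools a cell with its k-1
#' nearest neighbours; candidates are accepted greedily, rejecting any
#' whose membership shares more than `max_overlap` of its cells with an
#' already accepted metacell. Accepted metacells sum raw counts of their
#' members, then the whole matrix is log-normalized (counts per 10k,
#' log1p).
#'
#' @param counts_list named list of [labeled_counts()] (one per species),
#'   or a single object.
#' @param metadata [cell_metadata()] covering all cells.
#' @param cell_type cell type to build metacells for.
#' @param k cells aggregated per metacell (default 25).
#' @param max_overlap maximum shared-membership fraction between accepted
#'   metacells (default 0.5).
#' @param n_pcs PCA dimensions for the neighbour search (default 20).
#' @param min_stratum_cells strata with fewer cells are dropped with a
#'   warning (default `2 * k`).
#' @param max_per_stratum cap on accepted metacells per stratum
#'   (default unlimited).
#' @return object of class `metacell_matrix`: `expr` (genes x metacells,
#'   log-normalized), `keys` (per-metacell cell_type/sample_id/species/
#'   condition), `members` (list of member cell ids), `k`.
#' @export
construct_metacells <- function(counts_list, metadata, cell_type, k = 25,
                                max_overlap = 0, n_pcs = 20,
                                min_stratum_cells = 2 * k,
                                max_per_stratum = Inf) {
  if (inherits(counts_list, "labeled_counts")) {
    counts_list <- stats::setNames(list(counts_list),
                                   counts_list$species)
  }
  expr_cols <- list()
  keys <- list()
  members <- list()
  for (lc in counts_list) {
    md <- metadata[match(lc$cell_ids, metadata$cell_id), ]
    sel_ct <- which(md$cell_type == cell_type)
    if (!length(sel_ct)) next
    strata <- split(sel_ct, md$sample_id[sel_ct])
    for (snm in names(strata)) {
      idx <- strata[[snm]]
      if (length(idx) < min_stratum_cells) {
        warning("stratum ", snm, " (", lc$species, ") has ", length(idx),
                " cells (< ", min_stratum_cells, "); dropped",
                call. = FALSE)
        next
      }
      sub <- lc$counts[, idx, drop = FALSE]
      logn <- as.matrix(log_normalize(sub))
      keepg <- apply(logn, 1, stats::sd) > 0
      d <- min(n_pcs, sum(keepg) - 1, length(idx) - 1)
      emb <- if (d >= 1) {
        stats::prcomp(t(logn[keepg, , drop = FALSE]), rank. = d,
                      center = TRUE, scale. = FALSE)$x
      } else {
        # degenerate stratum (identical cells): arbitrary geometry
        matrix(0, length(idx), 1)
      }
      kk <- min(k, length(idx))
      accepted <- list()
      if (max_overlap == 0) {
        # disjoint pooling: each seed cell takes its nearest unused
        # neighbours, so metacells partition the stratum
        d2 <- as.matrix(stats::dist(emb))^2
        used <- rep(FALSE, length(idx))
        for (i in seq_len(length(idx))) {
          if (length(accepted) >= max_per_stratum) break
          if (used[i] || sum(!used) < kk) next
          free <- which(!used & seq_along(used) != i)
          cand <- c(i, free[order(d2[i, free])][seq_len(kk - 1)])
          used[cand] <- TRUE
          accepted[[length(accepted) + 1L]] <- cand
        }
      } else {
        nn <- knn_index(emb, NULL, kk - 1)
        for (i in seq_len(length(idx))) {
          if (length(accepted) >= max_per_stratum) break
          cand <- c(i, nn[i, ])
          ok <- TRUE
          for (a in accepted) {
            if (length(intersect(cand, a)) / kk > max_overlap) {
              ok <- FALSE; break
            }
          }
          if (!ok) next
          accepted[[length(accepted) + 1L]] <- cand
        }
      }
      for (ci in seq_along(accepted)) {
        cand <- accepted[[ci]]
        expr_cols[[length(expr_cols) + 1L]] <-
          Matrix::rowSums(sub[, cand, drop = FALSE])
        keys[[length(keys) + 1L]] <- data.frame(
          metacell = paste0(lc$species, "_", snm, "_mc", ci),
          cell_type = cell_type, sample_id = snm,
          species = lc$species,
          condition = md$condition[idx[1]],
          stringsAsFactors = FALSE
        )
        members[[length(members) + 1L]] <- lc$cell_ids[idx[cand]]
      }
    }
  }
  if (!length(expr_cols)) {
    stop("no stratum of cell type '", cell_type, "' has at least ",
         min_stratum_cells, " cells", call. = FALSE)
  }
  raw <- do.call(cbind, expr_cols)
  keys <- do.call(rbind, keys)
  colnames(raw) <- keys$metacell
  expr <- as.matrix(log_normalize(Matrix::Matrix(raw, sparse = TRUE)))
  structure(list(expr = expr, raw = raw, keys = keys, members = members,
                 k = as.integer(k)),
            class = "metacell_matrix")
}

#' @export
print.metacell_matrix <- function(x, ...) {
  cat("metacell_matrix: ", nrow(x$expr), " genes x ", ncol(x$expr),
      " metacells (k = ", x$k, ")\n", sep = "")
  invisible(x)
}
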