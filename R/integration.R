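#' Integration configuration
#'
#' @param n_anchor_features number of variable genes used as integration
#'   features (default 2000).
#' @param n_cca_dims canonical correlation dimensions (default 30).
#' @param k_mnn neighbours used when searching for mutual nearest
#'   neighbour anchor pairs (default 5).
#' @param k_score neighbours used when scoring anchor consistency
#'   (default 30).
#' @param subsample_to_match subsample the larger dataset to the smaller's
#'   cell count before anchor finding (default `TRUE`).
#' @return an `integration_config` list.
#' @export
integration_config <- function(n_anchor_features = 2000, n_cca_dims = 30,
                               k_mnn = 5, k_score = 30,
                               subsample_to_match = TRUE) {
  stopifnot(n_anchor_features > 0, n_cca_dims > 0, k_mnn > 0, k_score > 0)
  structure(list(n_anchor_features = as.integer(n_anchor_features),
                 n_cca_dims = as.integer(n_cca_dims),
                 k_mnn = as.integer(k_mnn),
                 k_score = as.integer(k_score),
                 subsample_to_match = isTRUE(subsample_to_match)),
            class = "integration_config")
}

#' Restrict two species' counts to the shared ortholog universe
#'
#' Genes are renamed to the human symbol of each retained 1:1 pair so the
#' two matrices share row names.
#' @noRd
restrict_to_orthologs <- function(counts_mouse, counts_human, map) {
  mg <- intersect(map$pairs$mouse, counts_mouse$gene_ids)
  pairs <- map$pairs[map$pairs$mouse %in% mg, , drop = FALSE]
  pairs <- pairs[pairs$human %in% counts_human$gene_ids, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no ortholog-mapped genes shared by both ",
                             "datasets", call. = FALSE)
  m <- counts_mouse$counts[pairs$mouse, , drop = FALSE]
  rownames(m) <- pairs$human
  h <- counts_human$counts[pairs$human, , drop = FALSE]
  list(mouse = m, human = h, pairs = pairs)
}

#' Per-gene standardized variance (mean-variance-trend feature selection)
#'
#' The "vst" selector: per-gene mean and variance of raw counts are
#' computed, a loess trend of log10(variance) on log10(mean) predicts the
#' expected standard deviation, counts are standardized by the predicted
#' SD, clipped above at sqrt(n_cells), and the variance of the clipped
#' standardized values is the gene's score.
#'
#' @param counts gene x cell count matrix.
#' @param loess_span span of the mean-variance trend smoother.
#' @return numeric vector of standardized variances, named by gene.
#' @export
standardized_variance <- function(counts, loess_span = 0.3) {
  n <- ncol(counts)
  mu <- Matrix::rowSums(counts) / n
  ex2 <- Matrix::rowSums(counts^2) / n
  v <- (ex2 - mu^2) * n / (n - 1)
  sv <- numeric(length(mu))
  usable <- v > 0 & mu > 0
  if (sum(usable) >= 4) {
    fit <- stats::loess(log10(v[usable]) ~ log10(mu[usable]),
                        span = loess_span, degree = 2)
    sd_pred <- sqrt(10^predict(fit))
    clip <- sqrt(n)
    x <- as.matrix(counts[usable, , drop = FALSE])
    z <- (x - mu[usable]) / sd_pred
    z[z > clip] <- clip
    sv[usable] <- apply(z, 1, stats::var)
  } else {
    sv[usable] <- v[usable]
  }
  names(sv) <- rownames(counts)
  sv
}

#' Select shared variable genes across both species
#'
#' Both count matrices are restricted to the ortholog universe,
#' concatenated on shared symbols, and scored by [standardized_variance()].
#' The top `n_anchor_features` genes are returned, ties broken
#' lexicographically by symbol.
#'
#' @param counts_mouse,counts_human [labeled_counts()] objects.
#' @param map an [ortholog_map()].
#' @param config an [integration_config()].
#' @return character vector of selected gene symbols (human convention),
#'   ordered by decreasing standardized variance.
#' @export
select_variable_genes <- function(counts_mouse, counts_human, map,
                                  config = integration_config()) {
  shared <- restrict_to_orthologs(counts_mouse, counts_human, map)
  combined <- cbind(shared$mouse, shared$human)
  sv <- standardized_variance(combined)
  ord <- order(-sv, names(sv))
  n <- config$n_anchor_features
  if (n > length(sv)) {
    warning("only ", length(sv), " shared genes available; returning all",
            call. = FALSE)
    n <- length(sv)
  }
  names(sv)[ord][seq_len(n)]
}

#' Anchor-based integration of two species into a joint embedding
#'
#' Canonical correlation analysis on the scaled expression of the shared
#' variable genes yields a joint low-dimensional space (via SVD of the
#' cross-product of the two scaled matrices); mutual nearest neighbour
#' cell pairs across the datasets define integration anchors; anchors are
#' scored by shared-neighbour overlap and the query dataset is corrected
#' by anchor-score-weighted difference vectors under a Gaussian distance
#' kernel.
#'
#' @param counts_mouse,counts_human [labeled_counts()] objects.
#' @param variable_genes character vector from [select_variable_genes()].
#' @param map an [ortholog_map()].
#' @param config an [integration_config()].
#' @param metadata optional [cell_metadata()]; when present, size-matching
#'   subsampling is stratified by cell type.
#' @param seed seed for the subsampling step.
#' @return list with `embedding` (cells x n_cca_dims, mouse rows first),
#'   `anchors` (data frame of anchor pairs with scores), and `cells_used`.
#' @export
integrate_datasets <- function(counts_mouse, counts_human, variable_genes,
                               map, config = integration_config(),
                               metadata = NULL, seed = 1) {
  shared <- restrict_to_orthologs(counts_mouse, counts_human, map)
  m <- shared$mouse; h <- shared$human
  if (config$subsample_to_match && ncol(m) != ncol(h)) {
    target <- min(ncol(m), ncol(h))
    big <- if (ncol(m) > ncol(h)) "mouse" else "human"
    x <- if (big == "mouse") m else h
    keep <- with_rng(substream(seed, 11), {
      if (!is.null(metadata)) {
        md <- metadata[match(colnames(x), metadata$cell_id), ]
        # proportional stratified subsample by cell type
        idx <- unlist(lapply(split(seq_len(ncol(x)), md$cell_type),
                             function(ii) {
          ni <- max(1L, round(length(ii) / ncol(x) * target))
          sample(ii, min(ni, length(ii)))
        }))
        sort(idx[seq_len(min(length(idx), target))])
      } else sort(sample.int(ncol(x), target))
    })
    if (big == "mouse") m <- m[, keep, drop = FALSE]
    else h <- h[, keep, drop = FALSE]
  }
  vg <- intersect(variable_genes, rownames(m))
  xm <- scale_rows(log_normalize(m)[vg, , drop = FALSE])
  xh <- scale_rows(log_normalize(h)[vg, , drop = FALSE])
  d <- min(config$n_cca_dims, ncol(xm) - 1, ncol(xh) - 1, length(vg) - 1)
  cc <- svd(crossprod(xm, xh), nu = d, nv = d)
  # weight canonical vectors by their singular values so informative
  # dimensions dominate the cell-cell geometry
  sv <- diag(cc$d[seq_len(d)], d, d)
  em <- cc$u[, seq_len(d), drop = FALSE] %*% sv
  eh <- cc$v[, seq_len(d), drop = FALSE] %*% sv
  l2 <- function(e) e / pmax(sqrt(rowSums(e^2)), 1e-12)
  em <- l2(em); eh <- l2(eh)
  rownames(em) <- colnames(m); rownames(eh) <- colnames(h)
  # mutual nearest neighbour anchors in the joint CCA space
  k1 <- min(config$k_mnn, nrow(eh)); k2 <- min(config$k_mnn, nrow(em))
  nn_mh <- knn_index(em, eh, k1)
  nn_hm <- knn_index(eh, em, k2)
  pairs <- which(vapply(seq_len(nrow(em)), function(i) {
    any(vapply(nn_mh[i, ], function(j) i %in% nn_hm[j, ], TRUE))
  }, TRUE))
  anchor <- do.call(rbind, lapply(pairs, function(i) {
    js <- nn_mh[i, ][vapply(nn_mh[i, ], function(j) i %in% nn_hm[j, ],
                            TRUE)]
    cbind(i, js)
  }))
  if (is.null(anchor) || nrow(anchor) == 0) {
    stop("no mutual nearest neighbour anchors found; consider a larger ",
         "k_mnn or more shared variable genes", call. = FALSE)
  }
  # score anchors by shared-neighbour overlap in the joint space
  all_emb <- rbind(em, eh)
  ks <- min(config$k_score, nrow(all_emb) - 1)
  nn_all <- knn_index(all_emb, NULL, ks)
  n_m <- nrow(em)
  raw <- vapply(seq_len(nrow(anchor)), function(r) {
    length(intersect(nn_all[anchor[r, 1], ], nn_all[n_m + anchor[r, 2], ]))
  }, 0)
  score <- if (diff(range(raw)) > 0) {
    (raw - min(raw)) / (max(raw) - min(raw))
  } else rep(1, length(raw))
  # correct the query (human) cells by weighted anchor difference vectors
  vec <- em[anchor[, 1], , drop = FALSE] - eh[anchor[, 2], , drop = FALSE]
  kw <- min(50L, nrow(anchor))
  anchor_pos <- eh[anchor[, 2], , drop = FALSE]
  nn_anchor <- knn_index(eh, anchor_pos, kw)
  eh_corr <- eh
  for (q in seq_len(nrow(eh))) {
    aidx <- nn_anchor[q, ]
    dq <- sqrt(rowSums((anchor_pos[aidx, , drop = FALSE] -
                          matrix(eh[q, ], kw, ncol(eh), byrow = TRUE))^2))
    band <- max(dq[kw], 1e-9)
    w <- score[aidx] * exp(-dq^2 / (2 * band^2))
    if (sum(w) <= 0) w <- rep(1, kw)
    eh_corr[q, ] <- eh[q, ] + colSums(vec[aidx, , drop = FALSE] * w) /
      sum(w)
  }
  emb <- rbind(em, eh_corr)
  list(embedding = emb,
       anchors = data.frame(mouse_cell = rownames(em)[anchor[, 1]],
                            human_cell = rownames(eh)[anchor[, 2]],
                            score = score, stringsAsFactors = FALSE),
       cells_used = list(mouse = colnames(m), human = colnames(h)))
}
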