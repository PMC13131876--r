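#' Soft power selection configuration
#'
#' @param target_r2 scale-free topology fit target (default 0.8): the
#'   chosen power is the smallest candidate whose degree distribution
#'   attains this model fit R-squared.
#' @param candidate_powers candidate exponents (default 1:20).
#' @param network_type `"signed"` (default) or `"unsigned"`.
#' @return a `soft_power_config` list.
#' @export
soft_power_config <- function(target_r2 = 0.8, candidate_powers = 1:20,
                              network_type = c("signed", "unsigned")) {
  network_type <- match.arg(network_type)
  stopifnot(target_r2 > 0, target_r2 <= 1, length(candidate_powers) >= 1)
  structure(list(target_r2 = target_r2,
                 candidate_powers = as.integer(candidate_powers),
                 network_type = network_type),
            class = "soft_power_config")
}

#' Weighted adjacency from a correlation matrix
#'
#' Signed networks use `((1 + cor) / 2)^power`; unsigned use
#' `|cor|^power`. The diagonal is zeroed (no self-adjacency).
#' @noRd
adjacency_from_cor <- function(cmat, power, network_type = "signed") {
  a <- if (network_type == "signed") ((1 + cmat) / 2)^power
       else abs(cmat)^power
  diag(a) <- 0
  a
}

#' Scale-free topology model fit of a degree distribution
#'
#' Connectivities are binned (10 equal-width bins); the fit is the
#' R-squared of the linear regression of log10 bin frequency on log10
#' mean bin connectivity over non-empty bins. Fewer than 3 usable bins
#' returns NA.
#' @noRd
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 2) return(NA_real_)
  if (diff(range(k)) < .Machine$double.eps^0.5) return(NA_real_)
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  mid <- tapply(k, bin, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 2) return(NA_real_)
  x <- log10(mid[ok]); y <- log10(freq[ok] / length(k))
  summary(stats::lm(y ~ x))$r.squared
}

#' Choose the soft-thresholding power
#'
#' For each candidate power the weighted adjacency is computed from the
#' gene-gene correlation matrix over metacells and the scale-free
#' topology fit R-squared of the connectivity distribution is assessed.
#' The chosen power is the smallest candidate reaching `target_r2`; if
#' none does, the candidate maximizing the fit is used with a warning.
#' Constant genes are excluded with a warning.
#'
#' @param expr genes x metacells expression matrix (or
#'   `metacell_matrix`).
#' @param config a [soft_power_config()].
#' @return list with `power`, `fit_table` (power, r_squared, mean_k),
#'   and `network_type`.
#' @export
pick_soft_power <- function(expr, config = soft_power_config()) {
  if (inherits(expr, "metacell_matrix")) expr <- expr$expr
  sdv <- apply(expr, 1, stats::sd)
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " constant gene(s) excluded from soft power ",
            "selection", call. = FALSE)
    expr <- expr[sdv > 0, , drop = FALSE]
  }
  cmat <- stats::cor(t(expr))
  fits <- vapply(config$candidate_powers, function(b) {
    a <- adjacency_from_cor(cmat, b, config$network_type)
    k <- rowSums(a)
    c(scale_free_fit(k), mean(k))
  }, numeric(2))
  tab <- data.frame(power = config$candidate_powers,
                    r_squared = fits[1, ], mean_k = fits[2, ])
  hit <- which(!is.na(tab$r_squared) & tab$r_squared >= config$target_r2)
  if (length(hit)) {
    power <- tab$power[hit[1]]
  } else {
    if (all(is.na(tab$r_squared))) {
      warning("scale-free fit undefined for all candidates; using the ",
              "smallest power", call. = FALSE)
      power <- tab$power[1]
    } else {
      power <- tab$power[which.max(tab$r_squared)]
      warning("no candidate power reached the target fit R^2 = ",
              config$target_r2, "; using argmax (power = ", power, ")",
              call. = FALSE)
    }
  }
  list(power = power, fit_table = tab,
       network_type = config$network_type)
}

#' Topological overlap matrix from an adjacency matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' k_i the connectivity of gene i; the diagonal is 1.
#'
#' @param a symmetric adjacency matrix with zero diagonal, entries in
#'   \[0, 1\].
#' @return the TOM, entries in \[0, 1\], symmetric, unit diagonal.
#' @export
tom_from_adjacency <- function(a) {
  k <- rowSums(a)
  l <- tcrossprod(a)            # a has zero diagonal, so this is sum_u
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

#' Consensus topological overlap across species
#'
#' Per species: gene-gene correlation over metacells, soft-thresholded
#' adjacency, TOM. Per-species TOMs are brought to a common scale by a
#' scalar factor matching the `q_scale` quantile of off-diagonal entries
#' to the first (reference) species, then combined element-wise at the
#' `q_consensus` quantile across species (default 0 = minimum, the
#' classic consensus choice).
#'
#' @param expr_by_species named list of genes x metacells matrices on the
#'   same (ortholog-shared) gene set, in the same row order.
#' @param power soft-thresholding exponent.
#' @param network_type `"signed"` or `"unsigned"`.
#' @param q_scale quantile used for cross-species TOM scaling
#'   (default 0.95).
#' @param q_consensus element-wise consensus quantile (default 0).
#' @return list with `consensus` (gene x gene TOM) and `per_species`
#'   TOMs (after scaling).
#' @export
consensus_tom <- function(expr_by_species, power,
                          network_type = "signed", q_scale = 0.95,
                          q_consensus = 0) {
  stopifnot(length(expr_by_species) >= 1)
  g0 <- rownames(expr_by_species[[1]])
  for (e in expr_by_species) {
    if (!identical(rownames(e), g0)) {
      stop("gene sets/order differ between species matrices",
           call. = FALSE)
    }
  }
  toms <- lapply(expr_by_species, function(e) {
    cmat <- suppressWarnings(stats::cor(t(e)))
    cmat[!is.finite(cmat)] <- 0
    tom_from_adjacency(adjacency_from_cor(cmat, power, network_type))
  })
  off <- upper.tri(toms[[1]])
  ref_q <- stats::quantile(toms[[1]][off], q_scale)
  toms <- lapply(toms, function(tm) {
    qi <- stats::quantile(tm[off], q_scale)
    if (qi > 0) tm <- tm * as.numeric(ref_q / qi)
    tm[tm > 1] <- 1
    diag(tm) <- 1
    tm
  })
  cons <- toms[[1]]
  if (length(toms) > 1) {
    if (q_consensus == 0) {
      for (i in seq_along(toms)[-1]) cons <- pmin(cons, toms[[i]])
    } else if (length(toms) == 2) {
      lo <- pmin(cons, toms[[2]]); hi <- pmax(cons, toms[[2]])
      cons <- lo + q_consensus * (hi - lo)
    } else {
      arr <- simplify2array(toms)
      cons <- apply(arr, c(1, 2), stats::quantile, probs = q_consensus)
    }
  }
  dimnames(cons) <- list(g0, g0)
  list(consensus = cons, per_species = toms)
}

#' Detect modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering on dissimilarity 1 - TOM,
#' followed by a tree cut. `method = "adaptive"` (default) scans the
#' dendrogram's merge heights and cuts at the height producing the
#' largest number of branches of at least `min_module_size` genes,
#' preferring the lowest (tightest) such height — so dense co-expression
#' blocks are isolated before the diffuse background coalesces — and
#' then rescues unassigned genes whose mean TOM to a detected module
#' exceeds both `pam_threshold` and their mean TOM to all genes.
#' `method = "height"` is a plain fixed cut at the `cut_quantile`
#' quantile of merge heights. Branches smaller than `min_module_size`
#' become grey; modules whose eigengenes (computed on `expr`, averaged
#' across species when a list is given) correlate above
#' `1 - merge_height` are merged iteratively.
#'
#' @param tom symmetric TOM with unit diagonal.
#' @param min_module_size smallest retained module (default 30).
#' @param merge_height eigengene dissimilarity below which modules merge
#'   (default 0.25).
#' @param expr optional expression matrix or list of per-species matrices
#'   for eigengene-based merging; merging is skipped when absent.
#' @param method `"adaptive"` or `"height"`.
#' @param cut_quantile quantile of merge heights for the fixed-height
#'   method (default 0.99).
#' @param pam_threshold minimum mean TOM for rescuing a grey gene in the
#'   adaptive method (default 0.1).
#' @return named character vector: gene -> module label (`"M1"`, `"M2"`,
#'   ... by decreasing size, `"grey"` = unassigned).
#' @export
detect_modules <- function(tom, min_module_size = 30,
                           merge_height = 0.25, expr = NULL,
                           method = c("adaptive", "height"),
                           cut_quantile = 0.99, pam_threshold = 0.1) {
  method <- match.arg(method)
  if (!isTRUE(all.equal(tom, t(tom), tolerance = 1e-8))) {
    stop("TOM must be symmetric", call. = FALSE)
  }
  genes <- rownames(tom) %||% paste0("g", seq_len(nrow(tom)))
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  if (method == "adaptive") {
    hs <- unique(stats::quantile(hc$height, seq(0.02, 0.98,
                                                by = 0.02)))
    best_n <- -1L; cut_h <- stats::quantile(hc$height, cut_quantile)
    for (h in hs) {
      cl_h <- stats::cutree(hc, h = h)
      n_big <- sum(table(cl_h) >= min_module_size)
      if (n_big > best_n) { best_n <- n_big; cut_h <- h }
    }
  } else {
    cut_h <- stats::quantile(hc$height, cut_quantile)
  }
  cl <- stats::cutree(hc, h = cut_h)
  # size filter
  sizes <- table(cl)
  lab <- ifelse(cl %in% as.integer(names(sizes)[sizes >=
                                                  min_module_size]),
                cl, NA)
  if (method == "adaptive" && anyNA(lab) && !all(is.na(lab))) {
    mods <- sort(unique(lab[!is.na(lab)]))
    mean_tom <- vapply(mods, function(m)
      rowMeans(tom[, !is.na(lab) & lab == m, drop = FALSE]),
      numeric(nrow(tom)))
    overall <- rowMeans(tom)
    for (i in which(is.na(lab))) {
      best <- which.max(mean_tom[i, ])
      if (mean_tom[i, best] > max(overall[i], pam_threshold)) {
        lab[i] <- mods[best]
      }
    }
  }
  assignment <- ifelse(is.na(lab), "grey", paste0("mod", lab))
  names(assignment) <- genes
  # iterative eigengene-based merging
  if (!is.null(expr) && merge_height > 0) {
    expr_list <- if (is.list(expr)) expr else list(expr)
    repeat {
      mods <- setdiff(unique(assignment), "grey")
      if (length(mods) < 2) break
      me_cor <- matrix(0, length(mods), length(mods),
                       dimnames = list(mods, mods))
      for (e in expr_list) {
        mes <- vapply(mods, function(m)
          module_eigengene(e[names(assignment)[assignment == m], ,
                             drop = FALSE]),
          numeric(ncol(e)))
        me_cor <- me_cor + stats::cor(mes) / length(expr_list)
      }
      diag(me_cor) <- -Inf
      top <- which(me_cor == max(me_cor), arr.ind = TRUE)[1, ]
      if (me_cor[top[1], top[2]] > 1 - merge_height) {
        assignment[assignment == mods[top[2]]] <- mods[top[1]]
      } else break
    }
  }
  # stable labels by decreasing size
  mods <- setdiff(unique(assignment), "grey")
  if (length(mods)) {
    sz <- sort(table(factor(assignment[assignment != "grey"], mods)),
               decreasing = TRUE)
    relabel <- stats::setNames(paste0("M", seq_along(sz)), names(sz))
    assignment[assignment != "grey"] <-
      relabel[assignment[assignment != "grey"]]
  }
  assignment
}

#' First-principal-component eigengene of a module submatrix
#'
#' Rows (genes) are standardized; the eigengene is the first right
#' singular vector's score over metacells, sign-oriented so that the
#' mean gene-eigengene correlation is non-negative, and rescaled to unit
#' variance.
#' @noRd
module_eigengene <- function(sub_expr) {
  x <- t(scale_rows(sub_expr, clip = Inf))   # metacells x genes
  if (ncol(x) == 1) {
    e <- x[, 1]
  } else {
    sv <- svd(x, nu = 1, nv = 0)
    e <- sv$u[, 1] * sv$d[1]
  }
  cors <- suppressWarnings(stats::cor(e, t(sub_expr)))
  if (mean(cors, na.rm = TRUE) < 0) e <- -e
  s <- stats::sd(e)
  if (s > 0) e <- e / s
  e
}

#' Module eigengenes, kME and hub genes
#'
#' Eigengenes are the unit-variance first principal components of each
#' module's standardized expression submatrix, sign-oriented so the mean
#' gene-eigengene correlation is non-negative. kME is the Pearson
#' correlation of every gene with every module eigengene; hub genes are
#' the top `n_hubs` genes of each module by own-module kME (ties broken
#' lexicographically).
#'
#' @param expr genes x metacells matrix (or `metacell_matrix`).
#' @param assignment named gene -> module vector from [detect_modules()].
#' @param cell_type label stored on the result.
#' @param n_hubs hub genes listed per module (default 10).
#' @return object of class `module_set` with `assignment`, `kme`,
#'   `hub_genes`, `eigengenes`, `cell_type`.
#' @export
eigengenes_and_hubs <- function(expr, assignment, cell_type = NA_character_,
                                n_hubs = 10) {
  keys <- NULL
  if (inherits(expr, "metacell_matrix")) {
    keys <- expr$keys
    expr <- expr$expr
  }
  assignment <- assignment[intersect(names(assignment), rownames(expr))]
  mods <- setdiff(unique(assignment), "grey")
  mods <- if (all(grepl("^M\\d+$", mods))) {
    mods[order(as.integer(sub("^M", "", mods)))]
  } else sort(mods)
  if (!length(mods)) stop("no non-grey modules to summarize",
                          call. = FALSE)
  mes <- matrix(0, ncol(expr), length(mods),
                dimnames = list(colnames(expr), mods))
  for (m in mods) {
    genes_m <- names(assignment)[assignment == m]
    if (length(genes_m) == 1) {
      warning("module ", m, " has a single gene; eigengene is its ",
              "standardized profile", call. = FALSE)
    }
    mes[, m] <- module_eigengene(expr[genes_m, , drop = FALSE])
  }
  kme <- suppressWarnings(stats::cor(t(expr[names(assignment), ,
                                            drop = FALSE]), mes))
  kme[!is.finite(kme)] <- 0
  hubs <- lapply(mods, function(m) {
    genes_m <- names(assignment)[assignment == m]
    v <- kme[genes_m, m]
    genes_m[order(-v, genes_m)][seq_len(min(n_hubs, length(genes_m)))]
  })
  names(hubs) <- mods
  structure(list(cell_type = cell_type, assignment = assignment,
                 kme = kme, hub_genes = hubs, eigengenes = mes,
                 keys = keys),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  mods <- setdiff(unique(x$assignment), "grey")
  cat("module_set [", x$cell_type, "]: ", length(mods), " modules over ",
      length(x$assignment), " genes (",
      sum(x$assignment == "grey"), " grey)\n", sep = "")
  invisible(x)
}

#' Differential module eigengene expression between conditions
#'
#' Per module and species, alcohol vs control eigengene values over
#' metacells are compared by a Wilcoxon rank-sum test; p-values are
#' BH-adjusted across modules within each species. A module is flagged
#' differential iff adjusted p < `alpha` (strict); direction is the sign
#' of (mean alcohol - mean control). Species with fewer than `min_per_group`
#' metacells in either condition are marked untestable.
#'
#' @param eigengenes metacell x module matrix (or a `module_set`).
#' @param keys per-metacell data frame with `species` and `condition`
#'   (taken from the module set when available).
#' @param alpha significance level (default 0.05).
#' @param min_per_group minimum metacells per condition (default 3).
#' @return data frame of class `module_de_result`: one row per
#'   (module, species) with `direction`, `p_value`, `p_adjusted`,
#'   `is_differential`, `testable`.
#' @export
differential_module_expression <- function(eigengenes, keys = NULL,
                                           alpha = 0.05,
                                           min_per_group = 3) {
  if (inherits(eigengenes, "module_set")) {
    keys <- keys %||% eigengenes$keys
    eigengenes <- eigengenes$eigengenes
  }
  if (is.null(keys)) stop("metacell keys are required", call. = FALSE)
  stopifnot(nrow(keys) == nrow(eigengenes))
  rows <- list()
  for (sp in unique(keys$species)) {
    sel <- keys$species == sp
    alc <- sel & keys$condition == "alcohol"
    ctl <- sel & keys$condition == "control"
    testable <- sum(alc) >= min_per_group && sum(ctl) >= min_per_group
    ps <- dirs <- rep(NA_real_, ncol(eigengenes))
    if (testable) {
      for (j in seq_len(ncol(eigengenes))) {
        rs <- rank_sum_test(eigengenes[alc, j], eigengenes[ctl, j])
        ps[j] <- rs$p_value
        dirs[j] <- sign(mean(eigengenes[alc, j]) -
                          mean(eigengenes[ctl, j]))
      }
      padj <- adjust_bh(ps)
    } else {
      padj <- ps
    }
    rows[[sp]] <- data.frame(
      module = colnames(eigengenes), species = sp,
      direction = ifelse(is.na(dirs), "none",
                         ifelse(dirs >= 0, "up", "down")),
      p_value = ps, p_adjusted = padj,
      is_differential = !is.na(padj) & padj < alpha,
      testable = testable, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- unique(c("module_de_result", class(out)))
  out
}

#' End-to-end consensus module detection for one cell type
#'
#' Convenience wrapper chaining the per-cell-type module stage: metacell
#' construction in both species, restriction to the ortholog-shared gene
#' set (human symbols), soft power selection on the pooled metacells,
#' consensus TOM, module detection with eigengene merging, per-species
#' eigengenes/kME/hubs, and differential eigengene testing.
#'
#' @param counts_mouse,counts_human [labeled_counts()] objects.
#' @param metadata [cell_metadata()].
#' @param map an [ortholog_map()].
#' @param cell_type cell type to analyse.
#' @param metacell_k,max_overlap,n_pcs,max_per_stratum metacell settings
#'   (see [construct_metacells()]).
#' @param soft_power a [soft_power_config()].
#' @param min_module_size,merge_height,q_consensus module detection
#'   settings.
#' @param n_hubs hub list length.
#' @return list with `assignment`, `power`, `module_sets` (per species),
#'   `de` (combined `module_de_result`), `tom` (consensus), and the two
#'   metacell matrices.
#' @export
consensus_module_pipeline <- function(counts_mouse, counts_human,
                                      metadata, map, cell_type,
                                      metacell_k = 25, max_overlap = 0,
                                      n_pcs = 20, max_per_stratum = Inf,
                                      soft_power = soft_power_config(),
                                      min_module_size = 30,
                                      merge_height = 0.25,
                                      q_consensus = 0, n_hubs = 10) {
  mc_m <- construct_metacells(counts_mouse, metadata, cell_type,
                              k = metacell_k, max_overlap = max_overlap,
                              n_pcs = n_pcs,
                              max_per_stratum = max_per_stratum)
  mc_h <- construct_metacells(counts_human, metadata, cell_type,
                              k = metacell_k, max_overlap = max_overlap,
                              n_pcs = n_pcs,
                              max_per_stratum = max_per_stratum)
  pairs <- map$pairs[map$pairs$mouse %in% rownames(mc_m$expr) &
                       map$pairs$human %in% rownames(mc_h$expr), ,
                     drop = FALSE]
  if (nrow(pairs) == 0) stop("no ortholog-shared genes in the metacell ",
                             "matrices", call. = FALSE)
  em <- mc_m$expr[pairs$mouse, , drop = FALSE]
  rownames(em) <- pairs$human
  eh <- mc_h$expr[pairs$human, , drop = FALSE]
  pw <- suppressWarnings(pick_soft_power(cbind(em, eh), soft_power))
  ct <- consensus_tom(list(mouse = em, human = eh), pw$power,
                      network_type = soft_power$network_type,
                      q_consensus = q_consensus)
  assignment <- detect_modules(ct$consensus,
                               min_module_size = min_module_size,
                               merge_height = merge_height,
                               expr = list(em, eh))
  mk_ms <- function(expr, keys, k, asg) {
    eigengenes_and_hubs(
      structure(list(expr = expr, keys = keys, k = k),
                class = "metacell_matrix"),
      asg, cell_type = cell_type, n_hubs = n_hubs)
  }
  # the mouse module set keeps mouse symbols; the shared assignment is
  # on human symbols (the consensus gene naming)
  em_m <- em
  rownames(em_m) <- pairs$mouse
  assignment_m <- assignment
  names(assignment_m) <- pairs$mouse[match(names(assignment),
                                           pairs$human)]
  ms_m <- mk_ms(em_m, mc_m$keys, mc_m$k, assignment_m)
  ms_h <- mk_ms(eh, mc_h$keys, mc_h$k, assignment)
  de <- rbind(differential_module_expression(ms_m),
              differential_module_expression(ms_h))
  list(assignment = assignment, power = pw$power,
       module_sets = list(mouse = ms_m, human = ms_h), de = de,
       tom = ct$consensus,
       metacells = list(mouse = mc_m, human = mc_h),
       gene_pairs = pairs)
}
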