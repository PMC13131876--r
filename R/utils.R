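#' @keywords internal
"_PACKAGE"

#' @importFrom Matrix Matrix readMM writeMM t rowSums colSums
#' @importFrom methods as is
#' @importFrom stats cor dist loess median na.omit p.adjust phyper
#'   predict prcomp quantile rbinom rnbinom rnorm runif sd var wilcox.test
#' @importFrom utils read.delim write.table head combn
NULL

SPECIES_LEVELS <- c("mouse", "human")
CONDITION_LEVELS <- c("control", "alcohol")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trim leading/trailing whitespace from gene symbols
#' @noRd
trim_ws <- function(x) gsub("^\\s+|\\s+$", "", x)

#' Library-size normalize to counts-per-10k and log1p
#'
#' The standard single-cell log-normalization: each cell (column) is scaled
#' to a library size of `scale_factor` and transformed with `log1p`.
#'
#' @param counts gene x cell matrix (sparse or dense) of non-negative counts.
#' @param scale_factor target library size (default 1e4).
#' @return matrix of the same class and dimensions.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  libs <- Matrix::colSums(counts)
  libs[libs == 0] <- 1
  if (inherits(counts, "sparseMatrix")) {
    m <- as(counts, "CsparseMatrix")
    m@x <- log1p(m@x / rep.int(libs, diff(m@p)) * scale_factor)
    m
  } else {
    log1p(sweep(counts, 2, libs, "/") * scale_factor)
  }
}

#' Row-scale a matrix (z-score per gene) with clipping
#' @noRd
scale_rows <- function(x, clip = 10) {
  x <- as.matrix(x)
  mu <- rowMeans(x)
  sdv <- apply(x, 1, stats::sd)
  sdv[sdv == 0] <- 1
  z <- (x - mu) / sdv
  z[z > clip] <- clip
  z[z < -clip] <- clip
  z
}

#' k-nearest neighbours by Euclidean distance (brute force)
#'
#' @param x query matrix (rows = points).
#' @param y reference matrix; defaults to `x` (self excluded from neighbours).
#' @param k number of neighbours.
#' @return integer matrix nrow(x) x k of row indices into `y`.
#' @noRd
knn_index <- function(x, y = NULL, k) {
  self <- is.null(y)
  if (self) y <- x
  d2 <- outer(rowSums(x^2), rep(1, nrow(y))) +
    outer(rep(1, nrow(x)), rowSums(y^2)) - 2 * x %*% t(y)
  d2[d2 < 0] <- 0
  idx <- matrix(0L, nrow(x), k)
  for (i in seq_len(nrow(x))) {
    di <- d2[i, ]
    if (self) di[i] <- Inf
    idx[i, ] <- order(di)[seq_len(k)]
  }
  idx
}

#' Derive a reproducible substream seed from a base seed
#'
#' Keeps derived seeds within the 32-bit signed integer range.
#' @noRd
substream <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647)
}

#' Evaluate an expression with a temporary RNG seed
#' @noRd
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Format a numeric value with 6 significant digits for report output
#' @noRd
fmt_num <- function(x) signif(x, 6)
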