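#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: for sorted p-values p_(1) <=
#' ... <= p_(m), q_(i) = min over j >= i of min(1, p_(j) * m / j). Used
#' everywhere an adjusted p-value threshold is applied in the pipeline.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the original order.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when both groups have at most `exact_max`
#' observations and there are no ties; otherwise the normal approximation
#' with average ranks, variance tie correction, and continuity correction.
#' Degenerate inputs where every observation is identical return p = 1.
#'
#' @param a,b numeric vectors (each non-empty).
#' @param exact_max per-group size cutoff for the exact branch (default 10).
#' @return list with `statistic` (the rank-sum W statistic for group `a`)
#'   and `p_value`.
#' @export
rank_sum_test <- function(a, b, exact_max = 10) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(c(a, b)))) {
    stop("non-finite values in rank-sum input", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0
  if (stats::var(c(a, b)) == 0) {
    # all observations identical: no evidence of a shift
    return(list(statistic = length(a) * length(b) / 2, p_value = 1))
  }
  use_exact <- !ties && length(a) <= exact_max && length(b) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE,
                       alternative = "two.sided")
  )
  p <- wt$p.value
  if (!is.finite(p)) p <- 1
  list(statistic = unname(wt$statistic), p_value = min(p, 1))
}

#' Vectorized approximate rank-sum test over matrix rows
#'
#' Normal approximation with tie and continuity corrections, applied to
#' every row of `x` comparing columns in `idx` against the rest. Used for
#' per-gene marker testing where thousands of tests are run at once.
#'
#' @param x numeric matrix (genes x cells).
#' @param idx logical or integer vector selecting group-1 columns.
#' @return data frame with `statistic` and `p_value` per row.
#' @noRd
rank_sum_rows <- function(x, idx) {
  n <- ncol(x)
  if (is.logical(idx)) idx <- which(idx)
  n1 <- length(idx)
  n2 <- n - n1
  stat <- p <- numeric(nrow(x))
  for (g in seq_len(nrow(x))) {
    r <- rank(x[g, ])
    w <- sum(r[idx]) - n1 * (n1 + 1) / 2
    tie_tab <- table(x[g, ])
    tie_term <- sum(tie_tab^3 - tie_tab)
    sig2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sig2 <= 0) { stat[g] <- w; p[g] <- 1; next }
    z <- w - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sig2)
    stat[g] <- w
    p[g] <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  data.frame(statistic = stat, p_value = p)
}

#' Upper-tail hypergeometric overlap test
#'
#' For gene sets `a` and `b` drawn from a common `universe`, tests whether
#' the observed overlap is larger than expected: p = P(X >= |a n b|) with
#' X ~ Hypergeometric(N = |universe|, K = |a|, n = |b|).
#'
#' @param set_a,set_b character vectors (subsets of `universe`).
#' @param universe character vector of all eligible genes.
#' @return upper-tail p-value in (0, 1].
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  universe <- unique(universe)
  out_a <- setdiff(set_a, universe)
  out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b)) {
    stop("sets are not subsets of the universe; offenders: ",
         paste(utils::head(c(out_a, out_b), 5), collapse = ", "),
         call. = FALSE)
  }
  N <- length(universe)
  K <- length(set_a)
  n <- length(set_b)
  k <- length(intersect(set_a, set_b))
  if (k == 0) return(1)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  min(max(p, .Machine$double.xmin), 1)
}
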