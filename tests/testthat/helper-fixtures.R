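# Shared fixtures and independent oracles used across the suite.

# tiny labeled_counts built in code
tiny_counts <- function(species = "mouse") {
  m <- Matrix::sparseMatrix(i = c(1, 3), j = c(1, 2), x = c(2, 1),
                            dims = c(3, 2))
  labeled_counts(m, c("Apoe", "Cd86", "Slc1a3"), c("c1", "c2"), species)
}

# adjusted Rand index (contingency-table form), independent of any
# clustering package
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

# brute-force BH step-up: q_(i) = min_{j >= i} min(1, p_(j) * m / j)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, ps * m / seq_len(m))
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- q
  out
}

# exact two-sided rank-sum p by full enumeration of group labelings
rank_sum_enum <- function(a, b) {
  n1 <- length(a)
  vals <- c(a, b)
  r <- rank(vals)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(vals), n1)
  ws <- apply(combos, 2, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  mu <- n1 * length(b) / 2
  min(1, mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12))
}

# upper-tail hypergeometric by explicit log-space pmf summation
hyper_enum <- function(N, K, n, k) {
  if (k == 0) return(1)
  j <- k:min(K, n)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}

# brute-force TOM: explicit double loop over the textbook formula
tom_oracle <- function(a) {
  p <- nrow(a)
  k <- rowSums(a)
  tom <- diag(p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      l <- sum(a[i, ] * a[, j])
      tom[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    }
  }
  tom
}

# minimal module_set stand-in for conservation tests that do not need
# expression data
fake_module_set <- function(assignment, hub_genes, cell_type = "glia") {
  structure(list(cell_type = cell_type, assignment = assignment,
                 kme = NULL, hub_genes = hub_genes, eigengenes = NULL,
                 keys = NULL),
            class = "module_set")
}

fake_module_de <- function(modules, species, differential = TRUE,
                           direction = "up") {
  data.frame(module = modules, species = species, direction = direction,
             p_value = 0.001, p_adjusted = 0.001,
             is_differential = differential, testable = TRUE,
             stringsAsFactors = FALSE)
}

empty_degs <- function() {
  deg_table(data.frame(gene = character(), cell_type = character(),
                       log2fc = numeric(), p_adjusted = numeric()))
}

# small two-species integration scenario with a mouse-private population
private_pop_config <- function(seed, ct_marker_frac = 0.05,
                               ct_marker_shift = 1.5) {
  synth_config(
    n_genes_shared = 300, n_genes_private_per_species = 20,
    cell_types = list(synth_cell_type("glia", 80),
                      synth_cell_type("neuron", 80),
                      synth_cell_type("mouse_private", 60,
                                      species = "mouse")),
    n_samples_per_group = 2, modules = list(), nb_dispersion = 2,
    ct_marker_frac = ct_marker_frac, ct_marker_shift = ct_marker_shift,
    seed = seed)
}

small_integration_config <- function() {
  integration_config(n_anchor_features = 200, n_cca_dims = 15,
                     k_score = 20)
}
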