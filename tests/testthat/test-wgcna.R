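test_that("TOM formula matches the closed-form toy and a brute-force oracle", {
  # three genes, all pairwise adjacency 1: TOM is identically 1
  a1 <- matrix(1, 3, 3); diag(a1) <- 0
  expect_equal(tom_from_adjacency(a1), matrix(1, 3, 3))

  set.seed(33)
  for (rep in 1:5) {
    a <- matrix(runif(400), 20, 20)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    tom <- tom_from_adjacency(a)
    expect_equal(tom, tom_oracle(a), tolerance = 1e-10)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom))
    expect_equal(diag(tom), rep(1, 20))
  }
})

# two blocks of perfectly correlated genes over 40 metacells
perfect_block_expr <- function(n1 = 5, n2 = 9, n_mc = 40, seed = 2,
                               common = 0) {
  set.seed(seed)
  v <- rnorm(n_mc); w <- rnorm(n_mc); z <- rnorm(n_mc)
  rows <- c(lapply(seq_len(n1), function(i) i * (v + common * z) + i),
            lapply(seq_len(n2), function(i) (i + 1) * (w + common * z)))
  x <- do.call(rbind, rows)
  rownames(x) <- sprintf("g%02d", seq_len(n1 + n2))
  x
}

test_that("soft power selection picks 1 on a perfectly modular toy", {
  x <- perfect_block_expr()
  res <- pick_soft_power(x, soft_power_config(target_r2 = 0.8))
  expect_equal(res$power, 1)
})

test_that("soft power falls back to the best fit with a warning", {
  set.seed(44)
  noisy <- matrix(rnorm(200 * 30), 200, 30)
  rownames(noisy) <- paste0("g", 1:200)
  expect_warning(
    res <- pick_soft_power(noisy, soft_power_config(target_r2 = 1.0)),
    "argmax")
  expect_true(res$power %in% 1:20)
  # constant genes are excluded with a warning
  noisy[1, ] <- 5
  expect_warning(suppressWarnings(pick_soft_power(noisy)) -> res2,
                 NA)
  expect_warning(pick_soft_power(noisy,
                                 soft_power_config(target_r2 = 0.5)),
                 "constant")
})

test_that("consensus of identical species matrices equals the single TOM", {
  x <- perfect_block_expr(n1 = 6, n2 = 6)
  res <- consensus_tom(list(a = x, b = x), power = 4)
  single <- consensus_tom(list(a = x), power = 4)
  expect_equal(res$consensus, single$consensus, tolerance = 1e-12)
  # the minimum-consensus never exceeds either scaled per-species TOM
  y <- x + matrix(rnorm(length(x), sd = 0.3), nrow(x))
  rownames(y) <- rownames(x)
  res2 <- consensus_tom(list(a = x, b = y), power = 4)
  expect_true(all(res2$consensus <= res2$per_species[[1]] + 1e-12))
  expect_true(all(res2$consensus <= res2$per_species[[2]] + 1e-12))
  # mismatching gene sets are a hard error
  z <- y
  rownames(z) <- rev(rownames(y))
  expect_error(consensus_tom(list(x, z), 4), "differ")
})

test_that("module detection recovers perfect blocks and honours limits", {
  x <- perfect_block_expr(n1 = 30, n2 = 30, n_mc = 50, common = 0.05)
  tom <- consensus_tom(list(x), power = 6)$consensus
  asg <- detect_modules(tom, min_module_size = 10, expr = x)
  expect_equal(length(setdiff(unique(asg), "grey")), 2)
  expect_equal(length(unique(asg[1:30])), 1)
  expect_equal(length(unique(asg[31:60])), 1)
  expect_false(asg[1] == asg[31])

  # nothing reaches the size floor: everything grey
  asg2 <- detect_modules(tom, min_module_size = 40)
  expect_true(all(asg2 == "grey"))

  # merge_height 1 collapses (positively correlated) modules into one
  xpos <- perfect_block_expr(n1 = 30, n2 = 30, n_mc = 50,
                             common = 0.4)
  tpos <- consensus_tom(list(xpos), power = 6)$consensus
  asg3 <- detect_modules(tpos, min_module_size = 10, merge_height = 1,
                         expr = xpos)
  expect_equal(length(setdiff(unique(asg3), "grey")), 1)

  expect_error(detect_modules(matrix(c(1, 0.2, 0.8, 1), 2, 2)),
               "symmetric")
})

test_that("eigengenes honour the perfect-correlation limit and sign symmetry", {
  set.seed(11)
  v <- rnorm(30)
  x <- rbind(a = 2 * v + 1, b = 5 * v - 2,
             c = rnorm(30), d = rnorm(30))
  asg <- c(a = "M1", b = "M1", c = "M2", d = "M2")
  ms <- suppressWarnings(eigengenes_and_hubs(x, asg, n_hubs = 2))
  expect_equal(unname(ms$kme["a", "M1"]), 1, tolerance = 1e-8)
  expect_equal(unname(ms$kme["b", "M1"]), 1, tolerance = 1e-8)
  expect_equal(unname(sd(ms$eigengenes[, "M1"])), 1, tolerance = 1e-8)
  expect_equal(unname(cor(ms$eigengenes[, "M1"], v)), 1,
               tolerance = 1e-8)

  # negating the module genes flips the eigengene, kME unchanged
  x2 <- x
  x2[c("a", "b"), ] <- -x2[c("a", "b"), ]
  ms2 <- suppressWarnings(eigengenes_and_hubs(x2, asg, n_hubs = 2))
  expect_equal(unname(cor(ms2$eigengenes[, "M1"],
                          ms$eigengenes[, "M1"])), -1,
               tolerance = 1e-8)
  expect_equal(abs(ms2$kme[c("a", "b"), "M1"]),
               abs(ms$kme[c("a", "b"), "M1"]), tolerance = 1e-8)

  # single-gene module warns and uses the standardized profile
  expect_warning(
    eigengenes_and_hubs(x, c(a = "M1", b = "grey", c = "grey",
                             d = "grey")),
    "single gene")
})

test_that("no single gene beats the eigengene at representing its module", {
  set.seed(23)
  for (rep in 1:10) {
    n_mc <- 30; n_g <- 12
    e <- rnorm(n_mc)
    x <- t(vapply(seq_len(n_g), function(i)
      runif(1, 0.5, 2) * e + rnorm(n_mc, sd = runif(1, 0.3, 1.5)),
      numeric(n_mc)))
    rownames(x) <- paste0("g", seq_len(n_g))
    asg <- stats::setNames(rep("M1", n_g), rownames(x))
    ms <- eigengenes_and_hubs(x, asg)
    me_cor <- mean(cor(ms$eigengenes[, 1], t(x)))
    gene_cors <- cor(t(x))
    best_gene <- max(rowMeans(gene_cors))
    expect_gte(me_cor + 1e-8, best_gene)
  }
})

test_that("differential eigengene testing flags shifts with direction", {
  set.seed(55)
  keys <- data.frame(species = rep(c("mouse", "human"), each = 20),
                     condition = rep(rep(c("control", "alcohol"),
                                         each = 10), 2))
  shifted <- rnorm(40) + ifelse(keys$condition == "alcohol", 2, 0)
  flat <- rnorm(40)
  eg <- cbind(M1 = shifted, M2 = flat)
  de <- differential_module_expression(eg, keys)
  m1 <- de[de$module == "M1", ]
  expect_true(all(m1$is_differential))
  expect_true(all(m1$direction == "up"))
  m2 <- de[de$module == "M2", ]
  expect_false(any(m2$is_differential))

  # the threshold is strict: alpha equal to the attained adjusted p
  # must not flag
  p_star <- de$p_adjusted[de$module == "M1" & de$species == "mouse"]
  de2 <- differential_module_expression(eg, keys, alpha = p_star)
  expect_false(de2$is_differential[de2$module == "M1" &
                                     de2$species == "mouse"])

  # a missing condition makes the species untestable, never flagged
  keys3 <- keys
  keys3$condition[keys3$species == "human"] <- "control"
  de3 <- differential_module_expression(eg, keys3)
  expect_false(any(de3$is_differential[de3$species == "human"]))
  expect_false(any(de3$testable[de3$species == "human"]))
})
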