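# mouse/human module sets over a 40-gene ortholog universe
conservation_fixture <- function() {
  mg <- sprintf("Mg%02d", 1:40)
  hg <- toupper(mg)
  map <- ortholog_map(mg, hg)
  m_assign <- stats::setNames(
    c(rep("M1", 12), rep("M2", 12), rep("grey", 16)), mg)
  h_assign <- stats::setNames(
    c(rep("M1", 12), rep("grey", 16), rep("M2", 12)), hg)
  m_ms <- fake_module_set(m_assign,
                          list(M1 = mg[1:5], M2 = mg[13:17]))
  h_ms <- fake_module_set(h_assign,
                          list(M1 = hg[1:5], M2 = hg[29:33]))
  list(map = map, mouse = m_ms, human = h_ms, mg = mg, hg = hg)
}

test_that("the three conservation criteria are conjunctive", {
  fx <- conservation_fixture()
  de_all <- rbind(fake_module_de(c("M1", "M2"), "mouse"),
                  fake_module_de(c("M1", "M2"), "human"))
  res <- match_modules(fx$mouse, fx$human, fx$map, de_all)
  top <- res[res$mouse_module == "M1" & res$human_module == "M1", ]
  expect_true(top$is_module_of_interest)
  expect_equal(top$n_overlap, 12)
  expect_gt(length(top$shared_hubs[[1]]), 0)

  # mouse M2 and human M2 share no genes: never of interest
  mm22 <- res[res$mouse_module == "M2" & res$human_module == "M2", ]
  expect_equal(mm22$n_overlap, 0)
  expect_false(mm22$is_module_of_interest)

  # identical membership but disjoint hub lists: criterion (1) fails
  h_no_hub <- fake_module_set(fx$human$assignment,
                              list(M1 = fx$hg[6:10],
                                   M2 = fx$hg[34:38]))
  res2 <- match_modules(fx$mouse, h_no_hub, fx$map, de_all)
  top2 <- res2[res2$mouse_module == "M1" & res2$human_module == "M1", ]
  expect_lt(top2$p_adjusted, 0.05)
  expect_false(top2$is_module_of_interest)

  # only mouse differential: criterion (3) fails
  de_half <- rbind(fake_module_de(c("M1", "M2"), "mouse"),
                   fake_module_de(c("M1", "M2"), "human",
                                  differential = FALSE))
  res3 <- match_modules(fx$mouse, fx$human, fx$map, de_half)
  top3 <- res3[res3$mouse_module == "M1" & res3$human_module == "M1", ]
  expect_false(top3$is_module_of_interest)
  expect_true(top3$p_adjusted < 0.05 &&
                length(top3$shared_hubs[[1]]) > 0)
})

test_that("module-DEG overlap reports trace through the ortholog map", {
  fx <- conservation_fixture()
  pair <- list(mouse_module = "M1", human_module = "M1")

  # empty DEG tables give an empty core overlap
  rep0 <- overlap_with_degs(pair, fx$mouse, fx$human, empty_degs(),
                            empty_degs(), fx$map)
  expect_equal(rep0$n_deg_overlap, 0)
  expect_equal(rep0$n_module_overlap, 12)

  # single-gene trace with both species' symbols and directions
  dm <- deg_table(data.frame(gene = "Mg03", cell_type = "glia",
                             log2fc = 1.1, p_adjusted = 0.001))
  dh <- deg_table(data.frame(gene = "MG03", cell_type = "glia",
                             log2fc = -0.5, p_adjusted = 0.002))
  rep1 <- overlap_with_degs(pair, fx$mouse, fx$human, dm, dh, fx$map,
                            cell_type = "glia")
  expect_equal(rep1$n_deg_overlap, 1)
  expect_equal(rep1$overlap_genes_with_degs$human_symbol, "MG03")
  expect_equal(rep1$overlap_genes_with_degs$mouse_symbol, "Mg03")
  expect_equal(rep1$overlap_genes_with_degs$mouse_direction, "up")
  expect_equal(rep1$overlap_genes_with_degs$human_direction, "down")
  expect_true(all(rep1$overlap_genes_with_degs$human_symbol %in%
                    rep1$overlap_genes_module_only))
})

test_that("planted DEG-core overlap is exactly recovered end to end", {
  cfg <- synth_config(
    n_genes_shared = 60,
    cell_types = list(synth_cell_type("glia", 20)),
    modules = list(planted_module("m", 1:20, "glia",
                                  condition_shift = 1.5)),
    regulons = list(planted_regulon("Tfa", 1:10,
                                    frac_targets_de = 0.5)),
    seed = 3)
  ds <- generate_dataset(cfg)
  degs <- emit_truth_deg_table(ds$truth)
  map <- synth_ortholog_map(cfg)
  mg <- sprintf("Shrg%04d", 1:60)
  asg_m <- stats::setNames(c(rep("M1", 20), rep("grey", 40)), mg)
  asg_h <- stats::setNames(c(rep("M1", 20), rep("grey", 40)),
                           toupper(mg))
  pair <- list(mouse_module = "M1", human_module = "M1")
  repx <- overlap_with_degs(pair,
                            fake_module_set(asg_m, list(M1 = mg[1:3])),
                            fake_module_set(asg_h,
                                            list(M1 = toupper(mg[1:3]))),
                            degs$mouse, degs$human, map,
                            cell_type = "glia")
  # all 20 module genes are DE in both species (conserved shifted module)
  expect_equal(repx$n_deg_overlap, 20)
})

test_that("hypergeometric matching is calibrated under the null", {
  set.seed(202)
  n_genes <- 200
  fractions <- numeric(50)
  for (s in 1:50) {
    mg <- sprintf("Ng%03d", 1:n_genes)
    hg <- toupper(mg)
    map <- ortholog_map(mg, hg)
    m_assign <- stats::setNames(sample(c("M1", "M2", "M3", "grey"),
                                       n_genes, replace = TRUE), mg)
    h_assign <- stats::setNames(sample(c("M1", "M2", "M3", "grey"),
                                       n_genes, replace = TRUE), hg)
    de <- rbind(fake_module_de(c("M1", "M2", "M3"), "mouse"),
                fake_module_de(c("M1", "M2", "M3"), "human"))
    res <- match_modules(
      fake_module_set(m_assign, list(M1 = mg[1], M2 = mg[2],
                                     M3 = mg[3])),
      fake_module_set(h_assign, list(M1 = hg[4], M2 = hg[5],
                                     M3 = hg[6])),
      map, de)
    fractions[s] <- mean(res$p_adjusted < 0.05)
  }
  rate <- mean(fractions)
  se <- sd(fractions) / sqrt(50)
  expect_lte(rate, 0.05 + 2 * max(se, 0.01))
})
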