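test_that("pedigree construction validates parent links", {
  chain <- tibble::tibble(cell_id = c(1L, 2L, 3L),
                          parent_id = c(NA, 1L, 2L), frame = 1:3)
  tree <- build_tree(chain)
  expect_identical(tree$roots, 1L)
  expect_identical(max(tree$nodes$depth), 2L)
  expect_error(build_tree(tibble::tibble(cell_id = c(1L, 2L),
                                         parent_id = c(NA, 9L))),
               "9")
  expect_warning(build_tree(tibble::tibble(cell_id = c(1L, 2L, 3L),
                                           parent_id = c(NA, NA, 1L))),
                 "2 roots")
  expect_error(build_tree(tibble::tibble(cell_id = c(1L, 2L),
                                         parent_id = c(2L, 1L))),
               "Cycle")
  expect_error(build_tree(tibble::tibble(cell_id = c(1L, 2L, 2L),
                                         parent_id = c(NA, 1L, NA))),
               "multiple parents")
})

test_that("growth-stage matching takes the first frame at or past the ratio", {
  tab <- tibble::tibble(cell_id = 1L, frame = 1:3,
                        bud_ratio = c(0.1, 0.18, 0.22), h = c(0.4, 0.5, 0.6))
  out <- stage_matched_h(tab)
  expect_identical(out$stage_frame, 3L)
  expect_identical(out$h, 0.6)
  exact <- tibble::tibble(cell_id = 1L, frame = 1:2,
                          bud_ratio = c(0.1, 0.2), h = c(0.1, 0.2))
  expect_identical(stage_matched_h(exact)$stage_frame, 2L) # inclusive
  never <- tibble::tibble(cell_id = 1L, frame = 1:3,
                          bud_ratio = c(0.05, 0.1, 0.15), h = 0.5)
  expect_identical(nrow(stage_matched_h(never)), 0L)
})

test_that("relation pairs link mothers, progeny, and aged selves", {
  pairs <- relation_pairs(toy_lineage_records())
  md <- pairs[pairs$relation == "M-D", ]
  # mother 1 at her stage frame (frame 2, h 0.52) vs daughter 2 at frame 4
  expect_identical(md$h_first[md$other_id == 2L], 0.52)
  expect_identical(md$h_second[md$other_id == 2L], 0.35)
  mmd <- pairs[pairs$relation == "M-M_D", ]
  # mother 1 at the daughter's stage frame 4: h 0.58
  expect_identical(mmd$h_second[mmd$mother_id == 1L & mmd$h_first == 0.52],
                   0.58)
  gd <- pairs[pairs$relation == "M-GD", ]
  # granddaughter 3 reaches 20% at frame 5 (0.3 at frame 5? first >= 0.2
  # is frame 5 with ratio 0.3): h 0.25; grandmother 1 stage h 0.52
  expect_identical(gd$h_first, 0.52)
  expect_identical(gd$h_second, 0.25)
  mmgd <- pairs[pairs$relation == "M-M_GD", ]
  expect_identical(mmgd$h_second, 0.60) # mother 1 at frame 5
})

test_that("rank correlations handle ties, tiny groups, constant vectors", {
  pairs <- tibble::tibble(
    population = 1L, relation = "M-D",
    h_first = c(1, 2, 3), h_second = c(2, 1, 3))
  out <- relation_correlation(pairs)
  expect_equal(out$rho, 0.5) # hand-computed rank correlation
  mono <- tibble::tibble(population = 1L, relation = "M-D",
                         h_first = 1:5, h_second = (1:5)^2)
  expect_equal(relation_correlation(mono)$rho, 1)
  rev <- tibble::tibble(population = 1L, relation = "M-D",
                        h_first = 1:5, h_second = 5:1)
  expect_equal(relation_correlation(rev)$rho, -1)
  small <- tibble::tibble(population = 1L, relation = "M-D",
                          h_first = 1:2, h_second = 2:1)
  expect_warning(out2 <- relation_correlation(small), "dropped")
  expect_identical(nrow(out2), 0L)
  const <- tibble::tibble(population = 1L, relation = "M-D",
                          h_first = c(1, 1, 1), h_second = 1:3)
  expect_warning(relation_correlation(const), "dropped")
})

test_that("paired comparison of relations behaves at the edges", {
  co <- tibble::tibble(
    population = rep(1:9, 2),
    relation = rep(c("M-M_D", "M-D"), each = 9),
    rho = c(seq(0.8, 0.88, 0.01), seq(0.5, 0.58, 0.01) +
              withr::with_seed(1, stats::rnorm(9, 0, 0.01))))
  res <- compare_relations(co, "M-M_D", "M-D")
  expect_lt(res$p_value, 0.05)
  expect_gt(res$mean_a, res$mean_b)
  same <- tibble::tibble(population = rep(1:4, 2),
                         relation = rep(c("A", "B"), each = 4),
                         rho = rep(c(0.7, 0.6, 0.8, 0.75), 2))
  expect_warning(r2 <- compare_relations(same, "A", "B"), "Zero-variance")
  expect_equal(r2$p_value, 1)
  expect_equal(r2$t, 0)
  one <- tibble::tibble(population = 1L, relation = c("A", "B"),
                        rho = c(0.5, 0.4))
  expect_error(compare_relations(one, "A", "B"), "at least 2")
})

test_that("asymmetric transmission separates self- from progeny correlation", {
  # strong asymmetry (few copies to the daughter): a mother's later self
  # stays closer to her original heteroplasmy than her daughter does
  pairs <- dplyr::bind_rows(lapply(1:9, function(p) {
    cfg <- generator_config(
      sim = sim_config(ndau = 6, nspl = 4, n_generations = 7),
      total_hours = 11.5, seed = 7 + 1000 * p)
    tr <- generate_truth_lineage(cfg)
    tr$h <- ifelse(tr$copies0 + tr$copies1 > 0,
                   tr$copies1 / (tr$copies0 + tr$copies1), NA_real_)
    pr <- relation_pairs(tr)
    pr$population <- p
    pr
  }))
  co <- suppressWarnings(relation_correlation(pairs))
  means <- tapply(co$rho, co$relation, mean, na.rm = TRUE)
  expect_gt(means[["M-M_D"]], means[["M-D"]])
  expect_lte(means[["M-GD"]], means[["M-D"]])
  res <- compare_relations(co, "M-M_D", "M-D")
  expect_gt(res$mean_a, res$mean_b)
})
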