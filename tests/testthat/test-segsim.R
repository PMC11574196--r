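test_that("sim_config enforces the model's parameter bounds", {
  expect_s3_class(sim_config(ndau = 16, nspl = 32), "sim_config")
  expect_error(sim_config(ndau = 17), "floor\\(n_copies/2\\)")
  expect_error(sim_config(ndau = 0), "ndau")
  expect_error(sim_config(nspl = 0), "nspl")
  expect_error(sim_config(nspl = 33), "nspl")
  expect_error(sim_config(n_copies = 1), "n_copies")
  expect_error(sim_config(founder_fraction1 = 1.2), "founder_fraction1")
})

test_that("daughter cap and transmitted-fraction rescaling match the model", {
  expect_identical(daughter_cap(32), 16L)
  expect_identical(daughter_cap(33), 16L)
  expect_identical(scale_ndau(14, 32, 56), 25L)
  expect_identical(scale_ndau(14, 32, 90), 39L)
})

test_that("founder patterns interleave, block, or reproduce explicit arrays", {
  expect_identical(init_founder(sim_config(n_copies = 32)),
                   rep(c(0L, 1L), 16))
  expect_identical(init_founder(sim_config(n_copies = 2, ndau = 1,
                                           nspl = 1)), c(0L, 1L))
  expect_identical(
    init_founder(sim_config(n_copies = 10, ndau = 5, nspl = 5,
                            founder_pattern = "non_mixed")),
    c(rep(0L, 5), rep(1L, 5)))
  expect_identical(
    init_founder(sim_config(n_copies = 10, ndau = 5, nspl = 5,
                            founder_pattern = "semi_mixed")),
    c(0L, 0L, 1L, 1L, 1L, 0L, 0L, 0L, 1L, 1L))
  expect_identical(
    init_founder(sim_config(n_copies = 6, ndau = 3, nspl = 3,
                            founder_pattern = "001101")),
    c(0L, 0L, 1L, 1L, 0L, 1L))
  expect_error(init_founder(sim_config(founder_pattern = "0101")), "length")
  # allele-1 count always matches the rounded fraction, for every pattern
  for (pat in c("mixed", "semi_mixed", "non_mixed")) {
    for (n in c(10L, 26L, 32L, 38L, 57L)) {
      for (f in c(0.25, 0.4, 0.5, 0.63)) {
        cfg <- sim_config(n_copies = n, ndau = 2, nspl = 2,
                          founder_pattern = pat, founder_fraction1 = f)
        arr <- init_founder(cfg)
        expect_length(arr, n)
        expect_identical(sum(arr), as.integer(round(n * f)))
      }
    }
  }
  expect_warning(init_founder(sim_config(founder_fraction1 = 0)),
                 "Degenerate founder")
})

test_that("relaxed replication grows to capacity and homoplasmy is absorbing", {
  withr::local_seed(1)
  grown <- replicate_to_capacity(rep(0L, 14), 32L)
  expect_identical(grown, rep(0L, 32))
  expect_identical(replicate_to_capacity(c(0L, 1L), 2L), c(0L, 1L))
  expect_error(replicate_to_capacity(rep(1L, 40), 32L), "depletion")
  # composition can only grow: each input allele keeps at least its count
  for (i in 1:20) {
    arr <- sample(c(0L, 1L), 8, replace = TRUE)
    out <- replicate_to_capacity(arr, 20L)
    expect_length(out, 20L)
    expect_gte(sum(out == 1L), sum(arr == 1L))
    expect_gte(sum(out == 0L), sum(arr == 0L))
  }
})

test_that("growing '01' to four copies is uniform on {1,2,3} (urn oracle)", {
  # exact enumeration of all pick sequences as the oracle
  oracle <- polya_count_distribution(c(0L, 1L), 4L)
  expect_equal(unname(oracle), rep(1 / 3, 3), tolerance = 1e-12)
  expect_identical(names(oracle), c("1", "2", "3"))
  withr::local_seed(42)
  draws <- replicate(3000, sum(replicate_to_capacity(c(0L, 1L), 4L)))
  tab <- table(factor(draws, levels = 1:3))
  expect_gt(stats::chisq.test(tab, p = unname(oracle))$p.value, 0.01)
})

test_that("shuffling permutes contiguous fragments and conserves alleles", {
  arr <- c(0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L)
  expect_identical(shuffle_array(arr, 1L), arr)
  expect_error(shuffle_array(arr, 9L), "nspl")
  withr::local_seed(7)
  for (i in 1:50) {
    nspl <- sample(2:8, 1)
    out <- shuffle_array(arr, nspl)
    expect_identical(sort(out), sort(arr))
  }
  # two copies, two fragments: both orders equally likely
  withr::local_seed(8)
  flips <- replicate(2000, paste(shuffle_array(c(0L, 1L), 2L),
                                 collapse = ""))
  expect_gt(stats::chisq.test(table(flips))$p.value, 0.01)
})

test_that("singleton fragments give a uniform random permutation", {
  # with nspl = length, fragment order is a uniform permutation: '0011'
  # yields the 4!/(2!2!) = 6 distinct strings with equal probability
  withr::local_seed(9)
  draws <- replicate(6000, paste(shuffle_array(c(0L, 0L, 1L, 1L), 4L),
                                 collapse = ""))
  tab <- table(draws)
  expect_length(tab, 6L)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("division is a fixed-end split conserving the allele multiset", {
  parts <- divide_array(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L), 3L)
  expect_identical(parts$daughter, c(0L, 0L, 0L))
  expect_identical(parts$mother, c(0L, 1L, 1L, 1L, 1L))
  arr32 <- rep(c(0L, 1L), 16)
  halves <- divide_array(arr32, 16L)
  expect_length(halves$mother, 16L)
  expect_length(halves$daughter, 16L)
  expect_identical(c(halves$daughter, halves$mother), arr32)
  expect_error(divide_array(arr32, 17L), "shorter")
  arr56 <- rep(c(0L, 1L), 28)
  s56 <- divide_array(arr56, 28L)
  expect_length(s56$mother, 28L)
  expect_length(s56$daughter, 28L)
})

test_that("allele_fraction counts allele 1", {
  expect_identical(allele_fraction(c(0L, 1L, 0L, 1L)), 0.5)
  expect_identical(allele_fraction(rep(1L, 5)), 1)
  expect_identical(allele_fraction(c(0L, 0L, 0L, 1L)), 0.25)
  expect_error(allele_fraction(integer(0)), "at least one")
})

test_that("population growth follows the division scheduling", {
  cfg <- sim_config(ndau = 14, nspl = 4, n_generations = 5, seed = 3)
  sim <- simulate_population(cfg)
  counts <- dplyr::count(sim, generation)$n
  expect_identical(counts, c(1L, 2L, 3L, 5L, 8L, 13L))
  expect_identical(unique(sim$time_h), seq(0, 7.5, by = 1.5))
  # without the daughter maturation delay, cells double every cycle
  cfg2 <- sim_config(ndau = 14, nspl = 4, n_generations = 3, seed = 3,
                     daughter_delay = FALSE)
  sim2 <- simulate_population(cfg2)
  expect_identical(dplyr::count(sim2, generation)$n, c(1L, 2L, 4L, 8L))
  # same config, same seed: bit-identical output
  expect_identical(simulate_population(cfg), sim)
})

test_that("a homoplasmic founder stays homoplasmic forever", {
  cfg <- sim_config(ndau = 10, nspl = 8, n_generations = 4,
                    founder_pattern = "mixed", founder_fraction1 = 0,
                    seed = 5)
  sim <- suppressWarnings(simulate_population(cfg))
  expect_true(all(sim$allele1_count == 0L))
  expect_true(all(sim$strict_homoplasmic == 1L))
  by_gen <- split(sim, sim$generation)
  expect_true(all(vapply(by_gen, homoplasmic_fraction, numeric(1)) == 1))
})

test_that("homoplasmy is absorbing: counts never drop, fractions rise", {
  # homoplasmic cells only beget homoplasmic cells, so the number of
  # strictly homoplasmic cells can never decrease; when every cell divides
  # each cycle the homoplasmic *fraction* is monotone too
  for (seed in 1:5) {
    cfg <- sim_config(ndau = 8, nspl = 4, n_generations = 5,
                      n_replicates = 2, seed = seed)
    sim <- simulate_population(cfg)
    for (r in unique(sim$replicate)) {
      sub <- sim[sim$replicate == r, ]
      n_homo <- vapply(split(sub, sub$generation),
                       function(s) sum(s$strict_homoplasmic), numeric(1))
      expect_true(all(diff(n_homo) >= 0))
    }
    cfg2 <- sim_config(ndau = 8, nspl = 4, n_generations = 5, seed = seed,
                       daughter_delay = FALSE)
    sim2 <- simulate_population(cfg2)
    fr <- vapply(split(sim2, sim2$generation), homoplasmic_fraction,
                 numeric(1))
    expect_true(all(diff(fr) >= -1e-12))
  }
})

test_that("homoplasmic_fraction supports strict and threshold modes", {
  snap <- tibble::tibble(allele_fraction = c(0, 0.5, 1))
  expect_equal(homoplasmic_fraction(snap, "strict"), 2 / 3)
  snap2 <- tibble::tibble(allele_fraction = c(0.2, 0.5, 0.9))
  expect_equal(homoplasmic_fraction(snap2, "thresholds",
                                    thresholds = c(0.33, 0.71)), 2 / 3)
  expect_error(homoplasmic_fraction(snap2[0, ]), "no cells")
})
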