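small_gen <- function(seed = 1, ...) {
  generator_config(sim = sim_config(ndau = 14, nspl = 4, n_generations = 3),
                   total_hours = 5, seed = seed, ...)
}

test_that("truth lineages respect copy-number bookkeeping", {
  cfg <- small_gen()
  truth <- generate_truth_lineage(cfg)
  n <- cfg$sim$n_copies
  expect_true(all(truth$copies0 >= 0 & truth$copies1 >= 0))
  expect_true(all(truth$copies0 + truth$copies1 <= n + 1e-9))
  # the founder starts at capacity
  f0 <- truth[truth$cell_id == 1L & truth$frame == 1L, ]
  expect_equal(f0$copies0 + f0$copies1, n)
  # a dividing mother dips below capacity and recovers within the cycle:
  # founder at the first post-division frame vs the next cycle boundary
  founder <- truth[truth$cell_id == 1L, ]
  mid <- founder[abs(founder$time_h - 1.75) < 1e-9, ]
  end <- founder[abs(founder$time_h - 3.0) < 1e-9, ]
  expect_lt(mid$copies0 + mid$copies1, n)
  expect_equal(end$copies0 + end$copies1, n, tolerance = 1e-9)
  # a daughter starts near zero and gains its allocation in the
  # exchange window
  d <- truth[truth$cell_id == 2L, ]
  expect_lt(d$copies0[1] + d$copies1[1], 1e-9)
  at_exchange_end <- d[which(d$time_h - d$time_h[1] >= 47.5 / 60)[1], ]
  expect_equal(at_exchange_end$copies0 + at_exchange_end$copies1,
               d$alloc0[1] + d$alloc1[1], tolerance = 1.5)
  # no dropout: no mature cell sits at zero copies
  mature_frames <- truth[truth$time_h - 1.5 * floor(truth$time_h / 1.5)
                         > 47.5 / 60, ]
  expect_true(all(mature_frames$copies0 + mature_frames$copies1 > 0))
})

test_that("volumes and bud ratios follow the growth model", {
  truth <- generate_truth_lineage(small_gen())
  expect_true(all(truth$volume > 0))
  expect_true(all(truth$bud_ratio >= 0, na.rm = TRUE))
  expect_true(all(truth$bud_ratio <= 1, na.rm = TRUE))
  # every dividing cell crosses the 20% bud stage at some frame
  budding <- truth[!is.na(truth$bud_ratio), ]
  expect_gt(nrow(budding), 0)
  expect_true(any(budding$bud_ratio >= 0.2))
})

test_that("a whole-series CAP window yields an exact exponential decay", {
  cfg <- generator_config(noise_cv = 0, background_sd = 0, seed = 3)
  ser <- generate_cap_series(cfg, hours = 6)
  A <- cfg$synthesis_gain * cfg$sim$n_copies /
    (cfg$protein_decay_k * cfg$volume_fl)
  C <- cfg$cell_autofluor + cfg$background_mean
  expect_equal(ser$intensity,
               A * exp(-cfg$protein_decay_k * ser$time_h) + C,
               tolerance = 1e-9)
})

test_that("constant copies without CAP hold the analytic steady state", {
  cfg <- generator_config(noise_cv = 0, background_sd = 0,
                          cell_autofluor = 0, seed = 4)
  times <- seq(0, 3, by = 0.25)
  truth <- tibble::tibble(frame = seq_along(times), time_h = times,
                          cell_id = 1L, parent_id = NA_integer_,
                          copies0 = 0, copies1 = 20,
                          volume = cfg$volume_fl, bud_ratio = NA_real_)
  rec <- copies_to_intensity(truth, cfg)
  ss <- cfg$synthesis_gain * 20 / (cfg$protein_decay_k * cfg$volume_fl) +
    cfg$background_mean
  expect_equal(rec$i_mkate, rep(ss, length(times)), tolerance = 1e-9)
  # zero copies, zero protein: background only
  truth0 <- dplyr::mutate(truth, copies1 = 0)
  rec0 <- copies_to_intensity(truth0, cfg)
  expect_equal(rec0$i_mkate, rep(cfg$background_mean, length(times)),
               tolerance = 1e-12)
})

test_that("foci streams are Poisson draws at the configured rate", {
  zero <- generate_foci_stream(generator_config(foci_rate_per_5min = 0,
                                                seed = 5))
  expect_true(all(zero$crossings == 0))
  s1 <- generate_foci_stream(generator_config(seed = 6), n_pairs = 93)
  s2 <- generate_foci_stream(generator_config(seed = 6), n_pairs = 93)
  expect_identical(s1, s2)
  expect_identical(nrow(s1), 93L)
})

test_that("the full study is reproducible and single-variant founders stay pure", {
  cfg <- small_gen(seed = 9)
  s1 <- generate_heteroplasmy_study(cfg, n_populations = 2)
  s2 <- generate_heteroplasmy_study(cfg, n_populations = 2)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth, s2$truth)
  expect_true(all(c("i_ng", "i_mkate", "bg_ng", "bg_mkate", "volume",
                    "bud_ratio", "parent_id") %in% names(s1$records)))
  # ground truth accompanies observables, same keys
  expect_identical(nrow(s1$records), nrow(s1$truth))
  pure <- generator_config(
    sim = sim_config(founder_fraction1 = 1, n_generations = 3),
    total_hours = 5, seed = 10)
  st <- suppressWarnings(generate_heteroplasmy_study(pure,
                                                     n_populations = 2))
  # median normalization is meaningless when one channel has no signal;
  # newborn buds at their birth frame have no mtDNA yet, so only cells
  # that already carry copies are classifiable
  htab <- suppressWarnings(add_h_values(st$records,
                                        median_normalize = FALSE))
  j <- merge(htab, st$truth[, c("population", "cell_id", "frame",
                                "copies0", "copies1")],
             by = c("population", "cell_id", "frame"))
  j <- j[!is.na(j$h) & j$copies0 + j$copies1 > 0.5, ]
  expect_true(all(classify_h(j$h) == "homo_mKate"))
})

test_that("the pipeline reproduces a three-class final h distribution", {
  cfg <- generator_config(sim = sim_config(ndau = 14, nspl = 4,
                                           n_generations = 5), seed = 42)
  study <- generate_heteroplasmy_study(cfg, n_populations = 9)
  htab <- suppressWarnings(add_h_values(study$records))
  last <- htab[htab$frame >= max(htab$frame) - 1 & !is.na(htab$h), ]
  shares <- prop.table(table(classify_h(last$h)))
  expect_true(all(shares > 0.05)) # NG-homoplasmic, heteroplasmic, mKate
  # h orientation: truth-homoplasmic mKate cells sit above the middle
  truth_last <- study$truth[study$truth$frame >= max(study$truth$frame) - 1, ]
  j <- merge(last, truth_last, by = c("population", "cell_id", "frame"))
  expect_gt(min(j$h[j$true_fraction1 == 1]), 0.5)
  expect_lt(max(j$h[j$true_fraction1 == 0]), 0.5)
})
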