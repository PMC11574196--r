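# Independent oracles and small fixtures used across test files.

# Exhaustive enumeration of Polya-urn growth: returns the exact probability
# distribution of the allele-1 count after growing `array` to `target`
# copies, where each step picks one existing copy uniformly at random and
# inserts an identical allele next to it. Enumerates every pick sequence.
polya_count_distribution <- function(array, target) {
  probs <- new.env()
  recurse <- function(arr, p) {
    if (length(arr) == target) {
      key <- as.character(sum(arr))
      probs[[key]] <- (if (is.null(probs[[key]])) 0 else probs[[key]]) + p
      return(invisible())
    }
    len <- length(arr)
    for (pos in seq_len(len)) {
      recurse(append(arr, arr[pos], after = pos), p / len)
    }
  }
  recurse(array, 1)
  counts <- sort(as.integer(ls(probs)))
  stats::setNames(vapply(as.character(counts), function(k) probs[[k]],
                         numeric(1)), counts)
}

# A minimal hand-built tracked-cell table: three generations
# (1 -> 2 -> 3), each cell observed over several frames with bud ratios
# crossing 20% and known h values.
toy_lineage_records <- function() {
  tibble::tibble(
    frame     = c(1L, 2L, 3L, 4L, 5L,   2L, 3L, 4L, 5L,   4L, 5L),
    cell_id   = c(1L, 1L, 1L, 1L, 1L,   2L, 2L, 2L, 2L,   3L, 3L),
    parent_id = c(NA, NA, NA, NA, NA,   1L, 1L, 1L, 1L,   2L, 2L),
    bud_ratio = c(0.1, 0.25, 0.4, 0.5, 0.6,
                  NA, 0.15, 0.22, 0.5,
                  0.18, 0.3),
    h         = c(0.50, 0.52, 0.55, 0.58, 0.60,
                  0.30, 0.32, 0.35, 0.40,
                  0.20, 0.25)
  )
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")

# trimodal h geometry with homoplasmic modes near 0.15 / 0.85
trimodal_sample <- function(n = 5000, seed = 5) {
  withr::with_seed(seed, {
    h <- c(stats::rnorm(0.3 * n, 0.15, 0.05),
           stats::rnorm(0.3 * n, 0.50, 0.08),
           stats::rnorm(0.4 * n, 0.85, 0.05))
    pmin(pmax(h, 0), 1)
  })
}
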