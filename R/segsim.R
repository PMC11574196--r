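#' Simulation configuration for mtDNA segregation
#'
#' Bundles all parameters of the array-based segregation model. Each cell
#' carries one unbranched mitochondrion, represented as an ordered integer
#' vector over alleles \{0, 1\}. Per synchronous cell cycle every cell
#' replicates its mtDNA back to `n_copies` by relaxed (Polya-urn)
#' replication, shuffles the array by splitting it into `nspl` contiguous
#' fragments that re-fuse in random order, and divides, passing the first
#' `ndau` copies to the daughter.
#'
#' @param n_copies Target mtDNA copies per cell (default 32, the measured
#'   average for diploid cells).
#' @param ndau Copies transmitted to the daughter per division. Capped at
#'   `floor(n_copies / 2)` (the daughter receives the shorter part).
#' @param nspl Number of fragments per shuffling event, in
#'   `1..n_copies`. `nspl = 1` means no shuffling.
#' @param founder_pattern One of `"mixed"` (maximally interleaved,
#'   `0101...`), `"semi_mixed"` (`0011100011...`), `"non_mixed"`
#'   (`0000011111...`), or an explicit allele sequence given as a string of
#'   0/1 characters or an integer vector.
#' @param founder_fraction1 Fraction of allele 1 in the founder (default 0.5).
#' @param n_generations Number of synchronous division cycles.
#' @param generation_hours Wall-clock duration of one cycle (default 1.5 h,
#'   so generation 5 falls at t = 7.5 h).
#' @param n_replicates Independent simulation runs.
#' @param seed RNG seed; replicate `r` uses `seed + r`.
#' @param daughter_delay If `TRUE` (default), a newborn daughter matures
#'   for one cycle — growing and replicating its mtDNA to capacity — before
#'   its first division, so cells per founder follow 1, 2, 3, 5, 8, 13, ...
#'   (division waits for the copy number to be reached, and replication is
#'   what limits the daughter). With `FALSE` every cell divides every
#'   cycle and cell counts double each generation.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(ndau = 14, nspl = 4, n_generations = 5)
sim_config <- function(n_copies = 32L, ndau = 14L, nspl = 4L,
                       founder_pattern = "mixed", founder_fraction1 = 0.5,
                       n_generations = 5L, generation_hours = 1.5,
                       n_replicates = 1L, seed = 1L,
                       daughter_delay = TRUE) {
  n_copies <- as.integer(n_copies)
  ndau <- as.integer(ndau)
  nspl <- as.integer(nspl)
  if (n_copies < 2L) stop("`n_copies` must be at least 2.")
  if (ndau < 1L || ndau > n_copies %/% 2L) {
    stop("`ndau` must satisfy 1 <= ndau <= floor(n_copies/2) = ",
         n_copies %/% 2L, " (the daughter receives the shorter part).")
  }
  if (nspl < 1L || nspl > n_copies) {
    stop("`nspl` must satisfy 1 <= nspl <= n_copies.")
  }
  if (n_generations < 0L) stop("`n_generations` must be >= 0.")
  if (founder_fraction1 < 0 || founder_fraction1 > 1) {
    stop("`founder_fraction1` must lie in [0, 1].")
  }
  structure(
    list(n_copies = n_copies, ndau = ndau, nspl = nspl,
         founder_pattern = founder_pattern,
         founder_fraction1 = founder_fraction1,
         n_generations = as.integer(n_generations),
         generation_hours = generation_hours,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed),
         daughter_delay = isTRUE(daughter_delay)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> n =", x$n_copies, "| ndau =", x$ndau, "| nspl =", x$nspl,
      "| founder =", if (is.character(x$founder_pattern) &&
                         length(x$founder_pattern) == 1L)
        x$founder_pattern else "<explicit>",
      sprintf("(f1 = %.2f)", x$founder_fraction1),
      "|", x$n_generations, "generations x", x$generation_hours, "h |",
      x$n_replicates, "replicate(s), seed", x$seed, "\n")
  invisible(x)
}

#' Maximum copies a daughter cell can inherit
#'
#' The daughter receives the shorter of the two division parts, so the cap
#' is half of the cell's copy number: 16 for 32 copies, 28 for 56, 45 for 90.
#'
#' @param n_copies Copies per cell.
#' @return Integer, `floor(n_copies / 2)`.
#' @export
daughter_cap <- function(n_copies) as.integer(n_copies) %/% 2L

#' Rescale a transmitted copy number to another total copy number
#'
#' Maps an `ndau` value at one copy number to the equivalent value at
#' another, keeping the transmitted fraction fixed (e.g. 14 of 32 copies is
#' ~44%, which corresponds to 25 of 56 and 39 of 90 copies).
#'
#' @param ndau Transmitted copies at the reference copy number.
#' @param n_from Reference copy number.
#' @param n_to New copy number.
#' @return Integer, `ndau / n_from * n_to` rounded half away from zero
#'   (14 of 32 maps to 25 of 56 and 39 of 90).
#' @export
scale_ndau <- function(ndau, n_from, n_to) {
  as.integer(floor(ndau / n_from * n_to + 0.5))
}

parse_allele_string <- function(x) {
  alleles <- as.integer(strsplit(x, "", fixed = TRUE)[[1]])
  if (anyNA(alleles) || !all(alleles %in% c(0L, 1L))) {
    stop("Explicit founder pattern must contain only 0 and 1 symbols.")
  }
  alleles
}

#' Construct the founder cell's mtDNA array
#'
#' Builds the allele sequence of the heteroplasmic founder. `"mixed"`
#' interleaves the two alleles maximally evenly (for a 50% fraction this is
#' `0101...`); `"semi_mixed"` and `"non_mixed"` generalise the block
#' patterns `0011100011...` and `0000011111...` to any copy number, always
#' with `round(n_copies * founder_fraction1)` copies of allele 1.
#'
#' @param config A [sim_config()].
#' @return Integer vector of 0/1 alleles of length `config$n_copies`.
#' @export
#' @examples
#' init_founder(sim_config(n_copies = 10, founder_pattern = "non_mixed"))
init_founder <- function(config) {
  n <- config$n_copies
  pat <- config$founder_pattern
  if (is.numeric(pat)) pat <- paste(as.integer(pat), collapse = "")
  if (!pat[1] %in% c("mixed", "semi_mixed", "non_mixed")) {
    alleles <- parse_allele_string(pat[1])
    if (length(alleles) != n) {
      stop("Explicit founder pattern length (", length(alleles),
           ") does not match n_copies (", n, ").")
    }
    return(alleles)
  }
  k <- as.integer(round(n * config$founder_fraction1))
  if (k == 0L || k == n) {
    warning("Degenerate founder: only one allele present (k1 = ", k,
            " of ", n, " copies).")
  }
  if (pat == "mixed") {
    # Bresenham-style even spreading of k ones among n positions
    idx <- seq_len(n)
    alleles <- as.integer(floor(idx * k / n) - floor((idx - 1L) * k / n))
  } else if (pat == "non_mixed") {
    alleles <- c(rep(0L, n - k), rep(1L, k))
  } else { # semi_mixed: tile the canonical block motif, repair the count
    motif <- c(0L, 0L, 1L, 1L, 1L, 0L, 0L, 0L, 1L, 1L)
    alleles <- rep_len(motif, n)
    excess <- sum(alleles) - k
    if (excess != 0L) {
      flip_from <- if (excess > 0L) 1L else 0L
      pos <- rev(which(alleles == flip_from))[seq_len(abs(excess))]
      alleles[pos] <- 1L - flip_from
    }
  }
  alleles
}

#' Relaxed replication of an mtDNA array up to capacity
#'
#' Grows the array to `target_n` copies one replication at a time. Each step
#' picks an existing molecule uniformly at random (a Polya urn: the same
#' molecule may template several rounds while others never replicate) and
#' inserts an identical copy immediately to the right of the template.
#'
#' @param array Integer 0/1 allele vector.
#' @param target_n Target copy number; must be `>= length(array)` (the model
#'   has no mtDNA degradation).
#' @return Integer allele vector of length `target_n`.
#' @export
#' @examples
#' set.seed(1)
#' replicate_to_capacity(c(0L, 1L), 4L)
replicate_to_capacity <- function(array, target_n) {
  len <- length(array)
  if (len > target_n) {
    stop("Array length (", len, ") exceeds target (", target_n,
         "); the model postulates no mtDNA depletion.")
  }
  while (len < target_n) {
    pos <- sample.int(len, 1L)
    array <- c(array[seq_len(pos)], array[pos],
               if (pos < len) array[(pos + 1L):len])
    len <- len + 1L
  }
  array
}

#' Fission-fusion shuffling of an mtDNA array
#'
#' Splits the array into `nspl` contiguous fragments at `nspl - 1` distinct
#' internal cut points drawn uniformly at random, then concatenates the
#' fragments in uniformly random order (never reversed). Mimics mitochondrial
#' fission followed by re-fusion; `nspl = 1` leaves the array unchanged.
#'
#' @param array Integer 0/1 allele vector.
#' @param nspl Number of fragments, in `1..length(array)`.
#' @return Integer allele vector, a permutation of the input fragments.
#' @export
shuffle_array <- function(array, nspl) {
  len <- length(array)
  nspl <- as.integer(nspl)
  if (nspl < 1L || nspl > len) {
    stop("`nspl` must satisfy 1 <= nspl <= length(array) = ", len, ".")
  }
  if (nspl == 1L || len == 1L) return(array)
  cuts <- sort(sample.int(len - 1L, nspl - 1L))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, len)
  order <- sample.int(nspl)
  unlist(lapply(order, function(i) array[starts[i]:ends[i]]),
         use.names = FALSE)
}

#' Divide an mtDNA array between mother and daughter
#'
#' The array splits into two parts; the daughter receives the shorter part
#' with exactly `ndau` copies. By convention the daughter takes the left
#' end; because shuffling randomises fragment order beforehand, this is
#' distributionally equivalent to a random end.
#'
#' @param array Integer 0/1 allele vector.
#' @param ndau Copies for the daughter; at most `floor(length(array) / 2)`.
#' @return List with integer vectors `mother` and `daughter`.
#' @export
#' @examples
#' divide_array(c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L), ndau = 3)
divide_array <- function(array, ndau) {
  len <- length(array)
  ndau <- as.integer(ndau)
  if (ndau < 1L || ndau > len %/% 2L) {
    stop("`ndau` must satisfy 1 <= ndau <= floor(length/2) = ", len %/% 2L,
         " (the daughter receives the shorter part).")
  }
  list(mother = array[(ndau + 1L):len], daughter = array[seq_len(ndau)])
}

#' Fraction of allele 1 in an array
#'
#' The ground-truth heteroplasmy of a simulated cell, on the same scale as
#' the fluorescence-derived h-value (allele 1 plays the role of the
#' mKate2-marked variant).
#'
#' @param array Integer 0/1 allele vector.
#' @return Numeric in `[0, 1]`.
#' @export
allele_fraction <- function(array) {
  if (length(array) < 1L) stop("Array must contain at least one copy.")
  mean(array == 1L)
}

# One synchronous cycle for one cell: replicate -> shuffle -> divide.
# Returns list(mother, daughter, replicated) where `replicated` is the
# at-capacity pre-division array (used by the synthetic-data generator).
cycle_cell <- function(array, config) {
  full <- replicate_to_capacity(array, config$n_copies)
  full <- shuffle_array(full, config$nspl)
  parts <- divide_array(full, config$ndau)
  c(parts, list(replicated = full))
}

#' Simulate the growth of heteroplasmic populations
#'
#' Runs the segregation model for `config$n_replicates` independent
#' populations, each founded by a single heteroplasmic cell at capacity.
#' Every synchronous cycle, each division-competent cell replicates to
#' capacity (Polya-urn), shuffles (`nspl` fragments) and divides (`ndau`
#' copies to the daughter); mother and daughter both persist. A cell may
#' only divide once it has reached the target copy number, so under the
#' default `daughter_delay` scheduling a newborn daughter spends one cycle
#' growing and replicating before its first division (cell counts per
#' founder follow 1, 2, 3, 5, 8, 13, ...); with `daughter_delay = FALSE`
#' every cell divides every cycle (2^g cells at generation g). There is no
#' cell death and no mtDNA loss.
#'
#' @param config A [sim_config()].
#' @param keep_events If `TRUE`, attach a per-division event table (used by
#'   the synthetic-data generator) as attribute `"events"`.
#' @return A tibble with one row per cell per generation snapshot:
#'   `replicate`, `generation`, `time_h`, `cell_id`, `parent_id` (NA for the
#'   founder), `allele1_count`, `n_copies`, `allele_fraction`,
#'   `strict_homoplasmic`. Cells are recorded post-division (mothers hold
#'   `n - ndau`, newborn daughters `ndau` copies; generation 0 is the
#'   founder at capacity).
#' @export
#' @examples
#' sim <- simulate_population(sim_config(ndau = 14, nspl = 4,
#'                                       n_generations = 3, seed = 7))
#' dplyr::count(sim, generation)
simulate_population <- function(config, keep_events = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  runs <- vector("list", config$n_replicates)
  events_all <- if (keep_events) vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    out <- withr::with_seed(config$seed + r, {
      simulate_one_population(config, keep_events)
    })
    out$snapshots$replicate <- r
    runs[[r]] <- out$snapshots
    if (keep_events) {
      out$events$replicate <- r
      events_all[[r]] <- out$events
    }
  }
  res <- dplyr::bind_rows(runs)
  res <- dplyr::select(res, "replicate", dplyr::everything())
  if (keep_events) {
    ev <- dplyr::bind_rows(events_all)
    ev <- dplyr::select(ev, "replicate", dplyr::everything())
    attr(res, "events") <- ev
  }
  res
}

simulate_one_population <- function(config, keep_events = FALSE) {
  founder <- init_founder(config)
  cells <- list(founder)
  ids <- 1L
  parents <- NA_integer_
  mature <- TRUE # the founder zygote is at capacity and divides first cycle
  next_id <- 2L
  snap <- function(gen, cells, ids, parents) {
    counts <- vapply(cells, function(a) sum(a == 1L), integer(1))
    lens <- lengths(cells)
    tibble::tibble(
      generation = gen,
      time_h = gen * config$generation_hours,
      cell_id = ids,
      parent_id = parents,
      allele1_count = counts,
      n_copies = lens,
      allele_fraction = counts / lens,
      strict_homoplasmic = as.integer(counts == 0L | counts == lens)
    )
  }
  snapshots <- list(snap(0L, cells, ids, parents))
  events <- if (keep_events) list()
  for (gen in seq_len(config$n_generations)) {
    n_cells <- length(cells)
    new_cells <- list()
    new_ids <- integer(0)
    new_parents <- integer(0)
    new_mature <- logical(0)
    ev_rows <- if (keep_events) list()
    for (i in seq_len(n_cells)) {
      if (!mature[i]) {
        # maturation cycle: grow and replicate to capacity, no division yet
        new_cells <- c(new_cells, list(replicate_to_capacity(
          cells[[i]], config$n_copies)))
        new_ids <- c(new_ids, ids[i])
        new_parents <- c(new_parents, parents[i])
        new_mature <- c(new_mature, TRUE)
        next
      }
      res <- cycle_cell(cells[[i]], config)
      new_cells <- c(new_cells, list(res$mother), list(res$daughter))
      new_ids <- c(new_ids, ids[i], next_id)
      new_parents <- c(new_parents, parents[i], ids[i])
      new_mature <- c(new_mature, TRUE, !config$daughter_delay)
      if (keep_events) {
        ev_rows <- c(ev_rows, list(tibble::tibble(
          generation = gen,
          mother_id = ids[i],
          daughter_id = next_id,
          pre_split1 = sum(res$replicated == 1L),
          pre_split_n = length(res$replicated),
          daughter1 = sum(res$daughter == 1L),
          daughter_n = length(res$daughter)
        )))
      }
      next_id <- next_id + 1L
    }
    cells <- new_cells
    ids <- new_ids
    parents <- new_parents
    mature <- new_mature
    snapshots[[gen + 1L]] <- snap(gen, cells, ids, parents)
    if (keep_events) events[[gen]] <- dplyr::bind_rows(ev_rows)
  }
  list(snapshots = dplyr::bind_rows(snapshots),
       events = if (keep_events) dplyr::bind_rows(events))
}

#' Fraction of homoplasmic cells in a population snapshot
#'
#' @param snapshot A data frame with columns `allele_fraction` (and, for
#'   `mode = "strict"`, implicitly exact 0/1 fractions), e.g. one
#'   generation of [simulate_population()] output.
#' @param mode `"strict"` counts cells whose allele fraction is exactly 0
#'   or 1; `"thresholds"` counts cells at or beyond the homoplasmy cutoffs,
#'   `allele_fraction <= thresholds[1]` or `>= thresholds[2]`, mirroring how
#'   empirical h-values are classified.
#' @param thresholds Length-2 numeric, low and high homoplasmy cutoffs on
#'   the h scale (defaults 0.33 and 0.71, the Gaussian-intersection values).
#' @return Numeric fraction in `[0, 1]`.
#' @export
homoplasmic_fraction <- function(snapshot,
                                 mode = c("strict", "thresholds"),
                                 thresholds = c(0.33, 0.71)) {
  mode <- match.arg(mode)
  h <- snapshot$allele_fraction
  if (length(h) == 0L) stop("Snapshot contains no cells.")
  if (mode == "strict") {
    mean(h == 0 | h == 1)
  } else {
    stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2])
    mean(h <= thresholds[1] | h >= thresholds[2])
  }
}
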