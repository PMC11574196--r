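#' Configuration for the synthetic time-lapse generator
#'
#' Parameters of the generator that emulates the per-cell tracking tables a
#' segmentation/tracking pipeline would export from a heteroplasmic
#' time-lapse experiment: ground-truth mtDNA copy trajectories driven by the
#' segregation simulator, fluorescent-protein turnover (which lags the DNA),
#' ambient background measured in cell-free areas, cellular
#' autofluorescence, photobleaching, measurement noise, and optional
#' translation-off (chloramphenicol, CAP) windows and mtDNA dropout.
#'
#' @param sim A [sim_config()] driving the ground-truth lineages.
#' @param protein_decay_k Fluorescent-protein turnover rate, per hour
#'   (default 0.31, the measured CAP decay constant).
#' @param synthesis_gain Protein synthesis per mtDNA copy per hour, a.u.
#' @param background_mean,background_sd Ambient background intensity per
#'   channel (a.u.); one value per frame is drawn and recorded in the
#'   `bg_*` fields, as if measured in a cell-free area.
#' @param cell_autofluor Cellular autofluorescence per channel per unit
#'   volume (a.u.); present in cells but absent from cell-free areas, so it
#'   survives background subtraction and keeps homoplasmic h peaks away
#'   from exactly 0 and 1.
#' @param photobleach_factor Per-frame multiplicative signal loss in (0, 1].
#' @param noise_cv Multiplicative measurement noise, coefficient of
#'   variation.
#' @param frame_interval_min Minutes between frames (default 15).
#' @param total_hours Length of the recording (default 8).
#' @param volume_fl Mature cell volume in fL.
#' @param dropout_rate Per-division probability that a daughter is born
#'   without mtDNA and stays dark, as do its descendants (emulates
#'   mtDNA-maintenance mutants; default 0).
#' @param cap_start_h,cap_end_h Optional translation-off window (hours);
#'   protein synthesis is zero inside it.
#' @param foci_rate_per_5min Mean mtDNA foci crossing the bud neck per
#'   5-minute window (default 1.18).
#' @param exchange_duration_min Duration of mother-daughter mitochondrial
#'   content exchange, minutes (default 47.5).
#' @param seed RNG seed for everything the generator draws.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(sim = sim_config(),
                             protein_decay_k = 0.31,
                             synthesis_gain = 1.2,
                             background_mean = 0.2, background_sd = 0.02,
                             cell_autofluor = 0.3,
                             photobleach_factor = 1,
                             noise_cv = 0.05,
                             frame_interval_min = 15,
                             total_hours = 8,
                             volume_fl = 40,
                             dropout_rate = 0,
                             cap_start_h = NULL, cap_end_h = NULL,
                             foci_rate_per_5min = 1.18,
                             exchange_duration_min = 47.5,
                             seed = 1L) {
  stopifnot(inherits(sim, "sim_config"),
            protein_decay_k > 0, synthesis_gain >= 0,
            background_mean >= 0, background_sd >= 0, cell_autofluor >= 0,
            photobleach_factor > 0, photobleach_factor <= 1,
            noise_cv >= 0, frame_interval_min > 0, total_hours > 0,
            volume_fl > 0, dropout_rate >= 0, dropout_rate <= 1,
            foci_rate_per_5min >= 0, exchange_duration_min > 0)
  structure(
    list(sim = sim, protein_decay_k = protein_decay_k,
         synthesis_gain = synthesis_gain,
         background_mean = background_mean, background_sd = background_sd,
         cell_autofluor = cell_autofluor,
         photobleach_factor = photobleach_factor, noise_cv = noise_cv,
         frame_interval_min = frame_interval_min, total_hours = total_hours,
         volume_fl = volume_fl, dropout_rate = dropout_rate,
         cap_start_h = cap_start_h, cap_end_h = cap_end_h,
         foci_rate_per_5min = foci_rate_per_5min,
         exchange_duration_min = exchange_duration_min,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Ground-truth per-frame copy-number trajectories of one lineage
#'
#' Runs the segregation simulator for a single founder and interpolates the
#' per-cycle bookkeeping onto the imaging frame grid. A daughter's copies
#' rise from 0 to its allocation during the first `exchange_duration_min`
#' after its birth division, then replicate to capacity over the rest of
#' the cycle; a dividing mother dips below capacity while copies leave
#' through the bud neck and is replenished by replication within the cycle.
#' Volumes follow a simple growth model: a newborn bud grows from 5% to
#' 55% of the mature volume during its first cycle, matures over the next,
#' and each budding mother's `bud_ratio` ramps accordingly.
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per cell per frame: `frame`, `time_h`,
#'   `cell_id`, `parent_id`, `copies0`, `copies1`, `volume`, `bud_ratio`
#'   (NA while a cell has no bud of its own).
#' @export
generate_truth_lineage <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  sim_cfg <- config$sim
  one <- sim_config(
    n_copies = sim_cfg$n_copies, ndau = sim_cfg$ndau, nspl = sim_cfg$nspl,
    founder_pattern = sim_cfg$founder_pattern,
    founder_fraction1 = sim_cfg$founder_fraction1,
    n_generations = sim_cfg$n_generations,
    generation_hours = sim_cfg$generation_hours,
    n_replicates = 1L, seed = config$seed
  )
  snap <- simulate_population(one, keep_events = TRUE)
  events <- attr(snap, "events")
  T_gen <- sim_cfg$generation_hours
  tex <- config$exchange_duration_min / 60
  dt <- config$frame_interval_min / 60
  times <- seq(0, config$total_hours, by = dt)
  frames <- seq_along(times)
  n_cap <- sim_cfg$n_copies

  # per-cell bookkeeping from snapshots and events
  cells <- unique(snap[, c("cell_id", "parent_id")])
  birth_gen <- vapply(cells$cell_id, function(id)
    min(snap$generation[snap$cell_id == id]), numeric(1))
  # allocation at birth (post-division counts)
  alloc <- lapply(cells$cell_id, function(id) {
    g <- min(snap$generation[snap$cell_id == id])
    row <- snap[snap$cell_id == id & snap$generation == g, ]
    c(one = row$allele1_count, n = row$n_copies)
  })
  # events keyed by (mother, generation): pre-split and daughter counts
  ev_key <- paste(events$mother_id, events$generation)
  dropout <- withr::with_seed(config$seed + 77L,
                              dropout_set(cells, events, config))

  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    id <- cells$cell_id[i]
    gb <- birth_gen[i]
    tb <- gb * T_gen
    live <- times >= tb - 1e-9
    tt <- times[live]
    if (length(tt) == 0L) next
    if (id %in% dropout) {
      c0 <- c1 <- rep(0, length(tt))
    } else {
      traj <- cell_copy_trajectory(id, gb, tt, alloc[[i]], events, ev_key,
                                   T_gen, tex, n_cap,
                                   total_gen = sim_cfg$n_generations)
      c0 <- traj$c0; c1 <- traj$c1
    }
    vol <- cell_volume(tt - tb, is_founder = is.na(cells$parent_id[i]),
                       T_gen, config$volume_fl)
    # bud ratio: the cell buds at each of its division times
    bud <- bud_ratio_series(id, gb, tt, events, T_gen, config$volume_fl, vol,
                            total_gen = sim_cfg$n_generations)
    rows[[i]] <- tibble::tibble(
      frame = frames[live], time_h = tt, cell_id = id,
      parent_id = cells$parent_id[i],
      copies0 = c0, copies1 = c1,
      alloc0 = if (id %in% dropout) 0 else
        unname(alloc[[i]]["n"] - alloc[[i]]["one"]),
      alloc1 = if (id %in% dropout) 0 else unname(alloc[[i]]["one"]),
      volume = vol, bud_ratio = bud
    )
  }
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$frame, .data$cell_id)
  out
}

# cells that lost mtDNA at birth (or descend from one)
dropout_set <- function(cells, events, config) {
  if (config$dropout_rate <= 0) return(integer(0))
  daughters <- events$daughter_id
  dropped <- daughters[stats::runif(length(daughters)) < config$dropout_rate]
  # propagate to descendants
  parent_of <- stats::setNames(cells$parent_id, cells$cell_id)
  dark <- logical(nrow(cells))
  names(dark) <- as.character(cells$cell_id)
  dark[as.character(dropped)] <- TRUE
  for (id in sort(cells$cell_id)) { # ids increase with birth order
    p <- parent_of[[as.character(id)]]
    if (!is.na(p) && isTRUE(dark[[as.character(p)]])) {
      dark[[as.character(id)]] <- TRUE
    }
  }
  as.integer(names(dark)[dark])
}

# piecewise copy-count trajectory for one cell at times tt (absolute hours)
cell_copy_trajectory <- function(id, gb, tt, birth_counts, events, ev_key,
                                 T_gen, tex, n_cap, total_gen) {
  c1 <- numeric(length(tt))
  c0 <- numeric(length(tt))
  for (j in seq_along(tt)) {
    t <- tt[j]
    g <- min(floor(t / T_gen + 1e-9), total_gen) # cycle index g -> [gT,(g+1)T)
    g <- max(g, gb)
    t0 <- g * T_gen
    u_ex <- if (tex > 0) min(max((t - t0) / tex, 0), 1) else 1
    u_cy <- min(max((t - t0) / T_gen, 0), 1)
    if (g == gb && gb > 0) {
      # first cycle of a daughter: gain the allocation over the exchange
      # window, then replicate to the next pre-split composition
      ev_next <- match(paste(id, g + 1L), ev_key)
      if (!is.na(ev_next)) {
        p1 <- events$pre_split1[ev_next]; pn <- events$pre_split_n[ev_next]
      } else {
        pn <- n_cap
        p1 <- birth_counts[["one"]] / max(birth_counts[["n"]], 1) * n_cap
      }
      d1 <- birth_counts[["one"]]; dn <- birth_counts[["n"]]
      u_rep <- if (T_gen > tex) {
        min(max((t - t0 - tex) / (T_gen - tex), 0), 1)
      } else u_cy
      c1[j] <- d1 * u_ex + (p1 - d1) * u_rep
      c0[j] <- (dn - d1) * u_ex + ((pn - p1) - (dn - d1)) * u_rep
    } else {
      # a mother cycle: divided at t0 (event at generation g), transfers its
      # daughter's copies out over the exchange window and replenishes
      ev <- match(paste(id, g), ev_key)
      if (is.na(ev)) {
        # founder's pre-division cycle (g = 0) or steady state
        ev1 <- match(paste(id, g + 1L), ev_key)
        if (!is.na(ev1)) {
          c1[j] <- events$pre_split1[ev1]
          c0[j] <- events$pre_split_n[ev1] - events$pre_split1[ev1]
        } else {
          c1[j] <- birth_counts["one"] / max(birth_counts["n"], 1) * n_cap
          c0[j] <- n_cap - c1[j]
        }
        next
      }
      p1 <- events$pre_split1[ev]; pn <- events$pre_split_n[ev]
      d1 <- events$daughter1[ev]; dn <- events$daughter_n[ev]
      k1 <- p1 - d1; kn <- pn - dn
      ev_next <- match(paste(id, g + 1L), ev_key)
      if (!is.na(ev_next)) {
        q1 <- events$pre_split1[ev_next]; qn <- events$pre_split_n[ev_next]
      } else {
        qn <- n_cap; q1 <- if (kn > 0) k1 / kn * n_cap else 0
      }
      c1[j] <- p1 - d1 * u_ex + (q1 - k1) * u_cy
      c0[j] <- (pn - p1) - (dn - d1) * u_ex + ((qn - q1) - (kn - k1)) * u_cy
    }
  }
  list(c0 = pmax(c0, 0), c1 = pmax(c1, 0))
}

# volume growth: bud 5% -> 55% of mature volume in first cycle after birth,
# matures to full volume over the second cycle, constant afterwards
cell_volume <- function(age_h, is_founder, T_gen, v_mature) {
  if (is_founder) return(rep(v_mature, length(age_h)))
  u1 <- pmin(pmax(age_h / T_gen, 0), 1)
  u2 <- pmin(pmax((age_h - T_gen) / T_gen, 0), 1)
  v_mature * (0.05 + 0.5 * u1 + 0.45 * u2)
}

bud_ratio_series <- function(id, gb, tt, events, T_gen, v_mature, own_vol,
                             total_gen) {
  bud <- rep(NA_real_, length(tt))
  my_div <- events[events$mother_id == id, , drop = FALSE]
  if (nrow(my_div) == 0L) return(bud)
  for (j in seq_along(tt)) {
    g <- floor(tt[j] / T_gen + 1e-9)
    if (any(my_div$generation == g + 1L)) {
      # budding during cycle [gT, (g+1)T); bud volume = newborn growth curve
      age <- tt[j] - g * T_gen
      bud_vol <- v_mature * (0.05 + 0.5 * min(max(age / T_gen, 0), 1))
      bud[j] <- bud_vol / own_vol[j]
    }
  }
  bud
}

#' Convert copy-number trajectories into cell-record fluorescence tables
#'
#' Per cell and mtDNA variant, the fluorescent fusion protein P follows
#' `dP/dt = synthesis_gain * copies - protein_decay_k * P` (synthesis is 0
#' inside the CAP window). Protein co-partitions with the organelles that
#' carry its template: a newborn bud starts empty and gains one
#' steady-state protein packet with every mtDNA copy arriving during its
#' exchange window, and when copies leave a mother through the bud neck
#' they take their protein share with them (the pool is trimmed in
#' proportion to any drop in copy number). Measured
#' intensity is `P / volume + cell_autofluor`, attenuated by
#' `photobleach_factor^frame`, perturbed by multiplicative Gaussian noise of
#' the configured CV, plus the frame's ambient background, whose true value
#' is recorded in the `bg_*` fields. Variant 1 maps to the mKate2 channel.
#'
#' @param truth Output of [generate_truth_lineage()].
#' @param config A [generator_config()].
#' @return A tibble of cell records: `frame`, `time_h`, `cell_id`,
#'   `parent_id`, `volume`, `i_ng`, `i_mkate`, `bg_ng`, `bg_mkate`,
#'   `bud_ratio`.
#' @export
copies_to_intensity <- function(truth, config) {
  stopifnot(inherits(config, "generator_config"))
  k <- config$protein_decay_k
  s <- config$synthesis_gain
  dtv <- config$frame_interval_min / 60
  cap_on <- function(t) {
    !is.null(config$cap_start_h) && !is.null(config$cap_end_h) &&
      t >= config$cap_start_h && t < config$cap_end_h
  }
  frames <- sort(unique(truth$frame))
  bg_ng_frame <- stats::setNames(
    pmax(stats::rnorm(length(frames), config$background_mean,
                      config$background_sd), 0), frames)
  bg_mk_frame <- stats::setNames(
    pmax(stats::rnorm(length(frames), config$background_mean,
                      config$background_sd), 0), frames)
  out <- vector("list", length(unique(truth$cell_id)))
  idx <- 0L
  for (id in unique(truth$cell_id)) {
    tr <- truth[truth$cell_id == id, ]
    tr <- tr[order(tr$frame), ]
    nf <- nrow(tr)
    p0 <- numeric(nf) # protein, variant 0
    p1 <- numeric(nf)
    # protein starts at the synthesis-on steady state of the initial copy
    # complement (a CAP window only stops synthesis going forward)
    p0[1] <- s * tr$copies0[1] / k
    p1[1] <- s * tr$copies1[1] / k
    is_founder <- is.na(tr$parent_id[1])
    influx_until <- tr$time_h[1] + config$exchange_duration_min / 60
    if (nf > 1) for (f in 2:nf) {
      sg <- if (cap_on(tr$time_h[f - 1])) 0 else s
      tgt0 <- sg * tr$copies0[f - 1] / k
      tgt1 <- sg * tr$copies1[f - 1] / k
      decay <- exp(-k * dtv)
      p0[f] <- tgt0 + (p0[f - 1] - tgt0) * decay
      p1[f] <- tgt1 + (p1[f - 1] - tgt1) * decay
      if (!is_founder && tr$time_h[f] <= influx_until + 1e-9) {
        # exchange window after birth: arriving copies carry their protein
        p0[f] <- p0[f] + s / k * max(tr$copies0[f] - tr$copies0[f - 1], 0)
        p1[f] <- p1[f] + s / k * max(tr$copies1[f] - tr$copies1[f - 1], 0)
      }
      # copies leaving the cell carry their co-localized protein along
      if (tr$copies0[f] < tr$copies0[f - 1]) {
        p0[f] <- p0[f] * tr$copies0[f] / max(tr$copies0[f - 1], 1e-9)
      }
      if (tr$copies1[f] < tr$copies1[f - 1]) {
        p1[f] <- p1[f] * tr$copies1[f] / max(tr$copies1[f - 1], 1e-9)
      }
    }
    bleach <- config$photobleach_factor^(tr$frame - 1L)
    noise <- function(n) {
      if (config$noise_cv > 0) 1 + stats::rnorm(n, 0, config$noise_cv)
      else rep(1, n)
    }
    sig_ng <- pmax((p0 / tr$volume + config$cell_autofluor) * bleach *
                     noise(nf), 0)
    sig_mk <- pmax((p1 / tr$volume + config$cell_autofluor) * bleach *
                     noise(nf), 0)
    idx <- idx + 1L
    out[[idx]] <- tibble::tibble(
      frame = tr$frame, time_h = tr$time_h, cell_id = id,
      parent_id = tr$parent_id, volume = tr$volume,
      i_ng = unname(sig_ng + bg_ng_frame[as.character(tr$frame)]),
      i_mkate = unname(sig_mk + bg_mk_frame[as.character(tr$frame)]),
      bg_ng = unname(bg_ng_frame[as.character(tr$frame)]),
      bg_mkate = unname(bg_mk_frame[as.character(tr$frame)]),
      bud_ratio = tr$bud_ratio
    )
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$frame, .data$cell_id)
}

#' Synthetic CAP (translation-off) fluorescence decay series
#'
#' Emulates the chloramphenicol experiment on a single cell with constant
#' mtDNA copy number: protein synthesis is switched off for the whole
#' recording, so intensity decays from its steady state toward the
#' background plateau, `I(t) = A exp(-k t) + C`.
#'
#' @param config A [generator_config()]; `protein_decay_k` sets the true
#'   rate, `noise_cv` and `background_sd` the noise (set both to 0 for a
#'   noiseless series).
#' @param hours Length of the series (default 6).
#' @param channel `"mkate"` or `"ng"` (label only).
#' @return A tibble with `time_h`, `intensity`, `channel`.
#' @export
generate_cap_series <- function(config, hours = 6, channel = "mkate") {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    dtv <- config$frame_interval_min / 60
    times <- seq(0, hours, by = dtv)
    n <- config$sim$n_copies
    truth <- tibble::tibble(
      frame = seq_along(times), time_h = times, cell_id = 1L,
      parent_id = NA_integer_,
      copies0 = if (channel == "ng") n else 0,
      copies1 = if (channel == "mkate") n else 0,
      volume = config$volume_fl, bud_ratio = NA_real_
    )
    cfg <- config
    cfg$cap_start_h <- 0
    cfg$cap_end_h <- hours + 1
    rec <- copies_to_intensity(truth, cfg)
    tibble::tibble(
      time_h = rec$time_h,
      intensity = if (channel == "mkate") rec$i_mkate else rec$i_ng,
      channel = channel
    )
  })
}

#' Synthetic mtDNA foci-crossing event stream
#'
#' Independent Poisson counts of foci crossing the mother-bud neck in one
#' 5-minute window per mother-bud pair, at the configured rate.
#'
#' @param config A [generator_config()].
#' @param n_pairs Number of mother-bud pairs (default 93).
#' @return A tibble with `pair_id`, `window_index`, `crossings`.
#' @export
generate_foci_stream <- function(config, n_pairs = 93L) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    tibble::tibble(
      pair_id = seq_len(n_pairs),
      window_index = 1L,
      crossings = stats::rpois(n_pairs, config$foci_rate_per_5min)
    )
  })
}

#' Generate a full synthetic heteroplasmy study
#'
#' Emulates the core experiment: several independent populations, each
#' grown from one heteroplasmic founder and imaged over the full recording.
#' Returns both the observable cell-record tables (what a tracking tool
#' would export) and the ground-truth allele fractions for validation.
#'
#' @param config A [generator_config()].
#' @param n_populations Number of independent founder populations
#'   (default 9).
#' @return A list with `records` (cell-record tibble with a `population`
#'   column) and `truth` (per-cell per-frame copy counts with
#'   `true_fraction1`).
#' @export
generate_heteroplasmy_study <- function(config, n_populations = 9L) {
  stopifnot(inherits(config, "generator_config"))
  recs <- vector("list", n_populations)
  truths <- vector("list", n_populations)
  for (p in seq_len(n_populations)) {
    cfg <- config
    cfg$seed <- config$seed + (p - 1L) * 1000L
    truth <- generate_truth_lineage(cfg)
    rec <- withr::with_seed(cfg$seed + 500L, copies_to_intensity(truth, cfg))
    truth$true_fraction1 <- ifelse(
      truth$copies0 + truth$copies1 > 0,
      truth$copies1 / (truth$copies0 + truth$copies1), NA_real_)
    truth$population <- p
    rec$population <- p
    recs[[p]] <- rec
    truths[[p]] <- truth
  }
  list(records = dplyr::bind_rows(recs), truth = dplyr::bind_rows(truths))
}
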