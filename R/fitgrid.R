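#' Fit a sigmoid to an empirical homoplasmy time course
#'
#' Least-squares fit of the logistic curve
#' `f(t) = L / (1 + exp(-r (t - t0)))` with `0 < L <= 1` and `r > 0`,
#' smoothing the raw fraction-homoplasmic-vs-time curve before it is
#' compared with simulations.
#'
#' @param curve A data frame with columns `time_h` (strictly increasing)
#'   and `fraction` (in `[0, 1]`), at least 4 points.
#' @return An object of class `sigmoid_fit`: list with `parameters`
#'   (named vector `L`, `r`, `t0`), `fitted` (tibble `time_h`, `fraction`,
#'   `fitted`), `rss`, `degenerate` (TRUE when the response is flat and the
#'   rate is unidentifiable), and `predict(times)` via [predict()].
#' @export
#' @examples
#' tt <- seq(0, 7.5, by = 1.5)
#' curve <- tibble::tibble(time_h = tt,
#'                         fraction = 0.6 / (1 + exp(-1.2 * (tt - 4))))
#' fit_sigmoid(curve)$parameters
fit_sigmoid <- function(curve) {
  stopifnot(all(c("time_h", "fraction") %in% names(curve)))
  t <- curve$time_h
  y <- curve$fraction
  if (length(t) < 4L) stop("Need at least 4 timepoints for a sigmoid fit.")
  if (is.unsorted(t, strictly = TRUE)) {
    stop("`time_h` must be strictly increasing.")
  }
  if (any(y < 0 | y > 1)) stop("Fractions must lie in [0, 1].")
  if (max(y) - min(y) < 1e-10) {
    warning("Constant homoplasmy curve: sigmoid rate is unidentifiable; ",
            "returning a degenerate flat fit.")
    pars <- c(L = max(max(y), 1e-12), r = NA_real_, t0 = NA_real_)
    return(structure(list(parameters = pars,
                          fitted = tibble::tibble(time_h = t, fraction = y,
                                                  fitted = y),
                          rss = 0, degenerate = TRUE),
                     class = "sigmoid_fit"))
  }
  start <- list(L = min(max(y) * 1.05, 1), r = 1,
                t0 = t[which.min(abs(y - max(y) / 2))])
  fit <- minpack.lm::nlsLM(
    y ~ L / (1 + exp(-r * (t - t0))),
    start = start,
    lower = c(L = 1e-6, r = 1e-6, t0 = min(t) - 10),
    upper = c(L = 1, r = 50, t0 = max(t) + 10),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  pars <- stats::coef(fit)
  fitted_y <- as.numeric(stats::predict(fit))
  structure(
    list(parameters = pars,
         fitted = tibble::tibble(time_h = t, fraction = y,
                                 fitted = fitted_y),
         rss = sum((y - fitted_y)^2), degenerate = FALSE),
    class = "sigmoid_fit"
  )
}

#' @export
predict.sigmoid_fit <- function(object, times, ...) {
  p <- object$parameters
  if (object$degenerate) return(rep(p[["L"]], length(times)))
  p[["L"]] / (1 + exp(-p[["r"]] * (times - p[["t0"]])))
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("<sigmoid_fit> f(t) = L / (1 + exp(-r (t - t0)))\n")
  print(round(x$parameters, 5))
  cat("RSS:", format(x$rss), if (x$degenerate) "(degenerate)", "\n")
  invisible(x)
}

#' Simulated homoplasmy-fraction time course
#'
#' Runs the segregation simulator and returns the homoplasmic fraction,
#' averaged over replicates, at each generation time of the snapshot grid
#' (t = 0, 1.5, ..., in hours).
#'
#' @param config A [sim_config()]; `n_replicates` controls the averaging.
#' @param mode,thresholds Passed to [homoplasmic_fraction()]; the default
#'   threshold mode mirrors how the empirical curve is produced from
#'   thresholded h values.
#' @return A tibble with `time_h` and `fraction`.
#' @export
simulate_curve <- function(config, mode = c("thresholds", "strict"),
                           thresholds = c(0.33, 0.71)) {
  mode <- match.arg(mode)
  sim <- simulate_population(config)
  out <- dplyr::group_by(sim, .data$replicate, .data$time_h)
  out <- dplyr::summarise(
    out,
    fraction = homoplasmic_fraction(dplyr::pick(dplyr::everything()),
                                    mode = mode, thresholds = thresholds),
    .groups = "drop"
  )
  out <- dplyr::group_by(out, .data$time_h)
  dplyr::summarise(out, fraction = mean(.data$fraction), .groups = "drop")
}

#' Least-squares grid search over (ndau, nspl)
#'
#' Fits the segregation model to an empirical homoplasmy time course by
#' exhaustive search: for every (ndau, nspl) pair, the simulator is run
#' `n_replicates` times, replicate curves are averaged, and the sum of
#' squared differences from the (optionally sigmoid-smoothed) empirical
#' fractions is computed over the comparison timepoints 1.5, 3, 4.5, 6 and
#' 7.5 h (t = 0 is excluded: every curve starts at the same value there).
#'
#' @param empirical A data frame with `time_h` and `fraction` — the
#'   empirical homoplasmic-fraction curve.
#' @param ndau_range,nspl_range Integer vectors of parameter values to scan
#'   (defaults 1..16 and 1..32 for 32 copies).
#' @param config Base [sim_config()] supplying copy number, founder,
#'   generations and generation duration.
#' @param n_replicates Simulator runs per grid pair (default 10).
#' @param seed Seed for the whole search; grid cell `j`, replicate `r` uses
#'   `seed + (j - 1) * n_replicates + r`, so the surface is reproducible.
#' @param smooth_empirical If `TRUE` (default) compare against the
#'   sigmoid-smoothed empirical curve, else against the raw fractions.
#' @param average_first If `TRUE` (default) average replicate curves before
#'   computing the squared distance; if `FALSE`, average per-replicate SSEs.
#' @param mode,thresholds Classification of simulated cells, passed to
#'   [homoplasmic_fraction()].
#' @return An object of class `grid_fit`: list with `grid` (tibble `ndau`,
#'   `nspl`, `sse`, plus mean simulated fraction per comparison timepoint),
#'   `best_ndau`, `best_nspl`, `n_replicates`, `times`, `empirical`
#'   (the comparison values actually used). Ties are broken by smaller
#'   `ndau`, then smaller `nspl`.
#' @export
grid_search <- function(empirical,
                        ndau_range = 1:16, nspl_range = 1:32,
                        config = sim_config(),
                        n_replicates = 10L, seed = config$seed,
                        smooth_empirical = TRUE, average_first = TRUE,
                        mode = c("thresholds", "strict"),
                        thresholds = c(0.33, 0.71)) {
  mode <- match.arg(mode)
  if (length(ndau_range) == 0L || length(nspl_range) == 0L) {
    stop("Empty parameter range.")
  }
  if (any(ndau_range > daughter_cap(config$n_copies))) {
    stop("ndau values above floor(n_copies/2) = ",
         daughter_cap(config$n_copies), " are not allowed.")
  }
  cmp_times <- setdiff(empirical$time_h, 0)
  target <- if (smooth_empirical) {
    sf <- fit_sigmoid(empirical)
    stats::predict(sf, cmp_times)
  } else {
    empirical$fraction[match(cmp_times, empirical$time_h)]
  }
  pairs <- tidyr::expand_grid(ndau = sort(unique(as.integer(ndau_range))),
                              nspl = sort(unique(as.integer(nspl_range))))
  n_gen <- as.integer(round(max(cmp_times) / config$generation_hours))
  rows <- vector("list", nrow(pairs))
  for (j in seq_len(nrow(pairs))) {
    cfg <- sim_config(
      n_copies = config$n_copies, ndau = pairs$ndau[j], nspl = pairs$nspl[j],
      founder_pattern = config$founder_pattern,
      founder_fraction1 = config$founder_fraction1,
      n_generations = n_gen, generation_hours = config$generation_hours,
      n_replicates = n_replicates,
      seed = seed + (j - 1L) * n_replicates
    )
    sim <- simulate_population(cfg)
    per_rep <- dplyr::summarise(
      dplyr::group_by(sim, .data$replicate, .data$time_h),
      fraction = homoplasmic_fraction(dplyr::pick(dplyr::everything()),
                                      mode = mode, thresholds = thresholds),
      .groups = "drop"
    )
    per_rep <- per_rep[per_rep$time_h %in% cmp_times, ]
    if (average_first) {
      mean_curve <- dplyr::summarise(dplyr::group_by(per_rep, .data$time_h),
                                     fraction = mean(.data$fraction),
                                     .groups = "drop")
      sim_frac <- mean_curve$fraction[match(cmp_times, mean_curve$time_h)]
      sse <- sum((sim_frac - target)^2)
    } else {
      wide <- tidyr::pivot_wider(per_rep, names_from = "time_h",
                                 values_from = "fraction")
      mat <- as.matrix(wide[, as.character(cmp_times)])
      sse <- mean(rowSums(sweep(mat, 2, target)^2))
      sim_frac <- colMeans(mat)
    }
    row <- tibble::tibble(ndau = pairs$ndau[j], nspl = pairs$nspl[j],
                          sse = sse)
    frac_cols <- stats::setNames(as.list(sim_frac),
                                 paste0("frac_", cmp_times, "h"))
    rows[[j]] <- dplyr::bind_cols(row, tibble::as_tibble(frac_cols))
  }
  grid <- dplyr::bind_rows(rows)
  ord <- order(grid$sse, grid$ndau, grid$nspl)
  best <- grid[ord[1], ]
  structure(
    list(grid = grid, best_ndau = best$ndau, best_nspl = best$nspl,
         n_replicates = as.integer(n_replicates), times = cmp_times,
         empirical = tibble::tibble(time_h = cmp_times, fraction = target),
         smooth_empirical = smooth_empirical,
         average_first = average_first),
    class = "grid_fit"
  )
}

#' @export
print.grid_fit <- function(x, ...) {
  cat("<grid_fit>", nrow(x$grid), "parameter pairs,",
      x$n_replicates, "replicates each\n")
  cat("Best fit: ndau =", x$best_ndau, ", nspl =", x$best_nspl,
      sprintf("(SSE = %.4g)\n", min(x$grid$sse)))
  invisible(x)
}
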