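#' Normalize per-cell fluorescence intensities
#'
#' Applies the measurement normalization chain to raw per-cell, per-frame
#' intensities: per channel, the cell-free background is subtracted (floored
#' at zero, intensities are physical), the result is divided by cell volume,
#' and then divided by the median of that quantity over all segmented cells
#' of the same frame. The per-frame median normalization makes channels
#' comparable across populations and absorbs photobleaching.
#'
#' @param records A data frame of cell records with columns `frame`,
#'   `cell_id`, `volume`, `i_ng`, `i_mkate`, `bg_ng`, `bg_mkate` (other
#'   columns such as `time_h`, `parent_id`, `bud_ratio` are carried
#'   through).
#' @param median_normalize Apply the per-frame, per-channel median
#'   normalization (default `TRUE`). Disable for populations where a whole
#'   channel carries no real signal (e.g. a single-variant control), where
#'   dividing by the median of autofluorescence would be meaningless.
#' @return A tibble with the input columns plus `i_ng_norm` and
#'   `i_mkate_norm`. Frames where a whole channel is zero after background
#'   correction keep zeros in that channel and raise a warning.
#' @export
#' @examples
#' rec <- tibble::tibble(frame = 1, cell_id = 1:2, volume = c(1, 1),
#'                       i_ng = c(4, 8), i_mkate = c(6, 6),
#'                       bg_ng = 2, bg_mkate = 2)
#' normalize_intensities(rec)
normalize_intensities <- function(records, median_normalize = TRUE) {
  need <- c("frame", "cell_id", "volume", "i_ng", "i_mkate",
            "bg_ng", "bg_mkate")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L) {
    stop("Missing cell-record columns: ", paste(miss, collapse = ", "))
  }
  if (any(records$volume <= 0)) stop("Cell volumes must be positive.")
  norm_channel <- function(raw, bg, volume, frame, channel) {
    per_vol <- pmax(raw - bg, 0) / volume
    if (!median_normalize) return(per_vol)
    med <- stats::ave(per_vol, frame, FUN = function(x) stats::median(x))
    zero <- med == 0
    if (any(zero)) {
      warning("Frame(s) ", paste(unique(frame[zero]), collapse = ", "),
              " have all-zero corrected ", channel,
              " intensities; normalized values set to 0.")
      med[zero] <- 1
    }
    per_vol / med
  }
  out <- tibble::as_tibble(records)
  out$i_ng_norm <- norm_channel(out$i_ng, out$bg_ng, out$volume,
                                out$frame, "NG")
  out$i_mkate_norm <- norm_channel(out$i_mkate, out$bg_mkate, out$volume,
                                   out$frame, "mKate2")
  out
}

#' Heteroplasmy value from two channel intensities
#'
#' `h = i_mkate / (i_ng + i_mkate)`: the red (mKate2) share of total
#' fluorescence. `h > 0.5` means the cell carries more of the
#' mKate2-marked mtDNA variant; values near 0 or 1 indicate homoplasmy.
#' Cells with zero signal in both channels have no defined h and return
#' `NA` with a warning (they are excluded from distributions).
#'
#' @param i_ng,i_mkate Non-negative normalized intensities (vectorized).
#' @return Numeric vector of h values in `[0, 1]`, `NA` where undefined.
#' @export
#' @examples
#' compute_h(c(1, 0, 5), c(1, 5, 0))
compute_h <- function(i_ng, i_mkate) {
  if (any(i_ng < 0, na.rm = TRUE) || any(i_mkate < 0, na.rm = TRUE)) {
    stop("Intensities must be non-negative.")
  }
  total <- i_ng + i_mkate
  h <- ifelse(total > 0, i_mkate / total, NA_real_)
  if (anyNA(h[!is.na(total)])) {
    warning(sum(total == 0, na.rm = TRUE),
            " cell(s) with zero signal in both channels; h set to NA.")
  }
  h
}

#' Build an h-value table from raw cell records
#'
#' Convenience pipeline: [normalize_intensities()] followed by
#' [compute_h()] on the normalized channels.
#'
#' @inheritParams normalize_intensities
#' @return A tibble with normalized intensities and an `h` column.
#' @export
add_h_values <- function(records, median_normalize = TRUE) {
  out <- normalize_intensities(records, median_normalize = median_normalize)
  out$h <- compute_h(out$i_ng_norm, out$i_mkate_norm)
  out
}

#' Coefficient of variation of fluorescence
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#' Used to contrast cell-to-cell signal variability between strains that
#' maintain mtDNA stably and strains that occasionally lose it.
#'
#' @param values Numeric vector, length >= 2, with positive mean.
#' @return The coefficient of variation.
#' @export
#' @examples
#' compute_cv(c(2, 4)) # sd sqrt(2) / mean 3
compute_cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("Need at least 2 values to compute a CV.")
  m <- mean(values)
  if (m <= 0) stop("CV undefined: mean must be positive.")
  stats::sd(values) / m
}

#' Normalize an intensity series to its first timepoint
#'
#' Divides every value by the median intensity of the first timepoint of
#' its replicate, so each replicate's series starts at 1. Used for decay
#' time courses where replicates differ in absolute brightness.
#'
#' @param data A data frame with at least a time column, an intensity
#'   column, and a replicate column.
#' @param time,intensity,replicate Column names (strings).
#' @return The input tibble with an added column `intensity_norm`.
#' @export
normalize_to_first_timepoint <- function(data, time = "time_h",
                                         intensity = "intensity",
                                         replicate = "replicate") {
  miss <- setdiff(c(time, intensity, replicate), names(data))
  if (length(miss) > 0L) stop("Missing columns: ", paste(miss, collapse = ", "))
  out <- tibble::as_tibble(data)
  out <- dplyr::group_by(out, .data[[replicate]])
  out <- dplyr::mutate(
    out,
    .first_med = stats::median(.data[[intensity]][
      .data[[time]] == min(.data[[time]])]),
    intensity_norm = .data[[intensity]] / .data[[".first_med"]]
  )
  out <- dplyr::ungroup(out)
  if (any(!is.finite(out$intensity_norm))) {
    stop("Zero median intensity at the first timepoint of some replicate.")
  }
  dplyr::select(out, -".first_med")
}
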