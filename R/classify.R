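#' Fit a three-component Gaussian mixture to h values
#'
#' Models the trimodal h distribution that emerges once segregation is under
#' way: a left peak of NG-homoplasmic cells, a middle peak of heteroplasmic
#' cells, and a right peak of mKate2-homoplasmic cells. Fitting is by
#' expectation-maximization with deterministic initialization (component
#' means at the 1/6, 3/6 and 5/6 sample quantiles, common initial sd, equal
#' weights), so a given sample always yields the same fit.
#'
#' @param h Numeric vector of h values in `[0, 1]`, length >= 30.
#' @param max_iter Maximum EM iterations (default 2000).
#' @param tol Convergence tolerance on the mean log-likelihood (default 1e-8).
#' @param sd_floor Lower bound on component standard deviations, guards
#'   against degenerate spikes (default 1e-4).
#' @return An object of class `gmm_fit`: a list with `components` (tibble of
#'   `weight`, `mean`, `sd`, ordered by mean), `loglik`, `n_iter`,
#'   `converged`, `n`, and `collapsed` (TRUE when a component's weight fell
#'   below 1% or adjacent components overlap more than they separate, e.g.
#'   on unimodal input).
#' @seealso [gaussian_intersection()], [derive_thresholds()]
#' @export
#' @examples
#' set.seed(1)
#' h <- c(rnorm(300, 0.15, 0.05), rnorm(300, 0.5, 0.08),
#'        rnorm(400, 0.85, 0.05))
#' fit_gaussian_mixture(pmin(pmax(h, 0), 1))
fit_gaussian_mixture <- function(h, max_iter = 2000L, tol = 1e-8,
                                 sd_floor = 1e-4) {
  h <- h[!is.na(h)]
  n <- length(h)
  if (n < 30L) stop("Need at least 30 h values to fit the mixture.")
  if (any(h < 0 | h > 1)) stop("h values must lie in [0, 1].")
  if (stats::sd(h) < sd_floor) {
    stop("Degenerate input: h values are (nearly) all identical.")
  }
  k <- 3L
  mu <- as.numeric(stats::quantile(h, probs = c(1, 3, 5) / 6, names = FALSE))
  sigma <- rep(max(stats::sd(h), sd_floor), k)
  w <- rep(1 / k, k)
  loglik_old <- -Inf
  loglik <- NA_real_
  converged <- FALSE
  last_change <- NA_real_
  dens <- matrix(0, n, k)
  for (iter in seq_len(max_iter)) {
    for (j in seq_len(k)) dens[, j] <- w[j] * stats::dnorm(h, mu[j], sigma[j])
    row_tot <- rowSums(dens)
    row_tot[row_tot == 0] <- .Machine$double.xmin
    loglik <- sum(log(row_tot))
    resp <- dens / row_tot
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.xmin
    w <- nk / n
    mu <- colSums(resp * h) / nk
    sigma <- sqrt(colSums(resp * (h - rep(mu, each = n))^2) / nk)
    sigma <- pmax(sigma, sd_floor)
    last_change <- abs(loglik - loglik_old) / n
    if (is.finite(loglik) && last_change < tol) {
      converged <- TRUE
      break
    }
    loglik_old <- loglik
  }
  if (!converged) {
    stop("EM did not converge after ", max_iter, " iterations ",
         sprintf("(last mean log-likelihood change %.3g).", last_change))
  }
  ord <- order(mu)
  mu_s <- mu[ord]; sd_s <- sigma[ord]
  overlapping <- any(diff(mu_s) < (sd_s[-3] + sd_s[-1]) / 2)
  collapsed <- any(w < 0.01) || overlapping
  if (collapsed) {
    warning("Mixture components collapsed or overlap strongly; ",
            "the h distribution may not be trimodal.")
  }
  structure(
    list(components = tibble::tibble(component = 1:3, weight = w[ord],
                                     mean = mu[ord], sd = sigma[ord]),
         loglik = loglik, n_iter = iter, converged = converged,
         n = n, collapsed = collapsed),
    class = "gmm_fit"
  )
}

#' @export
print.gmm_fit <- function(x, ...) {
  cat("<gmm_fit> 3-component Gaussian mixture on", x$n, "h values;",
      x$n_iter, "EM iterations, log-likelihood", format(x$loglik), "\n")
  print(x$components)
  invisible(x)
}

#' Intersection point of two weighted Gaussian curves
#'
#' Solves `w_a * dnorm(x, mu_a, sd_a) = w_b * dnorm(x, mu_b, sd_b)` for the
#' root lying strictly between the two component means — the natural
#' classification boundary between two adjacent mixture components. Solved
#' in closed form (the log-ratio is quadratic in x; linear for equal sds),
#' with a bisection fallback on the log-density difference.
#'
#' @param a,b Lists (or one-row data frames) with `weight`, `mean`, `sd`;
#'   `a$mean < b$mean` required.
#' @return The intersection h value, strictly between the means.
#' @export
#' @examples
#' gaussian_intersection(list(weight = 0.5, mean = 0.3, sd = 0.1),
#'                       list(weight = 0.5, mean = 0.7, sd = 0.1))
gaussian_intersection <- function(a, b) {
  wa <- a$weight; ma <- a$mean; sa <- a$sd
  wb <- b$weight; mb <- b$mean; sb <- b$sd
  if (!(ma < mb)) stop("Require a$mean < b$mean (distinct components).")
  stopifnot(sa > 0, sb > 0, wa > 0, wb > 0)
  # log wa - log sa - (x-ma)^2/(2 sa^2) = log wb - log sb - (x-mb)^2/(2 sb^2)
  A <- 1 / (2 * sb^2) - 1 / (2 * sa^2)
  B <- ma / sa^2 - mb / sb^2
  C <- log(wa / sa) - log(wb / sb) - ma^2 / (2 * sa^2) + mb^2 / (2 * sb^2)
  roots <- if (abs(A) < 1e-12) {
    if (abs(B) < 1e-12) numeric(0) else -C / B
  } else {
    disc <- B^2 - 4 * A * C
    if (disc < 0) numeric(0) else (-B + c(-1, 1) * sqrt(disc)) / (2 * A)
  }
  inside <- roots[roots > ma & roots < mb]
  if (length(inside) >= 1L) return(inside[1])
  # bisection fallback on the log-density difference
  f <- function(x) {
    (log(wa) - log(sa) - (x - ma)^2 / (2 * sa^2)) -
      (log(wb) - log(sb) - (x - mb)^2 / (2 * sb^2))
  }
  eps <- (mb - ma) * 1e-9
  lo <- ma + eps; hi <- mb - eps
  if (sign(f(lo)) == sign(f(hi))) {
    stop("No intersection strictly between the component means ",
         "(extreme weight imbalance).")
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Derive homoplasmy thresholds from a fitted mixture
#'
#' The low threshold is the intersection of the left (NG-homoplasmic) and
#' middle (heteroplasmic) Gaussian curves; the high threshold is the
#' intersection of the middle and right (mKate2-homoplasmic) curves.
#'
#' @param fit A [fit_gaussian_mixture()] object.
#' @return A named numeric vector `c(low = ..., high = ...)`.
#' @export
derive_thresholds <- function(fit) {
  stopifnot(inherits(fit, "gmm_fit"))
  comp <- fit$components
  low <- gaussian_intersection(comp[1, ], comp[2, ])
  high <- gaussian_intersection(comp[2, ], comp[3, ])
  c(low = low, high = high)
}

#' Classify cells by h value
#'
#' Cells strictly below the low threshold are homoplasmic for the NG-marked
#' variant; strictly above the high threshold, homoplasmic for the
#' mKate2-marked variant; otherwise heteroplasmic (boundary values count as
#' heteroplasmic).
#'
#' @param h Numeric vector of h values in `[0, 1]` (NA allowed, propagated).
#' @param thresholds Length-2 numeric `(low, high)` with
#'   `0 < low < high < 1`; defaults to the Gaussian-intersection values
#'   0.33 and 0.71.
#' @return Factor with levels `homo_NG`, `heteroplasmic`, `homo_mKate`.
#' @export
#' @examples
#' classify_h(c(0.2, 0.5, 0.9, 0.33))
classify_h <- function(h, thresholds = c(0.33, 0.71)) {
  stopifnot(length(thresholds) == 2L,
            thresholds[1] > 0, thresholds[2] < 1,
            thresholds[1] < thresholds[2])
  if (any(h < 0 | h > 1, na.rm = TRUE)) stop("h values must lie in [0, 1].")
  cls <- ifelse(h < thresholds[1], "homo_NG",
                ifelse(h > thresholds[2], "homo_mKate", "heteroplasmic"))
  factor(cls, levels = c("homo_NG", "heteroplasmic", "homo_mKate"))
}

#' Fraction of heteroplasmic cells
#'
#' @param h Numeric vector of h values (NA dropped).
#' @param thresholds Passed to [classify_h()].
#' @return Fraction of cells classified `heteroplasmic`.
#' @export
fraction_heteroplasmic <- function(h, thresholds = c(0.33, 0.71)) {
  h <- h[!is.na(h)]
  if (length(h) == 0L) stop("Need at least one h value.")
  mean(classify_h(h, thresholds) == "heteroplasmic")
}

#' Valley threshold between two intensity peaks
#'
#' For bimodal intensity distributions (cells with signal vs essentially
#' dark cells), returns the location of the kernel-density minimum between
#' the two highest modes — the per-replicate "signal / no signal" cutoff.
#' Uses a Gaussian KDE with Silverman's rule-of-thumb bandwidth; modes are
#' local density maxima rising above 10% of the global maximum.
#'
#' @param intensities Numeric vector, length >= 10.
#' @return The intensity at the valley minimum.
#' @export
#' @examples
#' set.seed(1)
#' valley_threshold(c(rnorm(500, 1, 0.2), rnorm(500, 10, 1)))
valley_threshold <- function(intensities) {
  intensities <- intensities[!is.na(intensities)]
  if (length(intensities) < 10L) {
    stop("Need at least 10 values for a density-based threshold.")
  }
  d <- stats::density(intensities, bw = "nrd0")
  y <- d$y
  k <- length(y)
  is_max <- y > c(-Inf, y[-k]) & y >= c(y[-1], -Inf)
  modes <- which(is_max & y > 0.1 * max(y))
  if (length(modes) < 2L) {
    stop("Distribution is not bimodal: fewer than two density modes found.")
  }
  # the two highest modes
  top2 <- sort(modes[order(y[modes], decreasing = TRUE)][1:2])
  between <- seq(top2[1], top2[2])
  d$x[between[which.min(y[between])]]
}
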