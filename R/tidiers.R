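#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Gaussian mixture fit
#'
#' @param x A [fit_gaussian_mixture()] object.
#' @param ... Unused.
#' @return One row per component: `component`, `weight`, `mean`, `sd`.
#' @method tidy gmm_fit
#' @export
tidy.gmm_fit <- function(x, ...) x$components

#' @rdname tidy.gmm_fit
#' @method glance gmm_fit
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble::tibble(n = x$n, loglik = x$loglik, n_iter = x$n_iter,
                 converged = x$converged, collapsed = x$collapsed)
}

#' Tidy a sigmoid fit
#'
#' @param x A [fit_sigmoid()] object.
#' @param ... Unused.
#' @return One row per parameter (`L`, `r`, `t0`) with its estimate.
#' @method tidy sigmoid_fit
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(term = names(x$parameters),
                 estimate = unname(x$parameters))
}

#' @rdname tidy.sigmoid_fit
#' @method glance sigmoid_fit
#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = nrow(x$fitted), degenerate = x$degenerate)
}

#' Tidy an exponential decay fit
#'
#' @param x A [fit_decay()] object.
#' @param ... Unused.
#' @return One row per parameter: `k` (with standard error), `amplitude`,
#'   `offset`.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("k", "amplitude", "offset"),
                 estimate = c(x$k, x$amplitude, x$offset),
                 std.error = c(x$k_sem, NA_real_, NA_real_))
}

#' @rdname tidy.decay_fit
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, n = nrow(x$fitted), no_decay = x$no_decay)
}

#' Tidy a grid-search fit
#'
#' @param x A [grid_search()] object.
#' @param ... Unused.
#' @return The full SSE surface, one row per (ndau, nspl) pair.
#' @method tidy grid_fit
#' @export
tidy.grid_fit <- function(x, ...) x$grid

#' @rdname tidy.grid_fit
#' @method glance grid_fit
#' @export
glance.grid_fit <- function(x, ...) {
  tibble::tibble(best_ndau = x$best_ndau, best_nspl = x$best_nspl,
                 min_sse = min(x$grid$sse),
                 n_pairs = nrow(x$grid), n_replicates = x$n_replicates)
}
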