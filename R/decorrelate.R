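#' Statistical inefficiency of a time series
#'
#' Estimates the integrated autocorrelation time `tau` and the statistical
#' inefficiency `g = 1 + 2 tau` of a scalar time series, the factor by which
#' correlated samples must be thinned to behave as independent draws. The
#' normalized autocovariances are summed with the triangular `(1 - t/N)`
#' factor and the sum is truncated at the first non-positive autocorrelation;
#' a constant series returns `g = 1` by convention.
#'
#' @param series Numeric vector, length >= 2.
#'
#' @return A `decorrelation_info` object: a list with `g`, `tau` (in units of
#'   the sampling interval) and `n` (series length).
#' @examples
#' set.seed(1)
#' statistical_inefficiency(rnorm(1000))$g  # ~1 for white noise
#' @export
statistical_inefficiency <- function(series) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 2L) {
    abort("`series` must contain at least 2 observations.",
          class = "abfe_invalid_input")
  }
  if (any(!is.finite(series))) {
    abort("`series` must be finite.", class = "abfe_invalid_input")
  }
  mu <- mean(series)
  d <- series - mu
  c0 <- mean(d * d)
  if (c0 <= .Machine$double.eps * max(1, mu^2)) {
    # constant (or numerically constant) series
    return(new_decorrelation_info(g = 1, tau = 0, n = n))
  }
  tau <- 0
  for (t in seq_len(n - 1L)) {
    rho <- sum(d[1:(n - t)] * d[(1 + t):n]) / ((n - t) * c0)
    if (rho <= 0) break
    tau <- tau + (1 - t / n) * rho
  }
  g <- max(1, 1 + 2 * tau)
  new_decorrelation_info(g = g, tau = (g - 1) / 2, n = n)
}

new_decorrelation_info <- function(g, tau, n) {
  structure(list(g = g, tau = tau, n = n), class = "decorrelation_info")
}

#' @export
print.decorrelation_info <- function(x, ...) {
  cat(sprintf("<decorrelation_info> g = %.3f, tau = %.3f, n = %d\n",
              x$g, x$tau, x$n))
  invisible(x)
}

#' Equilibration discard and decorrelation subsampling
#'
#' Prepares per-state index sets of effectively uncorrelated samples: the
#' first `floor(discard_fraction * n)` samples of each series are discarded as
#' equilibration, the statistical inefficiency `g` of the remainder is
#' estimated, and the retained samples are thinned with stride `ceiling(g)`
#' starting at the first post-equilibration frame.
#'
#' @param series A numeric vector, a list of numeric vectors (one per state),
#'   or a matrix with one column per state.
#' @param discard_fraction Fraction in `[0, 1)` of each series dropped from
#'   the front before decorrelation.
#' @param g Optional statistical inefficiency to use instead of estimating it
#'   from each series (a single value, recycled).
#'
#' @return A `decorrelation_plan`: list with `indices` (a list of integer
#'   vectors of retained 1-based indices into the original series) and `info`,
#'   a tibble with one row per state (`state`, `n_input`, `n_after_discard`,
#'   `g`, `tau`, `stride`, `n_effective`, `discard_fraction`).
#' @examples
#' prepare_samples(list(a = rnorm(100)), discard_fraction = 0.1)$info
#' @export
prepare_samples <- function(series, discard_fraction = 0, g = NULL) {
  if (!is.numeric(discard_fraction) || length(discard_fraction) != 1L ||
      is.na(discard_fraction) || discard_fraction < 0 || discard_fraction >= 1) {
    abort("`discard_fraction` must be a single number in [0, 1).",
          class = "abfe_invalid_input")
  }
  if (is.matrix(series)) {
    series <- lapply(seq_len(ncol(series)), function(j) series[, j])
  } else if (is.numeric(series)) {
    series <- list(series)
  }
  if (!is.list(series) || length(series) == 0L) {
    abort("`series` must be a numeric vector, list of vectors, or matrix.",
          class = "abfe_invalid_input")
  }
  labels <- names(series) %||% as.character(seq_along(series))

  rows <- vector("list", length(series))
  idx <- vector("list", length(series))
  for (k in seq_along(series)) {
    x <- as.numeric(series[[k]])
    n <- length(x)
    n_discard <- as.integer(floor(discard_fraction * n))
    first <- n_discard + 1L
    kept <- x[first:n]
    if (is.null(g)) {
      info <- statistical_inefficiency(kept)
      gk <- info$g
      tauk <- info$tau
    } else {
      gk <- g[[min(k, length(g))]]
      if (gk < 1) abort("`g` must be >= 1.", class = "abfe_invalid_input")
      tauk <- (gk - 1) / 2
    }
    stride <- as.integer(ceiling(gk - 1e-10))
    sel <- seq.int(first, n, by = stride)
    idx[[k]] <- as.integer(sel)
    rows[[k]] <- tibble(
      state = labels[k],
      n_input = n,
      n_after_discard = n - n_discard,
      g = gk,
      tau = tauk,
      stride = stride,
      n_effective = length(sel),
      discard_fraction = discard_fraction
    )
  }
  names(idx) <- labels
  structure(
    list(indices = idx, info = dplyr::bind_rows(rows)),
    class = "decorrelation_plan"
  )
}

#' @export
print.decorrelation_plan <- function(x, ...) {
  cat("<decorrelation_plan>\n")
  print(x$info)
  invisible(x)
}

#' @rdname prepare_samples
#' @param x A `decorrelation_plan`.
#' @param ... Unused.
#' @export
tidy.decorrelation_plan <- function(x, ...) x$info
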