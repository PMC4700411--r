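#' Reduced-potential container for multistate estimation
#'
#' Holds cross-evaluated reduced potentials: for every retained sample (drawn
#' while simulating some state k) the dimensionless potential energy
#' `u = U / kT` evaluated at every state of the schedule. This is the
#' substrate consumed by [mbar_solve()].
#'
#' @param u Numeric matrix, one row per sample and one column per evaluated
#'   state, entries dimensionless reduced potentials.
#' @param origin Integer vector of length `nrow(u)` giving the sampling state
#'   (column index) each row was generated from. Alternatively supply `n_k`.
#' @param n_k Integer vector of per-state sample counts; used when `origin` is
#'   `NULL`, in which case rows are assumed grouped by state in column order.
#' @param temperature_K Temperature in kelvin at which the potentials were
#'   reduced.
#' @param state_labels Optional character labels for the states; defaults to
#'   the column names of `u`.
#'
#' @return A `reduced_potentials` object.
#' @examples
#' u <- matrix(rnorm(20), ncol = 2)
#' rp <- reduced_potentials(u, n_k = c(5, 5))
#' rp$n_k
#' @export
reduced_potentials <- function(u, origin = NULL, n_k = NULL,
                               temperature_K = 298.15,
                               state_labels = NULL) {
  u <- as.matrix(u)
  storage.mode(u) <- "double"
  K <- ncol(u)
  N <- nrow(u)
  if (K < 2L) {
    abort("At least 2 evaluated states are required.",
          class = "abfe_invalid_input")
  }
  if (any(!is.finite(u))) {
    abort("All reduced potentials must be finite.",
          class = "abfe_invalid_input")
  }
  if (is.null(origin)) {
    if (is.null(n_k)) {
      abort("Supply either `origin` or `n_k`.", class = "abfe_invalid_input")
    }
    n_k <- as.integer(n_k)
    if (length(n_k) != K || any(n_k < 0L) || sum(n_k) != N) {
      abort("`n_k` must have one non-negative count per state, summing to nrow(u).",
            class = "abfe_invalid_input")
    }
    origin <- rep.int(seq_len(K), n_k)
  } else {
    origin <- as.integer(origin)
    if (length(origin) != N || any(origin < 1L | origin > K)) {
      abort("`origin` must give a state column index for every row of `u`.",
            class = "abfe_invalid_input")
    }
    n_k <- tabulate(origin, nbins = K)
  }
  if (sum(n_k) < 2L) {
    abort("At least 2 samples are required in total.",
          class = "abfe_invalid_input")
  }
  labels <- state_labels %||% colnames(u) %||% as.character(seq_len(K))
  colnames(u) <- labels
  structure(
    list(u = u, origin = origin, n_k = n_k,
         temperature_K = temperature_K, state_labels = labels),
    class = "reduced_potentials"
  )
}

#' @export
print.reduced_potentials <- function(x, ...) {
  cat(sprintf("<reduced_potentials> %d samples x %d states, T = %.2f K\n",
              nrow(x$u), ncol(x$u), x$temperature_K))
  cat("  samples per state:", paste(x$n_k, collapse = " "), "\n")
  invisible(x)
}

#' @export
as_tibble.reduced_potentials <- function(x, ...) {
  out <- as_tibble(x$u, .name_repair = "minimal")
  dplyr::bind_cols(tibble(state = x$origin), out)
}

# Resample rows within each sampling state with replacement.
resample_within_states <- function(data) {
  pick <- integer(0)
  for (k in which(data$n_k > 0L)) {
    rows <- which(data$origin == k)
    pick <- c(pick, rows[sample.int(length(rows), length(rows), replace = TRUE)])
  }
  pick
}

#' Solve the MBAR self-consistency equations
#'
#' Estimates the dimensionless free energy of every state from
#' cross-evaluated reduced potentials by the multistate Bennett acceptance
#' ratio. Self-consistent iteration with log-sum-exp stabilization is used,
#' switching to a damped Newton step on the sampled-state subspace when the
#' update stalls; the first state is pinned at `f = 0`.
#'
#' @param data A [reduced_potentials()] object.
#' @param tolerance Convergence tolerance on `max |delta f_k|`.
#' @param max_iterations Iteration cap; exceeding it raises a convergence
#'   error carrying the last residual.
#' @param f_init Optional warm-start vector of dimensionless free energies.
#' @param check_overlap If `TRUE`, compute the state-overlap matrix and flag
#'   the fit when consecutive states share essentially no phase space.
#'
#' @return An `mbar_fit` object with elements `f` (dimensionless, `f[1] = 0`),
#'   `converged`, `n_iterations`, `residual`, `overlap`, `low_overlap`, and
#'   the input data. Use [tidy()] for a per-state table, [mbar_delta_f()] for
#'   differences, and [mbar_weights()] for the per-sample weight matrix.
#' @examples
#' rp <- sample_gaussian_states(sigma = c(1, 2), n = 500, seed = 1)
#' fit <- mbar_solve(rp)
#' mbar_delta_f(fit, 1, 2)  # close to -log(2)
#' @export
mbar_solve <- function(data, tolerance = 1e-10, max_iterations = 10000L,
                       f_init = NULL, check_overlap = TRUE) {
  stopifnot(inherits(data, "reduced_potentials"))
  u <- data$u
  n_k <- data$n_k
  K <- ncol(u)
  sampled <- which(n_k > 0L)
  if (length(sampled) < 2L) {
    abort("At least two states must carry samples.",
          class = "abfe_invalid_input")
  }
  logN <- log(n_k[sampled])
  us <- u[, sampled, drop = FALSE]

  f <- rep(0, K)
  if (!is.null(f_init)) {
    if (length(f_init) != K) {
      abort("`f_init` must have one entry per state.",
            class = "abfe_invalid_input")
    }
    f <- f_init - f_init[1L]
  }

  # log denominator log D_n = logsumexp_l (log N_l + f_l - u_nl), sampled l
  log_denom <- function(fs) {
    row_logsumexp(sweep(-us, 2L, logN + fs, `+`))
  }
  sc_update <- function(logD) {
    fnew <- -apply(-u - logD, 2L, logsumexp)
    fnew - fnew[1L]
  }

  resid <- Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    logD <- log_denom(f[sampled])
    fnew <- sc_update(logD)
    resid_new <- max(abs(fnew - f))
    stalled <- iter > 4L && resid_new > 0.5 * resid && resid_new < 1
    f <- fnew
    resid <- resid_new
    if (resid < tolerance) break
    if (iter >= max_iterations) {
      abort(sprintf(
        "MBAR failed to converge in %d iterations (residual %.3e).",
        max_iterations, resid),
        class = "abfe_convergence_error", residual = resid)
    }
    if (stalled) {
      # damped Newton on the sampled states (first sampled state pinned)
      logD <- log_denom(f[sampled])
      W <- exp(sweep(-us, 2L, logN + f[sampled], `+`) - logD)
      grad <- colSums(W) - n_k[sampled]
      H <- diag(colSums(W), nrow = length(sampled)) - crossprod(W)
      free <- -1L  # drop the first sampled state
      delta <- tryCatch(
        solve(H[free, free, drop = FALSE], -grad[free]),
        error = function(e) NULL)
      if (!is.null(delta) && all(is.finite(delta))) {
        gn0 <- sum(grad^2)
        step <- 1
        fs <- f[sampled]
        for (h in 1:12) {
          trial <- fs
          trial[-1L] <- fs[-1L] + step * delta
          logDt <- row_logsumexp(sweep(-us, 2L, logN + trial, `+`))
          Wt <- exp(sweep(-us, 2L, logN + trial, `+`) - logDt)
          gn <- sum((colSums(Wt) - n_k[sampled])^2)
          if (is.finite(gn) && gn < gn0) {
            f[sampled] <- trial
            f <- f - f[1L]
            break
          }
          step <- step / 2
        }
      }
    }
  }

  logD <- log_denom(f[sampled])
  overlap <- NULL
  low_overlap <- FALSE
  if (check_overlap) {
    # A_nk = exp(f_k - u_nk - log D_n); O_ij = sum_n A_ni A_nj N_j
    A <- exp(sweep(-u, 2L, f, `+`) - logD)
    overlap <- crossprod(A, A * rep(1, nrow(A))) *
      matrix(n_k, K, K, byrow = TRUE)
    dimnames(overlap) <- list(data$state_labels, data$state_labels)
    if (K > 1L) {
      adjacent <- vapply(seq_len(K - 1L), function(k) {
        overlap[k, k + 1L] + overlap[k + 1L, k]
      }, numeric(1))
      if (any(adjacent < 1e-8)) {
        low_overlap <- TRUE
        warn("Consecutive states with essentially no phase-space overlap detected; MBAR estimates between them are unreliable.")
      }
    }
  }

  structure(
    list(f = stats::setNames(f, data$state_labels),
         converged = TRUE, n_iterations = iter, residual = resid,
         log_denom = logD, overlap = overlap, low_overlap = low_overlap,
         data = data, tolerance = tolerance),
    class = "mbar_fit"
  )
}

#' @export
print.mbar_fit <- function(x, ...) {
  cat(sprintf("<mbar_fit> %d states, %d samples, converged in %d iterations (residual %.2e)\n",
              length(x$f), nrow(x$data$u), x$n_iterations, x$residual))
  if (isTRUE(x$low_overlap)) cat("  warning: low phase-space overlap between consecutive states\n")
  invisible(x)
}

#' Free-energy difference between two states of an MBAR fit
#'
#' @param fit An `mbar_fit`.
#' @param i,j State indices (or labels); the value is `f_j - f_i`.
#' @param units `"reduced"` (dimensionless) or `"kcal/mol"` (multiplied by kT
#'   at the data temperature).
#' @return A single number.
#' @export
mbar_delta_f <- function(fit, i = 1L, j = length(fit$f),
                         units = c("reduced", "kcal/mol")) {
  units <- match.arg(units)
  if (is.character(i)) i <- match(i, names(fit$f))
  if (is.character(j)) j <- match(j, names(fit$f))
  df <- unname(fit$f[j] - fit$f[i])
  if (units == "kcal/mol") df <- df * .kB * fit$data$temperature_K
  df
}

#' Per-sample MBAR weight matrix
#'
#' Returns the matrix `W` with `W[n, k]` the normalized weight of sample `n`
#' in state `k`; rows sum to 1 and at convergence the column sums reproduce
#' the per-state sample counts.
#'
#' @param fit An `mbar_fit`.
#' @return A numeric matrix, samples by states.
#' @export
mbar_weights <- function(fit) {
  u <- fit$data$u
  n_k <- fit$data$n_k
  W <- exp(sweep(-u, 2L, log(pmax(n_k, .Machine$double.xmin)) + fit$f, `+`) -
             fit$log_denom)
  W[, n_k == 0L] <- 0
  W
}

#' Information-matrix covariance diagnostic for an MBAR fit
#'
#' Approximate asymptotic covariance of the dimensionless free energies,
#' computed as the pseudo-inverse of the observed information on the
#' sampled-state subspace with the first state pinned. This is a diagnostic
#' only: reported uncertainties in this package always come from bootstrap
#' resampling, which accounts for correlation structure the asymptotic
#' formula misses.
#'
#' @param fit An `mbar_fit`.
#' @return A K x K covariance matrix (rows/cols of unsampled states are NA).
#' @export
mbar_covariance <- function(fit) {
  data <- fit$data
  n_k <- data$n_k
  K <- length(fit$f)
  sampled <- which(n_k > 0L)
  us <- data$u[, sampled, drop = FALSE]
  logN <- log(n_k[sampled])
  W <- exp(sweep(-us, 2L, logN + fit$f[sampled], `+`) - fit$log_denom)
  H <- diag(colSums(W), nrow = length(sampled)) - crossprod(W)
  cov_s <- matrix(0, length(sampled), length(sampled))
  cov_s[-1L, -1L] <- tryCatch(solve(H[-1L, -1L, drop = FALSE]),
                              error = function(e) MASS_ginv(H[-1L, -1L, drop = FALSE]))
  out <- matrix(NA_real_, K, K, dimnames = list(names(fit$f), names(fit$f)))
  out[sampled, sampled] <- cov_s
  out
}

# Moore-Penrose pseudo-inverse via SVD (avoids importing MASS for one call)
MASS_ginv <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' @rdname mbar_solve
#' @param x An `mbar_fit`.
#' @param ... Unused.
#' @export
tidy.mbar_fit <- function(x, ...) {
  kT <- .kB * x$data$temperature_K
  tibble(
    state = names(x$f),
    f = unname(x$f),
    f_kcal_mol = unname(x$f) * kT,
    n_samples = x$data$n_k
  )
}

#' @rdname mbar_solve
#' @export
glance.mbar_fit <- function(x, ...) {
  tibble(
    n_states = length(x$f),
    n_samples = nrow(x$data$u),
    converged = x$converged,
    n_iterations = x$n_iterations,
    residual = x$residual,
    low_overlap = x$low_overlap
  )
}
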