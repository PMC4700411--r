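#' Free-energy estimate with bootstrap uncertainty
#'
#' Light-weight container for a free energy in kcal/mol with its bootstrap
#' replicate distribution. When bootstrap samples are present the value is
#' their mean and the uncertainty their sample standard deviation.
#'
#' @param value Free energy in kcal/mol (ignored when `boot` is given).
#' @param sd Standard deviation in kcal/mol (ignored when `boot` is given).
#' @param boot Optional numeric vector of bootstrap replicate values in
#'   kcal/mol; the first replicate is conventionally the unresampled estimate.
#' @param method,seed,n_boot,temperature_K Metadata recorded on the object.
#'
#' @return A `free_energy_estimate` object.
#' @export
free_energy_estimate <- function(value = NULL, sd = NULL, boot = NULL,
                                 method = "manual", seed = NA_integer_,
                                 n_boot = length(boot),
                                 temperature_K = 298.15) {
  if (!is.null(boot)) {
    boot <- as.numeric(boot)
    if (any(!is.finite(boot))) {
      abort("Bootstrap replicates must be finite.",
            class = "abfe_invalid_input")
    }
    value <- mean(boot)
    sd <- if (length(boot) > 1L) stats::sd(boot) else 0
  }
  if (is.null(value) || !is.finite(value)) {
    abort("`value` must be a finite number.", class = "abfe_invalid_input")
  }
  sd <- sd %||% 0
  if (!is.na(sd) && sd < 0) {
    abort("`sd` must be non-negative.", class = "abfe_invalid_input")
  }
  structure(
    list(value = value, sd = sd, boot = boot, method = method,
         seed = seed, n_boot = n_boot, temperature_K = temperature_K),
    class = "free_energy_estimate"
  )
}

#' @export
print.free_energy_estimate <- function(x, ...) {
  cat(sprintf("<free_energy_estimate> %.3f +/- %.3f kcal/mol (%s, n_boot = %s)\n",
              x$value, x$sd, x$method,
              if (is.null(x$n_boot) || x$n_boot == 0) "none" else x$n_boot))
  invisible(x)
}

#' @rdname free_energy_estimate
#' @param x A `free_energy_estimate`.
#' @param ... Unused.
#' @export
tidy.free_energy_estimate <- function(x, ...) {
  tibble(
    value_kcal_mol = x$value,
    sd_kcal_mol = x$sd,
    n_boot = x$n_boot %||% 0L,
    method = x$method,
    seed = x$seed
  )
}

#' @rdname free_energy_estimate
#' @export
glance.free_energy_estimate <- function(x, ...) tidy(x)

#' Bootstrapped MBAR free-energy difference between two states
#'
#' Runs MBAR on the original data and on `n_boot - 1` bootstrap resamples,
#' drawn with replacement independently within each sampling state (sample
#' counts preserved). Replicate 1 is the unresampled data. The reported value
#' is the mean of all replicates and the uncertainty their sample standard
#' deviation, converted to kcal/mol with kT at the data temperature.
#'
#' @param data A [reduced_potentials()] object (already decorrelated).
#' @param endpoints Length-2 integer vector of state indices; the difference
#'   reported is `f[endpoints[2]] - f[endpoints[1]]`.
#' @param n_boot Total number of replicates including the original sample.
#' @param seed Integer seed controlling the resampling.
#' @param tolerance,max_iterations Passed to [mbar_solve()].
#'
#' @return A [free_energy_estimate()] with the replicate vector attached.
#' @examples
#' rp <- sample_gaussian_states(sigma = c(1, 2), n = 400, seed = 7)
#' bootstrap_free_energy(rp, n_boot = 20, seed = 1)
#' @export
bootstrap_free_energy <- function(data, endpoints = c(1L, ncol(data$u)),
                                  n_boot = 200L, seed = 1L,
                                  tolerance = 1e-10,
                                  max_iterations = 10000L) {
  stopifnot(inherits(data, "reduced_potentials"))
  n_boot <- as.integer(n_boot)
  if (is.na(n_boot) || n_boot < 2L) {
    abort("`n_boot` must be at least 2.", class = "abfe_invalid_input")
  }
  if (length(endpoints) != 2L) {
    abort("`endpoints` must name exactly two states.",
          class = "abfe_invalid_input")
  }
  res <- bootstrap_multi(data, pairs = list(as.integer(endpoints)),
                         n_boot = n_boot, seed = seed,
                         tolerance = tolerance,
                         max_iterations = max_iterations)
  est <- res$estimates[[1L]]
  est$fit <- res$fit
  est
}

#' Pool bootstrap replicates across repeated calculations
#'
#' Combines independent repeats of the same calculation by concatenating
#' their bootstrap replicate sets (e.g. three repeats of 200 replicates give
#' a pool of 600) and reporting the mean and sample standard deviation of the
#' pool, so the final uncertainty reflects both the estimator's statistical
#' error and the spread between repeats.
#'
#' @param estimates A list of [free_energy_estimate()] objects, each carrying
#'   bootstrap replicates.
#' @return A [free_energy_estimate()] computed on the pooled replicates.
#' @export
combine_repeats <- function(estimates) {
  if (inherits(estimates, "free_energy_estimate")) estimates <- list(estimates)
  if (length(estimates) == 0L) {
    abort("At least one estimate is required.", class = "abfe_invalid_input")
  }
  boots <- lapply(estimates, function(e) {
    if (!inherits(e, "free_energy_estimate") || is.null(e$boot)) {
      abort("Every input must be a free_energy_estimate with bootstrap samples.",
            class = "abfe_invalid_input")
    }
    e$boot
  })
  pool <- unlist(boots, use.names = FALSE)
  temp <- estimates[[1L]]$temperature_K
  est <- free_energy_estimate(boot = pool, method = "pooled_repeats",
                              n_boot = length(pool), temperature_K = temp)
  if (length(pool) == 1L) est$sd <- 0
  est
}
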