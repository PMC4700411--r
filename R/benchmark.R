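#' BRD4(1) bromodomain inhibitor benchmark set
#'
#' Calculated and experimental standard binding free energies (kcal/mol, one
#' standard deviation) for 11 diverse inhibitors of the first bromodomain of
#' BRD4. Two calculation campaigns are included: one started from the holo
#' crystal structures (`table = 1`) and one from the best-scored docking
#' poses, which also carries the docking score for each ligand (`table = 2`).
#' Ligand 11's experimental value comes from a single measurement, so its
#' experimental uncertainty is missing, not zero. Values are stored at the
#' one-decimal precision at which they were reported; summary statistics are
#' always recomputed from the free-energy columns themselves.
#'
#' @param table Which campaign to return: `1` (crystal structures), `2`
#'   (docking poses) or `"both"`.
#' @return A tibble with columns `ligand`, `dG_calc`, `dG_calc_sd`,
#'   `dG_exp`, `dG_exp_sd`, `docking_dG`, `table`.
#' @examples
#' mae(brd4_benchmark(1)$dG_calc, brd4_benchmark(1)$dG_exp)
#' @export
brd4_benchmark <- function(table = "both") {
  path <- system.file("extdata", "brd4_affinities.csv", package = "abfe",
                      mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- as_tibble(d)
  if (!identical(table, "both")) {
    d <- d[d$table == as.integer(table), , drop = FALSE]
  }
  d
}

check_paired <- function(pred, obs, n_min = 1L) {
  if (length(pred) != length(obs)) {
    abort("`pred` and `obs` must have equal length.",
          class = "abfe_invalid_input")
  }
  if (length(pred) < n_min) {
    abort(sprintf("At least %d paired values are required.", n_min),
          class = "abfe_invalid_input")
  }
  if (any(!is.finite(pred)) || any(!is.finite(obs))) {
    abort("Inputs must be finite.", class = "abfe_invalid_input")
  }
}

#' Accuracy metrics for predicted versus experimental affinities
#'
#' `mae()` is the mean absolute error and `rmse()` the root mean squared
#' error, both in the units of the inputs; `pearson()` is the plug-in
#' product-moment correlation and `spearman()` the rank correlation with
#' midranks for ties.
#'
#' @param pred,obs Equal-length numeric vectors (predicted and reference).
#' @return A single number.
#' @examples
#' mae(c(-10, -9), c(-9.5, -9.5))
#' @export
mae <- function(pred, obs) {
  check_paired(pred, obs)
  mean(abs(pred - obs))
}

#' @rdname mae
#' @export
rmse <- function(pred, obs) {
  check_paired(pred, obs)
  sqrt(mean((pred - obs)^2))
}

#' @rdname mae
#' @export
pearson <- function(pred, obs) {
  check_paired(pred, obs, n_min = 3L)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) {
    abort("Correlation is undefined for zero-variance input.",
          class = "abfe_undefined_correlation")
  }
  stats::cor(pred, obs, method = "pearson")
}

#' @rdname mae
#' @export
spearman <- function(pred, obs) {
  check_paired(pred, obs, n_min = 3L)
  if (length(unique(pred)) < 2L || length(unique(obs)) < 2L) {
    abort("Correlation is undefined for zero-variance input.",
          class = "abfe_undefined_correlation")
  }
  stats::cor(pred, obs, method = "spearman")
}

#' Paired bootstrap of a benchmark metric
#'
#' Resamples ligand records with replacement (predicted and experimental
#' values stay paired) and reports the mean and sample standard deviation of
#' the metric across replicates.
#'
#' @param metric A function of `(pred, obs)`, e.g. [mae()].
#' @param pred,obs Equal-length numeric vectors.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return A list with `mean`, `sd` and the replicate vector `boot`.
#' @export
bootstrap_metric <- function(metric, pred, obs, n_boot = 10000L, seed = 1L) {
  check_paired(pred, obs, n_min = 2L)
  n_boot <- as.integer(n_boot)
  if (is.na(n_boot) || n_boot < 2L) {
    abort("`n_boot` must be at least 2.", class = "abfe_invalid_input")
  }
  n <- length(pred)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(metric(pred[idx], obs[idx]), error = function(e) NA_real_)
    }, numeric(1))
  })
  ok <- reps[is.finite(reps)]
  list(mean = mean(ok), sd = stats::sd(ok), boot = reps)
}

#' Benchmark summary of predicted against experimental free energies
#'
#' Computes MAE, RMSE, Pearson's r and Spearman's rho for a set of per-ligand
#' records, each with a paired bootstrap mean and standard deviation over
#' ligands. Plug-in values are authoritative; the bootstrap columns quantify
#' the sensitivity of each metric to the ligand set.
#'
#' @param records Data frame with at least the columns named by `pred` and
#'   `obs` (see [brd4_benchmark()] for the expected layout).
#' @param pred,obs Column names of the predicted and reference free energies.
#' @param n_boot Bootstrap replicates over ligands.
#' @param seed Integer seed.
#' @return A `benchmark_summary`: tibble with one row per metric (`metric`,
#'   `value`, `boot_mean`, `boot_sd`) plus attributes `n` and columns used.
#' @examples
#' benchmark_summary(brd4_benchmark(1), n_boot = 200)
#' @export
benchmark_summary <- function(records, pred = "dG_calc", obs = "dG_exp",
                              n_boot = 10000L, seed = 1L) {
  records <- as_tibble(records)
  if (!all(c(pred, obs) %in% names(records))) {
    abort(sprintf("`records` must contain columns `%s` and `%s`.", pred, obs),
          class = "abfe_invalid_input")
  }
  p <- records[[pred]]
  o <- records[[obs]]
  keep <- is.finite(p) & is.finite(o)
  p <- p[keep]
  o <- o[keep]
  metrics <- list(mae = mae, rmse = rmse, pearson_r = pearson,
                  spearman_rho = spearman)
  rows <- purrr::imap(metrics, function(fn, nm) {
    bt <- bootstrap_metric(fn, p, o, n_boot = n_boot, seed = seed)
    tibble(metric = nm, value = fn(p, o),
           boot_mean = bt$mean, boot_sd = bt$sd)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("benchmark_summary", class(out)),
            n = length(p), pred = pred, obs = obs,
            data = tibble(pred = p, obs = o))
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat(sprintf("<benchmark_summary> n = %d ligands (%s vs %s)\n",
              attr(x, "n"), attr(x, "pred"), attr(x, "obs")))
  NextMethod()
}

#' @rdname benchmark_summary
#' @param x A `benchmark_summary`.
#' @param ... Unused.
#' @export
glance.benchmark_summary <- function(x, ...) {
  wide <- stats::setNames(as.list(x$value), x$metric)
  dplyr::bind_cols(as_tibble(wide), tibble(n = attr(x, "n")))
}

#' @rdname benchmark_summary
#' @param object A `benchmark_summary`.
#' @export
autoplot.benchmark_summary <- function(object, ...) {
  d <- attr(object, "data")
  rng <- range(c(d$pred, d$obs))
  g <- glance(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$obs, y = .data$pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_abline(slope = 1, intercept = c(-1, 1),
                         colour = "grey80", linetype = 2) +
    ggplot2::geom_point(size = 2, colour = "firebrick") +
    ggplot2::coord_equal(xlim = rng, ylim = rng) +
    ggplot2::labs(
      x = "experimental dG (kcal/mol)", y = "predicted dG (kcal/mol)",
      title = sprintf("MAE %.2f, RMSE %.2f, r %.2f, rho %.2f (n = %d)",
                      g$mae, g$rmse, g$pearson_r, g$spearman_rho, g$n)) +
    ggplot2::theme_minimal()
}
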