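#' Read a per-window reduced-potential energy table
#'
#' Two dialects are supported. `"tsv"`: a tab-separated file whose header row
#' starts with `state` followed by one column label per evaluated state; each
#' data row holds the sampling-state index and the sample's reduced potential
#' at every evaluated state. `"xvg"`: the same column layout without a
#' header, with comment/header lines beginning `#` or `@` ignored, split on
#' arbitrary whitespace. Temperatures are never inferred from files; supply
#' them where the data are consumed.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"xvg"`.
#' @return A tibble with integer column `state` and one numeric column per
#'   evaluated state.
#' @export
read_energy_table <- function(path, dialect = c("tsv", "xvg")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "abfe_parse_error")
  }
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  if (dialect == "xvg") {
    keep <- !grepl("^[#@]", lines) & nzchar(trimws(lines))
    lines <- lines[keep]
    lineno <- lineno[keep]
    split_re <- "[ \t]+"
    labels <- NULL
  } else {
    keep <- nzchar(trimws(lines))
    lines <- lines[keep]
    lineno <- lineno[keep]
    if (length(lines) == 0L) {
      abort("Empty energy table.", class = "abfe_parse_error")
    }
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (header[1L] != "state") {
      abort(sprintf("Line %d: expected header starting with 'state'.",
                    lineno[1L]),
            class = "abfe_parse_error")
    }
    labels <- header[-1L]
    lines <- lines[-1L]
    lineno <- lineno[-1L]
    split_re <- "\t"
  }
  if (length(lines) == 0L) {
    abort("Energy table contains no data rows.", class = "abfe_parse_error")
  }
  fields <- strsplit(lines, split_re)
  ncols <- lengths(fields)
  if (length(unique(ncols)) != 1L) {
    bad <- lineno[which(ncols != ncols[1L])[1L]]
    abort(sprintf("Line %d: ragged row (%d fields, expected %d).",
                  bad, ncols[ncols != ncols[1L]][1L], ncols[1L]),
          class = "abfe_parse_error")
  }
  nc <- ncols[1L]
  if (nc < 3L) {
    abort("Energy tables need a state column and at least 2 state columns.",
          class = "abfe_parse_error")
  }
  if (!is.null(labels) && length(labels) != nc - 1L) {
    abort(sprintf("Header names %d states but rows have %d value columns.",
                  length(labels), nc - 1L),
          class = "abfe_parse_error")
  }
  m <- suppressWarnings(
    matrix(as.numeric(unlist(fields, use.names = FALSE)),
           nrow = length(fields), ncol = nc, byrow = TRUE))
  if (any(is.na(m))) {
    bad_row <- which(rowSums(is.na(m)) > 0)[1L]
    abort(sprintf("Line %d: non-numeric cell.", lineno[bad_row]),
          class = "abfe_parse_error")
  }
  u <- m[, -1L, drop = FALSE]
  colnames(u) <- labels %||% as.character(seq_len(nc - 1L))
  dplyr::bind_cols(tibble(state = as.integer(m[, 1L])),
                   as_tibble(u, .name_repair = "minimal"))
}

#' Write a reduced-potential energy table
#'
#' @param data A [reduced_potentials()] object or a data frame with a `state`
#'   column (the layout produced by [read_energy_table()]).
#' @param path Output file path (TSV dialect).
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(data, path) {
  if (inherits(data, "reduced_potentials")) {
    df <- as_tibble(data)
  } else {
    df <- as_tibble(data)
  }
  if (!"state" %in% names(df)) {
    abort("Energy tables need a `state` column.", class = "abfe_invalid_input")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read and validate a YAML run configuration
#'
#' The configuration names each leg's energy table (or a toy-model block),
#' the restraint (with the unit its angular force constants are declared in),
#' the temperature, estimator settings and additive corrections.
#'
#' @param path Path to a YAML document.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "abfe_parse_error")
  }
  cfg <- yaml::read_yaml(path)
  temp <- cfg$temperature %||% 298.15
  if (!is.numeric(temp) || temp <= 0) {
    abort("`temperature` must be positive.", class = "abfe_invalid_input")
  }
  cfg$temperature <- temp
  est <- cfg$estimator %||% list()
  cfg$estimator <- list(
    discard_fraction = est$discard_fraction %||% 0.1,
    n_boot = as.integer(est$n_boot %||% 200L),
    seed = as.integer(est$seed %||% 1L),
    tolerance = est$tolerance %||% 1e-10
  )
  legs <- cfg$legs %||% list()
  for (nm in names(legs)) {
    leg <- legs[[nm]]
    has_table <- !is.null(leg$energy_table)
    has_toy <- !is.null(leg$toy_model)
    if (has_table == has_toy) {
      abort(sprintf("Leg '%s' must declare exactly one of `energy_table` or `toy_model`.", nm),
            class = "abfe_invalid_input")
    }
    legs[[nm]]$dialect <- leg$dialect %||% "tsv"
  }
  cfg$legs <- legs
  if (!is.null(cfg$restraint)) {
    r <- cfg$restraint
    cfg$restraint <- boresch_restraint(
      r0 = r$r0, theta_A0 = r$theta_A0, theta_B0 = r$theta_B0,
      phi_A0 = r$phi_A0 %||% 0, phi_B0 = r$phi_B0 %||% 0,
      phi_C0 = r$phi_C0 %||% 0,
      k_r = r$k_r, k_theta_A = r$k_theta_A, k_theta_B = r$k_theta_B,
      k_phi_A = r$k_phi_A, k_phi_B = r$k_phi_B, k_phi_C = r$k_phi_C,
      angle_k_unit = r$angle_k_unit %||% "kcal/mol/rad2"
    )
  }
  structure(cfg, class = "run_config")
}

#' JSON report for package result objects
#'
#' Serializes estimates, cycle results and benchmark summaries to the JSON
#' report schema (energies in kcal/mol). `write_report()` writes to a file,
#' `report_json()` returns the JSON string.
#'
#' @param x A `free_energy_estimate`, `cycle_result`, `benchmark_summary`,
#'   `lambda_schedule` or plain list.
#' @param path Output path.
#' @param ... Unused.
#' @return JSON string (`report_json`) or `path` invisibly (`write_report`).
#' @export
report_json <- function(x, ...) UseMethod("report_json")

#' @export
report_json.default <- function(x, ...) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, na = "null"))
}

#' @export
report_json.free_energy_estimate <- function(x, leg = NULL, ...) {
  report_json.default(list(
    leg = leg, value_kcal_mol = x$value, sd_kcal_mol = x$sd,
    n_boot = x$n_boot %||% 0L, seed = x$seed, method = x$method,
    temperature_K = x$temperature_K
  ))
}

#' @export
report_json.cycle_result <- function(x, ...) {
  legs <- lapply(x$legs, function(l) {
    list(value_kcal_mol = l$value, sd_kcal_mol = l$sd)
  })
  report_json.default(list(
    legs = legs, corrections_kcal_mol = x$corrections,
    dG_bind_kcal_mol = x$dG_bind, sd_kcal_mol = x$sd,
    temperature_K = x$thermo$temperature_K
  ))
}

#' @export
report_json.benchmark_summary <- function(x, ...) {
  rows <- lapply(seq_len(nrow(x)), function(i) {
    list(metric = x$metric[i], value = x$value[i],
         boot_mean = x$boot_mean[i], boot_sd = x$boot_sd[i])
  })
  report_json.default(list(n_ligands = attr(x, "n"), metrics = rows))
}

#' @export
report_json.lambda_schedule <- function(x, ...) {
  report_json.default(list(
    environment = attr(x, "environment"),
    n_states = nrow(x),
    states = lapply(seq_len(nrow(x)), function(i) {
      list(state = x$state[i], leg = x$leg[i],
           lambda_restraint = x$lambda_restraint[i],
           lambda_coulomb = x$lambda_coulomb[i],
           lambda_vdw = x$lambda_vdw[i])
    })
  ))
}

#' @rdname report_json
#' @export
write_report <- function(x, path, ...) {
  writeLines(report_json(x, ...), path)
  invisible(path)
}
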