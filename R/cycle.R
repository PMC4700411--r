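#' Finite-size charge correction from per-frame values
#'
#' Summarizes externally computed per-frame residual-integrated-potential
#' (RIP) style corrections for charged ligands: the mean is applied as an
#' additive correction to the cycle, and a warning flag is raised when the
#' per-frame standard deviation reaches `warn_threshold`, since a large
#' conformational spread makes a single mean correction questionable.
#'
#' @param per_frame_values Numeric vector of per-frame correction values in
#'   kcal/mol (at least one).
#' @param warn_threshold Standard-deviation threshold in kcal/mol.
#' @return A `charge_correction` object with `mean`, `sd`, `values`,
#'   `warn_threshold` and logical `flagged`.
#' @export
apply_charge_correction <- function(per_frame_values, warn_threshold = 0.05) {
  v <- as.numeric(per_frame_values)
  if (length(v) < 1L || any(!is.finite(v))) {
    abort("`per_frame_values` must contain at least one finite value.",
          class = "abfe_invalid_input")
  }
  s <- if (length(v) > 1L) stats::sd(v) else 0
  flagged <- s >= warn_threshold
  if (flagged) {
    warn(sprintf(
      "Charge-correction spread (sd = %.3f kcal/mol) reaches the warning threshold (%.3f); the mean correction may be unreliable.",
      s, warn_threshold))
  }
  structure(
    list(mean = mean(v), sd = s, values = v,
         warn_threshold = warn_threshold, flagged = flagged),
    class = "charge_correction"
  )
}

#' @export
print.charge_correction <- function(x, ...) {
  cat(sprintf("<charge_correction> mean = %.4f, sd = %.4f kcal/mol (%d frames)%s\n",
              x$mean, x$sd, length(x$values),
              if (x$flagged) " [FLAGGED]" else ""))
  invisible(x)
}

as_estimate <- function(x, what) {
  if (inherits(x, "free_energy_estimate")) return(x)
  if (is.numeric(x) && length(x) == 1L && is.finite(x)) {
    return(free_energy_estimate(value = x, sd = 0, method = "fixed"))
  }
  abort(sprintf("`%s` must be a free_energy_estimate or a single number.", what),
        class = "abfe_invalid_input")
}

#' Assemble the standard binding free energy from the four cycle legs
#'
#' Sums the signed leg free energies of the thermodynamic cycle — solvent
#' decoupling (`A -> B`), analytic restraining of the non-interacting ligand
#' (`B -> C`), recoupling in the restrained complex (`D -> E`) and restraint
#' release in the complex (`E -> F`) — plus any additive corrections (charge
#' correction, long-range dispersion). The uncertainty is the root sum square
#' of the leg uncertainties.
#'
#' @param dG_solv_elec_vdw,dG_prot_elec_vdw,dG_prot_restr
#'   [free_energy_estimate()] objects (or plain numbers, taken as exact) for
#'   the sampled legs, in the cycle directions above, kcal/mol.
#' @param dG_solv_restr The analytic restraint term (number or estimate),
#'   kcal/mol.
#' @param corrections Named list of additive corrections: numbers or
#'   [apply_charge_correction()] objects (their mean is used).
#' @param thermo A [thermo_state()], recorded on the result.
#'
#' @return A `cycle_result` with per-leg estimates, corrections, and
#'   `dG_bind` / `sd` for the assembled standard binding free energy.
#' @export
assemble_cycle <- function(dG_solv_elec_vdw, dG_solv_restr,
                           dG_prot_elec_vdw, dG_prot_restr,
                           corrections = list(), thermo = thermo_state()) {
  legs <- list(
    solv_elec_vdw = as_estimate(dG_solv_elec_vdw, "dG_solv_elec_vdw"),
    solv_restr = as_estimate(dG_solv_restr, "dG_solv_restr"),
    prot_elec_vdw = as_estimate(dG_prot_elec_vdw, "dG_prot_elec_vdw"),
    prot_restr = as_estimate(dG_prot_restr, "dG_prot_restr")
  )
  if (length(corrections) > 0 &&
      (is.null(names(corrections)) || any(names(corrections) == ""))) {
    abort("All corrections must be named.", class = "abfe_invalid_input")
  }
  corr_vals <- vapply(corrections, function(cc) {
    if (inherits(cc, "charge_correction")) cc$mean
    else if (is.numeric(cc) && length(cc) == 1L && is.finite(cc)) as.numeric(cc)
    else abort("Corrections must be numbers or charge_correction objects.",
               class = "abfe_invalid_input")
  }, numeric(1))

  value <- sum(vapply(legs, `[[`, numeric(1), "value")) + sum(corr_vals)
  sd <- sqrt(sum(vapply(legs, `[[`, numeric(1), "sd")^2))
  structure(
    list(legs = legs, corrections = as.list(corr_vals),
         dG_bind = value, sd = sd, thermo = as_thermo_state(thermo)),
    class = "cycle_result"
  )
}

#' @export
print.cycle_result <- function(x, ...) {
  cat("<cycle_result>\n")
  for (nm in names(x$legs)) {
    cat(sprintf("  dG_%-14s %8.3f +/- %.3f kcal/mol\n",
                nm, x$legs[[nm]]$value, x$legs[[nm]]$sd))
  }
  for (nm in names(x$corrections)) {
    cat(sprintf("  corr %-12s %8.3f kcal/mol\n", nm, x$corrections[[nm]]))
  }
  cat(sprintf("  dG_bind (std)    %8.3f +/- %.3f kcal/mol\n", x$dG_bind, x$sd))
  invisible(x)
}

#' @rdname assemble_cycle
#' @param x A `cycle_result`.
#' @param ... Unused.
#' @export
tidy.cycle_result <- function(x, ...) {
  legs <- tibble(
    term = paste0("dG_", names(x$legs)),
    value_kcal_mol = vapply(x$legs, `[[`, numeric(1), "value"),
    sd_kcal_mol = vapply(x$legs, `[[`, numeric(1), "sd")
  )
  if (length(x$corrections)) {
    legs <- dplyr::bind_rows(legs, tibble(
      term = paste0("correction_", names(x$corrections)),
      value_kcal_mol = unlist(x$corrections, use.names = FALSE),
      sd_kcal_mol = 0
    ))
  }
  legs
}

#' @rdname assemble_cycle
#' @export
glance.cycle_result <- function(x, ...) {
  tibble(dG_bind_kcal_mol = x$dG_bind, sd_kcal_mol = x$sd,
         temperature_K = x$thermo$temperature_K)
}

#' @rdname assemble_cycle
#' @param object A `cycle_result`.
#' @export
autoplot.cycle_result <- function(object, ...) {
  d <- tidy(object)
  d$term <- factor(d$term, levels = rev(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value_kcal_mol, y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$value_kcal_mol - .data$sd_kcal_mol,
                   xmax = .data$value_kcal_mol + .data$sd_kcal_mol),
      height = 0.25) +
    ggplot2::geom_vline(xintercept = object$dG_bind, linetype = 2) +
    ggplot2::labs(x = "kcal/mol", y = NULL,
                  title = sprintf("Cycle legs (dG_bind = %.2f +/- %.2f kcal/mol)",
                                  object$dG_bind, object$sd)) +
    ggplot2::theme_minimal()
}

#' Combine multiple binding modes into one binding free energy
#'
#' For a ligand with several thermodynamically relevant binding modes the
#' overall binding constant is the sum of the per-mode constants, so the
#' combined free energy is `dG = -kT ln sum_i exp(-dG_i / kT)`, evaluated
#' with log-sum-exp stabilization. The combined value can never be above the
#' lowest individual mode. When the mode estimates carry bootstrap samples,
#' the uncertainty is propagated by repeatedly redrawing one bootstrap value
#' per mode and recombining (the first draw uses the original values).
#'
#' @param estimates List of [free_energy_estimate()] objects or a numeric
#'   vector of mode free energies in kcal/mol.
#' @param thermo A [thermo_state()] (or temperature in kelvin).
#' @param n_resample Number of resampled combinations used for the
#'   uncertainty when bootstrap samples are available.
#' @param seed Integer seed for the resampling.
#' @return A [free_energy_estimate()].
#' @examples
#' combine_binding_modes(c(-8, -8))  # -8 - kT ln 2
#' @export
combine_binding_modes <- function(estimates, thermo = thermo_state(),
                                  n_resample = 10000L, seed = 1L) {
  thermo <- as_thermo_state(thermo)
  kT <- thermo$kT
  if (is.numeric(estimates)) estimates <- as.list(estimates)
  if (inherits(estimates, "free_energy_estimate")) estimates <- list(estimates)
  if (length(estimates) == 0L) {
    abort("At least one binding mode is required.",
          class = "abfe_invalid_input")
  }
  estimates <- lapply(estimates, as_estimate, what = "estimates")
  values <- vapply(estimates, `[[`, numeric(1), "value")
  combine <- function(v) -kT * logsumexp(-v / kT)
  value <- combine(values)

  boots <- lapply(estimates, `[[`, "boot")
  have_boot <- !vapply(boots, is.null, logical(1))
  if (all(have_boot) && length(estimates) >= 1L) {
    draws <- with_seed(seed, {
      vapply(seq_len(n_resample), function(b) {
        if (b == 1L) return(value)
        combine(vapply(boots, function(bs) bs[sample.int(length(bs), 1L)],
                       numeric(1)))
      }, numeric(1))
    })
    est <- free_energy_estimate(boot = draws, method = "combined_modes",
                                seed = as.integer(seed),
                                n_boot = n_resample,
                                temperature_K = thermo$temperature_K)
    est
  } else {
    sds <- vapply(estimates, `[[`, numeric(1), "sd")
    # population weights for first-order propagation through the log-sum-exp
    w <- exp((-values + value) / kT)
    free_energy_estimate(value = value, sd = sqrt(sum((w * sds)^2)),
                         method = "combined_modes",
                         temperature_K = thermo$temperature_K)
  }
}
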