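#' Default restraint-switching lambda values
#'
#' The 12 non-uniformly spaced coupling values used to switch the Boresch
#' restraint on in the complex, concentrated near zero where the restraint
#' free-energy derivative is largest.
#' @export
default_restraint_lambdas <- c(0, 0.01, 0.025, 0.05, 0.075, 0.1,
                               0.15, 0.2, 0.3, 0.5, 0.75, 1.0)

#' Build the alchemical lambda schedule for one environment
#'
#' Constructs the ordered ladder of `(lambda_restraint, lambda_coulomb,
#' lambda_vdw)` states for a decoupling calculation. All lambdas are coupling
#' parameters: 1 means fully on. The complex schedule starts from the
#' physical, fully interacting and unrestrained complex, switches the
#' restraint on at full coupling, then annihilates the charges, then
#' decouples the van der Waals interactions through a soft core. The solvent
#' schedule has no restraint leg: charges off, then van der Waals off.
#' Boundary states shared by consecutive legs appear once, which with the
#' default spacings yields 42 complex and 31 solvent windows.
#'
#' @param environment `"complex"` or `"solvent"`.
#' @param dlam_coul Spacing of the coulombic leg; must divide 1 evenly.
#' @param dlam_vdw Spacing of the van der Waals leg; must divide 1 evenly.
#' @param restraint_lambdas Ordered restraint coupling values starting at 0
#'   and ending at 1 (complex only).
#'
#' @return A `lambda_schedule`: a tibble with columns `state`, `leg`,
#'   `lambda_restraint`, `lambda_coulomb`, `lambda_vdw`, and attributes
#'   `environment`.
#' @examples
#' nrow(build_lambda_schedule("complex"))  # 42
#' nrow(build_lambda_schedule("solvent"))  # 31
#' @export
build_lambda_schedule <- function(environment = c("complex", "solvent"),
                                  dlam_coul = 0.1, dlam_vdw = 0.05,
                                  restraint_lambdas = default_restraint_lambdas) {
  environment <- match.arg(environment)
  check_spacing <- function(d, name) {
    if (!is.numeric(d) || length(d) != 1L || d <= 0 || d > 1 ||
        abs(round(1 / d) - 1 / d) > 1e-9) {
      abort(sprintf("`%s` must evenly divide 1.", name),
            class = "abfe_invalid_input")
    }
  }
  check_spacing(dlam_coul, "dlam_coul")
  check_spacing(dlam_vdw, "dlam_vdw")

  coul <- seq(1, 0, by = -dlam_coul)
  vdw <- seq(1, 0, by = -dlam_vdw)

  if (environment == "complex") {
    restraint_lambdas <- as.numeric(restraint_lambdas)
    if (length(restraint_lambdas) < 2L ||
        restraint_lambdas[1L] != 0 ||
        restraint_lambdas[length(restraint_lambdas)] != 1 ||
        is.unsorted(restraint_lambdas, strictly = TRUE) ||
        any(restraint_lambdas < 0 | restraint_lambdas > 1)) {
      abort("`restraint_lambdas` must increase strictly from 0 to 1.",
            class = "abfe_invalid_input")
    }
    legs <- list(
      tibble(leg = "restraint_on",
             lambda_restraint = restraint_lambdas,
             lambda_coulomb = 1, lambda_vdw = 1),
      tibble(leg = "coulomb_off",
             lambda_restraint = 1,
             lambda_coulomb = coul, lambda_vdw = 1),
      tibble(leg = "vdw_off",
             lambda_restraint = 1,
             lambda_coulomb = 0, lambda_vdw = vdw)
    )
  } else {
    legs <- list(
      tibble(leg = "coulomb_off",
             lambda_restraint = 0,
             lambda_coulomb = coul, lambda_vdw = 1),
      tibble(leg = "vdw_off",
             lambda_restraint = 0,
             lambda_coulomb = 0, lambda_vdw = vdw)
    )
  }
  # consecutive legs share exactly one boundary state; keep the first copy
  out <- legs[[1L]]
  for (i in seq_along(legs)[-1L]) {
    out <- dplyr::bind_rows(out, legs[[i]][-1L, ])
  }
  out <- dplyr::mutate(out, state = dplyr::row_number(), .before = 1L)
  structure(out, class = c("lambda_schedule", class(out)),
            environment = environment)
}

#' Leg boundary indices of a lambda schedule
#'
#' Returns the state index at which each leg of the schedule ends (the shared
#' boundary state belongs to the earlier leg in the stored table but marks
#' the start of the next).
#'
#' @param schedule A `lambda_schedule`.
#' @return Named integer vector of last-state indices per leg.
#' @export
schedule_leg_ends <- function(schedule) {
  legs <- rle(schedule$leg)
  ends <- cumsum(legs$lengths)
  stats::setNames(as.integer(ends), legs$values)
}

#' @export
print.lambda_schedule <- function(x, ...) {
  cat(sprintf("<lambda_schedule> environment = %s, %d states\n",
              attr(x, "environment"), nrow(x)))
  NextMethod()
}

#' @rdname build_lambda_schedule
#' @param object A `lambda_schedule`.
#' @param ... Unused.
#' @export
autoplot.lambda_schedule <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              dplyr::starts_with("lambda_"),
                              names_to = "coupling", values_to = "lambda",
                              names_prefix = "lambda_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$state, y = .data$lambda,
                                     colour = .data$coupling)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "window", y = expression(lambda),
                  title = sprintf("%s schedule (%d windows)",
                                  attr(object, "environment"), nrow(object))) +
    ggplot2::theme_minimal()
}
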