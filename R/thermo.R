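#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# Boltzmann constant in kcal/(mol K)
.kB <- 0.0019872041

# Coulomb constant in kcal A / (mol e^2)
.coulomb_const <- 332.06

#' Thermodynamic reference state
#'
#' Bundles the temperature and the standard-state volume that define the
#' reference concentration for a standard binding free energy. The default
#' volume of 1660.539 A^3 per molecule corresponds to 1 mol/L.
#'
#' @param temperature_K Temperature in kelvin.
#' @param v_standard Standard-state volume in cubic angstroms.
#'
#' @return An object of class `thermo_state` with fields `temperature_K`,
#'   `kT` (kcal/mol) and `v_standard` (A^3).
#' @examples
#' th <- thermo_state(298.15)
#' th$kT
#' @export
thermo_state <- function(temperature_K = 298.15, v_standard = 1660.539) {
  if (!is.numeric(temperature_K) || length(temperature_K) != 1L ||
      !is.finite(temperature_K) || temperature_K <= 0) {
    abort("`temperature_K` must be a single positive number.",
          class = "abfe_invalid_input")
  }
  if (!is.numeric(v_standard) || length(v_standard) != 1L ||
      !is.finite(v_standard) || v_standard <= 0) {
    abort("`v_standard` must be a single positive number.",
          class = "abfe_invalid_input")
  }
  structure(
    list(temperature_K = temperature_K,
         kT = .kB * temperature_K,
         v_standard = v_standard),
    class = "thermo_state"
  )
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("<thermo_state> T = %.2f K, kT = %.5f kcal/mol, V0 = %.3f A^3\n",
              x$temperature_K, x$kT, x$v_standard))
  invisible(x)
}

as_thermo_state <- function(x) {
  if (inherits(x, "thermo_state")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(thermo_state(x))
  abort("Expected a `thermo_state` or a single temperature in kelvin.",
        class = "abfe_invalid_input")
}

# log(sum(exp(x))) without overflow; -Inf for empty/-Inf input
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp of a matrix (pmax loop beats apply() for tall matrices)
row_logsumexp <- function(m) {
  mx <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
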