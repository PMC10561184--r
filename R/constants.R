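#' Physical constants used throughout the kinetic machinery
#'
#' Returns the CODATA values of the fundamental constants in the mixed unit
#' system the pipeline works in: energies in kcal/mol everywhere, SI only
#' inside rate-constant prefactors and diffusion coefficients.
#'
#' @param temperature Default working temperature in kelvin. All rate and
#'   equilibrium evaluations default to 298.15 K.
#'
#' @return A list of class `physical_constants` with elements
#'   `boltzmann_constant` (J/K), `planck_constant` (J s), `gas_constant`
#'   (kcal mol^-1 K^-1), `avogadro_number` (mol^-1), `default_temperature` (K),
#'   and the derived conversion `cm1_to_kcal` (kcal/mol per cm^-1).
#'
#' @examples
#' pc <- physical_constants()
#' pc$gas_constant * pc$default_temperature      # RT ~ 0.5925 kcal/mol
#' pc$boltzmann_constant * 298.15 / pc$planck_constant  # kBT/h ~ 6.21e12 1/s
#' @export
physical_constants <- function(temperature = 298.15) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  structure(
    list(
      boltzmann_constant  = 1.380649e-23,
      planck_constant     = 6.62607015e-34,
      gas_constant        = 1.987204258e-3,
      avogadro_number     = 6.02214076e23,
      default_temperature = temperature,
      # h * c * N_A / 4184: wavenumber (cm^-1) -> kcal/mol
      cm1_to_kcal         = 2.859144e-3
    ),
    class = "physical_constants"
  )
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("<physical_constants>\n")
  cat(sprintf("  kB = %.6e J/K,  h = %.8e J s\n", x$boltzmann_constant, x$planck_constant))
  cat(sprintf("  R  = %.9f kcal/(mol K),  N_A = %.8e 1/mol\n", x$gas_constant, x$avogadro_number))
  cat(sprintf("  T  = %.2f K  (RT = %.6f kcal/mol, kBT/h = %.4e 1/s)\n",
              x$default_temperature,
              x$gas_constant * x$default_temperature,
              x$boltzmann_constant * x$default_temperature / x$planck_constant))
  invisible(x)
}

# RT in kcal/mol at a given temperature
rt_kcal <- function(temperature = 298.15) {
  physical_constants()$gas_constant * temperature
}

# Eyring prefactor kB*T/h in s^-1
eyring_prefactor <- function(temperature = 298.15) {
  pc <- physical_constants()
  pc$boltzmann_constant * temperature / pc$planck_constant
}

assert_scalar_finite <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0 (got %g)", name, x), call. = FALSE)
  }
  invisible(x)
}
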