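#' Conventional transition-state-theory rate constant
#'
#' Eyring rate with reaction-path degeneracy and tunneling correction:
#' \deqn{k = \sigma \kappa \frac{k_B T}{h} e^{-\Delta G^\ddagger / RT}}
#' The prefactor is in s^-1; for the bimolecular channels handled here the
#' result is interpreted in M^-1 s^-1 with the standard-state 1 M activation
#' free energy, as customary in solution-phase kinetics post-processing.
#'
#' @param activation_free_energy Gibbs free energy of activation, kcal/mol.
#' @param tunneling Tunneling correction kappa (dimensionless, > 0).
#' @param symmetry_number Reaction-path degeneracy sigma (integer >= 1).
#' @param temperature Temperature in K.
#'
#' @return Rate constant (M^-1 s^-1 for bimolecular standard states).
#' @examples
#' tst_rate(0)                      # ~6.21e12: bare kB*T/h
#' tst_rate(21.4, tunneling = 66.9) # ~8.6e-2: a slow hydrogen abstraction
#' @export
tst_rate <- function(activation_free_energy, tunneling = 1,
                     symmetry_number = 1L, temperature = 298.15) {
  assert_scalar_finite(activation_free_energy, "activation_free_energy")
  assert_scalar_finite(tunneling, "tunneling", positive = TRUE)
  assert_scalar_finite(temperature, "temperature", positive = TRUE)
  if (!is.numeric(symmetry_number) || length(symmetry_number) != 1L ||
      symmetry_number < 1 || symmetry_number != round(symmetry_number)) {
    stop("`symmetry_number` must be an integer >= 1", call. = FALSE)
  }
  symmetry_number * tunneling * eyring_prefactor(temperature) *
    exp(-activation_free_energy / rt_kcal(temperature))
}

#' Invert the TST expression for the activation free energy
#'
#' Given a rate constant, recover the Gibbs activation free energy under the
#' same sigma/kappa/temperature. Exact inverse of [tst_rate()].
#'
#' @inheritParams tst_rate
#' @param rate Rate constant (same units as [tst_rate()] output).
#' @return Activation free energy in kcal/mol.
#' @export
tst_barrier_from_rate <- function(rate, tunneling = 1, symmetry_number = 1L,
                                  temperature = 298.15) {
  assert_scalar_finite(rate, "rate", positive = TRUE)
  -rt_kcal(temperature) *
    log(rate / (symmetry_number * tunneling * eyring_prefactor(temperature)))
}

# Transmission probability through the asymmetric Eckart barrier,
# Johnston-Heicklen dimensionless form. v1, v2, e in kcal/mol; nu_kcal = h*nu
# in kcal/mol. Evaluated stably for large arguments via scaled exponentials.
eckart_transmission <- function(e, v1, v2, nu_kcal) {
  a1 <- 2 * pi * v1 / nu_kcal
  a2 <- 2 * pi * v2 / nu_kcal
  inv <- 1 / sqrt(a1) + 1 / sqrt(a2)
  xi <- e / v1
  b2 <- (xi - 1) * a1 + a2
  p <- numeric(length(e))
  open <- b2 >= 0 & e > 0            # channel closed below the product asymptote
  if (!any(open)) return(p)
  a <- 2 * sqrt(a1 * xi[open]) / inv
  b <- 2 * sqrt(b2[open]) / inv
  d2 <- a1 * a2 - pi^2 / 4
  apb <- a + b
  amb <- abs(a - b)
  if (d2 >= 0) {
    d <- 2 * sqrt(d2)
    # P = (cosh(a+b) - cosh(a-b)) / (cosh(a+b) + cosh(d)); scale by exp(-(a+b))
    big <- apb > 350 | d > 350
    pv <- numeric(length(apb))
    if (any(big)) {
      num <- 1 + exp(-2 * apb[big]) - exp(amb[big] - apb[big]) - exp(-amb[big] - apb[big])
      den <- 1 + exp(-2 * apb[big]) + exp(d - apb[big]) + exp(-d - apb[big])
      pv[big] <- num / den
    }
    if (any(!big)) {
      pv[!big] <- (cosh(apb[!big]) - cosh(amb[!big])) /
        (cosh(apb[!big]) + cosh(d))
    }
  } else {
    # shallow/thin barrier: cosh(d) -> cos(|d|), bounded
    dd <- cos(2 * sqrt(-d2))
    big <- apb > 350
    pv <- numeric(length(apb))
    if (any(big)) {
      num <- 1 + exp(-2 * apb[big]) - exp(amb[big] - apb[big]) - exp(-amb[big] - apb[big])
      den <- 1 + exp(-2 * apb[big]) + 2 * dd * exp(-apb[big])
      pv[big] <- num / den
    }
    if (any(!big)) {
      pv[!big] <- (cosh(apb[!big]) - cosh(amb[!big])) / (cosh(apb[!big]) + dd)
    }
  }
  p[open] <- pmin(pmax(pv, 0), 1)
  p
}

#' Eckart tunneling correction
#'
#' Thermally averaged transmission through the one-dimensional asymmetric
#' Eckart barrier:
#' \deqn{\kappa = \frac{e^{V_1/k_BT}}{k_B T}\int_0^\infty P(E)\, e^{-E/k_BT}\, dE}
#' with the analytic transmission probability \eqn{P(E)} parameterized by the
#' forward barrier V1, the reverse barrier V2 and the imaginary frequency.
#' kappa -> 1 as the imaginary frequency -> 0 (classical limit) and grows with
#' barrier height, frequency, and inverse temperature.
#'
#' @param params An [eckart_parameters()] object.
#' @param temperature Temperature in K.
#' @param rel_tol Relative tolerance of the adaptive quadrature.
#'
#' @return Dimensionless tunneling correction kappa (>= ~1 for real barriers).
#' @examples
#' eckart_kappa(eckart_parameters(5, 5, 1500))   # ~8.2 at 298.15 K
#' eckart_kappa(eckart_parameters(5, 5, 1))      # ~1: classical limit
#' @export
eckart_kappa <- function(params, temperature = 298.15, rel_tol = 1e-8) {
  stopifnot(inherits(params, "eckart_parameters"))
  assert_scalar_finite(temperature, "temperature", positive = TRUE)
  v1 <- params$forward_barrier
  v2 <- params$reverse_barrier
  nu_kcal <- params$imaginary_frequency * physical_constants()$cm1_to_kcal
  kt <- rt_kcal(temperature)
  upper <- v1 + 40 * kt
  # integrand of kappa in units of E/kT measured from the reactant zero;
  # exp((v1 - e)/kt) stays finite for the barrier range handled here
  f <- function(e) {
    eckart_transmission(e, v1, v2, nu_kcal) * exp((v1 - e) / kt)
  }
  q <- tryCatch(
    stats::integrate(f, lower = 0, upper = upper, rel.tol = rel_tol,
                     subdivisions = 400L),
    error = function(e) {
      stop(sprintf(
        "Eckart quadrature failed (V1 = %g, V2 = %g, nu = %g cm^-1, T = %g K): %s",
        v1, v2, params$imaginary_frequency, temperature, conditionMessage(e)),
        call. = FALSE)
    }
  )
  if (q$message != "OK") {
    stop(sprintf("Eckart quadrature did not converge: %s", q$message), call. = FALSE)
  }
  q$value / kt
}

#' Marcus activation free energy for electron transfer
#'
#' \deqn{\Delta G^\ddagger = \frac{\lambda}{4}\left(1 + \frac{\Delta G^0}{\lambda}\right)^2}
#' A parabola in the reaction free energy with vertex at (-lambda, 0): the
#' barrier vanishes when the driving force matches the reorganization energy
#' and rises again for more negative driving force (inverted region).
#'
#' @param input A [marcus_input()] with `reaction_free_energy` set, or a
#'   reorganization energy (kcal/mol) if `reaction_free_energy` is supplied.
#' @param reaction_free_energy Reaction free energy in kcal/mol (used when
#'   `input` is a bare number).
#'
#' @return Activation free energy in kcal/mol.
#' @examples
#' marcus_barrier(marcus_input(31.7, -14.9))  # 2.23
#' marcus_barrier(22.8, -27.4)                # 0.23 (inverted region)
#' @export
marcus_barrier <- function(input, reaction_free_energy = NULL) {
  if (inherits(input, "marcus_input")) {
    lambda <- input$reorganization_energy
    dg0 <- input$reaction_free_energy
    if (is.null(dg0)) {
      stop("marcus input carries no reaction_free_energy; barrier undefined",
           call. = FALSE)
    }
  } else {
    lambda <- input
    dg0 <- reaction_free_energy
    assert_scalar_finite(lambda, "reorganization_energy", positive = TRUE)
    assert_scalar_finite(dg0, "reaction_free_energy")
  }
  (lambda / 4) * (1 + dg0 / lambda)^2
}

#' Reorganization energy from the vertical energy gap
#'
#' Estimates the Marcus reorganization energy from the nonadiabatic vertical
#' energy difference and the reaction free energy. Two sign conventions are in
#' circulation; both are offered:
#' `"plus"` gives lambda = dE + dG0, `"minus"` gives lambda = dE - dG0.
#'
#' @param vertical_energy_gap Nonadiabatic reactant-to-vertical-product energy
#'   difference in kcal/mol.
#' @param reaction_free_energy Reaction free energy in kcal/mol.
#' @param sign_convention `"plus"` (default) or `"minus"`.
#'
#' @return Reorganization energy lambda in kcal/mol (> 0, else an error
#'   advising the other convention).
#' @export
marcus_lambda <- function(vertical_energy_gap, reaction_free_energy,
                          sign_convention = c("plus", "minus")) {
  sign_convention <- match.arg(sign_convention)
  assert_scalar_finite(vertical_energy_gap, "vertical_energy_gap")
  assert_scalar_finite(reaction_free_energy, "reaction_free_energy")
  lambda <- if (sign_convention == "plus") {
    vertical_energy_gap + reaction_free_energy
  } else {
    vertical_energy_gap - reaction_free_energy
  }
  if (lambda <= 0) {
    stop(sprintf(
      "non-positive reorganization energy (%g kcal/mol) under the '%s' convention; try the other one",
      lambda, sign_convention), call. = FALSE)
  }
  lambda
}

#' Smoluchowski diffusion-limited rate constant
#'
#' Steady-state Smoluchowski rate for an irreversible bimolecular encounter,
#' with Stokes-Einstein diffusion coefficients:
#' \deqn{k_D = 4\pi R_{AB} D_{AB} N_A, \quad D_i = \frac{k_B T}{6\pi\eta r_i}}
#' where \eqn{R_{AB} = r_A + r_B} and \eqn{D_{AB} = D_A + D_B}.
#'
#' @param radius_a,radius_b Hydrodynamic radii of the two reactants, angstrom.
#' @param viscosity Solvent dynamic viscosity in Pa s.
#' @param temperature Temperature in K.
#'
#' @return Diffusion rate constant in M^-1 s^-1.
#' @examples
#' smoluchowski_kd(2, 2, 8.91e-4)  # ~7.4e9 in water at 298.15 K
#' @export
smoluchowski_kd <- function(radius_a, radius_b, viscosity = 8.91e-4,
                            temperature = 298.15) {
  assert_scalar_finite(radius_a, "radius_a", positive = TRUE)
  assert_scalar_finite(radius_b, "radius_b", positive = TRUE)
  assert_scalar_finite(viscosity, "viscosity", positive = TRUE)
  assert_scalar_finite(temperature, "temperature", positive = TRUE)
  pc <- physical_constants()
  ra <- radius_a * 1e-10
  rb <- radius_b * 1e-10
  d_ab <- pc$boltzmann_constant * temperature / (6 * pi * viscosity) *
    (1 / ra + 1 / rb)
  # m^3 / (molecule s) -> L / (mol s)
  4 * pi * (ra + rb) * d_ab * pc$avogadro_number * 1000
}

#' Collins-Kimball diffusion correction
#'
#' Interpolates between activation control and diffusion control:
#' \deqn{k_{app} = \frac{k_D\, k_{act}}{k_D + k_{act}}}
#' The apparent rate never exceeds either input rate.
#'
#' @param thermal_rate Activation-controlled (TST) rate, M^-1 s^-1, >= 0.
#' @param diffusion_rate Diffusion-limited rate k_D, M^-1 s^-1, >= 0.
#'
#' @return Apparent rate constant k_app in M^-1 s^-1 (0 if both rates are 0).
#' @examples
#' collins_kimball(1e3, 1e9)    # ~1e3: activation-limited
#' collins_kimball(2e9, 2e9)    # 1e9
#' @export
collins_kimball <- function(thermal_rate, diffusion_rate) {
  stopifnot(is.numeric(thermal_rate), is.numeric(diffusion_rate),
            all(thermal_rate >= 0), all(diffusion_rate >= 0))
  out <- ifelse(thermal_rate + diffusion_rate == 0, 0,
                diffusion_rate * thermal_rate / (diffusion_rate + thermal_rate))
  # guard against overflow when one rate is Inf
  out[is.nan(out)] <- pmin(thermal_rate, diffusion_rate)[is.nan(out)]
  out
}
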