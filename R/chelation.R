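#' Formation (equilibrium) constant from a complexation free energy
#'
#' \deqn{K_f = e^{-\Delta G / RT}}
#'
#' @param delta_g Gibbs free energy of complexation in kcal/mol.
#' @param temperature Temperature in K.
#' @return Dimensionless equilibrium constant.
#' @examples
#' formation_constant(-9.2)    # ~5.5e6
#' formation_constant(-12.3)   # ~1.0e9
#' @export
formation_constant <- function(delta_g, temperature = 298.15) {
  assert_scalar_finite(delta_g, "delta_g")
  assert_scalar_finite(temperature, "temperature", positive = TRUE)
  exp(-delta_g / rt_kcal(temperature))
}

#' Apparent (speciation-corrected) equilibrium constant
#'
#' Each ligand protonation state contributes its formation constant weighted
#' by its mole fraction under the working conditions, K^II = K_f * f; the
#' apparent constant is the sum over states:
#' \deqn{K^{app} = \sum_i K_{f,i}\, f_i}
#'
#' @param k_f Numeric vector of formation constants per ligand state.
#' @param fractions Numeric vector of mole fractions (same length, each in
#'   `[0, 1]`).
#' @return The apparent equilibrium constant (0 for empty input).
#' @export
apparent_constant <- function(k_f, fractions) {
  stopifnot(is.numeric(k_f), is.numeric(fractions),
            length(k_f) == length(fractions))
  if (length(k_f) == 0L) return(0)
  if (any(fractions < 0 | fractions > 1)) {
    stop("mole fractions must lie in [0, 1]", call. = FALSE)
  }
  sum(k_f * fractions)
}

#' Metal-ligand complexation result
#'
#' Convenience wrapper computing, for one metal-ligand pair, the formation
#' constant, the speciation-corrected K^II per state and the apparent
#' constant.
#'
#' @param delta_g Numeric vector of complexation free energies (kcal/mol), one
#'   per chelation-active ligand state.
#' @param fractions Mole fractions of those states.
#' @param labels Optional state labels.
#' @param temperature Temperature in K.
#' @return A list of class `complexation_result` with `formation_constant`,
#'   `corrected_constant` (K^II per state) and `apparent_constant`.
#' @export
complexation_result <- function(delta_g, fractions, labels = NULL,
                                temperature = 298.15) {
  stopifnot(length(delta_g) == length(fractions))
  kf <- vapply(delta_g, formation_constant, 0.0, temperature = temperature)
  kii <- kf * fractions
  structure(
    list(labels = labels, formation_constant = kf, corrected_constant = kii,
         apparent_constant = apparent_constant(kf, fractions)),
    class = "complexation_result"
  )
}

#' @export
print.complexation_result <- function(x, ...) {
  cat("<complexation_result>\n")
  for (i in seq_along(x$formation_constant)) {
    lab <- if (is.null(x$labels)) sprintf("state %d", i) else x$labels[i]
    cat(sprintf("  %-12s K_f = %.3e   K^II = %.3e\n", lab,
                x$formation_constant[i], x$corrected_constant[i]))
  }
  cat(sprintf("  K^app = %.3e\n", x$apparent_constant))
  invisible(x)
}

#' Pro-oxidant electron-transfer rate of a metal complex
#'
#' Kinetics of the single-electron transfer between a metal complex and a
#' physiological reductant (ascorbate, superoxide): the activation free energy
#' comes from Marcus theory, the thermal rate from TST (kappa = 1, sigma = 1),
#' and the apparent rate from the Collins-Kimball interpolation against the
#' supplied aqueous diffusion limit.
#'
#' @param marcus A [marcus_input()] with reorganization energy and reaction
#'   free energy set, or a numeric reorganization energy (then supply
#'   `reaction_free_energy`).
#' @param diffusion_rate Diffusion-limited rate constant for the pair,
#'   M^-1 s^-1.
#' @param reaction_free_energy Reaction free energy in kcal/mol (when `marcus`
#'   is a bare number).
#' @param temperature Temperature in K.
#'
#' @return A list of class `rate_evaluation`: `barrier_used` (kcal/mol),
#'   `thermal_rate`, `diffusion_rate`, `apparent_rate` (M^-1 s^-1),
#'   `tunneling_used` (always 1 here).
#' @examples
#' prooxidant_rate(marcus_input(31.7, -14.9), diffusion_rate = 3.85e9)
#' @export
prooxidant_rate <- function(marcus, diffusion_rate,
                            reaction_free_energy = NULL,
                            temperature = 298.15) {
  assert_scalar_finite(diffusion_rate, "diffusion_rate", positive = TRUE)
  barrier <- marcus_barrier(marcus, reaction_free_energy)
  thermal <- tst_rate(barrier, tunneling = 1, symmetry_number = 1L,
                      temperature = temperature)
  structure(
    list(barrier_used = barrier, tunneling_used = 1,
         thermal_rate = thermal, diffusion_rate = diffusion_rate,
         apparent_rate = collins_kimball(thermal, diffusion_rate)),
    class = "rate_evaluation"
  )
}

#' @export
print.rate_evaluation <- function(x, ...) {
  cat("<rate_evaluation>\n")
  cat(sprintf("  dG_act = %.3f kcal/mol, kappa = %.3g\n",
              x$barrier_used, x$tunneling_used))
  cat(sprintf("  k = %.3e, k_D = %.3e, k_app = %.3e M^-1 s^-1\n",
              x$thermal_rate, x$diffusion_rate, x$apparent_rate))
  invisible(x)
}

#' Rate table for a set of complex-reductant redox steps
#'
#' Mirrors the usual presentation of pro-oxidant kinetics: one row per
#' (complex, reductant) pair with reorganization energy, reaction free energy,
#' Marcus activation energy, thermal and apparent rate constants.
#'
#' @param steps A data frame (or tibble) with columns `complex`, `reductant`,
#'   `lambda`, `delta_g`, `k_D` (per-pair diffusion limit, M^-1 s^-1).
#' @param temperature Temperature in K.
#' @return A tibble adding `delta_g_act`, `k`, `k_app`.
#' @export
prooxidant_table <- function(steps, temperature = 298.15) {
  stopifnot(is.data.frame(steps),
            all(c("complex", "reductant", "lambda", "delta_g", "k_D") %in% names(steps)))
  out <- tibble::as_tibble(steps)
  ev <- lapply(seq_len(nrow(out)), function(i) {
    prooxidant_rate(marcus_input(out$lambda[i], out$delta_g[i]),
                    diffusion_rate = out$k_D[i], temperature = temperature)
  })
  out$delta_g_act <- vapply(ev, `[[`, 0.0, "barrier_used")
  out$k <- vapply(ev, `[[`, 0.0, "thermal_rate")
  out$k_app <- vapply(ev, `[[`, 0.0, "apparent_rate")
  out
}
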