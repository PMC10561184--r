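#' pKa from the free energy of the proton-exchange reaction
#'
#' Converts the solution Gibbs free energy of the hydroxide-assisted
#' proton-exchange reaction (AH + OH- -> A- + H2O, with explicit water
#' co-reactants) into a macroscopic pKa:
#' \deqn{pK_a = \frac{\Delta G_{sol}}{RT \ln 10} + C}
#' where C is the reference constant of the thermodynamic cycle (default 14,
#' the water autoionization reference appropriate for the hydroxide-exchange
#' scheme).
#'
#' @param delta_g_sol Gibbs free energy of the exchange reaction in solution,
#'   kcal/mol.
#' @param temperature Temperature in K.
#' @param reference_constant Additive reference constant of the cycle.
#'
#' @return A dimensionless pKa. The relation is exactly invertible:
#'   `delta_g_sol = (pKa - C) * RT * log(10)`.
#' @examples
#' pka_from_energy(0)                      # 14
#' pka_from_energy(-5.593, 298.15, 14)     # ~9.9
#' @export
pka_from_energy <- function(delta_g_sol, temperature = 298.15,
                            reference_constant = 14) {
  assert_scalar_finite(delta_g_sol, "delta_g_sol")
  assert_scalar_finite(temperature, "temperature", positive = TRUE)
  assert_scalar_finite(reference_constant, "reference_constant")
  delta_g_sol / (rt_kcal(temperature) * log(10)) + reference_constant
}

#' Free energy implied by a pKa (inverse of [pka_from_energy()])
#'
#' @inheritParams pka_from_energy
#' @param pka Target pKa.
#' @return Gibbs free energy of the exchange reaction in kcal/mol.
#' @export
energy_from_pka <- function(pka, temperature = 298.15, reference_constant = 14) {
  assert_scalar_finite(pka, "pka")
  (pka - reference_constant) * rt_kcal(temperature) * log(10)
}

#' Acid-base mole fractions at a given pH
#'
#' Equilibrium populations of the protonation states of a (poly)protic acid
#' at a given pH, most-protonated state first. State j (j = 0 is the fully
#' protonated form) has relative weight
#' \deqn{w_j = 10^{\sum_{i \le j} (pH - pK_{a,i})}}
#' and the fractions are the normalized weights. Computed in log10 space with
#' the maximum subtracted, so extreme pH values do not overflow.
#'
#' @param acid_base An [acid_base_system()], or a numeric vector of ascending
#'   pKa values.
#' @param ph The pH.
#'
#' @return Named numeric vector of mole fractions summing to 1 (names are the
#'   state labels if available).
#' @examples
#' mole_fractions(9.9, ph = 7.4)            # 0.9968 / 0.0032
#' mole_fractions(c(4.4, 10.3), ph = 7.4)   # 0.0010 / 0.9977 / 0.0013
#' @export
mole_fractions <- function(acid_base, ph) {
  if (inherits(acid_base, "acid_base_system")) {
    pka <- acid_base$pka_values
    labels <- acid_base$state_labels
  } else {
    stopifnot(is.numeric(acid_base))
    pka <- as.numeric(acid_base)
    if (length(pka) > 1L && any(diff(pka) <= 0)) {
      stop("pKa values must be strictly ascending", call. = FALSE)
    }
    labels <- NULL
  }
  assert_scalar_finite(ph, "ph")
  if (length(pka) == 0L) {
    out <- 1
    names(out) <- labels
    return(out)
  }
  log_w <- c(0, cumsum(ph - pka))
  log_w <- log_w - max(log_w)
  w <- 10^log_w
  out <- w / sum(w)
  if (!is.null(labels)) names(out) <- labels
  out
}

#' Speciation summary table
#'
#' Mole fractions of every protonation state at a given pH, with percentages
#' rounded half-up to two decimals (the convention used when quoting
#' physiological populations).
#'
#' @inheritParams mole_fractions
#' @return A tibble with columns `state`, `charge_index` (0 = fully
#'   protonated), `mole_fraction`, `percent`.
#' @export
speciate <- function(acid_base, ph = 7.4) {
  f <- mole_fractions(acid_base, ph)
  labels <- names(f) %||% paste0("state", seq_along(f) - 1L)
  tibble::tibble(
    state = labels,
    charge_index = seq_along(f) - 1L,
    mole_fraction = as.numeric(f),
    percent = round_half_up(100 * as.numeric(f), 2)
  )
}

# round half away from zero (the convention of the quoted percentages),
# unlike base round()'s round-half-even
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
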