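#' Reaction medium
#'
#' A solvent environment a scavenging reaction takes place in. Aqueous media
#' carry a pH (speciation applies); lipid media do not (the phenol cannot
#' dissociate, so only the neutral form is present). The viscosity feeds the
#' Stokes-Einstein diffusion coefficients behind the Smoluchowski diffusion
#' rate; a per-radical diffusion-limit override can be supplied where the
#' diffusion rate is known directly (e.g. channels reported at the diffusion
#' limit whose underlying radii are not available).
#'
#' @param name Medium label, e.g. `"water"` or `"pentyl ethanoate"`.
#' @param is_aqueous Logical flag; `TRUE` iff `ph` is given.
#' @param ph pH of the medium (aqueous only), or `NULL`.
#' @param viscosity Dynamic viscosity in Pa s.
#' @param diffusion_limit_override Optional named numeric vector of diffusion
#'   rate constants (M^-1 s^-1), named by radical label, or a single unnamed
#'   value applied to every radical.
#'
#' @return An object of class `medium`.
#' @examples
#' medium("water", is_aqueous = TRUE, ph = 7.4)
#' medium("pentyl ethanoate", is_aqueous = FALSE, viscosity = 8.62e-4)
#' @export
medium <- function(name, is_aqueous, ph = NULL, viscosity = 8.91e-4,
                   diffusion_limit_override = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.logical(is_aqueous), length(is_aqueous) == 1L)
  if (is_aqueous && is.null(ph)) {
    stop("aqueous medium requires `ph`", call. = FALSE)
  }
  if (!is_aqueous && !is.null(ph)) {
    stop("non-aqueous medium must not carry `ph`", call. = FALSE)
  }
  if (!is.null(ph)) assert_scalar_finite(ph, "ph")
  assert_scalar_finite(viscosity, "viscosity", positive = TRUE)
  if (!is.null(diffusion_limit_override)) {
    stopifnot(is.numeric(diffusion_limit_override), all(diffusion_limit_override > 0))
  }
  structure(
    list(name = name, is_aqueous = is_aqueous, ph = ph, viscosity = viscosity,
         diffusion_limit_override = diffusion_limit_override),
    class = "medium"
  )
}

#' Acid-base (protonation-state) state of a compound
#'
#' @param label State label, e.g. `"neutral"`, `"monoanion"`, `"dianion"`.
#' @param charge Integer formal charge of the state.
#' @param mole_fraction Equilibrium population of the state at the working pH,
#'   in `[0, 1]`, or `NULL` if it is to be computed from the pKa set.
#'
#' @return An object of class `species_state`.
#' @export
species_state <- function(label, charge = 0L, mole_fraction = NULL) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  stopifnot(is.numeric(charge), length(charge) == 1L, charge == round(charge))
  if (!is.null(mole_fraction)) {
    assert_scalar_finite(mole_fraction, "mole_fraction")
    if (mole_fraction < 0 || mole_fraction > 1) {
      stop("`mole_fraction` must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(
    list(label = label, charge = as.integer(charge), mole_fraction = mole_fraction),
    class = "species_state"
  )
}

#' Macroscopic acid-base system
#'
#' Ordered pKa ladder of a (possibly polyprotic) acid together with the labels
#' of its protonation states, most-protonated first. A system with `n` pKa
#' values has `n + 1` states.
#'
#' @param pka_values Numeric vector of macroscopic pKa values, strictly
#'   ascending. May be empty (no dissociation).
#' @param state_labels Character vector of length `length(pka_values) + 1`.
#'
#' @return An object of class `acid_base_system`.
#' @examples
#' acid_base_system(9.9, c("Oli", "Oli-"))
#' acid_base_system(c(4.4, 10.3), c("OliA", "OliA-", "OliA-2"))
#' @export
acid_base_system <- function(pka_values, state_labels) {
  stopifnot(is.numeric(pka_values) || length(pka_values) == 0L)
  pka_values <- as.numeric(pka_values)
  if (anyNA(pka_values) || any(!is.finite(pka_values))) {
    stop("`pka_values` must be finite", call. = FALSE)
  }
  if (length(pka_values) > 1L && any(diff(pka_values) <= 0)) {
    stop("`pka_values` must be strictly ascending", call. = FALSE)
  }
  stopifnot(is.character(state_labels))
  if (length(state_labels) != length(pka_values) + 1L) {
    stop(sprintf("need %d state labels for %d pKa values (got %d)",
                 length(pka_values) + 1L, length(pka_values), length(state_labels)),
         call. = FALSE)
  }
  structure(
    list(pka_values = pka_values, state_labels = state_labels),
    class = "acid_base_system"
  )
}

#' Eckart barrier parameters
#'
#' Parameters of the one-dimensional asymmetric Eckart potential used for the
#' tunneling correction: zero-point-corrected forward and reverse barrier
#' heights and the magnitude of the imaginary frequency at the saddle point.
#'
#' @param forward_barrier Forward barrier V1 in kcal/mol (> 0).
#' @param reverse_barrier Reverse barrier V2 in kcal/mol (> 0).
#' @param imaginary_frequency Magnitude of the imaginary frequency in cm^-1 (> 0).
#'
#' @return An object of class `eckart_parameters`.
#' @export
eckart_parameters <- function(forward_barrier, reverse_barrier, imaginary_frequency) {
  assert_scalar_finite(forward_barrier, "forward_barrier", positive = TRUE)
  assert_scalar_finite(reverse_barrier, "reverse_barrier", positive = TRUE)
  assert_scalar_finite(imaginary_frequency, "imaginary_frequency", positive = TRUE)
  structure(
    list(forward_barrier = forward_barrier, reverse_barrier = reverse_barrier,
         imaginary_frequency = imaginary_frequency),
    class = "eckart_parameters"
  )
}

#' Marcus-theory input for a single electron transfer
#'
#' @param reorganization_energy Nuclear reorganization energy lambda in
#'   kcal/mol (> 0).
#' @param reaction_free_energy Gibbs free energy of the electron transfer in
#'   kcal/mol, or `NULL` when only lambda is known (the barrier then cannot be
#'   evaluated and a fixed rate must accompany the channel).
#' @param vertical_energy_gap Optional nonadiabatic reactant-to-vertical-product
#'   energy difference in kcal/mol (used to estimate lambda).
#'
#' @return An object of class `marcus_input`.
#' @export
marcus_input <- function(reorganization_energy, reaction_free_energy = NULL,
                         vertical_energy_gap = NULL) {
  assert_scalar_finite(reorganization_energy, "reorganization_energy", positive = TRUE)
  if (!is.null(reaction_free_energy)) {
    assert_scalar_finite(reaction_free_energy, "reaction_free_energy")
  }
  if (!is.null(vertical_energy_gap)) {
    assert_scalar_finite(vertical_energy_gap, "vertical_energy_gap")
  }
  structure(
    list(reorganization_energy = reorganization_energy,
         reaction_free_energy = reaction_free_energy,
         vertical_energy_gap = vertical_energy_gap),
    class = "marcus_input"
  )
}

MECHANISMS <- c("FHT", "RAF", "SET")

#' One reaction channel of an antioxidant
#'
#' A single (mechanism, site, radical, medium, protonation state) combination
#' with whatever kinetic parameterization is available: a TST activation free
#' energy with a tunneling correction (scalar kappa or Eckart parameters), a
#' Marcus input (SET), a flag that the channel proceeds at the diffusion limit,
#' or a directly supplied rate constant.
#'
#' @param mechanism `"FHT"`, `"RAF"` or `"SET"`.
#' @param site Reactive site label (e.g. `"1OH"`, `"7CH"`, `"C1-C6"`).
#' @param radical Radical label (e.g. `"HO"`, `"HOO"`, `"Asc"`, `"O2"`).
#' @param medium Medium name (character) matching one of the profile's media.
#' @param species_state State label matching the profile's acid-base states.
#' @param symmetry_number Reaction-path degeneracy sigma (integer >= 1).
#' @param activation_free_energy TST Gibbs activation free energy in kcal/mol,
#'   or `NULL`.
#' @param tunneling Tunneling correction: a positive scalar kappa, an
#'   [eckart_parameters()] object, or `NULL` (kappa = 1).
#' @param marcus A [marcus_input()] object (SET channels), or `NULL`.
#' @param reaction_free_energy Gibbs free energy of reaction in kcal/mol
#'   (used by the exergonicity screen), or `NULL`.
#' @param barrierless `TRUE` for channels that proceed at the diffusion limit.
#' @param fixed_rate Directly supplied rate constant in M^-1 s^-1, or `NULL`.
#'
#' @return An object of class `reaction_channel`.
#' @export
reaction_channel <- function(mechanism, site, radical, medium, species_state,
                             symmetry_number = 1L,
                             activation_free_energy = NULL,
                             tunneling = NULL,
                             marcus = NULL,
                             reaction_free_energy = NULL,
                             barrierless = FALSE,
                             fixed_rate = NULL) {
  mechanism <- match.arg(mechanism, MECHANISMS)
  stopifnot(is.character(site), length(site) == 1L)
  stopifnot(is.character(radical), length(radical) == 1L)
  stopifnot(is.character(medium), length(medium) == 1L)
  stopifnot(is.character(species_state), length(species_state) == 1L)
  stopifnot(is.numeric(symmetry_number), length(symmetry_number) == 1L)
  if (symmetry_number < 1 || symmetry_number != round(symmetry_number)) {
    stop("`symmetry_number` must be an integer >= 1", call. = FALSE)
  }
  if (!is.null(activation_free_energy)) {
    assert_scalar_finite(activation_free_energy, "activation_free_energy")
  }
  if (!is.null(tunneling) && !inherits(tunneling, "eckart_parameters")) {
    assert_scalar_finite(tunneling, "tunneling")
    if (tunneling < 0) stop("scalar `tunneling` must be >= 0", call. = FALSE)
  }
  if (!is.null(marcus) && !inherits(marcus, "marcus_input")) {
    stop("`marcus` must be a marcus_input object", call. = FALSE)
  }
  if (!is.null(reaction_free_energy)) {
    assert_scalar_finite(reaction_free_energy, "reaction_free_energy")
  }
  stopifnot(is.logical(barrierless), length(barrierless) == 1L)
  if (!is.null(fixed_rate)) assert_scalar_finite(fixed_rate, "fixed_rate", positive = TRUE)

  ch <- structure(
    list(mechanism = mechanism, site = site, radical = radical,
         medium = medium, species_state = species_state,
         symmetry_number = as.integer(symmetry_number),
         activation_free_energy = activation_free_energy,
         tunneling = tunneling, marcus = marcus,
         reaction_free_energy = reaction_free_energy,
         barrierless = barrierless, fixed_rate = fixed_rate),
    class = "reaction_channel"
  )
  validate_channel(ch)
  ch
}

validate_channel <- function(ch) {
  id <- channel_id(ch)
  if (ch$mechanism == "SET") {
    has_marcus_barrier <- !is.null(ch$marcus) && !is.null(ch$marcus$reaction_free_energy)
    if (!has_marcus_barrier && is.null(ch$fixed_rate) && !isTRUE(ch$barrierless)) {
      stop(sprintf(
        "channel %s: SET channels need a marcus input (with reaction free energy) or a fixed_rate",
        id), call. = FALSE)
    }
  } else {
    if (is.null(ch$activation_free_energy) && !isTRUE(ch$barrierless) &&
        is.null(ch$fixed_rate)) {
      stop(sprintf(
        "channel %s: %s channels need an activation_free_energy, barrierless = TRUE, or a fixed_rate",
        id, ch$mechanism), call. = FALSE)
    }
  }
  invisible(ch)
}

channel_id <- function(ch) {
  paste(ch$mechanism, ch$site, ch$species_state, ch$radical, ch$medium, sep = "/")
}

#' Thermochemistry record for one bond/site
#'
#' Gas-phase bookkeeping attached to a profile: the solution free energy of
#' the proton-exchange reaction behind a pKa, and the enthalpies behind a bond
#' dissociation enthalpy (BDE = H(radical) + H(H atom) - H(parent)).
#'
#' @param label Record label (e.g. a bond or site name).
#' @param solution_free_energy Gibbs free energy of the proton-exchange
#'   reaction in solution, kcal/mol, or `NULL`.
#' @param enthalpy_parent,enthalpy_radical,enthalpy_h_atom Enthalpies in
#'   kcal/mol; all three or none.
#'
#' @return An object of class `thermo_record` whose `bde` element is derived
#'   exactly from the three enthalpies when present.
#' @export
thermo_record <- function(label, solution_free_energy = NULL,
                          enthalpy_parent = NULL, enthalpy_radical = NULL,
                          enthalpy_h_atom = NULL) {
  stopifnot(is.character(label), length(label) == 1L)
  comps <- list(enthalpy_parent, enthalpy_radical, enthalpy_h_atom)
  n_given <- sum(!vapply(comps, is.null, logical(1)))
  if (n_given != 0L && n_given != 3L) {
    stop("supply all three enthalpies or none", call. = FALSE)
  }
  bde <- if (n_given == 3L) enthalpy_radical + enthalpy_h_atom - enthalpy_parent else NULL
  structure(
    list(label = label, solution_free_energy = solution_free_energy,
         enthalpy_parent = enthalpy_parent, enthalpy_radical = enthalpy_radical,
         enthalpy_h_atom = enthalpy_h_atom, bde = bde),
    class = "thermo_record"
  )
}

#' Antioxidant kinetic profile
#'
#' The root input of the pipeline: a compound with its acid-base system, the
#' media it is studied in, and its reaction channels.
#'
#' @param compound Compound label.
#' @param acid_base An [acid_base_system()].
#' @param media List of [medium()] objects (unique names).
#' @param channels List of [reaction_channel()] objects.
#' @param states Optional list of [species_state()] objects carrying supplied
#'   mole fractions per state label. States not listed get computed fractions.
#' @param gas_phase_thermo Optional list of [thermo_record()] objects.
#'
#' @return A validated object of class `antioxidant_profile`.
#' @seealso [read_profile()], [evaluate_profile()]
#' @export
antioxidant_profile <- function(compound, acid_base, media, channels,
                                states = NULL, gas_phase_thermo = NULL) {
  stopifnot(is.character(compound), length(compound) == 1L)
  stopifnot(inherits(acid_base, "acid_base_system"))
  stopifnot(is.list(media), all(vapply(media, inherits, logical(1), "medium")))
  stopifnot(is.list(channels),
            all(vapply(channels, inherits, logical(1), "reaction_channel")))
  if (!is.null(states)) {
    stopifnot(is.list(states),
              all(vapply(states, inherits, logical(1), "species_state")))
  }
  if (!is.null(gas_phase_thermo)) {
    stopifnot(is.list(gas_phase_thermo),
              all(vapply(gas_phase_thermo, inherits, logical(1), "thermo_record")))
  }
  prof <- structure(
    list(compound = compound, acid_base = acid_base, media = media,
         channels = channels, states = states,
         gas_phase_thermo = gas_phase_thermo),
    class = "antioxidant_profile"
  )
  validate_profile(prof)
}

#' Validate an antioxidant profile
#'
#' Enforces the structural invariants: unique medium names, every channel
#' referring to a declared medium and acid-base state, and supplied mole
#' fractions summing to 1 within 1e-9 (per set of states carrying them).
#'
#' @param profile An `antioxidant_profile`.
#' @return The profile, invisibly unchanged, or an error naming the offender.
#' @export
validate_profile <- function(profile) {
  stopifnot(inherits(profile, "antioxidant_profile"))
  med_names <- vapply(profile$media, `[[`, character(1), "name")
  if (anyDuplicated(med_names)) stop("duplicate medium names", call. = FALSE)
  labels <- profile$acid_base$state_labels
  for (ch in profile$channels) {
    if (!ch$medium %in% med_names) {
      stop(sprintf("channel %s: unknown medium '%s'", channel_id(ch), ch$medium),
           call. = FALSE)
    }
    if (!ch$species_state %in% labels) {
      stop(sprintf("channel %s: species state '%s' not among acid-base states (%s)",
                   channel_id(ch), ch$species_state, paste(labels, collapse = ", ")),
           call. = FALSE)
    }
    validate_channel(ch)
  }
  if (!is.null(profile$states) && length(profile$states) > 0L) {
    st_labels <- vapply(profile$states, `[[`, character(1), "label")
    bad <- setdiff(st_labels, labels)
    if (length(bad) > 0L) {
      stop(sprintf("states %s not among acid-base states", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    fr <- vapply(profile$states, function(s) s$mole_fraction %||% NA_real_, 0.0)
    if (!anyNA(fr) && length(fr) == length(labels)) {
      if (abs(sum(fr) - 1) > 1e-9) {
        stop(sprintf("supplied mole fractions sum to %.10f, not 1 (tolerance 1e-9)",
                     sum(fr)), call. = FALSE)
      }
    }
  }
  invisible(profile)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.antioxidant_profile <- function(x, ...) {
  cat(sprintf("<antioxidant_profile> %s\n", x$compound))
  cat(sprintf("  media: %s\n",
              paste(vapply(x$media, `[[`, character(1), "name"), collapse = ", ")))
  cat(sprintf("  acid-base states: %s", paste(x$acid_base$state_labels, collapse = " / ")))
  if (length(x$acid_base$pka_values)) {
    cat(sprintf("  (pKa %s)", paste(format(x$acid_base$pka_values), collapse = ", ")))
  }
  cat("\n")
  cat(sprintf("  channels: %d", length(x$channels)))
  if (length(x$channels)) {
    tab <- table(vapply(x$channels, `[[`, character(1), "mechanism"))
    cat(sprintf("  (%s)", paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' @export
print.reaction_channel <- function(x, ...) {
  cat(sprintf("<reaction_channel> %s\n", channel_id(x)))
  if (!is.null(x$activation_free_energy)) {
    cat(sprintf("  dG_act = %.2f kcal/mol", x$activation_free_energy))
    if (!is.null(x$tunneling) && !inherits(x$tunneling, "eckart_parameters")) {
      cat(sprintf(", kappa = %.3g", x$tunneling))
    }
    cat("\n")
  }
  if (inherits(x$tunneling, "eckart_parameters")) {
    cat(sprintf("  Eckart: V1 = %.2f, V2 = %.2f kcal/mol, nu = %.0f cm^-1\n",
                x$tunneling$forward_barrier, x$tunneling$reverse_barrier,
                x$tunneling$imaginary_frequency))
  }
  if (!is.null(x$marcus)) {
    cat(sprintf("  Marcus: lambda = %.2f kcal/mol%s\n",
                x$marcus$reorganization_energy,
                if (is.null(x$marcus$reaction_free_energy)) ""
                else sprintf(", dG0 = %.2f kcal/mol", x$marcus$reaction_free_energy)))
  }
  if (isTRUE(x$barrierless)) cat("  barrierless (diffusion-limited)\n")
  if (!is.null(x$fixed_rate)) cat(sprintf("  fixed rate = %.3g M^-1 s^-1\n", x$fixed_rate))
  invisible(x)
}
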