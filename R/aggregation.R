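#' Exergonicity screen
#'
#' Keeps only channels whose reaction free energy is strictly negative; only
#' energetically favorable channels enter the kinetic treatment. Channels
#' without a recorded reaction free energy pass through unscreened (their
#' viability was decided upstream). Dropped channels are reported via
#' `message()`.
#'
#' @param channels List of [reaction_channel()] objects.
#' @param quiet Suppress the per-channel drop messages.
#'
#' @return The filtered channel list.
#' @export
screen_exergonic <- function(channels, quiet = FALSE) {
  stopifnot(is.list(channels))
  keep <- vapply(channels, function(ch) {
    dg <- ch$reaction_free_energy
    if (is.null(dg)) return(TRUE)
    ok <- dg < 0
    if (!ok && !quiet) {
      message(sprintf("dropping endergonic channel %s (dG_r = %+.2f kcal/mol)",
                      channel_id(ch), dg))
    }
    ok
  }, logical(1))
  channels[keep]
}

# per-channel apparent rate constant; returns list(thermal, diffusion, apparent,
# kappa_used, barrier_used)
channel_rate <- function(ch, med, temperature = 298.15,
                         default_radii = c(2.0, 2.0)) {
  kd <- diffusion_rate_for(med, ch$radical, temperature, default_radii)
  if (!is.null(ch$fixed_rate)) {
    return(list(thermal = NA_real_, diffusion = kd, apparent = ch$fixed_rate,
                kappa_used = NA_real_, barrier_used = NA_real_))
  }
  if (isTRUE(ch$barrierless)) {
    return(list(thermal = Inf, diffusion = kd, apparent = kd,
                kappa_used = NA_real_, barrier_used = 0))
  }
  if (ch$mechanism == "SET") {
    barrier <- marcus_barrier(ch$marcus)
    kappa <- 1
  } else {
    barrier <- ch$activation_free_energy
    kappa <- if (is.null(ch$tunneling)) {
      1
    } else if (inherits(ch$tunneling, "eckart_parameters")) {
      eckart_kappa(ch$tunneling, temperature)
    } else {
      ch$tunneling
    }
  }
  thermal <- tst_rate(barrier, tunneling = kappa,
                      symmetry_number = ch$symmetry_number,
                      temperature = temperature)
  list(thermal = thermal, diffusion = kd,
       apparent = collins_kimball(thermal, kd),
       kappa_used = kappa, barrier_used = barrier)
}

diffusion_rate_for <- function(med, radical, temperature = 298.15,
                               default_radii = c(2.0, 2.0)) {
  ov <- med$diffusion_limit_override
  if (!is.null(ov)) {
    if (!is.null(names(ov)) && radical %in% names(ov)) return(unname(ov[[radical]]))
    if (is.null(names(ov)) && length(ov) == 1L) return(unname(ov))
    if (!is.null(names(ov)) && "default" %in% names(ov)) return(unname(ov[["default"]]))
  }
  smoluchowski_kd(default_radii[1], default_radii[2], med$viscosity, temperature)
}

#' Weight channel rates by acid-base mole fractions
#'
#' Attaches `k_f = f * k_app` to each channel result. Aqueous channels take
#' the mole fraction of their protonation state (supplied in the profile or
#' computed from the pKa set at the working pH); lipid-medium channels use
#' f = 1, since no dissociation occurs there.
#'
#' @param results A tibble of per-channel results carrying at least `state`,
#'   `medium`, `k_app` columns (as produced inside [evaluate_profile()]).
#' @param fractions Named numeric vector of mole fractions per state label.
#' @param aqueous Named logical vector: is each medium aqueous?
#'
#' @return The tibble with columns `f` and `k_f` filled in.
#' @export
weight_channels <- function(results, fractions, aqueous) {
  stopifnot(is.data.frame(results))
  f <- vapply(seq_len(nrow(results)), function(i) {
    if (!isTRUE(aqueous[[results$medium[i]]])) return(1)
    st <- results$state[i]
    if (!st %in% names(fractions)) {
      stop(sprintf("no mole fraction available for state '%s'", st), call. = FALSE)
    }
    fractions[[st]]
  }, 0.0)
  results$f <- f
  results$k_f <- results$f * results$k_app
  results
}

#' Branching ratios
#'
#' Percentage contribution of each channel to the overall rate constant:
#' `Gamma_i = 100 * k_f_i / sum(k_f)`. Sums to exactly 100 before rounding.
#'
#' @param weighted_rates Numeric vector of mole-fraction-weighted rates k_f.
#' @return Numeric vector of branching ratios in percent.
#' @examples
#' branching_ratios(c(9.6, 9.6, 0.023))
#' @export
branching_ratios <- function(weighted_rates) {
  stopifnot(is.numeric(weighted_rates), all(weighted_rates >= 0))
  total <- sum(weighted_rates)
  if (length(weighted_rates) == 0L) return(numeric(0))
  if (total <= 0) {
    stop("all weighted rates are zero; branching ratios undefined", call. = FALSE)
  }
  100 * weighted_rates / total
}

#' Overall rate constant
#'
#' Sum of the mole-fraction-weighted rate constants of all reaction channels
#' of a compound toward one radical in one medium.
#'
#' @param weighted_rates Numeric vector of k_f values (M^-1 s^-1).
#' @return The overall rate constant (0 for an empty set).
#' @examples
#' overall_rate(c(9.60, 9.60, 2.30e-2))   # 1.92e1
#' @export
overall_rate <- function(weighted_rates) {
  stopifnot(is.numeric(weighted_rates))
  if (length(weighted_rates) == 0L) return(0)
  sum(weighted_rates)
}

#' Evaluate a full antioxidant profile
#'
#' Runs the whole per-compound pipeline: exergonicity screen, per-channel
#' apparent rate constants (fixed rates, diffusion-limited channels, TST with
#' scalar or Eckart tunneling, Marcus/TST for electron transfer, all
#' Collins-Kimball-corrected), speciation at the working pH, mole-fraction
#' weighting, branching ratios and overall rate constants per radical and
#' medium.
#'
#' @param profile An [antioxidant_profile()].
#' @param config A [run_config()] (temperature, pH, ...).
#' @param screen Apply the exergonicity screen before rating channels.
#'
#' @return A tibble with one row per channel: `compound`, `radical`, `medium`,
#'   `mechanism`, `site`, `state`, `barrier`, `kappa`, `k_thermal`, `k_D`,
#'   `k_app`, `f`, `k_f`, `gamma`, `k_overall` (the last two computed within
#'   each compound x radical x medium group).
#' @export
evaluate_profile <- function(profile, config = run_config(), screen = TRUE) {
  validate_profile(profile)
  channels <- profile$channels
  if (screen) channels <- screen_exergonic(channels, quiet = config$log_level == "quiet")
  meds <- stats::setNames(profile$media,
                          vapply(profile$media, `[[`, character(1), "name"))
  aqueous <- vapply(meds, `[[`, logical(1), "is_aqueous")

  if (length(channels) == 0L) {
    return(tibble::tibble(
      compound = character(0), radical = character(0), medium = character(0),
      mechanism = character(0), site = character(0), state = character(0),
      barrier = numeric(0), kappa = numeric(0), k_thermal = numeric(0),
      k_D = numeric(0), k_app = numeric(0), f = numeric(0), k_f = numeric(0),
      gamma = numeric(0), k_overall = numeric(0)))
  }

  rows <- lapply(channels, function(ch) {
    r <- channel_rate(ch, meds[[ch$medium]], config$temperature)
    tibble::tibble(
      compound = profile$compound, radical = ch$radical, medium = ch$medium,
      mechanism = ch$mechanism, site = ch$site, state = ch$species_state,
      barrier = r$barrier_used, kappa = r$kappa_used,
      k_thermal = r$thermal, k_D = r$diffusion, k_app = r$apparent)
  })
  res <- do.call(rbind, rows)

  fractions <- profile_fractions(profile, config$ph)
  res <- weight_channels(res, fractions, aqueous)

  grp <- interaction(res$radical, res$medium, drop = TRUE)
  res$gamma <- NA_real_
  res$k_overall <- NA_real_
  for (g in levels(grp)) {
    idx <- which(grp == g)
    res$gamma[idx] <- branching_ratios(res$k_f[idx])
    res$k_overall[idx] <- overall_rate(res$k_f[idx])
  }
  res
}

# mole fractions per state label: supplied ones win, remainder computed from
# the pKa ladder at the given pH
profile_fractions <- function(profile, ph) {
  labels <- profile$acid_base$state_labels
  computed <- mole_fractions(profile$acid_base, ph)
  names(computed) <- labels
  if (!is.null(profile$states)) {
    for (s in profile$states) {
      if (!is.null(s$mole_fraction)) computed[[s$label]] <- s$mole_fraction
    }
  }
  computed
}
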