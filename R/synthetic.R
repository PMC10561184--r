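#' Configuration for the synthetic profile generator
#'
#' Value ranges default to what phenolic antioxidants toward oxygenated
#' radicals actually span: hydrogen-abstraction barriers of a few to ~25
#' kcal/mol, electron-transfer reorganization energies of ~5-45 kcal/mol,
#' phenol/carboxyl pKa values between 3 and 12, and mostly exergonic channels.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param n_sites Number of abstraction sites (1-6).
#' @param barrier_range Interval (kcal/mol) the FHT/RAF activation free
#'   energies are drawn from.
#' @param lambda_range Interval (kcal/mol) for SET reorganization energies.
#' @param pka_count Number of pKa values (0-3); 0 yields a lipid-only profile
#'   with a single neutral state.
#' @param pka_range Interval the pKa values are drawn from.
#' @param media List of [medium()] objects; defaults to water at pH 7.4 plus
#'   pentyl ethanoate.
#' @param exergonic_fraction Probability that a channel's reaction free energy
#'   is negative.
#' @param tunneling `"scalar"` (draw kappa directly) or `"eckart"` (draw
#'   Eckart barrier parameters, imaginary frequencies 800-3200 cm^-1).
#'
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_sites = 3L,
                             barrier_range = c(2, 25),
                             lambda_range = c(5, 45),
                             pka_count = 1L, pka_range = c(3, 12),
                             media = NULL, exergonic_fraction = 0.9,
                             tunneling = c("scalar", "eckart")) {
  tunneling <- match.arg(tunneling)
  stopifnot(n_sites >= 1L, n_sites <= 6L, pka_count >= 0L, pka_count <= 3L,
            length(barrier_range) == 2L, diff(barrier_range) > 0,
            length(lambda_range) == 2L, diff(lambda_range) > 0,
            length(pka_range) == 2L, diff(pka_range) > 0,
            exergonic_fraction >= 0, exergonic_fraction <= 1)
  if (is.null(media)) {
    media <- list(
      medium("water", is_aqueous = TRUE, ph = 7.4, viscosity = 8.91e-4),
      medium("pentyl ethanoate", is_aqueous = FALSE, viscosity = 8.62e-4)
    )
  }
  structure(
    list(seed = as.integer(seed), n_sites = as.integer(n_sites),
         barrier_range = barrier_range, lambda_range = lambda_range,
         pka_count = as.integer(pka_count), pka_range = pka_range,
         media = media, exergonic_fraction = exergonic_fraction,
         tunneling = tunneling),
    class = "generator_config"
  )
}

# run code under a local RNG seed without disturbing the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic antioxidant profile
#'
#' Draws a multi-site antioxidant with FHT channels at every site, a RAF
#' channel per medium (when the compound has at least two sites), and SET
#' channels for each deprotonated state in each aqueous medium. Deterministic
#' for a fixed seed; the result always passes [validate_profile()].
#'
#' @param config A [generator_config()].
#' @return An [antioxidant_profile()].
#' @examples
#' prof <- generate_profile(generator_config(seed = 42))
#' prof
#' @export
generate_profile <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_local_seed(config$seed, {
    n_states <- config$pka_count + 1L
    state_labels <- c("neutral", if (n_states > 1L)
      paste0("anion", seq_len(n_states - 1L)))
    pka <- sort(stats::runif(config$pka_count, config$pka_range[1],
                             config$pka_range[2]))
    acid_base <- acid_base_system(pka, state_labels)

    media <- config$media
    if (config$pka_count == 0L) {
      media <- Filter(function(m) !m$is_aqueous, media)
      if (length(media) == 0L) {
        media <- list(medium("pentyl ethanoate", is_aqueous = FALSE,
                             viscosity = 8.62e-4))
      }
    }

    draw_dgr <- function() {
      if (stats::runif(1) < config$exergonic_fraction) {
        -stats::runif(1, 0.5, 30)
      } else {
        stats::runif(1, 0.1, 10)
      }
    }
    draw_tunneling <- function(barrier, dgr) {
      if (config$tunneling == "scalar") {
        exp(stats::runif(1, log(1), log(2500)))
      } else {
        eckart_parameters(
          forward_barrier = barrier,
          reverse_barrier = max(barrier - min(dgr, 0), 0.5),
          imaginary_frequency = stats::runif(1, 800, 3200))
      }
    }

    channels <- list()
    for (med in media) {
      for (i in seq_len(config$n_sites)) {
        barrier <- stats::runif(1, config$barrier_range[1], config$barrier_range[2])
        dgr <- draw_dgr()
        channels[[length(channels) + 1L]] <- reaction_channel(
          mechanism = "FHT", site = sprintf("%dOH", i), radical = "HOO",
          medium = med$name, species_state = "neutral",
          activation_free_energy = barrier,
          tunneling = draw_tunneling(barrier, dgr),
          reaction_free_energy = dgr)
      }
      if (config$n_sites >= 2L) {
        channels[[length(channels) + 1L]] <- reaction_channel(
          mechanism = "RAF", site = "C1-C6", radical = "HOO",
          medium = med$name, species_state = "neutral",
          activation_free_energy = stats::runif(1, config$barrier_range[1],
                                                config$barrier_range[2]),
          reaction_free_energy = draw_dgr())
      }
      if (med$is_aqueous && n_states > 1L) {
        for (s in state_labels[-1]) {
          lambda <- stats::runif(1, config$lambda_range[1], config$lambda_range[2])
          channels[[length(channels) + 1L]] <- reaction_channel(
            mechanism = "SET", site = "e", radical = "HOO",
            medium = med$name, species_state = s,
            marcus = marcus_input(lambda,
                                  reaction_free_energy = -stats::runif(1) * 0.9 * lambda),
            reaction_free_energy = draw_dgr())
        }
      }
    }

    antioxidant_profile(
      compound = sprintf("synthetic-%d", config$seed),
      acid_base = acid_base, media = media, channels = channels)
  })
}

# ---- bundled reference profiles --------------------------------------------

#' Bundled alkylresorcinol reference profiles
#'
#' The package ships transcriptions of the published kinetic parameterization
#' of olivetol (Oli) and olivetolic acid (OliA) toward the hydroxyl (HO) and
#' hydroperoxyl (HOO) radicals in water (pH 7.4) and pentyl ethanoate, as YAML
#' profile files under `inst/extdata/profiles/`.
#'
#' @param name One of `"oli_hoo"`, `"olia_hoo"`, `"oli_ho"`, `"olia_ho"`; or
#'   `NULL` to list the available names.
#' @return An [antioxidant_profile()], or a character vector of names.
#' @examples
#' bundled_profile("oli_hoo")
#' @export
bundled_profile <- function(name = NULL) {
  dir <- system.file("extdata", "profiles", package = "radkin")
  avail <- sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
  avail <- setdiff(avail, "cu_olia_redox")
  if (is.null(name)) return(avail)
  name <- match.arg(name, avail)
  read_profile(file.path(dir, paste0(name, ".yaml")), format = "yaml")
}

#' Expected outputs for the bundled reference profiles
#'
#' Published reference values used as regression anchors by the test suite:
#' overall rate constants and branching ratios per compound/radical/medium,
#' speciation percentages at pH 7.4, and the copper-complex chelation and
#' pro-oxidant kinetics table.
#'
#' @return A nested list of reference numbers.
#' @export
bundled_expected <- function() {
  list(
    speciation = list(
      oli  = list(pka = 9.9, ph = 7.4, percent = c(99.68, 0.32)),
      olia = list(pka = c(4.4, 10.3), ph = 7.4, percent = c(0.10, 99.77, 0.13))
    ),
    overall = list(
      oli_hoo  = list(`pentyl ethanoate` = 1.92e1, water = 5.76e6),
      # the water value is the self-consistent f * k_app sum; the published
      # table prints 1.87e6 for the SET row, inconsistent with its own
      # f = 0.0013 and k_app = 1.20e9 (see fixture notes)
      olia_hoo = list(`pentyl ethanoate` = 8.70e-2, water = 1.56e6),
      oli_ho   = list(`pentyl ethanoate` = 5.42e9, water = 4.73e9),
      olia_ho  = list(`pentyl ethanoate` = 5.36e9, water = 4.70e9)
    ),
    gamma = list(
      oli_hoo_pe  = c(50, 50, 0),
      oli_ho_w    = c(0, 48, 48, 2, 1),     # SET, 1OH, 3OH, 7CH, RAF
      olia_ho_pe  = c(49, 49, 1, 2)
    ),
    chelation = list(
      mono = list(delta_g = -9.2, k = 5.39e6),
      bi   = list(delta_g = -12.3, k = 1.10e9)
    ),
    prooxidant = list(
      barriers = c(2.2, 1.4, 0.6, 6.4, 1.4, 0.2),
      rates = c(1.45e11, 6.01e11, 2.19e12, 1.18e8, 5.89e11, 4.18e12)
    )
  )
}

#' Bundled copper-complex redox set
#'
#' The chelation free energies of the Cu(II)-olivetolic-acid monoanion
#' complexes and the Marcus parameterization of their single-electron-transfer
#' reactions with superoxide and ascorbate, read from the bundled
#' `cu_olia_redox.yaml`. The per-pair diffusion limits are back-solved from
#' the published (k, k_app) pairs, as the source does not report them.
#'
#' @return A list with `complexation` (tibble: denticity, delta_g),
#'   `ligand_fraction`, and `redox` (tibble: complex, reductant, lambda,
#'   delta_g, k_D).
#' @export
bundled_chelation <- function() {
  path <- system.file("extdata", "profiles", "cu_olia_redox.yaml",
                      package = "radkin")
  read_chelation_set(path)
}

#' Read a chelation/redox set file
#'
#' YAML document with `schema: 1`, a `complexation` list (denticity, delta_g
#' in kcal/mol), an optional `ligand_fraction`, and a `redox_steps` list
#' (complex, reductant, lambda, delta_g, k_D).
#'
#' @param path Path to the YAML file.
#' @return See [bundled_chelation()].
#' @export
read_chelation_set <- function(path) {
  raw <- yaml::read_yaml(path)
  reject_unknown(raw, c("schema", "metal", "ligand", "ligand_fraction",
                        "complexation", "redox_steps", "notes"), path)
  if (is.null(raw$schema) || as.integer(raw$schema) != PROFILE_SCHEMA_VERSION) {
    stop(sprintf("%s: unsupported schema version", path), call. = FALSE)
  }
  comp <- do.call(rbind, lapply(raw$complexation %||% list(), function(x) {
    reject_unknown(x, c("denticity", "delta_g"), paste0(path, "$complexation"))
    stopifnot(x$denticity %in% c("mono", "bi"))
    data.frame(denticity = x$denticity, delta_g = x$delta_g,
               stringsAsFactors = FALSE)
  }))
  redox <- do.call(rbind, lapply(raw$redox_steps %||% list(), function(x) {
    reject_unknown(x, c("complex", "reductant", "lambda", "delta_g", "k_D"),
                   paste0(path, "$redox_steps"))
    data.frame(complex = x$complex, reductant = x$reductant,
               lambda = x$lambda, delta_g = x$delta_g, k_D = x$k_D,
               stringsAsFactors = FALSE)
  }))
  list(metal = raw$metal, ligand = raw$ligand,
       ligand_fraction = raw$ligand_fraction %||% 1,
       complexation = if (is.null(comp)) NULL else tibble::as_tibble(comp),
       redox = if (is.null(redox)) NULL else tibble::as_tibble(redox))
}
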