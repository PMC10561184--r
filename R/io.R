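PROFILE_SCHEMA_VERSION <- 1L

PROFILE_FIELDS <- c("schema", "compound", "acid_base", "media", "states",
                    "channels", "gas_phase_thermo", "notes")
MEDIUM_FIELDS  <- c("name", "is_aqueous", "ph", "viscosity",
                    "diffusion_limit_override")
STATE_FIELDS   <- c("label", "charge", "mole_fraction")
CHANNEL_FIELDS <- c("mechanism", "site", "radical", "medium", "species_state",
                    "symmetry_number", "activation_free_energy", "tunneling",
                    "marcus", "reaction_free_energy", "barrierless", "fixed_rate")
ECKART_FIELDS  <- c("forward_barrier", "reverse_barrier", "imaginary_frequency")
MARCUS_FIELDS  <- c("reorganization_energy", "reaction_free_energy",
                    "vertical_energy_gap")
THERMO_FIELDS  <- c("label", "solution_free_energy", "enthalpy_parent",
                    "enthalpy_radical", "enthalpy_h_atom")

reject_unknown <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0L) {
    stop(sprintf("unknown field(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Read an antioxidant profile
#'
#' Reads a profile from JSON, YAML, or a CSV bundle (a directory holding
#' `profile.csv`, `media.csv`, `species.csv`, `channels.csv`). The file must
#' declare `schema: 1`; unknown schema versions and unknown fields are
#' rejected with a named error, and all structural invariants are enforced on
#' load.
#'
#' A scalar tunneling value of exactly 0 is treated as "not reported" — a
#' transmission coefficient of zero would annihilate the rate — and replaced
#' by 1 with a warning.
#'
#' @param path Path to the profile file (or bundle directory for
#'   `format = "csv"`).
#' @param format `"json"`, `"yaml"` or `"csv"`; guessed from the extension
#'   when omitted.
#'
#' @return A validated [antioxidant_profile()].
#' @export
read_profile <- function(path, format = c("auto", "json", "yaml", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) {
      "csv"
    } else {
      switch(tolower(tools::file_ext(path)),
             json = "json", yaml = "yaml", yml = "yaml",
             stop(sprintf("cannot guess profile format from '%s'", path),
                  call. = FALSE))
    }
  }
  if (format != "csv" && !file.exists(path)) {
    stop(sprintf("profile file '%s' does not exist", path), call. = FALSE)
  }
  raw <- switch(format,
    json = jsonlite::fromJSON(path, simplifyVector = FALSE),
    yaml = yaml::read_yaml(path),
    csv  = read_profile_csv_bundle(path)
  )
  profile_from_list(raw, where = path)
}

profile_from_list <- function(raw, where = "profile") {
  if (!is.list(raw)) stop(sprintf("%s: not a mapping", where), call. = FALSE)
  reject_unknown(raw, PROFILE_FIELDS, where)
  schema <- raw$schema
  if (is.null(schema) || length(schema) != 1L || as.integer(schema) != PROFILE_SCHEMA_VERSION) {
    stop(sprintf("%s: unsupported or missing schema version (need %d)",
                 where, PROFILE_SCHEMA_VERSION), call. = FALSE)
  }
  if (is.null(raw$compound)) stop(sprintf("%s: missing 'compound'", where), call. = FALSE)

  ab_raw <- raw$acid_base %||% list(pka_values = list(), state_labels = list("neutral"))
  reject_unknown(ab_raw, c("pka_values", "state_labels"), paste0(where, "$acid_base"))
  acid_base <- acid_base_system(
    pka_values = as.numeric(unlist(ab_raw$pka_values %||% list())),
    state_labels = as.character(unlist(ab_raw$state_labels))
  )

  media <- lapply(seq_along(raw$media %||% list()), function(i) {
    m <- raw$media[[i]]
    reject_unknown(m, MEDIUM_FIELDS, sprintf("%s$media[[%d]]", where, i))
    ov <- m$diffusion_limit_override
    if (!is.null(ov)) ov <- unlist(ov)
    medium(name = m$name, is_aqueous = isTRUE(m$is_aqueous), ph = m$ph,
           viscosity = m$viscosity %||% 8.91e-4, diffusion_limit_override = ov)
  })

  states <- lapply(seq_along(raw$states %||% list()), function(i) {
    s <- raw$states[[i]]
    reject_unknown(s, STATE_FIELDS, sprintf("%s$states[[%d]]", where, i))
    species_state(label = s$label, charge = s$charge %||% 0L,
                  mole_fraction = s$mole_fraction)
  })
  if (length(states) == 0L) states <- NULL

  channels <- lapply(seq_along(raw$channels %||% list()), function(i) {
    ch <- raw$channels[[i]]
    id <- sprintf("%s$channels[[%d]]", where, i)
    reject_unknown(ch, CHANNEL_FIELDS, id)
    tun <- ch$tunneling
    if (!is.null(tun) && is.list(tun)) {
      reject_unknown(tun, ECKART_FIELDS, paste0(id, "$tunneling"))
      tun <- eckart_parameters(tun$forward_barrier, tun$reverse_barrier,
                               tun$imaginary_frequency)
    } else if (!is.null(tun) && tun == 0) {
      warning(sprintf("%s: tunneling correction reported as 0; treating as absent (kappa = 1)",
                      id), call. = FALSE)
      tun <- NULL
    }
    mar <- ch$marcus
    if (!is.null(mar)) {
      reject_unknown(mar, MARCUS_FIELDS, paste0(id, "$marcus"))
      mar <- marcus_input(mar$reorganization_energy, mar$reaction_free_energy,
                          mar$vertical_energy_gap)
    }
    tryCatch(
      reaction_channel(
        mechanism = ch$mechanism, site = ch$site, radical = ch$radical,
        medium = ch$medium, species_state = ch$species_state,
        symmetry_number = ch$symmetry_number %||% 1L,
        activation_free_energy = ch$activation_free_energy,
        tunneling = tun, marcus = mar,
        reaction_free_energy = ch$reaction_free_energy,
        barrierless = isTRUE(ch$barrierless), fixed_rate = ch$fixed_rate),
      error = function(e) stop(sprintf("%s: %s", id, conditionMessage(e)),
                               call. = FALSE)
    )
  })

  thermo <- lapply(seq_along(raw$gas_phase_thermo %||% list()), function(i) {
    tr <- raw$gas_phase_thermo[[i]]
    reject_unknown(tr, THERMO_FIELDS, sprintf("%s$gas_phase_thermo[[%d]]", where, i))
    thermo_record(tr$label, tr$solution_free_energy, tr$enthalpy_parent,
                  tr$enthalpy_radical, tr$enthalpy_h_atom)
  })
  if (length(thermo) == 0L) thermo <- NULL

  antioxidant_profile(compound = raw$compound, acid_base = acid_base,
                      media = media, channels = channels, states = states,
                      gas_phase_thermo = thermo)
}

profile_to_list <- function(profile) {
  validate_profile(profile)
  drop_null <- function(x) x[!vapply(x, is.null, logical(1))]
  list(
    schema = PROFILE_SCHEMA_VERSION,
    compound = profile$compound,
    acid_base = list(pka_values = as.list(profile$acid_base$pka_values),
                     state_labels = as.list(profile$acid_base$state_labels)),
    media = lapply(profile$media, function(m) drop_null(list(
      name = m$name, is_aqueous = m$is_aqueous, ph = m$ph,
      viscosity = m$viscosity,
      diffusion_limit_override = if (is.null(m$diffusion_limit_override)) NULL
                                 else as.list(m$diffusion_limit_override)))),
    states = if (is.null(profile$states)) NULL else
      lapply(profile$states, function(s) drop_null(list(
        label = s$label, charge = s$charge, mole_fraction = s$mole_fraction))),
    channels = lapply(profile$channels, function(ch) drop_null(list(
      mechanism = ch$mechanism, site = ch$site, radical = ch$radical,
      medium = ch$medium, species_state = ch$species_state,
      symmetry_number = ch$symmetry_number,
      activation_free_energy = ch$activation_free_energy,
      tunneling = if (inherits(ch$tunneling, "eckart_parameters"))
        unclass(ch$tunneling) else ch$tunneling,
      marcus = if (is.null(ch$marcus)) NULL else drop_null(unclass(ch$marcus)),
      reaction_free_energy = ch$reaction_free_energy,
      barrierless = if (isTRUE(ch$barrierless)) TRUE else NULL,
      fixed_rate = ch$fixed_rate))),
    gas_phase_thermo = if (is.null(profile$gas_phase_thermo)) NULL else
      lapply(profile$gas_phase_thermo, function(tr) drop_null(list(
        label = tr$label, solution_free_energy = tr$solution_free_energy,
        enthalpy_parent = tr$enthalpy_parent,
        enthalpy_radical = tr$enthalpy_radical,
        enthalpy_h_atom = tr$enthalpy_h_atom)))
  )
}

#' Write an antioxidant profile
#'
#' Serializes a profile to JSON or YAML (full double precision, so numeric
#' fields round-trip) or to a CSV bundle directory.
#'
#' @param profile An [antioxidant_profile()].
#' @param path Output file (or directory for `format = "csv"`).
#' @param format `"json"`, `"yaml"` or `"csv"`; guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, format = c("auto", "json", "yaml", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     json = "json", yaml = "yaml", yml = "yaml", "csv")
  }
  lst <- profile_to_list(profile)
  lst <- lst[!vapply(lst, is.null, logical(1))]
  switch(format,
    json = jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"),
    yaml = yaml::write_yaml(lst, path, precision = 15L),
    csv  = write_profile_csv_bundle(lst, path)
  )
  invisible(path)
}

# ---- CSV bundle -------------------------------------------------------------

fmt_num <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v) format(v, digits = 15), character(1)))
}

write_profile_csv_bundle <- function(lst, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  meta <- data.frame(
    key = c("schema", "compound", "pka_values", "state_labels"),
    value = c(as.character(lst$schema), lst$compound,
              paste(fmt_num(unlist(lst$acid_base$pka_values)), collapse = ";"),
              paste(unlist(lst$acid_base$state_labels), collapse = ";")),
    stringsAsFactors = FALSE)
  utils::write.csv(meta, file.path(dir, "profile.csv"), row.names = FALSE)

  media <- do.call(rbind, lapply(lst$media, function(m) data.frame(
    name = m$name, is_aqueous = m$is_aqueous,
    ph = fmt_num(m$ph %||% NA_real_),
    viscosity = fmt_num(m$viscosity),
    diffusion_limit_override = if (is.null(m$diffusion_limit_override)) "" else
      paste(sprintf("%s=%s", names(m$diffusion_limit_override) %||%
                      rep("default", length(m$diffusion_limit_override)),
                    fmt_num(unlist(m$diffusion_limit_override))), collapse = ";"),
    stringsAsFactors = FALSE)))
  utils::write.csv(media, file.path(dir, "media.csv"), row.names = FALSE)

  states <- lst$states %||% list()
  sp <- if (length(states)) do.call(rbind, lapply(states, function(s) data.frame(
    label = s$label, charge = s$charge %||% 0L,
    mole_fraction = fmt_num(s$mole_fraction %||% NA_real_),
    stringsAsFactors = FALSE)))
  else data.frame(label = character(0), charge = integer(0),
                  mole_fraction = character(0))
  utils::write.csv(sp, file.path(dir, "species.csv"), row.names = FALSE)

  chans <- do.call(rbind, lapply(lst$channels, function(ch) {
    eck <- if (is.list(ch$tunneling)) ch$tunneling else NULL
    data.frame(
      mechanism = ch$mechanism, site = ch$site, radical = ch$radical,
      medium = ch$medium, species_state = ch$species_state,
      symmetry_number = ch$symmetry_number,
      activation_free_energy = fmt_num(ch$activation_free_energy %||% NA_real_),
      tunneling = fmt_num(if (is.list(ch$tunneling)) NA_real_ else
        ch$tunneling %||% NA_real_),
      eckart_forward = fmt_num(eck$forward_barrier %||% NA_real_),
      eckart_reverse = fmt_num(eck$reverse_barrier %||% NA_real_),
      eckart_frequency = fmt_num(eck$imaginary_frequency %||% NA_real_),
      marcus_lambda = fmt_num(ch$marcus$reorganization_energy %||% NA_real_),
      marcus_dg0 = fmt_num(ch$marcus$reaction_free_energy %||% NA_real_),
      marcus_gap = fmt_num(ch$marcus$vertical_energy_gap %||% NA_real_),
      reaction_free_energy = fmt_num(ch$reaction_free_energy %||% NA_real_),
      barrierless = isTRUE(ch$barrierless),
      fixed_rate = fmt_num(ch$fixed_rate %||% NA_real_),
      stringsAsFactors = FALSE)
  }))
  if (is.null(chans)) {
    chans <- data.frame(mechanism = character(0), site = character(0),
                        radical = character(0), medium = character(0),
                        species_state = character(0))
  }
  utils::write.csv(chans, file.path(dir, "channels.csv"), row.names = FALSE)
  invisible(dir)
}

csv_num <- function(x) {
  if (is.null(x) || is.na(x) || !nzchar(as.character(x))) NULL else as.numeric(x)
}

read_profile_csv_bundle <- function(dir) {
  need <- file.path(dir, c("profile.csv", "media.csv", "species.csv", "channels.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0L) {
    stop(sprintf("CSV bundle incomplete; missing %s",
                 paste(basename(missing), collapse = ", ")), call. = FALSE)
  }
  meta <- utils::read.csv(need[1], stringsAsFactors = FALSE, colClasses = "character")
  kv <- stats::setNames(meta$value, meta$key)
  split_semi <- function(s) if (!nzchar(s)) character(0) else strsplit(s, ";", fixed = TRUE)[[1]]

  media_df <- utils::read.csv(need[2], stringsAsFactors = FALSE)
  media <- lapply(seq_len(nrow(media_df)), function(i) {
    ov_str <- as.character(media_df$diffusion_limit_override[i] %||% "")
    ov <- NULL
    if (!is.na(ov_str) && nzchar(ov_str)) {
      parts <- strsplit(split_semi(ov_str), "=", fixed = TRUE)
      ov <- stats::setNames(vapply(parts, function(p) as.numeric(p[2]), 0.0),
                            vapply(parts, `[[`, character(1), 1))
    }
    list(name = media_df$name[i], is_aqueous = isTRUE(media_df$is_aqueous[i]),
         ph = csv_num(media_df$ph[i]), viscosity = csv_num(media_df$viscosity[i]),
         diffusion_limit_override = ov)
  })

  sp_df <- utils::read.csv(need[3], stringsAsFactors = FALSE)
  states <- lapply(seq_len(nrow(sp_df)), function(i) list(
    label = sp_df$label[i], charge = sp_df$charge[i],
    mole_fraction = csv_num(sp_df$mole_fraction[i])))

  ch_df <- utils::read.csv(need[4], stringsAsFactors = FALSE)
  channels <- lapply(seq_len(nrow(ch_df)), function(i) {
    row <- ch_df[i, ]
    eck <- NULL
    if (!is.null(csv_num(row$eckart_forward))) {
      eck <- list(forward_barrier = csv_num(row$eckart_forward),
                  reverse_barrier = csv_num(row$eckart_reverse),
                  imaginary_frequency = csv_num(row$eckart_frequency))
    }
    mar <- NULL
    if (!is.null(csv_num(row$marcus_lambda))) {
      mar <- list(reorganization_energy = csv_num(row$marcus_lambda),
                  reaction_free_energy = csv_num(row$marcus_dg0),
                  vertical_energy_gap = csv_num(row$marcus_gap))
    }
    list(mechanism = row$mechanism, site = row$site, radical = row$radical,
         medium = row$medium, species_state = row$species_state,
         symmetry_number = row$symmetry_number,
         activation_free_energy = csv_num(row$activation_free_energy),
         tunneling = eck %||% csv_num(row$tunneling), marcus = mar,
         reaction_free_energy = csv_num(row$reaction_free_energy),
         barrierless = isTRUE(row$barrierless), fixed_rate = csv_num(row$fixed_rate))
  })

  list(schema = as.integer(kv[["schema"]]), compound = kv[["compound"]],
       acid_base = list(pka_values = as.list(as.numeric(split_semi(kv[["pka_values"]]))),
                        state_labels = as.list(split_semi(kv[["state_labels"]]))),
       media = media, states = states, channels = channels)
}

# ---- report writer ----------------------------------------------------------

REPORT_COLUMNS <- c("mechanism", "site", "state", "delta_g_act", "kappa",
                    "k_app", "f", "k_f", "gamma", "k_overall")

sig3 <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("")
    if (is.infinite(v)) return(if (v > 0) "Inf" else "-Inf")
    trimws(formatC(signif(v, 3), format = "g", digits = 3))
  }, character(1))
}

#' Write a channel-results report
#'
#' Writes the per-channel results of [evaluate_profile()] as a CSV file or a
#' GitHub-flavored markdown table, with the canonical column order
#' mechanism, site, state, dG_act, kappa, k_app, f, k_f, Gamma, k_overall.
#' Rates are formatted to 3 significant figures; branching ratios are rounded
#' to the nearest integer; negligible weighted rates (below 1e-6 of the
#' overall rate) are displayed as `~0`.
#'
#' @param results Tibble from [evaluate_profile()] (possibly filtered); an
#'   empty tibble yields a header-only file.
#' @param path Output file path.
#' @param format `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results))
  df <- as.data.frame(results)
  if (nrow(df) > 0L) {
    negligible <- !is.na(df$k_f) & !is.na(df$k_overall) & df$k_overall > 0 &
      df$k_f < 1e-6 * df$k_overall
    out <- data.frame(
      mechanism = df$mechanism, site = df$site, state = df$state,
      delta_g_act = sig3(df$barrier), kappa = sig3(df$kappa),
      k_app = sig3(df$k_app), f = sig3(df$f),
      k_f = ifelse(negligible, "~0", sig3(df$k_f)),
      gamma = as.character(round_half_up(df$gamma, 0)),
      k_overall = sig3(df$k_overall),
      stringsAsFactors = FALSE)
  } else {
    out <- as.data.frame(stats::setNames(
      replicate(length(REPORT_COLUMNS), character(0), simplify = FALSE),
      REPORT_COLUMNS))
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop(sprintf("cannot write report to '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  on.exit(close(con))
  if (format == "csv") {
    utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  } else {
    writeLines(markdown_table(out), con)
  }
  invisible(path)
}

markdown_table <- function(df) {
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  if (nrow(df) == 0L) return(c(header, sep))
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Read back a CSV channel report
#'
#' Parses a report written by [write_report()] (`format = "csv"`) into a
#' tibble with numeric columns; `~0` entries become 0.
#'
#' @param path Path to the CSV report.
#' @return A tibble with the report columns.
#' @export
read_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  stopifnot(identical(names(df), REPORT_COLUMNS))
  num <- function(x) {
    x[x == "~0"] <- "0"
    suppressWarnings(as.numeric(x))
  }
  tibble::tibble(
    mechanism = df$mechanism, site = df$site, state = df$state,
    delta_g_act = num(df$delta_g_act), kappa = num(df$kappa),
    k_app = num(df$k_app), f = num(df$f), k_f = num(df$k_f),
    gamma = num(df$gamma), k_overall = num(df$k_overall))
}
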