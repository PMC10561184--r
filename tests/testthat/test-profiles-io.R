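make_roundtrip_profile <- function() {
  antioxidant_profile(
    compound = "rt-test",
    acid_base = acid_base_system(c(4.412345678912, 10.3), c("n", "a1", "a2")),
    media = list(
      medium("water", TRUE, ph = 7.4, viscosity = 8.91e-4,
             diffusion_limit_override = c(HOO = 1.9123456789e9)),
      medium("pentyl ethanoate", FALSE, viscosity = 8.62e-4)
    ),
    channels = list(
      reaction_channel("FHT", "1OH", "HOO", "water", "n",
                       activation_free_energy = 18.801234567891,
                       tunneling = 2476.9, reaction_free_energy = -5.25),
      reaction_channel("FHT", "7CH", "HOO", "pentyl ethanoate", "n",
                       activation_free_energy = 21.4,
                       tunneling = eckart_parameters(5.5, 7.25, 1234.5)),
      reaction_channel("SET", "e", "HOO", "water", "a2",
                       marcus = marcus_input(2.0, -8.123456789012)),
      reaction_channel("RAF", "C1-C6", "HOO", "water", "a1",
                       barrierless = TRUE)
    ),
    states = list(species_state("n", 0L, 0.0010),
                  species_state("a1", -1L, 0.9977),
                  species_state("a2", -2L, 0.0013))
  )
}

channel_numbers <- function(prof) {
  unlist(lapply(prof$channels, function(ch) c(
    ch$activation_free_energy, ch$reaction_free_energy,
    if (inherits(ch$tunneling, "eckart_parameters")) unlist(unclass(ch$tunneling))
    else ch$tunneling,
    ch$marcus$reorganization_energy, ch$marcus$reaction_free_energy,
    ch$fixed_rate)))
}

test_that("profiles round-trip through json, yaml and the csv bundle", {
  prof <- make_roundtrip_profile()
  for (fmt in c("json", "yaml", "csv")) {
    path <- file.path(withr::local_tempdir(),
                      if (fmt == "csv") "bundle" else paste0("p.", fmt))
    write_profile(prof, path, fmt)
    back <- read_profile(path, fmt)
    expect_identical(back$compound, prof$compound)
    expect_equal(back$acid_base$pka_values, prof$acid_base$pka_values,
                 tolerance = 1e-12, label = fmt)
    expect_equal(channel_numbers(back), channel_numbers(prof),
                 tolerance = 1e-12, label = fmt)
    expect_equal(
      vapply(back$states, `[[`, 0.0, "mole_fraction"),
      vapply(prof$states, `[[`, 0.0, "mole_fraction"), tolerance = 1e-12)
    expect_equal(back$media[[1]]$diffusion_limit_override,
                 prof$media[[1]]$diffusion_limit_override, tolerance = 1e-12)
    # evaluated results agree between original and round-tripped profile
    expect_equal(evaluate_profile(back, run_config(log_level = "quiet"))$k_app,
                 evaluate_profile(prof, run_config(log_level = "quiet"))$k_app,
                 tolerance = 1e-10)
  }
})

test_that("the bundled hydroperoxyl fixture parses into the expected shape", {
  prof <- bundled_profile("oli_hoo")
  expect_identical(prof$compound, "Oli")
  expect_length(prof$media, 2L)
  expect_length(prof$channels, 7L)  # 3 lipid FHT + anion SET + 3 aqueous FHT
  mechs <- vapply(prof$channels, `[[`, character(1), "mechanism")
  expect_setequal(unique(mechs), c("FHT", "SET"))
})

test_that("unknown schema versions and unknown fields are rejected by name", {
  d <- withr::local_tempdir()
  f <- file.path(d, "bad.yaml")
  writeLines(c("schema: 99", "compound: x"), f)
  expect_error(read_profile(f), "schema version")
  writeLines(c("schema: 1", "compound: x", "frobnicate: 1"), f)
  expect_error(read_profile(f), "frobnicate")
  writeLines(c("schema: 1", "compound: x",
               "acid_base: {pka_values: [5], state_labels: [neu, ani]}",
               "channels:",
               "- {mechanism: FHT, site: 1OH, radical: HOO, medium: water,",
               "   species_state: neu, activation_free_energy: 10, bogus_field: 2}",
               "media:", "- {name: water, is_aqueous: true, ph: 7.4}"), f)
  expect_error(read_profile(f), "bogus_field")
  expect_error(read_profile(file.path(d, "absent.yaml")), "does not exist")
})

test_that("schema invariants are enforced on load", {
  d <- withr::local_tempdir()
  f <- file.path(d, "bad.yaml")
  # SET channel with neither marcus-with-dG0 nor fixed rate
  writeLines(c("schema: 1", "compound: x",
               "acid_base: {pka_values: [5], state_labels: [neu, ani]}",
               "media:", "- {name: water, is_aqueous: true, ph: 7.4}",
               "channels:",
               "- {mechanism: SET, site: e, radical: HOO, medium: water,",
               "   species_state: ani, marcus: {reorganization_energy: 20}}"), f)
  expect_error(read_profile(f), "SET channels need")
  # supplied fractions not summing to 1
  writeLines(c("schema: 1", "compound: x",
               "acid_base: {pka_values: [5], state_labels: [neu, ani]}",
               "media:", "- {name: water, is_aqueous: true, ph: 7.4}",
               "states:",
               "- {label: neu, charge: 0, mole_fraction: 0.6}",
               "- {label: ani, charge: -1, mole_fraction: 0.3}",
               "channels: []"), f)
  expect_error(read_profile(f), "sum to")
  # channel naming an undeclared state
  expect_error(
    make_test_profile(list(reaction_channel("FHT", "1OH", "HOO", "water",
                                            "ghost",
                                            activation_free_energy = 5))),
    "ghost")
})

test_that("a tunneling correction recorded as 0 is ingested as absent with a warning", {
  d <- withr::local_tempdir()
  f <- file.path(d, "zero_kappa.yaml")
  writeLines(c("schema: 1", "compound: x",
               "acid_base: {pka_values: [], state_labels: [neu]}",
               "media:", "- {name: water, is_aqueous: true, ph: 7.4}",
               "channels:",
               "- {mechanism: FHT, site: 7CH, radical: HO, medium: water,",
               "   species_state: neu, activation_free_energy: 4.3, tunneling: 0.0}"), f)
  expect_warning(prof <- read_profile(f), "treating as absent")
  expect_null(prof$channels[[1]]$tunneling)
})

test_that("reports write the canonical columns and round-trip through read_report", {
  res <- evaluate_profile(bundled_profile("oli_hoo"), run_config(log_level = "quiet"))
  pe <- res[res$medium == "pentyl ethanoate", ]
  d <- withr::local_tempdir()
  f <- file.path(d, "report.csv")
  write_report(pe, f, "csv")
  back <- read_report(f)
  expect_identical(names(back),
                   c("mechanism", "site", "state", "delta_g_act", "kappa",
                     "k_app", "f", "k_f", "gamma", "k_overall"))
  expect_equal(back$gamma, c(50, 50, 0))
  expect_equal(back$k_app, signif(pe$k_app, 3))
  # markdown table has a header, a separator and one row per channel
  fmd <- file.path(d, "report.md")
  write_report(pe, fmd, "markdown")
  lines <- readLines(fmd)
  expect_length(lines, 2L + nrow(pe))
  expect_match(lines[1], "^\\| mechanism \\|")
  # single channel: branching ratio 100
  one <- res[res$medium == "pentyl ethanoate", ][1, ]
  one$gamma <- 100; one$k_overall <- one$k_f
  write_report(one, f, "csv")
  expect_equal(read_report(f)$gamma, 100)
  # empty results: header-only file
  write_report(res[0, ], f, "csv")
  expect_equal(nrow(read_report(f)), 0L)
})
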