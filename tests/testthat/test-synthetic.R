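test_that("generation is deterministic for a fixed seed, byte-for-byte", {
  p1 <- generate_profile(generator_config(seed = 42))
  p2 <- generate_profile(generator_config(seed = 42))
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.yaml"); f2 <- file.path(d, "b.yaml")
  write_profile(p1, f1, "yaml"); write_profile(p2, f2, "yaml")
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(
    readLines(f1),
    { write_profile(generate_profile(generator_config(seed = 43)), f2, "yaml")
      readLines(f2) }))
  # the generator does not disturb the caller's RNG stream
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generate_profile(generator_config(seed = 7))); after <- runif(3)
  expect_identical(before, after)
})

test_that("generated profiles validate and cover all mechanisms", {
  prof <- generate_profile(generator_config(seed = 42))
  expect_silent(validate_profile(prof))
  mechs <- vapply(prof$channels, `[[`, character(1), "mechanism")
  expect_setequal(unique(mechs), c("FHT", "RAF", "SET"))
})

test_that("a zero-pKa config yields lipid-only media with unit fractions", {
  prof <- generate_profile(generator_config(seed = 5, pka_count = 0L))
  expect_true(all(!vapply(prof$media, `[[`, logical(1), "is_aqueous")))
  r <- evaluate_profile(prof, run_config(log_level = "quiet"), screen = FALSE)
  expect_true(all(r$f == 1))
})

test_that("generated barriers in a narrow band give rates in the predicted band", {
  # TST closed form on the interval endpoints bounds every generated rate
  cfg <- generator_config(seed = 9, barrier_range = c(19.0, 19.2),
                          pka_count = 0L, tunneling = "scalar")
  prof <- generate_profile(cfg)
  fht <- Filter(function(ch) ch$mechanism == "FHT", prof$channels)
  for (ch in fht) {
    k <- tst_rate(ch$activation_free_energy, ch$tunneling)
    k_ref <- tst_rate(19.1, 145.8)          # 9.6 at the band center
    lo <- tst_rate(19.2, ch$tunneling); hi <- tst_rate(19.0, ch$tunneling)
    expect_true(k >= lo && k <= hi)
    expect_lt(abs(log(k_ref / 9.6)), log(1.2))
  }
})

test_that("inverting the TST rate recovers generated barriers to 1e-9 kcal/mol", {
  for (seed in c(1, 2, 3, 17, 99)) {
    prof <- generate_profile(generator_config(seed = seed, tunneling = "scalar"))
    for (ch in prof$channels) {
      if (ch$mechanism != "FHT") next
      k <- tst_rate(ch$activation_free_energy, ch$tunneling, ch$symmetry_number)
      back <- tst_barrier_from_rate(k, ch$tunneling, ch$symmetry_number)
      expect_lt(abs(back - ch$activation_free_energy), 1e-9)
    }
  }
})

test_that("every generated profile flows through the full pipeline without error", {
  cfg_quiet <- run_config(log_level = "quiet")
  for (seed in 1:1000) {
    prof <- generate_profile(generator_config(
      seed = seed,
      n_sites = (seed %% 3L) + 1L,
      pka_count = seed %% 4L))
    r <- evaluate_profile(prof, cfg_quiet)
    if (nrow(r) > 0L) {
      expect_true(all(is.finite(r$k_f)))
      expect_true(all(r$k_app <= r$k_D * (1 + 1e-12)))
      gsum <- tapply(r$gamma, interaction(r$radical, r$medium, drop = TRUE), sum)
      expect_true(all(abs(gsum - 100) < 1e-9))
    }
  }
  # the Eckart ingestion path flows through as well
  for (seed in 1:25) {
    prof <- generate_profile(generator_config(seed = seed, tunneling = "eckart"))
    r <- evaluate_profile(prof, cfg_quiet)
    expect_true(all(is.finite(r$k_app)))
    expect_true(all(r$kappa >= 0.99 | is.na(r$kappa)))
  }
})
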