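test_that("weighting multiplies apparent rates by state fractions, lipid media use f = 1", {
  res <- tibble::tibble(
    state = c("anion", "neutral", "neutral"),
    medium = c("water", "water", "pentyl ethanoate"),
    k_app = c(2.10e9, 1.50e9, 5.0e8))
  fr <- c(neutral = 0.9968, anion = 0.0032)
  aq <- c(water = TRUE, `pentyl ethanoate` = FALSE)
  out <- weight_channels(res, fr, aq)
  expect_equal(out$k_f[1], 6.72e6)
  expect_equal(out$k_f[2], 0.9968 * 1.50e9)
  expect_equal(out$k_f[3], 5.0e8)   # lipid: k_f = k_app
  # published anchor: f = 0.0013, k_app = 1.50e9 -> 1.95e6
  out2 <- weight_channels(
    tibble::tibble(state = "dianion", medium = "water", k_app = 1.50e9),
    c(dianion = 0.0013), c(water = TRUE))
  expect_equal(out2$k_f, 1.95e6)
  expect_error(
    weight_channels(tibble::tibble(state = "ghost", medium = "water", k_app = 1),
                    fr, aq),
    "ghost")
})

test_that("branching ratios are percentages of the weighted-rate total", {
  g <- branching_ratios(c(2.29264e9, 2.29264e9, 9.17056e7, 4.48e7, 6.72e6))
  expect_equal(round(g), c(48, 48, 2, 1, 0))
  expect_equal(sum(g), 100)
  expect_equal(branching_ratios(42), 100)
  expect_equal(branching_ratios(c(5, 5)), c(50, 50))
  expect_error(branching_ratios(c(0, 0)), "zero")
  set.seed(7)
  for (i in 1:50) {
    g <- branching_ratios(10^runif(sample(2:8, 1), -3, 11))
    expect_equal(sum(g), 100, tolerance = 1e-9)
  }
})

test_that("overall rate is the exact permutation-invariant sum with neutral zero", {
  expect_equal(signif(overall_rate(c(9.60, 9.60, 2.30e-2)), 3), 1.92e1)
  expect_equal(signif(overall_rate(c(5.76e6, 2.69e2, 2.69e2, 9.37e-1)), 3), 5.76e6)
  expect_identical(overall_rate(numeric(0)), 0)
  x <- c(3.5e4, 1.2e9, 6.7e2, 9.9e6)
  expect_equal(overall_rate(x), overall_rate(rev(x)))
  expect_equal(overall_rate(c(x, 0)), overall_rate(x))
  expect_gte(overall_rate(x), max(x))
})

test_that("the exergonicity screen keeps strictly favorable channels only", {
  mk <- function(dgr) reaction_channel("FHT", "1OH", "HOO", "water", "neutral",
                                       activation_free_energy = 10,
                                       reaction_free_energy = dgr)
  chans <- list(mk(-6.5), mk(2.0), mk(0), mk(-30.3), mk(NULL))
  expect_message(kept <- screen_exergonic(chans), "endergonic")
  dg <- vapply(kept, function(ch) ch$reaction_free_energy %||% NA_real_, 0.0)
  expect_equal(dg[!is.na(dg)], c(-6.5, -30.3))
  expect_length(kept, 3L)   # the unscreened no-dG channel passes through
  expect_silent(screen_exergonic(chans, quiet = TRUE))
})

test_that("evaluate_profile assembles the bundled hydroperoxyl tables", {
  r <- evaluate_profile(bundled_profile("oli_hoo"), run_config(log_level = "quiet"))
  pe <- r[r$medium == "pentyl ethanoate", ]
  expect_equal(signif(pe$k_overall[1], 3), 1.92e1)
  expect_equal(round(pe$gamma), c(50, 50, 0))
  w <- r[r$medium == "water", ]
  expect_equal(signif(w$k_overall[1], 3), 5.76e6)
  expect_equal(round(w$gamma[w$mechanism == "SET"]), 100)

  r2 <- evaluate_profile(bundled_profile("olia_hoo"), run_config(log_level = "quiet"))
  # computed TST route for the lipid 7CH channel
  pe2 <- r2[r2$medium == "pentyl ethanoate", ]
  expect_equal(pe2$k_app, 8.70e-2, tolerance = 0.05)
  expect_equal(pe2$gamma, 100)
  # self-consistent weighted SET rate (the source table prints 1.87e6 against
  # its own f * k_app = 1.56e6; we keep the arithmetic honest)
  w2 <- r2[r2$medium == "water" & r2$mechanism == "SET", ]
  expect_equal(w2$k_f, 0.0013 * 1.20e9)
})

test_that("evaluate_profile assembles the bundled hydroxyl tables", {
  exp_overall <- bundled_expected()$overall
  for (nm in c("oli_ho", "olia_ho")) {
    r <- evaluate_profile(bundled_profile(nm), run_config(log_level = "quiet"))
    for (med in names(exp_overall[[nm]])) {
      got <- unique(r$k_overall[r$medium == med])
      expect_equal(signif(got, 3), exp_overall[[nm]][[med]],
                   label = sprintf("%s overall in %s", nm, med))
    }
  }
  # hydroxyl branching in water: FHT at the phenolic sites dominates
  r <- evaluate_profile(bundled_profile("oli_ho"), run_config(log_level = "quiet"))
  w <- r[r$medium == "water", ]
  expect_equal(round(w$gamma[w$site %in% c("1OH", "3OH")]), c(48, 48))
  expect_equal(round(w$gamma[w$mechanism == "SET"]), 0)
})

test_that("an empty profile evaluates to an empty result", {
  prof <- make_test_profile(list())
  r <- evaluate_profile(prof)
  expect_s3_class(r, "tbl_df")
  expect_identical(nrow(r), 0L)
})
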