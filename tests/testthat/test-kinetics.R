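test_that("physical constants satisfy the canonical derived values", {
  pc <- physical_constants()
  expect_equal(pc$gas_constant * pc$default_temperature, 0.5925, tolerance = 1e-4 / 0.5925)
  expect_equal(pc$boltzmann_constant * pc$default_temperature / pc$planck_constant,
               6.212e12, tolerance = 1e-3)
})

test_that("TST rate reproduces the Eyring prefactor and printed slow channels", {
  expect_equal(tst_rate(0), 6.212e12, tolerance = 1e-3)
  # slow hydrogen abstraction with a large tunneling correction
  expect_equal(tst_rate(21.4, tunneling = 66.9), 8.70e-2, tolerance = 0.05)
  # Marcus-derived barrier feeding TST
  expect_equal(tst_rate(marcus_barrier(31.7, -14.9)), 1.45e11, tolerance = 0.05)
})

test_that("TST rate is monotone in the barrier and linear in kappa and sigma", {
  b <- seq(1, 25, by = 3)
  k <- vapply(b, tst_rate, 0.0)
  expect_true(all(diff(k) < 0))
  expect_equal(tst_rate(10, tunneling = 7), 7 * tst_rate(10))
  expect_equal(tst_rate(10, symmetry_number = 3L), 3 * tst_rate(10))
  expect_error(tst_rate(10, tunneling = -1), "tunneling")
  expect_error(tst_rate(10, symmetry_number = 0L), "symmetry_number")
})

test_that("barrier is recovered from the rate by inversion", {
  for (b in c(0.3, 5, 12.7, 24.1)) {
    k <- tst_rate(b, tunneling = 13.7, symmetry_number = 2L, temperature = 310)
    expect_equal(tst_barrier_from_rate(k, tunneling = 13.7, symmetry_number = 2L,
                                       temperature = 310),
                 b, tolerance = 1e-10 / b)
  }
})

test_that("Eckart kappa matches the frozen brute-force quadrature values", {
  # values frozen from an independent dense trapezoidal oracle
  expect_equal(eckart_kappa(eckart_parameters(5, 5, 1500)), 8.191673,
               tolerance = 0.005)
  expect_equal(eckart_kappa(eckart_parameters(10, 15, 1000)), 3.102746,
               tolerance = 0.005)
  expect_equal(eckart_kappa(eckart_parameters(3, 20, 2000)), 9.560853,
               tolerance = 0.005)
})

test_that("Eckart kappa approaches 1 in the classical (low-frequency) limit", {
  expect_equal(eckart_kappa(eckart_parameters(5, 5, 1)), 1, tolerance = 1e-3)
  expect_equal(eckart_kappa(eckart_parameters(12, 18, 1)), 1, tolerance = 1e-3)
})

test_that("Eckart kappa decreases with temperature", {
  k298 <- eckart_kappa(eckart_parameters(5, 5, 1500), 298.15)
  k596 <- eckart_kappa(eckart_parameters(5, 5, 1500), 596.30)
  expect_lt(k596, k298)
  expect_equal(k596, 1.822592, tolerance = 0.005)  # frozen oracle value
})

test_that("Eckart kappa agrees with the quadrature oracle across the parameter grid", {
  grid <- expand.grid(v1 = c(1, 5, 12, 25), dv = c(0, 5),
                      freq = c(300, 1500, 3500), temp = c(250, 298.15, 350))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ref <- oracle_eckart_kappa(g$v1, g$v1 + g$dv, g$freq, g$temp)
    got <- eckart_kappa(eckart_parameters(g$v1, g$v1 + g$dv, g$freq), g$temp)
    expect_equal(got, ref, tolerance = 0.005,
                 label = sprintf("kappa(V1=%g, V2=%g, nu=%g, T=%g)",
                                 g$v1, g$v1 + g$dv, g$freq, g$temp))
  }
})

test_that("Marcus barrier is the displaced parabola with vertex (-lambda, 0)", {
  expect_equal(marcus_barrier(31.7, -14.9), 2.2258675, tolerance = 1e-6)
  expect_equal(marcus_barrier(22.8, -27.4), 0.2320175, tolerance = 1e-6)  # inverted
  expect_identical(marcus_barrier(20, -20), 0)
  # symmetry about the vertex and curvature 1/(2 lambda) by finite differences
  lambda <- 17.3
  for (dx in c(1, 5, 12)) {
    expect_equal(marcus_barrier(lambda, -lambda + dx),
                 marcus_barrier(lambda, -lambda - dx))
  }
  h <- 1e-3
  second <- (marcus_barrier(lambda, -3 + h) - 2 * marcus_barrier(lambda, -3) +
               marcus_barrier(lambda, -3 - h)) / h^2
  expect_equal(second, 1 / (2 * lambda), tolerance = 1e-5)
  expect_error(marcus_barrier(-1, 5), "reorganization_energy")
})

test_that("reorganization energy follows the selected sign convention", {
  expect_equal(marcus_lambda(20, 0, "plus"), 20)
  expect_equal(marcus_lambda(20, 0, "minus"), 20)
  expect_equal(marcus_lambda(15, -5, "minus"), 20)
  expect_equal(marcus_lambda(15, -5, "plus"), 10)
  expect_error(marcus_lambda(5, -10, "plus"), "convention")
})

test_that("Smoluchowski diffusion rate matches the closed-form oracle and scalings", {
  got <- smoluchowski_kd(2, 2, 8.91e-4, 298.15)
  expect_equal(got, oracle_smoluchowski(2, 2, 8.91e-4, 298.15), tolerance = 1e-12)
  expect_gt(got, 1e9)
  expect_lt(got, 1e10)
  # doubling viscosity halves k_D
  expect_equal(smoluchowski_kd(2, 2, 2 * 8.91e-4), got / 2)
  # equal radii: k_D independent of the common radius
  expect_equal(smoluchowski_kd(5, 5, 8.91e-4), got)
})

test_that("Collins-Kimball interpolation respects both limits and the bound", {
  expect_equal(collins_kimball(1e3, 1e9), 9.99999e2, tolerance = 1e-5)
  expect_equal(collins_kimball(2e9, 2e9), 1e9)
  expect_identical(collins_kimball(0, 0), 0)
  set.seed(11)
  ka <- 10^runif(1e6, -2, 13)
  kd <- 10^runif(1e6, 6, 11)
  kapp <- collins_kimball(ka, kd)
  expect_true(all(kapp <= pmin(ka, kd) * (1 + 1e-12)))
  expect_true(all(kapp >= 0))
})
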