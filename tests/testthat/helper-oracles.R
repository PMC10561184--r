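# Independent oracles coded separately from the package implementation.

# Brute-force thermally averaged Eckart transmission: plain-cosh
# Johnston-Heicklen transmission probability integrated by a dense
# trapezoidal rule. No log-space guards, no adaptive quadrature -- valid for
# the moderate barrier/frequency grid it is used on.
oracle_eckart_kappa <- function(v1, v2, freq_cm, temp, n = 50000L) {
  nu <- freq_cm * 2.859144e-3          # cm^-1 -> kcal/mol
  kt <- 1.987204258e-3 * temp
  a1 <- 2 * pi * v1 / nu
  a2 <- 2 * pi * v2 / nu
  inv <- 1 / sqrt(a1) + 1 / sqrt(a2)
  e <- seq(0, v1 + 60 * kt, length.out = n)
  xi <- e / v1
  b2 <- (xi - 1) * a1 + a2
  p <- numeric(n)
  ok <- b2 >= 0 & e > 0
  a <- 2 * sqrt(a1 * xi[ok]) / inv
  b <- 2 * sqrt(b2[ok]) / inv
  d2 <- a1 * a2 - pi^2 / 4
  dd <- if (d2 >= 0) cosh(2 * sqrt(d2)) else cos(2 * sqrt(-d2))
  p[ok] <- (cosh(a + b) - cosh(a - b)) / (cosh(a + b) + dd)
  integrand <- p * exp((v1 - e) / kt)
  h <- e[2] - e[1]
  (sum(integrand) - 0.5 * (integrand[1] + integrand[n])) * h / kt
}

# step-by-step Stokes-Einstein / Smoluchowski evaluation (spreadsheet style)
oracle_smoluchowski <- function(ra_ang, rb_ang, eta, temp) {
  kb <- 1.380649e-23
  na <- 6.02214076e23
  da <- kb * temp / (6 * pi * eta * (ra_ang * 1e-10))
  db <- kb * temp / (6 * pi * eta * (rb_ang * 1e-10))
  rab <- (ra_ang + rb_ang) * 1e-10
  4 * pi * rab * (da + db) * na * 1000
}

rel_err <- function(x, ref) abs(x / ref - 1)

make_test_profile <- function(channels, pka = 9.9,
                              labels = c("neutral", "anion"),
                              states = NULL) {
  antioxidant_profile(
    compound = "test",
    acid_base = acid_base_system(pka, labels),
    media = list(
      medium("water", is_aqueous = TRUE, ph = 7.4, viscosity = 8.91e-4),
      medium("pentyl ethanoate", is_aqueous = FALSE, viscosity = 8.62e-4)
    ),
    channels = channels,
    states = states
  )
}
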