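# Crowding-function algebra: forward map, power-law inverse, flux correction,
# strong Allee growth, catalogue consistency and serialization.

test_that("forward map reproduces the closed-form diffusivities of the catalogue", {
  Cs <- seq(0, 1, length.out = 101)
  for (nm in c("linear", "increasing", "decreasing",
               "powerlaw-m1", "powerlaw-m2", "powerlaw-m3")) {
    pair <- crowding_catalogue(nm, D0 = 1)
    D <- diffusivity_from_crowding(pair$G, D0 = 1)
    expect_lt(max(abs(D$value(Cs) - pair$D$value(Cs))), 1e-10,
              label = paste("catalogue pair", nm))
  }
  # spot values: constant D for the linear crowding function, and the
  # increasing form evaluated at C = 0.5
  Dlin <- diffusivity_from_crowding(crowding_catalogue("linear")$G, D0 = 1)
  expect_equal(Dlin$value(c(0, 0.3, 0.999)), c(1, 1, 1))
  Dinc <- diffusivity_from_crowding(crowding_catalogue("increasing")$G, D0 = 1)
  expect_equal(Dinc$value(0.5), 1.375)
  # at C = 0 every G with G(0) = 1 gives D = D0
  for (nm in c("linear", "increasing", "decreasing")) {
    D <- diffusivity_from_crowding(crowding_catalogue(nm)$G, D0 = 2.5)
    expect_equal(D$value(0), 2.5)
  }
})

test_that("forward map handles user-supplied G without analytic derivative", {
  G <- crowding_g(function(C) (1 - C) * (1 + C / 2), label = "fd test")
  D <- diffusivity_from_crowding(G, D0 = 1)
  Cs <- seq(0, 0.99, length.out = 50)
  expect_lt(max(abs(D$value(Cs) - (1 + Cs * (1 - Cs / 2)))), 1e-7)
  # finite-difference derivative agrees with a central-difference check
  dfd <- G$derivative(seq(0.1, 0.9, by = 0.1))
  expect_lt(max(abs(dfd - (-1 / 2 - seq(0.1, 0.9, by = 0.1)))), 1e-6)
  # a crowding function with G(1) != 0 is diagnosed near the pole
  Gbad <- crowding_g(function(C) rep(1, length(C)),
                     function(C) rep(0, length(C)), label = "constant")
  expect_warning(diffusivity_from_crowding(Gbad, 1), "G\\(1\\)")
})

test_that("power-law inverse map matches the series oracle and its endpoints", {
  Cs <- seq(0.01, 0.99, by = 0.02)
  for (m in c(1, 2, 3)) {
    expect_lt(max(abs(crowding_from_powerlaw(m, Cs) -
                      oracle_powerlaw_G(m, Cs))), 1e-10,
              label = paste("m =", m))
    expect_identical(crowding_from_powerlaw(m, 0), 0)
    expect_identical(crowding_from_powerlaw(m, 1), 0)
  }
  # non-integer exponent goes through the Euler-transformed series
  expect_lt(max(abs(crowding_from_powerlaw(1.5, Cs) -
                    oracle_powerlaw_G(1.5, Cs))), 1e-10)
  # m = 0 collapses to the linear crowding function
  expect_equal(crowding_from_powerlaw(0, Cs), 1 - Cs)
  # closed-form value at C = 0.5 for m = 1
  expect_equal(crowding_from_powerlaw(1, 0.5), 0.5 * (1 + log(0.5)))
})

test_that("power-law crowding functions round-trip through the forward map", {
  Cs <- seq(0.02, 0.98, length.out = 50)
  for (m in c(1, 2, 3)) {
    pair <- crowding_catalogue(sprintf("powerlaw-m%d", m), D0 = 0.25)
    D <- diffusivity_from_crowding(pair$G, D0 = 0.25)
    expect_lt(max(abs(D$value(Cs) - 0.25 * Cs^m)), 1e-8,
              label = paste("round trip m =", m))
  }
})

test_that("flux correction has the sign of D - D0 and the printed closed forms", {
  Cs <- seq(0, 1, length.out = 101)
  lin <- crowding_catalogue("linear")
  expect_equal(lin$H(Cs), rep(0, length(Cs)))
  inc <- crowding_catalogue("increasing")
  expect_equal(inc$H(Cs), Cs * (1 - Cs / 2))
  expect_true(all(inc$H(Cs) >= 0))
  dec <- crowding_catalogue("decreasing")
  expect_equal(dec$H(1), -0.5)
  expect_true(all(dec$H(Cs) <= 0))
  # sign law across the catalogue: H >= 0 iff D >= D0 pointwise
  for (nm in catalogue_names()) {
    pair <- crowding_catalogue(nm, D0 = 0.7)
    expect_equal(pair$H(Cs) >= 0, pair$D$value(Cs) >= 0.7,
                 label = paste("sign law", nm))
  }
})

test_that("strong Allee growth has the stated roots, signs and extremes", {
  F_fn <- strong_allee_growth(0.4)
  expect_equal(F_fn$value(0), -1)
  expect_equal(F_fn$value(0.4), 0)
  expect_equal(F_fn$value(1), 0)
  expect_equal(F_fn$value(0.7), 0.225)
  Cs <- seq(0, 1, length.out = 401)
  expect_true(all(abs(F_fn$value(Cs)) <= 1))
  expect_true(all(F_fn$value(Cs[Cs < 0.4 & Cs > 0]) < 0))
  expect_true(all(F_fn$value(Cs[Cs > 0.4 & Cs < 1]) > 0))
  # thresholds that would push |F| beyond 1 are probability overflows
  expect_error(strong_allee_growth(0.6), "overflow")
})

test_that("rate constants derive D0 and lambda and warn when growth is fast", {
  rc <- rate_constants(M = 1, P = 0.006)
  expect_equal(rc$D0, 0.25)
  expect_equal(rc$lambda, 0.006)
  rc2 <- rate_constants(M = 0.8, P = 0.05, delta = 2, tau = 0.5)
  expect_equal(rc2$D0, 0.8 * 4 / (4 * 0.5))
  expect_equal(rc2$lambda, 0.1)
  expect_warning(rate_constants(M = 1, P = 0.5), "P << M")
})

test_that("crowding configs serialize and rebuild, with a restricted grammar", {
  for (nm in c("linear", "powerlaw-m2")) {
    pair <- crowding_catalogue(nm, D0 = 0.25)
    cfg <- crowding_config(pair)
    back <- crowding_from_config(cfg)
    Cs <- seq(0, 1, length.out = 21)
    expect_equal(back$G$value(Cs), pair$G$value(Cs))
    expect_equal(back$D$value(Cs), pair$D$value(Cs))
  }
  # expression models evaluate through the restricted grammar only
  pair <- crowding_from_config(list(kind = "expression",
                                    expression = "(1 - C) * (1 + C/2)",
                                    D0 = 1))
  expect_equal(pair$G$value(0.5), 0.625)
  expect_lt(abs(pair$D$value(0.5) - 1.375), 1e-7)
  expect_error(crowding_from_expression("system('ls')"), "not allowed")
  expect_error(crowding_from_expression("x + 1"), "variable C")
})

test_that("tabulation writes the documented columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  tab <- tabulate_crowding("linear", file = f, n = 11)
  expect_named(tab, c("C", "G", "dGdC", "D", "H"))
  back <- read.csv(f)
  expect_equal(back$D, rep(1, 11))
  expect_equal(back$G, 1 - back$C)
})

test_that("invalid movement crowding functions are flagged, not blocked", {
  expect_warning(G <- crowding_g(function(C) 1.5 * (1 - C)), "\\[0, 1\\]")
  expect_false(G$valid)
})
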