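test_that("log-linear interpolation is exact at grid nodes and brackets between them", {
  fat <- kf_material("fat")
  i <- c(3L, 20L, 47L)
  expect_equal(mu_at(fat, fat$energies[i]), fat$mu_total[i])
  mid <- (fat$energies[i] + fat$energies[i + 1L]) / 2
  v <- mu_at(fat, mid)
  lo <- pmin(fat$mu_total[i], fat$mu_total[i + 1L])
  hi <- pmax(fat$mu_total[i], fat$mu_total[i + 1L])
  expect_true(all(v >= lo & v <= hi))
})

test_that("queries outside the tabulated range name the material and bounds", {
  fat <- kf_material("fat")
  expect_error(mu_at(fat, 5), "fat")
  expect_error(mu_at(fat, 200), "outside tabulated range")
})

test_that("exponential fit recovers noiseless parameters to machine precision", {
  e <- seq(14, 34, by = 2)
  a <- 7.3; b <- 0.11
  fit <- fit_exponential(e, a * exp(-b * e))
  expect_equal(fit$amplitude, a, tolerance = 1e-9)
  expect_equal(fit$decay_rate, b, tolerance = 1e-9)
  expect_lt(fit$residual, 1e-10)
  # round-trip: evaluating at the inputs reproduces them within the residual
  expect_equal(predict(fit, e), a * exp(-b * e), tolerance = 1e-9)
})

test_that("fitted decay-rate ordering follows the generating ordering", {
  e <- seq(14, 34, by = 2)
  f_slow <- fit_exponential(e, 5 * exp(-0.05 * e))
  f_fast <- fit_exponential(e, 5 * exp(-0.12 * e))
  expect_lt(f_slow$decay_rate, f_fast$decay_rate)
})

test_that("fit validation rejects degenerate input", {
  expect_error(fit_exponential(c(10, 20), c(1, 0.5)), "at least 3")
  expect_error(fit_exponential(c(10, 20, 20), c(1, 0.5, 0.5)), "at least 3")
  expect_error(fit_exponential(c(10, 20, 30), c(1, -0.5, 0.2)), "positive")
})

test_that("bundled tissue points reproduce an independent log-space regression", {
  pts <- read.csv(extdata_csv("tissue_points_synthetic"))
  for (mat in c("fat", "fibrous")) {
    p <- pts[pts$material == mat, ]
    fit <- fit_exponential(p$energy_keV, p$mu_per_cm)
    # oracle: ordinary least squares on log(mu)
    ols <- lm(log(mu_per_cm) ~ energy_keV, data = p)
    expect_equal(fit$amplitude, exp(unname(coef(ols)[1])), tolerance = 1e-12)
    expect_equal(fit$decay_rate, -unname(coef(ols)[2]), tolerance = 1e-12)
    # extraction at the Kalpha energy matches the oracle's prediction
    expect_equal(predict(fit, 28.46),
                 exp(unname(coef(ols)[1] + coef(ols)[2] * 28.46)),
                 tolerance = 1e-12)
    expect_true(all(is.finite(predict(fit, c(11.20, 12.50, 28.46, 33.29)))))
    expect_true(all(predict(fit, c(11.20, 12.50, 28.46, 33.29)) > 0))
  }
})

test_that("contrast-layer effective coefficient is the loaded iodine mass attenuation", {
  # tumor loading: 0.300 g/cm^3 x 0.56 packing = 0.168 g/cm^3 effective
  iod <- kf_material("iodine")
  expect_equal(iodine_equivalent_mu(40, 0.300, 0.56),
               0.168 * mass_mu_at(iod, 40))
  # fibrous loading gives 0.042 g/cm^3
  expect_equal(iodine_equivalent_mu(40, 0.300, 0.14),
               0.042 * mass_mu_at(iod, 40))
  # linear in concentration
  expect_equal(iodine_equivalent_mu(35, 0.600, 0.14),
               2 * iodine_equivalent_mu(35, 0.300, 0.14))
  expect_error(iodine_equivalent_mu(40, 0.3, 0), "packing_density")
  expect_error(iodine_equivalent_mu(40, -1, 0.5), "concentration")
  expect_error(iodine_equivalent_mu(2, 0.3, 0.5), "outside tabulated range")
})

test_that("photoelectric fraction behaves as a relative probability", {
  pure <- flat_curve(2, mu_pe = 2)
  expect_equal(photoelectric_fraction(pure, c(10, 30, 50)), rep(1, 3))
  iod <- kf_material("iodine")
  # identity at a grid node
  i <- match(40, iod$energies)
  expect_equal(photoelectric_fraction(iod, 40), iod$mu_pe[i] / iod$mu_total[i])
  # falls with energy away from the edge (photoelectric drops faster)
  f <- photoelectric_fraction(iod, c(34, 40, 46, 52))
  expect_true(all(diff(f) < 0))
  expect_true(all(f > 0 & f <= 1))
  expect_error(photoelectric_fraction(kf_material("fat"), 30),
               "no photoelectric")
})

test_that("K-shell fraction is zero below the edge and a proper probability above", {
  expect_identical(kshell_fraction(33.0), 0)
  expect_identical(kshell_fraction(c(10, 20, 33.17)), rep(0, 3))
  e <- seq(33.18, 50, by = 0.5)
  f <- kshell_fraction(e)
  expect_true(all(f > 0 & f < 1))
  # stable under small perturbation just above the edge
  expect_equal(kshell_fraction(33.18), kshell_fraction(33.30),
               tolerance = 0.02)
})

test_that("every bundled material satisfies positivity and component ordering", {
  for (name in c("fat", "fibrous", "tumor", "iodine", "silicon",
                 "aluminium", "gadolinium", "air")) {
    m <- kf_material(name)
    expect_true(all(diff(m$energies) > 0), info = name)
    expect_true(all(m$mu_total > 0), info = name)
    if (!is.null(m$mu_pe)) {
      expect_true(all(m$mu_pe <= m$mu_total * (1 + 1e-9)), info = name)
    }
  }
})

test_that("fat attenuates less than fibrous and tumor at the K-line energies", {
  for (e in c(28.46, 33.29)) {
    mu_f <- mu_at(kf_material("fat"), e)
    expect_lt(mu_f, mu_at(kf_material("fibrous"), e))
    expect_lt(mu_f, mu_at(kf_material("tumor"), e))
  }
})

test_that("constructor validation catches malformed curves", {
  expect_error(attenuation_curve("x", c(10, 9), c(1, 1)), "ascending")
  expect_error(attenuation_curve("x", c(10, 20), c(1, -1)), "positive")
  expect_error(attenuation_curve("x", c(10, 20), c(1, 1), mu_pe = c(2, 2)),
               "exceed")
})

test_that("iodine fluorescence constants are internally consistent", {
  p <- iodine_fluorescence()
  expect_lt(p$e_kalpha, p$k_edge)
  expect_gt(p$e_kbeta1, p$k_edge)
  expect_true(all(unlist(p[c("omega_kalpha", "omega_kbeta", "xi_KL")]) > 0))
  expect_true(all(unlist(p[c("omega_kalpha", "omega_kbeta", "xi_KL")]) <= 1))
})
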