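test_that("Sauerbrey conversion gives the standard quartz constant and scalings", {
  expect_equal(sauerbrey_mass(0, 3), 0)
  ## C = sqrt(rho_q mu_q) / (2 f0^2) ~ 17.7 ng cm^-2 Hz^-1 at 5 MHz
  expect_equal(sauerbrey_mass(-1, 1), 17.67, tolerance = 0.005)
  expect_equal(sauerbrey_mass(-3, 3), sauerbrey_mass(-1, 1))
  df <- c(-0.5, -2, -10)
  expect_equal(sauerbrey_mass(4 * df, 5), 4 * sauerbrey_mass(df, 5))
  expect_error(sauerbrey_mass(-1, 2), "odd")
})

test_that("coverage-to-dG inverts the Langmuir isotherm", {
  ## theta = 0.5 at x = 1e-7: dG = -RT ln(1e7)
  expect_equal(coverage_to_dG(125, 250, 1e-7, 298),
               -8.314462618 * 298 * log(1e7), tolerance = 1e-12)
  expect_lt(coverage_to_dG(125, 250, 1e-7, 298) / 1000, -39)
  ## sign flips as K crosses 1: theta/(1-theta) = x at the crossing
  x <- 1e-4
  th_cross <- x / (1 + x)
  expect_gt(coverage_to_dG(250 * th_cross * 0.9, 250, x, 300), 0)
  expect_lt(coverage_to_dG(250 * th_cross * 1.1, 250, x, 300), 0)
  expect_error(coverage_to_dG(260, 250, 1e-7, 298), "gamma_max")
})

test_that("Langmuir forward then inversion is the identity over the coverage range", {
  theta <- seq(0.01, 0.99, length.out = 50)
  x <- 1.26e-7; gm <- 250; T <- 305
  K <- theta / ((1 - theta) * x)
  dG <- -8.314462618 * T * log(K)
  mass <- gm * K * x / (1 + K * x)
  back <- coverage_to_dG(mass, gm, x, T)
  expect_lt(max(abs(back - dG) / abs(dG)), 1e-9)
})

test_that("noise-free generation round-trips to the generator's dG and classes match at zero barrier", {
  p <- thermo_gen_params(noise_sd = 0)
  tab <- gen_temperature_adsorption(p)
  t_ref <- mean(p$temps)
  for (cls in c("scl", "control")) {
    sub <- tab[tab$class == cls & tab$replicate == "rep1", ]
    dS <- p$dS_intrinsic + if (cls == "scl") p$dS_barrier else 0
    dH <- p$dH + if (cls == "scl") p$dS_barrier * t_ref else 0
    dG_true <- dH - sub$temperature_K * dS
    dG_back <- coverage_to_dG(sub$mass_ng_cm2, p$gamma_max,
                              p$bulk_mole_fraction, sub$temperature_K)
    expect_lt(max(abs(dG_back - dG_true) / abs(dG_true)), 1e-9)
  }
  p0 <- thermo_gen_params(noise_sd = 0, dS_barrier = 0)
  tab0 <- gen_temperature_adsorption(p0)
  scl <- tab0[tab0$surface == "cholesterol_scl", "mass_ng_cm2"]
  ctl <- tab0[tab0$surface == "thiocholesterol_sam", "mass_ng_cm2"]
  expect_equal(scl, ctl)
})

test_that("dG(T) slope fit recovers enthalpy and entropy with the stated signs", {
  T <- seq(288, 313, by = 5)
  exact <- data.frame(temperature_K = T, dG = -40000 + 200 * T)
  ## zero-residual input: silence summary.lm's perfect-fit warning
  sl <- suppressWarnings(fit_dG_slope(exact))
  expect_equal(sl$dH, -40000, tolerance = 1e-9)
  expect_equal(sl$dS, -200, tolerance = 1e-9)
  expect_lt(sl$dS_se, 1e-9)
  ## positive slope means negative adsorption entropy
  expect_lt(sl$dS, 0)

  set.seed(5)
  noisy <- data.frame(temperature_K = rep(T, 3),
                      dG = -40000 + 200 * rep(T, 3) + rnorm(18, 0, 300))
  sn <- fit_dG_slope(noisy)
  expect_lt(abs(sn$dS - (-200)), 3 * sn$dS_se)
  expect_error(fit_dG_slope(data.frame(temperature_K = rep(300, 4),
                                       dG = rnorm(4))), "temperatures")
})

test_that("barrier subtraction and its degenerate cases are exact", {
  expect_equal(entropic_barrier(-150, 50)$barrier, -200)
  expect_equal(entropic_barrier(-7, -7)$barrier, 0)
  b <- entropic_barrier(-150, c(40, 60), se_scl = 3, se_controls = c(4, 4))
  expect_equal(b$barrier, -200)
  expect_equal(b$barrier_se, sqrt(9 + (16 + 16) / 4))
  expect_error(entropic_barrier(-150, numeric(0)), "control")
})

test_that("the full synthetic chain recovers the entropic barrier without bias", {
  for (B in c(-100, -200, -300)) {
    est <- vapply(seq_len(200), function(i) {
      p <- thermo_gen_params(dS_barrier = B, seed = 40000 + i)
      tab <- gen_temperature_adsorption(p)
      barrier_from_table(tab, gamma_max = p$gamma_max,
                         bulk_mole_fraction = p$bulk_mole_fraction)$barrier
    }, 0)
    err <- est - B
    sem <- sd(err) / sqrt(length(err))
    expect_lt(abs(mean(err)), 3 * sem)
    expect_lt(abs(mean(err)), 5)   # and small in absolute terms
  }
})

test_that("geometric entropy estimator follows R ln(area ratio) and is antisymmetric", {
  expect_equal(geometric_entropy(1.3, 1.3)$dS_per_unit, 0)
  g <- geometric_entropy(0.5, 1.0, footprint_units = 1)
  expect_equal(g$dS_per_protein, -8.314462618 * log(2), tolerance = 1e-12)
  expect_equal(g$dS_per_protein, -5.7628, tolerance = 1e-4)
  a <- geometric_entropy(0.38, 1.9)$dS_per_unit
  b <- geometric_entropy(1.9, 0.38)$dS_per_unit
  expect_identical(a, -b)
  ## reconstructed sterol geometry: about -160 J mol^-1 K^-1 per protein
  expect_equal(geometric_entropy()$dS_per_protein, -160, tolerance = 0.005)
  expect_error(geometric_entropy(-1, 2), "areas")
})

test_that("hydrogen-bond equivalents scale linearly and match the worked value", {
  expect_equal(hydrogen_bond_equivalent(0), 0)
  expect_equal(hydrogen_bond_equivalent(-200, 310, 20), 3.1)
  expect_equal(hydrogen_bond_equivalent(-100, 310, 20),
               hydrogen_bond_equivalent(-200, 310, 20) / 2)
})
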