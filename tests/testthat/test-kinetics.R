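test_that("closed-form site decay matches RK4 integration across orders", {
  times <- seq(0, 60, length.out = 25)
  grid <- expand.grid(order = 1:4, k = c(0.05, 0.5), sigma0 = c(0.5, 1, 2))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    exact <- bond_density_solution(times, g$k, g$sigma0, g$order)
    rk4 <- rk4_sigma(times, g$k, g$sigma0, g$order)
    expect_lt(max(abs(exact - rk4) / exact), 1e-8)
  }
})

test_that("site decay honors initial condition, zero rate, and the worked value", {
  expect_equal(bond_density_solution(0, 0.7, 1.3, 3), 1.3)
  expect_equal(bond_density_solution(c(0, 5, 50), 0, 2, 2), rep(2, 3))
  expect_equal(bond_density_solution(3, 0.5, 1, 3), 0.5)
  expect_error(bond_density_solution(1, 0.5, 1, 0), "order")
})

test_that("force model starts at zero, saturates, and is nondecreasing", {
  expect_equal(force_model(0, 3, 0.5, 1, 2), 0)
  expect_equal(force_model(3, 3, 0.5, 1, 2), 1.0)
  expect_lt(force_model(1e6, 3, 0.5, 1, 2), 2)
  expect_gt(force_model(1e6, 3, 0.5, 1, 2), 1.99)
  set.seed(101)
  for (i in 1:25) {
    o <- sample(1:4, 1)
    f <- force_model(seq(0, 100, length.out = 200), o, runif(1, 0.01, 2),
                     runif(1, 0.1, 3), runif(1, 0.5, 5))
    expect_true(all(diff(f) >= -1e-12))
  }
})

test_that("force-curve generator reproduces the closed form and is seeded", {
  p0 <- kinetics_params(noise_cv = 0, seed = 9)
  cur <- gen_adhesion_force_curves(p0)
  expect_equal(cur$force_nN[1], 0)
  mu <- force_model(cur$contact_time_s, p0$order, p0$rate, p0$sigma0,
                    p0$force_scale)
  expect_lt(max(abs(cur$force_nN - mu)[mu > 0] / mu[mu > 0]), 1e-10)
  rk4 <- p0$force_scale * (1 - rk4_sigma(cur$contact_time_s, p0$rate,
                                         p0$sigma0, p0$order) / p0$sigma0)
  expect_equal(cur$force_nN, rk4, tolerance = 1e-8)

  p <- kinetics_params(noise_cv = 0.08, seed = 21)
  a <- gen_adhesion_force_curves(p, n_curves = 3)
  b <- gen_adhesion_force_curves(p, n_curves = 3)
  expect_identical(a, b)
  expect_equal(a$force_nN[a$contact_time_s == 0], rep(0, 3))
  expect_error(gen_adhesion_force_curves(p, times = c(0, 2, 2, 3)),
               "increasing")
})

test_that("fitting recovers the lumped rate exactly from noise-free data", {
  p <- kinetics_params(noise_cv = 0, rate = 0.2, sigma0 = 1.5,
                       force_scale = 2.5)
  cur <- gen_adhesion_force_curves(p)
  fit <- fit_kinetics(cur, 3)
  kappa_true <- p$rate * p$sigma0^2
  expect_lt(abs(fit$kappa - kappa_true) / kappa_true, 1e-6)
  expect_lt(abs(fit$force_scale - 2.5) / 2.5, 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
})

test_that("a zero-force series is flagged as low-information", {
  flat <- data.frame(contact_time_s = 0:10, force_nN = rep(0, 11))
  fit <- fit_kinetics(flat, 3)
  expect_equal(fit$force_scale, 0)
  expect_match(fit$flag, "low-information")
})

test_that("order selection identifies the generating order in exact cases", {
  ## 4-point noise-free order-2 curve: exact class membership
  t4 <- c(0, 5, 15, 40)
  cur2 <- data.frame(contact_time_s = t4,
                     force_nN = force_model(t4, 2, 0.3, 1, 2))
  expect_equal(select_order(cur2, orders = 1:4)$order, 2L)
  ## order-1 data at low noise
  p1 <- kinetics_params(order = 1L, rate = 0.1, noise_cv = 0.01, seed = 4)
  cur1 <- pool_curves(gen_adhesion_force_curves(p1, n_curves = 30))
  expect_equal(select_order(cur1, orders = 1:4)$order, 1L)
})

test_that("pooled AICc selection recovers third-order kinetics reliably", {
  ## one replicate = a pooled 100-curve experiment, 12 contact times 0-60 s
  hits <- 0L
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    p <- kinetics_params(noise_cv = 0.05, seed = 3000 + i)
    cur <- gen_adhesion_force_curves(p, times = seq(0, 60, length.out = 12),
                                     n_curves = 100)
    hits <- hits + (select_order(pool_curves(cur), orders = 1:4)$order == 3L)
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("repeat-force normalization matches its arithmetic definition", {
  const <- data.frame(force_nN = rep(3.2, 16))
  r <- normalize_repeat_forces(const)
  expect_equal(r$normalized$force_norm, rep(1, 16))
  expect_equal(r$cv_by_location$cv, 0)

  two <- data.frame(force_nN = c(1, 3))
  r2 <- normalize_repeat_forces(two)
  expect_equal(r2$normalized$force_norm, c(0.5, 1.5))
  expect_equal(r2$cv_by_location$cv, 0.5)

  expect_error(normalize_repeat_forces(data.frame(force_nN = c(-1, 1))),
               "zero mean")
})

test_that("normalization is idempotent and scale-invariant", {
  set.seed(7)
  x <- data.frame(force_nN = rlnorm(16), location_id = "a", condition = "c")
  r1 <- normalize_repeat_forces(x)
  xs <- x; xs$force_nN <- 37.5 * x$force_nN
  r2 <- normalize_repeat_forces(xs)
  expect_equal(r1$normalized$force_norm, r2$normalized$force_norm)
  again <- x; again$force_nN <- r1$normalized$force_norm
  expect_equal(normalize_repeat_forces(again)$normalized$force_norm,
               r1$normalized$force_norm)
})

test_that("fluctuating surfaces show larger repeat-force dispersion than rigid ones", {
  set.seed(12)
  scl <- data.frame(force_nN = 2 * rlnorm(16 * 4, sdlog = 0.3),
                    location_id = rep(sprintf("scl%d", 1:4), each = 16),
                    condition = "scl")
  sam <- data.frame(force_nN = 2 + rnorm(16 * 4, sd = 0.05),
                    location_id = rep(sprintf("sam%d", 1:4), each = 16),
                    condition = "sam")
  r <- normalize_repeat_forces(rbind(scl, sam))
  cv <- setNames(r$cv_by_condition$cv, r$cv_by_condition$condition)
  expect_gt(cv[["scl"]], cv[["sam"]])
})
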