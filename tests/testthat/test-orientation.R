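test_that("interface selection returns the topmost layer and freezes at the reference", {
  tr <- build_multilayer(rotor_config())
  sel <- select_interface(tr)
  expect_length(sel, 128L)
  expect_true(all(tr$molecules$layer[match(sel, tr$molecules$molecule_id)] == 4L))
  ## cutoff spanning all z selects everything
  expect_length(select_interface(tr, cutoff = 100), 512L)
  ## z-based selection is frozen at the reference frame even if molecules
  ## later swap heights
  zz <- matrix(c(5, 1,
                 1, 5), nrow = 2, byrow = TRUE)
  toy <- make_toy_traj(x = c(1, 2), y = c(1, 1),
                       axes = list(axes_from_tilt(c(0, 0)),
                                   axes_from_tilt(c(0, 0))),
                       head_z = zz)
  expect_equal(select_interface(toy, cutoff = 1), 1L)
})

test_that("tilt angles follow arccos of the z component and are azimuth-invariant", {
  toy <- make_toy_traj(x = 1:3, y = rep(1, 3),
                       axes = list(rbind(c(0, 0, 1), c(1, 0, 0), c(0, 0, -1))))
  a <- tilt_angles(toy, selection = 1:3)
  expect_equal(as.vector(a), c(0, 90, 180))
  set.seed(8)
  for (i in 1:10) {
    u <- matrix(rnorm(30), 10, 3)
    u <- u / sqrt(rowSums(u^2))
    phi <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(phi), -sin(phi), 0), c(sin(phi), cos(phi), 0), c(0, 0, 1))
    t1 <- make_toy_traj(x = 1:10, y = rep(1, 10), axes = list(u))
    t2 <- make_toy_traj(x = 1:10, y = rep(1, 10), axes = list(u %*% t(R)))
    expect_equal(tilt_angles(t1, 1:10), tilt_angles(t2, 1:10),
                 tolerance = 1e-10)
  }
})

test_that("orientation correlation equals the brute-force pair oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    n_frames <- sample(1:5, 1)
    axes <- lapply(seq_len(n_frames), function(f) {
      u <- matrix(rnorm(3 * n), n, 3)
      u / sqrt(rowSums(u^2))
    })
    toy <- make_toy_traj(x = runif(n, 0, 10), y = runif(n, 0, 10),
                         axes = axes, box = c(10, 10, 50))
    cc <- orientation_correlation(toy, selection = seq_len(n),
                                  bin_width = 0.5, max_distance = 5,
                                  windows = 2)
    bf <- brute_force_cr(toy, seq_len(n), 0.5, 5)
    expect_equal(cc$n_pairs, bf$n_pairs)
    expect_equal(cc$c_r, bf$c_r, tolerance = 1e-12)
  }
})

test_that("correlation is 1 for aligned axes, near 0 for isotropic axes, and bounded", {
  n <- 256
  set.seed(3)
  xy <- expand.grid(x = (1:16) - 0.5, y = (1:16) - 0.5)
  aligned <- make_toy_traj(xy$x, xy$y,
                           axes = list(matrix(rep(c(0, 0, 1), each = n), n, 3)),
                           box = c(16, 16, 50))
  ca <- orientation_correlation(aligned, seq_len(n), bin_width = 0.25,
                                max_distance = 4)
  expect_true(all(ca$c_r[ca$n_pairs > 0] == 1))
  expect_true(all(is.na(ca$c_r[ca$n_pairs == 0])))

  u <- matrix(rnorm(3 * n), n, 3); u <- u / sqrt(rowSums(u^2))
  iso <- make_toy_traj(xy$x, xy$y, axes = list(u), box = c(16, 16, 50))
  ci <- orientation_correlation(iso, seq_len(n), bin_width = 0.25,
                                max_distance = 4)
  pop <- ci$n_pairs > 0
  expect_true(all(abs(ci$c_r[pop]) <= 3 / sqrt(ci$n_pairs[pop])))
  expect_true(all(abs(ci$c_r[pop]) <= 1))
})

test_that("decay distance recovers the scale of exponential curves and censors flat ones", {
  for (xi in c(0.3, 0.5, 1, 2)) {
    d <- seq(0.05, 4, by = 0.1)
    curve <- data.frame(bin_center = d, c_r = exp(-d / xi), sd = 0,
                        n_pairs = 100L)
    dd <- decay_distance(curve)
    ## threshold is 1/e of the first bin, so the crossing sits one decay
    ## length beyond the first bin center; recovery within one bin width
    expect_lt(abs(dd - xi), 0.101)
  }
  flat <- data.frame(bin_center = seq(0.05, 3, 0.1), c_r = 0.8, sd = 0,
                     n_pairs = 10L)
  df <- decay_distance(flat)
  expect_true(is.infinite(df))
  expect_true(attr(df, "censored"))
})

test_that("interfacial z-RMSD is zero iff heights equal the reference and tracks shifts", {
  z <- matrix(1, 4, 6)
  static <- make_toy_traj(1:6, rep(1, 6),
                          axes = rep(list(axes_from_tilt(rep(0, 6))), 4),
                          head_z = z)
  r <- interface_z_rmsd(static, selection = 1:6)
  expect_equal(r$rmsd, rep(0, 4))

  z2 <- z; z2[2, ] <- z[2, ] + 0.37
  shifted <- make_toy_traj(1:6, rep(1, 6),
                           axes = rep(list(axes_from_tilt(rep(0, 6))), 4),
                           head_z = z2)
  r2 <- interface_z_rmsd(shifted, selection = 1:6)
  expect_equal(r2$rmsd[2], 0.37)
  expect_true(all((r2$rmsd == 0) == apply(z2 == z2[1, ][col(z2)], 1, all)))

  ## s.e.m. across trajectories
  r3 <- interface_z_rmsd(list(static, shifted), selection = 1:6)
  expect_equal(r3$rmsd[2], 0.185)
  expect_false(any(is.na(r3$sem)))
  expect_error(interface_z_rmsd(static, selection = 99), "selection")
})

test_that("flip detection applies hysteresis correctly", {
  ## monotone recovery: exactly one down-to-up event
  s1 <- make_toy_traj(1, 1, axes = lapply(c(170, 150, 125, 95, 70, 40, 20),
                                          axes_from_tilt))
  f1 <- detect_flips(s1, selection = 1)
  expect_equal(nrow(f1$events), 1L)
  expect_equal(f1$events$direction, "down_to_up")
  expect_equal(f1$recovered_fraction, 1)

  ## oscillation inside the 60-120 band: no events
  s2 <- make_toy_traj(1, 1, axes = lapply(c(61, 119, 65, 115, 62, 118),
                                          axes_from_tilt))
  f2 <- detect_flips(s2, selection = 1)
  expect_equal(nrow(f2$events), 0L)

  ## repeated full swings: every confirmed crossing is an event
  s3 <- make_toy_traj(1, 1, axes = lapply(c(170, 20, 170, 20), axes_from_tilt))
  f3 <- detect_flips(s3, selection = 1)
  expect_equal(nrow(f3$events), 3L)

  expect_error(detect_flips(s1, selection = 1, aligned_threshold = 130,
                            reverted_threshold = 120), "threshold")
})
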