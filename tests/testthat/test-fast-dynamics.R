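test_that("grayscale opening matches the sliding min/max oracle", {
  set.seed(30)
  m <- matrix(rnorm(50 * 50), 50, 50)
  expect_equal(grayscale_opening(m, c(5, 5)), opening_oracle(m, c(5, 5)))
  expect_equal(grayscale_opening(m, c(3, 7)), opening_oracle(m, c(3, 7)))
  cst <- matrix(2.5, 20, 20)
  expect_equal(grayscale_opening(cst, c(5, 5)), cst)
  # anti-extensive on anything
  expect_true(all(grayscale_opening(m, c(5, 5)) <= m))
  expect_error(grayscale_opening(m, c(51, 5)), "dimension error")
  expect_error(grayscale_opening(m, c(4, 4)))
})

test_that("fast component keeps ripples and passes wide slow bumps", {
  # slow bump with support much wider than the 33-frame element
  i <- 1:400
  slow <- 20 * exp(-((i - 200) / 120)^2)
  m_slow <- matrix(rep(slow, each = 50), 50, 400)
  L_Q <- fast_component(m_slow, c(33, 33))
  expect_lt(max(abs(L_Q)), 0.05 * 20)
  # a 300 Hz ripple riding on a gentle bump survives with >= 0.8 amplitude
  dt <- 231e-6
  ii <- 1:140
  gentle <- 8 * exp(-((ii - 70) / 60)^2)
  rip <- 1.5 * sin(2 * pi * 300 * (ii - 1) * dt)
  m2 <- matrix(rep(gentle + rip, each = 50), 50, 140)
  L_Q2 <- fast_component(m2, c(33, 33))
  sig <- L_Q2[25, ]
  bc <- band_components(sig, dt)
  amp <- (max(bc$comp_II[30:110]) - min(bc$comp_II[30:110])) / 2
  expect_gte(amp, 0.8 * 1.5)
  # zero map -> zero fast component
  expect_true(all(fast_component(matrix(0, 40, 40)) == 0))
})

test_that("border signals average the lateral bands", {
  L_Q <- matrix(0, 80, 30)
  bs <- border_signals(L_Q)
  expect_true(all(bs$L_QL == 0) && all(bs$L_QR == 0))
  # symmetric map with mirror-symmetric bands -> identical signals
  sym <- outer(sin(pi * (1:80) / 81), cos(seq(0, 3, length.out = 30)))
  bs2 <- border_signals(sym, bands = list(left = 10:30, right = 51:71))
  expect_equal(bs2$L_QL, bs2$L_QR, tolerance = 1e-10)
  # left-sided ripple -> left band dominates
  left <- matrix(0, 80, 30); left[10:30, ] <- 1
  bs3 <- border_signals(left)
  expect_gt(sum(bs3$L_QL), 10 * sum(bs3$L_QR))
  expect_error(border_signals(L_Q, list(left = 0:5, right = 60:70)),
               "config error")
})

test_that("spectrum maps bins to frequencies and finds pure tones", {
  dt <- 231e-6
  expect_error(deformation_spectrum(rnorm(10), dt), "too-short")
  z <- deformation_spectrum(rep(0, 140), dt)
  expect_true(all(z$magnitude == 0))
  expect_equal(z$freq_hz[1], 0)
  expect_equal(length(z$magnitude), 71)
  # sinusoid exactly on bin 10: (k-1)/(I dt) with k = 10
  f10 <- 9 / (140 * dt)
  x <- sin(2 * pi * f10 * (0:139) * dt)
  sp <- deformation_spectrum(x, dt)
  expect_equal(which.max(sp$magnitude), 10L)
  # 300 Hz lands within the bins-7..15 window
  x300 <- sin(2 * pi * 300 * (0:139) * dt)
  expect_true(which.max(deformation_spectrum(x300, dt)$magnitude) %in% 7:15)
})

test_that("band components split, superpose and are idempotent", {
  dt <- 231e-6
  t <- (0:139) * dt
  # DC-only signal is pure region I
  bc <- band_components(rep(3, 140), dt)
  expect_equal(bc$comp_I, rep(3, 140))
  expect_true(all(abs(bc$comp_II) < 1e-12))
  # a pure in-band tone (on a DFT bin, ~309 Hz, so there is no leakage)
  # is pure region II
  f_II <- 10 / (140 * dt)
  x <- sin(2 * pi * f_II * t)
  bc2 <- band_components(x, dt)
  expect_lt(sqrt(mean((bc2$comp_II - x)^2)) / sqrt(mean(x^2)), 1e-10)
  expect_lt(max(abs(bc2$comp_I)), 1e-10)
  # superposition: slow (bin 3, ~62 Hz) + fast tones recover their addends
  f_I <- 2 / (140 * dt)
  y_slow <- 2 * sin(2 * pi * f_I * t)
  bc3 <- band_components(y_slow + x, dt)
  expect_equal(bc3$comp_I, y_slow, tolerance = 1e-8)
  expect_equal(bc3$comp_II, x, tolerance = 1e-8)
  expect_equal(bc3$comp_I_plus_II, bc3$comp_I + bc3$comp_II)
  # idempotence: re-projecting a component returns it unchanged
  bc4 <- band_components(bc3$comp_II, dt)
  expect_equal(bc4$comp_II, bc3$comp_II, tolerance = 1e-10)
  expect_lt(max(abs(bc4$comp_I)), 1e-10)
})

test_that("band energies never exceed the signal energy", {
  set.seed(31)
  for (k in 1:8) {
    x <- rnorm(140)
    bc <- band_components(x, 231e-6)
    expect_lte(sum(bc$comp_I^2) + sum(bc$comp_II^2), sum(x^2) + 1e-9)
  }
})

test_that("a single injected frequency dominates the fast-map spectrum", {
  dt <- 231e-6
  for (f in c(220, 300, 430)) {
    p <- small_phantom_params(deflection_amplitude = 10,
                              ripple_amplitude = 2, ripple_freq_hz = f,
                              ripple_start = 30, ripple_stop = 120)
    ph <- generate_phantom(p)
    fd <- fast_dynamics(ph$truth$L_TR, frame_interval_s = dt)
    mag <- fd$F_QL$magnitude
    mag[1:3] <- 0                     # ignore DC/opening pedestal
    k <- which.max(mag)
    expect_equal(fd$freq_hz[k], f, tolerance = 0.08)
  }
})
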