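test_that("phantom parameter invariants are enforced", {
  expect_error(phantom_params(deflection_width = 600), "border columns")
  expect_error(phantom_params(ripple_freq_hz = 3000), "Nyquist")
  expect_error(phantom_params(noise_sigma = -1), "noise_sigma")
  expect_error(phantom_params(deflection_onset = 1), "onset")
  expect_error(small_phantom_params(deflection_amplitude = 80), "deeper")
})

test_that("phantom truth satisfies the decomposition identities by construction", {
  p <- small_phantom_params(deflection_amplitude = 12, eyeball_left = 2,
                            eyeball_right = 8, ripple_amplitude = 1)
  ph <- generate_phantom(p)
  tr <- ph$truth
  expect_equal(tr$L_T, tr$L_TO + tr$L_TR, tolerance = 1e-12)
  expect_true(all(tr$L_T[, 1] == 0))
  # borders carry only eyeball motion
  expect_equal(tr$L_T[1, ], tr$L_TO[1, ])
  expect_equal(tr$L_T[192, ], tr$L_TO[192, ])
  # at least 20 undeformed border columns
  expect_true(all(tr$L_TR[c(1:20, 173:192), ] == 0))
})

test_that("a fixed seed reproduces the phantom byte for byte", {
  p <- small_phantom_params(deflection_amplitude = 8, noise_sigma = 0.05,
                            seed = 123)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a$sequence$data, b$sequence$data)
  p2 <- small_phantom_params(deflection_amplitude = 8, noise_sigma = 0.05,
                             seed = 124)
  expect_false(identical(generate_phantom(p2)$sequence$data, a$sequence$data))
})

test_that("static phantoms render a static scene and zero deformation", {
  p <- small_phantom_params(deflection_amplitude = 0, eyeball_left = 0,
                            eyeball_right = 0, noise_sigma = 0)
  ph <- generate_phantom(p)
  expect_true(all(ph$sequence$data[, , 1] == ph$sequence$data[, , 70]))
  expect_true(all(ph$truth$L_T == 0))
})

test_that("closed loop: extracted contour matches truth within tolerance", {
  # noiseless: within 1 px everywhere (both routes)
  p <- small_phantom_params(deflection_amplitude = 15, eyeball_left = 2,
                            eyeball_right = 7, noise_sigma = 0)
  ph <- generate_phantom(p)
  filt <- median_filter_seq(ph$sequence)
  co_c <- extract_edge_canny(filt, refine_on = ph$sequence)
  expect_lt(max(abs(co_c - ph$truth$contour)), 1)
  co_o <- extract_edge_otsu(filt, refine_on = ph$sequence)
  expect_lt(max(abs(co_o - ph$truth$contour)), 1)
  # the two detectors agree within 2 px
  expect_lt(max(abs(co_c - co_o)), 2)
  # noisy: within 2 px at sigma 0.05 after smoothing
  pn <- small_phantom_params(deflection_amplitude = 15, eyeball_left = 2,
                             eyeball_right = 7, noise_sigma = 0.05, seed = 5)
  phn <- generate_phantom(pn)
  fn <- median_filter_seq(phn$sequence)
  con <- smooth_contour(interpolate_contour(
    extract_edge_canny(fn, refine_on = phn$sequence)))
  expect_lt(max(abs(con - phn$truth$contour)), 2)
})

test_that("closed loop: amplitude recovery within the 1% band", {
  p <- small_phantom_params(deflection_amplitude = 40, apex_row = 30,
                            sagitta = 12, noise_sigma = 0)
  ph <- generate_phantom(p)
  rep <- run_pipeline(ph$sequence)
  expect_gte(rep$max_deflection, 0.99 * ph$truth$max_deflection)
  expect_lte(rep$max_deflection, 1.01 * ph$truth$max_deflection)
})

test_that("closed loop: injected ripple is seen at the right frequency and duration", {
  p <- small_phantom_params(deflection_amplitude = 12, eyeball_left = 2,
                            eyeball_right = 6, ripple_amplitude = 2,
                            ripple_freq_hz = 300, ripple_start = 50,
                            ripple_stop = 90, noise_sigma = 0.01, seed = 9)
  ph <- generate_phantom(p)
  rep <- run_pipeline(ph$sequence)
  # spectral argmax over the non-slow bins sits at the ripple frequency
  mag <- pmax(rep$fast$F_QL$magnitude, rep$fast$F_QR$magnitude)
  mag[1:4] <- 0
  expect_true(which.max(mag) %in% 7:15)
  # measured duration reflects the 41-frame gate (the band-limited envelope
  # reads a hard gate several frames short; see the methods vignette)
  expect_gte(rep$features$w3, 20)
  expect_lte(rep$features$w3, 45)
  expect_equal(ph$truth$ripple_duration_frames, 41L)
})

test_that("cohorts are deterministic and separable by construction", {
  coh0 <- generate_cohort(n_eyes = 0)
  expect_equal(nrow(coh0$table), 0L)
  # analysis-free cohorts are cheap and reproducible
  c1 <- generate_cohort(n_eyes = 4, dims = c(200L, 288L, 140L), seed = 3,
                        analyze = FALSE)
  c2 <- generate_cohort(n_eyes = 4, dims = c(200L, 288L, 140L), seed = 3,
                        analyze = FALSE)
  expect_identical(c1$table, c2$table)
  expect_equal(c1$table$class, as.character(1:4))
})
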