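test_that("3-D median filtering matches the brute-force oracle", {
  set.seed(10)
  arr <- array(runif(12 * 11 * 9), dim = c(12, 11, 9))
  s <- image_sequence(arr)
  expect_equal(median_filter_seq(s, c(3, 3, 3))$data,
               median3d_oracle(arr, c(3, 3, 3)))
  expect_equal(median_filter_seq(s, c(5, 5, 5))$data,
               median3d_oracle(arr, c(5, 5, 5)))
  # constants pass through; isolated salt is removed
  cst <- image_sequence(array(0.4, c(5, 5, 5)))
  expect_equal(median_filter_seq(cst)$data, array(0.4, c(5, 5, 5)))
  salt <- array(0, c(7, 7, 7)); salt[4, 4, 4] <- 1
  expect_equal(max(median_filter_seq(image_sequence(salt))$data), 0)
  expect_error(median_filter_seq(cst, c(7, 3, 3)), "dimension error")
})

test_that("Otsu threshold equals exhaustive between-class-variance search", {
  expect_error(otsu_threshold(rep(0.5, 10)), "degenerate")
  two <- c(0, 0, 0, 1, 1, 1)
  thr <- otsu_threshold(two)
  expect_gt(thr, 0); expect_lt(thr, 1)
  expect_true(all(two[two > thr] == 1) && all(two[two <= thr] == 0))
  set.seed(11)
  for (k in 1:20) {
    vals <- c(rnorm(80, 0.25, 0.05), rnorm(60, 0.7, 0.08))
    vals <- pmin(pmax(vals, 0), 1)
    expect_equal(otsu_threshold(vals), otsu_oracle(vals))
  }
  # narrow mode plus one outlier: finite threshold, no crash
  expect_true(is.finite(otsu_threshold(c(rnorm(50, 0.2, 0.01), 0.99))))
  # vectorized per-column route agrees with the scalar function
  set.seed(12)
  fr <- matrix(runif(200 * 8), 200, 8)
  expect_equal(corneadyn:::otsu_threshold_cols(fr),
               apply(fr, 2, otsu_threshold))
})

test_that("erosion-XOR of a filled shape is its 8-connected inner boundary", {
  set.seed(13)
  for (k in 1:5) {
    shape <- matrix(FALSE, 20, 25)
    r0 <- sample(3:8, 1); r1 <- sample(12:18, 1)
    c0 <- sample(3:10, 1); c1 <- sample(15:23, 1)
    shape[r0:r1, c0:c1] <- TRUE
    if (k > 3) shape[sample(20, 30, TRUE) + 20 * (sample(25, 30, TRUE) - 1)] <- TRUE
    er <- corneadyn:::erode_rect_cpp(shape * 1, 3L, 3L)
    xor_b <- shape & !(er == 1)
    expect_equal(xor_b, inner_boundary_oracle(shape))
  }
})

test_that("both edge routes find a flat slab's top row", {
  s <- make_slab_seq(top = 30, bottom = 45)
  par <- edge_params(subpixel = FALSE)
  co_otsu <- extract_edge_otsu(s, par)
  expect_true(all(co_otsu == 30))
  co_canny <- extract_edge_canny(s, par)
  expect_true(all(abs(co_canny - 30) <= 1))
})

test_that("topmost rule reports the cornea above a brighter iris band", {
  s <- make_slab_seq(M = 200, top = 50, bottom = 60, value = 0.7)
  s$data[150:165, , ] <- 1        # iris-like band, brighter than the cornea
  s <- image_sequence(s$data)
  par <- edge_params(subpixel = FALSE)
  expect_true(all(extract_edge_otsu(s, par) <= 60))
  expect_true(all(abs(extract_edge_canny(s, par) - 50) <= 1))
})

test_that("contour validity flags discontinuities and large jumps", {
  co <- matrix(100, 40, 20)
  v <- validate_contour(co)
  expect_true(v$ok)
  expect_equal(v$max_interframe_jump, 0)
  co2 <- co; co2[, 11] <- 112     # one 12-px interframe step
  v2 <- validate_contour(co2)
  expect_false(v2$ok)
  expect_equal(v2$max_interframe_jump, 12)
  co3 <- co; co3[7, 3] <- NA
  v3 <- validate_contour(co3)
  expect_false(v3$ok)
  expect_equal(v3$n_discontinuities, 1L)
  # a 30-px deflection spread over 40 frames keeps per-frame steps small
  ramp <- matrix(rep(100 + 30 * (0:19) / 19, each = 40), 40, 20)
  expect_true(validate_contour(ramp)$ok)
})

test_that("missing columns interpolate; whole-frame failures abort", {
  co <- matrix(rep(50 + sin(seq(0, 3, length.out = 30)) * 5, 4), 30, 4)
  co_na <- co; co_na[c(10, 11), 2] <- NA
  fixed <- interpolate_contour(co_na)
  expect_false(anyNA(fixed))
  expect_lt(max(abs(fixed - co)), 0.2)
  co_bad <- co; co_bad[, 3] <- NA
  expect_error(interpolate_contour(co_bad), "frame 3")
})

test_that("contour smoothing is a true 3x3 median", {
  set.seed(14)
  m <- matrix(runif(25 * 18, 40, 60), 25, 18)
  expect_equal(smooth_contour(m), median2d_oracle(m, c(3, 3)),
               ignore_attr = TRUE)
  cst <- matrix(7, 10, 10)
  expect_equal(smooth_contour(cst), cst, ignore_attr = TRUE)
  spike <- cst; spike[5, 5] <- 12
  expect_equal(smooth_contour(spike), cst, ignore_attr = TRUE)
  expect_error(smooth_contour(matrix(c(1, NA, 3, 4), 2)), "missing")
})

test_that("contour values fall when a bright structure replaces dark rows above nothing below", {
  # adding bright content strictly below the contour leaves it unchanged
  s <- make_slab_seq(M = 100, top = 40, bottom = 55)
  par <- edge_params(subpixel = FALSE)
  before <- extract_edge_canny(s, par)
  s2 <- s$data; s2[80:90, , ] <- 0.9
  after <- extract_edge_canny(image_sequence(s2), par)
  expect_true(all(after <= before))
})
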