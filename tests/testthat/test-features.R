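test_that("pattern and pattern error behave as constructed", {
  N <- 40; I <- 60
  L_TO <- matrix(rep(seq(0, 5, length.out = I), each = N), N, I)
  L_TR <- matrix(0, N, I)
  L_V <- build_pattern(L_TO, L_TR)
  # with zero deflection the pattern is the apex-column eyeball trace
  expect_equal(L_V, matrix(L_TO[round(N / 2), ], N, I, byrow = TRUE),
               ignore_attr = TRUE)
  expect_error(pattern_error(matrix(0, 3, 3), matrix(0, 4, 3)),
               "dimension error")
  L_T <- L_TO + L_TR
  expect_true(all(pattern_error(L_V, L_V) == 0))
  # linearity
  A <- matrix(rnorm(N * I), N, I); B <- matrix(rnorm(N * I), N, I)
  expect_equal(pattern_error(3 * A, 3 * B), 3 * pattern_error(A, B),
               ignore_attr = TRUE)
})

test_that("w1 is the maximum of the error map and shift-invariant", {
  expect_equal(feature_w1(matrix(0, 5, 5)), 0)
  m <- matrix(0, 30, 20); m[12, 7] <- 37.2
  expect_equal(feature_w1(m), 37.2)
  # adding a constant to both L_T and L_V cancels
  L_T <- matrix(rnorm(100), 10, 10); L_V <- matrix(rnorm(100), 10, 10)
  expect_equal(feature_w1(pattern_error(L_T + 5, L_V + 5)),
               feature_w1(pattern_error(L_T, L_V)))
})

test_that("w2 takes the larger spectrum over bins 7..15 only", {
  z <- rep(0, 71)
  expect_equal(feature_w2(z, z), 0)
  FL <- z; FL[10] <- 28.6
  FR <- z; FR[12] <- 11
  expect_equal(feature_w2(FL, FR), 28.6)
  # a spike at bin 5 is outside the window
  F5 <- z; F5[5] <- 100
  expect_equal(feature_w2(F5, z), 0)
  F16 <- z; F16[16] <- 100
  expect_equal(feature_w2(F16, z), 0)
  expect_error(feature_w2(z[1:10], z[1:10]), "too short")
})

test_that("w3 spans the envelope's 80%-of-maximum range", {
  # constant-amplitude quadrature pair over all frames -> w3 = I
  # (carrier on a DFT bin so the endpoint samples stay above threshold)
  I <- 140; dt <- 231e-6
  f_bin <- 10 / (I * dt)
  xl <- tone_burst(f_bin, 1, I)
  xr <- tone_burst(f_bin, 1, I, quadrature = TRUE)
  expect_equal(feature_w3(xl, xr)$frames, I)
  # single-frame spike
  sp <- rep(0, I); sp[77] <- 1
  expect_equal(feature_w3(sp, sp * 0)$frames, 1)
  # all-zero envelope
  expect_equal(feature_w3(rep(0, I), rep(0, I))$frames, 0)
  # boxcar-modulated quadrature burst over frames 40..69 -> 30 +- 1
  for (ph in c(0, 0.9, 2.1)) {
    xl <- tone_burst(300, 40, 69, phase = ph)
    xr <- tone_burst(300, 40, 69, phase = ph, quadrature = TRUE)
    w3 <- feature_w3(xl, xr, frame_interval_s = dt)
    expect_gte(w3$frames, 29); expect_lte(w3$frames, 31)
    expect_equal(w3$ms, w3$frames * dt * 1e3)
  }
})

test_that("Gini impurity matches hand-computed values", {
  expect_equal(gini_impurity(c(1, 1, 2, 2)), 0.5)
  expect_equal(gini_impurity(rep(1, 7)), 0)
  expect_equal(gini_impurity(c(1, 2, 3, 4)), 0.75)
})

test_that("CART reproduces the reference eye table perfectly", {
  tab <- eye_feature_table()
  expect_equal(dim(tab), c(10L, 5L))
  tree <- train_cart(tab[, c("w1", "w2", "w3")], tab$class)
  # pure leaves: every training row classified correctly
  pred <- predict(tree, tab[, c("w1", "w2", "w3")])
  expect_equal(as.integer(pred), tab$class)
  leaves_pure <- function(node) {
    if (node$type == "leaf") return(!node$impure)
    leaves_pure(node$left) && leaves_pure(node$right)
  }
  expect_true(leaves_pure(tree$root))
  # the two reference vectors route to their printed classes
  expect_equal(as.integer(classify(tree, c(48.4, 20.3, 25.1))), 4L)
  expect_equal(as.integer(classify(tree, c(20.2, 28.6, 28.6))), 3L)
})

test_that("CART agrees with rpart on the reference table", {
  skip_if_not_installed("rpart")
  tab <- eye_feature_table()
  tree <- train_cart(tab[, c("w1", "w2", "w3")], tab$class)
  rp <- rpart::rpart(factor(class) ~ w1 + w2 + w3, data = tab,
                     method = "class",
                     control = rpart::rpart.control(minsplit = 2,
                                                    minbucket = 1, cp = -1,
                                                    maxcompete = 0,
                                                    maxsurrogate = 0))
  rp_pred <- as.integer(as.character(predict(rp, tab, type = "class")))
  my_pred <- as.integer(predict(tree, tab[, c("w1", "w2", "w3")]))
  expect_equal(my_pred, rp_pred)
  expect_equal(my_pred, tab$class)
})

test_that("CART degenerate inputs follow the contract", {
  # single class -> single leaf
  t1 <- train_cart(data.frame(x = 1:4), rep("a", 4))
  expect_equal(t1$root$type, "leaf")
  expect_equal(unname(predict(t1, data.frame(x = 99))), "a")
  # two points, two classes -> one split at the midpoint
  t2 <- train_cart(data.frame(x = c(1, 3)), c("a", "b"))
  expect_equal(t2$root$type, "split")
  expect_equal(t2$root$threshold, 2)
  # conflicting duplicates -> impure leaf flagged, majority label
  t3 <- train_cart(data.frame(x = c(1, 1, 1)), c("a", "a", "b"))
  expect_equal(t3$root$type, "leaf")
  expect_true(t3$root$impure)
  expect_equal(t3$root$label, "a")
  expect_error(train_cart(data.frame(x = 1), "a"), "at least 2")
})

test_that("CART achieves zero training error on separable random sets", {
  set.seed(40)
  for (k in 1:5) {
    n <- 24
    cls <- sample(1:3, n, replace = TRUE)
    X <- data.frame(u = cls * 10 + runif(n, -3, 3),
                    v = rnorm(n))
    tree <- train_cart(X, cls)
    expect_equal(as.integer(predict(tree, X)), cls)
  }
})

test_that("trees survive a JSON round trip", {
  tab <- eye_feature_table()
  tree <- train_cart(tab[, c("w1", "w2", "w3")], tab$class)
  path <- file.path(tempdir(), "tree.json")
  tree_to_json(tree, path)
  back <- tree_from_json(path)
  expect_equal(predict(back, tab[, c("w1", "w2", "w3")]),
               predict(tree, tab[, c("w1", "w2", "w3")]))
  expect_equal(back$features, tree$features)
})
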