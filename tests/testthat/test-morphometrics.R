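test_that("slit_length matches direct recomputation", {
  expect_equal(slit_length(c(0, 0), c(0, 0)), 0)
  expect_equal(slit_length(c(0, 0), c(3, 4)), 5)
  set.seed(21)
  for (i in 1:20) {
    a <- runif(2, -50, 50); b <- runif(2, -50, 50)
    expect_equal(slit_length(a, b), sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2))
    expect_identical(slit_length(a, b), slit_length(b, a))
  }
})

test_that("slit_angle follows the undirected + right-plate-complement convention", {
  expect_equal(slit_angle(c(0, 0), c(10, 0), 1),
               c(raw = 0, adjusted = 0))
  expect_equal(slit_angle(c(0, 0), c(0, 10), 4),
               c(raw = 90, adjusted = 90))
  expect_equal(slit_angle(c(0, 0), c(1, 1), 5),
               c(raw = 45, adjusted = 135))
  # invariant to swapping start and end
  set.seed(22)
  for (i in 1:20) {
    a <- runif(2, -10, 10); b <- runif(2, -10, 10)
    k <- sample(1:6, 1)
    expect_equal(slit_angle(a, b, k), slit_angle(b, a, k), tolerance = 1e-10)
  }
  expect_error(slit_angle(c(1, 1), c(1, 1), 2), "degenerate")
})

test_that("plate widths come from the fixed 1-based point pairs", {
  # three vertical slits per plate: left at x = 0, 10, 20; right at
  # x = 100, 110, 120; every slit spans y in [0, 50]
  vertical <- function(xs) {
    do.call(rbind, lapply(xs, function(x) rbind(c(x, 0), c(x, 50))))
  }
  lm <- rbind(vertical(c(0, 10, 20)), vertical(c(100, 110, 120)))
  w <- plate_widths(lm)
  expect_equal(unname(w), c(20, 20, 20, 20, 120, 80))

  # all points collinear on the x-axis at unit spacing
  lm2 <- cbind(1:12, 0)
  w2 <- plate_widths(lm2)
  expect_equal(w2[["wideL"]], 4)
  expect_equal(w2[["narrow"]], 2)

  # mirror reflection leaves all six widths unchanged
  lm3 <- random_landmarks()
  refl <- cbind(-lm3[, 1], lm3[, 2])
  expect_equal(plate_widths(refl), plate_widths(lm3))
})

test_that("extract_features populates all 27 variables consistently", {
  vertical <- function(xs) {
    do.call(rbind, lapply(xs, function(x) rbind(c(x, 0), c(x, 50))))
  }
  lm <- rbind(vertical(c(0, 10, 20)), vertical(c(100, 110, 120)))
  tab <- as_specimen_table(specimen_row("v", lm = lm))
  f <- extract_features(tab)
  expect_equal(unlist(f[paste0("length", 1:6)]), rep(50, 6),
               ignore_attr = TRUE)
  expect_equal(f$totalSlitLength, 300)
  expect_equal(unlist(f[paste0("angle", 1:6)]), rep(90, 6),
               ignore_attr = TRUE)
  expect_equal(f$total_within, 80)
  expect_equal(f$total_between, 200)
  expect_equal(f$ratio_within, 1)
  expect_equal(f$ratio_between, 1.5)
  nf <- length(feature_names())
  expect_equal(names(f)[(ncol(f) - nf + 1):ncol(f)], feature_names())
})

test_that("features are invariant under rigid motions and scale correctly", {
  set.seed(23)
  for (i in 1:5) {
    lm <- random_landmarks()
    tab <- as_specimen_table(specimen_row("r", lm = lm))
    f0 <- extract_features(tab)

    ang <- runif(1, 0, 360); shift <- runif(2, -100, 100)
    lm2 <- rigid_transform(lm, ang, shift)
    tab2 <- as_specimen_table(specimen_row("r", lm = lm2))
    f1 <- extract_features(tab2, axis = ang)
    expect_equal(as.numeric(f1[feature_names()]),
                 as.numeric(f0[feature_names()]), tolerance = 1e-9)

    # uniform scaling: lengths/widths scale, angles and ratios do not
    s <- runif(1, 0.5, 3)
    tab3 <- as_specimen_table(specimen_row("r", lm = lm * s))
    f2 <- extract_features(tab3)
    expect_equal(f2$length1, s * f0$length1, tolerance = 1e-9)
    expect_equal(f2$narrow, s * f0$narrow, tolerance = 1e-9)
    expect_equal(f2$angle4, f0$angle4, tolerance = 1e-9)
    expect_equal(f2$ratio_between, f0$ratio_between, tolerance = 1e-9)
    # ... equivalently, the scale argument applied to distances
    f3 <- extract_features(tab, scale = s)
    expect_equal(f3$length1, s * f0$length1, tolerance = 1e-12)
  }
})

test_that("total slit length is the exact sum and degenerate ratios are NA", {
  set.seed(24)
  lm <- random_landmarks()
  tab <- as_specimen_table(specimen_row("t", lm = lm))
  f <- extract_features(tab)
  expect_identical(f$totalSlitLength,
                   sum(as.numeric(f[paste0("length", 1:6)])))

  # zero narrow between-plate width: point 8 placed on point 6
  lm[8, ] <- lm[6, ]
  tab2 <- as_specimen_table(specimen_row("t", lm = lm))
  f2 <- extract_features(tab2)
  expect_true(is.na(f2$ratio_between))
  expect_false(is.infinite(f2$ratio_between))
})
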