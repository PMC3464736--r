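test_that("labeling follows 8-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE          # diagonal touch: one component
  cs <- label_components(m)
  expect_equal(nrow(cs$stats), 1L)
  expect_equal(cs$stats$area, 2L)

  m2 <- matrix(FALSE, 5, 5)
  m2[2, 2] <- TRUE; m2[2, 4] <- TRUE        # one-pixel gap: two components
  cs2 <- label_components(m2)
  expect_equal(nrow(cs2$stats), 2L)
  # raster order: (2,2) before (2,4)
  expect_identical(cs2$labels[2, 2], 1L)
  expect_identical(cs2$labels[2, 4], 2L)

  expect_equal(nrow(label_components(matrix(FALSE, 3, 3))$stats), 0L)
})

test_that("labeling matches the flood-fill oracle on random masks", {
  set.seed(31)
  for (i in 1:12) {
    m <- matrix(runif(64 * 64) < runif(1, 0.15, 0.5), 64, 64)
    cs <- label_components(m)
    expect_identical(cs$labels, flood_fill_labels(m))
  }
})

test_that("components partition the foreground", {
  set.seed(5)
  m <- matrix(runif(80 * 60) < 0.3, 80, 60)
  cs <- label_components(m)
  expect_equal(sum(cs$stats$area), sum(m))
  expect_identical(cs$labels > 0L, m)
  expect_identical(cs$stats$label, seq_len(nrow(cs$stats)))
})

test_that("central moments match direct summation; degenerate shapes", {
  expect_equal(central_moments(cbind(4, 7)), c(mu20 = 0, mu02 = 0, mu11 = 0))
  # horizontal run of 3 pixels: spread along columns only
  run <- cbind(rep(2, 3), 1:3)
  expect_equal(central_moments(run), c(mu20 = 0, mu02 = 2, mu11 = 0))

  set.seed(17)
  for (i in 1:10) {
    pix <- unique(cbind(sample(1:30, 40, TRUE), sample(1:30, 40, TRUE)))
    expect_equal(central_moments(pix), moments_bruteforce(pix))
  }
})

test_that("eccentricity has the documented degenerate values and range", {
  expect_equal(moment_eccentricity(0, 0, 0), 0)          # single pixel
  line <- central_moments(cbind(rep(5, 8), 1:8))         # straight segment
  expect_equal(moment_eccentricity(line[1], line[2], line[3]), 1)
  diag_line <- central_moments(cbind(1:9, 1:9))          # 45-degree segment
  expect_equal(moment_eccentricity(diag_line[1], diag_line[2], diag_line[3]), 1)
  set.seed(3)
  e <- moment_eccentricity(runif(50, 0, 9), runif(50, 0, 9), runif(50, -3, 3))
  expect_true(all(e >= 0 & e <= 1))
})

test_that("rasterized ellipses recover the closed-form eccentricity", {
  for (ratio in c(2, 5, 10)) {
    pix <- rasterize_ellipse(c(100, 100), 50, 50 / ratio, angle = 0.4)
    mu <- central_moments(pix)
    expect_equal(moment_eccentricity(mu[1], mu[2], mu[3]),
                 sqrt(1 - 1 / ratio^2), tolerance = 0.02)
  }
  disk <- rasterize_ellipse(c(50, 50), 25, 25)
  mu <- central_moments(disk)
  expect_lte(moment_eccentricity(mu[1], mu[2], mu[3]), 0.1)
})

test_that("moments and eccentricity are translation invariant; rotation by 90 degrees swaps axes", {
  set.seed(23)
  m <- matrix(FALSE, 40, 40)
  m[cbind(sample(5:20, 30, TRUE), sample(5:20, 30, TRUE))] <- TRUE
  st <- label_components(m)$stats

  shifted <- matrix(FALSE, 40, 40)
  shifted[6:40, 11:40] <- m[1:35, 1:30]
  st2 <- label_components(shifted)$stats
  expect_equal(st2$mu20, st$mu20)
  expect_equal(st2$mu02, st$mu02)
  expect_equal(st2$mu11, st$mu11)
  expect_equal(st2$eccentricity, st$eccentricity)

  rot <- t(m)[, rev(seq_len(nrow(m)))]    # 90-degree rotation
  pix_m <- which(m, arr.ind = TRUE)
  pix_r <- which(rot, arr.ind = TRUE)
  mu_m <- moments_bruteforce(pix_m)
  mu_r <- moments_bruteforce(pix_r)
  expect_equal(mu_r[["mu20"]], mu_m[["mu02"]])
  expect_equal(mu_r[["mu02"]], mu_m[["mu20"]])
  expect_equal(moment_eccentricity(mu_r[1], mu_r[2], mu_r[3]),
               moment_eccentricity(mu_m[1], mu_m[2], mu_m[3]))
})

test_that("elongation is monotone in the axis ratio", {
  e <- vapply(seq(10, 40, by = 10), function(a) {
    mu <- central_moments(rasterize_ellipse(c(80, 80), a, 8, angle = 1.1))
    moment_eccentricity(mu[1], mu[2], mu[3])
  }, numeric(1))
  expect_true(all(diff(e) > 0))
})

test_that("component_pixels returns the pixels of one component", {
  m <- matrix(FALSE, 6, 6); m[2:3, 2:3] <- TRUE; m[6, 6] <- TRUE
  cs <- label_components(m)
  expect_equal(nrow(component_pixels(cs, 1L)), 4L)
  expect_equal(component_pixels(cs, 2L)[1, ], c(row = 6L, col = 6L))
})
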