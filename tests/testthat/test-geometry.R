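test_that("box-diagonal Feret reproduces the worked oval and Pythagorean cases", {
  expect_equal(feretBoxdiag(15, 17), sqrt(15^2 + 17^2))
  expect_equal(round(feretBoxdiag(15, 17), 1), 22.7)
  expect_lt(abs(feretBoxdiag(15, 17) - 22.6), 0.1)
  expect_equal(feretBoxdiag(3, 4), 5)
  expect_error(feretBoxdiag(0, 4), "extents")
  expect_error(feretBoxdiag(3, -1), "extents")
})

test_that("rotating calipers equal the brute-force hull-pair oracle exactly", {
  for (seed in 1:120) {
    set.seed(seed)
    pts <- matrix(rnorm(2 * sample(3:80, 1)), ncol = 2)
    hull <- afmchrom:::convexHull(pts)
    expect_equal(afmchrom:::feretMaxCalipers(hull),
                 afmchrom:::feretMaxBruteForce(pts), tolerance = 1e-12)
  }
})

test_that("a rasterized square has caliper max s*sqrt(2) and min width s", {
  s <- 21
  m <- Topograph(matrix(0, 40, 40))
  z <- m@heights
  z[10:(10 + s - 1), 10:(10 + s - 1)] <- 2
  sq <- analyzeTopograph(Topograph(z), flatten = FALSE)
  expect_equal(sq$feret_max_nm, s * sqrt(2), tolerance = 0.08)
  expect_equal(sq$feret_min_nm, s, tolerance = 0.08)
})

test_that("the vectorized 3x3 median filter matches a direct median", {
  set.seed(7)
  z <- matrix(rnorm(25 * 31), 25, 31)
  ref <- matrix(0, 25, 31)
  pad <- rbind(z[1, ], z, z[25, ])
  pad <- cbind(pad[, 1], pad, pad[, 31])
  for (i in 1:25) for (j in 1:31)
    ref[i, j] <- median(pad[i:(i + 2), j:(j + 2)])
  expect_equal(afmchrom:::medianFilter3(z), ref)
})
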