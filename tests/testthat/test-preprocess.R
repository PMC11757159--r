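test_that("an exact plane is recovered to numerical precision", {
  z <- outer(1:32, 1:32, function(i, j) 1 + 0.01 * j + 0.02 * i)
  fl <- flattenPlane(Topograph(z))
  expect_lt(max(abs(heights(fl$topograph))), 1e-9)
  # flat zero grid: unchanged, zero plane
  f0 <- flattenPlane(Topograph(matrix(0, 20, 20)))
  expect_identical(heights(f0$topograph), matrix(0, 20, 20))
  expect_equal(unname(f0$report$plane), c(0, 0, 0))
})

test_that("flattening preserves peak-above-background within 2%", {
  t0 <- diskTopograph(10, 2.5, side = 64)   # dome covers < 5% of pixels
  z <- heights(t0) + outer(1:64, 1:64, function(i, j) 0.4 + 0.008 * j - 0.005 * i)
  fl <- flattenPlane(Topograph(z))
  bg <- estimateBackground(fl$topograph)
  expect_equal(max(heights(fl$topograph)) - bg$level, 2.5, tolerance = 0.02)
})

test_that("flattening is idempotent", {
  set.seed(3)
  z <- outer(1:48, 1:48, function(i, j) 0.01 * j - 0.02 * i) +
    matrix(rnorm(48^2, 0, 0.05), 48, 48)
  f1 <- flattenPlane(Topograph(z))
  f2 <- flattenPlane(f1$topograph)
  expect_lt(max(abs(heights(f2$topograph) - heights(f1$topograph))), 1e-6)
})

test_that("scan-line alignment removes constructed row offsets", {
  # realistic scan widths: the per-row median estimator needs enough
  # background pixels for its own noise to sit below background sd / 10
  set.seed(4)
  z <- matrix(rnorm(96 * 1024, 0, 0.03), 96, 1024)
  z[seq(2, 96, 2), ] <- z[seq(2, 96, 2), ] + 0.3  # even rows offset
  al <- alignLines(Topograph(z))
  rowMed <- apply(heights(al), 1, median)
  expect_lt(max(abs(rowMed)), 0.01)
  # near-idempotence on already-aligned data
  al2 <- alignLines(al)
  expect_lt(max(abs(heights(al2) - heights(al))),
            estimateBackground(al)$sd / 10 + 1e-9)
})

test_that("background level and sd come from the histogram mode", {
  set.seed(5)
  tN <- Topograph(matrix(rnorm(64^2, 0, 0.05), 64, 64))
  bg <- estimateBackground(tN)
  expect_lt(abs(bg$level), 0.01)
  expect_lt(abs(bg$sd - 0.05), 0.01)
  # all-zero field
  bg0 <- estimateBackground(Topograph(matrix(0, 16, 16)))
  expect_equal(bg0$level, 0)
  expect_equal(bg0$sd, 0)
  # 20% particle pixels at ~2 nm do not shift the mode
  z <- matrix(rnorm(64^2, 0, 0.05), 64, 64)
  pick <- sample(length(z), round(0.2 * length(z)))
  z[pick] <- rnorm(length(pick), 2, 0.2)
  bgm <- estimateBackground(Topograph(z))
  expect_lt(abs(bgm$level), 0.02)
})

test_that("measured particle heights are invariant to the background tilt", {
  f0 <- presetField("H3_async", nParticles = 30, seed = 21,
                    noise_sd_nm = 0.05)
  m0 <- analyzeTopograph(f0$topograph)
  zT <- heights(f0$topograph) +
    outer(seq_len(nrow(heights(f0$topograph))),
          seq_len(ncol(heights(f0$topograph))),
          function(i, j) 2 + 0.004 * j - 0.006 * i)
  mT <- analyzeTopograph(Topograph(zT, pixelSize(f0$topograph)))
  expect_equal(nrow(mT), nrow(m0))
  expect_lt(max(abs(sort(mT$height_nm) / sort(m0$height_nm) - 1)), 0.02)
})
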