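test_that("straight and diagonal runs have analytic chain-code lengths", {
  m <- matrix(FALSE, 32, 120)
  m[16, 6:105] <- TRUE                    # 100 px horizontal run
  tr <- traceContour(m, 0.5)
  expect_equal(tr$contour_nm, 99 * 0.5)   # n - 1 steps
  md <- matrix(FALSE, 64, 64)
  for (i in 10:59) md[i, i] <- TRUE       # 50 px diagonal
  trd <- traceContour(md, 1)
  expect_equal(trd$contour_nm, 49 * sqrt(2))
})

test_that("contour-to-bp conversion is exact, linear and invertible", {
  expect_equal(contourToBp(53.0), 156L)
  expect_equal(contourToBp(0), 0L)
  expect_equal(contourToBp(147 * 0.34), 147L)
  bp <- sample.int(500, 25)
  expect_equal(contourToBp(bp * 0.34), as.integer(bp))
  expect_equal(contourToBp(bp * 0.5, rise_per_bp = 0.5), as.integer(bp))
  expect_error(contourToBp(-1), ">= 0")
})

test_that("planted 53-nm chains are traced within 10% across seeds", {
  lens <- vapply(1:20, function(s) {
    set.seed(s)
    cv <- Topograph(matrix(0, 200, 200))
    sp <- filamentSpec(53, theta0 = stats::runif(1, 0, 2 * pi),
                       start_nm = c(100, 100))
    cv <- afmchrom:::renderFilamentPath(sampleWlcFilament(sp, 1), 0.5, cv)
    tr <- traceContour(segmentFilaments(cv), 1)
    sum(tr$contour_nm)
  }, numeric(1))
  expect_lt(abs(mean(lens) / 53 - 1), 0.10)
})

test_that("every trace is at least as long as its end-to-end distance", {
  f <- presetField("freeDNA", nFilaments = 15, seed = 23, noise_sd_nm = 0.05)
  tr <- traceFilaments(f$topograph)
  expect_true(all(tr$contour_nm >= tr$end_to_end_nm - 1e-9))
})

test_that("a filament occluded by a nucleosome splits into two components", {
  cv <- Topograph(matrix(0, 120, 120))
  path <- cbind(seq(10.5, 109.5, by = 1), rep(60.5, 100))
  cv <- afmchrom:::renderFilamentPath(path, 0.5, cv)
  cv <- renderParticle(nucleosomeSpec(c(60.5, 60.5), 2.5, 12), cv)
  det <- detectParticles(cv)
  mask <- segmentFilaments(cv, particleLabels = det$labels)
  lab <- afmchrom:::labelMask8(mask)
  expect_gte(max(lab), 2L)
  tr <- traceContour(mask, 1)
  expect_gte(nrow(tr), 2L)
})

test_that("an ensemble of planted filaments is recovered without length bias", {
  f <- presetField("freeDNA", nFilaments = 40, seed = 29, noise_sd_nm = 0.05)
  tr <- traceFilaments(f$topograph)
  expect_equal(nrow(tr), 40L)
  se <- sd(f$truth$bp) / sqrt(nrow(f$truth))
  expect_lt(abs(mean(tr$bp) - mean(f$truth$bp)), 3 * se)
})

test_that("empty fields segment to an empty mask", {
  mask <- segmentFilaments(Topograph(matrix(0, 32, 32)))
  expect_false(any(mask))
  expect_equal(nrow(traceContour(mask, 1)), 0L)
})
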