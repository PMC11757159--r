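test_that("a dome peak renders exactly at its center and composes by maximum", {
  t0 <- Topograph(matrix(0, 64, 64))
  t1 <- renderParticle(nucleosomeSpec(c(31.5, 31.5), 2.5, 12), t0)
  expect_equal(max(heights(t1)), 2.5)
  # overlap: pointwise maximum of the individual bumps (occlusion)
  sA <- nucleosomeSpec(c(28.5, 31.5), 2.0, 12)
  sB <- nucleosomeSpec(c(34.5, 31.5), 3.0, 12)
  both <- renderParticle(sB, renderParticle(sA, t0))
  expect_equal(heights(both),
               pmax(heights(renderParticle(sA, t0)),
                    heights(renderParticle(sB, t0))))
})

test_that("a rendered complex footprint carries the planted box-diagonal Feret", {
  t0 <- Topograph(matrix(0, 96, 96))
  tc <- renderParticle(complexSpec(c(48.5, 48.5), 5.8, 27.4,
                                   roundness = 0.79, theta = 0.4), t0)
  m <- analyzeTopograph(tc, flatten = FALSE)
  expect_equal(nrow(m), 1L)
  expect_equal(m$height_nm, 5.8, tolerance = 1e-6)
  expect_equal(m$feret_boxdiag_nm, 27.4, tolerance = 1 / 27.4)  # +/- 1 px
})

test_that("particle specs reject non-physical dimensions", {
  expect_error(nucleosomeSpec(c(0, 0), -1, 12), "> 0")
  expect_error(nucleosomeSpec(c(0, 0), 2, 12, axisRatio = 1.4), "0, 1")
  expect_error(complexSpec(c(0, 0), 5.8, 0), "> 0")
  expect_error(complexSpec(c(0, 0), 5.8, 27, nVertices = 12), "4 and 8")
  expect_error(filamentSpec(-3), "> 0")
})

test_that("worm-like-chain sampling satisfies rigid-rod and Kratky-Porod limits", {
  # rigid rod: zero angular variance
  p <- sampleWlcFilament(filamentSpec(53, persistence_nm = 1e12), 1)
  expect_equal(sqrt(sum((p[nrow(p), ] - p[1, ])^2)), 53, tolerance = 1e-6)
  # Monte-Carlo mean-squared end-to-end vs the 2-D closed form
  set.seed(42)
  L <- 53; P <- 50
  r2 <- replicate(1000, {
    pa <- sampleWlcFilament(filamentSpec(L, persistence_nm = P), 1)
    sum((pa[nrow(pa), ] - pa[1, ])^2)
  })
  closed <- 4 * P * L - 8 * P^2 * (1 - exp(-L / (2 * P)))
  expect_lt(abs(mean(r2) / closed - 1), 0.05)
  # below two segments is rejected
  expect_error(sampleWlcFilament(filamentSpec(0.5), 1), "two segments")
})

test_that("field rendering is deterministic with complete ground truth", {
  fs <- fieldSpec(seed = 5, preset = "CENPA_async", nParticles = 20,
                  noise_sd_nm = 0.05)
  f1 <- renderField(fs)
  f2 <- renderField(fs)
  expect_identical(heights(f1$topograph), heights(f2$topograph))
  expect_equal(nrow(f1$truth), 20L)
  expect_true(all(f1$truth$kind == "nucleosome"))
  expect_identical(f1$truth, f2$truth)
  expect_equal(topoMeta(f1$topograph)$seed, 5L)
  # empty field: all zero
  f0 <- renderField(fieldSpec(seed = 1))
  expect_true(all(heights(f0$topograph) == 0))
  expect_equal(nrow(f0$truth), 0L)
})

test_that("noise-, tilt- and tip-free fields peak exactly at the tallest planted object", {
  f <- presetField("CENPA_async", nParticles = 25, seed = 9,
                   noise_sd_nm = 0)
  expect_equal(max(heights(f$topograph)), max(f$truth$height_nm))
})

test_that("planted heights follow the preset distribution across seeds", {
  pr <- afmPresets("CENPA_async")
  h <- unlist(lapply(1:10, function(s)
    renderField(fieldSpec(seed = s, preset = "CENPA_async",
                          nParticles = 50))$truth$height_nm))
  se <- pr$height_sd / sqrt(length(h))
  expect_lt(abs(mean(h) - pr$height_mean), 3 * se)
  expect_lt(abs(sd(h) - pr$height_sd), 3 * pr$height_sd / sqrt(2 * length(h)))
})

test_that("tip dilation broadens footprints but preserves wide-feature peaks", {
  t0 <- diskTopograph(12, 2.5)
  expect_identical(heights(applyTipDilation(t0, 0)), heights(t0))
  td <- applyTipDilation(t0, 3.5)
  expect_true(all(heights(td) >= heights(t0)))
  expect_equal(max(heights(td)), max(heights(t0)), tolerance = 1e-9)
  m0 <- analyzeTopograph(t0, flatten = FALSE)
  md <- analyzeTopograph(td, flatten = FALSE)
  expect_gt(md$feret_max_nm, m0$feret_max_nm)
  # double dilation dominates single dilation pointwise (not idempotent)
  tdd <- applyTipDilation(td, 3.5)
  expect_true(all(heights(tdd) >= heights(td)))
  expect_gt(sum(heights(tdd) - heights(td)), 0)
})

test_that("cryo-EM heights convert to in-air AFM predictions", {
  expect_equal(cryoemToAfmHeight(9.3), 4.65)
  expect_equal(cryoemToAfmHeight(0), 0)
  expect_equal(cryoemToAfmHeight(5.0, 0.5), 2.5)
  expect_error(cryoemToAfmHeight(5, 0), "attenuation")
  expect_error(cryoemToAfmHeight(5, 1.2), "attenuation")
  expect_error(cryoemToAfmHeight(-1), ">= 0")
})

test_that("unknown presets are rejected with the available names", {
  expect_error(afmPresets("NOPE"), "CENPA_async")
  expect_error(fieldSpec(seed = 1, preset = "NOPE"), "available")
})
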