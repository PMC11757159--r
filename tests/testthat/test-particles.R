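test_that("well-separated planted domes are each detected at their centers", {
  f <- presetField("CENPA_async", nParticles = 10, seed = 31,
                   noise_sd_nm = 0)
  det <- detectParticles(f$topograph)
  expect_equal(length(det$regions), 10L)
  m <- analyzeTopograph(f$topograph, flatten = FALSE)
  ord <- order(m$x_nm)
  tru <- f$truth[order(f$truth$x_nm), ]
  expect_true(all(abs(m$x_nm[ord] - tru$x_nm) <= 1))
  expect_true(all(abs(m$y_nm[ord] - tru$y_nm) <= 1))
  # per-particle height error < 1% on the noise-free field
  expect_lt(max(abs(m$height_nm[ord] / tru$height_nm - 1)), 0.01)
})

test_that("an empty flat field yields no detections", {
  det <- detectParticles(Topograph(matrix(0, 64, 64)))
  expect_equal(length(det$regions), 0L)
})

test_that("border-touching particles are flagged and excluded by default", {
  t0 <- renderParticle(nucleosomeSpec(c(2.5, 32.5), 2.5, 12),
                       Topograph(matrix(0, 64, 64)))
  det <- detectParticles(t0)
  expect_true(any(det$border))
  m <- analyzeTopograph(t0, flatten = FALSE)
  expect_equal(nrow(m), 0L)
  mKeep <- analyzeTopograph(t0, flatten = FALSE, keepBorder = TRUE)
  expect_true(all(mKeep$border_flag))
})

test_that("a rasterized disk measures its planted height, diameter and roundness", {
  d12 <- analyzeTopograph(diskTopograph(12, 2.5), flatten = FALSE)
  expect_equal(d12$height_nm, 2.5)
  expect_equal(d12$feret_max_nm, 12, tolerance = 1 / 12)
  expect_gte(d12$roundness, 0.95)
  d40 <- analyzeTopograph(diskTopograph(40, 2.5), flatten = FALSE)
  expect_lt(abs(d40$roundness - 1), 0.05)
})

test_that("a 2:1 ellipse has roundness one half", {
  e <- analyzeTopograph(diskTopograph(40, 2.5, axisRatio = 0.5, theta = 0.7),
                        flatten = FALSE)
  expect_equal(e$roundness, 0.5, tolerance = 0.1)
  expect_lt(abs(e$roundness - 0.5), 0.05)
})

test_that("classification gates separate nucleosomes, complexes and debris", {
  row <- function(h, bd, area, npx = 50)
    data.frame(particle_id = 1L, x_nm = 0, y_nm = 0, height_nm = h,
               area_nm2 = area, feret_max_nm = bd * 0.8, feret_min_nm = bd * 0.6,
               feret_boxdiag_nm = bd, eqdiam_nm = 2 * sqrt(area / pi),
               roundness = 0.8, npx = npx, class_label = "unclassified",
               border_flag = FALSE)
  expect_equal(classifyParticles(row(5.8, 27.4, 629))$class_label, "complex")
  expect_equal(classifyParticles(row(2.7, 15.7, 130))$class_label, "nucleosome")
  expect_equal(classifyParticles(row(0.4, 8, 20))$class_label, "debris")
  # tall but tiny junk is not a complex
  expect_equal(classifyParticles(row(5.0, 10, 60))$class_label, "debris")
})

test_that("population summaries partition by ground-truth class when gates match", {
  specs <- c(
    lapply(1:4, function(i)
      nucleosomeSpec(c(40 + 80 * (i - 1) + 0.5, 40.5), 1.8, 12.4,
                     axisRatio = 0.8)),
    lapply(1:4, function(i)
      complexSpec(c(40 + 80 * (i - 1) + 0.5, 140.5), 5.8, 27.4,
                  roundness = 0.79, theta = i / 3))
  )
  fs <- fieldSpec(width_px = 360, height_px = 200, seed = 2,
                  contents = specs, noise_sd_nm = 0.02)
  f <- renderField(fs)
  m <- analyzeTopograph(f$topograph)
  expect_equal(sum(m$class_label == "nucleosome"), 4L)
  expect_equal(sum(m$class_label == "complex"), 4L)
  sm <- summarizePopulation(m)
  expect_setequal(unique(sm$class), c("nucleosome", "complex"))
  expect_equal(sm$n[sm$class == "complex" & sm$metric == "height_nm"], 4L)
  # single-particle degenerate summary
  s1 <- summarizePopulation(m[1, ])
  expect_equal(s1$sd[s1$metric == "height_nm"], 0)
  expect_equal(s1$n[s1$metric == "height_nm"], 1L)
})

test_that("Feret ordering holds on random pixel blobs", {
  for (seed in 1:150) {
    ctr <- randomBlob(sample(4:100, 1), seed)
    if (nrow(ctr) < 4) next
    hull <- afmchrom:::convexHull(afmchrom:::footprintHullPoints(ctr, 1))
    fmax <- afmchrom:::feretMaxCalipers(hull)
    fmin <- afmchrom:::feretMinCalipers(hull)
    pe <- afmchrom:::principalExtents(ctr, hull)
    bd <- feretBoxdiag(pe$major, pe$minor)
    expect_lte(fmin, fmax + 1e-9)
    expect_lte(fmax, bd + 1e-9)
  }
})

test_that("roundness stays in (0, 1] and the height-Feret R^2 in [0, 1]", {
  f <- presetField("CENPC_complex_async", nParticles = 40, seed = 17,
                   noise_sd_nm = 0.05)
  m <- analyzeTopograph(f$topograph)
  expect_true(all(m$roundness > 0 & m$roundness <= 1 + 1e-9))
  r2 <- heightFeretR2(m)
  expect_gte(r2, 0)
  expect_lte(r2, 1)
})

test_that("tip dilation never shrinks the caliper and keeps heights", {
  f <- presetField("CENPA_async", nParticles = 8, seed = 19, noise_sd_nm = 0)
  m0 <- analyzeTopograph(f$topograph, flatten = FALSE)
  td <- applyTipDilation(f$topograph, 3)
  m1 <- analyzeTopograph(td, flatten = FALSE)
  expect_equal(nrow(m1), nrow(m0))
  o0 <- order(m0$x_nm); o1 <- order(m1$x_nm)
  expect_true(all(m1$feret_max_nm[o1] >= m0$feret_max_nm[o0] - 1e-9))
  expect_equal(m1$height_nm[o1], m0$height_nm[o0], tolerance = 0.02)
})
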