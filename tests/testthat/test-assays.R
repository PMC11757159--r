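test_that("two-group ANOVA equals the squared pooled t", {
  set.seed(11)
  g <- list(a = rnorm(12), b = rnorm(15, 0.4))
  a <- oneWayAnova(g)
  tt <- t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(a$p, tt$p.value, tolerance = 1e-12)
})

test_that("ANOVA matches a brute-force sum-of-squares oracle", {
  g <- list(a = c(4.1, 5.2, 3.9, 4.8, 5.0),
            b = c(6.3, 5.9, 6.8, 6.1, 6.5),
            c = c(4.9, 5.5, 5.1, 5.3, 4.7))
  a <- oneWayAnova(g)
  bf <- bruteAnova(g)
  expect_equal(a$F, bf$F, tolerance = 1e-10)
  expect_equal(a$p, bf$p, tolerance = 1e-10)
  # equal group means: F = 0
  gz <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(oneWayAnova(gz)$F, 0, tolerance = 1e-12)
  # all identical: p = 1 convention with a warning
  expect_warning(az <- oneWayAnova(list(a = c(2, 2), b = c(2, 2))), "convention")
  expect_equal(az$p, 1)
})

test_that("two-group Tukey HSD collapses to the pooled t test", {
  set.seed(12)
  g <- list(a = rnorm(20, 0, 1), b = rnorm(20, 0.7, 1))
  th <- tukeyHsd(g)
  tt <- t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(th$pairs$p_adj, tt$p.value, tolerance = 1e-6)
  expect_warning(thz <- tukeyHsd(list(a = c(1, 1, 1), b = c(1, 1, 1))),
                 "convention")
  expect_true(all(thz$pairs$p_adj == 1))
  expect_false(any(thz$pairs$significant))
})

test_that("the CENP-A vs CENP-C-associated height contrast is reliably detected", {
  hits <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    g <- list(cenpa = rnorm(150, 1.8, 0.3), assoc = rnorm(150, 2.5, 0.4))
    tukeyHsd(g)$pairs$significant
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("paired t matches the textbook formula and handles degeneracies", {
  x <- c(12.1, 14.2, 13.3, 15.8, 11.9, 14.0)
  y <- c(11.4, 13.1, 13.5, 14.6, 11.1, 13.2)
  d <- x - y
  tRef <- mean(d) / (sd(d) / sqrt(length(d)))
  pRef <- 2 * pt(-abs(tRef), length(d) - 1)
  pt_ <- pairedT(x, y)
  expect_equal(pt_$t, tRef, tolerance = 1e-10)
  expect_equal(pt_$p, pRef, tolerance = 1e-10)
  expect_warning(eq <- pairedT(x, x), "convention")
  expect_equal(eq$t, 0); expect_equal(eq$p, 1)
  expect_warning(sh <- pairedT(x, x + 0.5), "limit")
  expect_equal(sh$p, 0); expect_true(sh$degenerate)
  expect_error(pairedT(1:3, 1:4), "equal length")
})

test_that("immuno-AFM verdicts reproduce the control and positive conditions", {
  set.seed(77)
  h3 <- list(no_ab = rnorm(50, 2.2, 0.2), primary = rnorm(50, 2.1, 0.2),
             secondary = rnorm(50, 2.2, 0.1))
  expect_false(assessShift(h3)$positive_identification)
  ca <- list(no_ab = rnorm(50, 2.2, 0.2), primary = rnorm(50, 2.5, 0.3),
             secondary = rnorm(50, 4.6, 1.4))
  expect_true(assessShift(ca)$positive_identification)
  fab <- list(no_ab = rnorm(50, 2.2, 0.2), fab = rnorm(50, 3.2, 0.6))
  expect_true(assessShift(fab)$positive_identification)
  expect_error(assessShift(list(primary = 1:5, secondary = 1:5)), "no_ab")
  expect_error(assessShift(list(no_ab = rnorm(5, 2), primary = rnorm(5, 2))),
               "secondary or fab")
  expect_error(assessShift(list(no_ab = c(2, 2.1), secondary = c(2, 2.2))),
               "at least 3")
})

test_that("identical condition distributions stay below the nominal error rate", {
  fp <- vapply(1:200, function(s) {
    set.seed(3000 + s)
    sm <- list(no_ab = rnorm(50, 2.2, 0.2), primary = rnorm(50, 2.2, 0.2),
               secondary = rnorm(50, 2.2, 0.2))
    assessShift(sm)$positive_identification
  }, logical(1))
  expect_lte(mean(fp), 0.05 + 0.02)
})

test_that("complete digestion yields exact mononucleosome protections", {
  s147 <- simulateLadder(ladderSpec(147, 30, 5, 1, 1, 500, seed = 1))
  expect_true(all(s147$fragments_bp == 147L))
  expect_equal(s147$modal_bp, 147L)
  s120 <- simulateLadder(ladderSpec(120, 25, 5, 1, 1, 500, seed = 1))
  expect_true(all(s120$fragments_bp == 120L))
  expect_equal(s120$modal_bp, 120L)
  # one uncut linker in a dinucleosome: 2*147 + 30
  s2 <- simulateLadder(ladderSpec(147, 30, 2, 0, 1, 10, seed = 1))
  expect_true(all(s2$fragments_bp == 2L * 147L + 30L))
})

test_that("fragments respect m*footprint + (m-1)*linker and conserve mass", {
  for (s in 1:10) {
    sp <- ladderSpec(147, 30, sample(2:8, 1), runif(1), runif(1, 0.2, 1),
                     200, seed = s)
    lad <- simulateLadder(sp)
    m <- (lad$fragments_bp + sp$linker_bp) / (sp$footprint_bp + sp$linker_bp)
    expect_true(all(abs(m - round(m)) < 1e-9))
    expect_equal(sum(lad$fragments_bp) + lad$n_cuts * sp$linker_bp,
                 lad$total_array_bp)
  }
})

test_that("refractory chromatin yields longer fragments", {
  wins <- vapply(1:40, function(s) {
    a <- simulateLadder(ladderSpec(147, 30, 8, 0.9, 1, 500, seed = 5000 + s))
    b <- simulateLadder(ladderSpec(147, 30, 8, 0.9, 0.3, 500,
                                   seed = 6000 + s))
    compareLadders(a, b)$mean_difference > 0
  }, logical(1))
  expect_gte(mean(wins), 0.99)
  # identical spec and seed: identical summaries
  a1 <- simulateLadder(ladderSpec(147, 30, 5, 0.7, 1, 200, seed = 9))
  a2 <- simulateLadder(ladderSpec(147, 30, 5, 0.7, 1, 200, seed = 9))
  expect_identical(compareLadders(a1, a2)$mean_difference, 0)
  # full digestion on both sides: equal means
  b1 <- simulateLadder(ladderSpec(147, 30, 5, 1, 1, 200, seed = 10))
  b2 <- simulateLadder(ladderSpec(147, 30, 5, 1, 1, 200, seed = 11))
  expect_equal(compareLadders(b1, b2)$mean_difference, 0)
})

test_that("comparative-Ct expression reproduces the worked fold changes", {
  q0 <- data.frame(group = c("control", "treatment"),
                   ct_target = c(24, 25), ct_reference = c(20, 21))
  expect_equal(relativeExpression(q0)$fold, 1)
  q1 <- data.frame(group = c("control", "treatment"),
                   ct_target = c(24, 26), ct_reference = c(20, 21))
  expect_equal(relativeExpression(q1)$fold, 0.5)
  q <- data.frame(group = c("control", "treatment"),
                  ct_target = c(24.0, 26.32), ct_reference = c(20, 21))
  r <- relativeExpression(q)
  expect_equal(r$ddCt, 1.32)
  expect_equal(r$fold, 2^-1.32)
  expect_equal(r$fold, 0.40, tolerance = 0.005)
  expect_equal(r$percent_change, -60, tolerance = 0.01)
  expect_error(relativeExpression(q[q$group == "control", ]), "present")
})

test_that("relative expression is invariant to per-sample Ct rescaling", {
  set.seed(8)
  q <- data.frame(group = rep(c("control", "treatment"), each = 3),
                  ct_target = runif(6, 22, 28), ct_reference = runif(6, 18, 22))
  r0 <- relativeExpression(q)
  q2 <- q
  shift <- ifelse(q2$group == "treatment", 3.7, -1.2)
  q2$ct_target <- q2$ct_target + shift
  q2$ct_reference <- q2$ct_reference + shift
  r1 <- relativeExpression(q2)
  expect_equal(r1$fold, r0$fold, tolerance = 1e-12)
})
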