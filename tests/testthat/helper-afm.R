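# shared fixture builders (all fixtures are generated in code)

# a noise-free topograph holding one circular dome, centered on a pixel
# center so the planted peak is sampled exactly
diskTopograph <- function(diameter_nm, peak_nm = 2.5, side = NULL,
                          axisRatio = 1, theta = 0) {
  side <- side %||% max(32L, as.integer(4 * diameter_nm))
  c0 <- side / 2 + 0.5
  renderParticle(nucleosomeSpec(c(c0, c0), peak_nm, diameter_nm,
                                axisRatio = axisRatio, theta = theta),
                 Topograph(matrix(0, side, side)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random 8-connected pixel blob (random-walk union), as center coordinates
randomBlob <- function(npx, seed) {
  set.seed(seed)
  steps <- matrix(sample(c(-1L, 0L, 1L), 2L * npx, replace = TRUE), ncol = 2)
  pts <- unique(apply(steps, 2, cumsum))
  pts + 0.5  # pixel centers at half-integer coordinates, 1 nm/px
}

# brute-force one-way ANOVA from raw sums of squares (independent oracle)
bruteAnova <- function(groups) {
  val <- unlist(groups)
  k <- length(groups)
  n <- length(val)
  gm <- mean(val)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  Fv <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = Fv, p = stats::pf(Fv, k - 1, n - k, lower.tail = FALSE))
}
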