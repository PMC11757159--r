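# Decision procedures and statistics: immuno-AFM height-shift
# identification (one-way ANOVA + Tukey HSD), paired t, the MNase
# protection-ladder simulator, and comparative-Ct qPCR.

asGroups <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  groups
}

#' One-way analysis of variance
#'
#' Classical between/within mean-square F ratio via [stats::aov()]. With
#' zero within-group variance and equal means the degenerate case returns
#' p = 1 (with a warning) rather than NaN.
#'
#' @param groups named list of numeric vectors, or a data.frame with
#'   columns `group` and `value`; >= 2 groups with >= 2 values each.
#' @return list with `F`, `p`, `df_between`, `df_within`, and the group
#'   summary table.
#' @export
oneWayAnova <- function(groups) {
  g <- asGroups(groups)
  if (any(lengths(g) < 2L)) stop("each group needs n >= 2")
  val <- unlist(g, use.names = FALSE)
  fac <- factor(rep(names(g), lengths(g)), levels = names(g))
  tab <- data.frame(group = names(g), n = lengths(g),
                    mean = vapply(g, mean, numeric(1)),
                    sd = vapply(g, stats::sd, numeric(1)),
                    row.names = NULL)
  if (all(tab$sd < .Machine$double.eps)) {
    if (max(tab$mean) - min(tab$mean) < .Machine$double.eps) {
      warning("all values identical; returning p = 1 by convention")
      return(list(F = 0, p = 1, df_between = length(g) - 1L,
                  df_within = length(val) - length(g), groups = tab))
    }
  }
  fit <- stats::aov(val ~ fac)
  s <- summary(fit)[[1]]
  Fv <- s[["F value"]][1]
  pv <- s[["Pr(>F)"]][1]
  if (!is.finite(Fv)) { Fv <- 0; pv <- 1 }
  list(F = Fv, p = pv, df_between = s[["Df"]][1], df_within = s[["Df"]][2],
       groups = tab)
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' Studentized-range-adjusted pairwise comparisons after a one-way ANOVA,
#' via [stats::TukeyHSD()] (Tukey-Kramer for unequal n).
#'
#' @param groups as in [oneWayAnova()].
#' @param alpha significance level for the `significant` flag (default
#'   0.05).
#' @return list with the `anova` result and `pairs`, a data.frame of
#'   pairwise difference, adjusted p and significance flag.
#' @export
tukeyHsd <- function(groups, alpha = 0.05) {
  g <- asGroups(groups)
  if (any(lengths(g) < 2L)) stop("each group needs n >= 2")
  val <- unlist(g, use.names = FALSE)
  fac <- factor(rep(names(g), lengths(g)), levels = names(g))
  if (stats::var(val) < .Machine$double.eps) {
    a <- suppressWarnings(oneWayAnova(g))
    nm <- utils::combn(names(g), 2)
    pairs <- data.frame(pair = paste(nm[2, ], nm[1, ], sep = "-"),
                        diff = 0, lwr = 0, upr = 0, p_adj = 1,
                        significant = FALSE)
    warning("all values identical; adjusted p = 1 by convention")
    return(list(anova = a, pairs = pairs, alpha = alpha))
  }
  a <- oneWayAnova(g)
  th <- stats::TukeyHSD(stats::aov(val ~ fac), conf.level = 1 - alpha)$fac
  pairs <- data.frame(pair = rownames(th), diff = th[, "diff"],
                      lwr = th[, "lwr"], upr = th[, "upr"],
                      p_adj = th[, "p adj"],
                      significant = th[, "p adj"] < alpha,
                      row.names = NULL)
  list(anova = a, pairs = pairs, alpha = alpha)
}

#' Paired two-sided t test
#'
#' Classical paired t on the differences via [stats::t.test()]. Identical
#' vectors (zero-variance differences, zero shift) return t = 0, p = 1;
#' a constant non-zero shift with zero-variance differences is the p -> 0
#' limit and is flagged `degenerate`.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return list with `t`, `p`, `df`, `mean_difference`, `degenerate`.
#' @export
pairedT <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  if (length(x) < 2L) stop("need at least two pairs")
  d <- x - y
  if (stats::sd(d) < .Machine$double.eps) {
    md <- mean(d)
    if (abs(md) < .Machine$double.eps) {
      warning("identical pairs; returning p = 1 by convention")
      return(list(t = 0, p = 1, df = length(x) - 1L, mean_difference = 0,
                  degenerate = TRUE))
    }
    warning("constant non-zero shift with zero-variance differences; ",
            "p -> 0 limit")
    return(list(t = sign(md) * Inf, p = 0, df = length(x) - 1L,
                mean_difference = md, degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_difference = unname(ht$estimate),
       degenerate = FALSE)
}

#' Immuno-AFM height-shift identification
#'
#' Decides whether a nucleosome population is recognized by an antibody
#' from the height shift it induces: one-way ANOVA across the labelling
#' conditions followed by Tukey HSD; a positive identification requires
#' the secondary-antibody (or Fab) condition to differ from the
#' no-antibody condition with adjusted p < alpha AND a mean height
#' increase of at least `min_shift_nm`. The 0.5 nm default splits the
#' smallest real positive shift (~1 nm, Fab) from negative-control drift
#' (~0.1 nm) with margin; it is a package decision, echoed in the output.
#'
#' @param samples named list of height vectors (nm) by condition; must
#'   contain `no_ab` and at least one of `secondary`, `fab`; conditions
#'   `primary` etc. are included in the ANOVA. Each condition needs
#'   n >= 3.
#' @param alpha significance level (default 0.05).
#' @param min_shift_nm minimum mean shift for a positive call (default
#'   0.5).
#' @return a `ShiftVerdict` list: condition summary, ANOVA, Tukey pairs,
#'   per-condition shift vs `no_ab`, and `positive_identification`.
#' @examples
#' set.seed(1)
#' s <- list(no_ab = rnorm(50, 2.2, 0.2), primary = rnorm(50, 2.5, 0.3),
#'           secondary = rnorm(50, 4.6, 1.4))
#' assessShift(s)$positive_identification  # TRUE
#' @export
assessShift <- function(samples, alpha = 0.05, min_shift_nm = 0.5) {
  if (!is.list(samples) || is.null(names(samples)))
    stop("samples must be a named list of condition height vectors")
  known <- c("no_ab", "primary", "secondary", "fab")
  if (!all(names(samples) %in% known))
    stop("unknown condition(s): ",
         paste(setdiff(names(samples), known), collapse = ", "),
         "; use ", paste(known, collapse = ", "))
  if (!"no_ab" %in% names(samples))
    stop("samples must include the no_ab condition")
  if (!any(c("secondary", "fab") %in% names(samples)))
    stop("samples must include a secondary or fab condition")
  if (any(lengths(samples) < 3L))
    stop("each condition needs at least 3 heights")
  if (any(unlist(samples) <= 0))
    stop("heights must be positive")
  th <- tukeyHsd(samples, alpha = alpha)
  ref <- mean(samples$no_ab)
  probes <- intersect(c("secondary", "fab"), names(samples))
  shifts <- vapply(probes, function(cn) mean(samples[[cn]]) - ref,
                   numeric(1))
  pOf <- function(cn) {
    i <- which(th$pairs$pair %in% paste0(cn, "-no_ab") |
                 th$pairs$pair %in% paste0("no_ab-", cn))
    th$pairs$p_adj[i][1]
  }
  padj <- vapply(probes, pOf, numeric(1))
  positive <- any(padj < alpha & shifts >= min_shift_nm)
  list(conditions = th$anova$groups, anova = th$anova[c("F", "p")],
       pairs = th$pairs,
       shifts = data.frame(condition = probes, shift_nm = shifts,
                           p_adj = padj, row.names = NULL),
       alpha = alpha, min_shift_nm = min_shift_nm,
       positive_identification = positive)
}

#' MNase protection-ladder specification
#'
#' Models nucleosome arrays digested by micrococcal nuclease: each array
#' carries `arrayLength` nucleosomes protecting `footprint_bp` each
#' (147 bp for H3, 120 bp for CENP-A), joined by linkers of `linker_bp`;
#' each internal linker is cut independently with probability
#' `cut_probability * refractoriness`. Refractoriness < 1 models
#' complexes (such as CENP-C-bound chromatin) that shield their linker
#' DNA, producing longer fragments.
#'
#' @param footprint_bp protected bp per nucleosome (> 0).
#' @param linker_bp linker bp between adjacent nucleosomes (>= 0).
#' @param arrayLength nucleosomes per array: a single integer, or a
#'   vector sampled uniformly per array.
#' @param cut_probability per-linker cut probability in `[0, 1]`.
#' @param refractoriness multiplier on the cut probability in `(0, 1]`.
#' @param n_arrays number of arrays digested.
#' @param seed integer seed (mandatory).
#' @return a `LadderSpec` list.
#' @export
ladderSpec <- function(footprint_bp = 147, linker_bp = 30, arrayLength = 5,
                       cut_probability = 0.9, refractoriness = 1,
                       n_arrays = 1000, seed) {
  if (missing(seed) || !is.finite(seed)) stop("ladderSpec: seed is mandatory")
  if (footprint_bp <= 0) stop("footprint_bp must be > 0")
  if (linker_bp < 0) stop("linker_bp must be >= 0")
  if (cut_probability < 0 || cut_probability > 1)
    stop("cut_probability must be in [0, 1]")
  if (refractoriness <= 0 || refractoriness > 1)
    stop("refractoriness must be in (0, 1]")
  if (any(arrayLength < 1)) stop("arrayLength must be >= 1")
  structure(list(footprint_bp = as.integer(footprint_bp),
                 linker_bp = as.integer(linker_bp),
                 arrayLength = as.integer(arrayLength),
                 cut_probability = cut_probability,
                 refractoriness = refractoriness,
                 n_arrays = as.integer(n_arrays), seed = as.integer(seed)),
            class = "LadderSpec")
}

#' Simulate an MNase protection ladder
#'
#' Digests `n_arrays` arrays per the [ladderSpec()]: every internal
#' linker is cut independently with probability `p * r`; a maximal uncut
#' run of m nucleosomes yields a fragment of
#' `m * footprint + (m - 1) * linker` bp. Terminal (flanking) DNA is
#' fully trimmed, so complete digestion yields exact mononucleosome
#' protections (147 bp H3 / 120 bp CENP-A).
#'
#' @param spec a [ladderSpec()].
#' @return list with `fragments_bp` (integer vector), `n_cuts`,
#'   `total_array_bp`, `modal_bp`, and the spec.
#' @examples
#' s <- simulateLadder(ladderSpec(footprint_bp = 147, cut_probability = 1,
#'                                seed = 1))
#' s$modal_bp  # 147
#' @export
simulateLadder <- function(spec) {
  stopifnot(inherits(spec, "LadderSpec"))
  set.seed(spec$seed)
  pcut <- spec$cut_probability * spec$refractoriness
  frags <- vector("list", spec$n_arrays)
  ncuts <- 0L
  totbp <- 0
  for (i in seq_len(spec$n_arrays)) {
    k <- if (length(spec$arrayLength) == 1L) spec$arrayLength else
      sample(spec$arrayLength, 1L)
    totbp <- totbp + k * spec$footprint_bp + (k - 1L) * spec$linker_bp
    cuts <- if (k > 1L) stats::runif(k - 1L) < pcut else logical(0)
    ncuts <- ncuts + sum(cuts)
    # maximal uncut runs -> nucleosome-run sizes
    m <- integer(0)
    cur <- 1L
    for (cut in cuts) {
      if (cut) { m <- c(m, cur); cur <- 1L } else cur <- cur + 1L
    }
    m <- c(m, cur)
    frags[[i]] <- m * spec$footprint_bp + (m - 1L) * spec$linker_bp
  }
  fragments <- unlist(frags)
  tab <- table(fragments)
  list(fragments_bp = as.integer(fragments), n_cuts = ncuts,
       total_array_bp = totbp,
       modal_bp = as.integer(names(tab)[which.max(tab)]), spec = spec)
}

#' Compare two protection ladders
#'
#' @param a,b results of [simulateLadder()] (or integer fragment
#'   vectors).
#' @return list with per-sample mean fragment length, monosome fraction
#'   (fragments no longer than one footprint), and the mean difference
#'   b - a.
#' @export
compareLadders <- function(a, b) {
  getf <- function(x) if (is.list(x)) x$fragments_bp else as.integer(x)
  getfp <- function(x) if (is.list(x)) x$spec$footprint_bp else NA_integer_
  fa <- getf(a); fb <- getf(b)
  fpa <- getfp(a); fpb <- getfp(b)
  monoFrac <- function(f, fp) if (is.na(fp)) NA_real_ else mean(f <= fp)
  list(mean_a = mean(fa), mean_b = mean(fb),
       mono_fraction_a = monoFrac(fa, fpa),
       mono_fraction_b = monoFrac(fb, fpb),
       mean_difference = mean(fb) - mean(fa))
}

#' Relative expression by the comparative-Ct method
#'
#' Computes per-sample delta-Ct (target minus reference, e.g. GAPDH),
#' the treatment-vs-control delta-delta-Ct, the fold change
#' `2^-ddCt`, and the percent change. A ddCt of 1.32 gives fold 0.40,
#' i.e. a ~60 % reduction.
#'
#' @param q data.frame with columns `group` (control / treatment),
#'   `ct_target`, `ct_reference`, and optionally `sample`; Ct values > 0,
#'   >= 1 replicate per group.
#' @param control,treatment labels of the two groups in `q$group`.
#' @return list with `ddCt`, `fold` (2^-ddCt), `percent_change`, and the
#'   per-group mean delta-Ct table.
#' @examples
#' q <- data.frame(group = c("control", "treatment"),
#'                 ct_target = c(24.0, 26.32), ct_reference = c(20, 21))
#' relativeExpression(q)$fold  # ~0.40
#' @export
relativeExpression <- function(q, control = "control",
                               treatment = "treatment") {
  stopifnot(is.data.frame(q),
            all(c("group", "ct_target", "ct_reference") %in% names(q)))
  if (any(q$ct_target <= 0 | q$ct_reference <= 0))
    stop("Ct values must be > 0")
  if (!all(c(control, treatment) %in% q$group))
    stop("both groups ('", control, "', '", treatment,
         "') must be present")
  dct <- q$ct_target - q$ct_reference
  mc <- mean(dct[q$group == control])
  mt <- mean(dct[q$group == treatment])
  ddct <- mt - mc
  fold <- 2^(-ddct)
  list(ddCt = ddct, fold = fold, percent_change = (fold - 1) * 100,
       group_dCt = data.frame(group = c(control, treatment),
                              mean_dCt = c(mc, mt),
                              n = c(sum(q$group == control),
                                    sum(q$group == treatment))))
}
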