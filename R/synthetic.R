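# Synthetic AFM topograph generator: particle and filament specs, raster
# rendering with occlusion (pointwise maximum), probe-tip convolution,
# background tilt and scan noise, with a ground-truth table for every
# planted object.

truncNorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

#' Nucleosome particle specification
#'
#' Describes one nucleosome-class bump: an elliptical cosine-tapered dome.
#' The dome's half-maximum footprint is an ellipse whose major extent equals
#' `diameter_nm` and whose minor/major ratio is `axisRatio`, so the planted
#' "diameter" is directly comparable to the measured half-max caliper.
#'
#' @param center_nm length-2 (x, y) position in nm.
#' @param peak_nm apparent peak height above background (nm, > 0).
#' @param diameter_nm half-max footprint major extent (nm, > 0).
#' @param axisRatio minor/major extent ratio in (0, 1].
#' @param theta major-axis orientation (radians).
#' @return a `ParticleSpec` list.
#' @export
nucleosomeSpec <- function(center_nm, peak_nm, diameter_nm,
                           axisRatio = 1, theta = 0) {
  if (peak_nm <= 0 || diameter_nm <= 0)
    stop("nucleosomeSpec: peak_nm and diameter_nm must be > 0")
  if (axisRatio <= 0 || axisRatio > 1)
    stop("nucleosomeSpec: axisRatio must be in (0, 1]")
  structure(list(kind = "nucleosome", center = as.numeric(center_nm),
                 peak = peak_nm, diameter = diameter_nm,
                 axisRatio = axisRatio, theta = theta),
            class = "ParticleSpec")
}

#' CENP-C-complex particle specification
#'
#' Describes one large-complex bump: a flat-topped convex-polygon prism
#' with a cosine-tapered rim. The half-maximum outline is the polygon
#' itself, constructed so that its principal-axis extents (a, b) satisfy
#' `sqrt(a^2 + b^2) = feret_nm` (the box-diagonal Feret convention used for
#' complex diameters) and `b/a = roundness`.
#'
#' @param center_nm length-2 (x, y) position in nm.
#' @param peak_nm apparent peak height above background (nm, > 0).
#' @param feret_nm box-diagonal Feret of the half-max footprint (nm, > 0).
#' @param roundness minor/major extent ratio in (0, 1].
#' @param nVertices polygon vertex count (4-8; default 6).
#' @param theta orientation (radians).
#' @param rimFrac cosine rim half-width as a fraction of the footprint
#'   gauge (default 0.25).
#' @return a `ParticleSpec` list.
#' @export
complexSpec <- function(center_nm, peak_nm, feret_nm, roundness = 0.79,
                        nVertices = 6, theta = 0, rimFrac = 0.25) {
  if (peak_nm <= 0 || feret_nm <= 0)
    stop("complexSpec: peak_nm and feret_nm must be > 0")
  if (roundness <= 0 || roundness > 1)
    stop("complexSpec: roundness must be in (0, 1]")
  if (nVertices < 4 || nVertices > 8)
    stop("complexSpec: nVertices must be between 4 and 8")
  if (rimFrac <= 0 || rimFrac >= 1)
    stop("complexSpec: rimFrac must be in (0, 1)")
  a <- feret_nm / sqrt(1 + roundness^2)
  b <- roundness * a
  structure(list(kind = "complex", center = as.numeric(center_nm),
                 peak = peak_nm, feret = feret_nm, roundness = roundness,
                 extents = c(a, b), nVertices = as.integer(nVertices),
                 theta = theta, rimFrac = rimFrac),
            class = "ParticleSpec")
}

#' Nucleosome-free DNA filament specification
#'
#' @param contour_nm total contour length (nm); alternatively give `bp`.
#' @param bp length in base pairs (converted at `rise_per_bp`).
#' @param persistence_nm worm-like-chain persistence length (nm, > 0).
#' @param ridgeHeight_nm apparent filament height (nm); must stay below the
#'   nucleosome detection gate (default 0.5).
#' @param start_nm (x, y) start position in nm (may be NA; placed later).
#' @param theta0 initial tangent direction (radians).
#' @param rise_per_bp helical rise used for the bp conversion (nm/bp).
#' @return a `FilamentSpec` list.
#' @export
filamentSpec <- function(contour_nm = NULL, bp = NULL, persistence_nm = 50,
                         ridgeHeight_nm = 0.5, start_nm = c(NA, NA),
                         theta0 = 0, rise_per_bp = 0.34) {
  if (is.null(contour_nm)) {
    if (is.null(bp)) stop("filamentSpec: give contour_nm or bp")
    contour_nm <- bp * rise_per_bp
  }
  if (contour_nm <= 0) stop("filamentSpec: contour_nm must be > 0")
  if (persistence_nm <= 0) stop("filamentSpec: persistence_nm must be > 0")
  if (ridgeHeight_nm <= 0 || ridgeHeight_nm >= 0.8)
    stop("filamentSpec: ridgeHeight_nm must be in (0, 0.8) nm, below the ",
         "nucleosome height gate")
  structure(list(kind = "filament", contour = contour_nm,
                 persistence = persistence_nm, ridge = ridgeHeight_nm,
                 start = as.numeric(start_nm), theta0 = theta0),
            class = "FilamentSpec")
}

#' Sample a worm-like-chain filament path
#'
#' Discretizes a 2-D worm-like chain as a fixed-segment-length chain with
#' independent Gaussian tangent-angle increments of variance
#' `segment / persistence`. This is the physical 2-D (surface-equilibrated)
#' worm-like chain: tangent correlations decay as `exp(-s / (2P))` and the
#' mean-squared end-to-end distance follows the 2-D Kratky-Porod relation
#' `<R^2> = 4 P L - 8 P^2 (1 - exp(-L / (2P)))`.
#'
#' @param spec a [filamentSpec()].
#' @param pixel_size_nm segment length (nm); the path is sampled at one
#'   point per pixel.
#' @param seed optional integer seed (set locally if given).
#' @return (n+1) x 2 matrix of (x, y) positions in nm, starting at
#'   `spec$start` (or the origin when unset).
#' @examples
#' p <- sampleWlcFilament(filamentSpec(53, persistence_nm = 1e9), 1)
#' sqrt(sum((p[nrow(p), ] - p[1, ])^2))  # rigid-rod limit: ~53
#' @export
sampleWlcFilament <- function(spec, pixel_size_nm, seed = NULL) {
  stopifnot(inherits(spec, "FilamentSpec"))
  s <- pixel_size_nm
  if (spec$contour < 2 * s)
    stop("sampleWlcFilament: contour_length (", spec$contour,
         " nm) must be at least two segments (", 2 * s, " nm)")
  if (!is.null(seed)) set.seed(seed)
  n <- max(2L, as.integer(round(spec$contour / s)))
  sdInc <- sqrt(s / spec$persistence)
  th <- spec$theta0 + cumsum(c(0, stats::rnorm(n - 1L, 0, sdInc)))
  x0 <- if (all(is.finite(spec$start))) spec$start else c(0, 0)
  cbind(x0[1] + c(0, cumsum(s * cos(th))),
        x0[2] + c(0, cumsum(s * sin(th))))
}

# pixel-center coordinates (nm) for a column/row index range
pxCenters <- function(idx, p) (idx - 0.5) * p

#' Render one particle onto a topograph
#'
#' Stamps the particle's smooth bump onto the canvas. Nucleosomes are
#' elliptical cosine-tapered domes; complexes are flat-topped polygonal
#' prisms with a cosine-tapered rim whose half-max outline is the spec's
#' polygon. Surfaces compose by pointwise maximum: the AFM observes the
#' topmost surface, overlapping objects occlude rather than add.
#'
#' @param spec a [nucleosomeSpec()] or [complexSpec()].
#' @param canvas a [Topograph-class] to stamp onto.
#' @return the updated `Topograph`; if the bump support extends beyond the
#'   canvas, `meta$border_objects` is incremented.
#' @examples
#' t0 <- Topograph(matrix(0, 64, 64))
#' # center on a pixel center so the sampled peak is exact
#' t1 <- renderParticle(nucleosomeSpec(c(31.5, 31.5), 2.5, 12), t0)
#' max(heights(t1))  # exactly 2.5 at the center
#' @export
renderParticle <- function(spec, canvas) {
  stopifnot(inherits(spec, "ParticleSpec"), is(canvas, "Topograph"))
  z <- canvas@heights
  p <- canvas@pixelSize
  nr <- nrow(z); nc <- ncol(z)
  cx <- spec$center[1]; cy <- spec$center[2]
  # support radius in nm
  rad <- if (spec$kind == "nucleosome") {
    spec$diameter
  } else {
    (1 + spec$rimFrac) * max(abs(polygonWithExtents(
      spec$nVertices, spec$extents[1], spec$extents[2], 0)))
  }
  j0 <- max(1L, floor((cx - rad) / p) + 1L)
  j1 <- min(nc, ceiling((cx + rad) / p))
  i0 <- max(1L, floor((cy - rad) / p) + 1L)
  i1 <- min(nr, ceiling((cy + rad) / p))
  border <- (cx - rad < 0) || (cx + rad > nc * p) ||
            (cy - rad < 0) || (cy + rad > nr * p)
  if (j1 < j0 || i1 < i0) {
    meta <- canvas@meta
    meta$border_objects <- (meta$border_objects %||% 0L) + 1L
    return(Topograph(z, p, meta))
  }
  jj <- j0:j1; ii <- i0:i1
  dx <- rep(pxCenters(jj, p) - cx, each = length(ii))
  dy <- rep(pxCenters(ii, p) - cy, times = length(jj))
  bump <- if (spec$kind == "nucleosome") {
    th <- spec$theta
    u <- cos(th) * dx + sin(th) * dy
    v <- -sin(th) * dx + cos(th) * dy
    A <- spec$diameter; B <- spec$axisRatio * spec$diameter
    rho <- sqrt((u / A)^2 + (v / B)^2)
    spec$peak * 0.5 * (1 + cos(pi * pmin(rho, 1)))
  } else {
    poly <- polygonWithExtents(spec$nVertices, spec$extents[1],
                               spec$extents[2], spec$theta)
    tg <- polygonGauge(poly, cbind(dx, dy))
    w <- spec$rimFrac
    h <- numeric(length(tg))
    h[tg <= 1 - w] <- spec$peak
    rim <- tg > 1 - w & tg < 1 + w
    h[rim] <- spec$peak * 0.5 * (1 + cos(pi * (tg[rim] - (1 - w)) / (2 * w)))
    h
  }
  sub <- matrix(bump, nrow = length(ii), ncol = length(jj))
  z[ii, jj] <- pmax(z[ii, jj], sub)
  meta <- canvas@meta
  if (border) meta$border_objects <- (meta$border_objects %||% 0L) + 1L
  Topograph(z, p, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stamp a filament path as a cosine-profile ridge (pointwise maximum)
renderFilamentPath <- function(path, ridge, canvas, halfWidth_nm = 2) {
  z <- canvas@heights
  p <- canvas@pixelSize
  nr <- nrow(z); nc <- ncol(z)
  w <- halfWidth_nm
  wpx <- ceiling(w / p)
  for (k in seq_len(nrow(path))) {
    cx <- path[k, 1]; cy <- path[k, 2]
    jc <- floor(cx / p) + 1L; ic <- floor(cy / p) + 1L
    jj <- max(1L, jc - wpx):min(nc, jc + wpx)
    ii <- max(1L, ic - wpx):min(nr, ic + wpx)
    if (!length(jj) || !length(ii)) next
    dx <- rep(pxCenters(jj, p) - cx, each = length(ii))
    dy <- rep(pxCenters(ii, p) - cy, times = length(jj))
    d <- sqrt(dx^2 + dy^2)
    b <- ifelse(d < w, ridge * 0.5 * (1 + cos(pi * d / w)), 0)
    sub <- matrix(b, nrow = length(ii), ncol = length(jj))
    z[ii, jj] <- pmax(z[ii, jj], sub)
  }
  setTopoHeights(canvas, z)
}

#' Probe-tip convolution as grayscale dilation
#'
#' Models the lateral broadening caused by the finite AFM tip as grayscale
#' morphological dilation of the height field with a spherical-cap
#' structuring element of the given radius. The output is pointwise >= the
#' input, and the maximum height of features wider than the tip is
#' unchanged.
#'
#' @param t a [Topograph-class].
#' @param tip_radius_nm tip radius in nm (>= 0; 0 is the identity).
#' @return the dilated `Topograph`.
#' @export
applyTipDilation <- function(t, tip_radius_nm) {
  stopifnot(is(t, "Topograph"))
  if (tip_radius_nm < 0) stop("tip_radius_nm must be >= 0")
  if (tip_radius_nm == 0) return(t)
  z <- t@heights
  p <- t@pixelSize
  r <- tip_radius_nm
  kpx <- floor(r / p)
  out <- z
  nr <- nrow(z); nc <- ncol(z)
  for (dr in -kpx:kpx) for (dc in -kpx:kpx) {
    d2 <- (dr * p)^2 + (dc * p)^2
    if (d2 > r^2) next
    if (dr == 0 && dc == 0) next
    cap <- sqrt(r^2 - d2) - r  # <= 0, zero at the apex
    si <- max(1L, 1L - dr):min(nr, nr - dr)
    sj <- max(1L, 1L - dc):min(nc, nc - dc)
    out[si, sj] <- pmax(out[si, sj], z[si + dr, sj + dc] + cap)
  }
  setTopoHeights(t, out, list(tip_radius_nm = r))
}

#' Predicted in-air AFM height from a cryo-EM height
#'
#' In-air tapping-mode AFM reads nucleosome-scale particles at roughly half
#' their cryo-EM/crystallographic height; this helper applies that
#' attenuation to predict the AFM-apparent height of a structure of known
#' cryo-EM height (e.g. 9.3 nm -> 4.65 nm at the default factor).
#'
#' @param h_cryo_nm cryo-EM height (nm, >= 0).
#' @param attenuation_factor multiplicative attenuation in (0, 1].
#' @return predicted AFM height (nm).
#' @examples
#' cryoemToAfmHeight(9.3)  # 4.65
#' @export
cryoemToAfmHeight <- function(h_cryo_nm, attenuation_factor = 0.5) {
  if (any(h_cryo_nm < 0)) stop("h_cryo_nm must be >= 0")
  if (attenuation_factor <= 0 || attenuation_factor > 1)
    stop("attenuation_factor must be in (0, 1]")
  h_cryo_nm * attenuation_factor
}

#' Synthetic field specification
#'
#' Describes a whole synthetic topograph: canvas geometry, background
#' plane, scan noise, probe tip, and either an explicit list of particle /
#' filament specs or a preset name with object counts. The seed is
#' mandatory and echoed into all outputs.
#'
#' @param width_px,height_px canvas size in pixels (>= 16).
#' @param pixel_size_nm physical pixel edge (nm, > 0).
#' @param plane_tilt numeric (a, b, c): background plane `a + b x + c y`
#'   (nm; x, y in nm).
#' @param noise_sd_nm per-pixel Gaussian scan-noise sd (nm, >= 0).
#' @param tip_radius_nm spherical-cap tip radius for dilation (nm, >= 0).
#' @param seed integer seed (mandatory).
#' @param contents explicit list of [nucleosomeSpec()] / [complexSpec()] /
#'   [filamentSpec()] objects (used when no preset is given).
#' @param preset preset name from [afmPresets()].
#' @param nParticles,nFilaments object counts drawn from the preset.
#' @param nVertices polygon vertex count for preset-drawn complexes.
#' @return a `FieldSpec` list.
#' @export
fieldSpec <- function(width_px = 512, height_px = 512, pixel_size_nm = 1,
                      plane_tilt = c(0, 0, 0), noise_sd_nm = 0,
                      tip_radius_nm = 0, seed, contents = list(),
                      preset = NULL, nParticles = 0, nFilaments = 0,
                      nVertices = 6) {
  if (missing(seed) || !is.finite(seed))
    stop("fieldSpec: an integer seed is mandatory")
  if (noise_sd_nm < 0) stop("fieldSpec: noise_sd_nm must be >= 0")
  if (tip_radius_nm < 0) stop("fieldSpec: tip_radius_nm must be >= 0")
  if (width_px < 16 || height_px < 16)
    stop("fieldSpec: field must be at least 16 x 16 px")
  if (!is.null(preset)) afmPresets(preset)  # validates the name
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 pixel_size_nm = pixel_size_nm,
                 plane_tilt = as.numeric(plane_tilt),
                 noise_sd_nm = noise_sd_nm, tip_radius_nm = tip_radius_nm,
                 seed = as.integer(seed), contents = contents,
                 preset = preset, nParticles = as.integer(nParticles),
                 nFilaments = as.integer(nFilaments),
                 nVertices = as.integer(nVertices)),
            class = "FieldSpec")
}

# worst-case support radius (nm) for grid placement
specSupportRadius <- function(spec) {
  if (spec$kind == "nucleosome") return(spec$diameter + 1)
  if (spec$kind == "complex") {
    poly <- polygonWithExtents(spec$nVertices, spec$extents[1],
                               spec$extents[2], 0)
    return((1 + spec$rimFrac) * max(sqrt(rowSums(poly^2))) + 1)
  }
  stop("no support radius for filaments")
}

# draw object parameter tables from a preset (consumes RNG)
drawFromPreset <- function(pr, nParticles, nFilaments, nVertices) {
  specs <- list()
  if (nParticles > 0) {
    if (pr$kind == "filament")
      stop("preset '", pr$name, "' generates filaments; use nFilaments")
    h <- truncNorm(nParticles, pr$height_mean, pr$height_sd, lower = 0.2)
    lat <- truncNorm(nParticles, pr$lateral_mean, pr$lateral_sd, lower = 1)
    rnd <- truncNorm(nParticles, pr$roundness_mean, pr$roundness_sd,
                     lower = 0.05, upper = 1)
    th <- stats::runif(nParticles, 0, pi)
    for (i in seq_len(nParticles)) {
      specs[[length(specs) + 1L]] <- if (pr$kind == "nucleosome") {
        nucleosomeSpec(c(NA, NA), h[i], lat[i], axisRatio = rnd[i],
                       theta = th[i])
      } else {
        complexSpec(c(NA, NA), h[i], lat[i], roundness = rnd[i],
                    nVertices = nVertices, theta = th[i])
      }
    }
  }
  if (nFilaments > 0) {
    prf <- if (pr$kind == "filament") pr else afmPresets("freeDNA")
    bp <- truncNorm(nFilaments, prf$bp_mean, prf$bp_sd, lower = 30)
    th0 <- stats::runif(nFilaments, 0, 2 * pi)
    for (i in seq_len(nFilaments)) {
      specs[[length(specs) + 1L]] <-
        filamentSpec(bp = bp[i], ridgeHeight_nm = prf$height_mean,
                     theta0 = th0[i])
    }
  }
  specs
}

#' Render a synthetic field
#'
#' Renders all objects of a [fieldSpec()] onto a zero canvas (composing by
#' pointwise maximum), applies tip dilation, adds the background plane and
#' per-pixel Gaussian noise, and returns the topograph together with a
#' ground-truth table listing every planted object and its true
#' parameters. Fully reproducible: the same spec yields a bit-identical
#' raster.
#'
#' Preset-drawn objects are laid out on a jittered grid whose cells are
#' sized from the worst-case object support, and centers are snapped to
#' pixel centers so planted peak heights are sampled exactly.
#'
#' @param fs a [fieldSpec()].
#' @return list with elements `topograph` ([Topograph-class], seed and
#'   preset echoed in `meta`) and `truth` (data.frame: one row per planted
#'   object with its true parameters).
#' @export
renderField <- function(fs) {
  stopifnot(inherits(fs, "FieldSpec"))
  set.seed(fs$seed)
  p <- fs$pixel_size_nm
  W <- fs$width_px * p; H <- fs$height_px * p
  canvas <- Topograph(matrix(0, fs$height_px, fs$width_px), p,
                      meta = list(seed = fs$seed,
                                  preset = fs$preset %||% "explicit"))
  specs <- fs$contents
  placed <- length(specs) > 0L   # explicit contents carry their centers
  if (!is.null(fs$preset)) {
    pr <- afmPresets(fs$preset)
    specs <- drawFromPreset(pr, fs$nParticles, fs$nFilaments, fs$nVertices)
    placed <- FALSE
  }
  nObj <- length(specs)
  paths <- vector("list", nObj)
  if (nObj > 0L && !placed) {
    # jittered grid layout sized to the worst-case support
    isFil <- vapply(specs, function(s) s$kind == "filament", logical(1))
    reqs <- rep(0, nObj)
    if (any(!isFil))
      reqs[!isFil] <- vapply(specs[!isFil], specSupportRadius, numeric(1))
    cellFil <- 0
    if (any(isFil)) {
      Lmax <- max(vapply(specs[isFil], function(s) s$contour, numeric(1)))
      # a cell must hold the worst-case contour un-curled: forcing long
      # chains into smaller cells curls them into self-contacts that the
      # tracer (which splits at junctions) cannot undo
      cellFil <- max(96, ceiling(Lmax + 10))
    }
    cellPart <- if (any(!isFil)) 2 * (max(reqs) + 1) else 0
    cell <- max(cellPart, cellFil)
    k <- ceiling(sqrt(nObj))
    if (k * cell > min(W, H) + 1e-9) {
      if (cellPart * k > min(W, H) + 1e-9)
        stop("renderField: field too small for ", nObj, " objects needing ",
             sprintf("%.0f", k * cell), " nm; enlarge the field or use ",
             "presetField() which auto-sizes")
      # only a rare long filament is oversized: shrink the cells and let
      # the bounding-box resampler curl it into place
      cell <- min(W, H) / k
    }
    cw <- W / k; ch <- H / k
    ord <- sample.int(k * k, nObj)
    for (i in seq_len(nObj)) {
      ri <- (ord[i] - 1L) %/% k; ci <- (ord[i] - 1L) %% k
      ccx <- (ci + 0.5) * cw; ccy <- (ri + 0.5) * ch
      if (!isFil[i]) {
        mx <- max(0, cw / 2 - reqs[i] - 1); my <- max(0, ch / 2 - reqs[i] - 1)
        cx <- ccx + stats::runif(1, -mx, mx)
        cy <- ccy + stats::runif(1, -my, my)
        # snap to a pixel center so the planted peak is sampled exactly
        cx <- (round(cx / p - 0.5) + 0.5) * p
        cy <- (round(cy / p - 0.5) + 0.5) * p
        specs[[i]]$center <- c(cx, cy)
      } else {
        # sample the path, then translate its bounding box into the cell
        for (try in 1:100) {
          path <- sampleWlcFilament(specs[[i]], p)
          bb <- c(diff(range(path[, 1])), diff(range(path[, 2])))
          if (all(bb <= c(cw, ch) - 6)) break
        }
        mx <- max(0, (cw - bb[1]) / 2 - 3); my <- max(0, (ch - bb[2]) / 2 - 3)
        off <- c(ccx - mean(range(path[, 1])) + stats::runif(1, -mx, mx),
                 ccy - mean(range(path[, 2])) + stats::runif(1, -my, my))
        path <- sweep(path, 2, -off)
        specs[[i]]$start <- path[1, ]
        paths[[i]] <- path
      }
    }
  } else if (nObj > 0L) {
    for (i in seq_len(nObj)) {
      if (specs[[i]]$kind == "filament") {
        if (!all(is.finite(specs[[i]]$start)))
          stop("explicit filament contents need a finite start_nm")
        paths[[i]] <- sampleWlcFilament(specs[[i]], p)
      }
    }
  }
  # render (surfaces occlude: pointwise maximum)
  for (i in seq_len(nObj)) {
    s <- specs[[i]]
    canvas <- if (s$kind == "filament") {
      renderFilamentPath(paths[[i]], s$ridge, canvas)
    } else {
      renderParticle(s, canvas)
    }
  }
  truth <- do.call(rbind, lapply(seq_len(nObj), function(i) {
    s <- specs[[i]]
    if (s$kind == "filament") {
      data.frame(object_id = i, kind = "filament",
                 x_nm = s$start[1], y_nm = s$start[2],
                 height_nm = s$ridge, lateral_nm = NA_real_,
                 roundness = NA_real_, theta = s$theta0,
                 contour_nm = s$contour, bp = s$contour / 0.34)
    } else {
      data.frame(object_id = i, kind = s$kind,
                 x_nm = s$center[1], y_nm = s$center[2],
                 height_nm = s$peak,
                 lateral_nm = if (s$kind == "nucleosome") s$diameter else s$feret,
                 roundness = if (s$kind == "nucleosome") s$axisRatio else s$roundness,
                 theta = s$theta, contour_nm = NA_real_, bp = NA_real_)
    }
  }))
  if (is.null(truth))
    truth <- data.frame(object_id = integer(), kind = character(),
                        x_nm = numeric(), y_nm = numeric(),
                        height_nm = numeric(), lateral_nm = numeric(),
                        roundness = numeric(), theta = numeric(),
                        contour_nm = numeric(), bp = numeric())
  if (fs$tip_radius_nm > 0)
    canvas <- applyTipDilation(canvas, fs$tip_radius_nm)
  z <- canvas@heights
  tl <- fs$plane_tilt
  if (any(tl != 0)) {
    xs <- pxCenters(seq_len(ncol(z)), p)
    ys <- pxCenters(seq_len(nrow(z)), p)
    z <- z + tl[1] + outer(ys, xs, function(y, x) tl[2] * x + tl[3] * y)
  }
  if (fs$noise_sd_nm > 0)
    z <- z + matrix(stats::rnorm(length(z), 0, fs$noise_sd_nm),
                    nrow(z), ncol(z))
  canvas <- setTopoHeights(canvas, z,
                           list(noise_sd_nm = fs$noise_sd_nm,
                                tip_radius_nm = fs$tip_radius_nm))
  list(topograph = canvas, truth = truth)
}

#' Render a preset-drawn field with an auto-sized canvas
#'
#' Convenience wrapper around [fieldSpec()] + [renderField()]: draws
#' `nParticles` particles and/or `nFilaments` filaments from a preset and
#' sizes the canvas so the jittered-grid layout holds every worst-case
#' object without overlap (minimum 512 px on a side).
#'
#' @param preset preset name (see [afmPresets()]).
#' @param nParticles,nFilaments object counts.
#' @param seed integer seed (mandatory).
#' @param noise_sd_nm,tip_radius_nm,pixel_size_nm,plane_tilt,nVertices as
#'   in [fieldSpec()].
#' @return as [renderField()].
#' @examples
#' f <- presetField("CENPA_async", nParticles = 20, seed = 7)
#' nrow(f$truth)
#' @export
presetField <- function(preset, nParticles = 0, nFilaments = 0, seed,
                        noise_sd_nm = 0.05, tip_radius_nm = 0,
                        pixel_size_nm = 1, plane_tilt = c(0, 0, 0),
                        nVertices = 6) {
  pr <- afmPresets(preset)
  nObj <- nParticles + nFilaments
  if (nObj < 1) stop("presetField: no objects requested")
  cellP <- 0
  if (nParticles > 0) {
    latMax <- pr$lateral_mean + 3 * pr$lateral_sd
    cellP <- if (pr$kind == "nucleosome") 2 * (latMax + 3)
             else 2 * (0.66 * latMax + 3)
  }
  cellF <- 0
  if (nFilaments > 0) {
    prf <- if (pr$kind == "filament") pr else afmPresets("freeDNA")
    # 4.5-sd worst case: a draw beyond the canvas estimate would force
    # renderField to curl the chain into a smaller cell
    Lmax <- (prf$bp_mean + 4.5 * prf$bp_sd) * 0.34
    cellF <- max(96, ceiling(Lmax + 10))
  }
  cell <- max(cellP, cellF)
  k <- ceiling(sqrt(nObj))
  side <- max(512L, as.integer(ceiling(k * cell / pixel_size_nm)) + 2L)
  fs <- fieldSpec(width_px = side, height_px = side,
                  pixel_size_nm = pixel_size_nm, plane_tilt = plane_tilt,
                  noise_sd_nm = noise_sd_nm, tip_radius_nm = tip_radius_nm,
                  seed = seed, preset = preset, nParticles = nParticles,
                  nFilaments = nFilaments, nVertices = nVertices)
  renderField(fs)
}
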