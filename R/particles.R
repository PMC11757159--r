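# Particle detection and morphometry: thresholding, 8-connected labeling,
# peak-above-background height, half-max footprints, rotating-calipers
# Feret diameters, the box-diagonal Feret convention, roundness, and
# nucleosome / complex / debris classification.

#' Detection configuration
#'
#' @param threshold_nm absolute detection threshold above the background
#'   level (nm); if `NULL` (default) it is derived as
#'   `max(thresholdFactor * background_sd, thresholdFloor)`.
#' @param thresholdFactor multiple of the background sd (default 3).
#' @param thresholdFloor minimum threshold (nm, default 0.5).
#' @param minArea_nm2 minimum region area kept (default 40).
#' @param excludeBorder drop regions touching the image border (default
#'   TRUE; they are still flagged in the output).
#' @param halfMax define the measured footprint at half of
#'   (peak - background) rather than at the detection threshold (default
#'   TRUE; stabilizes diameters against the threshold choice).
#' @param watershed split merged regions at local maxima (default FALSE;
#'   needs EBImage).
#' @param watershedMinSep_nm minimum peak separation for a split (nm).
#' @param despeckle read peaks and footprints from a 3x3-median despeckled
#'   image (default FALSE: the median clips curved dome crests by their
#'   minor-axis curvature, ~pi^2 p^2 / (4 B^2) nm for a dome of half-max
#'   minor extent B, which at nucleosome scale outweighs the small upward
#'   bias of max-over-noisy-pixels at ~0.05 nm scan noise; enable for
#'   heavily speckled scans).
#' @param peakSmooth_sigma_px light Gaussian smoothing (sd in px) applied
#'   before peak reads and half-max cuts when the background sd exceeds
#'   0.01 nm (default 0.6 px). On noisy scans the raw max-over-pixels
#'   inflates flat-topped peaks by E\[max\] of the scan noise (and thereby
#'   shrinks half-max footprints); the smoothed read trades that for a
#'   small curvature-proportional crest rounding. Noise-free data are
#'   always read raw; 0 disables.
#' @param localBackground measure heights against a local annulus median
#'   instead of the global background level (default FALSE: mica is
#'   atomically flat, the global mode is the reference).
#' @param roundnessMode "calipers" (feret_min / feret_max, default) or
#'   "ellipse" (principal-axis minor / major extents).
#' @return a `DetectionConfig` list.
#' @export
detectionConfig <- function(threshold_nm = NULL, thresholdFactor = 3,
                            thresholdFloor = 0.5, minArea_nm2 = 40,
                            excludeBorder = TRUE, halfMax = TRUE,
                            watershed = FALSE, watershedMinSep_nm = 6,
                            despeckle = FALSE, peakSmooth_sigma_px = 0.6,
                            localBackground = FALSE,
                            roundnessMode = c("calipers", "ellipse")) {
  if (!is.null(threshold_nm) && threshold_nm <= 0)
    stop("threshold_nm must be > 0")
  if (minArea_nm2 <= 0) stop("minArea_nm2 must be > 0")
  structure(list(threshold_nm = threshold_nm,
                 thresholdFactor = thresholdFactor,
                 thresholdFloor = thresholdFloor,
                 minArea_nm2 = minArea_nm2, excludeBorder = excludeBorder,
                 halfMax = halfMax, watershed = watershed,
                 watershedMinSep_nm = watershedMinSep_nm,
                 despeckle = despeckle,
                 peakSmooth_sigma_px = peakSmooth_sigma_px,
                 localBackground = localBackground,
                 roundnessMode = match.arg(roundnessMode)),
            class = "DetectionConfig")
}

#' Classification gates
#'
#' Default gates: a particle is a nucleosome if its height lies in
#' `[0.8, 4)` nm and its gate Feret is at most 21 nm; a complex if its
#' height is >= 4 nm or its gate Feret exceeds 21 nm, provided its
#' footprint area is at least 150 nm^2; everything else is debris. The
#' gate Feret uses the box-diagonal convention by default, matching the
#' convention of the reported complex diameters; 21 nm is the
#' sd-weighted midpoint between the nucleosome (~15.7 +/- 2 nm) and
#' asynchronous-complex (~27.4 +/- 2.7 nm) box-diagonal populations, so
#' low-height complexes are still caught by their lateral size.
#'
#' @param nucHeight_nm length-2 nucleosome height window (nm).
#' @param nucFeretMax_nm nucleosome maximum gate Feret (nm).
#' @param cpxHeight_nm complex minimum height (nm).
#' @param cpxFeret_nm complex minimum gate Feret (nm).
#' @param cpxMinArea_nm2 complex minimum footprint area (nm^2).
#' @param gateFeret which Feret feeds the gates: "boxdiag" (default) or
#'   "max".
#' @return a `ClassificationGates` list.
#' @export
classificationGates <- function(nucHeight_nm = c(0.8, 4.0),
                                nucFeretMax_nm = 21,
                                cpxHeight_nm = 4.0, cpxFeret_nm = 21,
                                cpxMinArea_nm2 = 150,
                                gateFeret = c("boxdiag", "max")) {
  structure(list(nucHeight_nm = nucHeight_nm,
                 nucFeretMax_nm = nucFeretMax_nm,
                 cpxHeight_nm = cpxHeight_nm, cpxFeret_nm = cpxFeret_nm,
                 cpxMinArea_nm2 = cpxMinArea_nm2,
                 gateFeret = match.arg(gateFeret)),
            class = "ClassificationGates")
}

# measurement image: median despeckle if asked, else adaptive Gaussian
# smoothing on noisy scans, else the raw heights
measureImage <- function(z, config, bg) {
  if (config$despeckle) return(medianFilter3(z))
  sig <- config$peakSmooth_sigma_px %||% 0
  if (sig > 0 && bg$sd > 0.01) return(gaussianSmooth(z, sig))
  z
}

# 8-connected labeling of a logical mask (igraph components over the
# foreground pixel adjacency graph)
labelMask8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (!length(idx)) return(lab)
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  edges <- NULL
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- rows + sh[1]; c2 <- cols + sh[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- mask[nb]
    if (any(hit))
      edges <- rbind(edges, cbind(pos[idx[ok][hit]], pos[nb[hit]]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# optional marker-based watershed split of a labelled mask (EBImage)
watershedSplit <- function(lab, zrel, minSep_px) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    warning("watershed split requested but EBImage is not available")
    return(lab)
  }
  img <- zrel
  img[lab == 0L] <- 0
  ws <- EBImage::watershed(EBImage::as.Image(img), tolerance = 0.5,
                           ext = max(1L, as.integer(minSep_px)))
  m <- EBImage::imageData(ws)
  storage.mode(m) <- "integer"
  m
}

#' Detect particles in a flattened topograph
#'
#' Thresholds the (optionally despeckled) height field above the
#' background, groups pixels by 8-connectivity, removes regions smaller
#' than the minimum area, and flags regions touching the border.
#'
#' @param t a flattened [Topograph-class].
#' @param config a [detectionConfig()].
#' @param background optional precomputed [estimateBackground()] result.
#' @return list with `regions` (list of pixel linear indices), `border`
#'   (logical per region), `labels` (label matrix), `threshold_nm`
#'   (absolute threshold above background used), `background`, and the
#'   despeckled image used for measurement.
#' @export
detectParticles <- function(t, config = detectionConfig(),
                            background = NULL) {
  stopifnot(is(t, "Topograph"), inherits(config, "DetectionConfig"))
  z <- t@heights
  p <- t@pixelSize
  bg <- background %||% estimateBackground(t)
  zf <- measureImage(z, config, bg)
  thr <- config$threshold_nm %||%
    max(config$thresholdFactor * bg$sd, config$thresholdFloor)
  if (thr < bg$sd)
    warning("detection threshold (", signif(thr, 3),
            " nm) is below the background sd (", signif(bg$sd, 3), " nm)")
  mask <- zf > bg$level + thr
  lab <- labelMask8(mask)
  if (config$watershed && max(lab) > 0L)
    lab <- watershedSplit(lab, pmax(zf - bg$level, 0),
                          config$watershedMinSep_nm / p)
  minPx <- max(1L, ceiling(config$minArea_nm2 / p^2))
  if (max(lab) > 0L) {
    pix <- split(which(lab > 0L), lab[lab > 0L])
    pix <- pix[lengths(pix) >= minPx]
  } else pix <- list()
  nr <- nrow(z); nc <- ncol(z)
  border <- vapply(pix, function(ii) {
    r <- ((ii - 1L) %% nr) + 1L; cc <- ((ii - 1L) %/% nr) + 1L
    any(r == 1L | r == nr | cc == 1L | cc == nc)
  }, logical(1))
  list(regions = unname(pix), border = unname(border), labels = lab,
       threshold_nm = thr, background = bg, despeckled = zf)
}

# measure one region (pixel linear indices) -> one-row data.frame
emptyMeasurement <- function() {
  data.frame(particle_id = integer(), x_nm = numeric(), y_nm = numeric(),
             height_nm = numeric(), area_nm2 = numeric(),
             feret_max_nm = numeric(), feret_min_nm = numeric(),
             feret_boxdiag_nm = numeric(), eqdiam_nm = numeric(),
             roundness = numeric(), npx = integer(),
             class_label = character(), border_flag = logical())
}

measureRegion <- function(pixels, t, bg, config, zf, id = 1L,
                          borderFlag = FALSE) {
  if (!length(pixels)) return(emptyMeasurement())
  z <- t@heights
  p <- t@pixelSize
  nr <- nrow(z)
  zr <- zf
  level <- bg$level
  if (config$localBackground) {
    rows <- ((pixels - 1L) %% nr) + 1L
    cols <- ((pixels - 1L) %/% nr) + 1L
    m <- 4L
    ri <- max(1L, min(rows) - m):min(nr, max(rows) + m)
    ci <- max(1L, min(cols) - m):min(ncol(z), max(cols) + m)
    box <- as.vector(outer(ri, (ci - 1L) * nr, `+`))
    ann <- setdiff(box, pixels)
    if (length(ann) >= 8L) level <- stats::median(z[ann])
  }
  peak <- max(zr[pixels])
  height <- peak - level
  # footprint membership on the raw heights: the denoised read sets the
  # half-max level, but footprint pixels are judged as scanned
  fp <- if (config$halfMax) pixels[z[pixels] >= level + height / 2] else pixels
  out <- data.frame(particle_id = id, x_nm = NA_real_, y_nm = NA_real_,
                    height_nm = height, area_nm2 = NA_real_,
                    feret_max_nm = NA_real_, feret_min_nm = NA_real_,
                    feret_boxdiag_nm = NA_real_, eqdiam_nm = NA_real_,
                    roundness = NA_real_, npx = length(fp),
                    class_label = "debris", border_flag = borderFlag)
  if (length(fp) < 4L) return(out)
  rows <- ((fp - 1L) %% nr) + 1L
  cols <- ((fp - 1L) %/% nr) + 1L
  centers <- cbind(pxCenters(cols, p), pxCenters(rows, p))
  out$x_nm <- mean(centers[, 1]); out$y_nm <- mean(centers[, 2])
  out$area_nm2 <- length(fp) * p^2
  hull <- convexHull(footprintHullPoints(centers, p))
  fmax <- feretMaxCalipers(hull)
  fmin <- feretMinCalipers(hull)
  pe <- principalExtents(centers, hull)
  out$feret_max_nm <- fmax
  out$feret_min_nm <- fmin
  out$feret_boxdiag_nm <- feretBoxdiag(pe$major, pe$minor)
  out$eqdiam_nm <- 2 * sqrt(out$area_nm2 / pi)
  out$roundness <- if (config$roundnessMode == "ellipse") {
    pe$minor / pe$major
  } else if (fmax > 0) fmin / fmax else NA_real_
  out$class_label <- "unclassified"
  out
}

#' Measure a detected particle
#'
#' Computes the Table-1-style morphometry of one detected region: peak
#' height above background, half-max footprint area, rotating-calipers
#' maximum/minimum Feret diameters, the box-diagonal Feret (diagonal of
#' the principal-axis bounding box -- the convention used for complex
#' diameters), equivalent-circle diameter and roundness
#' (feret_min / feret_max; 1 for a perfect circle). Footprints smaller
#' than 4 px are rejected as debris.
#'
#' @param region pixel linear indices of one region from
#'   [detectParticles()].
#' @param t the flattened [Topograph-class].
#' @param background an [estimateBackground()] result.
#' @param config a [detectionConfig()].
#' @param id particle id for the output row.
#' @return one-row data.frame of `ParticleMeasurement` fields.
#' @export
measureParticle <- function(region, t, background, config = detectionConfig(),
                            id = 1L) {
  zf <- measureImage(t@heights, config, background)
  measureRegion(region, t, background, config, zf, id = id)
}

#' Classify measured particles
#'
#' Applies the [classificationGates()] to a measurement table, assigning
#' `nucleosome`, `complex` or `debris` to each row.
#'
#' @param measurements data.frame from [analyzeTopograph()] /
#'   [measureParticle()].
#' @param gates a [classificationGates()].
#' @return the data.frame with `class_label` filled in.
#' @export
classifyParticles <- function(measurements, gates = classificationGates()) {
  stopifnot(inherits(gates, "ClassificationGates"))
  m <- measurements
  if (!nrow(m)) return(m)
  gf <- if (gates$gateFeret == "boxdiag") m$feret_boxdiag_nm else m$feret_max_nm
  h <- m$height_nm
  lab <- rep("debris", nrow(m))
  isNuc <- !is.na(gf) & h >= gates$nucHeight_nm[1] &
    h < gates$nucHeight_nm[2] & gf <= gates$nucFeretMax_nm
  isCpx <- !is.na(gf) & !isNuc &
    (h >= gates$cpxHeight_nm | gf > gates$cpxFeret_nm) &
    m$area_nm2 >= gates$cpxMinArea_nm2
  lab[isNuc] <- "nucleosome"
  lab[isCpx] <- "complex"
  lab[m$npx < 4L] <- "debris"
  m$class_label <- lab
  m
}

#' Full morphometry of one topograph
#'
#' Convenience pipeline stage: flatten (optional), detect, measure and
#' classify every particle of a topograph.
#'
#' @param t a [Topograph-class].
#' @param config a [detectionConfig()].
#' @param gates a [classificationGates()].
#' @param flatten run [flattenPlane()] first (default TRUE).
#' @param keepBorder keep border-touching regions (flagged) instead of
#'   dropping them (default follows `config$excludeBorder`).
#' @return data.frame of per-particle measurements.
#' @export
analyzeTopograph <- function(t, config = detectionConfig(),
                             gates = classificationGates(),
                             flatten = TRUE, keepBorder = !config$excludeBorder) {
  if (flatten) t <- flattenPlane(t)$topograph
  det <- detectParticles(t, config)
  keep <- if (keepBorder) seq_along(det$regions) else which(!det$border)
  rows <- lapply(seq_along(keep), function(k) {
    i <- keep[k]
    measureRegion(det$regions[[i]], t, det$background, config,
                  det$despeckled, id = k, borderFlag = det$border[i])
  })
  m <- if (length(rows)) do.call(rbind, rows) else emptyMeasurement()
  classifyParticles(m, gates)
}

#' Population summary table
#'
#' Per class and per metric: mean, sd and n, in the layout of a
#' measurement-summary table (one row per class x metric).
#'
#' @param measurements data.frame of particle measurements.
#' @param metrics metric columns to summarize.
#' @param dropDebris exclude debris rows (default TRUE).
#' @return data.frame with columns class, metric, mean, sd, n.
#' @export
summarizePopulation <- function(measurements,
                                metrics = c("height_nm", "feret_max_nm",
                                            "feret_boxdiag_nm", "eqdiam_nm",
                                            "area_nm2", "roundness"),
                                dropDebris = TRUE) {
  m <- measurements
  if (dropDebris && nrow(m)) m <- m[m$class_label != "debris", , drop = FALSE]
  if (!nrow(m)) {
    warning("summarizePopulation: no measurements")
    return(data.frame(class = character(), metric = character(),
                      mean = numeric(), sd = numeric(), n = integer()))
  }
  out <- do.call(rbind, lapply(split(m, m$class_label), function(g) {
    do.call(rbind, lapply(metrics, function(mt) {
      v <- g[[mt]][is.finite(g[[mt]])]
      data.frame(class = g$class_label[1], metric = mt,
                 mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
                 n = length(v))
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Height-Feret correlation
#'
#' R^2 of the linear regression of particle height on Feret diameter, the
#' per-population correlation statistic reported alongside complex
#' morphometry.
#'
#' @param measurements data.frame of particle measurements.
#' @param feret which Feret column to use (default the box-diagonal).
#' @return R^2 in `[0, 1]` (NA with fewer than 3 particles).
#' @export
heightFeretR2 <- function(measurements, feret = "feret_boxdiag_nm") {
  ok <- is.finite(measurements$height_nm) & is.finite(measurements[[feret]])
  if (sum(ok) < 3) return(NA_real_)
  summary(stats::lm(measurements$height_nm[ok] ~ measurements[[feret]][ok]))$r.squared
}
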