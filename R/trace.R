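# Nucleosome-free DNA tracing: low-band segmentation, Zhang-Suen
# skeletonization, spur pruning, path walking with (1, sqrt(2)) chain-code
# step weights, and conversion of contour length to base pairs.

# Zhang-Suen thinning of a logical mask, vectorized over matrix shifts.
skeletonizeMask <- function(mask) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    cs <- max(1L, 1L + dc):min(nc, nc + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours clockwise from north: P2 P3 P4 P5 P6 P7 P8 P9
      P2 <- shift(m, 1, 0);  P3 <- shift(m, 1, -1)
      P4 <- shift(m, 0, -1); P5 <- shift(m, -1, -1)
      P6 <- shift(m, -1, 0); P7 <- shift(m, -1, 1)
      P8 <- shift(m, 0, 1);  P9 <- shift(m, 1, 1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (!P2 & P3) + (!P3 & P4) + (!P4 & P5) + (!P5 & P6) +
           (!P6 & P7) + (!P7 & P8) + (!P8 & P9) + (!P9 & P2)
      cond <- m & B >= 2 & B <= 6 & A == 1
      if (sub == 1) {
        cond <- cond & !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        cond <- cond & !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  thinCleanup(m)
}

# Zhang-Suen can leave 2-px-wide diagonal staircases whose pixels all have
# degree >= 3 and would be mistaken for junctions. Remove redundant pixels
# sequentially: a pixel whose ring transition number is 1 can be deleted
# without breaking connectivity; restrict to degree >= 3 so endpoints and
# line interiors are untouched.
ringOffsets <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
                    c(1, 0), c(1, -1), c(0, -1), c(-1, -1))

# 8-adjacency among the ring cells themselves: consecutive positions,
# plus orthogonal neighbours across a missing corner (N-E, E-S, S-W, W-N)
ringAdjacency <- local({
  adj <- matrix(FALSE, 8, 8)
  for (a in 1:8) for (b in 1:8) {
    if (a == b) next
    d <- abs(ringOffsets[[a]] - ringOffsets[[b]])
    adj[a, b] <- max(d) <= 1L
  }
  adj
})

ringNeighbours <- function(m, i, nr, nc) {
  r <- ((i - 1L) %% nr) + 1L; cc <- ((i - 1L) %/% nr) + 1L
  nb <- logical(8)
  for (k in 1:8) {
    r2 <- r + ringOffsets[[k]][1]; c2 <- cc + ringOffsets[[k]][2]
    nb[k] <- r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc && m[r2, c2]
  }
  nb
}

# number of connected foreground arcs around a pixel: 1 for a line end or
# interior of a blob edge, 2 for a through-path, >= 3 for a true branch
ringComponents <- function(nb) {
  seen <- rep(FALSE, 8)
  comps <- 0L
  for (k in 1:8) {
    if (!nb[k] || seen[k]) next
    comps <- comps + 1L
    stack <- k
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      nxt <- which(nb & ringAdjacency[v, ] & !seen)
      stack <- c(stack, nxt)
    }
  }
  comps
}

thinCleanup <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  repeat {
    deg <- maskDegree(m)
    cand <- which(m & deg >= 3L)
    if (!length(cand)) break
    removed <- FALSE
    for (i in cand) {
      if (!m[i]) next
      if (ringComponents(ringNeighbours(m, i, nr, nc)) == 1L) {
        m[i] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  m
}

# 8-neighbour degree of each TRUE pixel
maskDegree <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  deg <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    cs <- max(1L, 1L + dc):min(nc, nc + dc)
    deg[rs, cs] <- deg[rs, cs] + m[rs - dr, cs - dc]
  }
  deg * m
}

# remove skeleton spurs shorter than minLen pixels (dangling paths that
# terminate at a junction); free-standing short paths are kept
pruneSpurs <- function(skel, minLen = 5L) {
  nr <- nrow(skel); nc <- ncol(skel)
  repeat {
    deg <- maskDegree(skel)
    ends <- which(skel & deg == 1L)
    if (!length(ends)) break
    removedAny <- FALSE
    for (e in ends) {
      if (!skel[e]) next
      path <- integer(0)
      cur <- e; prev <- 0L
      isSpur <- FALSE
      repeat {
        path <- c(path, cur)
        if (length(path) >= minLen) break
        r <- ((cur - 1L) %% nr) + 1L; cc <- ((cur - 1L) %/% nr) + 1L
        nbr <- integer(0)
        for (dr in -1:1) for (dc in -1:1) {
          if (dr == 0 && dc == 0) next
          r2 <- r + dr; c2 <- cc + dc
          if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
          ii <- (c2 - 1L) * nr + r2
          if (skel[ii] && ii != prev) nbr <- c(nbr, ii)
        }
        if (!length(nbr)) break                      # free-standing path
        if (length(nbr) > 1L || deg[nbr[1]] >= 3L) { # reached a junction
          isSpur <- TRUE
          break
        }
        prev <- cur; cur <- nbr[1]
      }
      if (isSpur && length(path) < minLen) {
        skel[path] <- FALSE
        removedAny <- TRUE
      }
    }
    if (!removedAny) break
  }
  skel
}

#' Segment filament (naked-DNA) pixels
#'
#' Selects pixels in a low height band above the background -- DNA ridges
#' sit well below the nucleosome height gate -- after masking out particle
#' footprints (dilated so particle skirts are not counted as DNA). Small
#' components are dropped.
#'
#' @param t a flattened [Topograph-class].
#' @param low_band_nm height band (nm above background) taken as filament
#'   signal; default `c(0.2, 0.8)`.
#' @param particleLabels optional label matrix from [detectParticles()];
#'   labelled pixels (dilated by `dilate_px`) are removed.
#' @param dilate_px dilation radius (px) applied to the particle mask
#'   (default 4: covers the sub-threshold dome skirt between the
#'   detection threshold and the band floor, plus the segmentation
#'   smoothing halo, in addition to any tip broadening).
#' @param minPx minimum component size kept (default 10).
#' @param background optional [estimateBackground()] result.
#' @param despeckle segment on a 3x3 box-mean smoothed image (default
#'   TRUE): thin ridges sit only a few noise-sd above the band floor, and
#'   an unsmoothed mask grows ragged nubs that the skeleton mistakes for
#'   junctions (a median would also clip the thin crest toward the floor).
#'   Measurement stages keep using the raw heights.
#' @return logical filament mask.
#' @export
segmentFilaments <- function(t, low_band_nm = c(0.2, 0.8),
                             particleLabels = NULL, dilate_px = 4,
                             minPx = 10L, background = NULL,
                             despeckle = TRUE) {
  stopifnot(is(t, "Topograph"))
  z <- if (despeckle) boxFilter3(t@heights) else t@heights
  bg <- background %||% estimateBackground(t)
  rel <- z - bg$level
  mask <- rel >= low_band_nm[1] & rel <= low_band_nm[2]
  if (!is.null(particleLabels) && any(particleLabels > 0L)) {
    pm <- particleLabels > 0L
    if (dilate_px > 0) {
      nr <- nrow(pm); nc <- ncol(pm)
      dil <- pm
      for (dr in -dilate_px:dilate_px) for (dc in -dilate_px:dilate_px) {
        if (dr == 0 && dc == 0) next
        rs <- max(1L, 1L + dr):min(nr, nr + dr)
        cs <- max(1L, 1L + dc):min(nc, nc + dc)
        dil[rs, cs] <- dil[rs, cs] | pm[rs - dr, cs - dc]
      }
      pm <- dil
    }
    mask <- mask & !pm
  }
  lab <- labelMask8(mask)
  if (max(lab) > 0L) {
    keep <- which(tabulate(lab[lab > 0L]) >= minPx)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  mask
}

# walk one simple path (pixel linear indices, all degree <= 2) and return
# the ordered path and its chain-code length
walkPath <- function(pixels, nr, p) {
  n <- length(pixels)
  if (n == 1L)
    return(list(path = pixels, length_nm = 0))
  nbrOf <- function(cur, excl) {
    r <- ((cur - 1L) %% nr) + 1L; cc <- ((cur - 1L) %/% nr) + 1L
    out <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      ii <- (cc + dc - 1L) * nr + (r + dr)
      if (!is.na(match(ii, pixels)) && !(ii %in% excl)) out <- c(out, ii)
    }
    out
  }
  # find an endpoint (one neighbour); cycles start anywhere
  start <- pixels[1]
  for (px in pixels) {
    if (length(nbrOf(px, integer(0))) == 1L) { start <- px; break }
  }
  path <- integer(n)
  path[1] <- start
  visited <- start
  len <- 0
  for (i in 2:n) {
    nb <- nbrOf(path[i - 1L], visited)
    if (!length(nb)) { path <- path[seq_len(i - 1L)]; break }
    # prefer 4-neighbours so diagonal shortcuts do not skip path pixels
    r0 <- ((path[i - 1L] - 1L) %% nr); c0 <- ((path[i - 1L] - 1L) %/% nr)
    rr <- ((nb - 1L) %% nr); ccn <- ((nb - 1L) %/% nr)
    diag <- (abs(rr - r0) + abs(ccn - c0)) == 2L
    nb <- nb[order(diag)][1]
    step <- if ((abs(((nb - 1L) %% nr) - r0) + abs(((nb - 1L) %/% nr) - c0)) == 2L)
      sqrt(2) else 1
    len <- len + step
    path[i] <- nb
    visited <- c(visited, nb)
  }
  list(path = path, length_nm = len * p)
}

#' Convert contour length to base pairs
#'
#' @param contour_length_nm contour length(s) in nm (>= 0).
#' @param rise_per_bp helical rise per base pair (nm; default 0.34, B-form
#'   DNA). Printed in every trace-output header.
#' @return integer base pairs, `round(contour / rise)`.
#' @examples
#' contourToBp(53)    # 156
#' contourToBp(49.98) # 147
#' @export
contourToBp <- function(contour_length_nm, rise_per_bp = 0.34) {
  if (any(contour_length_nm < 0)) stop("contour length must be >= 0")
  if (rise_per_bp <= 0) stop("rise_per_bp must be > 0")
  as.integer(round(contour_length_nm / rise_per_bp))
}

#' Trace filament contours in a binary mask
#'
#' Skeletonizes the mask (Zhang-Suen), prunes spurs shorter than
#' `minSpur_px`, splits branched skeletons at junction pixels (flagged),
#' and walks every simple path end-to-end. Step length is one pixel for
#' 4-neighbour moves and sqrt(2) pixels for diagonal moves. Cyclic
#' skeletons are flagged and opened at an arbitrary pixel.
#'
#' @param mask logical filament mask (from [segmentFilaments()]).
#' @param pixel_size_nm physical pixel edge (nm).
#' @param rise_per_bp conversion constant for the bp estimate (nm/bp).
#' @param minSpur_px spur-pruning threshold (px, default 5).
#' @param minPath_px minimum traced path length kept (px, default 5).
#' @return data.frame of `FilamentTrace` records: trace_id, contour_nm,
#'   bp, end coordinates (nm), path pixel count, end_to_end_nm, branched
#'   and cyclic flags; ordered pixel paths in `attr(, "paths")`.
#' @export
traceContour <- function(mask, pixel_size_nm = 1, rise_per_bp = 0.34,
                         minSpur_px = 5L, minPath_px = 5L) {
  nr <- nrow(mask)
  skel <- pruneSpurs(skeletonizeMask(mask), minSpur_px)
  lab <- labelMask8(skel)
  out <- list(); paths <- list()
  if (max(lab) > 0L) {
    degAll <- maskDegree(skel)
    ncg <- ncol(mask)
    comps <- split(which(lab > 0L), lab[lab > 0L])
    tid <- 0L
    for (comp in comps) {
      deg <- degAll[comp]
      # true branch points have >= 3 connected neighbour arcs; staircase
      # corners can reach degree 3 with only two arcs and are path pixels
      arms <- vapply(comp, function(i) {
        if (degAll[i] < 3L) return(degAll[i])
        ringComponents(ringNeighbours(skel, i, nr, ncg))
      }, integer(1))
      branched <- any(arms >= 3L)
      cyclic <- length(comp) > 2L && all(deg == 2L) && !branched
      pieces <- if (branched) {
        sub <- matrix(FALSE, nr, ncol(mask))
        sub[comp[arms <= 2L]] <- TRUE
        lb <- labelMask8(sub)
        if (max(lb) > 0L) split(which(lb > 0L), lb[lb > 0L]) else list()
      } else list(comp)
      for (pc in pieces) {
        if (length(pc) < minPath_px) next
        w <- walkPath(pc, nr, pixel_size_nm)
        tid <- tid + 1L
        e1 <- w$path[1]; e2 <- w$path[length(w$path)]
        r1 <- ((e1 - 1L) %% nr) + 1L; c1 <- ((e1 - 1L) %/% nr) + 1L
        r2 <- ((e2 - 1L) %% nr) + 1L; c2 <- ((e2 - 1L) %/% nr) + 1L
        out[[tid]] <- data.frame(
          trace_id = tid, contour_nm = w$length_nm,
          bp = contourToBp(w$length_nm, rise_per_bp),
          x_start_nm = pxCenters(c1, pixel_size_nm),
          y_start_nm = pxCenters(r1, pixel_size_nm),
          x_end_nm = pxCenters(c2, pixel_size_nm),
          y_end_nm = pxCenters(r2, pixel_size_nm),
          npx = length(w$path),
          end_to_end_nm = sqrt((pxCenters(c1, pixel_size_nm) -
                                  pxCenters(c2, pixel_size_nm))^2 +
                               (pxCenters(r1, pixel_size_nm) -
                                  pxCenters(r2, pixel_size_nm))^2),
          branched = branched, cyclic = cyclic)
        paths[[tid]] <- w$path
      }
    }
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(trace_id = integer(), contour_nm = numeric(), bp = integer(),
               x_start_nm = numeric(), y_start_nm = numeric(),
               x_end_nm = numeric(), y_end_nm = numeric(), npx = integer(),
               end_to_end_nm = numeric(), branched = logical(),
               cyclic = logical())
  attr(df, "rise_per_bp") <- rise_per_bp
  attr(df, "paths") <- paths
  df
}

#' Segment and trace filaments in one call
#'
#' Convenience stage: estimate background, detect particles (for
#' masking), segment the low band and trace contours.
#'
#' @param t a flattened [Topograph-class].
#' @param config a [detectionConfig()] for the particle masking step.
#' @param low_band_nm,rise_per_bp,minSpur_px as in the underlying stages.
#' @param flatten run [flattenPlane()] first (default TRUE).
#' @return as [traceContour()].
#' @export
traceFilaments <- function(t, config = detectionConfig(),
                           low_band_nm = c(0.2, 0.8), rise_per_bp = 0.34,
                           minSpur_px = 5L, flatten = TRUE) {
  if (flatten) t <- flattenPlane(t)$topograph
  bg <- estimateBackground(t)
  # particles masked before DNA segmentation must sit above the DNA band,
  # otherwise noisy ridge crests near the detection floor are masked as
  # particles and cut the filaments
  cfgMask <- config
  cfgMask$threshold_nm <- max(config$threshold_nm %||% 0,
                              config$thresholdFloor,
                              low_band_nm[2] + 3 * bg$sd)
  det <- detectParticles(t, cfgMask, background = bg)
  mask <- segmentFilaments(t, low_band_nm, particleLabels = det$labels,
                           background = bg)
  traceContour(mask, t@pixelSize, rise_per_bp, minSpur_px)
}
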