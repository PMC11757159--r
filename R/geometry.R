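# Planar geometry used by the morphometry stage: convex hulls, rotating
# calipers, principal-axis extents, and the paper-compatible box-diagonal
# Feret convention.

#' Box-diagonal Feret diameter
#'
#' Combines two orthogonal footprint extents into a single caliper-style
#' diameter as the diagonal of the principal-axis bounding box,
#' `sqrt(a^2 + b^2)`. This is the convention under which an oval footprint
#' of extents 15 x 17 nm has a Feret diameter of ~22.6 nm, and it is the
#' convention used for the large-complex diameters reported by the pipeline
#' (column `feret_boxdiag_nm`).
#'
#' @param extent_a,extent_b orthogonal extents (nm), both > 0; vectorized.
#' @return `sqrt(extent_a^2 + extent_b^2)` (nm).
#' @examples
#' feretBoxdiag(15, 17)  # ~22.67
#' feretBoxdiag(3, 4)    # 5
#' @export
feretBoxdiag <- function(extent_a, extent_b) {
  if (!all(is.finite(extent_a)) || !all(is.finite(extent_b)) ||
      any(extent_a <= 0) || any(extent_b <= 0))
    stop("feretBoxdiag: extents must be finite and > 0")
  sqrt(extent_a^2 + extent_b^2)
}

# Convex hull of a set of points, counter-clockwise, as an n x 2 matrix.
convexHull <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) == 1L) return(pts)
  if (nrow(pts) == 2L) return(pts)
  h <- grDevices::chull(pts[, 1], pts[, 2])  # clockwise indices
  pts[rev(h), , drop = FALSE]                # counter-clockwise
}

# Rotating-calipers maximum Feret diameter: the largest distance between
# two hull vertices, found by sweeping antipodal pairs around the hull.
# Exact for convex polygons; O(h) after the hull.
feretMaxCalipers <- function(hull) {
  n <- nrow(hull)
  if (n == 1L) return(0)
  if (n == 2L) return(sqrt(sum((hull[1, ] - hull[2, ])^2)))
  area2 <- function(a, b, c)
    abs((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  best <- 0
  j <- 2L
  nxt <- function(i) if (i == n) 1L else i + 1L
  for (i in seq_len(n)) {
    i2 <- nxt(i)
    # advance j while the triangle height over edge (i, i2) still grows
    while (area2(hull[i, ], hull[i2, ], hull[nxt(j), ]) >
           area2(hull[i, ], hull[i2, ], hull[j, ])) {
      j <- nxt(j)
    }
    best <- max(best,
                sum((hull[i, ] - hull[j, ])^2),
                sum((hull[i2, ] - hull[j, ])^2))
  }
  sqrt(best)
}

# Rotating-calipers minimum width: for each hull edge, the largest distance
# of any hull vertex from the edge's supporting line; the minimum over
# edges is the minimum caliper width of the convex polygon.
feretMinCalipers <- function(hull) {
  n <- nrow(hull)
  if (n <= 2L) return(0)
  wmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < .Machine$double.eps) next
    nrm <- c(-e[2], e[1]) / len
    d <- (hull[, 1] - hull[i, 1]) * nrm[1] + (hull[, 2] - hull[i, 2]) * nrm[2]
    wmin <- min(wmin, max(abs(d)))
  }
  if (!is.finite(wmin)) 0 else wmin
}

# Brute-force maximum pairwise distance; independent oracle for the
# calipers (used in tests, exported for reuse as a cross-check).
feretMaxBruteForce <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  d <- as.matrix(stats::dist(pts))
  max(d)
}

# Principal-axis extents of a footprint. Axes from the covariance of the
# pixel centers (area-weighted, stable); extents as the spread of the
# supplied hull points projected on those axes.
principalExtents <- function(centers, pts) {
  if (nrow(centers) == 1L) {
    ax <- diag(2)
  } else {
    cv <- stats::cov(centers)
    if (!all(is.finite(cv)) || sum(abs(cv)) < .Machine$double.eps) {
      ax <- diag(2)
    } else {
      ax <- eigen(cv, symmetric = TRUE)$vectors
    }
  }
  e <- sort(c(diff(range(pts %*% ax[, 1])), diff(range(pts %*% ax[, 2]))),
            decreasing = TRUE)
  list(major = e[1], minor = e[2], axes = ax)
}

# Hull support points of a footprint under the half-pixel edge convention:
# each pixel is represented by its center expanded by a half-pixel square
# (center +/- p/4). A full-corner hull is the footprint Minkowski-dilated
# by one whole pixel square (one pixel too wide in every direction), a
# center-only hull is symmetrically too narrow; rim pixels are on average
# half-covered by the continuous footprint, so the half-square expansion
# estimates continuous extents without pixel-quantization bias. Using one
# point set for every Feret quantity keeps feret_min <= feret_max <=
# feret_boxdiag structural.
footprintHullPoints <- function(centers, p) {
  q <- p / 4
  rbind(cbind(centers[, 1] - q, centers[, 2] - q),
        cbind(centers[, 1] + q, centers[, 2] - q),
        cbind(centers[, 1] - q, centers[, 2] + q),
        cbind(centers[, 1] + q, centers[, 2] + q))
}

# --- convex polygon helpers used by the generator -------------------------

# Vertices of a unit polygon with nVertices, first vertex on +x; scaled so
# its principal-axis extents are exactly (a, b), then rotated by theta.
# Returns an n x 2 matrix centered on the origin.
polygonWithExtents <- function(nVertices, a, b, theta = 0) {
  stopifnot(nVertices >= 3L, a > 0, b > 0)
  ang <- 2 * pi * (seq_len(nVertices) - 1L) / nVertices
  v <- cbind(cos(ang), sin(ang))
  v <- sweep(v, 2, colMeans(v))  # center (regular polygons already centered)
  # scale x and y so the extents along the coordinate axes equal (a, b);
  # the polygon is symmetric about the x axis, so these are principal axes
  sx <- a / diff(range(v[, 1]))
  sy <- b / diff(range(v[, 2]))
  v <- cbind(v[, 1] * sx, v[, 2] * sy)
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  v %*% t(rot)
}

# Gauge (radial scale) function of a convex polygon containing the origin:
# t(x) such that x lies on the boundary of t * P. Vectorized over query
# points (m x 2). t <= 1 inside P.
polygonGauge <- function(poly, pts) {
  n <- nrow(poly)
  tmax <- rep(0, nrow(pts))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- poly[j, ] - poly[i, ]
    nrm <- c(e[2], -e[1])                    # outward for CCW polygons
    h <- sum(nrm * poly[i, ])
    if (h < 0) { nrm <- -nrm; h <- -h }      # orientation-agnostic
    ti <- (pts[, 1] * nrm[1] + pts[, 2] * nrm[2]) / h
    tmax <- pmax(tmax, ti)
  }
  tmax
}

# --- 3x3 median despeckle -------------------------------------------------

# Vectorized 3x3 median filter (Paeth median-of-9 sorting network) with
# replicated borders. Used to stabilize peak-height reads against
# single-pixel scan noise.
medianFilter3 <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  pad <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  sh <- function(dr, dc) pad[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  p0 <- sh(0, 0); p1 <- sh(0, 1); p2 <- sh(0, 2)
  p3 <- sh(1, 0); p4 <- sh(1, 1); p5 <- sh(1, 2)
  p6 <- sh(2, 0); p7 <- sh(2, 1); p8 <- sh(2, 2)
  srt <- function(a, b) list(lo = pmin(a, b), hi = pmax(a, b))
  s <- srt(p1, p2); p1 <- s$lo; p2 <- s$hi
  s <- srt(p4, p5); p4 <- s$lo; p5 <- s$hi
  s <- srt(p7, p8); p7 <- s$lo; p8 <- s$hi
  s <- srt(p0, p1); p0 <- s$lo; p1 <- s$hi
  s <- srt(p3, p4); p3 <- s$lo; p4 <- s$hi
  s <- srt(p6, p7); p6 <- s$lo; p7 <- s$hi
  s <- srt(p1, p2); p1 <- s$lo; p2 <- s$hi
  s <- srt(p4, p5); p4 <- s$lo; p5 <- s$hi
  s <- srt(p7, p8); p7 <- s$lo; p8 <- s$hi
  p3 <- pmax(p0, p3); p5 <- pmin(p5, p8)
  s <- srt(p4, p7); p4 <- s$lo; p7 <- s$hi
  p6 <- pmax(p3, p6); p4 <- pmax(p1, p4); p2 <- pmin(p2, p5)
  p4 <- pmin(p4, p7)
  s <- srt(p4, p2); p4 <- s$lo; p2 <- s$hi
  p4 <- pmax(p6, p4)
  pmin(p4, p2)
}

# 3x3 box (mean) filter with replicated borders; used to stabilize
# low-band segmentation where ridges sit a few noise-sd above the floor
boxFilter3 <- function(z) {
  nr <- nrow(z); nc <- ncol(z)
  pad <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, nc, drop = FALSE])
  sh <- function(dr, dc) pad[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  (sh(0, 0) + sh(0, 1) + sh(0, 2) + sh(1, 0) + sh(1, 1) + sh(1, 2) +
     sh(2, 0) + sh(2, 1) + sh(2, 2)) / 9
}

# separable Gaussian smoothing (radius-2 kernel) with replicated borders;
# light denoising before peak reads on noisy scans
gaussianSmooth <- function(z, sigma_px = 0.6) {
  k <- stats::dnorm(-2:2, sd = sigma_px)
  k <- k / sum(k)
  nr <- nrow(z); nc <- ncol(z)
  padR <- rbind(z[1, , drop = FALSE], z[1, , drop = FALSE], z,
                z[nr, , drop = FALSE], z[nr, , drop = FALSE])
  zr <- k[1] * padR[1:nr, ] + k[2] * padR[2:(nr + 1), ] +
    k[3] * padR[3:(nr + 2), ] + k[4] * padR[4:(nr + 3), ] +
    k[5] * padR[5:(nr + 4), ]
  padC <- cbind(zr[, 1, drop = FALSE], zr[, 1, drop = FALSE], zr,
                zr[, nc, drop = FALSE], zr[, nc, drop = FALSE])
  k[1] * padC[, 1:nc] + k[2] * padC[, 2:(nc + 1)] +
    k[3] * padC[, 3:(nc + 2)] + k[4] * padC[, 4:(nc + 3)] +
    k[5] * padC[, 5:(nc + 4)]
}
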