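#' @import methods
NULL

#' Topograph: an AFM height raster
#'
#' The unit of analysis throughout the package. A `Topograph` holds a 2-D
#' raster of surface heights in nanometres together with the physical edge
#' length of one (square) pixel and free-form provenance metadata (field id,
#' seed, preset name, processing history).
#'
#' Pixel conventions: indices are (row, col) with row 1 at the top; pixel
#' (i, j) covers the half-open square `[(j-1)p, jp) x [(i-1)p, ip)` in
#' physical nm coordinates with origin at the top-left pixel corner, where
#' `p` is the pixel size.
#'
#' @slot heights numeric matrix of heights (nm), all finite.
#' @slot pixelSize positive scalar, physical edge of one pixel (nm).
#' @slot meta list of free-form provenance (seed, preset, flags).
#'
#' @aliases Topograph-class
#' @exportClass Topograph
setClass("Topograph",
  representation(heights = "matrix", pixelSize = "numeric", meta = "list"),
  prototype(heights = matrix(0, 16, 16), pixelSize = 1, meta = list())
)

setValidity("Topograph", function(object) {
  h <- object@heights
  if (!is.numeric(h)) return("heights must be a numeric matrix")
  if (nrow(h) < 16L || ncol(h) < 16L)
    return("heights must be at least 16 x 16 pixels")
  if (!all(is.finite(h))) return("all height values must be finite")
  p <- object@pixelSize
  if (length(p) != 1L || !is.finite(p) || p <= 0)
    return("pixelSize must be a single positive finite number (nm)")
  TRUE
})

#' Construct a Topograph
#'
#' @param heights numeric matrix of heights in nm (>= 16 x 16, all finite).
#' @param pixelSize physical pixel edge length in nm (> 0).
#' @param meta list of free-form provenance metadata.
#' @return A [Topograph-class] object.
#' @examples
#' t <- Topograph(matrix(0, 32, 32), pixelSize = 1)
#' dim(t)
#' @export
Topograph <- function(heights, pixelSize = 1, meta = list()) {
  storage.mode(heights) <- "double"
  new("Topograph", heights = heights, pixelSize = as.numeric(pixelSize),
      meta = meta)
}

#' @describeIn Topograph Extract the height matrix (nm).
#' @param x,object a `Topograph`.
#' @export
setGeneric("heights", function(x) standardGeneric("heights"))

#' @rdname Topograph
#' @export
setMethod("heights", "Topograph", function(x) x@heights)

#' @describeIn Topograph Extract the pixel size (nm / px).
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname Topograph
#' @export
setMethod("pixelSize", "Topograph", function(x) x@pixelSize)

#' @describeIn Topograph Extract the metadata list.
#' @export
setGeneric("topoMeta", function(x) standardGeneric("topoMeta"))

#' @rdname Topograph
#' @export
setMethod("topoMeta", "Topograph", function(x) x@meta)

#' @rdname Topograph
#' @export
setMethod("dim", "Topograph", function(x) dim(x@heights))

setMethod("show", "Topograph", function(object) {
  d <- dim(object@heights)
  rng <- range(object@heights)
  cat(sprintf("Topograph: %d x %d px at %g nm/px (%.3g x %.3g nm)\n",
              d[1], d[2], object@pixelSize,
              d[2] * object@pixelSize, d[1] * object@pixelSize))
  cat(sprintf("  height range: [%.3g, %.3g] nm\n", rng[1], rng[2]))
  if (length(object@meta)) {
    keys <- names(object@meta)
    shown <- keys[keys %in% c("preset", "seed", "field_id", "flattened")]
    for (k in shown) cat(sprintf("  %s: %s\n", k,
                                 paste(format(object@meta[[k]]), collapse = " ")))
  }
  invisible(NULL)
})

# internal: replace the height matrix, keeping/merging metadata
setTopoHeights <- function(x, h, extraMeta = list()) {
  m <- x@meta
  m[names(extraMeta)] <- extraMeta
  Topograph(h, x@pixelSize, m)
}
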