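# Formats and the end-to-end pipeline: plain-text topograph I/O
# (matrix TSV and XYZ), lossless YAML configuration, deterministic CSV
# tables and the run manifest.

fmtNum <- function(x) sprintf("%.17g", x)

#' Write a topograph to plain text
#'
#' Two dialects: `matrix_tsv` -- a 3-line header (`# rows:`, `# cols:`,
#' `# pixel_size_nm:`) followed by the tab-separated height matrix in nm
#' -- and `xyz_text` -- three tab-separated columns x_nm, y_nm, z_nm, one
#' pixel per line. Full double precision; a write/read round trip is
#' bit-identical.
#'
#' @param t a [Topograph-class].
#' @param path output file path.
#' @param dialect `"matrix_tsv"` (default) or `"xyz_text"`.
#' @return `path`, invisibly.
#' @export
writeTopograph <- function(t, path, dialect = c("matrix_tsv", "xyz_text")) {
  stopifnot(is(t, "Topograph"))
  dialect <- match.arg(dialect)
  z <- t@heights
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "matrix_tsv") {
    writeLines(c(sprintf("# rows: %d", nrow(z)),
                 sprintf("# cols: %d", ncol(z)),
                 sprintf("# pixel_size_nm: %s", fmtNum(t@pixelSize))), con)
    utils::write.table(matrix(fmtNum(z), nrow(z), ncol(z)), con,
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    p <- t@pixelSize
    xs <- pxCenters(rep(seq_len(ncol(z)), each = nrow(z)), p)
    ys <- pxCenters(rep(seq_len(nrow(z)), times = ncol(z)), p)
    utils::write.table(cbind(fmtNum(xs), fmtNum(ys), fmtNum(as.vector(z))),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a topograph from plain text
#'
#' Counterpart of [writeTopograph()]. The XYZ dialect requires a complete
#' regular grid: unique sorted x and y spacings must agree within 1e-6
#' (relative), rows may appear in any order, and a missing grid point is
#' an error naming the gap coordinates.
#'
#' @param path input file path.
#' @param dialect `"auto"` (default: matrix when the `# rows:` header is
#'   present), `"matrix_tsv"` or `"xyz_text"`.
#' @return a [Topograph-class].
#' @export
readTopograph <- function(path, dialect = c("auto", "matrix_tsv",
                                            "xyz_text")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (dialect == "auto")
    dialect <- if (length(lines) && grepl("^# rows:", lines[1]))
      "matrix_tsv" else "xyz_text"
  if (dialect == "matrix_tsv") {
    if (length(lines) < 4L)
      stop(path, ": matrix_tsv needs a 3-line header plus data")
    hdr <- function(i, key) {
      if (!grepl(paste0("^# ", key, ":"), lines[i]))
        stop(path, " line ", i, ": expected '# ", key, ":' header")
      as.numeric(sub(paste0("^# ", key, ":\\s*"), "", lines[i]))
    }
    nr <- as.integer(hdr(1, "rows")); nc <- as.integer(hdr(2, "cols"))
    px <- hdr(3, "pixel_size_nm")
    body <- lines[-(1:3)]
    body <- body[nzchar(body)]
    if (length(body) != nr)
      stop(path, ": expected ", nr, " data rows, found ", length(body))
    z <- matrix(NA_real_, nr, nc)
    for (i in seq_len(nr)) {
      f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
      if (length(f) != nc)
        stop(path, " line ", i + 3L, ": expected ", nc, " columns, found ",
             length(f), " (ragged matrix)")
      v <- suppressWarnings(as.numeric(f))
      if (anyNA(v)) {
        bad <- which(is.na(v))[1]
        stop(path, " line ", i + 3L, ", column ", bad,
             ": non-numeric cell '", f[bad], "'")
      }
      z[i, ] <- v
    }
    return(Topograph(z, px, meta = list(source = path)))
  }
  # xyz_text
  body <- lines[nzchar(lines) & !grepl("^#", lines)]
  sp <- strsplit(body, "[\t ]+")
  nf <- lengths(sp)
  if (any(nf != 3L))
    stop(path, " line ", which(nf != 3L)[1], ": expected 3 columns (x y z)")
  m <- suppressWarnings(matrix(as.numeric(unlist(sp)), ncol = 3,
                               byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop(path, " line ", bad, ": non-numeric cell")
  }
  xs <- sort(unique(m[, 1])); ys <- sort(unique(m[, 2]))
  gridSpacing <- function(v, axis) {
    if (length(v) < 2L) stop(path, ": degenerate ", axis, " grid")
    d <- diff(v)
    if (max(d) - min(d) > 1e-6 * max(abs(d)))
      stop(path, ": irregular ", axis, " spacing (", fmtNum(min(d)), " vs ",
           fmtNum(max(d)), " nm)")
    mean(d)
  }
  dx <- gridSpacing(xs, "x"); dy <- gridSpacing(ys, "y")
  if (abs(dx - dy) > 1e-6 * max(dx, dy))
    stop(path, ": x spacing (", fmtNum(dx), ") != y spacing (", fmtNum(dy),
         ") -- pixels must be square")
  nr <- length(ys); nc <- length(xs)
  if (nrow(m) != nr * nc) {
    have <- paste(match(m[, 1], xs), match(m[, 2], ys))
    all_ <- as.vector(outer(seq_len(nc), seq_len(nr), paste))
    gap <- setdiff(all_, have)[1]
    ij <- as.integer(strsplit(gap, " ")[[1]])
    stop(path, ": incomplete grid; missing point at x = ",
         fmtNum(xs[ij[1]]), ", y = ", fmtNum(ys[ij[2]]), " nm")
  }
  z <- matrix(NA_real_, nr, nc)
  z[cbind(match(m[, 2], ys), match(m[, 1], xs))] <- m[, 3]
  if (anyNA(z)) stop(path, ": duplicate and missing grid points")
  Topograph(z, dx, meta = list(source = path))
}

#' Pipeline configuration
#'
#' Bundles every tunable of the pipeline -- detection, classification
#' gates, background mode, the DNA band and bp conversion, statistics
#' defaults and the seed -- into one serializable object. All lengths are
#' nm, areas nm^2, probabilities dimensionless.
#'
#' @param detection a [detectionConfig()].
#' @param gates a [classificationGates()].
#' @param low_band_nm DNA segmentation band (nm above background).
#' @param rise_per_bp bp conversion constant (nm/bp).
#' @param alpha significance level for group statistics.
#' @param min_shift_nm immuno-AFM positive-shift floor (nm).
#' @param trace_dna run the DNA tracing stage in [runPipeline()].
#' @param seed integer seed echoed into outputs.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(detection = detectionConfig(),
                           gates = classificationGates(),
                           low_band_nm = c(0.2, 0.8), rise_per_bp = 0.34,
                           alpha = 0.05, min_shift_nm = 0.5,
                           trace_dna = TRUE, seed = 1L) {
  structure(list(detection = detection, gates = gates,
                 low_band_nm = low_band_nm, rise_per_bp = rise_per_bp,
                 alpha = alpha, min_shift_nm = min_shift_nm,
                 trace_dna = trace_dna, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Write / read a pipeline configuration (YAML)
#'
#' Lossless round trip (15 significant digits); unknown keys in a read
#' file are rejected rather than silently defaulted.
#'
#' @param config a [pipelineConfig()].
#' @param path YAML file path.
#' @return `writeConfig`: `path` invisibly; `readConfig`: the
#'   `PipelineConfig`.
#' @export
writeConfig <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  plain <- rapply(unclass(config), identity, how = "replace")
  yaml::write_yaml(plain, path, precision = 15)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  tpl <- pipelineConfig()
  checkKeys <- function(got, want, where) {
    extra <- setdiff(names(got), names(want))
    if (length(extra))
      stop("unknown config key(s) in ", where, ": ",
           paste(extra, collapse = ", "))
  }
  checkKeys(raw, tpl, "top level")
  checkKeys(raw$detection, tpl$detection, "detection")
  checkKeys(raw$gates, tpl$gates, "gates")
  dropNull <- function(x) x[!vapply(x, is.null, logical(1))]
  det <- do.call(detectionConfig, dropNull(raw$detection %||% list()))
  gat <- do.call(classificationGates, dropNull(raw$gates %||% list()))
  top <- dropNull(raw[setdiff(names(raw), c("detection", "gates"))])
  do.call(pipelineConfig, c(top, list(detection = det, gates = gat)))
}

csvWithHeader <- function(df, path, comments) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", comments), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), "NA", sprintf("%.15g", v)))
  utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
}

#' Write pipeline output tables
#'
#' Deterministic CSV output: fixed headers, units and provenance (seed,
#' config hash) in `#` comment lines, rows ordered by id, 15-digit
#' numeric formatting. Identical inputs produce byte-identical files.
#'
#' @param measurements particle measurement data.frame (may be empty).
#' @param traces filament trace data.frame (may be NULL).
#' @param summaries summary data.frame from [summarizePopulation()] (may
#'   be NULL).
#' @param out_dir output directory (created if needed).
#' @param config optional [pipelineConfig()], hashed into the headers.
#' @param seed optional seed echoed into the headers.
#' @return named character vector of written paths, invisibly.
#' @export
writeTables <- function(measurements, traces = NULL, summaries = NULL,
                        out_dir, config = NULL, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- if (is.null(config)) "none" else {
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeConfig(config, tmp)
    unname(tools::md5sum(tmp))
  }
  prov <- c(sprintf("config_md5: %s", hash),
            sprintf("seed: %s", if (is.null(seed)) "NA" else seed))
  out <- character(0)
  pPath <- file.path(out_dir, "particles.csv")
  m <- measurements[order(measurements$particle_id), , drop = FALSE]
  csvWithHeader(m, pPath,
                c("particle morphometry; units: nm, nm^2", prov))
  out["particles"] <- pPath
  if (!is.null(traces)) {
    tPath <- file.path(out_dir, "traces.csv")
    tr <- traces[order(traces$trace_id), , drop = FALSE]
    rise <- attr(traces, "rise_per_bp") %||% 0.34
    csvWithHeader(tr, tPath,
                  c("filament traces; units: nm, bp",
                    sprintf("rise_per_bp_nm: %s", rise), prov))
    out["traces"] <- tPath
  }
  if (!is.null(summaries)) {
    sPath <- file.path(out_dir, "summary.csv")
    csvWithHeader(summaries, sPath,
                  c("population summary; units: nm, nm^2", prov))
    out["summary"] <- sPath
  }
  invisible(out)
}

#' Run the full analysis pipeline
#'
#' Executes flatten, detect, measure, classify, (optionally) trace
#' and summarize on one or more topographs, logging per-stage counts to
#' standard error. Any stage error aborts with the stage name and input
#' id. Given the same config and inputs the outputs are byte-identical.
#'
#' @param config a [pipelineConfig()].
#' @param inputs a [Topograph-class], a list of them, or a character
#'   vector of topograph file paths.
#' @param out_dir optional output directory for [writeTables()] plus a
#'   JSON run manifest.
#' @param quiet suppress progress logging.
#' @return list with `measurements`, `traces`, `summary`, `manifest`
#'   (and `files` when `out_dir` is given).
#' @export
runPipeline <- function(config = pipelineConfig(), inputs, out_dir = NULL,
                        quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is(inputs, "Topograph")) inputs <- list(inputs)
  if (is.character(inputs)) {
    paths <- inputs
    inputs <- lapply(paths, readTopograph)
  } else paths <- paste0("topograph_", seq_along(inputs))
  log <- function(...) if (!quiet) message("[afmchrom] ", sprintf(...))
  stage <- function(name, id, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed on input '", id, "': ",
           conditionMessage(e), call. = FALSE))
  }
  allM <- list(); allT <- list()
  for (i in seq_along(inputs)) {
    id <- paths[i]
    t0 <- inputs[[i]]
    fl <- stage("flatten", id, flattenPlane(t0))
    tf <- fl$topograph
    log("%s: flattened (background %.3g +/- %.3g nm)", id,
        fl$report$background_level, fl$report$background_sd)
    m <- stage("analyze", id,
               analyzeTopograph(tf, config$detection, config$gates,
                                flatten = FALSE))
    if (nrow(m)) m$input <- id
    log("%s: %d particles (%s)", id, nrow(m),
        paste(names(table(m$class_label)), table(m$class_label),
              sep = "=", collapse = ", "))
    allM[[i]] <- m
    if (config$trace_dna) {
      tr <- stage("trace-dna", id,
                  traceFilaments(tf, config$detection,
                                 low_band_nm = config$low_band_nm,
                                 rise_per_bp = config$rise_per_bp,
                                 flatten = FALSE))
      if (nrow(tr)) tr$input <- id
      log("%s: %d DNA traces", id, nrow(tr))
      allT[[i]] <- tr
    }
  }
  m <- do.call(rbind, allM)
  if (!is.null(m) && nrow(m)) m$particle_id <- seq_len(nrow(m))
  tr <- if (length(allT)) do.call(rbind, allT) else NULL
  if (!is.null(tr) && nrow(tr)) {
    tr$trace_id <- seq_len(nrow(tr))
    attr(tr, "rise_per_bp") <- config$rise_per_bp
  }
  sm <- if (!is.null(m) && nrow(m)) summarizePopulation(m) else
    suppressWarnings(summarizePopulation(emptyMeasurement()))
  manifest <- list(package = "afmchrom",
                   version = tryCatch(
                     as.character(utils::packageVersion("afmchrom")),
                     error = function(e) "dev"),
                   seed = config$seed, inputs = paths,
                   n_particles = if (is.null(m)) 0L else nrow(m),
                   n_traces = if (is.null(tr)) 0L else nrow(tr))
  res <- list(measurements = m %||% emptyMeasurement(), traces = tr,
              summary = sm, manifest = manifest)
  if (!is.null(out_dir)) {
    files <- writeTables(res$measurements, tr, sm, out_dir,
                         config = config, seed = config$seed)
    mPath <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, mPath, auto_unbox = TRUE, pretty = TRUE)
    res$files <- c(files, manifest = mPath)
  }
  res
}
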