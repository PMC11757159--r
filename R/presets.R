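# Shipped generative presets: per-population normal distributions of peak
# height, lateral size and roundness for nucleosomes and CENP-C complexes
# (per cell-cycle stage), plus the nucleosome-free DNA length preset.
#
# Lateral size is interpreted per kind: for nucleosomes it is the maximum
# caliper (major extent) of the half-max footprint ("diameter"); for
# complexes it is the paper-convention box-diagonal Feret of the half-max
# footprint. Heights are apparent peak heights above background (nm).

presetTable <- function() {
  nuc <- function(name, stage, hm, hs, lm, ls, rm, rs)
    data.frame(name = name, kind = "nucleosome", stage = stage,
               height_mean = hm, height_sd = hs,
               lateral_mean = lm, lateral_sd = ls,
               roundness_mean = rm, roundness_sd = rs,
               bp_mean = NA_real_, bp_sd = NA_real_)
  cpx <- function(name, stage, hm, hs, lm, ls, rm, rs)
    within(nuc(name, stage, hm, hs, lm, ls, rm, rs), kind <- "complex")
  rbind(
    nuc("Bulk_async_table1",  "async", 2.7, 0.4, 12.7, 0.7, 0.87, 0.05),
    nuc("H3_async",           "async", 2.5, 0.3, 12.7, 0.7, 0.87, 0.05),
    nuc("CENPA_async",        "async", 1.8, 0.3, 12.4, 1.6, 0.78, 0.09),
    nuc("CENPC_assoc_async",  "async", 2.5, 0.4, 12.8, 1.9, 0.87, 0.05),
    cpx("CENPC_complex_async","async", 5.8, 2.1, 27.4, 2.7, 0.79, 0.11),
    nuc("Bulk_G1",            "G1",    2.5, 0.4, 14.0, 2.8, 0.68, 0.13),
    nuc("CENPA_G1",           "G1",    1.9, 0.3, 14.0, 2.0, 0.77, 0.12),
    nuc("CENPC_assoc_G1",     "G1",    2.4, 0.4, 14.3, 2.9, 0.70, 0.13),
    cpx("CENPC_complex_G1",   "G1",    6.2, 2.7, 64.1, 25.8, 0.71, 0.13),
    nuc("Bulk_S",             "S",     2.8, 0.7, 13.5, 2.6, 0.69, 0.13),
    nuc("CENPA_S",            "S",     2.4, 0.3, 13.8, 1.9, 0.61, 0.10),
    nuc("CENPC_assoc_S",      "S",     2.5, 0.3, 14.1, 2.6, 0.75, 0.12),
    cpx("CENPC_complex_S",    "S",     6.0, 2.1, 67.8, 33.4, 0.75, 0.12),
    nuc("Bulk_G2",            "G2",    2.6, 0.3, 14.2, 2.7, 0.73, 0.11),
    nuc("CENPA_G2",           "G2",    2.0, 0.2, 14.0, 2.1, 0.75, 0.11),
    nuc("CENPC_assoc_G2",     "G2",    2.9, 0.2, 14.4, 2.9, 0.77, 0.12),
    cpx("CENPC_complex_G2",   "G2",    6.7, 2.6, 72.4, 25.5, 0.74, 0.14),
    nuc("Bulk_M",             "M",     2.5, 0.5, 14.2, 2.8, 0.69, 0.13),
    nuc("CENPA_M",            "M",     1.9, 0.2, 14.5, 1.0, 0.75, 0.10),
    nuc("CENPC_assoc_M",      "M",     2.4, 0.6, 14.0, 2.8, 0.69, 0.13),
    cpx("CENPC_complex_M",    "M",     7.5, 3.8, 62.2, 26.0, 0.73, 0.12),
    nuc("InVitro_H3",         "invitro", 2.5, 0.4, 11.9, 1.6, 0.71, 0.12),
    data.frame(name = "freeDNA", kind = "filament", stage = "async",
               height_mean = 0.5, height_sd = 0,
               lateral_mean = NA_real_, lateral_sd = NA_real_,
               roundness_mean = NA_real_, roundness_sd = NA_real_,
               bp_mean = 156, bp_sd = 90)
  )
}

#' Generative presets for synthetic AFM fields
#'
#' Returns the registry of shipped population presets: per-population mean
#' and sd of apparent peak height (nm), lateral size (nm) and roundness for
#' nucleosome and CENP-C-complex classes across cell-cycle stages, and the
#' nucleosome-free DNA length preset (`freeDNA`, 156 +/- 90 bp). Lateral
#' size means the half-max footprint's major caliper extent for
#' nucleosomes, and the box-diagonal Feret (see [feretBoxdiag()]) for
#' complexes.
#'
#' @param name optional preset name; if given, the single matching row is
#'   returned (error listing available presets if unknown).
#' @return data.frame with one row per preset.
#' @examples
#' afmPresets("CENPA_async")
#' head(afmPresets())
#' @export
afmPresets <- function(name = NULL) {
  tab <- presetTable()
  if (is.null(name)) return(tab)
  i <- match(name, tab$name)
  if (is.na(i))
    stop("unknown preset '", name, "'; available: ",
         paste(tab$name, collapse = ", "))
  tab[i, , drop = FALSE]
}
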