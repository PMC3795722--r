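#' Probe element of a genomic barcode
#'
#' A probe element is one named signal of the fibre-FISH barcode: 1 to 3
#' labelled genomic intervals ("bars") of a single fluorescence colour.
#'
#' @param id element identifier, e.g. `"GMC01"`, `"FP1"`, `"RNU2-4P"`.
#' @param color one of `"red"`, `"green"`, `"blue"`.
#' @param bars two-column matrix or data.frame of 0-based half-open bp
#'   intervals (start, end), 1 to 3 rows, sorted and non-overlapping.
#' @param role one of `"gmc"`, `"flank_centromeric"`, `"flank_telomeric"`,
#'   `"array_probe"`, `"pseudogene"`.
#' @return an object of class `probe_element`.
#' @export
probe_element <- function(id, color, bars, role) {
  color <- match.arg(color, c("red", "green", "blue"))
  role <- match.arg(role, c("gmc", "flank_centromeric", "flank_telomeric",
                            "array_probe", "pseudogene"))
  bars <- as.matrix(bars)
  storage.mode(bars) <- "double"
  colnames(bars) <- c("start", "end")
  if (nrow(bars) < 1 || nrow(bars) > 3)
    fc_error("fc_invalid_element", sprintf("element %s: needs 1-3 bars", id))
  if (any(bars < 0))
    fc_error("fc_invalid_element", sprintf("element %s: negative coordinate", id))
  if (any(bars[, "end"] <= bars[, "start"]))
    fc_error("fc_invalid_element", sprintf("element %s: empty bar", id))
  if (nrow(bars) > 1) {
    if (is.unsorted(bars[, "start"], strictly = TRUE) ||
        any(bars[-1, "start"] < bars[-nrow(bars), "end"]))
      fc_error("fc_invalid_element",
               sprintf("element %s: bars must be sorted, non-overlapping", id))
  }
  structure(list(id = id, color = color, bars = bars, role = role),
            class = "probe_element")
}

#' Tandem-repeat unit model
#'
#' The repeat unit of the array with the sub-interval targeted by the unit
#' probes. The two unit probes target close regions and appear as a single
#' signal, so the model carries one contiguous labelled span per unit copy
#' (a named constant; the probe fragment sizes are 434 and 1,959 bp).
#'
#' @param unit_length repeat-unit length in bp (default 6132).
#' @param label_offset start of the labelled span within the unit, bp.
#' @param label_span length of the labelled span, bp (default 434 + 1959 = 2393).
#' @param color signal colour of the unit probe.
#' @return an object of class `repeat_unit_model`.
#' @export
repeat_unit_model <- function(unit_length = 6132, label_offset = 1000,
                              label_span = 2393, color = "red") {
  if (label_offset < 0 || label_offset + label_span > unit_length)
    fc_error("fc_invalid_unit", "labelled span must lie within the unit")
  if (label_span >= unit_length)
    fc_error("fc_invalid_unit", "labelled span must be shorter than the unit")
  structure(list(unit_length = unit_length, label_offset = label_offset,
                 label_span = label_span, color = color),
            class = "repeat_unit_model")
}

#' Locus map of a barcoded tandem-array region
#'
#' Ordered probe elements in a linear reference frame (centromere to
#' telomere) around a tandem-array insertion point, together with the repeat
#' unit model and the named distance constants of the locus.
#'
#' @param reference_name name of the linear frame.
#' @param elements list of [probe_element()] in centromere-to-telomere order.
#' @param array_anchor bp position at which the array is inserted.
#' @param unit a [repeat_unit_model()].
#' @param constants named list of locus constants (see [default_locus_map()]).
#' @return an object of class `locus_map`.
#' @export
locus_map <- function(reference_name, elements, array_anchor, unit, constants) {
  ids <- vapply(elements, `[[`, "", "id")
  if (anyDuplicated(ids))
    fc_error("fc_invalid_map", "duplicate element ids")
  spans <- t(vapply(elements, function(e) range(e$bars), numeric(2)))
  if (is.unsorted(spans[, 1], strictly = TRUE) ||
      any(spans[-1, 1] < spans[-nrow(spans), 2]))
    fc_error("fc_invalid_map", "elements must be strictly ordered, non-overlapping")
  roles <- vapply(elements, `[[`, "", "role")
  cent <- roles %in% c("gmc", "flank_centromeric")
  tel <- roles %in% c("flank_telomeric", "pseudogene")
  if (any(spans[cent, 2] > array_anchor))
    fc_error("fc_invalid_map", "centromeric elements must precede the array anchor")
  if (any(spans[tel, 1] < array_anchor))
    fc_error("fc_invalid_map", "telomeric elements must follow the array anchor")
  map <- structure(list(reference_name = reference_name, elements = elements,
                        array_anchor = array_anchor, unit = unit,
                        constants = constants),
                   class = "locus_map")
  motif <- calibration_motif_span(map)
  if (!is.null(constants$calibration_motif_bp) &&
      diff(motif) != constants$calibration_motif_bp)
    fc_error("fc_invalid_map",
             sprintf("calibration motif spans %d bp, expected %d",
                     diff(motif), constants$calibration_motif_bp))
  map
}

#' @export
print.locus_map <- function(x, ...) {
  cat(sprintf("<locus_map> %s: %d elements, array anchor at %s bp, unit %d bp\n",
              x$reference_name, length(x$elements),
              format(x$array_anchor, big.mark = ","), x$unit$unit_length))
  invisible(x)
}

#' Calibration-motif span of a map
#'
#' bp interval of the stretch-calibration motif: first bar start of the
#' motif's start element to last bar end of its end element.
#'
#' @param map a [locus_map()].
#' @return length-2 numeric bp interval.
#' @export
calibration_motif_span <- function(map) {
  cs <- map$constants
  s <- map_element(map, cs$calibration_start_element)
  e <- map_element(map, cs$calibration_end_element)
  as.numeric(c(s$bars[1, "start"], e$bars[nrow(e$bars), "end"]))
}

#' Look up a probe element by id
#' @param map a [locus_map()].
#' @param id element id.
#' @return the [probe_element()].
#' @export
map_element <- function(map, id) {
  ids <- vapply(map$elements, `[[`, "", "id")
  i <- match(id, ids)
  if (is.na(i)) fc_error("fc_unknown_element", sprintf("no element '%s'", id))
  map$elements[[i]]
}

#' Packaged default locus map (chr17q21 barcode model)
#'
#' A self-contained linear model of the 17q21 region around the RNU2
#' macrosatellite: a 17-element Genomic Morse Code barcode spanning 200 kb
#' over the BRCA1 region, flanking probes FP1/FP2 ending 7.3 kb centromeric
#' of the array and FP3/FP4 starting 2 kb telomeric of it, the 6,132-bp
#' repeat unit, and the cross-hybridizing RNU2-4P pseudogene 63.4 kb
#' telomeric of the array. Coordinates are 0-based half-open and anchored so
#' the array insertion point equals 41,399,577, letting assembly coordinates
#' be used literally. GMC bar coordinates within the 200-kb barcode are a
#' versioned packaged default (the barcode schema fixes colours and bar
#' counts, not bp positions); the 128-kb calibration motif runs from the
#' first bar of GMC01 to the last bar of GMC11, and the designated BRCA1-end
#' anchor is the last bar of GMC09, 123.7 kb centromeric of the array.
#'
#' @return a [locus_map()].
#' @export
default_locus_map <- function() {
  A <- 41399577          # array insertion point (assembly-anchored)
  G0 <- A - 220000       # start of the 200-kb GMC barcode

  # irregular spacing on purpose: an aperiodic bar pattern is what makes a
  # barcode identifiable from partial fibres
  gmc <- list(
    list("GMC01", "green", rbind(c(0, 1400), c(2200, 3400))),
    list("GMC02", "blue",  rbind(c(9500, 10800))),
    list("GMC03", "green", rbind(c(24000, 25200), c(26000, 27400), c(28200, 29400))),
    list("GMC04", "red",   rbind(c(31800, 33300))),
    list("GMC05", "blue",  rbind(c(47000, 48300), c(49100, 50400))),
    list("GMC06", "green", rbind(c(58000, 59400))),
    list("GMC07", "blue",  rbind(c(72500, 73700), c(75100, 76300))),
    list("GMC08", "green", rbind(c(81000, 82500))),
    list("GMC09", "blue",  rbind(c(91500, 93000), c(94800, 96300))),
    list("GMC10", "red",   rbind(c(104800, 106200))),
    list("GMC11", "green", rbind(c(123200, 124700), c(126500, 128000))),
    list("GMC12", "blue",  rbind(c(137000, 138400), c(139200, 140600))),
    list("GMC13", "green", rbind(c(149500, 151000))),
    list("GMC14", "red",   rbind(c(158700, 159900), c(160700, 162100))),
    list("GMC15", "blue",  rbind(c(172000, 173500))),
    list("GMC16", "green", rbind(c(186000, 187300), c(188100, 189400), c(190200, 191500))),
    list("GMC17", "blue",  rbind(c(194000, 195600)))
  )
  elements <- lapply(gmc, function(g)
    probe_element(g[[1]], g[[2]], g[[3]] + G0, "gmc"))

  elements <- c(elements, list(
    # FP1 (4,393 bp) and FP2 (4,860 bp); FP2 ends 7.3 kb centromeric of the array
    probe_element("FP1", "green",
                  rbind(c(A - 17353, A - 15353), c(A - 14460, A - 12960)),
                  "flank_centromeric"),
    probe_element("FP2", "blue",
                  rbind(c(A - 12160, A - 10160), c(A - 9300, A - 7300)),
                  "flank_centromeric"),
    # FP3 (7,009 bp) starts 2 kb telomeric of the array; FP4 (5,340 bp)
    probe_element("FP3", "green",
                  rbind(c(A + 2000, A + 4500), c(A + 6009, A + 9009)),
                  "flank_telomeric"),
    probe_element("FP4", "blue",
                  rbind(c(A + 9909, A + 12409), c(A + 12749, A + 15249)),
                  "flank_telomeric"),
    # single-copy pseudogene (289 bp) cross-reacting with the unit probe
    probe_element("RNU2-4P", "red", rbind(c(A + 63400, A + 63689)),
                  "pseudogene")
  ))

  constants <- list(
    flank_gap_centromeric_bp = 7300,
    flank_gap_telomeric_bp = 2000,
    calibration_start_element = "GMC01",
    calibration_end_element = "GMC11",
    calibration_motif_bp = 128000,
    brca1_end_anchor = "GMC09",
    brca1_end_to_array_bp = 123700,
    array_to_rnu2_4p_bp = 63400,
    default_stretch_kb_per_um = 2.0,
    junction_right_bp = 416, junction_right_unit_bp = 36,
    junction_left_bp = 92, junction_left_unit_bp = 47
  )

  locus_map("chr17-model", elements, A, repeat_unit_model(), constants)
}
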