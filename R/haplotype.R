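#' Expand a diploid-locus map into a physical haplotype
#'
#' Inserts `n` adjacent repeat-unit copies at the map's array anchor and
#' shifts every telomeric element by `n * unit_length`, producing the
#' physical coordinate layout of one chromosome.
#'
#' @param map a [locus_map()].
#' @param n repeat-unit copy number (integer >= 1).
#' @return an object of class `haplotype` with `element_layout` (data.frame of
#'   id/start/end for elements and `unit[i]` copies), `labels` (data.frame of
#'   labelled spans: color/start/end/source), `allele_n` and `total_span`.
#' @export
build_haplotype <- function(map, n) {
  if (length(n) != 1 || is.na(n) || n < 1 || n != floor(n))
    fc_error("fc_invalid_allele", "repeat copy number must be an integer >= 1")
  n <- as.integer(n)
  u <- map$unit
  A <- map$array_anchor
  shift <- n * u$unit_length

  lay <- list(); lab <- list()
  for (e in map$elements) {
    span <- range(e$bars)
    off <- if (span[1] >= A) shift else 0
    lay[[length(lay) + 1L]] <- data.frame(
      id = e$id, start = span[1] + off, end = span[2] + off)
    lab[[length(lab) + 1L]] <- data.frame(
      color = e$color, start = e$bars[, "start"] + off,
      end = e$bars[, "end"] + off, source = e$id)
  }
  i <- seq_len(n)
  ustart <- A + (i - 1) * u$unit_length
  lay[[length(lay) + 1L]] <- data.frame(
    id = sprintf("unit[%d]", i), start = ustart, end = ustart + u$unit_length)
  lab[[length(lab) + 1L]] <- data.frame(
    color = u$color, start = ustart + u$label_offset,
    end = ustart + u$label_offset + u$label_span,
    source = sprintf("unit[%d]", i))

  layout <- do.call(rbind, lay)
  layout <- layout[order(layout$start), , drop = FALSE]
  labels <- do.call(rbind, lab)
  labels <- labels[order(labels$start), , drop = FALSE]
  rownames(layout) <- rownames(labels) <- NULL

  structure(list(
    allele_n = n,
    element_layout = layout,
    labels = labels,
    array_start = A,
    array_end = A + shift,
    hap_start = min(layout$start),
    hap_end = max(layout$end),
    total_span = max(layout$end) - min(layout$start),
    map = map
  ), class = "haplotype")
}

#' @export
print.haplotype <- function(x, ...) {
  cat(sprintf("<haplotype> allele n=%d, span %s bp (%d labelled spans)\n",
              x$allele_n, format(x$total_span, big.mark = ","),
              nrow(x$labels)))
  invisible(x)
}

#' Expected labelled-signal layout within a window
#'
#' Returns the labelled probe spans of a haplotype intersecting a bp window,
#' clipped to it, in genomic order. The cross-reacting pseudogene signal is a
#' red span whose `source` distinguishes it from array-unit signals. An empty
#' or inverted window yields an empty layout.
#'
#' @param hap a [build_haplotype()] result.
#' @param window length-2 numeric, bp interval (0-based half-open).
#' @return data.frame with columns color, start, end, source.
#' @export
expected_signal_layout <- function(hap, window) {
  empty <- hap$labels[0, , drop = FALSE]
  if (length(window) != 2 || is.na(window[1]) || is.na(window[2]) ||
      window[2] <= window[1])
    return(empty)
  lb <- hap$labels
  keep <- lb$end > window[1] & lb$start < window[2]
  out <- lb[keep, , drop = FALSE]
  if (nrow(out)) {
    out$start <- pmax(out$start, window[1])
    out$end <- pmin(out$end, window[2])
  }
  rownames(out) <- NULL
  out
}
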