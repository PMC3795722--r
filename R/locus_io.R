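# BED + YAML sidecar serialization of a locus map.

.color_rgb <- c(red = "255,0,0", green = "0,255,0", blue = "0,0,255")

#' Export a locus map to BED (with a YAML sidecar for constants)
#'
#' Writes one BED record per probe bar (0-based half-open; `name` encodes
#' element id, role and bar index as `id|role|bar`; colour in `itemRgb`) and
#' a YAML sidecar holding the repeat-unit model, array anchor and locus
#' constants. [read_locus_bed()] round-trips the map.
#'
#' @param map a [locus_map()].
#' @param bed_path output BED path.
#' @param yaml_path sidecar path (default `<bed_path>.yaml`).
#' @return invisibly, the data.frame of BED records written.
#' @export
export_locus_bed <- function(map, bed_path,
                             yaml_path = paste0(bed_path, ".yaml")) {
  recs <- do.call(rbind, lapply(map$elements, function(e) {
    data.frame(chrom = map$reference_name,
               start = e$bars[, "start"], end = e$bars[, "end"],
               name = sprintf("%s|%s|%d", e$id, e$role, seq_len(nrow(e$bars))),
               score = 0, strand = ".",
               thickStart = e$bars[, "start"], thickEnd = e$bars[, "end"],
               itemRgb = .color_rgb[[e$color]])
  }))
  utils::write.table(
    format(recs, scientific = FALSE, trim = TRUE), bed_path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  side <- list(
    reference_name = map$reference_name,
    array_anchor = map$array_anchor,
    unit = unclass(map$unit),
    constants = map$constants
  )
  yaml::write_yaml(side, yaml_path)
  invisible(recs)
}

#' Read a locus map written by [export_locus_bed()]
#'
#' @param bed_path BED path.
#' @param yaml_path sidecar path (default `<bed_path>.yaml`).
#' @return a [locus_map()].
#' @export
read_locus_bed <- function(bed_path, yaml_path = paste0(bed_path, ".yaml")) {
  recs <- utils::read.table(bed_path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "name",
                                          "score", "strand", "thickStart",
                                          "thickEnd", "itemRgb"))
  side <- yaml::read_yaml(yaml_path)
  parts <- do.call(rbind, strsplit(recs$name, "|", fixed = TRUE))
  recs$id <- parts[, 1]; recs$role <- parts[, 2]
  recs$color <- names(.color_rgb)[match(recs$itemRgb, .color_rgb)]
  elements <- lapply(unique(recs$id), function(id) {
    r <- recs[recs$id == id, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    probe_element(id, r$color[1], cbind(r$start, r$end), r$role[1])
  })
  ord <- order(vapply(elements, function(e) e$bars[1, "start"], 0))
  u <- side$unit
  locus_map(side$reference_name, elements[ord], side$array_anchor,
            repeat_unit_model(u$unit_length, u$label_offset, u$label_span,
                              u$color),
            side$constants)
}
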