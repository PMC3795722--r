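# Placement of a tandem array in an assembly from clone interval-match
# evidence. Alignments are represented as interval matches only: each
# evidence row maps a contig interval onto a target (the reference assembly,
# the repeat unit, or one of the array junction fragments).

.valid_targets <- c("reference", "repeat_unit", "junction_left", "junction_right")

#' Validate a table of interval-match segments
#'
#' @param segments data.frame with columns contig_id, contig_start,
#'   contig_end, target, target_start, target_end, orientation ("+"/"-").
#' @param unit_length repeat-unit length (bounds `repeat_unit` matches).
#' @param junction_right_bp,junction_left_bp junction fragment lengths.
#' @return the validated data.frame.
#' @export
match_segments <- function(segments, unit_length = 6132,
                           junction_right_bp = 416, junction_left_bp = 92) {
  need <- c("contig_id", "contig_start", "contig_end", "target",
            "target_start", "target_end", "orientation")
  if (!all(need %in% names(segments)))
    fc_error("fc_invalid_evidence",
             paste("evidence needs columns:", paste(need, collapse = ", ")))
  if (any(!segments$target %in% .valid_targets))
    fc_error("fc_invalid_evidence", "unknown target type")
  if (any(segments$contig_end <= segments$contig_start) ||
      any(segments$target_end <= segments$target_start))
    fc_error("fc_invalid_evidence", "empty match interval")
  lim <- c(repeat_unit = unit_length, junction_right = junction_right_bp,
           junction_left = junction_left_bp)
  for (tg in names(lim)) {
    r <- segments[segments$target == tg, , drop = FALSE]
    if (nrow(r) && any(r$target_start < 0 | r$target_end > lim[[tg]]))
      fc_error("fc_invalid_evidence",
               sprintf("%s match outside [0, %d)", tg, lim[[tg]]))
  }
  segments[order(segments$contig_id, segments$contig_start), , drop = FALSE]
}

#' Read/write evidence TSV
#' @param path TSV file path.
#' @rdname evidence_tsv
#' @export
read_evidence_tsv <- function(path) {
  match_segments(utils::read.table(path, sep = "\t", header = TRUE,
                                   stringsAsFactors = FALSE))
}

#' @param segments evidence data.frame (see [match_segments()]).
#' @rdname evidence_tsv
#' @export
write_evidence_tsv <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Map a contig-coordinate interval onto the reference through the contig's
# own reference-match segments. Mapping is clipped to the reference anchors
# (no extrapolation); returns NULL when the interval has no anchored part.
.ref_place <- function(contig_segments, start, end) {
  anchors <- contig_segments[contig_segments$target == "reference", , drop = FALSE]
  if (!nrow(anchors)) return(NULL)
  pieces <- NULL
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    s <- max(start, a$contig_start); e <- min(end, a$contig_end)
    if (e <= s) next
    if (identical(a$orientation, "-")) {
      rs <- a$target_end - (e - a$contig_start)
      re <- a$target_end - (s - a$contig_start)
    } else {
      rs <- a$target_start + (s - a$contig_start)
      re <- a$target_start + (e - a$contig_start)
    }
    pieces <- rbind(pieces, c(rs, re))
  }
  if (is.null(pieces)) return(NULL)
  c(min(pieces[, 1]), max(pieces[, 2]))
}

# Union of reference intervals covered by a contig's reference matches.
.footprint <- function(contig_segments) {
  a <- contig_segments[contig_segments$target == "reference", , drop = FALSE]
  if (!nrow(a)) return(NULL)
  iv <- a[order(a$target_start), c("target_start", "target_end"), drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$target_start[i] <= out$target_end[nrow(out)]) {
      out$target_end[nrow(out)] <- max(out$target_end[nrow(out)], iv$target_end[i])
    } else out <- rbind(out, iv[i, ])
  }
  out
}

.union_overlap <- function(f1, f2) {
  if (is.null(f1) || is.null(f2)) return(0)
  tot <- 0
  for (i in seq_len(nrow(f1))) for (j in seq_len(nrow(f2)))
    tot <- tot + interval_overlap(f1$target_start[i], f1$target_end[i],
                                  f2$target_start[j], f2$target_end[j])
  tot
}

# Merge reference intervals into blocks, joining gaps <= tol.
.merge_blocks <- function(iv, tol) {
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= out[nrow(out), 2] + tol) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    } else out <- rbind(out, iv[i, , drop = FALSE])
  }
  out
}

#' Infer the tandem-array insertion interval from match evidence
#'
#' Places repeat-unit-portion matches and right-junction matches on the
#' reference (via each contig's reference anchors) and returns the reference
#' span covered by unit-portion matches whose telomeric edge coincides,
#' within `tolerance`, with the repeat/flank boundary inside a right-junction
#' placement. With no junction anchor the result is `ambiguous`; two disjoint
#' anchored candidates raise an ambiguity error listing both.
#'
#' @param evidence data.frame of match segments (see [match_segments()]).
#' @param tolerance bp tolerance for junction-edge coincidence (default 50).
#' @param junction_right_unit_bp bp of repeat unit inside the right junction
#'   fragment (default 36).
#' @return an object of class `placement_result`: list with `array_interval`,
#'   `supporting_evidence`, `flagged_contigs`, `status`.
#' @export
infer_array_interval <- function(evidence, tolerance = 50,
                                 junction_right_unit_bp = 36) {
  segs <- match_segments(evidence)
  if (!any(segs$target == "reference"))
    fc_error("fc_invalid_evidence", "need at least one reference-matching segment")
  by_contig <- split(segs, segs$contig_id)

  units <- NULL; unit_contigs <- character()
  jbounds <- numeric(); jstarts <- numeric(); j_contigs <- character()
  for (cid in names(by_contig)) {
    cs <- by_contig[[cid]]
    for (i in which(cs$target == "repeat_unit")) {
      p <- .ref_place(cs, cs$contig_start[i], cs$contig_end[i])
      if (!is.null(p)) {
        units <- rbind(units, p)
        unit_contigs <- c(unit_contigs, cid)
      }
    }
    for (i in which(cs$target == "junction_right")) {
      p <- .ref_place(cs, cs$contig_start[i], cs$contig_end[i])
      if (is.null(p)) next
      # boundary between the repeat-unit part and unique flank inside the
      # junction; the unit part is centromeric of the flank
      ori <- cs$orientation[i]
      off <- junction_right_unit_bp - cs$target_start[i]
      b <- if (identical(ori, "-")) p[2] - max(off, 0) else p[1] + max(off, 0)
      jbounds <- c(jbounds, b)
      jstarts <- c(jstarts, p[1])
      j_contigs <- c(j_contigs, cid)
    }
  }

  res <- function(interval, support, status) {
    structure(list(array_interval = interval, supporting_evidence = support,
                   flagged_contigs = list(), status = status),
              class = "placement_result")
  }
  if (is.null(units) || !length(jbounds))
    return(res(NULL, character(), "ambiguous"))

  blocks <- .merge_blocks(units, tolerance)
  anchored <- vapply(seq_len(nrow(blocks)), function(i) {
    any(abs(blocks[i, 2] - jbounds) <= tolerance |
          abs(blocks[i, 2] - jstarts) <= tolerance)
  }, logical(1))
  if (!any(anchored)) return(res(NULL, character(), "ambiguous"))
  if (sum(anchored) > 1) {
    cand <- blocks[anchored, , drop = FALSE]
    fc_error("fc_ambiguous_anchor",
             paste("conflicting anchored array intervals:",
                   paste(sprintf("(%s, %s)", cand[, 1], cand[, 2]),
                         collapse = " vs ")),
             candidates = cand)
  }
  blk <- blocks[anchored, , drop = TRUE]
  in_blk <- units[, 2] > blk[1] & units[, 1] < blk[2]
  support <- unique(c(unit_contigs[in_blk], j_contigs))
  res(c(blk[1], blk[2]), support, "resolved")
}

#' @export
print.placement_result <- function(x, ...) {
  if (identical(x$status, "resolved")) {
    cat(sprintf("<placement_result> resolved: array at (%s, %s), support: %s\n",
                format(x$array_interval[1], big.mark = ","),
                format(x$array_interval[2], big.mark = ","),
                paste(x$supporting_evidence, collapse = ", ")))
  } else cat("<placement_result> ambiguous (no junction-anchored interval)\n")
  invisible(x)
}

#' Order contigs into overlap chains
#'
#' Builds the contig overlap graph from shared reference footprints (edges
#' where the overlap is at least `min_overlap` bp) and returns the maximal
#' chains ordered centromere to telomere. A cyclic or branching overlap graph
#' raises an error naming the contigs involved.
#'
#' @param evidence data.frame of match segments.
#' @param min_overlap minimum bp overlap to count as adjacency (default 300).
#' @return list of character vectors (contig ids), one per chain.
#' @export
order_contigs <- function(evidence, min_overlap = 300) {
  segs <- match_segments(evidence)
  by_contig <- split(segs, segs$contig_id)
  ids <- names(by_contig)
  fps <- lapply(by_contig, .footprint)
  placed <- ids[!vapply(fps, is.null, logical(1))]
  n <- length(placed)
  adj <- matrix(FALSE, n, n, dimnames = list(placed, placed))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (.union_overlap(fps[[placed[i]]], fps[[placed[j]]]) >= min_overlap)
        adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  comp <- rep(NA_integer_, n); k <- 0
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1; queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  chains <- lapply(seq_len(k), function(cc) {
    mem <- which(comp == cc)
    deg <- rowSums(adj[mem, mem, drop = FALSE])
    nedge <- sum(adj[mem, mem, drop = FALSE]) / 2
    if (nedge >= length(mem) && length(mem) > 2)
      fc_error("fc_cyclic_overlap",
               paste("cyclic contig overlaps among:",
                     paste(placed[mem], collapse = ", ")))
    if (any(deg > 2))
      fc_error("fc_cyclic_overlap",
               paste("branching contig overlaps at:",
                     paste(placed[mem[deg > 2]], collapse = ", ")))
    starts <- vapply(placed[mem], function(id) fps[[id]]$target_start[1], 0)
    placed[mem][order(starts)]
  })
  ord <- order(vapply(chains, function(ch) fps[[ch[1]]]$target_start[1], 0))
  chains[ord]
}

#' Flag contigs whose repeat-bearing end contradicts the chain layout
#'
#' A contig is flagged when a (non-repeat-mediated) overlap with its chain
#' neighbour maps to the same contig end that carries repeat-unit matches: in
#' a consistent assembly the repeat block faces the array, opposite the
#' unique-sequence neighbour. Overlaps whose reference span intersects
#' repeat-unit placements are repeat-mediated and never trigger a flag.
#'
#' @param evidence data.frame of match segments.
#' @param chains result of [order_contigs()] (computed if missing).
#' @param min_overlap passed to [order_contigs()] when `chains` is missing.
#' @return data.frame with columns contig_id, reason (0 rows if consistent).
#' @export
flag_misassembly <- function(evidence, chains = NULL, min_overlap = 300) {
  segs <- match_segments(evidence)
  if (is.null(chains)) chains <- order_contigs(segs, min_overlap)
  by_contig <- split(segs, segs$contig_id)
  fps <- lapply(by_contig, .footprint)

  # reference placements of all repeat-unit matches (for repeat-mediation)
  unit_ref <- NULL
  for (cs in by_contig) {
    for (i in which(cs$target == "repeat_unit")) {
      p <- .ref_place(cs, cs$contig_start[i], cs$contig_end[i])
      if (!is.null(p)) unit_ref <- rbind(unit_ref, p)
    }
  }

  contig_len <- vapply(by_contig, function(cs) max(cs$contig_end), 0)
  end_side <- function(cid, pos) {
    if (pos < contig_len[[cid]] / 2) "left" else "right"
  }
  repeat_sides <- function(cid) {
    cs <- by_contig[[cid]]
    r <- cs[cs$target == "repeat_unit", , drop = FALSE]
    if (!nrow(r)) return(character())
    L <- contig_len[[cid]]
    unique(ifelse(r$contig_start < L - r$contig_end, "left", "right"))
  }
  # map a reference position into contig coordinates via reference anchors
  to_contig <- function(cid, refpos) {
    a <- by_contig[[cid]]
    a <- a[a$target == "reference", , drop = FALSE]
    hits <- which(a$target_start <= refpos & refpos <= a$target_end)
    if (!length(hits)) return(NA_real_)
    a <- a[hits[1], ]
    if (identical(a$orientation, "-"))
      a$contig_start + (a$target_end - refpos)
    else
      a$contig_start + (refpos - a$target_start)
  }

  flags <- NULL
  for (ch in chains) {
    if (length(ch) < 2) next
    for (k in seq_len(length(ch) - 1)) {
      p <- ch[k]; q <- ch[k + 1]
      f1 <- fps[[p]]; f2 <- fps[[q]]
      lo <- max(min(f1$target_start), min(f2$target_start))
      hi <- min(max(f1$target_end), max(f2$target_end))
      if (hi <= lo) next
      mediated <- !is.null(unit_ref) &&
        any(interval_overlap(unit_ref[, 1], unit_ref[, 2], lo, hi) > 0)
      if (mediated) next
      mid <- (lo + hi) / 2
      for (cid in c(p, q)) {
        cpos <- to_contig(cid, mid)
        if (is.na(cpos)) next
        if (end_side(cid, cpos) %in% repeat_sides(cid))
          flags <- rbind(flags, data.frame(contig_id = cid,
                                           reason = "repeat block on wrong end"))
      }
    }
  }
  if (is.null(flags))
    return(data.frame(contig_id = character(), reason = character()))
  unique(flags)
}

#' Worked placement evidence at the published coordinates
#'
#' Match evidence encoding the assembly's own records near the array: the
#' residual repeat-unit portion at reference 41,399,577-41,401,198 and the
#' right-junction fragment at 41,401,163-41,401,579, carried on a contig that
#' matches the reference identically over the surrounding region.
#'
#' @return evidence data.frame suitable for [infer_array_interval()].
#' @export
rnu2_worked_evidence <- function() {
  match_segments(data.frame(
    contig_id = "chr17-assembly",
    contig_start = c(41390000, 41399577, 41401163),
    contig_end = c(41420000, 41401198, 41401579),
    target = c("reference", "repeat_unit", "junction_right"),
    target_start = c(41390000, 1440, 0),
    target_end = c(41420000, 3061, 416),
    orientation = "+"
  ))
}

#' Write a placement result to JSON
#' @param result a `placement_result`.
#' @param path output path.
#' @export
write_placement_json <- function(result, path) {
  jsonlite::write_json(list(
    status = result$status,
    array_interval = result$array_interval,
    supporting_evidence = result$supporting_evidence,
    flagged_contigs = result$flagged_contigs
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
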