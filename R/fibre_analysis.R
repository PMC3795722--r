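# Per-fibre inference: barcode matching with orientation resolution and
# scale fitting, per-fibre stretch calibration from the 128-kb motif,
# flank-integrity gating, repeat counting and distance measurement.
#
# The barcode is matched as two rigid blocks: the centromeric block (GMC
# elements, FP1, FP2) and the telomeric block (FP3, FP4, pseudogene). Their
# separation depends on the unknown repeat copy number, so each block gets
# its own offset while sharing a single scale factor.

.block_bars <- function(map) {
  rows <- do.call(rbind, lapply(map$elements, function(e) {
    data.frame(element = e$id, color = e$color, role = e$role,
               bar = seq_len(nrow(e$bars)),
               start_bp = e$bars[, "start"], end_bp = e$bars[, "end"])
  }))
  # positions relative to the array anchor keep block offsets small, so a
  # stretch error of a few percent cannot masquerade as a block shift
  rows$mid_kb <- (rows$start_bp + rows$end_bp) / 2000 - map$array_anchor / 1000
  rows$block <- ifelse(rows$end_bp <= map$array_anchor, "cent", "tel")
  rows
}

# Greedy one-to-one assignment of expected bars to observed signals of the
# same colour at predicted positions pred_kb, tolerance tol_kb. Returns
# indices into obs (NA when unmatched).
.greedy_assign <- function(pred_kb, colors, obs_mid_kb, obs_color, tol_kb) {
  used <- rep(FALSE, length(obs_mid_kb))
  hit <- rep(NA_integer_, length(pred_kb))
  for (i in seq_along(pred_kb)) {
    ok <- which(!used & obs_color == colors[i])
    if (!length(ok)) next
    d <- abs(obs_mid_kb[ok] - pred_kb[i])
    j <- which.min(d)
    if (d[j] <= tol_kb) {
      hit[i] <- ok[j]
      used[ok[j]] <- TRUE
    }
  }
  hit
}

# Candidate block offsets by vote-binning observed-minus-expected positions
# over colour-consistent (non-red) pairs; red signals cannot anchor because
# the array contributes an unknown number of red signals.
.candidate_offsets <- function(bars, obs_mid_kb, obs_color, top = 10) {
  idx_e <- which(bars$color != "red")
  idx_o <- which(obs_color != "red")
  if (!length(idx_e) || !length(idx_o)) return(numeric())
  offs <- as.vector(outer(obs_mid_kb[idx_o], bars$mid_kb[idx_e], "-"))
  cols_ok <- as.vector(outer(obs_color[idx_o], bars$color[idx_e], "=="))
  offs <- offs[cols_ok]
  if (!length(offs)) return(numeric())
  bin <- round(offs / 2)
  tab <- sort(table(bin), decreasing = TRUE)
  keep <- names(tab)[seq_len(min(top, length(tab)))]
  vapply(keep, function(b) mean(offs[bin == as.numeric(b)]), 0)
}

# Fit quality is ranked by non-red matches: the array contributes dozens of
# red signals, so a red expected bar finds some red signal at almost any
# offset and must carry next to no weight in model selection.
.score_block <- function(bars, off, obs_mid_kb, obs_color, tol_kb) {
  hit <- .greedy_assign(bars$mid_kb + off, bars$color, obs_mid_kb, obs_color,
                        tol_kb)
  n <- sum(!is.na(hit))
  n_gb <- sum(!is.na(hit) & bars$color != "red")
  rss <- if (n) sum((obs_mid_kb[hit[!is.na(hit)]] -
                       (bars$mid_kb[!is.na(hit)] + off))^2) else Inf
  list(hit = hit, n = n, n_gb = n_gb, score = n_gb + 0.2 * (n - n_gb),
       rss = rss, off = off)
}

.match_one_orientation <- function(obs, map, bars, tol_kb) {
  nominal <- map$constants$default_stretch_kb_per_um
  obs_mid_kb <- (obs$start_um + obs$end_um) / 2 * nominal
  cent <- bars[bars$block == "cent", , drop = FALSE]
  tel <- bars[bars$block == "tel", , drop = FALSE]
  null_fit <- list(hit = NULL, n = 0, n_gb = 0, score = 0, rss = 0,
                   off = NA_real_)
  # flank edges relative to the array anchor (kb)
  fp2e <- -map$constants$flank_gap_centromeric_bp / 1000
  fp3s <- map$constants$flank_gap_telomeric_bp / 1000

  scale_block <- function(bl, slope) {
    bl$mid_kb <- slope * bl$mid_kb
    bl
  }
  # red array signals delimit the flank blocks: the first (last) red start
  # (end) predicts where FP2 (FP3) must sit, up to dropped leading/trailing
  # units, giving extra anchor candidates for fibres showing few flank bars
  u <- map$unit
  lead_kb <- (map$constants$flank_gap_centromeric_bp + u$label_offset) / 1000
  trail_kb <- (u$unit_length - u$label_offset - u$label_span +
                 map$constants$flank_gap_telomeric_bp) / 1000
  red_i <- which(obs$color == "red")
  derived_offs <- function(block, slope) {
    if (!length(red_i)) return(numeric())
    if (block == "cent") {
      r <- sort(obs$start_um[red_i] * nominal)[seq_len(min(2, length(red_i)))]
      as.vector(outer(r, slope * (lead_kb + (0:1) * u$unit_length / 1000 +
                                    fp2e), "-"))
    } else {
      r <- sort(obs$end_um[red_i] * nominal, decreasing = TRUE)
      r <- r[seq_len(min(2, length(red_i)))]
      as.vector(outer(r, slope * (trail_kb + (0:1) * u$unit_length / 1000 -
                                    fp3s), "+"))
    }
  }
  cands_for <- function(bl, slope) {
    sb <- scale_block(bl, slope)
    offs <- c(.candidate_offsets(sb, obs_mid_kb, obs$color),
              derived_offs(bl$block[1], slope))
    lapply(offs, function(o)
      .score_block(sb, o, obs_mid_kb, obs$color, tol_kb))
  }
  refit_at <- function(bl, fit, slope) {
    if (is.null(fit$hit) || !any(!is.na(fit$hit))) return(null_fit)
    h <- fit$hit
    icpt <- mean(obs_mid_kb[h[!is.na(h)]] - slope * bl$mid_kb[!is.na(h)])
    .score_block(scale_block(bl, slope), icpt, obs_mid_kb, obs$color, tol_kb)
  }
  # robust (median-of-pairwise-slopes) shared scale factor: immune to a
  # single bar-level misassignment that would bias least squares
  slope_from <- function(bc, bt) {
    slopes <- numeric()
    for (z in list(list(cent, bc), list(tel, bt))) {
      h <- z[[2]]$hit
      if (is.null(h) || sum(!is.na(h)) < 2) next
      eb <- z[[1]]$mid_kb[!is.na(h)]
      ob <- obs_mid_kb[h[!is.na(h)]]
      de <- as.vector(outer(eb, eb, "-"))
      do_ <- as.vector(outer(ob, ob, "-"))
      keep <- de > 5
      slopes <- c(slopes, do_[keep] / de[keep])
    }
    s <- if (length(slopes)) stats::median(slopes) else 1
    if (is.na(s) || s < 0.8 || s > 1.2) 1 else s
  }

  # the telomeric block must sit telomeric of the centromeric block by at
  # least the flank gaps plus one repeat unit (jitter margin allowed);
  # offsets are intercepts of the scaled model, so predicted boundary
  # positions are off + slope * edge
  pair_ok <- function(a, b, slope) {
    if (is.na(a$off) || is.na(b$off)) return(TRUE)
    (b$off + slope * fp3s) - (a$off + slope * fp2e) >= 10
  }
  pick_pair <- function(sc, st, slope) {
    best <- NULL
    for (a in sc) for (b in st) {
      if (!pair_ok(a, b, slope)) next
      cand <- list(cent = a, tel = b, n = a$n + b$n,
                   score = a$score + b$score, rss = a$rss + b$rss)
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score && cand$rss < best$rss)) best <- cand
    }
    best
  }

  best <- pick_pair(c(cands_for(cent, 1), list(null_fit)),
                    c(cands_for(tel, 1), list(null_fit)), 1)
  prev_key <- ""
  for (iter in 1:3) {
    slope <- slope_from(best$cent, best$tel)
    sc <- list(refit_at(cent, best$cent, slope))
    st <- list(refit_at(tel, best$tel, slope))
    # a weak or empty block gets fresh slope-corrected candidates
    if (sc[[1]]$n_gb < 4) sc <- c(sc, cands_for(cent, slope))
    if (st[[1]]$n_gb < 3) st <- c(st, cands_for(tel, slope))
    cand <- pick_pair(c(sc, list(null_fit)), c(st, list(null_fit)), slope)
    if (!is.null(cand) &&
        (cand$score > best$score ||
           (cand$score == best$score && cand$rss <= best$rss)))
      best <- cand
    key <- paste(c(best$cent$hit, "|", best$tel$hit), collapse = ",")
    if (identical(key, prev_key)) break
    prev_key <- key
  }

  matches <- rbind(
    if (!is.null(best$cent$hit)) cbind(cent, obs_idx = best$cent$hit),
    if (!is.null(best$tel$hit)) cbind(tel, obs_idx = best$tel$hit))
  if (is.null(matches)) {
    matches <- cbind(bars[0, , drop = FALSE], obs_idx = integer())
  } else {
    matches <- matches[!is.na(matches$obs_idx), , drop = FALSE]
  }
  list(matches = matches, n_bars = best$n, n_gb = best$cent$n_gb + best$tel$n_gb,
       n_elements = length(unique(matches$element)), rss = best$rss)
}

#' Match observed fibre signals to the locus barcode
#'
#' Tries both orientations; in each, fits per-block offsets by position
#' voting, greedily assigns observed signals to expected probe bars of the
#' same colour within `tol_kb`, refines a single shared scale factor by
#' least squares over the matched pairs, and re-assigns once. The
#' orientation matching more barcode elements wins; a tie leaves the
#' orientation `unknown`.
#'
#' @param fibre data.frame of one fibre's signals: columns channel (R/G/B),
#'   start_um, end_um, sorted by start.
#' @param map a [locus_map()].
#' @param tol_kb assignment tolerance in kb at nominal stretch (default 5).
#' @param min_elements fewer matched elements than this gives status
#'   `unusable` (default 4).
#' @return an object of class `fibre_call`.
#' @export
match_barcode <- function(fibre, map, tol_kb = 5, min_elements = 4) {
  empty_call <- function() {
    structure(list(fibre_id = fibre$fibre_id[1] %||% NA_character_,
                   orientation = "unknown", matches = NULL,
                   matched_elements = character(), signals = NULL,
                   stretch_estimate = NA_real_, integrity = "none",
                   status = "unusable", n_red_signals = NA_integer_,
                   repeat_count = NA_integer_, distances = list()),
              class = "fibre_call")
  }
  if (is.null(fibre) || !nrow(fibre)) return(empty_call())
  bars <- .block_bars(map)
  color_of <- c(R = "red", G = "green", B = "blue")
  fwd <- data.frame(start_um = fibre$start_um, end_um = fibre$end_um,
                    color = unname(color_of[fibre$channel]))
  L <- max(fwd$end_um)
  rev <- data.frame(start_um = L - fwd$end_um, end_um = L - fwd$start_um,
                    color = fwd$color)

  m_fwd <- .match_one_orientation(fwd, map, bars, tol_kb)
  m_rev <- .match_one_orientation(rev, map, bars, tol_kb)

  # orientation by non-red matched bars (red signals match anywhere along
  # the array), then by matched elements; a tie stays unknown
  key_fwd <- c(m_fwd$n_gb, m_fwd$n_elements)
  key_rev <- c(m_rev$n_gb, m_rev$n_elements)
  if (key_fwd[1] > key_rev[1] ||
      (key_fwd[1] == key_rev[1] && key_fwd[2] > key_rev[2])) {
    orientation <- "+"; m <- m_fwd; obs <- fwd
  } else if (key_rev[1] > key_fwd[1] ||
             (key_rev[1] == key_fwd[1] && key_rev[2] > key_fwd[2])) {
    orientation <- "-"; m <- m_rev; obs <- rev
  } else {
    orientation <- "unknown"; m <- m_fwd; obs <- fwd
  }
  if (m$n_elements < min_elements) {
    call <- empty_call()
    call$orientation <- orientation
    return(call)
  }

  matches <- m$matches
  matches$obs_start_um <- obs$start_um[matches$obs_idx]
  matches$obs_end_um <- obs$end_um[matches$obs_idx]
  matched_elements <- unique(matches$element)

  fp_cent <- all(c("FP1", "FP2") %in% matched_elements)
  fp_tel <- all(c("FP3", "FP4") %in% matched_elements)
  integrity <- if (fp_cent && fp_tel) "full"
  else if (fp_cent) "centromeric_only"
  else if (fp_tel) "telomeric_only"
  else "none"

  call <- structure(list(
    fibre_id = fibre$fibre_id[1] %||% NA_character_,
    orientation = orientation,
    matches = matches,
    matched_elements = matched_elements,
    signals = obs,   # oriented (centromere -> telomere) coordinates
    stretch_estimate = NA_real_,
    integrity = integrity,
    status = if (integrity == "full") "countable" else "measurable_only",
    n_red_signals = NA_integer_,
    repeat_count = NA_integer_,
    distances = list()
  ), class = "fibre_call")
  call$stretch_estimate <- tryCatch(calibrate_stretch(call, map),
                                    fibrecall_error = function(e) NA_real_)
  call
}

#' @export
print.fibre_call <- function(x, ...) {
  cat(sprintf("<fibre_call> %s: %s, %d elements, integrity %s, status %s",
              x$fibre_id, x$orientation, length(x$matched_elements),
              x$integrity, x$status))
  if (!is.na(x$repeat_count)) cat(sprintf(", %d repeats", x$repeat_count))
  cat("\n")
  invisible(x)
}

#' Stretch factor from a measured calibration-motif span
#'
#' @param span_um measured span of the calibration motif in um.
#' @param motif_kb genomic length of the motif in kb (default 128).
#' @return stretching factor in kb/um.
#' @export
stretch_from_motif_span <- function(span_um, motif_kb = 128) {
  if (any(span_um <= 0))
    fc_error("fc_calibration_unavailable", "motif span must be positive")
  motif_kb / span_um
}

#' Calibrate the per-fibre stretching factor
#'
#' Measures the observed um span of the designated calibration motif (the
#' first bar of the motif's start element to the last bar of its end
#' element) and returns genomic length / measured span. Requires both motif
#' ends matched on the fibre; otherwise a calibration-unavailable error is
#' raised and distances stay in um only.
#'
#' @param call a [match_barcode()] result.
#' @param map a [locus_map()].
#' @return stretching factor in kb/um.
#' @export
calibrate_stretch <- function(call, map) {
  cs <- map$constants
  m <- call$matches
  if (is.null(m))
    fc_error("fc_calibration_unavailable", "no matched elements")
  s_el <- map_element(map, cs$calibration_start_element)
  e_el <- map_element(map, cs$calibration_end_element)
  a <- m[m$element == s_el$id & m$bar == 1, , drop = FALSE]
  b <- m[m$element == e_el$id & m$bar == nrow(e_el$bars), , drop = FALSE]
  if (!nrow(a) || !nrow(b))
    fc_error("fc_calibration_unavailable",
             "calibration motif not fully matched on this fibre")
  span_um <- b$obs_end_um[1] - a$obs_start_um[1]
  stretch_from_motif_span(span_um, cs$calibration_motif_bp / 1000)
}

# red signals strictly between the telomeric edge of FP2 and the centromeric
# edge of FP3 (oriented um coordinates), merged when separated by less than
# merge_gap_kb at the working stretch. The two flank edges are predicted
# from every matched bar of FP2/FP3 (not a single observed bar edge), so a
# dropped edge bar does not shift the counting region by a bar width.
.array_red_signals <- function(call, map, merge_gap_kb = 1) {
  m <- call$matches
  cs <- map$constants
  stretch <- if (!is.na(call$stretch_estimate)) call$stretch_estimate
  else cs$default_stretch_kb_per_um
  fp2_bp <- map$array_anchor - cs$flank_gap_centromeric_bp
  fp3_bp <- map$array_anchor + cs$flank_gap_telomeric_bp
  m2 <- m[m$element == "FP2", , drop = FALSE]
  m3 <- m[m$element == "FP3", , drop = FALSE]
  fp2_end <- if (nrow(m2))
    mean(m2$obs_end_um + (fp2_bp - m2$end_bp) / 1000 / stretch) else -Inf
  fp3_start <- if (nrow(m3))
    mean(m3$obs_start_um - (m3$start_bp - fp3_bp) / 1000 / stretch) else Inf
  sig <- call$signals
  mid <- (sig$start_um + sig$end_um) / 2
  red <- which(sig$color == "red" & mid > fp2_end & mid < fp3_start)
  red <- setdiff(red, m$obs_idx)
  if (!length(red)) {
    return(list(starts = numeric(), ends = numeric(), fp2_end = fp2_end,
                fp3_start = fp3_start, stretch = stretch))
  }
  s <- sig$start_um[red]; e <- sig$end_um[red]
  o <- order(s); s <- s[o]; e <- e[o]
  ms <- s[1]; me <- e[1]; outs <- c(); oute <- c()
  for (i in seq_along(s)[-1]) {
    if ((s[i] - me) * stretch < merge_gap_kb) {
      me <- max(me, e[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- s[i]; me <- e[i]
    }
  }
  outs <- c(outs, ms); oute <- c(oute, me)
  # without motif calibration, the array's own 6.132-kb period calibrates
  # the stretch used for gap arithmetic
  if (is.na(call$stretch_estimate) && length(outs) >= 6) {
    period_um <- stats::median(diff(outs))
    if (is.finite(period_um) && period_um > 0) {
      s2 <- map$unit$unit_length / 1000 / period_um
      if (abs(s2 / stretch - 1) < 0.15) stretch <- s2
    }
  }
  list(starts = outs, ends = oute, fp2_end = fp2_end, fp3_start = fp3_start,
       stretch = stretch)
}

#' Count repeat units on an intact fibre
#'
#' Requires full flank integrity (FP1-FP4 matched). Red signals strictly
#' between the telomeric edge of FP2 and the centromeric edge of FP3 are
#' merged when closer than `merge_gap_kb`, then counted; dark gaps wider
#' than the expected inter-unit gap by multiples of the unit length add the
#' corresponding number of dropped units, so the count estimates the true
#' copy number rather than the number of detections. The cross-reacting
#' pseudogene signal lies telomeric of FP3/FP4 and is never included.
#'
#' @param call a [match_barcode()] result with `integrity == "full"`.
#' @param map a [locus_map()].
#' @param merge_gap_kb adjacent red detections closer than this merge
#'   (default 1 kb, under half the inter-unit dark gap).
#' @return integer repeat-unit count.
#' @export
count_repeats <- function(call, map, merge_gap_kb = 1) {
  if (!identical(call$integrity, "full"))
    fc_error("fc_gating", "repeat counting requires intact FP1-FP4 flanks")
  u <- map$unit
  cs <- map$constants
  ar <- .array_red_signals(call, map, merge_gap_kb)
  unit_kb <- u$unit_length / 1000
  lead_kb <- (cs$flank_gap_centromeric_bp + u$label_offset) / 1000
  gap_kb <- (u$unit_length - u$label_span) / 1000
  trail_kb <- (u$unit_length - u$label_offset - u$label_span +
                 cs$flank_gap_telomeric_bp) / 1000
  m <- length(ar$starts)
  if (m == 0) {
    span_kb <- (ar$fp3_start - ar$fp2_end) * ar$stretch
    return(max(0L, as.integer(round((span_kb - lead_kb - trail_kb + gap_kb) /
                                      unit_kb))))
  }
  gaps <- c((ar$starts[1] - ar$fp2_end) * ar$stretch - lead_kb,
            if (m > 1) (ar$starts[-1] - ar$ends[-m]) * ar$stretch - gap_kb,
            (ar$fp3_start - ar$ends[m]) * ar$stretch - trail_kb)
  dropped <- pmax(0, round(gaps / unit_kb))
  as.integer(m + sum(dropped))
}

#' Measure calibrated distances on a fibre
#'
#' Distances use the fibre's own calibrated stretch factor, never the
#' nominal one. The BRCA1-to-array distance runs from the designated
#' BRCA1-end anchor bar to the inferred array start (first red array signal
#' start minus the unit label offset). Measurements whose anchors are not
#' matched are omitted.
#'
#' @param call a [match_barcode()] result.
#' @param map a [locus_map()].
#' @return list with (where measurable) `brca1_to_array_kb`,
#'   `signal_lengths_kb`, `gap_lengths_kb`.
#' @export
measure_distances <- function(call, map) {
  out <- list()
  stretch <- call$stretch_estimate
  if (is.na(stretch)) return(out)
  m <- call$matches
  if (!"FP2" %in% call$matched_elements) return(out)
  ar <- .array_red_signals(call, map)
  first_red <- NA_real_
  if (is.finite(ar$fp3_start)) {
    # full array visible: signal and gap lengths are meaningful
    if (length(ar$starts)) {
      first_red <- ar$starts[1]
      out$signal_lengths_kb <- (ar$ends - ar$starts) * stretch
      if (length(ar$starts) > 1)
        out$gap_lengths_kb <-
          (ar$starts[-1] - ar$ends[-length(ar$ends)]) * stretch
    }
  } else if (length(ar$starts)) {
    # fibre ends inside the array: the array boundary is still measurable
    # if the first red sits within a few units of FP2
    cand <- ar$starts[1]
    max_lead_um <- (map$constants$flank_gap_centromeric_bp / 1000 +
                      3 * map$unit$unit_length / 1000) / stretch
    if (cand - ar$fp2_end <= max_lead_um) first_red <- cand
  }
  if (!is.na(first_red)) {
    anchor_id <- map$constants$brca1_end_anchor
    a_el <- map_element(map, anchor_id)
    a <- m[m$element == anchor_id & m$bar == nrow(a_el$bars), , drop = FALSE]
    if (nrow(a)) {
      out$brca1_to_array_kb <- (first_red - a$obs_end_um[1]) * stretch -
        map$unit$label_offset / 1000
    }
  }
  out
}

#' Analyse one fibre end to end
#'
#' [match_barcode()] plus stretch calibration, raw red-signal count,
#' gap-corrected repeat count (when flank integrity is full) and calibrated
#' distances.
#'
#' @inheritParams match_barcode
#' @param merge_gap_kb see [count_repeats()].
#' @return a `fibre_call` with all fields populated.
#' @export
analyze_fibre <- function(fibre, map, tol_kb = 5, merge_gap_kb = 1,
                          min_elements = 4) {
  call <- match_barcode(fibre, map, tol_kb, min_elements)
  if (identical(call$status, "unusable")) return(call)
  if (identical(call$integrity, "full")) {
    ar <- .array_red_signals(call, map, merge_gap_kb)
    call$n_red_signals <- length(ar$starts)
    call$repeat_count <- count_repeats(call, map, merge_gap_kb)
  }
  call$distances <- measure_distances(call, map)
  call
}

#' Analyse a table of fibres
#'
#' @param fibres data.frame of signals for many fibres (columns fibre_id,
#'   individual_id, channel, start_um, end_um).
#' @param map a [locus_map()].
#' @inheritParams analyze_fibre
#' @return data.frame of per-fibre calls: fibre_id, individual_id,
#'   orientation, n_matched_elements, integrity, status, stretch_kb_per_um,
#'   n_red_signals, repeat_count, brca1_to_array_kb.
#' @export
analyze_fibres <- function(fibres, map, tol_kb = 5, merge_gap_kb = 1,
                           min_elements = 4) {
  ids <- unique(fibres$fibre_id)
  rows <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    fib <- fibres[fibres$fibre_id == ids[k], , drop = FALSE]
    call <- analyze_fibre(fib, map, tol_kb, merge_gap_kb, min_elements)
    d <- call$distances
    rows[[k]] <- data.frame(
      fibre_id = ids[k],
      individual_id = fib$individual_id[1] %||% NA_character_,
      orientation = call$orientation,
      n_matched_elements = length(call$matched_elements),
      integrity = call$integrity,
      status = call$status,
      stretch_kb_per_um = call$stretch_estimate,
      n_red_signals = call$n_red_signals,
      repeat_count = call$repeat_count,
      brca1_to_array_kb = d$brca1_to_array_kb %||% NA_real_,
      mean_signal_kb = if (length(d$signal_lengths_kb))
        mean(d$signal_lengths_kb) else NA_real_,
      mean_gap_kb = if (length(d$gap_lengths_kb))
        mean(d$gap_lengths_kb) else NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write per-fibre calls to TSV
#' @param calls data.frame from [analyze_fibres()].
#' @param path output path.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
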