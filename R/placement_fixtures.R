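# Synthetic clone-evidence fixtures with ground truth by construction.

#' Simulate contig interval-match evidence around a planted array
#'
#' Generates a reference region whose tandem array sits at a known interval,
#' tiles it with contigs carrying realistic unique-sequence overlaps, puts
#' repeat-unit blocks on the two array-adjacent contig ends (plus the
#' residual unit portion and right-junction records present in the
#' reference), and optionally mis-assembles one contig by moving its
#' repeat-unit block to the opposite end. Ground truth (planted interval,
#' contig order, swapped contig) is returned alongside.
#'
#' @param seed integer seed.
#' @param n_contigs number of contigs (>= 4; default 5).
#' @param array_interval planted reference interval of the residual unit
#'   portion (default the published coordinates).
#' @param copy_number repeat-unit copies represented in the adjacent clone
#'   ends (affects repeat-block sizes only, not the interval).
#' @param contig_bp approximate unique-contig length in bp.
#' @param overlap_range min/max bp of unique neighbour overlaps.
#' @param swap `NULL` for a consistent fixture, `"auto"` to end-swap one
#'   repeat-bearing contig chosen at random, or a contig id.
#' @return list with `evidence` (data.frame), `truth` (list: array_interval,
#'   order, swapped).
#' @export
simulate_placement_evidence <- function(seed, n_contigs = 5,
                                        array_interval = c(41399577, 41401198),
                                        copy_number = 5,
                                        contig_bp = 20000,
                                        overlap_range = c(400, 1500),
                                        swap = NULL) {
  if (n_contigs < 4)
    fc_error("fc_invalid_config", "need at least 4 contigs")
  set.seed(seed)
  as <- array_interval[1]; ae <- array_interval[2]
  resid <- ae - as
  unit_len <- 6132
  # split: contigs 1..j are centromeric of the array, j+1..n telomeric
  j <- sample(2:(n_contigs - 2), 1)
  lens <- round(stats::runif(n_contigs, 0.8, 1.2) * contig_bp)
  ovs <- round(stats::runif(n_contigs - 1, overlap_range[1], overlap_range[2]))

  rows <- list()
  add <- function(cid, cs, ce, tg, ts, te, ori = "+") {
    rows[[length(rows) + 1L]] <<- data.frame(
      contig_id = cid, contig_start = cs, contig_end = ce, target = tg,
      target_start = ts, target_end = te, orientation = ori)
  }
  rep_block <- min(copy_number, 2) * unit_len  # clones carry a couple of units at most

  # centromeric side: tile so contig j ends exactly at the array start
  ref_end <- as
  for (k in j:1) {
    cid <- sprintf("ctg%02d", k)
    ref_start <- ref_end - lens[k]
    if (k == j) {
      # unique part then repeat block at the telomeric (right) end
      add(cid, 0, lens[k], "reference", ref_start, ref_end)
      add(cid, lens[k], lens[k] + rep_block, "repeat_unit",
          0, min(rep_block, unit_len))
    } else {
      add(cid, 0, lens[k], "reference", ref_start, ref_end)
    }
    ref_end <- ref_start + ovs[max(k - 1, 1)]
  }
  # telomeric side: contig j+1 starts with a repeat block, then the residual
  # unit portion that is also part of its reference match from the array start
  ref_start <- as
  for (k in (j + 1):n_contigs) {
    cid <- sprintf("ctg%02d", k)
    if (k == j + 1) {
      r0 <- rep_block                      # contig coord where ref match begins
      add(cid, r0, r0 + lens[k], "reference", as, as + lens[k])
      add(cid, 0, r0, "repeat_unit", 0, min(rep_block, unit_len))
      add(cid, r0, r0 + resid, "repeat_unit",
          1440, 1440 + resid)              # residual portion, on the reference
      add(cid, r0 + resid - 36, r0 + resid + 380, "junction_right", 0, 416)
      ref_start <- as + lens[k] - ovs[k]
    } else {
      add(cid, 0, lens[k], "reference", ref_start, ref_start + lens[k])
      ref_start <- ref_start + lens[k] - ifelse(k < n_contigs, ovs[k], 0)
    }
  }
  ev <- do.call(rbind, rows)

  swapped <- NA_character_
  if (!is.null(swap)) {
    cands <- sprintf("ctg%02d", c(j, j + 1))
    swapped <- if (identical(swap, "auto")) sample(cands, 1) else swap
    on_ctg <- ev$contig_id == swapped
    len <- max(ev$contig_end[on_ctg])
    # the repeat-unit block not anchored to the reference is what the
    # assembler glued to the wrong end: move it there and shift the rest
    ref_lo <- min(ev$contig_start[on_ctg & ev$target == "reference"])
    ref_hi <- max(ev$contig_end[on_ctg & ev$target == "reference"])
    movable <- on_ctg & ev$target == "repeat_unit" &
      (ev$contig_start >= ref_hi | ev$contig_end <= ref_lo)
    B <- sum(ev$contig_end[movable] - ev$contig_start[movable])
    at_right <- min(ev$contig_start[movable]) >= ref_hi
    if (at_right) {
      ev$contig_start[on_ctg & !movable] <- ev$contig_start[on_ctg & !movable] + B
      ev$contig_end[on_ctg & !movable] <- ev$contig_end[on_ctg & !movable] + B
      shift <- min(ev$contig_start[movable])
      ev$contig_start[movable] <- ev$contig_start[movable] - shift
      ev$contig_end[movable] <- ev$contig_end[movable] - shift
    } else {
      ev$contig_start[on_ctg & !movable] <- ev$contig_start[on_ctg & !movable] - B
      ev$contig_end[on_ctg & !movable] <- ev$contig_end[on_ctg & !movable] - B
      ev$contig_start[movable] <- ev$contig_start[movable] + (len - B)
      ev$contig_end[movable] <- ev$contig_end[movable] + (len - B)
    }
  }

  list(evidence = match_segments(ev),
       truth = list(array_interval = array_interval,
                    order = sprintf("ctg%02d", seq_len(n_contigs)),
                    split_after = j,
                    swapped = swapped))
}
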