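# Aggregation of per-fibre repeat counts into diploid genotypes and
# cohort-level statistics (allele table, observed heterozygosity, distance
# summaries).

#' Call a diploid genotype from per-fibre repeat counts
#'
#' Single-linkage clustering of integer counts with linkage distance at most
#' `merge_tol`; clusters are ranked by support (fibre count). A second
#' allele is called iff the runner-up cluster has support of at least
#' `min_support` and its representative differs from the top one by more
#' than `merge_tol`; otherwise the call is homozygous for the top cluster.
#' Cluster representatives are medians with ties broken to the lower value.
#'
#' @param counts integer repeat counts from integrity-full fibres only.
#' @param min_support minimum fibres supporting an allele (default 2).
#' @param merge_tol maximum copy difference merged into one cluster
#'   (default 1).
#' @param individual_id optional id copied to the output.
#' @param min_conf_fibres single-cluster calls from fewer intact fibres than
#'   this carry a confidence note (default 6).
#' @return one-row data.frame: individual_id, allele_low, allele_high,
#'   support_low, support_high, heterozygous, n_fibres, confidence_note.
#' @export
call_genotype <- function(counts, min_support = 2, merge_tol = 1,
                          individual_id = NA_character_,
                          min_conf_fibres = 6) {
  counts <- counts[!is.na(counts)]
  if (length(counts) < min_support)
    fc_error("fc_no_call",
             sprintf("only %d usable fibre counts (min_support = %d)",
                     length(counts), min_support))
  s <- sort(counts)
  brk <- which(diff(s) > merge_tol)
  cl_id <- cumsum(c(1, seq_along(s)[-1] %in% (brk + 1)))
  clusters <- split(s, cl_id)
  rep_of <- vapply(clusters, function(v) sort(v)[ceiling(length(v) / 2)], 0)
  support <- lengths(clusters)
  ord <- order(-support, rep_of)
  top <- ord[1]
  second <- if (length(ord) > 1) ord[2] else NA

  note <- ""
  if (!is.na(second) && support[second] >= min_support &&
      abs(rep_of[second] - rep_of[top]) > merge_tol) {
    alleles <- sort(c(rep_of[top], rep_of[second]))
    supp <- support[c(top, second)][order(c(rep_of[top], rep_of[second]))]
    het <- TRUE
  } else {
    alleles <- rep(rep_of[top], 2)
    supp <- rep(support[top], 2)
    het <- FALSE
    if (length(counts) < min_conf_fibres)
      note <- sprintf("single cluster from %d fibres; second allele may be missed",
                      length(counts))
  }
  data.frame(individual_id = individual_id,
             allele_low = as.integer(alleles[1]),
             allele_high = as.integer(alleles[2]),
             support_low = as.integer(supp[1]),
             support_high = as.integer(supp[2]),
             heterozygous = het,
             n_fibres = length(counts),
             confidence_note = note)
}

#' Genotype every individual of a calls table
#'
#' Groups gap-corrected repeat counts of countable (integrity-full) fibres
#' by individual and applies [call_genotype()]. Individuals with too few
#' countable fibres are reported with NA alleles and a note instead of an
#' error.
#'
#' @param calls data.frame from [analyze_fibres()].
#' @inheritParams call_genotype
#' @return data.frame, one row per individual.
#' @export
genotype_cohort <- function(calls, min_support = 2, merge_tol = 1,
                            min_conf_fibres = 6) {
  ok <- calls[calls$status == "countable" & !is.na(calls$repeat_count), ,
              drop = FALSE]
  ids <- unique(calls$individual_id)
  rows <- lapply(ids, function(ind) {
    cts <- ok$repeat_count[ok$individual_id == ind]
    tryCatch(
      call_genotype(cts, min_support, merge_tol, ind, min_conf_fibres),
      fc_no_call = function(e)
        data.frame(individual_id = ind, allele_low = NA_integer_,
                   allele_high = NA_integer_, support_low = 0L,
                   support_high = 0L, heterozygous = NA, n_fibres = length(cts),
                   confidence_note = conditionMessage(e)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a cohort allele table
#'
#' Tallies allele occurrences over the included chromosomes and reports
#' frequencies rounded half-away-from-zero to 2 decimals. By default all
#' 2 x n chromosomes count; a manifest data.frame (individual_id,
#' allele_rank in 1:2 with 1 = lower allele, include logical) restricts the
#' tally to the flagged unrelated chromosomes.
#'
#' @param genotypes data.frame from [genotype_cohort()] (needs allele_low,
#'   allele_high).
#' @param manifest optional per-chromosome include table (see above); or a
#'   logical vector parallel to genotypes marking fully included individuals.
#' @return object of class `allele_table`: data.frame (repeat_units,
#'   occurrences, frequency) with attributes `chromosomes` and
#'   `distinct_alleles`.
#' @export
build_allele_table <- function(genotypes, manifest = NULL) {
  g <- genotypes[!is.na(genotypes$allele_low), , drop = FALSE]
  if (!nrow(g)) fc_error("fc_empty_input", "no called genotypes")
  chroms <- data.frame(
    individual_id = rep(g$individual_id, 2),
    allele_rank = rep(1:2, each = nrow(g)),
    allele = c(g$allele_low, g$allele_high))
  if (is.logical(manifest)) {
    keep_ids <- g$individual_id[manifest[!is.na(genotypes$allele_low)]]
    chroms <- chroms[chroms$individual_id %in% keep_ids, , drop = FALSE]
  } else if (is.data.frame(manifest)) {
    key <- paste(chroms$individual_id, chroms$allele_rank)
    inc <- paste(manifest$individual_id[manifest$include],
                 manifest$allele_rank[manifest$include])
    chroms <- chroms[key %in% inc, , drop = FALSE]
  }
  if (!nrow(chroms)) fc_error("fc_empty_input", "no chromosomes included")
  tab <- table(chroms$allele)
  out <- data.frame(repeat_units = as.integer(names(tab)),
                    occurrences = as.integer(tab))
  out <- out[order(out$repeat_units), , drop = FALSE]
  out$frequency <- round_half_up(out$occurrences / sum(out$occurrences), 2)
  rownames(out) <- NULL
  structure(out, chromosomes = sum(out$occurrences),
            distinct_alleles = nrow(out),
            class = c("allele_table", "data.frame"))
}

#' Observed heterozygosity
#'
#' Fraction of individuals whose two called alleles differ.
#'
#' @param genotypes data.frame with a `heterozygous` column (NA-called
#'   individuals are excluded).
#' @return list with `raw` and `rounded` (2 dp, half away from zero) plus
#'   `n_individuals`.
#' @export
observed_heterozygosity <- function(genotypes) {
  h <- genotypes$heterozygous[!is.na(genotypes$heterozygous)]
  if (!length(h)) fc_error("fc_empty_input", "no called genotypes")
  raw <- sum(h) / length(h)
  list(raw = raw, rounded = round_half_up(raw, 2), n_individuals = length(h))
}

#' Summarise fibre distance measurements
#'
#' Sample mean and sd (n-1 denominator) of the BRCA1-to-array distance and
#' of red signal and gap lengths over measurable calls; a quantity with
#' fewer than two values is omitted.
#'
#' @param calls data.frame from [analyze_fibres()].
#' @return list of summaries, each with mean, sd and n.
#' @export
summarize_distances <- function(calls) {
  one <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NULL)
    list(mean = mean(v), sd = stats::sd(v), n = length(v))
  }
  out <- list(brca1_to_array_kb = one(calls$brca1_to_array_kb),
              signal_length_kb = one(calls$mean_signal_kb),
              gap_length_kb = one(calls$mean_gap_kb))
  out[!vapply(out, is.null, logical(1))]
}

#' @export
print.allele_table <- function(x, ...) {
  cat(sprintf("<allele_table> %d distinct alleles over %d chromosomes\n",
              attr(x, "distinct_alleles"), attr(x, "chromosomes")))
  print.data.frame(x, ...)
  invisible(x)
}
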