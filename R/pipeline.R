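# End-to-end convenience wrapper: simulate (or load) fibres, analyse them,
# genotype individuals, and assemble cohort statistics.

#' Run the full genotyping pipeline on a fibre dataset
#'
#' @param dataset a `cohort_dataset` from [simulate_cohort()], or a fibre
#'   signal data.frame (columns fibre_id, individual_id, channel, start_um,
#'   end_um).
#' @param map a [locus_map()]; taken from the dataset when available.
#' @param manifest optional unrelated-chromosome manifest passed to
#'   [build_allele_table()] (data.frame individual_id, allele_rank, include,
#'   or logical vector per individual).
#' @param tol_kb,merge_gap_kb,min_elements per-fibre analysis parameters
#'   (see [analyze_fibre()]).
#' @param min_support,merge_tol,min_conf_fibres genotype-calling parameters
#'   (see [call_genotype()]).
#' @return list with `calls`, `genotypes`, `allele_table`, `heterozygosity`,
#'   `distance_summary`, and `gating` (fibre counts by status).
#' @export
run_genotyping_pipeline <- function(dataset, map = NULL, manifest = NULL,
                                    tol_kb = 5, merge_gap_kb = 1,
                                    min_elements = 4, min_support = 2,
                                    merge_tol = 1, min_conf_fibres = 6) {
  if (inherits(dataset, "cohort_dataset")) {
    fibres <- dataset$fibres
    if (is.null(map)) map <- dataset$map
  } else {
    fibres <- dataset
    if (is.null(map)) map <- default_locus_map()
  }
  calls <- analyze_fibres(fibres, map, tol_kb, merge_gap_kb, min_elements)
  genotypes <- genotype_cohort(calls, min_support, merge_tol, min_conf_fibres)
  allele_table <- build_allele_table(genotypes, manifest)
  het <- observed_heterozygosity(genotypes)
  list(calls = calls,
       genotypes = genotypes,
       allele_table = allele_table,
       heterozygosity = het,
       distance_summary = summarize_distances(calls),
       gating = table(calls$status))
}

#' Unrelated-chromosome manifest from a truth genotype table
#'
#' Marks both chromosomes of every individual flagged `unrelated` in a
#' genotype table (e.g. [rnu2_cohort_genotypes()]) as included.
#'
#' @param genotypes data.frame with individual_id and unrelated columns.
#' @return manifest data.frame (individual_id, allele_rank, include).
#' @export
unrelated_manifest <- function(genotypes) {
  data.frame(individual_id = rep(genotypes$individual_id, each = 2),
             allele_rank = rep(1:2, nrow(genotypes)),
             include = rep(genotypes$unrelated %||% TRUE, each = 2))
}

#' Exact-genotype recovery rate against truth
#'
#' @param truth data.frame with individual_id, allele_1, allele_2.
#' @param genotypes called genotypes from [genotype_cohort()].
#' @return fraction of individuals whose called (low, high) pair equals the
#'   true sorted allele pair.
#' @export
genotype_recovery_rate <- function(truth, genotypes) {
  m <- merge(truth, genotypes, by = "individual_id")
  lo <- pmin(m$allele_1, m$allele_2)
  hi <- pmax(m$allele_1, m$allele_2)
  mean(!is.na(m$allele_low) & m$allele_low == lo & m$allele_high == hi)
}

#' Write genotypes / allele table / cohort stats
#'
#' @param genotypes,allele_table,stats pipeline outputs.
#' @param path output path.
#' @rdname cohort_io
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  utils::write.table(genotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
write_allele_table_tsv <- function(allele_table, path) {
  utils::write.table(as.data.frame(allele_table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
write_stats_json <- function(stats, path) {
  jsonlite::write_json(stats, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
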