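# Published allele spectrum of the RNU2 macrosatellite and the cohort
# construction used throughout the package's worked examples.

#' Published allele spectrum (46 unrelated chromosomes)
#'
#' The 28 distinct repeat-unit alleles observed among 46 unrelated
#' chromosomes, with occurrence counts and printed 2-dp frequencies.
#'
#' @return data.frame with columns repeat_units, occurrences, frequency.
#' @export
rnu2_allele_spectrum <- function() {
  occ <- c(`6` = 1, `8` = 1, `9` = 1, `11` = 2, `12` = 1, `13` = 1, `14` = 2,
           `15` = 1, `16` = 1, `17` = 1, `18` = 3, `19` = 5, `20` = 1,
           `21` = 2, `22` = 2, `23` = 1, `25` = 1, `27` = 2, `28` = 2,
           `29` = 2, `30` = 1, `32` = 2, `34` = 2, `35` = 2, `36` = 1,
           `37` = 2, `47` = 2, `82` = 1)
  data.frame(repeat_units = as.integer(names(occ)),
             occurrences = as.integer(occ),
             frequency = round_half_up(occ / sum(occ), 2),
             row.names = NULL)
}

#' Study-cohort genotypes built from the published spectrum
#'
#' Deterministic diploid genotypes for a 41-individual cohort: 23 unrelated
#' founders whose 46 chromosomes carry exactly the published allele multiset,
#' plus (optionally) 18 relatives who re-use founder genotypes
#' identical-by-descent, one of them homozygous (19,19), so that 40 of 41
#' individuals are heterozygous. Founder pairs are formed by sorting the
#' 46-chromosome multiset and pairing rank k with rank k+23, which keeps the
#' two alleles of every individual at least 14 copies apart (the family
#' structure behind the published chromosome set is not reconstructable, so
#' the pairing is the package's own, chosen so diploid calling is
#' well-posed).
#'
#' @param include_related include the 18 related individuals (default TRUE).
#' @return data.frame with columns individual_id, allele_1, allele_2,
#'   unrelated (logical: chromosomes count toward the unrelated set).
#' @export
rnu2_cohort_genotypes <- function(include_related = TRUE) {
  spec <- rnu2_allele_spectrum()
  chroms <- sort(rep(spec$repeat_units, spec$occurrences))
  stopifnot(length(chroms) == 46)
  founders <- data.frame(
    individual_id = sprintf("F%02d", 1:23),
    allele_1 = chroms[1:23], allele_2 = chroms[24:46],
    unrelated = TRUE)
  if (!include_related) return(founders)
  rel <- founders[c(1:17, 12), c("allele_1", "allele_2")]
  rel$individual_id <- sprintf("R%02d", 1:18)
  rel$unrelated <- FALSE
  rel[18, c("allele_1", "allele_2")] <- c(19, 19)  # the homozygous individual
  out <- rbind(founders, rel[, names(founders)])
  rownames(out) <- NULL
  out
}
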