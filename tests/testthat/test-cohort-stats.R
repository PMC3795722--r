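# independent re-implementation of the genotype-calling rules used as an
# oracle: single linkage via hclust, same ranking and tie-breaks
oracle_genotype <- function(counts, min_support = 2, merge_tol = 1) {
  s <- sort(counts)
  if (length(unique(s)) == 1) {
    cl <- rep(1, length(s))
  } else {
    hc <- stats::hclust(stats::dist(s), method = "single")
    cl <- stats::cutree(hc, h = merge_tol + 1e-9)
  }
  reps <- vapply(split(s, cl), function(v) sort(v)[ceiling(length(v) / 2)], 0)
  supp <- lengths(split(s, cl))
  ord <- order(-supp, reps)
  top <- ord[1]
  if (length(ord) > 1 && supp[ord[2]] >= min_support &&
      abs(reps[ord[2]] - reps[top]) > merge_tol) {
    sort(c(reps[top], reps[ord[2]]))
  } else rep(reps[top], 2)
}

test_that("genotype calling resolves clean two-cluster and merged cases", {
  g <- call_genotype(c(19, 19, 19, 19, 19, 6, 6, 6, 6))
  expect_identical(c(g$allele_low, g$allele_high), c(6L, 19L))
  expect_true(g$heterozygous)
  expect_identical(c(g$support_low, g$support_high), c(4L, 5L))

  g2 <- call_genotype(c(21, 21, 22, 21))
  expect_identical(c(g2$allele_low, g2$allele_high), c(21L, 21L))
  expect_false(g2$heterozygous)

  g3 <- call_genotype(c(14, 15))
  expect_identical(c(g3$allele_low, g3$allele_high), c(14L, 14L))
  expect_match(g3$confidence_note, "second allele may be missed")

  expect_error(call_genotype(c(19)), class = "fc_no_call")
})

test_that("genotype calling agrees with the single-linkage oracle", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    counts <- sample(1:40, n, replace = TRUE)
    got <- call_genotype(counts)
    expect_identical(c(got$allele_low, got$allele_high),
                     as.integer(oracle_genotype(counts)),
                     info = paste(counts, collapse = ","))
  }
})

test_that("genotype calling is invariant to count permutation", {
  set.seed(42)
  counts <- c(19, 18, 19, 19, 6, 6, 7, 19, 6)
  ref <- call_genotype(counts)
  for (i in 1:10) {
    p <- call_genotype(sample(counts))
    expect_identical(p$allele_low, ref$allele_low)
    expect_identical(p$allele_high, ref$allele_high)
  }
})

test_that("allele tables conserve chromosomes and reproduce printed rounding", {
  g1 <- data.frame(individual_id = "solo", allele_low = 20L, allele_high = 20L,
                   heterozygous = FALSE)
  at1 <- build_allele_table(g1)
  expect_equal(as.data.frame(at1),
               data.frame(repeat_units = 20L, occurrences = 2L,
                          frequency = 1.00),
               ignore_attr = TRUE)
  # occurrences always sum to 2 x individuals
  set.seed(9)
  g2 <- data.frame(individual_id = sprintf("I%d", 1:15),
                   allele_low = sample(5:30, 15, TRUE),
                   allele_high = sample(31:60, 15, TRUE),
                   heterozygous = TRUE)
  at2 <- build_allele_table(g2)
  expect_identical(sum(at2$occurrences), 30L)
  expect_false(is.unsorted(at2$repeat_units, strictly = TRUE))
  # frequency rounding reproduces the published table from occurrences alone
  spec <- rnu2_allele_spectrum()
  freq <- round_half_up(spec$occurrences / sum(spec$occurrences), 2)
  expect_equal(freq, spec$frequency)
  expect_equal(freq[spec$repeat_units == 18], 0.07)   # 3/46
  expect_equal(freq[spec$repeat_units == 19], 0.11)   # 5/46
  expect_equal(freq[spec$repeat_units == 11], 0.04)   # 2/46
  expect_equal(freq[spec$repeat_units == 6], 0.02)    # 1/46
})

test_that("observed heterozygosity counts and rounds correctly", {
  g <- data.frame(heterozygous = c(rep(TRUE, 40), FALSE))
  h <- observed_heterozygosity(g)
  expect_equal(h$raw, 40 / 41)
  expect_equal(h$rounded, 0.98)
  expect_equal(observed_heterozygosity(
    data.frame(heterozygous = rep(FALSE, 5)))$rounded, 0)
  # independent recount over random genotype lists
  set.seed(13)
  for (i in 1:20) {
    lo <- sample(5:20, 30, TRUE); hi <- sample(5:20, 30, TRUE)
    g2 <- data.frame(heterozygous = lo != hi)
    expect_equal(observed_heterozygosity(g2)$raw, mean(lo != hi))
  }
  expect_error(observed_heterozygosity(data.frame(heterozygous = logical())),
               class = "fc_empty_input")
})

test_that("distance summaries use sample statistics and omit sparse inputs", {
  calls <- data.frame(brca1_to_array_kb = rep(123.7, 72),
                      mean_signal_kb = c(120, 126, 132),
                      mean_gap_kb = c(4.3, NA, NA))
  calls <- calls[rep(1, 72), ]
  calls$mean_signal_kb <- NA
  calls$mean_signal_kb[1:3] <- c(120, 126, 132)
  calls$mean_gap_kb <- NA
  calls$mean_gap_kb[1] <- 4.3
  s <- summarize_distances(calls)
  expect_equal(s$brca1_to_array_kb$mean, 123.7)
  expect_equal(s$brca1_to_array_kb$sd, 0)
  expect_identical(s$brca1_to_array_kb$n, 72L)
  expect_equal(s$signal_length_kb$mean, 126)
  expect_equal(s$signal_length_kb$sd, 6)
  expect_null(s$gap_length_kb)   # a single value is omitted
})

test_that("the unrelated-chromosome manifest filters the allele table", {
  g <- data.frame(individual_id = c("F1", "F2", "R1"),
                  allele_low = c(6L, 11L, 6L), allele_high = c(19L, 30L, 19L),
                  heterozygous = TRUE)
  man <- data.frame(individual_id = rep(c("F1", "F2", "R1"), each = 2),
                    allele_rank = rep(1:2, 3),
                    include = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE))
  at <- build_allele_table(g, man)
  expect_identical(attr(at, "chromosomes"), 4L)
  expect_identical(at$occurrences[at$repeat_units == 6], 1L)
})
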