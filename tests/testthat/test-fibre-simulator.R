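test_that("identical config and seed give byte-identical output", {
  g <- data.frame(individual_id = c("A", "B"), allele_1 = c(6, 19),
                  allele_2 = c(19, 30))
  cfg <- cohort_config(genotypes = g, fibres_per_individual = 5, seed = 11)
  f1 <- tempfile(); f2 <- tempfile()
  on.exit(unlink(c(f1, f2)))
  write_fibre_tsv(simulate_cohort(cfg), f1)
  write_fibre_tsv(simulate_cohort(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("fibre record counts follow the configuration", {
  g <- data.frame(individual_id = sprintf("I%02d", 1:5),
                  allele_1 = 10, allele_2 = 25)
  cfg <- cohort_config(genotypes = g, fibres_per_individual = 4, seed = 3)
  ds <- simulate_cohort(cfg)
  expect_identical(nrow(ds$truth), 20L)
  expect_identical(length(unique(ds$truth$fibre_id)), 20L)
})

test_that("genotype sampling honours explicit lists and frequency tables", {
  cfg <- cohort_config(genotypes = data.frame(allele_1 = 6, allele_2 = 19))
  g <- sample_genotypes(cfg)
  expect_equal(c(g$allele_1, g$allele_2), c(6, 19))
  # degenerate spectrum
  cfg2 <- cohort_config(n_individuals = 7,
                        allele_spectrum = data.frame(repeat_units = 20,
                                                     frequency = 1),
                        seed = 5)
  g2 <- sample_genotypes(cfg2)
  expect_true(all(g2$allele_1 == 20 & g2$allele_2 == 20))
  # published spectrum: empirical frequency of the 19-copy allele
  cfg3 <- cohort_config(n_individuals = 5000, seed = 2)
  g3 <- sample_genotypes(cfg3)
  p <- 5 / 46
  emp <- mean(c(g3$allele_1, g3$allele_2) == 19)
  expect_lt(abs(emp - p), 3 * sqrt(p * (1 - p) / 10000))
  # bad frequency table
  cfg4 <- cohort_config(allele_spectrum = data.frame(repeat_units = c(6, 19),
                                                     frequency = c(0.5, 0.4)))
  expect_error(sample_genotypes(cfg4), class = "fc_invalid_config")
})

test_that("noise-free fibres carry the exact expected signals", {
  hap <- build_haplotype(test_map, 19)
  fib <- full_span_fibre(hap, zero_noise_config())
  sig <- fib$signals
  reds <- sig[sig$channel == "R" & grepl("^unit\\[", sig$truth_source), ]
  expect_identical(nrow(reds), 19L)
  # each labelled span is label_span / stretch um long
  expect_equal(reds$end_um - reds$start_um,
               rep(test_map$unit$label_span / 1000 / 2, 19))
})

test_that("orientation reversal mirrors the signal pattern", {
  hap <- build_haplotype(test_map, 12)
  fwd <- full_span_fibre(hap, zero_noise_config(), seed = 9)
  rev <- full_span_fibre(hap, zero_noise_config(orientation_prob = 1), seed = 9)
  expect_identical(fwd$truth$orientation, "+")
  expect_identical(rev$truth$orientation, "-")
  expect_equal(sort(fwd$signals$end_um - fwd$signals$start_um),
               sort(rev$signals$end_um - rev$signals$start_um))
  expect_identical(fwd$signals$channel, base::rev(rev$signals$channel))
})

test_that("dropout thins array signals at the configured rate", {
  cfg <- cohort_config(boundary_jitter_sd_kb = 0, false_signal_rate = 0,
                       stretch_sd = 0, orientation_prob = 0,
                       dropout_prob = 0.02, fibre_length_mean_kb = 1200,
                       fibre_length_sd_kb = 0, seed = 1)
  hap <- build_haplotype(test_map, 19)
  counts <- vapply(1:400, function(s) {
    sig <- full_span_fibre(hap, cfg, seed = s)$signals
    sum(grepl("^unit\\[", sig$truth_source))
  }, 0)
  expect_lt(abs(mean(counts) - 19 * 0.98),
            3 * sqrt(19 * 0.02 * 0.98 / 400))
})

test_that("boundary jitter propagates to signal-length spread as sqrt(2)*J", {
  J <- 0.3
  cfg <- cohort_config(boundary_jitter_sd_kb = J, dropout_prob = 0,
                       false_signal_rate = 0, stretch_sd = 0,
                       orientation_prob = 0, fibre_length_mean_kb = 1200,
                       fibre_length_sd_kb = 0, seed = 4)
  hap <- build_haplotype(test_map, 40)
  lens <- unlist(lapply(1:260, function(s) {
    sig <- full_span_fibre(hap, cfg, seed = s)$signals
    sig <- sig[grepl("^unit\\[", sig$truth_source), ]
    sig$end_um - sig$start_um
  }))
  expect_gt(length(lens), 10000)
  expect_lt(abs(stats::sd(lens) - sqrt(2) * J / 2), 0.1 * sqrt(2) * J / 2)
})

test_that("no signal extends beyond the fibre window image", {
  cfg <- cohort_config(genotypes = data.frame(allele_1 = 30, allele_2 = 45),
                       fibres_per_individual = 40, seed = 8)
  ds <- simulate_cohort(cfg)
  for (fid in unique(ds$fibres$fibre_id)) {
    sig <- ds$fibres[ds$fibres$fibre_id == fid, ]
    tr <- ds$truth[ds$truth$fibre_id == fid, ]
    img <- (tr$window_end_bp - tr$window_start_bp) / 1000 / tr$stretch_kb_per_um
    if (nrow(sig)) {
      expect_true(all(sig$start_um >= -1e-9))
      expect_true(all(sig$end_um <= img + 1e-9))
    }
  }
})

test_that("intact-fibre top-up guarantees flank-spanning coverage per chromosome", {
  g <- data.frame(individual_id = "X", allele_1 = 82, allele_2 = 9)
  cfg <- cohort_config(genotypes = g, fibres_per_individual = 5,
                       min_intact_per_haplotype = 10, seed = 2)
  ds <- simulate_cohort(cfg)
  for (h in 1:2) {
    n <- c(g$allele_1, g$allele_2)[h]
    hap <- build_haplotype(test_map, n)
    span <- c(min(hap$element_layout$start[hap$element_layout$id == "FP1"]),
              max(hap$element_layout$end[hap$element_layout$id == "FP4"]))
    tr <- ds$truth[ds$truth$haplotype == h, ]
    n_intact <- sum(tr$window_start_bp <= span[1] & tr$window_end_bp >= span[2])
    expect_gte(n_intact, 10)
  }
})
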