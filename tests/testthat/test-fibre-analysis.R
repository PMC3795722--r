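test_that("noise-free fibres are matched completely and counted exactly", {
  hap <- build_haplotype(test_map, 19)
  fib <- full_span_fibre(hap, zero_noise_config())
  call <- analyze_fibre(fib$signals, test_map)
  expect_identical(call$orientation, "+")
  expect_identical(call$integrity, "full")
  expect_identical(call$status, "countable")
  expect_length(call$matched_elements, 22)   # 17 GMC + FP1-4 + RNU2-4P
  expect_identical(call$repeat_count, 19L)
  expect_identical(call$n_red_signals, 19L)
  expect_equal(call$stretch_estimate, 2.0)
  expect_equal(call$distances$brca1_to_array_kb, 123.7)
  expect_equal(call$distances$signal_lengths_kb, rep(2.393, 19))
  expect_equal(call$distances$gap_lengths_kb, rep(3.739, 18))
})

test_that("reversed fibres give the same matched set, count and distances", {
  hap <- build_haplotype(test_map, 27)
  fwd <- full_span_fibre(hap, zero_noise_config(), seed = 5)
  rev <- full_span_fibre(hap, zero_noise_config(orientation_prob = 1), seed = 5)
  cf <- analyze_fibre(fwd$signals, test_map)
  cr <- analyze_fibre(rev$signals, test_map)
  expect_identical(cr$orientation, "-")
  expect_setequal(cr$matched_elements, cf$matched_elements)
  expect_identical(cr$repeat_count, cf$repeat_count)
  expect_equal(cr$distances$brca1_to_array_kb, cf$distances$brca1_to_array_kb)
  expect_equal(cr$stretch_estimate, cf$stretch_estimate)
})

test_that("dropping FP3 degrades integrity to centromeric_only", {
  hap <- build_haplotype(test_map, 11)
  fib <- full_span_fibre(hap, zero_noise_config())
  sig <- fib$signals[fib$signals$truth_source != "FP3", ]
  call <- analyze_fibre(sig, test_map)
  expect_identical(call$integrity, "centromeric_only")
  expect_identical(call$status, "measurable_only")
  expect_true(is.na(call$repeat_count))
  expect_error(count_repeats(call, test_map), class = "fc_gating")
})

test_that("repeat counting never happens without all four intact flanks", {
  hap <- build_haplotype(test_map, 15)
  fib <- full_span_fibre(hap, zero_noise_config())
  for (fp in c("FP1", "FP2", "FP3", "FP4")) {
    sig <- fib$signals[fib$signals$truth_source != fp, ]
    call <- analyze_fibre(sig, test_map)
    expect_false(identical(call$integrity, "full"))
    expect_true(is.na(call$repeat_count))
  }
})

test_that("stretch calibration is exact arithmetic on the motif span", {
  expect_equal(stretch_from_motif_span(64), 2.0)
  expect_equal(round(stretch_from_motif_span(58.18), 4), 2.2001)
  expect_error(stretch_from_motif_span(0), class = "fc_calibration_unavailable")
  # simulated fibre with true stretch 1.9 and zero jitter recovers 1.9
  hap <- build_haplotype(test_map, 10)
  fib <- full_span_fibre(hap, zero_noise_config(stretch_mean = 1.9))
  call <- analyze_fibre(fib$signals, test_map)
  expect_equal(call$stretch_estimate, 1.9)
  expect_equal(call$distances$brca1_to_array_kb, 123.7)
})

test_that("calibration errors when the motif is not fully matched", {
  hap <- build_haplotype(test_map, 10)
  fib <- full_span_fibre(hap, zero_noise_config())
  sig <- fib$signals[fib$signals$truth_source != "GMC11", ]
  call <- match_barcode(sig, test_map)
  expect_error(calibrate_stretch(call, test_map),
               class = "fc_calibration_unavailable")
  expect_true(is.na(call$stretch_estimate))
})

test_that("split detections merge and dropped units are imputed from gaps", {
  hap <- build_haplotype(test_map, 19)
  fib <- full_span_fibre(hap, zero_noise_config())
  sig <- fib$signals
  # split one array signal into two detections 0.5 kb apart
  i <- which(sig$truth_source == "unit[7]")
  left <- sig[i, ]; right <- sig[i, ]
  left$end_um <- left$start_um + 0.9 / 2          # 0.9 kb piece
  right$start_um <- right$end_um - 0.9 / 2
  sig2 <- rbind(sig[-i, ], left, right)
  sig2 <- sig2[order(sig2$start_um), ]
  call <- analyze_fibre(sig2, test_map)
  expect_identical(call$repeat_count, 19L)
  # drop one interior unit entirely: gap imputation restores the count
  sig3 <- sig[sig$truth_source != "unit[10]", ]
  call3 <- analyze_fibre(sig3, test_map)
  expect_identical(call3$n_red_signals, 18L)
  expect_identical(call3$repeat_count, 19L)
  # drop the first and last unit: boundary gaps impute as well
  sig4 <- sig[!sig$truth_source %in% c("unit[1]", "unit[19]"), ]
  call4 <- analyze_fibre(sig4, test_map)
  expect_identical(call4$repeat_count, 19L)
})

test_that("the cross-reacting pseudogene signal is never counted", {
  hap <- build_haplotype(test_map, 8)
  fib <- full_span_fibre(hap, zero_noise_config())
  call <- analyze_fibre(fib$signals, test_map)
  expect_true("RNU2-4P" %in% call$matched_elements)
  expect_identical(call$repeat_count, 8L)
})

test_that("empty and unmatchable fibres are unusable", {
  empty <- data.frame(fibre_id = character(), channel = character(),
                      start_um = numeric(), end_um = numeric())
  expect_identical(match_barcode(empty, test_map)$status, "unusable")
  junk <- data.frame(fibre_id = "j", channel = c("R", "G"),
                     start_um = c(0, 5), end_um = c(1, 6))
  expect_identical(match_barcode(junk, test_map)$status, "unusable")
})

test_that("calibrated distances are invariant to the simulated stretch", {
  for (s_true in c(1.8, 2.0, 2.2)) {
    hap <- build_haplotype(test_map, 13)
    fib <- full_span_fibre(hap, zero_noise_config(stretch_mean = s_true))
    call <- analyze_fibre(fib$signals, test_map)
    expect_equal(call$stretch_estimate, s_true)
    expect_equal(call$distances$brca1_to_array_kb, 123.7)
    expect_equal(call$distances$signal_lengths_kb, rep(2.393, 13))
  }
})

test_that("orientation and counts survive default noise on both strands", {
  g <- data.frame(individual_id = "N", allele_1 = 19, allele_2 = 19)
  cfg <- cohort_config(genotypes = g, fibres_per_individual = 12,
                       min_intact_per_haplotype = 4, seed = 31)
  ds <- simulate_cohort(cfg)
  calls <- analyze_fibres(ds$fibres, test_map)
  merged <- merge(calls, ds$truth, by = "fibre_id")
  # fragments showing a couple of signals can be genuinely ambiguous; a
  # solidly matched barcode must always resolve the true orientation
  known <- merged[merged$orientation.x != "unknown" &
                    merged$n_matched_elements >= 6, ]
  expect_gt(nrow(known), 5)
  expect_true(all(known$orientation.x == known$orientation.y))
  # gating soundness: counts only from integrity-full fibres
  expect_true(all(is.na(calls$repeat_count[calls$integrity != "full"])))
})
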