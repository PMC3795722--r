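# Synthetic combed-DNA fibre generator: produces per-fibre signal tables
# with the statistical structure the analysis assumes (random breakage,
# per-fibre stretch near 2 kb/um, boundary jitter, dropout, spurious
# signals, random orientation) plus ground truth for evaluation.

.channel_of <- c(red = "R", green = "G", blue = "B")

#' Cohort simulation configuration
#'
#' @param n_individuals number of diploid individuals (ignored when
#'   `genotypes` is given).
#' @param genotypes explicit genotype table (data.frame with columns
#'   individual_id, allele_1, allele_2 and optionally unrelated), or `NULL`
#'   to sample alleles from `allele_spectrum`.
#' @param allele_spectrum data.frame (repeat_units, frequency) to sample
#'   alleles from; defaults to the published spectrum
#'   ([rnu2_allele_spectrum()]).
#' @param fibres_per_individual fibres drawn per individual before any
#'   intact-fibre top-up.
#' @param fibre_length_mean_kb,fibre_length_sd_kb fibre length distribution
#'   (normal, kb; defaults 400 and 80).
#' @param stretch_mean,stretch_sd per-fibre stretching factor distribution
#'   (kb/um; truncated normal within 3 sd; defaults 2.0 and 0.05).
#' @param boundary_jitter_sd_kb additive noise sd applied independently to
#'   each signal boundary, in kb before um conversion (default 0.3).
#' @param dropout_prob per-signal dropout probability (default 0.02).
#' @param false_signal_rate Poisson mean of spurious signals per fibre
#'   (default 0.1).
#' @param orientation_prob probability a fibre is imaged reversed (default 0.5).
#' @param min_intact_per_haplotype if > 0, additional fibres are generated
#'   for each chromosome, with window conditioned to span FP1..FP4, until
#'   this many fibres fully cover the flanked array (conditional sampling
#'   from the same length distribution).
#' @param seed integer cohort seed.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 41, genotypes = NULL,
                          allele_spectrum = rnu2_allele_spectrum(),
                          fibres_per_individual = 15,
                          fibre_length_mean_kb = 400, fibre_length_sd_kb = 80,
                          stretch_mean = 2.0, stretch_sd = 0.05,
                          boundary_jitter_sd_kb = 0.3, dropout_prob = 0.02,
                          false_signal_rate = 0.1, orientation_prob = 0.5,
                          min_intact_per_haplotype = 0, seed = 1) {
  probs <- c(dropout_prob, orientation_prob)
  if (any(probs < 0 | probs > 1))
    fc_error("fc_invalid_config", "probabilities must be in [0, 1]")
  if (any(c(fibre_length_sd_kb, stretch_sd, boundary_jitter_sd_kb,
            false_signal_rate) < 0))
    fc_error("fc_invalid_config", "sds and rates must be >= 0")
  if (stretch_mean <= 0)
    fc_error("fc_invalid_config", "stretch_mean must be > 0")
  rm(probs)
  structure(as.list(environment()), class = "cohort_config")
}

#' Sample diploid genotypes for a cohort
#'
#' With explicit `genotypes` in the config they are passed through in order;
#' otherwise two alleles per individual are drawn independently from the
#' allele-frequency spectrum (frequencies must sum to 1 within 0.01).
#'
#' @param config a [cohort_config()].
#' @return data.frame: individual_id, allele_1, allele_2, unrelated.
#' @export
sample_genotypes <- function(config) {
  if (!is.null(config$genotypes)) {
    g <- as.data.frame(config$genotypes)
    if (!all(c("allele_1", "allele_2") %in% names(g)))
      fc_error("fc_invalid_config", "genotypes need allele_1/allele_2 columns")
    if (any(g$allele_1 < 1 | g$allele_2 < 1))
      fc_error("fc_invalid_allele", "alleles must be >= 1")
    if (is.null(g$individual_id))
      g$individual_id <- sprintf("I%03d", seq_len(nrow(g)))
    if (is.null(g$unrelated)) g$unrelated <- TRUE
    return(g[, c("individual_id", "allele_1", "allele_2", "unrelated")])
  }
  spec <- config$allele_spectrum
  # occurrence counts carry exact weights; a printed frequency column may
  # not sum to 1 after rounding, so it is only validated when used directly
  if (!is.null(spec$occurrences)) {
    f <- spec$occurrences / sum(spec$occurrences)
  } else {
    f <- spec$frequency
    if (abs(sum(f) - 1) > 0.01)
      fc_error("fc_invalid_config",
               "allele frequencies must sum to 1 (within 0.01)")
  }
  set.seed(substream_seed(config$seed, 0L))
  n <- config$n_individuals
  a <- matrix(spec$repeat_units[sample.int(nrow(spec), 2 * n, replace = TRUE,
                                           prob = f)],
              ncol = 2)
  data.frame(individual_id = sprintf("I%03d", seq_len(n)),
             allele_1 = a[, 1], allele_2 = a[, 2], unrelated = TRUE)
}

# flanked-array span of a haplotype: FP1 first bar to FP4 last bar
.flank_span <- function(hap) {
  lay <- hap$element_layout
  c(lay$start[lay$id == "FP1"], lay$end[lay$id == "FP4"])
}

#' Simulate one combed fibre from a haplotype
#'
#' Draws a fibre window over the haplotype (length from the configured
#' normal distribution, truncated at the haplotype ends), takes the expected
#' labelled-signal layout in that window, then applies dropout, independent
#' boundary jitter (kb, before um conversion), the fibre's stretch factor,
#' spurious signals, and random orientation. Signals never extend beyond the
#' fibre window image.
#'
#' @param hap a [build_haplotype()] result.
#' @param config a [cohort_config()].
#' @param seed substream seed for this fibre.
#' @param fibre_id,individual_id identifiers copied to the output.
#' @param cover optional bp interval the window must fully cover (length and
#'   placement are then sampled conditionally).
#' @return list with `signals` (data.frame fibre_id, individual_id, channel,
#'   start_um, end_um, truth_source) and `truth` (one-row data.frame).
#' @export
simulate_fibre <- function(hap, config, seed, fibre_id = "fib1",
                           individual_id = "I001", cover = NULL) {
  set.seed(seed)
  u_hap <- stats::runif(1)  # haplotype-choice slot, kept for stream stability

  len_lo <- 50
  if (!is.null(cover)) len_lo <- max(len_lo, (cover[2] - cover[1]) / 1000)
  L_kb <- rtruncnorm(1, config$fibre_length_mean_kb, config$fibre_length_sd_kb,
                     lower = len_lo)
  L <- L_kb * 1000

  if (is.null(cover)) {
    u <- stats::runif(1, hap$hap_start - L + 1000, hap$hap_end - 1000)
  } else {
    lo <- max(hap$hap_start, cover[2] - L)
    hi <- max(lo, min(cover[1], hap$hap_end - L))
    u <- stats::runif(1, lo, hi)
  }
  window <- c(max(u, hap$hap_start), min(u + L, hap$hap_end))

  layout <- expected_signal_layout(hap, window)
  nsig <- nrow(layout)
  keep <- stats::runif(nsig) >= config$dropout_prob
  jit <- stats::rnorm(2 * nsig, 0, config$boundary_jitter_sd_kb * 1000)
  layout$start <- layout$start + jit[seq_len(nsig)]
  layout$end <- layout$end + jit[nsig + seq_len(nsig)]
  layout <- layout[keep, , drop = FALSE]

  n_false <- stats::rpois(1, config$false_signal_rate)
  if (n_false > 0) {
    fs <- stats::runif(n_false, window[1], window[2])
    fl <- stats::runif(n_false, 500, 3000)
    fcol <- sample(names(.channel_of), n_false, replace = TRUE)
    layout <- rbind(layout, data.frame(color = fcol, start = fs, end = fs + fl,
                                       source = "noise"))
  }
  stretch <- rtruncnorm(1, config$stretch_mean, config$stretch_sd,
                        lower = config$stretch_mean - 3 * config$stretch_sd,
                        upper = config$stretch_mean + 3 * config$stretch_sd)
  reversed <- stats::runif(1) < config$orientation_prob

  # clip to the window image, drop what jitter pushed fully outside
  layout$start <- pmax(layout$start, window[1])
  layout$end <- pmin(layout$end, window[2])
  layout <- layout[layout$end - layout$start > 1, , drop = FALSE]

  fib_um <- (window[2] - window[1]) / 1000 / stretch
  s_um <- (layout$start - window[1]) / 1000 / stretch
  e_um <- (layout$end - window[1]) / 1000 / stretch
  if (reversed) {
    tmp <- s_um
    s_um <- fib_um - e_um
    e_um <- fib_um - tmp
  }
  ord <- order(s_um)
  signals <- data.frame(
    fibre_id = rep(fibre_id, length(ord)),
    individual_id = rep(individual_id, length(ord)),
    channel = unname(.channel_of[layout$color[ord]]),
    start_um = s_um[ord], end_um = e_um[ord],
    truth_source = layout$source[ord])
  truth <- data.frame(
    fibre_id = fibre_id, individual_id = individual_id,
    haplotype = NA_integer_, allele = hap$allele_n,
    window_start_bp = window[1], window_end_bp = window[2],
    stretch_kb_per_um = stretch,
    orientation = if (reversed) "-" else "+")
  list(signals = signals, truth = truth)
}

#' Simulate a diploid cohort of combed fibres
#'
#' Composition of [sample_genotypes()] and [simulate_fibre()]: every fibre
#' comes from one of the individual's two haplotypes (chosen at random), and
#' when `min_intact_per_haplotype > 0` each chromosome is topped up with
#' conditionally placed fibres until that many fully span FP1..FP4.
#' Identical (config, seed) give byte-identical output; per-fibre RNG
#' substreams are derived from the cohort seed by counter.
#'
#' @param config a [cohort_config()].
#' @param map a [locus_map()] (default [default_locus_map()]).
#' @return object of class `cohort_dataset`: list with `config`, `map`,
#'   `fibres` (signal data.frame), `truth` (per-fibre data.frame),
#'   `genotypes` (truth genotype table).
#' @export
simulate_cohort <- function(config, map = default_locus_map()) {
  genotypes <- sample_genotypes(config)
  hap_cache <- new.env(parent = emptyenv())
  get_hap <- function(n) {
    key <- as.character(n)
    if (is.null(hap_cache[[key]])) hap_cache[[key]] <- build_haplotype(map, n)
    hap_cache[[key]]
  }

  sig_list <- list(); truth_list <- list()
  counter <- 0L
  for (i in seq_len(nrow(genotypes))) {
    ind <- genotypes$individual_id[i]
    alleles <- c(genotypes$allele_1[i], genotypes$allele_2[i])
    intact <- c(0L, 0L)
    emit <- function(hap_idx, cover = NULL) {
      counter <<- counter + 1L
      hap <- get_hap(alleles[hap_idx])
      fid <- sprintf("%s_f%04d", ind, counter)
      fib <- simulate_fibre(hap, config, substream_seed(config$seed, counter),
                            fibre_id = fid, individual_id = ind, cover = cover)
      fib$truth$haplotype <- hap_idx
      span <- .flank_span(hap)
      if (fib$truth$window_start_bp <= span[1] &&
          fib$truth$window_end_bp >= span[2])
        intact[hap_idx] <<- intact[hap_idx] + 1L
      sig_list[[length(sig_list) + 1L]] <<- fib$signals
      truth_list[[length(truth_list) + 1L]] <<- fib$truth
    }
    for (f in seq_len(config$fibres_per_individual)) {
      set.seed(substream_seed(config$seed, counter + 1L))
      hap_idx <- 1L + (stats::runif(1) < 0.5)
      emit(hap_idx)
    }
    if (config$min_intact_per_haplotype > 0) {
      for (hap_idx in 1:2) {
        while (intact[hap_idx] < config$min_intact_per_haplotype)
          emit(hap_idx, cover = .flank_span(get_hap(alleles[hap_idx])))
      }
    }
  }
  structure(list(config = config, map = map,
                 fibres = do.call(rbind, sig_list),
                 truth = do.call(rbind, truth_list),
                 genotypes = genotypes),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d individuals, %d fibres, %d signals (seed %d)\n",
              nrow(x$genotypes), nrow(x$truth), nrow(x$fibres),
              x$config$seed))
  invisible(x)
}

#' Write/read fibre signal tables and truth sidecars
#'
#' The signal TSV has columns fibre_id, individual_id, channel, start_um,
#' end_um (um, 4 decimals) and no truth column; the truth sidecar carries
#' per-fibre ground truth so the analysis path cannot see it.
#'
#' @param dataset a `cohort_dataset` (or a fibre signal data.frame for
#'   `write_fibre_tsv`).
#' @param path output path.
#' @rdname fibre_tsv
#' @export
write_fibre_tsv <- function(dataset, path) {
  df <- if (inherits(dataset, "cohort_dataset")) dataset$fibres else dataset
  out <- data.frame(fibre_id = df$fibre_id, individual_id = df$individual_id,
                    channel = df$channel,
                    start_um = sprintf("%.4f", df$start_um),
                    end_um = sprintf("%.4f", df$end_um))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname fibre_tsv
#' @export
read_fibre_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname fibre_tsv
#' @export
write_truth_tsv <- function(dataset, path) {
  tr <- dataset$truth
  out <- data.frame(fibre_id = tr$fibre_id, haplotype = tr$haplotype,
                    window_start_bp = tr$window_start_bp,
                    window_end_bp = tr$window_end_bp,
                    stretch_kb_per_um = sprintf("%.6f", tr$stretch_kb_per_um),
                    orientation = tr$orientation)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
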