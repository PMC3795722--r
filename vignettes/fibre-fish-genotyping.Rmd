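---
title: "Genotyping a macrosatellite from combed-DNA fibre FISH: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping a macrosatellite from combed-DNA fibre FISH: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrecall)
```

# The problem

The *RNU2* macrosatellite is a nearly perfect tandem array of a 6,132-bp
unit on chromosome 17q21, roughly 124 kb telomeric of *BRCA1*. Arrays run
from a handful to dozens of copies per chromosome (observed range 6–82),
so a single allele spans 37–503 kb — far beyond PCR, and collapsed to a
fragment of one unit in the reference assembly. Molecular combing
stretches single DNA molecules uniformly (nominally 2 kb/µm) on a surface;
FISH with a multi-colour probe set then paints each molecule with a
"Genomic Morse Code" (GMC) barcode, one red signal per repeat unit, and
flanking probes on either side of the array. Copy number becomes a direct
counting problem on single molecules — provided each fibre can be
identified, oriented, calibrated and quality-gated. `fibrecall` implements
that inference, the cohort statistics built on it, the assembly-placement
logic from clone interval evidence, and a synthetic fibre generator that
makes the whole pipeline testable without microscopes.

# The locus model

`default_locus_map()` describes the region in a self-contained linear
frame, 0-based and half-open, anchored so the array insertion point is
position 41,399,577 — printed assembly coordinates can therefore be used
literally without shipping a genome. Its named constants are the
scientifically meaningful quantities:

| constant | value | meaning |
|---|---|---|
| `unit_length` | 6,132 bp | repeat-unit length |
| labelled span | 2,393 bp at offset 1,000 | region of the unit covered by the two unit probes (434 + 1,959 bp), which appear as one red signal |
| `flank_gap_centromeric_bp` | 7,300 bp | FP2 end to array start |
| `flank_gap_telomeric_bp` | 2,000 bp | array end to FP3 start |
| `calibration_motif_bp` | 128,000 bp | GMC01 first bar to GMC11 last bar; calibrates per-fibre stretch |
| `brca1_end_to_array_bp` | 123,700 bp | designated BRCA1-end anchor (GMC09 last bar) to array start |
| `array_to_rnu2_4p_bp` | 63,400 bp | array end to the cross-hybridizing *RNU2-4P* pseudogene |
| `default_stretch_kb_per_um` | 2.0 | nominal combing stretch |

The probe fragment sizes (FP1 4,393; FP2 4,860; FP3 7,009; FP4 5,340 bp)
fix the flank bar extents. The 17 GMC elements (1–3 bars each, one colour
per element) are a packaged, versioned default: the barcode schema fixes
colours and bar counts but not bp positions, so the coordinates here are
the package's own, chosen deliberately **aperiodic** — a regular grid of
bar spacings would make partial fibres ambiguous under offset voting
(several shifts of a periodic pattern align equally well). The labelled
sub-interval of the unit is likewise a named constant: the two unit probes
target close regions and merge into one signal, but their offset within
the unit is not derivable from fragment sizes alone, so any choice is
legitimate as long as it is explicit; distances to the "array start" are
corrected by this offset.

`build_haplotype(map, n)` expands the map into one chromosome: `n`
adjacent unit copies at the anchor, telomeric elements shifted by
`n * 6132`. Every copy adds exactly 6,132 bp to the total span, which the
test suite asserts as a property.

# The synthetic fibre generator

`simulate_cohort()` is first-class, tested code: it defines the study
conditions under which the pipeline's statistical claims hold.

* **Genotypes.** Default allele spectrum: the 28 observed alleles with
  their occurrence counts over 46 unrelated chromosomes (range 6–82;
  `rnu2_allele_spectrum()`). `rnu2_cohort_genotypes()` builds the
  41-individual study cohort deterministically: 23 unrelated founders
  carrying exactly that multiset, plus 18 relatives re-using founder
  genotypes identical-by-descent, one of them homozygous (19,19), so 40/41
  individuals are heterozygous. The real family structure behind the
  published chromosome set is not reconstructable, so the founder pairing
  is the package's own: the sorted 46-chromosome multiset is paired rank k
  with rank k+23, which keeps every individual's two alleles at least 14
  copies apart and makes diploid calling well-posed. Which chromosomes
  count as "unrelated" is an explicit per-chromosome manifest flag, never
  an inference.
* **Fibre windows.** Length ~ Normal(400, 80) kb — a realistic combed-DNA
  fibre length scale — placed uniformly and truncated at the haplotype
  ends. With `min_intact_per_haplotype = N`, each chromosome is topped up
  with fibres whose window is *conditioned* to span FP1..FP4: length is
  drawn from the same distribution truncated at the required span (exact
  inverse-CDF truncated normal), placement uniform among covering
  positions. This reproduces the study design of collecting enough intact
  fibres per allele without changing the physical length model.
* **Noise.** Per-fibre stretch ~ truncated Normal(2.0, 0.05) kb/µm (±3 sd,
  forbidding non-physical values); each signal boundary jittered
  independently with sd 0.3 kb *before* µm conversion; per-signal dropout
  0.02; spurious signals Poisson(0.1) per fibre with random colour and
  position; fibre reversed with probability 0.5. Dropout and false-signal
  rates are not quantified in the source study; these defaults are
  declared, tunable parameters of realistic magnitude. Independent
  boundary jitter means a signal's measured length has sd √2·J and a dark
  gap accumulates two boundaries as well — which is why gap spreads exceed
  signal-length spreads in this kind of data; the suite checks the √2
  closed form at n > 10,000 signals.
* **Determinism.** One cohort seed; each fibre draws from a substream
  seeded by a counter hash, so identical (config, seed) give byte-identical
  TSVs and generation order cannot leak between fibres. Truth (window,
  haplotype, stretch, orientation, per-signal source) is written to a
  sidecar the analysis path never reads.

What the generator does **not** emulate: image formation (signals are
intervals, not pixels), optical resolution limits and signal splitting,
somatic mosaicism, inverted or rearranged repeat patterns, and
non-uniform local stretching. Passing tests therefore show the inference
is correct *under this noise model*, not that microscope-specific
artefacts are handled.

# Per-fibre inference

`match_barcode()` must solve a small registration problem: observed µm
signals vs expected bp layout with unknown window offset, unknown
orientation, an unknown number of repeat units separating the two flank
blocks, and a scale error of a few percent (true stretch vs nominal).

* Expected bars form two rigid blocks — centromeric (GMC, FP1, FP2) and
  telomeric (FP3, FP4, *RNU2-4P*) — with positions expressed **relative to
  the array anchor**. Keeping the numbers small matters: against absolute
  coordinates of ~41.4 Mb, a 5% scale error shifts an apparent offset by
  thousands of kb and swamps the real geometry.
* Candidate block offsets come from vote-binning observed-minus-expected
  positions over colour-consistent non-red pairs (2-kb bins, top 10), plus
  candidates derived from the array's own red signals: the first red start
  predicts where FP2 must end, the last red end where FP3 must start, up
  to a dropped leading/trailing unit. These derived anchors are what make
  flank-only fibres (large alleles) reliably matchable.
* Each candidate is scored by greedy one-to-one assignment within a 5-kb
  tolerance. **Red expected bars get weight 0.2 in model selection**: an
  array contributes up to dozens of red signals, so a red bar finds a
  match at almost any offset and carries no discriminative information.
* The block pair is chosen jointly under a physical constraint (the
  telomeric block must sit telomeric of the centromeric one by at least
  the flank gaps plus one unit), then a single shared scale factor is
  estimated by the median of pairwise slopes over matched pairs — robust
  to a single bar-level misassignment, where least squares is not — and
  the assign/refit loop iterates (up to 3 rounds) until the matched set
  stabilises. Iterating is necessary: at ~10% scale error a single
  refinement pass can converge to an off-by-one-bar fixed point.
* Orientation: both orientations are fitted; the one explaining more
  non-red bars (then more elements) wins; an exact tie is reported
  `unknown`. Reversing a fibre and re-analysing yields identical matched
  sets, counts and distances — asserted as a property.

`calibrate_stretch()` divides the motif's genomic length (128 kb) by its
measured µm span, taken between *observed* signal boundaries of the two
designated anchor bars; 64.00 µm gives exactly 2.0 kb/µm. All distance
outputs use this per-fibre factor, never the nominal stretch; when the
motif is off-fibre, distances are simply not reported for that fibre.

`count_repeats()` is gated: it refuses anything but full integrity (all of
FP1–FP4 matched), the testable analogue of counting "only on fibres with
intact flanking probes". Within the gate:

* the counting region runs between the FP2 telomeric edge and FP3
  centromeric edge, each **predicted from every matched bar of the
  element** rather than read off one observed bar — a dropped edge bar
  would otherwise shift the boundary by a whole bar width;
* red detections closer than `merge_gap_kb = 1` kb merge (safely under
  half the 3.74-kb inter-unit dark gap, so true gaps never merge);
* a dark gap exceeding its expected value (3.74 kb interior; 8.3 / 4.74 kb
  at the boundaries) by ≈ k·6.132 kb adds k imputed units. Raw detections
  are kept as `n_red_signals`; `repeat_count` is the dropout-corrected
  estimate. Without imputation, a 2% dropout makes large alleles
  systematically undercounted (an 82-unit array loses 1.6 units in
  expectation), and exact recovery would be impossible under the
  generator's own defaults;
* when motif calibration is unavailable (flank-only fibres), the stretch
  used for this gap arithmetic is taken from the array's own 6.132-kb
  period (median inter-signal spacing) — the array calibrates itself;
* the *RNU2-4P* cross-reaction lies telomeric of FP3 and is excluded by
  position.

`measure_distances()` reports the BRCA1-end-to-array distance as the
calibrated distance from the designated anchor bar to the first red array
signal minus the unit label offset — i.e. to the inferred array start — so
its noise-free value is exactly the 123.7-kb map constant. The telomeric
flank is not required for this measurement: a fibre that ends inside the
array still shows the boundary (the first red must then sit within three
units of FP2 to exclude stray signals).

# Genotyping and cohort statistics

`call_genotype()` clusters integer counts by single linkage with linkage
distance ≤ 1 copy, ranks clusters by fibre support, and calls a second
allele only with ≥ 2 supporting fibres and a representative more than 1
copy from the first — the testable analogue of replicate human counting
that agreed within one copy. Representatives are medians with ties to the
lower value; the suite cross-checks the whole rule against an independent
`hclust`-based re-implementation on 200 random inputs. Homozygous calls
from fewer than 6 intact fibres carry a confidence note, since a missed
second allele cannot be excluded there.

`build_allele_table()` tallies occurrences over the included chromosomes
and rounds frequencies half-away-from-zero at 2 decimals, which reproduces
the published frequency column exactly from the occurrence column (1/46 →
0.02, 2/46 → 0.04, 3/46 → 0.07, 5/46 → 0.11). Note that such a rounded
column need not sum to 1 — with many 1/46 rows it sums to 0.94 — so no
sum-to-one constraint is imposed on rounded frequencies.
`observed_heterozygosity()` is the fraction of individuals with two
distinct called alleles (40/41 → 0.9756 → 0.98).

# Array placement from clone evidence

Alignment results are represented as interval matches only — running an
aligner is out of scope. Each evidence row maps a contig interval onto a
target: the reference, the 6,132-bp repeat unit, or a junction fragment
(right junction 416 bp = 36 unit + 380 flank; left 92 bp = 47 + 45).
Reference placement of unit/junction matches is obtained by composing with
the contig's own reference matches, clipped to those anchors (no
extrapolation into unsequenced repeat).

`infer_array_interval()` returns the reference span of unit-portion
matches whose telomeric edge coincides — within a 50-bp tolerance, which
guards rounded inputs against the paper-style exact bookkeeping — with the
unit/flank boundary inside a right-junction placement. No junction anchor
→ `ambiguous`; two disjoint anchored spans → an error listing both.
Placement is invariant under uniform translation, and on synthetic
fixtures the recovered interval equals the planted one exactly for any
copy number.

`order_contigs()` chains contigs by unique reference-footprint overlaps of
at least 300 bp (so both a ~500-bp and a 1.3-kb overlap count, while
typical interspersed-repeat match noise does not), erroring on cyclic or
branching overlap graphs. `flag_misassembly()` encodes the contig-15-style
reasoning: an overlap whose reference span intersects repeat-unit matches
is repeat-mediated and proves nothing; a *unique* neighbour overlap that
maps to the same contig end that carries a repeat-unit block means the
repeat block is on the wrong end, and the contig is flagged. The fixture
generator plants a known array, tiles contigs with unique overlaps, puts
repeat blocks on the two array-adjacent ends, and can move one block to
the wrong end; across seeded fixtures exactly the swapped contig is
flagged and never any other.

# Numerical choices and degenerate inputs

* 0-based half-open intervals everywhere; empty or inverted windows yield
  empty layouts, not errors.
* `tol_kb = 5` (assignment), `merge_gap_kb = 1`, junction tolerance 50 bp,
  `min_overlap = 300` bp, `min_support = 2`, `merge_tol = 1` copy — each
  argued above; all are function arguments, not hidden constants.
* Fibres matching fewer than 4 elements are `unusable`; empty fibres are
  handled explicitly.
* Errors are classed conditions (`fc_gating`, `fc_no_call`,
  `fc_calibration_unavailable`, `fc_ambiguous_anchor`, ...) so callers can
  distinguish gating from failure.
* Problem sizes in the shipped tests and acceptance script: the cohort run
  simulates 41 individuals at 15 fibres each plus intact top-ups (~1,250
  fibres); property checks use 72-fibre distance panels, 20-seed recovery
  replicates of a 5-individual cohort, 50 seeded placement fixtures, and
  zero-noise sweeps over alleles 1–100. These sizes give stable statistics
  while keeping a full run in minutes on one CPU.

# Known limitations

* The barcode matcher assumes the two flank blocks are rigid; large
  insertions or inversions *within* the array (which combing can in
  principle reveal) are not modelled or detected.
* Gap-based dropout imputation assumes missing units, not missing
  stretches of fibre; a fibre broken inside the array is excluded by the
  integrity gate rather than rescued.
* The homozygote/missed-allele ambiguity is flagged, not resolved: an
  individual whose fibres show one cluster is called homozygous with a
  note when support is thin.
* The observed ~2 kb offset between a measured BRCA1-array distance and
  the assembly-derived expectation in real data cannot be adjudicated from
  coordinates alone (measurement bias vs annotation difference); the
  simulator treats the 123.7-kb constant as truth and the pipeline is
  validated against that.
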