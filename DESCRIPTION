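Package: fibrecall
Title: Macrosatellite Copy-Number Genotyping from Combed-DNA Fibre FISH
Version: 0.2.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for genotyping large variable-number tandem repeats
    (macrosatellites) by fluorescent in situ hybridization on combed DNA
    fibres. Models a multi-colour genomic barcode around a tandem array,
    simulates diploid cohorts of single-molecule fibre signal tables with
    realistic stretching, jitter, dropout and orientation noise, matches
    observed fibre signals back to the barcode, calibrates per-fibre
    stretching factors from a motif of known genomic length, counts repeat
    units between intact flanking probes, aggregates per-fibre counts into
    diploid allele calls and cohort allele tables with observed
    heterozygosity, and places the array in an assembly from clone
    interval-match evidence, including detection of contigs whose
    repeat-bearing end is inconsistent with the contig overlap layout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
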