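Package: imprintscan
Title: Genome-Wide Detection of Imprinted Expression from Reciprocal-Cross
    Allelic Read Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Identifies genomically imprinted loci from reciprocal-cross
    RNA-seq of seed tissues. Short reads (or pre-assigned per-SNP allelic
    counts) from the two reciprocal F1 hybrids are assigned a parental
    origin via diagnostic SNP reads, normalized between crosses, and scanned
    both in overlapping 1 kb windows and over annotated features (transcript
    isoforms, introns, intergenic regions). Parental expression bias is
    tested against the tissue baseline (2 maternal : 1 paternal in triploid
    endosperm, 1:1 in embryo) with a Pearson chi-square test, and features
    significant in both crosses are classified as maternally or paternally
    imprinted, subspecies-biased, or discordant. Includes a screen for
    parent-of-origin-biased alternative splicing, downstream
    characterization (clustering, repeat proximity, GC content, GO
    enrichment), and a synthetic reciprocal-cross data generator with
    recorded ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
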