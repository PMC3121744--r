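---
title: "Detecting genomic imprinting from reciprocal-cross allelic read counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genomic imprinting from reciprocal-cross allelic read counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintscan)
```

## The design and the model

Genomic imprinting is parent-of-origin-dependent expression: one parental
allele of a gene is silenced or strongly suppressed. In flowering plants
imprinting is concentrated in the endosperm, the triploid nutritive tissue
of the seed that carries two maternal genome copies and one paternal copy.
A single F1 tissue cannot separate imprinting from ordinary allelic
(cis-regulatory) differences between the two parental genotypes; the
reciprocal-cross design can. With two subspecies A and B, the crosses
A&#9792;&times;B&#9794; and B&#9792;&times;A&#9794; swap which genotype is
maternal, so:

* a *parent-of-origin* effect keeps the same favored **parent** in both
  crosses, while
* an *allelic (subspecies)* effect keeps the same favored **allele**, which
  means the favored parent flips between crosses.

Reads are informative only where the two parental genomes differ. A **SNP
read** aligns perfectly and uniquely to one parental genome, aligns to the
other with exactly one mismatch, that mismatch is a reported SNP, and the
read covers exactly one reported SNP. Each SNP read is therefore assignable
to a parental genome, and with the cross direction, to a parent.

For a feature with normalized maternal and paternal counts $R_{mat}$ and
$R_{pat}$, the parental expression bias is the favored-parent read
fraction, e.g.

$$B_{mat} = \frac{R_{mat}}{R_{mat} + R_{pat}},$$

and the expected maternal count $R_e$ proportions $R_{mat}+R_{pat}$ into
the tissue baseline: $2\!:\!1$ maternal:paternal in endosperm, $1\!:\!1$ in
embryo. Departure from $R_e$ is tested with a plain Pearson chi-square on
the two categories (df = 1, no continuity correction), reported as
$-\log_{10} P$, computed in log space so mono-allelic features with huge
statistics do not underflow. A feature is significant at
$-\log_{10} P \ge 1.3$ (i.e. $P \le 0.05$); ties at the threshold are
significant. Evidence from the two crosses is combined by the **minimum
rule**: the combined bias and significance are those of the *less*
significant cross, so a single strong cross can never carry a call.

Per-feature calls (`imprint_calls()`):

* both crosses significant, same parental direction &rarr;
  `maternal_imprint` / `paternal_imprint`;
* both significant, direction flips with the cross &rarr;
  `subspecies_a_bias` / `subspecies_b_bias` (the same allele exceeds its
  expectation in both crosses);
* fewer than `min_reads` (default 10) normalized reads in one cross with a
  significant other cross &rarr; `one_cross_candidate`; low coverage
  otherwise &rarr; `low_coverage`;
* everything else profiled &rarr; `unbiased` (`discordant` is kept as a
  guard but is unreachable with two categories once both crosses are
  significant).

One design point deserves note: a feature below the read floor in one
cross whose other cross is *not* significant is classified `low_coverage`,
not `unbiased`, so that the non-coverage calls exactly partition the
features profiled with at least 10 reads in both crosses.

## Scans

Two redundant genome-wide scans maximize discovery from annotated and
unannotated regions:

* **Physical windows**: overlapping 1 kb windows every 0.5 kb. A read
  belongs to a window through its SNP position (a point, not the read
  span), so every interior SNP read is counted by exactly two windows. A
  trailing window of 500 bp or less is dropped because it is wholly
  contained in its predecessor.
* **Annotated features**: every transcript isoform independently (its exon
  set), per-gene exon-union and intron units, and intergenic intervals
  (maximal gaps, split at 10 kb for reporting). For conservation
  accounting every SNP is allocated to exactly one of
  exon-union > intron > intergenic (precedence for nested annotation), so
  the three partition totals sum exactly to the total assigned SNP reads -
  an invariant the pipeline checks on every run. Isoforms of a gene with
  identical per-SNP support are collapsed into one compound-annotated
  record.

`reconcile_scans()` cross-tabulates the two analyses, and
`poe_splicing_scan()` screens for parent-of-origin-biased splicing: a gene
whose sub-features (isoform, exon-union, intron unit, or an in-gene
window) mix maternally and paternally imprinted calls. The motivating
real-data pattern is maternally biased truncated transcripts terminating
in an intron alongside paternally biased full-length transcripts, which is
exactly the pattern the synthetic generator plants for its `poe_splicing`
class (maternal-favored intron reads, paternal-favored exon reads).

## Normalization

The two reciprocal libraries differ in sequencing yield, so raw counts are
converted to reads per million and rescaled by a fixed constant
$C = \overline{T}/10^6$ (the mean of the two library totals, i.e. total
assigned SNP reads per cross), rounding half-up to integers:
equal library totals leave counts untouched, and counts stay on the scale
of the observed data. The mean was chosen for $C$ because the
normalization is only defined up to "a fixed constant returning values to
integer counts of similar scale"; any fixed constant yields the same
inference up to rounding.

## The synthetic-data generator

The generator emulates the reciprocal-cross study conditions so the whole
pipeline can be exercised against a recorded truth:

* two colinear parental haplotypes differing only at planted SNPs
  (default rate 0.004/bp, comparable to two rice subspecies at roughly one
  SNP per 250 bp); no indels, so homologous coordinates coincide;
* a gene &rarr; mRNA &rarr; exon annotation with 2-4 exons per gene and
  optional exon-skipping second isoforms;
* one read library per cross per tissue (no replicates, as in a
  single-library reciprocal design); endosperm reads are 36 bases, embryo
  reads 75 bases (the pipeline analyses only their first 36 bases so
  multi-SNP exclusion risk matches between tissues);
* per-SNP read depth Poisson around a per-locus mean drawn log-normal
  across loci (median 35, sdlog 0.6), reproducing the long right tail of
  real SNP-read depth; allelic sampling is binomial with the maternal
  probability encoding each locus's truth class (a beta-binomial
  overdispersion switch exists but defaults to off, since the data model
  states nothing beyond binomial);
* a fraction of reads (default 5%) carries a known 3' adaptor suffix, and
  reads are reported on a random strand, exercising trimming and
  strand-symmetric assignment;
* truth classes: maternal/paternal imprints at a configurable bias
  (default 0.95 favored-origin fraction), subspecies-biased loci (favored
  *allele* fixed, so its parental role flips between crosses), biallelic
  loci at the tissue baseline, deliberately low-coverage loci, intergenic
  maternal transcripts, and `poe_splicing` loci.

What it does *not* emulate - sequencing errors, quality scores, indels,
paired ends, mapping ambiguity beyond literal sequence duplication,
contamination of maternal tissue - bounds what green tests mean: recovery
results demonstrate the statistical machinery and bookkeeping under the
declared sampling model, not robustness to alignment artifacts in real
libraries.

## Numerical and design choices

* **"Repetitive" reads** (the complexity filter) are undefined beyond
  intent in the source method; here the repetitive fraction is the share
  of read bases covered by maximal tandem repeats of period 1-3 with at
  least three copies, found by exhaustive scan. Requiring only two copies
  would cover roughly half of a random 36-mer by period-1 chance pairings
  alone and reject typical unique sequence, which is clearly not the
  intent; with three copies a random read scores about 0.2. Reads
  strictly above 0.5 are excluded.
* **Exact-match assignment** replaces a short-read aligner: an 18-mer seed
  index (18 = the minimum post-filter read length) via `Biostrings`
  dictionary matching, verified over the full read on both strands. On
  colinear haplotypes this reproduces the accept/reject semantics of the
  SNP-read rules exactly; reads containing `N` cannot match and are
  rejected.
* **Coordinates** follow the Bioconductor 1-based closed convention
  internally (`GRanges`); BED output and window tiling use 0-based
  half-open spans.
* **Chi-square accuracy**: the plain Pearson test tracks the central
  mid-P exact binomial within 0.01 for totals of 100 or more (checked
  exhaustively in the tests); at the 10-read floor the nominal 5% level is
  held only approximately, which is why the floor exists.
* **Micro-clusters**: the source material lists near-adjacent candidate
  pairs without defining a rule; here a pair of imprinted genes with at
  most one intervening annotated gene or a gap of at most 20 kb counts as
  a micro-cluster.
* **Repeat proximity** uses a two-sided permutation test (default 10,000
  random same-size gene sets; median nearest-repeat distance and mean
  flank density, overall and per repeat class), as no specific statistic
  is prescribed for this comparison.
* **GO enrichment** is the upper-tail hypergeometric test against the
  expressed background (every transcript with at least 10 reads);
  Benjamini-Hochberg values are reported alongside, and likewise a BH
  column accompanies the per-feature calls as supplementary output - the
  calls themselves use the fixed per-feature 0.05 threshold.

## Problem sizes used in validation

The bundled validation uses deliberately desk-scale simulations: a
1,000-gene, 1.8 Mb recovery bundle (100 maternal, 100 paternal, 100
subspecies-biased, 700 biallelic loci at a fixed per-SNP depth of 50 per
cross, about 350,000 reads), 2,000-feature null panels at depth 100 for
type-I error, and a 70-gene bundle with 25 planted splicing loci. Genes
that receive no SNP under the genome-wide SNP rate are flagged untestable
and excluded from sensitivity denominators, mirroring the fact that only
genes profiled with SNPs can be assessed at all.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7)
bundle <- simulate_bundle(cfg)
res <- run_pipeline(bundle)
print(res)
recovery_stats(res)
```

## Known limitations

* The assigner expects colinear haplotypes (SNPs only); structural
  variation between real parental genomes would need a true aligner
  upstream, after which the count-level entry point
  (`read_counts_table()`) applies unchanged.
* Single libraries per cross mean biological variance is not separable
  from sampling variance; the chi-square treats reads as independent
  draws.
* The fixed 0.05 per-feature threshold, kept for fidelity to the source
  method, implies a known genome-wide false-positive budget; the
  supplementary BH column lets users apply FDR control if they prefer.
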