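# Hand-built genome pairs and small bundles used across the test files.

# deterministic random sequence
rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# genome pair from explicit haplotype strings; SNP table derived from the
# differences unless overridden (override lets tests break the invariant
# deliberately, e.g. an unreported difference)
make_genome_pair <- function(seq_a, seq_b, chrom = "chrT", snps = NULL) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  stopifnot(length(a) == length(b))
  if (is.null(snps)) {
    pos <- which(a != b)
    snps <- data.frame(chrom = rep(chrom, length(pos)), pos = pos,
                       allele_a = a[pos], allele_b = b[pos],
                       stringsAsFactors = FALSE)
  }
  structure(
    list(
      seq_a = Biostrings::DNAStringSet(stats::setNames(seq_a, chrom)),
      seq_b = Biostrings::DNAStringSet(stats::setNames(seq_b, chrom)),
      snps = snps,
      chrom_lengths = stats::setNames(length(a), chrom)
    ),
    class = "genome_pair"
  )
}

substitute_base <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# a small, quick endosperm bundle shared by several files
quick_bundle <- function(seed = 11, reads = TRUE, ...) {
  suppressWarnings(simulate_bundle(sim_config(seed = seed, ...), reads = reads))
}

# exact two-sided binomial oracle, central mid-P form: twice the smaller
# tail with half-weight on the observed outcome (the discreteness-corrected
# exact test that the large-sample chi-square approximates)
binom_midp <- function(m, tot, p) {
  lo <- pbinom(m - 1, tot, p) + 0.5 * dbinom(m, tot, p)
  hi <- pbinom(m, tot, p, lower.tail = FALSE) + 0.5 * dbinom(m, tot, p)
  pmin(1, 2 * pmin(lo, hi))
}

# exhaustive upper-tail hypergeometric by term-by-term enumeration
hyper_tail_enum <- function(k, K, N, n) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
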