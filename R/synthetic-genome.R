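#' Build a pair of parental genomes differing at planted SNPs
#'
#' Generates random chromosome sequences for subspecies A ("Nipponbare-like")
#' and derives the subspecies B ("93-11-like") haplotype by substituting a
#' different base at positions drawn uniformly at random at rate `snp_rate`.
#' The two haplotypes are colinear (equal length, no indels) and differ
#' exactly at the SNP positions. SNPs are not spaced apart, so reads covering
#' two SNPs do occur and exercise the single-SNP read filter.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length in bp (recycled across chromosomes);
#'   must be at least twice the read length you intend to simulate.
#' @param snp_rate per-base probability of a SNP, in (0, 0.1).
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `genome_pair`: list with `seq_a`, `seq_b`
#'   (named [Biostrings::DNAStringSet] of equal widths), `snps` (data.frame
#'   `chrom`, `pos` 1-based, `allele_a`, `allele_b`) and `chrom_lengths`
#'   (named integer vector).
#' @export
build_genome_pair <- function(n_chrom = 1L, chrom_len = 10000L,
                              snp_rate = 0.005, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(chrom_len < 100)) stop("chrom_len too small")
  if (snp_rate < 0 || snp_rate >= 0.1) stop("snp_rate must be in [0, 0.1)")
  chrom_len <- rep_len(as.integer(chrom_len), n_chrom)
  chroms <- sprintf("chr%02d", seq_len(n_chrom))
  bases <- c("A", "C", "G", "T")
  seq_a <- character(n_chrom)
  seq_b <- character(n_chrom)
  snps <- vector("list", n_chrom)
  for (i in seq_len(n_chrom)) {
    a <- sample(bases, chrom_len[i], replace = TRUE)
    pos <- which(stats::runif(chrom_len[i]) < snp_rate)
    b <- a
    if (length(pos)) {
      alt <- vapply(a[pos], function(ref) sample(setdiff(bases, ref), 1L), "")
      b[pos] <- alt
      snps[[i]] <- data.frame(
        chrom = chroms[i], pos = pos,
        allele_a = a[pos], allele_b = alt,
        stringsAsFactors = FALSE
      )
    } else {
      snps[[i]] <- data.frame(
        chrom = character(), pos = integer(),
        allele_a = character(), allele_b = character(),
        stringsAsFactors = FALSE
      )
    }
    seq_a[i] <- paste(a, collapse = "")
    seq_b[i] <- paste(b, collapse = "")
  }
  names(seq_a) <- names(seq_b) <- names(chrom_len) <- chroms
  structure(
    list(
      seq_a = Biostrings::DNAStringSet(seq_a),
      seq_b = Biostrings::DNAStringSet(seq_b),
      snps = do.call(rbind, snps),
      chrom_lengths = chrom_len
    ),
    class = "genome_pair"
  )
}

#' @export
print.genome_pair <- function(x, ...) {
  cat(sprintf(
    "genome_pair: %d chromosome(s), %s bp total, %d SNPs\n",
    length(x$chrom_lengths), format(sum(x$chrom_lengths), big.mark = ","),
    nrow(x$snps)
  ))
  invisible(x)
}

#' Simulate a gene annotation over a genome pair
#'
#' Lays genes down sequentially along each chromosome with a gene -> mRNA ->
#' exon hierarchy: each gene has 2-4 exons separated by introns, and genes
#' are separated by intergenic gaps. A configurable fraction of genes gets a
#' second transcript isoform that skips one internal exon, so isoform-level
#' analysis and identical-support collapsing are exercised.
#'
#' @param genomes a [build_genome_pair()] object.
#' @param n_genes maximum number of genes to place (placement stops when a
#'   chromosome runs out of room).
#' @param exon_len,intron_len,gap_len typical exon, intron and intergenic
#'   gap lengths in bp.
#' @param isoform_prob probability that a gene with >= 3 exons receives a
#'   second, exon-skipping isoform.
#' @return A [GenomicRanges::GRanges] (1-based, closed) with metadata
#'   columns `type` (`gene`/`mRNA`/`exon`), `ID`, `Parent` and `gene_id`.
#' @export
simulate_annotation <- function(genomes, n_genes = 50L, exon_len = 300L,
                                intron_len = 200L, gap_len = 400L,
                                isoform_prob = 0.2) {
  stopifnot(inherits(genomes, "genome_pair"))
  rows <- list()
  gid <- 0L
  for (ch in names(genomes$chrom_lengths)) {
    len <- genomes$chrom_lengths[[ch]]
    cursor <- gap_len
    while (gid < n_genes) {
      n_exons <- sample(2:4, 1L)
      e_len <- pmax(50L, as.integer(round(stats::rnorm(n_exons, exon_len, exon_len / 4))))
      i_len <- pmax(50L, as.integer(round(stats::rnorm(n_exons - 1L, intron_len, intron_len / 4))))
      g_len <- sum(e_len) + sum(i_len)
      if (cursor + g_len + gap_len > len) break
      gid <- gid + 1L
      gene_id <- sprintf("gene%04d", gid)
      e_start <- cursor + c(0L, cumsum(e_len[-n_exons] + i_len)) + 1L
      e_end <- e_start + e_len - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = e_start, end = e_end, type = "exon",
        ID = sprintf("%s.1.exon%d", gene_id, seq_len(n_exons)),
        Parent = sprintf("%s.1", gene_id), gene_id = gene_id,
        stringsAsFactors = FALSE
      )
      tx <- data.frame(
        chrom = ch, start = min(e_start), end = max(e_end), type = "mRNA",
        ID = sprintf("%s.1", gene_id), Parent = gene_id, gene_id = gene_id,
        stringsAsFactors = FALSE
      )
      gene <- data.frame(
        chrom = ch, start = min(e_start), end = max(e_end), type = "gene",
        ID = gene_id, Parent = NA_character_, gene_id = gene_id,
        stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1L]] <- tx
      rows[[length(rows) + 1L]] <- gene
      if (n_exons >= 3L && stats::runif(1) < isoform_prob) {
        skip <- sample(2:(n_exons - 1L), 1L)
        keep <- setdiff(seq_len(n_exons), skip)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = e_start[keep], end = e_end[keep], type = "exon",
          ID = sprintf("%s.2.exon%d", gene_id, seq_along(keep)),
          Parent = sprintf("%s.2", gene_id), gene_id = gene_id,
          stringsAsFactors = FALSE
        )
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = min(e_start), end = max(e_end), type = "mRNA",
          ID = sprintf("%s.2", gene_id), Parent = gene_id, gene_id = gene_id,
          stringsAsFactors = FALSE
        )
      }
      cursor <- max(e_end) + gap_len
    }
  }
  if (!length(rows)) stop("no genes could be placed; enlarge the genome")
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = "+",
    type = df$type, ID = df$ID, Parent = df$Parent, gene_id = df$gene_id
  )
  GenomeInfoDb::seqlengths(gr) <-
    genomes$chrom_lengths[GenomeInfoDb::seqlevels(gr)]
  sort(gr)
}

truth_classes <- c(
  "maternal_imprint", "paternal_imprint",
  "subspecies_a_bias", "subspecies_b_bias",
  "biallelic", "low_coverage", "poe_splicing"
)

#' Plant ground-truth expression classes on annotated genes
#'
#' Randomly assigns genes to truth classes (imprinted, subspecies-biased,
#' biallelic, low-coverage, or parent-of-origin splicing) and draws each
#' locus a mean per-SNP read depth from a log-normal, reproducing the
#' long-tailed depth distribution of real SNP-read data. Optionally plants
#' maternally-expressed transcripts in intergenic gaps.
#'
#' Parent-of-origin splicing loci follow the confirmed real-data pattern:
#' maternally favored intron reads and paternally favored exon reads.
#'
#' @param annotation a [simulate_annotation()] GRanges.
#' @param class_counts named integer vector over
#'   `r paste(truth_classes, collapse = ", ")`; classes omitted default to 0
#'   and remaining genes are biallelic only if `biallelic` is given.
#' @param bias_level favored-origin read fraction for biased classes,
#'   in (0.5, 1].
#' @param depth_median,depth_sdlog median and log-sd of the per-locus mean
#'   SNP read depth (per cross); `depth_sdlog = 0` gives fixed depth.
#' @param low_coverage_depth mean depth used for `low_coverage` loci.
#' @param n_intergenic_maternal number of additional maternally-imprinted
#'   transcripts planted in intergenic gaps.
#' @param seed optional integer seed.
#' @return data.frame of class `imprint_truth`: `feature_id`, `chrom`,
#'   `start`, `end` (1-based closed), `truth_class`, `bias_level`,
#'   `mean_depth`, `testable`.
#' @export
make_truth_loci <- function(annotation, class_counts, bias_level = 0.95,
                            depth_median = 35, depth_sdlog = 0.6,
                            low_coverage_depth = 1.5,
                            n_intergenic_maternal = 0L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bad <- setdiff(names(class_counts), truth_classes)
  if (length(bad)) stop("unknown truth class: ", paste(bad, collapse = ", "))
  if (bias_level < 0.5 || bias_level > 1) stop("bias_level must be in [0.5, 1]")
  genes <- annotation[annotation$type == "gene"]
  n_needed <- sum(class_counts)
  if (n_needed > length(genes)) stop("not enough genes for the requested classes")
  picked <- sample(seq_along(genes), n_needed)
  cls <- rep(names(class_counts), class_counts)
  g <- genes[picked]
  depth <- stats::rlnorm(n_needed, meanlog = log(depth_median), sdlog = depth_sdlog)
  depth[cls == "low_coverage"] <- low_coverage_depth
  truth <- data.frame(
    feature_id = g$gene_id,
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g),
    end = GenomicRanges::end(g),
    truth_class = cls,
    bias_level = ifelse(cls %in% c("biallelic", "low_coverage"), 0.5, bias_level),
    mean_depth = depth,
    testable = TRUE,
    stringsAsFactors = FALSE
  )
  if (n_intergenic_maternal > 0L) {
    gaps <- intergenic_gaps(annotation)
    gaps <- gaps[GenomicRanges::width(gaps) >= 700]
    if (length(gaps) < n_intergenic_maternal) {
      stop("not enough intergenic room for planted transcripts")
    }
    pick <- sample(seq_along(gaps), n_intergenic_maternal)
    ig <- gaps[pick]
    st <- GenomicRanges::start(ig) + 100L
    truth_ig <- data.frame(
      feature_id = sprintf("igtx%03d", seq_len(n_intergenic_maternal)),
      chrom = as.character(GenomicRanges::seqnames(ig)),
      start = st,
      end = st + 499L,
      truth_class = "maternal_imprint",
      bias_level = bias_level,
      mean_depth = stats::rlnorm(n_intergenic_maternal,
                                 log(depth_median), depth_sdlog),
      testable = TRUE,
      stringsAsFactors = FALSE
    )
    truth <- rbind(truth, truth_ig)
  }
  class(truth) <- c("imprint_truth", "data.frame")
  truth
}

# maximal intervals not covered by any annotated gene (1-based closed)
intergenic_gaps <- function(annotation) {
  genes <- annotation[annotation$type == "gene"]
  sl <- GenomeInfoDb::seqlengths(annotation)
  cov <- GenomicRanges::reduce(genes, ignore.strand = TRUE)
  gaps <- GenomicRanges::gaps(cov)
  gaps[GenomicRanges::strand(gaps) == "*" & !is.na(sl[as.character(GenomicRanges::seqnames(gaps))])]
}
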