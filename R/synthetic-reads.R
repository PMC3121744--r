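#' Simulation configuration for one reciprocal-cross experiment
#'
#' Collects the generator settings that define the simulated study: tissue
#' (which sets the expected maternal share: 2/3 endosperm, 1/2 embryo), read
#' length (36 for endosperm libraries, 75 for embryo libraries), adaptor
#' contamination, and the genome/annotation/truth sizes used by
#' [simulate_bundle()]. One read library is generated per cross per tissue,
#' with no replicates, matching the single-library reciprocal-cross design.
#'
#' @inheritParams maternal_fraction
#' @param read_length simulated read length; defaults to 36 (endosperm) or
#'   75 (embryo).
#' @param adaptor 3' adaptor appended to contaminated reads.
#' @param adaptor_frac fraction of reads carrying an adaptor suffix.
#' @param overdispersion beta-binomial overdispersion rho in \[0, 1) for
#'   allelic sampling; 0 (default) is plain binomial.
#' @param n_chrom,chrom_len,snp_rate genome settings, see
#'   [build_genome_pair()].
#' @param n_genes,isoform_prob annotation settings, see
#'   [simulate_annotation()].
#' @param class_counts,bias_level,depth_median,depth_sdlog,n_intergenic_maternal
#'   truth settings, see [make_truth_loci()].
#' @param seed integer seed fixing the whole bundle.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(tissue = c("endosperm", "embryo"),
                       read_length = NULL,
                       adaptor = "AGATCGGAAGAGC", adaptor_frac = 0.05,
                       overdispersion = 0,
                       n_chrom = 2L, chrom_len = 60000L, snp_rate = 0.004,
                       n_genes = 40L, isoform_prob = 0.2,
                       class_counts = c(maternal_imprint = 4L,
                                        paternal_imprint = 4L,
                                        subspecies_a_bias = 2L,
                                        subspecies_b_bias = 2L,
                                        biallelic = 24L,
                                        low_coverage = 2L),
                       bias_level = 0.95,
                       depth_median = 35, depth_sdlog = 0.6,
                       n_intergenic_maternal = 0L,
                       seed = 1L) {
  tissue <- match.arg(tissue)
  if (is.null(read_length)) {
    read_length <- if (tissue == "endosperm") 36L else 75L
  }
  if (overdispersion < 0 || overdispersion >= 1) {
    stop("overdispersion must be in [0, 1)")
  }
  structure(
    list(
      tissue = tissue, read_length = as.integer(read_length),
      adaptor = adaptor, adaptor_frac = adaptor_frac,
      overdispersion = overdispersion,
      n_chrom = n_chrom, chrom_len = chrom_len, snp_rate = snp_rate,
      n_genes = n_genes, isoform_prob = isoform_prob,
      class_counts = class_counts, bias_level = bias_level,
      depth_median = depth_median, depth_sdlog = depth_sdlog,
      n_intergenic_maternal = n_intergenic_maternal,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Per-SNP sampling plan for one tissue: which SNPs belong to which truth
# locus, the per-read maternal probability in each cross direction, and the
# per-SNP mean depth. poe_splicing loci get maternally favored intron SNPs
# and paternally favored exon SNPs.
locus_snp_plan <- function(genomes, annotation, truth, tissue) {
  snps <- genomes$snps
  if (is.null(snps) || !nrow(snps)) stop("genome pair has no SNPs")
  snp_gr <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
  exons <- annotation[annotation$type == "exon"]
  base <- maternal_fraction(tissue)
  genic <- truth$feature_id %in% exons$gene_id

  # SNP/locus pairs within the locus spans
  span <- GenomicRanges::GRanges(truth$chrom, IRanges::IRanges(truth$start, truth$end))
  hit <- GenomicRanges::findOverlaps(snp_gr, span)
  si <- S4Vectors::queryHits(hit)   # SNP index
  ti <- S4Vectors::subjectHits(hit) # truth row

  # which of those SNPs lie in an exon of that locus's own gene
  ex_union <- GenomicRanges::reduce(
    S4Vectors::split(GenomicRanges::granges(exons), exons$gene_id)
  )
  exh <- GenomicRanges::findOverlaps(snp_gr, ex_union)
  ex_pair <- paste(S4Vectors::queryHits(exh),
                   names(ex_union)[S4Vectors::subjectHits(exh)])
  in_exon <- paste(si, truth$feature_id[ti]) %in% ex_pair
  # genic loci use exonic SNPs only, except poe_splicing which also uses
  # intronic SNPs; intergenic transcripts use every SNP in their span
  cls <- truth$truth_class[ti]
  sub <- ifelse(genic[ti] & !in_exon, "intron", "exon")
  keep <- !genic[ti] | in_exon | cls == "poe_splicing"
  si <- si[keep]; ti <- ti[keep]; cls <- cls[keep]; sub <- sub[keep]

  b <- truth$bias_level[ti]
  p_mat_a <- ifelse(cls == "maternal_imprint", b,
             ifelse(cls == "paternal_imprint", 1 - b,
             ifelse(cls == "subspecies_a_bias", b,        # allele A maternal here
             ifelse(cls == "subspecies_b_bias", 1 - b,
             ifelse(cls == "poe_splicing", ifelse(sub == "intron", b, 1 - b),
                    base)))))
  p_mat_b <- ifelse(cls == "maternal_imprint", b,
             ifelse(cls == "paternal_imprint", 1 - b,
             ifelse(cls == "subspecies_a_bias", 1 - b,    # allele A now paternal
             ifelse(cls == "subspecies_b_bias", b,
             ifelse(cls == "poe_splicing", ifelse(sub == "intron", b, 1 - b),
                    base)))))
  plan <- data.frame(
    feature_id = truth$feature_id[ti], truth_class = cls,
    chrom = snps$chrom[si], pos = snps$pos[si], sub_feature = sub,
    p_mat_a = p_mat_a, p_mat_b = p_mat_b,
    mean_depth = truth$mean_depth[ti],
    stringsAsFactors = FALSE
  )
  # untestable: no SNP at all, or a poe locus missing either sub-feature
  has_rows <- truth$feature_id %in% plan$feature_id
  poe_ok <- vapply(seq_len(nrow(truth)), function(i) {
    if (truth$truth_class[i] != "poe_splicing") return(TRUE)
    p <- plan$sub_feature[plan$feature_id == truth$feature_id[i]]
    any(p == "exon") && any(p == "intron")
  }, logical(1))
  untestable <- truth$feature_id[!has_rows | !poe_ok]
  plan <- plan[!plan$feature_id %in% untestable, , drop = FALSE]
  if (length(untestable)) {
    warning("truth loci with no usable SNP marked untestable: ",
            paste(untestable, collapse = ", "))
  }
  list(plan = plan, untestable = untestable)
}

# allelic sampling: binomial, or beta-binomial when rho > 0
r_allelic <- function(n, size, prob, rho = 0) {
  if (rho <= 0) return(stats::rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  stats::rbinom(n, size, stats::rbeta(n, a, b))
}

#' Simulate one cross's SNP read library
#'
#' Draws, for every SNP of every testable truth locus, a Poisson read depth
#' around the locus mean and assigns each read a parental origin by a
#' Bernoulli draw whose maternal probability encodes the locus truth class
#' (oriented by parent for imprint classes, by allele for subspecies
#' classes, and equal to the tissue baseline for biallelic loci). Reads are
#' exact substrings of the originating haplotype covering the SNP, on a
#' random strand, with an optional 3' adaptor suffix on a configurable
#' fraction to exercise preprocessing.
#'
#' @param genomes a [build_genome_pair()] object.
#' @param annotation a [simulate_annotation()] GRanges.
#' @param truth a [make_truth_loci()] data.frame.
#' @param config a [sim_config()].
#' @param cross_direction `"A_mother"` (subspecies A as seed parent) or
#'   `"B_mother"`.
#' @return list with `reads` (named character vector), `read_info`
#'   (data.frame `id`, `feature_id`, `chrom`, `pos`, `origin`, `allele`,
#'   `adaptor` flag: the simulator's oracle labels), `expected` (per-locus
#'   expected maternal/paternal read counts) and `untestable` (feature ids
#'   with no usable SNP).
#' @export
simulate_cross_reads <- function(genomes, annotation, truth, config,
                                 cross_direction = c("A_mother", "B_mother")) {
  cross_direction <- match.arg(cross_direction)
  stopifnot(inherits(config, "sim_config"))
  lp <- locus_snp_plan(genomes, annotation, truth, config$tissue)
  plan <- lp$plan
  if (is.null(plan) || !nrow(plan)) stop("no testable loci in truth table")
  L <- config$read_length
  p_mat <- if (cross_direction == "A_mother") plan$p_mat_a else plan$p_mat_b
  mat_allele <- if (cross_direction == "A_mother") "A" else "B"
  chr_a <- as.character(genomes$seq_a)
  chr_b <- as.character(genomes$seq_b)
  depth <- stats::rpois(nrow(plan), plan$mean_depth)
  n_mat <- r_allelic(nrow(plan), depth, p_mat, config$overdispersion)

  out_seq <- vector("list", nrow(plan))
  out_off <- vector("list", nrow(plan))
  out_info <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    d <- depth[i]
    if (d == 0L) next
    ch <- plan$chrom[i]
    pos <- plan$pos[i]
    clen <- genomes$chrom_lengths[[ch]]
    origin <- rep(c("maternal", "paternal"), c(n_mat[i], d - n_mat[i]))
    allele <- ifelse((origin == "maternal") == (mat_allele == "A"), "A", "B")
    lo <- max(1L, pos - L + 1L)
    hi <- min(pos, clen - L + 1L)
    starts <- if (hi >= lo) sample(lo:hi, d, replace = TRUE) else rep(lo, d)
    hap <- ifelse(allele == "A", chr_a[ch], chr_b[ch])
    out_seq[[i]] <- substr(hap, starts, starts + L - 1L)
    out_off[[i]] <- pos - starts + 1L # SNP offset on the plus strand
    out_info[[i]] <- data.frame(
      feature_id = plan$feature_id[i], chrom = ch, pos = pos,
      origin = origin, allele = allele,
      stringsAsFactors = FALSE
    )
  }
  info <- do.call(rbind, out_info)
  reads <- unlist(out_seq)
  off <- unlist(out_off)
  nr <- length(reads)
  # random strand: half the reads are reported as reverse-complement
  rc <- stats::runif(nr) < 0.5
  if (any(rc)) {
    reads[rc] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[rc])
    ))
    off[rc] <- L - off[rc] + 1L # SNP offset within the reported read
  }
  # 3' adaptor read-through on a fraction of reads: the last k bases are
  # adaptor, so the genomic part shortens; only applied when the SNP stays
  # inside the genomic prefix
  adp <- stats::runif(nr) < config$adaptor_frac
  if (any(adp)) {
    k <- sample(5:min(12L, nchar(config$adaptor)), sum(adp), replace = TRUE)
    ok <- off[adp] <= L - k
    w <- which(adp)[ok]
    kk <- k[ok]
    if (length(w)) {
      reads[w] <- paste0(substr(reads[w], 1L, L - kk),
                         substr(config$adaptor, 1L, kk))
    }
    adp[] <- FALSE
    adp[w] <- TRUE
  }
  info$adaptor <- adp
  ids <- sprintf("%s_r%07d", cross_direction, seq_along(reads))
  names(reads) <- ids
  info <- cbind(id = ids, info, stringsAsFactors = FALSE)
  agg <- rowsum(cbind(depth, depth * p_mat), plan$feature_id)
  expected <- data.frame(
    feature_id = rownames(agg),
    expected_total = agg[, 1], expected_mat = agg[, 2],
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(reads = reads, read_info = info, expected = expected,
       untestable = lp$untestable)
}

#' Simulate per-SNP allelic count tables directly (no read strings)
#'
#' Count-level counterpart of [simulate_cross_reads()]: draws the same
#' per-SNP depths and allelic splits but emits the aggregated per-SNP
#' maternal/paternal counts for one cross, bypassing read generation and
#' assignment. Useful for fast statistical validation of the downstream
#' scan machinery.
#'
#' @inheritParams simulate_cross_reads
#' @return data.frame `chrom`, `pos`, `r_mat_raw`, `r_pat_raw` with
#'   attributes `cross_direction` and `tissue`.
#' @export
simulate_allelic_counts <- function(genomes, annotation, truth, config,
                                    cross_direction = c("A_mother", "B_mother")) {
  cross_direction <- match.arg(cross_direction)
  stopifnot(inherits(config, "sim_config"))
  plan <- locus_snp_plan(genomes, annotation, truth, config$tissue)$plan
  if (is.null(plan) || !nrow(plan)) stop("no testable loci in truth table")
  p_mat <- if (cross_direction == "A_mother") plan$p_mat_a else plan$p_mat_b
  depth <- stats::rpois(nrow(plan), plan$mean_depth)
  n_mat <- r_allelic(nrow(plan), depth, p_mat, config$overdispersion)
  out <- data.frame(
    chrom = plan$chrom, pos = plan$pos,
    r_mat_raw = n_mat, r_pat_raw = depth - n_mat,
    stringsAsFactors = FALSE
  )
  out <- out[out$r_mat_raw + out$r_pat_raw > 0, , drop = FALSE]
  attr(out, "cross_direction") <- cross_direction
  attr(out, "tissue") <- config$tissue
  out
}

#' Simulate a complete reciprocal-cross bundle
#'
#' Builds the genome pair, annotation and planted truth from a
#' [sim_config()], then simulates both reciprocal read libraries
#' (`A_mother` and `B_mother`). The seed in the config fixes the whole
#' bundle: the same config yields byte-identical output.
#'
#' @param config a [sim_config()].
#' @param reads if `FALSE`, emit count tables (`simulate_allelic_counts()`)
#'   instead of read libraries.
#' @return list of class `sim_bundle` with `genomes`, `annotation`, `truth`,
#'   `config`, and either `reads`/`read_info`/`expected` or `counts`, each a
#'   list with `A_mother` and `B_mother` entries.
#' @export
simulate_bundle <- function(config = sim_config(), reads = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genomes <- build_genome_pair(config$n_chrom, config$chrom_len,
                               config$snp_rate)
  annotation <- simulate_annotation(genomes, n_genes = config$n_genes,
                                    isoform_prob = config$isoform_prob)
  truth <- make_truth_loci(
    annotation, config$class_counts,
    bias_level = config$bias_level,
    depth_median = config$depth_median, depth_sdlog = config$depth_sdlog,
    n_intergenic_maternal = config$n_intergenic_maternal
  )
  out <- list(genomes = genomes, annotation = annotation, truth = truth,
              config = config)
  if (reads) {
    a <- simulate_cross_reads(genomes, annotation, truth, config, "A_mother")
    b <- simulate_cross_reads(genomes, annotation, truth, config, "B_mother")
    out$reads <- list(A_mother = a$reads, B_mother = b$reads)
    out$read_info <- list(A_mother = a$read_info, B_mother = b$read_info)
    out$expected <- list(A_mother = a$expected, B_mother = b$expected)
    out$truth$testable[out$truth$feature_id %in%
                         c(a$untestable, b$untestable)] <- FALSE
  } else {
    out$counts <- list(
      A_mother = simulate_allelic_counts(genomes, annotation, truth, config,
                                         "A_mother"),
      B_mother = simulate_allelic_counts(genomes, annotation, truth, config,
                                         "B_mother")
    )
  }
  class(out) <- "sim_bundle"
  out
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(
    "sim_bundle (%s): %d chrom, %d SNPs, %d genes, %d truth loci\n",
    x$config$tissue, length(x$genomes$chrom_lengths), nrow(x$genomes$snps),
    sum(x$annotation$type == "gene"), nrow(x$truth)
  ))
  if (!is.null(x$reads)) {
    cat(sprintf("  reads: A_mother %d, B_mother %d\n",
                length(x$reads$A_mother), length(x$reads$B_mother)))
  }
  invisible(x)
}
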