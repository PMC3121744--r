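#' Read and write SNP tables
#'
#' The SNP table is a four-column TSV (`chrom`, `pos`, `allele_a`,
#' `allele_b`) with 1-based positions; it is the coordinate backbone for
#' allelic assignment.
#'
#' @param path file path.
#' @return `read_snp_table()` returns the data.frame; writers return the
#'   path invisibly.
#' @export
read_snp_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "allele_a", "allele_b")
  if (!all(need %in% names(df))) {
    stop("SNP table must have columns ", paste(need, collapse = ", "))
  }
  validate_snp_table(df)
  df
}

#' @param snps SNP data.frame as above.
#' @rdname read_snp_table
#' @export
write_snp_table <- function(snps, path) {
  utils::write.table(snps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_snp_table <- function(snps) {
  if (any(duplicated(paste(snps$chrom, snps$pos)))) {
    stop("duplicate SNP positions")
  }
  if (any(snps$allele_a == snps$allele_b)) {
    stop("SNP alleles must differ")
  }
  invisible(snps)
}

#' Minimal VCF 4.2 export and import of the SNP table
#'
#' Writes the SNP table as a minimal 8-column VCF (allele A as REF, allele
#' B as ALT) and reads such files back, keeping only what the pipeline
#' uses: chromosome, 1-based position and the two alleles.
#'
#' @param snps SNP data.frame (`chrom`, `pos`, `allele_a`, `allele_b`).
#' @param path file path.
#' @return `read_vcf_minimal()` returns a SNP data.frame; the writer
#'   returns the path invisibly.
#' @export
write_vcf_minimal <- function(snps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=imprintscan",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(snps)) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                       snps$chrom, snps$pos, snps$allele_a, snps$allele_b),
               con)
  }
  invisible(path)
}

#' @rdname write_vcf_minimal
#' @export
read_vcf_minimal <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(data.frame(chrom = character(), pos = integer(),
                      allele_a = character(), allele_b = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  if (ncol(parts) < 5) stop("malformed VCF record")
  data.frame(
    chrom = parts[, 1], pos = as.integer(parts[, 2]),
    allele_a = parts[, 4], allele_b = parts[, 5],
    stringsAsFactors = FALSE
  )
}

#' Read a pre-assigned per-SNP allelic count table
#'
#' Count-level entry point for users starting from their own aligner: a TSV
#' with columns `chrom`, `pos`, `cross` (`A_mother`/`B_mother`),
#' `r_mat_raw`, `r_pat_raw`.
#'
#' @param path file path.
#' @return list of count data.frames named `A_mother` and `B_mother`.
#' @export
read_counts_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "cross", "r_mat_raw", "r_pat_raw")
  if (!all(need %in% names(df))) {
    stop("counts table must have columns ", paste(need, collapse = ", "))
  }
  lapply(c(A_mother = "A_mother", B_mother = "B_mother"), function(cr) {
    x <- df[df$cross == cr, c("chrom", "pos", "r_mat_raw", "r_pat_raw")]
    rownames(x) <- NULL
    attr(x, "cross_direction") <- cr
    x
  })
}

#' @param counts list of per-cross count tables.
#' @rdname read_counts_table
#' @export
write_counts_table <- function(counts, path) {
  df <- do.call(rbind, lapply(names(counts), function(cr) {
    x <- counts[[cr]]
    data.frame(chrom = x$chrom, pos = x$pos, cross = cr,
               r_mat_raw = x$r_mat_raw, r_pat_raw = x$r_pat_raw,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write significant windows as BED
#'
#' BED uses 0-based half-open coordinates, which is also the convention of
#' [tile_windows()] output, so spans are written as-is with the call and
#' the combined `-log10 P` as name and score.
#'
#' @param windows a [window_scan()] result (or any data.frame with `chrom`,
#'   `start`, `end`, optionally `call` and `neglog10p`).
#' @param path file path.
#' @export
write_bed_windows <- function(windows, path) {
  name <- if (!is.null(windows$call)) as.character(windows$call) else "."
  score <- if (!is.null(windows$neglog10p)) {
    ifelse(is.na(windows$neglog10p), 0, round(windows$neglog10p, 2))
  } else 0
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", windows$chrom,
                   as.integer(windows$start), as.integer(windows$end),
                   name, format(score, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated bundle to disk
#'
#' Emits the complete fixture bundle as plain-text files: the two parental
#' genome FASTAs, the SNP table (TSV and minimal VCF), the GFF3 annotation,
#' one read FASTA (or FASTQ with dummy qualities) per cross, and the truth
#' table. The bundle is re-readable losslessly with [read_bundle()].
#'
#' @param bundle a [simulate_bundle()] object.
#' @param dir output directory (created if needed).
#' @param fastq write reads as FASTQ with constant quality "I" instead of
#'   FASTA.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, fastq = FALSE) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(bundle$genomes$seq_a, file.path(dir, "genome_a.fasta"))
  Biostrings::writeXStringSet(bundle$genomes$seq_b, file.path(dir, "genome_b.fasta"))
  write_snp_table(bundle$genomes$snps, file.path(dir, "snps.tsv"))
  write_vcf_minimal(bundle$genomes$snps, file.path(dir, "snps.vcf"))
  export_annotation_gff3(bundle$annotation, file.path(dir, "annotation.gff3"))
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$reads)) {
    for (cr in names(bundle$reads)) {
      r <- Biostrings::DNAStringSet(bundle$reads[[cr]])
      if (fastq) {
        Biostrings::writeXStringSet(
          r, file.path(dir, sprintf("reads_%s.fastq", cr)), format = "fastq",
          qualities = Biostrings::BStringSet(strrep("I", Biostrings::width(r)))
        )
      } else {
        Biostrings::writeXStringSet(r, file.path(dir, sprintf("reads_%s.fasta", cr)))
      }
    }
  }
  if (!is.null(bundle$counts)) {
    write_counts_table(bundle$counts, file.path(dir, "counts.tsv"))
  }
  cfg <- bundle$config
  cfg$class_counts <- as.list(cfg$class_counts)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a bundle directory back
#'
#' @param dir a directory written by [write_bundle()].
#' @return a list shaped like a [simulate_bundle()] result (class
#'   `sim_bundle`).
#' @export
read_bundle <- function(dir) {
  seq_a <- Biostrings::readDNAStringSet(file.path(dir, "genome_a.fasta"))
  seq_b <- Biostrings::readDNAStringSet(file.path(dir, "genome_b.fasta"))
  names(seq_a) <- sub("\\s.*", "", names(seq_a))
  names(seq_b) <- sub("\\s.*", "", names(seq_b))
  genomes <- structure(
    list(seq_a = seq_a, seq_b = seq_b,
         snps = read_snp_table(file.path(dir, "snps.tsv")),
         chrom_lengths = stats::setNames(Biostrings::width(seq_a), names(seq_a))),
    class = "genome_pair"
  )
  annotation <- import_annotation_gff3(file.path(dir, "annotation.gff3"),
                                       genomes$chrom_lengths)
  truth <- utils::read.delim(file.path(dir, "truth.tsv"),
                             stringsAsFactors = FALSE)
  class(truth) <- c("imprint_truth", "data.frame")
  out <- list(genomes = genomes, annotation = annotation, truth = truth)
  cfg_path <- file.path(dir, "config.json")
  if (file.exists(cfg_path)) {
    cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    cfg$class_counts <- unlist(cfg$class_counts)
    class(cfg) <- "sim_config"
    out$config <- cfg
  }
  reads <- list()
  for (cr in c("A_mother", "B_mother")) {
    fa <- file.path(dir, sprintf("reads_%s.fasta", cr))
    fq <- file.path(dir, sprintf("reads_%s.fastq", cr))
    if (file.exists(fa)) {
      r <- Biostrings::readDNAStringSet(fa)
    } else if (file.exists(fq)) {
      r <- Biostrings::readDNAStringSet(fq, format = "fastq")
    } else {
      next
    }
    reads[[cr]] <- stats::setNames(as.character(r), sub("\\s.*", "", names(r)))
  }
  if (length(reads)) out$reads <- reads
  cnt_path <- file.path(dir, "counts.tsv")
  if (file.exists(cnt_path)) out$counts <- read_counts_table(cnt_path)
  class(out) <- "sim_bundle"
  out
}

# GFF3 round-trip via rtracklayer; gene -> mRNA -> exon hierarchy with
# ID/Parent links is preserved.
export_annotation_gff3 <- function(annotation, path) {
  gr <- annotation
  gr$Parent <- ifelse(is.na(gr$Parent), "", gr$Parent)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

import_annotation_gff3 <- function(path, chrom_lengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  parent <- as.character(S4Vectors::mcols(gr)$Parent)
  parent[parent == "" | parent == "character(0)"] <- NA_character_
  type <- as.character(gr$type)
  id <- as.character(gr$ID)
  # recover gene_id through the Parent chain if absent
  gene_id <- if (!is.null(gr$gene_id)) as.character(gr$gene_id) else {
    g <- ifelse(type == "gene", id, parent)
    tx2gene <- stats::setNames(parent[type == "mRNA"], id[type == "mRNA"])
    ex <- type == "exon"
    g[ex] <- tx2gene[g[ex]]
    g
  }
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr), IRanges::ranges(gr), strand = GenomicRanges::strand(gr),
    type = type, ID = id, Parent = parent, gene_id = gene_id
  )
  if (!is.null(chrom_lengths)) {
    GenomeInfoDb::seqlengths(out) <-
      chrom_lengths[GenomeInfoDb::seqlevels(out)]
  }
  sort(out)
}
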