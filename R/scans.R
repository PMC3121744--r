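#' Tile a genome into overlapping 1 kb windows every 0.5 kb
#'
#' Window starts advance by `step` from 0; each window extends `width` bases
#' or to the chromosome end. A trailing window of `step` bases or fewer is
#' dropped because it is wholly contained in the previous window, so no
#' unshareable sliver is ever tested. Coordinates are 0-based half-open
#' (BED convention); every interior position falls in exactly two windows.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param width,step window width and step in bp (defaults 1000 and 500).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open).
#' @examples
#' tile_windows(c(chr1 = 3000)) # 5 windows starting 0, 500, ..., 2000
#' @export
tile_windows <- function(chrom_lengths, width = 1000L, step = 500L) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths >= 1))
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0L, len - 1L, by = step)
    ends <- pmin(starts + width, len)
    w <- ends - starts
    if (length(starts) > 1L && w[length(w)] <= step) {
      starts <- starts[-length(starts)]
      ends <- ends[-length(ends)]
    }
    data.frame(chrom = ch, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

windows_to_gr <- function(windows) {
  GenomicRanges::GRanges(windows$chrom,
                         IRanges::IRanges(windows$start + 1L, windows$end))
}

snp_gr_from_counts <- function(counts) {
  GenomicRanges::GRanges(counts$chrom, IRanges::IRanges(counts$pos, counts$pos))
}

# sum a per-SNP column into bins defined by hits (query = SNPs, subject = bins)
sum_by_bin <- function(hits, values, n_bins) {
  v <- numeric(n_bins)
  if (length(S4Vectors::queryHits(hits))) {
    s <- rowsum(values[S4Vectors::queryHits(hits)], S4Vectors::subjectHits(hits))
    v[as.integer(rownames(s))] <- s[, 1]
  }
  v
}

#' Scan 1 kb windows for parental expression bias
#'
#' Sums normalized per-SNP counts into overlapping windows (a read counts in
#' a window when its SNP position falls inside it) and classifies every
#' window with [imprint_calls()]. Windows with fewer than `min_reads`
#' normalized reads in either cross are `low_coverage` and not tested.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param counts normalized count tables for both crosses, as returned by
#'   [normalize_between_crosses()] (list `A_mother`, `B_mother` with columns
#'   `r_mat`, `r_pat`).
#' @inheritParams imprint_calls
#' @param width,step see [tile_windows()].
#' @return data.frame of windows with summed counts, per-cross statistics
#'   and the `call` column.
#' @export
window_scan <- function(chrom_lengths, counts,
                        tissue = c("endosperm", "embryo"),
                        min_reads = 10, threshold = 1.3,
                        width = 1000L, step = 500L) {
  tissue <- match.arg(tissue)
  win <- tile_windows(chrom_lengths, width = width, step = step)
  wgr <- windows_to_gr(win)
  sums <- lapply(counts[c("A_mother", "B_mother")], function(x) {
    h <- GenomicRanges::findOverlaps(snp_gr_from_counts(x), wgr)
    list(mat = sum_by_bin(h, x$r_mat, length(wgr)),
         pat = sum_by_bin(h, x$r_pat, length(wgr)))
  })
  calls <- imprint_calls(
    sums$A_mother$mat, sums$A_mother$pat,
    sums$B_mother$mat, sums$B_mother$pat,
    tissue = tissue, min_reads = min_reads, threshold = threshold
  )
  add_bh_column(cbind(win, calls))
}

significant_calls <- c("maternal_imprint", "paternal_imprint")

#' Build the annotated feature units for the feature-level scan
#'
#' Units are: every transcript isoform (its exon set), the exon-union and
#' intron complement of every gene, and intergenic intervals (maximal
#' inter-annotation gaps, split at `intergenic_split` bp for reporting).
#'
#' @param annotation annotation GRanges (`type` gene/mRNA/exon, `gene_id`,
#'   `ID`, `Parent`).
#' @param intergenic_split maximum reported intergenic unit size (default
#'   10 kb).
#' @return list with `grl` ([GenomicRanges::GRangesList] of unit intervals)
#'   and `meta` (data.frame `unit_id`, `kind`, `gene_id`).
#' @export
build_feature_units <- function(annotation, intergenic_split = 10000L) {
  exons <- annotation[annotation$type == "exon"]
  tx_grl <- S4Vectors::split(GenomicRanges::granges(exons), exons$Parent)
  tx_gene <- vapply(S4Vectors::split(exons$gene_id, exons$Parent),
                    function(g) g[[1]], "")
  gene_ex <- GenomicRanges::reduce(
    S4Vectors::split(GenomicRanges::granges(exons), exons$gene_id)
  )
  gene_span <- unlist(range(gene_ex))
  introns <- GenomicRanges::psetdiff(gene_span, gene_ex[names(gene_span)])
  introns <- introns[S4Vectors::elementNROWS(introns) > 0]
  ig <- intergenic_gaps(annotation)
  ig_chunks <- GenomicRanges::GRangesList()
  if (length(ig)) {
    chunks <- unlist(GenomicRanges::tile(ig, width = intergenic_split))
    ig_chunks <- S4Vectors::split(chunks, seq_along(chunks))
  }
  grl <- c(tx_grl, gene_ex, introns, ig_chunks)
  meta <- data.frame(
    unit_id = c(names(tx_grl),
                paste0(names(gene_ex), ":exons"),
                paste0(names(introns), ":introns"),
                if (length(ig_chunks)) sprintf("intergenic%04d", seq_along(ig_chunks)) else character()),
    kind = c(rep("cdna_isoform", length(tx_grl)),
             rep("exon_union", length(gene_ex)),
             rep("intron", length(introns)),
             rep("intergenic", length(ig_chunks))),
    gene_id = c(unname(tx_gene[names(tx_grl)]),
                names(gene_ex), names(introns),
                rep(NA_character_, length(ig_chunks))),
    stringsAsFactors = FALSE
  )
  names(grl) <- meta$unit_id
  list(grl = grl, meta = meta)
}

# exon > intron > intergenic precedence for each SNP (conservation partition)
partition_snps <- function(snp_gr, units) {
  kinds <- units$meta$kind
  in_exon <- IRanges::overlapsAny(
    snp_gr, unlist(units$grl[kinds == "exon_union"])
  )
  in_intron <- IRanges::overlapsAny(
    snp_gr, unlist(units$grl[kinds == "intron"])
  )
  cls <- rep("intergenic", length(snp_gr))
  cls[in_intron] <- "intron"
  cls[in_exon] <- "exon"
  cls
}

#' Feature-level scan: isoforms, introns and intergenic regions
#'
#' Allocates normalized per-SNP counts to annotated feature units and
#' classifies each unit with [imprint_calls()]. A SNP contributes to every
#' transcript isoform whose exons contain it, and - for conservation
#' accounting - to exactly one of the partition classes exon-union, intron
#' or intergenic (precedence in that order when annotations are nested), so
#' the partition totals equal the total SNP reads exactly. Isoforms of one
#' gene with identical per-SNP support are collapsed into one compound
#' record.
#'
#' @inheritParams window_scan
#' @param annotation annotation GRanges.
#' @param intergenic_split see [build_feature_units()].
#' @return data.frame with `unit_id`, `kind`, `gene_id`, span (`chrom`,
#'   `start`, `end`, 1-based), `n_snps`, `compound` flag, counts, per-cross
#'   statistics and `call`; attribute `conservation` holds the partition
#'   totals per cross.
#' @export
feature_scan <- function(annotation, counts,
                         tissue = c("endosperm", "embryo"),
                         min_reads = 10, threshold = 1.3,
                         intergenic_split = 10000L) {
  tissue <- match.arg(tissue)
  units <- build_feature_units(annotation, intergenic_split)
  kinds <- units$meta$kind
  n_units <- nrow(units$meta)

  per_cross <- lapply(counts[c("A_mother", "B_mother")], function(x) {
    sg <- snp_gr_from_counts(x)
    cls <- partition_snps(sg, units)
    mat <- numeric(n_units)
    pat <- numeric(n_units)
    h <- GenomicRanges::findOverlaps(sg, units$grl)
    q <- S4Vectors::queryHits(h)
    s <- S4Vectors::subjectHits(h)
    # partition precedence: intron/intergenic units only take SNPs of their
    # own class; isoform and exon-union units take exonic SNPs they contain
    keep <- (kinds[s] %in% c("cdna_isoform", "exon_union") & cls[q] == "exon") |
      (kinds[s] == "intron" & cls[q] == "intron") |
      (kinds[s] == "intergenic" & cls[q] == "intergenic")
    h2 <- h[keep]
    list(
      mat = sum_by_bin(h2, x$r_mat, n_units),
      pat = sum_by_bin(h2, x$r_pat, n_units),
      hits = h2, cls = cls, x = x
    )
  })

  calls <- imprint_calls(
    per_cross$A_mother$mat, per_cross$A_mother$pat,
    per_cross$B_mother$mat, per_cross$B_mother$pat,
    tissue = tissue, min_reads = min_reads, threshold = threshold
  )
  span <- unlist(range(units$grl))
  n_snps <- vapply(c("A_mother", "B_mother"), function(nm) {
    tabulate(S4Vectors::subjectHits(per_cross[[nm]]$hits), n_units)
  }, integer(n_units))
  res <- cbind(
    units$meta,
    data.frame(
      chrom = as.character(GenomicRanges::seqnames(span)),
      start = GenomicRanges::start(span), end = GenomicRanges::end(span),
      n_snps = pmax(n_snps[, 1], n_snps[, 2]),
      compound = FALSE, stringsAsFactors = FALSE
    ),
    calls
  )

  # collapse isoforms of a gene with identical per-SNP support everywhere
  res <- collapse_identical_isoforms(res, per_cross)
  res <- add_bh_column(res)

  conservation <- lapply(per_cross, function(pc) {
    tot <- pc$x$r_mat + pc$x$r_pat
    c(exon = sum(tot[pc$cls == "exon"]),
      intron = sum(tot[pc$cls == "intron"]),
      intergenic = sum(tot[pc$cls == "intergenic"]),
      total = sum(tot))
  })
  attr(res, "conservation") <- conservation
  attr(res, "tissue") <- tissue
  res
}

collapse_identical_isoforms <- function(res, per_cross) {
  iso <- which(res$kind == "cdna_isoform")
  if (length(iso) < 2L) return(res)
  sig <- vapply(iso, function(i) {
    parts <- vapply(c("A_mother", "B_mother"), function(nm) {
      pc <- per_cross[[nm]]
      q <- S4Vectors::queryHits(pc$hits)[S4Vectors::subjectHits(pc$hits) == i]
      paste(sprintf("%s:%d:%d:%d", pc$x$chrom[q], pc$x$pos[q],
                    pc$x$r_mat[q], pc$x$r_pat[q]), collapse = ",")
    }, "")
    paste(parts, collapse = "|")
  }, "")
  grp <- paste(res$gene_id[iso], sig)
  drop <- integer()
  for (g in unique(grp[duplicated(grp)])) {
    members <- iso[grp == g]
    keep <- members[1L]
    res$unit_id[keep] <- paste(res$unit_id[members], collapse = ";")
    res$compound[keep] <- TRUE
    drop <- c(drop, members[-1L])
  }
  if (length(drop)) res <- res[-drop, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Reconcile the window and feature scans
#'
#' Labels every significant window by whether it overlaps a candidate
#' (imprinted) feature, merely overlaps annotation, or is intergenic, and
#' counts for every candidate feature the significant windows supporting
#' it. Also tallies the analysis-specific candidates in each direction.
#'
#' @param windows a [window_scan()] result.
#' @param features a [feature_scan()] result.
#' @param annotation annotation GRanges (gene spans define "annotated").
#' @return list with `windows` (significant windows plus `overlap` label),
#'   `features` (candidate features plus `n_support_windows`), and
#'   `summary` (named counts, including window-only and feature-only
#'   candidates).
#' @export
reconcile_scans <- function(windows, features, annotation) {
  sig_w <- windows[windows$call %in% significant_calls, , drop = FALSE]
  sig_f <- features[features$call %in% significant_calls, , drop = FALSE]
  genes <- annotation[annotation$type == "gene"]
  wgr <- windows_to_gr(sig_w)
  fgr <- GenomicRanges::GRanges(sig_f$chrom, IRanges::IRanges(sig_f$start, sig_f$end))
  lab <- rep("intergenic", nrow(sig_w))
  lab[IRanges::overlapsAny(wgr, genes, ignore.strand = TRUE)] <- "overlaps_annotation_only"
  lab[IRanges::overlapsAny(wgr, fgr)] <- "overlaps_candidate_feature"
  sig_w$overlap <- lab
  sig_f$n_support_windows <- GenomicRanges::countOverlaps(fgr, wgr)
  list(
    windows = sig_w,
    features = sig_f,
    summary = c(
      n_sig_windows = nrow(sig_w),
      n_sig_features = nrow(sig_f),
      n_window_only = sum(lab != "overlaps_candidate_feature"),
      n_window_intergenic = sum(lab == "intergenic"),
      n_feature_only = sum(sig_f$n_support_windows == 0)
    )
  )
}

#' Screen for parent-of-origin-biased splicing
#'
#' A gene is a candidate when transcripts of opposite parental bias arise
#' from it: at least one of its sub-features (transcript isoform,
#' exon-union, intron unit, or a significant window fully inside the gene)
#' is called maternally imprinted and at least one paternally imprinted.
#' The canonical real-data pattern is maternally favored intron reads with
#' paternally favored exon reads (intron-retained maternal truncations
#' versus full-length paternal transcripts).
#'
#' @param features a [feature_scan()] result.
#' @param windows a [window_scan()] result (optional; `NULL` to screen
#'   annotated units only).
#' @param annotation annotation GRanges.
#' @return data.frame with one row per candidate gene: `gene_id`,
#'   `n_maternal_parts`, `n_paternal_parts`, `maternal_parts`,
#'   `paternal_parts` (semicolon-joined unit ids).
#' @export
poe_splicing_scan <- function(features, windows = NULL, annotation) {
  genes <- annotation[annotation$type == "gene"]
  gene_ids <- genes$gene_id
  fu <- features[!is.na(features$gene_id) &
                   features$call %in% significant_calls, , drop = FALSE]
  parts <- data.frame(
    gene_id = fu$gene_id, part = fu$unit_id,
    call = as.character(fu$call), stringsAsFactors = FALSE
  )
  if (!is.null(windows)) {
    sig_w <- windows[windows$call %in% significant_calls, , drop = FALSE]
    if (nrow(sig_w)) {
      wgr <- windows_to_gr(sig_w)
      h <- GenomicRanges::findOverlaps(wgr, genes, type = "within",
                                       ignore.strand = TRUE)
      if (length(h)) {
        parts <- rbind(parts, data.frame(
          gene_id = gene_ids[S4Vectors::subjectHits(h)],
          part = sprintf("window:%s:%d-%d",
                         sig_w$chrom[S4Vectors::queryHits(h)],
                         sig_w$start[S4Vectors::queryHits(h)],
                         sig_w$end[S4Vectors::queryHits(h)]),
          call = as.character(sig_w$call[S4Vectors::queryHits(h)]),
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  out <- lapply(split(parts, parts$gene_id), function(p) {
    m <- p$part[p$call == "maternal_imprint"]
    f <- p$part[p$call == "paternal_imprint"]
    if (!length(m) || !length(f)) return(NULL)
    data.frame(
      gene_id = p$gene_id[1],
      n_maternal_parts = length(m), n_paternal_parts = length(f),
      maternal_parts = paste(m, collapse = ";"),
      paternal_parts = paste(f, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(
      gene_id = character(), n_maternal_parts = integer(),
      n_paternal_parts = integer(), maternal_parts = character(),
      paternal_parts = character(), stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}
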