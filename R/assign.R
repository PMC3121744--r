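#' Assign reads a parental origin via diagnostic SNP reads
#'
#' Implements the SNP-read rules on colinear parental haplotypes with an
#' exact-match assigner: a read is accepted if and only if it
#'
#' 1. matches one genome perfectly at exactly one location (both strands
#'    searched),
#' 2. has exactly one mismatch to the other genome at the homologous
#'    location,
#' 3. that mismatch coincides with a reported SNP, and
#' 4. the read covers exactly one reported SNP.
#'
#' Matching is seeded with the first 18 bases of each read orientation
#' (18 = the minimum post-filter read length) via a [Biostrings::PDict]
#' lookup, then verified over the full read. Reads containing characters
#' outside ACGT are rejected as `no_hit` (exact matching).
#'
#' The rejection reasons partition all non-assigned reads:
#' `no_hit` (no perfect match anywhere), `multi_hit` (more than one perfect
#' location in a genome), `zero_or_multi_mismatch` (no SNP in the read, or
#' mismatches beyond reported SNPs), `mismatch_not_snp`, and `multi_snp`
#' (the read spans more than one reported SNP).
#'
#' @param reads named character vector of preprocessed read sequences.
#' @param genomes a [build_genome_pair()] object (or any list with
#'   `seq_a`, `seq_b` DNAStringSets and a `snps` table).
#' @param cross_direction `"A_mother"` if subspecies A was the seed parent
#'   of this library, else `"B_mother"`; with the carried allele this
#'   determines the parental origin (allele A is maternal iff A is the
#'   mother).
#' @param seed_length seed width for the exact-match index (default 18).
#' @return data.frame with one row per input read: `id`, `status`
#'   (`"assigned"` or a rejection reason), `chrom`, `pos` (1-based SNP
#'   position), `strand`, `allele` (`"A"`/`"B"`), `origin`
#'   (`"maternal"`/`"paternal"`); attribute `cross_direction`.
#' @export
assign_reads <- function(reads, genomes, cross_direction = c("A_mother", "B_mother"),
                         seed_length = 18L) {
  cross_direction <- match.arg(cross_direction)
  n <- length(reads)
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_len(n))
  status <- rep(NA_character_, n)
  chrom <- rep(NA_character_, n)
  pos <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n)
  allele <- rep(NA_character_, n)
  len <- nchar(reads)
  bad <- grepl("[^ACGT]", reads) | len < seed_length
  status[bad] <- "no_hit"
  ok <- which(!bad)

  if (length(ok)) {
    fwd <- unname(reads[ok])
    rcv <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(fwd)))
    both <- c(fwd, rcv)
    n_ok <- length(ok)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(substr(both, 1L, seed_length)))
    chr_a <- as.character(genomes$seq_a)
    chr_b <- as.character(genomes$seq_b)

    hits <- list()
    for (g in c("A", "B")) {
      chr_seq <- if (g == "A") genomes$seq_a else genomes$seq_b
      chr_str <- if (g == "A") chr_a else chr_b
      for (ch in names(chr_seq)) {
        m <- Biostrings::matchPDict(pd, chr_seq[[ch]])
        cnt <- S4Vectors::elementNROWS(m)
        pi <- rep(seq_along(cnt), cnt)
        st <- unlist(Biostrings::startIndex(m), use.names = FALSE)
        if (!length(pi)) next
        ri <- ifelse(pi > n_ok, pi - n_ok, pi)       # read index within ok
        sd <- ifelse(pi > n_ok, "-", "+")
        rl <- nchar(both[pi])
        en <- st + rl - 1L
        keep <- en <= nchar(chr_str[ch])
        if (!any(keep)) next
        full <- substring(chr_str[ch], st[keep], en[keep]) == both[pi[keep]]
        if (!any(full)) next
        k <- which(keep)[full]
        hits[[length(hits) + 1L]] <- data.frame(
          ri = ri[k], strand = sd[k], genome = g, chrom = ch,
          start = st[k], end = en[k], stringsAsFactors = FALSE
        )
      }
    }
    if (length(hits)) {
      h <- do.call(rbind, hits)
      # a palindromic read would report the same location twice
      h <- h[!duplicated(h[, c("ri", "genome", "chrom", "start")]), , drop = FALSE]
      na <- tabulate(h$ri[h$genome == "A"], nbins = n_ok)
      nb <- tabulate(h$ri[h$genome == "B"], nbins = n_ok)
      st_ok <- rep("no_hit", n_ok)
      st_ok[na > 1L | nb > 1L] <- "multi_hit"
      st_ok[na == 1L & nb == 1L] <- "zero_or_multi_mismatch"
      cand <- which((na == 1L & nb == 0L) | (na == 0L & nb == 1L))
      if (length(cand)) {
        hc <- h[h$ri %in% cand, , drop = FALSE]
        hc <- hc[order(hc$ri), , drop = FALSE]
        other_str <- ifelse(hc$genome == "A", chr_b[hc$chrom], chr_a[hc$chrom])
        other_sub <- substr(other_str, hc$start, hc$end)
        plus_read <- both[ifelse(hc$strand == "+", hc$ri, hc$ri + n_ok)]
        mm <- mapply(function(a, b) {
          d <- which(charToRaw(a) != charToRaw(b))
          c(length(d), if (length(d)) d[1L] else NA_integer_)
        }, plus_read, other_sub, USE.NAMES = FALSE)
        n_mm <- mm[1L, ]
        mm_pos <- hc$start + mm[2L, ] - 1L
        snp_key <- paste(genomes$snps$chrom, genomes$snps$pos)
        one_at_snp <- n_mm == 1L & paste(hc$chrom, mm_pos) %in% snp_key
        st_c <- rep("zero_or_multi_mismatch", nrow(hc))
        st_c[n_mm == 1L & !one_at_snp] <- "mismatch_not_snp"
        st_c[one_at_snp] <- "assigned"
        if (any(n_mm >= 2L)) {
          # all mismatches at reported SNPs => the read spans several SNPs
          multi <- which(n_mm >= 2L)
          for (j in multi) {
            a <- charToRaw(plus_read[j]); b <- charToRaw(other_sub[j])
            d <- hc$start[j] + which(a != b) - 1L
            if (all(paste(hc$chrom[j], d) %in% snp_key)) st_c[j] <- "multi_snp"
          }
        }
        st_ok[hc$ri] <- st_c
        asn <- st_c == "assigned"
        idx <- ok[hc$ri[asn]]
        chrom[idx] <- hc$chrom[asn]
        pos[idx] <- mm_pos[asn]
        strand[idx] <- hc$strand[asn]
        allele[idx] <- hc$genome[asn]
      }
      status[ok] <- st_ok
    } else {
      status[ok] <- "no_hit"
    }
  }
  origin <- ifelse((allele == "A") == (cross_direction == "A_mother"),
                   "maternal", "paternal")
  out <- data.frame(
    id = names(reads), status = status, chrom = chrom, pos = pos,
    strand = strand, allele = allele, origin = origin,
    stringsAsFactors = FALSE
  )
  attr(out, "cross_direction") <- cross_direction
  out
}

#' Aggregate read assignments to per-SNP allelic counts
#'
#' Sums assigned reads into raw maternal/paternal counts per SNP for one
#' cross. The total of all counts equals the number of assigned reads
#' exactly, and the result is invariant to input order.
#'
#' @param assignments an [assign_reads()] result (rows with
#'   `status != "assigned"` are ignored).
#' @return data.frame `chrom`, `pos`, `r_mat_raw`, `r_pat_raw`, sorted by
#'   position; attribute `cross_direction` carried over.
#' @export
aggregate_counts <- function(assignments) {
  a <- assignments[assignments$status == "assigned", , drop = FALSE]
  if (!nrow(a)) {
    out <- data.frame(chrom = character(), pos = integer(),
                      r_mat_raw = integer(), r_pat_raw = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "cross_direction") <- attr(assignments, "cross_direction")
    return(out)
  }
  key <- paste(a$chrom, a$pos)
  mat <- rowsum((a$origin == "maternal") + 0L, key)
  pat <- rowsum((a$origin == "paternal") + 0L, key)
  parts <- do.call(rbind, strsplit(rownames(mat), " ", fixed = TRUE))
  out <- data.frame(
    chrom = parts[, 1], pos = as.integer(parts[, 2]),
    r_mat_raw = as.integer(mat[, 1]), r_pat_raw = as.integer(pat[, 1]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cross_direction") <- attr(assignments, "cross_direction")
  out
}

#' Normalize allelic counts between the two crosses
#'
#' The two reciprocal libraries differ in total assigned SNP reads, so raw
#' counts are converted to reads per million and rescaled by a fixed
#' constant `C = mean(library totals) / 1e6` to return integer counts on
#' the same scale as the raw data:
#' `normalized = round(raw / library_total * 1e6 * C)`, rounding half up.
#' Equal library totals leave counts unchanged.
#'
#' @param counts list of two [aggregate_counts()] tables, named `A_mother`
#'   and `B_mother`.
#' @return the same list with integer columns `r_mat` and `r_pat` added;
#'   attributes `library_totals` and `norm_constant` on the list.
#' @export
normalize_between_crosses <- function(counts) {
  stopifnot(all(c("A_mother", "B_mother") %in% names(counts)))
  totals <- vapply(counts[c("A_mother", "B_mother")],
                   function(x) sum(x$r_mat_raw) + sum(x$r_pat_raw), numeric(1))
  if (any(totals <= 0)) stop("zero library total; nothing to normalize")
  cc <- mean(totals) / 1e6
  out <- lapply(c(A_mother = "A_mother", B_mother = "B_mother"), function(nm) {
    x <- counts[[nm]]
    scale <- 1e6 * cc / totals[[nm]]
    x$r_mat <- as.integer(floor(x$r_mat_raw * scale + 0.5))
    x$r_pat <- as.integer(floor(x$r_pat_raw * scale + 0.5))
    x
  })
  attr(out, "library_totals") <- totals
  attr(out, "norm_constant") <- cc
  out
}
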