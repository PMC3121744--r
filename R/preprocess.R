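#' Trim a 3' adaptor suffix from reads
#'
#' Removes the longest read suffix that exactly matches a prefix of the
#' adaptor, requiring at least `min_overlap` matching bases; reads with no
#' such overlap are returned unchanged. This models adaptor read-through at
#' the 3' end of short cDNA fragments.
#'
#' @param reads character vector of read sequences (may be named).
#' @param adaptor adaptor sequence, non-empty.
#' @param min_overlap minimum suffix/prefix overlap to trim (default 5).
#' @return character vector of trimmed reads, same length and names.
#' @export
trim_adaptor <- function(reads, adaptor, min_overlap = 5L) {
  if (!nzchar(adaptor)) stop("adaptor must be non-empty")
  n <- nchar(reads)
  done <- logical(length(reads))
  out <- reads
  for (k in seq(min(nchar(adaptor), max(n, 0L)), min_overlap)) {
    if (k < min_overlap) break
    pref <- substr(adaptor, 1L, k)
    idx <- which(!done & n >= k & substr(out, n - k + 1L, n) == pref)
    if (length(idx)) {
      out[idx] <- substr(out[idx], 1L, n[idx] - k)
      done[idx] <- TRUE
    }
  }
  out
}

#' Fraction of a read covered by short tandem repeats
#'
#' Scans exhaustively for maximal tandem repeats of period 1 to `max_period`
#' with at least `min_copies` full copies and returns the fraction of read
#' bases covered by any such repeat. Pure homopolymer or di/tri-nucleotide
#' repeat reads score 1; typical random sequence scores well below 0.5.
#'
#' @param read a single read sequence.
#' @param max_period largest repeat period considered (default 3).
#' @param min_copies minimum number of tandem copies for a run to count
#'   (default 3; with only two copies chance pairings in random sequence
#'   would dominate).
#' @return fraction in \[0, 1\].
#' @export
repetitive_fraction <- function(read, max_period = 3L, min_copies = 3L) {
  s <- strsplit(read, "", fixed = TRUE)[[1]]
  n <- length(s)
  if (n == 0L) return(0)
  covered <- logical(n)
  for (p in seq_len(min(max_period, n - 1L))) {
    eq <- s[seq_len(n - p)] == s[seq_len(n - p) + p]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      span <- r$lengths[j] + p # bases from starts[j] to ends[j] + p
      if (span >= min_copies * p) {
        covered[starts[j]:(ends[j] + p)] <- TRUE
      }
    }
  }
  mean(covered)
}

#' Filter trimmed reads on length and complexity
#'
#' Excludes reads shorter than `min_length` bases (reason `"short"`) or with
#' more than `max_repetitive` of their bases in short tandem repeats
#' (reason `"repetitive"`, see [repetitive_fraction()]).
#'
#' @param reads character vector of trimmed read sequences.
#' @param min_length minimum kept length (default 18).
#' @param max_repetitive maximum tolerated repetitive fraction (default 0.5,
#'   exclusive: reads strictly above are dropped).
#' @return data.frame with columns `keep` (logical) and `reason`
#'   (`""`, `"short"` or `"repetitive"`).
#' @export
filter_reads <- function(reads, min_length = 18L, max_repetitive = 0.5) {
  keep <- rep(TRUE, length(reads))
  reason <- rep("", length(reads))
  short <- nchar(reads) < min_length
  keep[short] <- FALSE
  reason[short] <- "short"
  idx <- which(!short)
  if (length(idx)) {
    rf <- vapply(reads[idx], repetitive_fraction, numeric(1), USE.NAMES = FALSE)
    rep_bad <- rf > max_repetitive
    keep[idx[rep_bad]] <- FALSE
    reason[idx[rep_bad]] <- "repetitive"
  }
  data.frame(keep = keep, reason = reason, stringsAsFactors = FALSE)
}

#' Truncate embryo reads to the endosperm read length
#'
#' Embryo libraries are sequenced longer (75 bases) than endosperm libraries
#' (36 bases); only the first 36 bases of embryo reads are analysed so the
#' risk of a read covering more than one SNP stays comparable between the
#' tissues. Reads already at or below the cutoff are unchanged.
#'
#' @param reads character vector of read sequences.
#' @param cutoff retained prefix length (default 36).
#' @return truncated reads.
#' @export
truncate_embryo <- function(reads, cutoff = 36L) {
  substr(reads, 1L, cutoff)
}

#' Preprocess a read library
#'
#' Applies the full preprocessing chain: 3' adaptor trimming (if an adaptor
#' is given), truncation to 36 bases for embryo reads, then the length and
#' complexity filters. Every input read ends in exactly one bucket:
#' kept, `"short"`, or `"repetitive"`.
#'
#' @param reads named character vector of raw read sequences.
#' @inheritParams maternal_fraction
#' @param adaptor 3' adaptor sequence or `NULL` to skip trimming.
#' @param min_length,max_repetitive see [filter_reads()].
#' @return list with `reads` (named character vector of kept, processed
#'   reads) and `log` (data.frame `id`, `keep`, `reason` for all inputs).
#' @export
preprocess_reads <- function(reads, tissue = c("endosperm", "embryo"),
                             adaptor = NULL, min_length = 18L,
                             max_repetitive = 0.5) {
  tissue <- match.arg(tissue)
  if (is.null(names(reads))) {
    names(reads) <- sprintf("read%06d", seq_along(reads))
  }
  proc <- reads
  if (!is.null(adaptor)) proc <- trim_adaptor(proc, adaptor)
  if (tissue == "embryo") proc <- truncate_embryo(proc)
  flt <- filter_reads(proc, min_length = min_length,
                      max_repetitive = max_repetitive)
  list(
    reads = proc[flt$keep],
    log = data.frame(id = names(reads), keep = flt$keep, reason = flt$reason,
                     stringsAsFactors = FALSE)
  )
}
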