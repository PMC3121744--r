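#' Clustering statistics of imprinted candidates
#'
#' Computes, per chromosome, nearest-neighbor distances between significant
#' windows (midpoint to midpoint), the median of those distances, and the
#' number/fraction of windows with another candidate within `pair_window`
#' bp. Also reports micro-clusters: pairs of imprinted genes separated by
#' at most one intervening annotated gene or by a gap of at most
#' `micro_gap` bp - the plant counterpart of the large imprinted clusters
#' of mammals.
#'
#' @param sig_windows data.frame of significant windows (`chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param imprinted_genes data.frame of imprinted genes (`gene_id`,
#'   `chrom`, `start`, `end`); may be empty.
#' @param annotation annotation GRanges (for counting intervening genes);
#'   `NULL` disables the intervening-gene rule.
#' @param pair_window window pairing distance in bp (default 10 kb).
#' @param micro_gap maximum gene-gap for a micro-cluster (default 20 kb).
#' @return list of class `cluster_report`: `nn_distances`,
#'   `median_nn_distance`, `n_within_pair_window`, `frac_within_pair_window`,
#'   `micro_clusters` (data.frame of gene pairs).
#' @export
cluster_stats <- function(sig_windows, imprinted_genes = NULL,
                          annotation = NULL, pair_window = 10000L,
                          micro_gap = 20000L) {
  if (nrow(sig_windows) < 1L) stop("at least one candidate window required")
  mid <- (sig_windows$start + sig_windows$end) / 2
  nn <- unlist(lapply(split(mid, sig_windows$chrom), function(m) {
    if (length(m) < 2L) return(numeric())
    m <- sort(m)
    gaps <- diff(m)
    pmin(c(Inf, gaps), c(gaps, Inf))
  }), use.names = FALSE)
  med <- if (length(nn)) stats::median(nn) else NA_real_
  n_close <- sum(nn <= pair_window)
  micro <- data.frame(
    gene1 = character(), gene2 = character(), gap = integer(),
    n_between = integer(), stringsAsFactors = FALSE
  )
  if (!is.null(imprinted_genes) && nrow(imprinted_genes) >= 2L) {
    for (ch in unique(imprinted_genes$chrom)) {
      g <- imprinted_genes[imprinted_genes$chrom == ch, , drop = FALSE]
      g <- g[order(g$start), , drop = FALSE]
      if (nrow(g) < 2L) next
      for (i in seq_len(nrow(g) - 1L)) {
        gap <- g$start[i + 1L] - g$end[i]
        n_between <- NA_integer_
        if (!is.null(annotation)) {
          genes <- annotation[annotation$type == "gene"]
          between <- genes[as.character(GenomicRanges::seqnames(genes)) == ch &
                             GenomicRanges::start(genes) > g$end[i] &
                             GenomicRanges::end(genes) < g$start[i + 1L]]
          n_between <- length(between)
        }
        if ((!is.na(n_between) && n_between <= 1L) || gap <= micro_gap) {
          micro <- rbind(micro, data.frame(
            gene1 = g$gene_id[i], gene2 = g$gene_id[i + 1L],
            gap = gap, n_between = n_between, stringsAsFactors = FALSE
          ))
        }
      }
    }
  }
  structure(
    list(
      nn_distances = nn,
      median_nn_distance = med,
      n_within_pair_window = n_close,
      frac_within_pair_window = if (length(nn)) n_close / length(nn) else NA_real_,
      micro_clusters = micro
    ),
    class = "cluster_report"
  )
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf(
    "cluster_report: median NN distance %s bp, %d windows within pairing distance (%.1f%%), %d micro-cluster(s)\n",
    format(x$median_nn_distance, big.mark = ","), x$n_within_pair_window,
    100 * x$frac_within_pair_window, nrow(x$micro_clusters)
  ))
  invisible(x)
}

#' Repeat and transposon proximity of candidate genes
#'
#' For every gene, the distance to the nearest annotated repeat (0 when a
#' repeat overlaps the gene) and the repeat-covered fraction within
#' `flank` bp of the gene body. Candidates are compared with the background
#' of all genes by a two-sided permutation test on random same-size gene
#' sets (median of distances, mean of densities), overall and per repeat
#' class.
#'
#' @param candidate_ids gene ids of imprinted candidates.
#' @param genes GRanges of all annotated genes with a `gene_id` column.
#' @param repeats GRanges of repeats with a `class` metadata column.
#' @param flank flank width in bp for the density measure (default 5 kb).
#' @param n_perm number of permutations (default 10000).
#' @param seed optional seed; fixed seed gives exact reproducibility.
#' @return list of class `repeat_report`: `per_gene` data.frame,
#'   `distance_p`, `density_p`, `per_class` data.frame and the observed
#'   candidate/background summaries.
#' @export
repeat_proximity <- function(candidate_ids, genes, repeats, flank = 5000L,
                             n_perm = 10000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(candidate_ids %in% genes$gene_id))
  n_genes <- length(genes)
  if (!length(repeats)) {
    return(structure(list(
      per_gene = data.frame(gene_id = genes$gene_id, distance = NA_real_,
                            density = NA_real_),
      distance_p = NA_real_, density_p = NA_real_,
      per_class = data.frame()
    ), class = "repeat_report"))
  }
  d2n <- GenomicRanges::distanceToNearest(genes, repeats, ignore.strand = TRUE)
  distance <- rep(NA_real_, n_genes)
  distance[S4Vectors::queryHits(d2n)] <- S4Vectors::mcols(d2n)$distance
  flanked <- GenomicRanges::resize(genes, GenomicRanges::width(genes) + 2L * flank,
                                   fix = "center")
  flanked <- GenomicRanges::trim(flanked)
  covered_fraction <- function(bins, track) {
    h <- GenomicRanges::findOverlaps(bins, track, ignore.strand = TRUE)
    v <- numeric(length(bins))
    if (length(h)) {
      w <- GenomicRanges::width(GenomicRanges::pintersect(
        bins[S4Vectors::queryHits(h)], track[S4Vectors::subjectHits(h)],
        ignore.strand = TRUE
      ))
      s <- rowsum(w, S4Vectors::queryHits(h))
      v[as.integer(rownames(s))] <- s[, 1]
    }
    v / GenomicRanges::width(bins)
  }
  rep_red <- GenomicRanges::reduce(repeats, ignore.strand = TRUE)
  density <- covered_fraction(flanked, rep_red)

  is_cand <- genes$gene_id %in% candidate_ids
  n_cand <- sum(is_cand)
  perm_test <- function(metric, fun) {
    obs <- fun(metric[is_cand])
    perm <- vapply(seq_len(n_perm), function(i) {
      fun(metric[sample.int(n_genes, n_cand)])
    }, numeric(1))
    min(1, 2 * min((sum(perm <= obs) + 1) / (n_perm + 1),
                   (sum(perm >= obs) + 1) / (n_perm + 1)))
  }
  med_na <- function(x) stats::median(x, na.rm = TRUE)
  mean_na <- function(x) mean(x, na.rm = TRUE)
  distance_p <- perm_test(distance, med_na)
  density_p <- perm_test(density, mean_na)

  classes <- unique(as.character(repeats$class))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    rc <- GenomicRanges::reduce(repeats[repeats$class == cl],
                                ignore.strand = TRUE)
    dens <- covered_fraction(flanked, rc)
    data.frame(
      class = cl,
      candidate_density = mean_na(dens[is_cand]),
      background_density = mean_na(dens),
      p_value = perm_test(dens, mean_na),
      stringsAsFactors = FALSE
    )
  }))
  structure(
    list(
      per_gene = data.frame(gene_id = genes$gene_id, distance = distance,
                            density = density, candidate = is_cand,
                            stringsAsFactors = FALSE),
      candidate_median_distance = med_na(distance[is_cand]),
      background_median_distance = med_na(distance),
      candidate_mean_density = mean_na(density[is_cand]),
      background_mean_density = mean_na(density),
      distance_p = distance_p, density_p = density_p,
      per_class = per_class, n_perm = n_perm
    ),
    class = "repeat_report"
  )
}

#' @export
print.repeat_report <- function(x, ...) {
  cat(sprintf(
    "repeat_report: candidate median distance %s (background %s), P = %.3g; density %.3f vs %.3f, P = %.3g\n",
    format(x$candidate_median_distance, big.mark = ","),
    format(x$background_median_distance, big.mark = ","),
    x$distance_p, x$candidate_mean_density, x$background_mean_density,
    x$density_p
  ))
  invisible(x)
}

#' GC content of features and candidate-versus-background comparison
#'
#' GC fraction over each feature span on the subspecies A haplotype, with a
#' Wilcoxon rank-sum comparison of candidates against the background.
#'
#' @param features GRanges of feature spans with a `gene_id` (or name)
#'   column.
#' @param genomes a [build_genome_pair()] object.
#' @param candidate_ids ids of candidate features (optional).
#' @return list with `per_feature` (data.frame `id`, `gc`) and, when
#'   candidates are given, `candidate_mean`, `background_mean` and
#'   `p_value` (rank-sum).
#' @export
gc_content <- function(features, genomes, candidate_ids = NULL) {
  ids <- if (!is.null(features$gene_id)) features$gene_id else names(features)
  seqs <- Biostrings::DNAStringSet(lapply(seq_along(features), function(i) {
    ch <- as.character(GenomicRanges::seqnames(features[i]))
    Biostrings::subseq(genomes$seq_a[[ch]],
                       GenomicRanges::start(features[i]),
                       GenomicRanges::end(features[i]))
  }))
  gc <- as.numeric(Biostrings::letterFrequency(seqs, "GC", as.prob = TRUE))
  out <- list(per_feature = data.frame(id = ids, gc = gc,
                                       stringsAsFactors = FALSE))
  if (!is.null(candidate_ids)) {
    is_cand <- ids %in% candidate_ids
    if (any(is_cand) && any(!is_cand)) {
      wt <- stats::wilcox.test(gc[is_cand], gc[!is_cand])
      out$candidate_mean <- mean(gc[is_cand])
      out$background_mean <- mean(gc[!is_cand])
      out$p_value <- wt$p.value
    }
  }
  out
}

#' Hypergeometric GO term enrichment
#'
#' Upper-tail hypergeometric test per term: the probability of observing at
#' least `k` candidates annotated with the term, given `K` of the `N`
#' background genes carry it and `n` candidates were drawn. The background
#' is the expressed set (all transcripts with at least 10 reads), and
#' candidates must be a subset of it. Benjamini-Hochberg adjusted values
#' are reported alongside.
#'
#' @param candidate_ids candidate gene ids (subset of `background_ids`).
#' @param background_ids expressed background gene ids.
#' @param term_map data.frame with columns `gene_id` and `term_id`
#'   (one row per annotation).
#' @return data.frame: `term_id`, `k_candidates_with_term`, `n_candidates`,
#'   `K_background_with_term`, `N_background`, `p_value`, `q_value`.
#' @export
go_enrichment <- function(candidate_ids, background_ids, term_map) {
  candidate_ids <- unique(candidate_ids)
  background_ids <- unique(background_ids)
  if (!all(candidate_ids %in% background_ids)) {
    stop("candidates must be a subset of the expressed background")
  }
  tm <- term_map[term_map$gene_id %in% background_ids, , drop = FALSE]
  tm <- unique(tm[, c("gene_id", "term_id")])
  n <- length(candidate_ids)
  N <- length(background_ids)
  terms <- unique(tm$term_id)
  res <- do.call(rbind, lapply(terms, function(t) {
    with_term <- tm$gene_id[tm$term_id == t]
    K <- length(with_term)
    k <- sum(candidate_ids %in% with_term)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(
      term_id = t, k_candidates_with_term = k, n_candidates = n,
      K_background_with_term = K, N_background = N, p_value = p,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(res)) {
    return(data.frame(
      term_id = character(), k_candidates_with_term = integer(),
      n_candidates = integer(), K_background_with_term = integer(),
      N_background = integer(), p_value = numeric(), q_value = numeric(),
      stringsAsFactors = FALSE
    ))
  }
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$p_value), , drop = FALSE]
}
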