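#' Run the full imprinting detection pipeline
#'
#' Orchestrates the stages on a reciprocal-cross bundle (simulated or read
#' from disk): read preprocessing (adaptor trim, embryo truncation, length
#' and complexity filters), SNP-read assignment, per-SNP aggregation,
#' between-cross normalization, the window and annotated-feature scans,
#' reciprocal-cross classification, scan reconciliation, the
#' parent-of-origin splicing screen, and candidate clustering statistics.
#' Bundles carrying pre-assigned count tables instead of reads skip the
#' read stages.
#'
#' @param bundle a [simulate_bundle()] / [read_bundle()] object, or a path
#'   to a bundle directory.
#' @inheritParams imprint_calls
#' @param strong_bias combined-bias cutoff for the "strong" candidate
#'   subset (default 0.9, i.e. at least 90% of reads from one parent).
#' @param adaptor 3' adaptor to trim (default from the bundle config).
#' @param out_dir optional output directory; when given, candidate tables
#'   (full and strong subset), a BED of significant windows and a JSON
#'   summary are written there.
#' @return An object of class `imprint_scan`; see [print.imprint_scan()].
#'   Fields: `tissue`, `preprocess` (per-cross filter tallies), `assign`
#'   (per-cross status tallies), `counts` (normalized per-SNP tables),
#'   `windows`, `features`, `reconciled`, `splicing`, `clusters`,
#'   `candidates`, `strong_candidates` and `summary`.
#' @export
run_pipeline <- function(bundle, min_reads = 10, threshold = 1.3,
                         strong_bias = 0.9, adaptor = NULL, out_dir = NULL) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  stopifnot(inherits(bundle, "sim_bundle"))
  tissue <- bundle$config$tissue
  if (is.null(tissue)) tissue <- attr(bundle$counts$A_mother, "tissue")
  if (is.null(tissue)) stop("bundle does not declare its tissue")
  if (is.null(adaptor) && !is.null(bundle$config$adaptor)) {
    adaptor <- bundle$config$adaptor
  }

  preprocess <- NULL
  assign_tallies <- NULL
  if (!is.null(bundle$reads)) {
    raw_counts <- list()
    preprocess <- list()
    assign_tallies <- list()
    for (cr in c("A_mother", "B_mother")) {
      pp <- preprocess_reads(bundle$reads[[cr]], tissue = tissue,
                             adaptor = adaptor)
      asg <- assign_reads(pp$reads, bundle$genomes, cross_direction = cr)
      raw_counts[[cr]] <- aggregate_counts(asg)
      preprocess[[cr]] <- table(ifelse(pp$log$keep, "kept", pp$log$reason))
      assign_tallies[[cr]] <- table(asg$status)
    }
  } else if (!is.null(bundle$counts)) {
    raw_counts <- bundle$counts
  } else {
    stop("bundle has neither reads nor counts")
  }
  counts <- normalize_between_crosses(raw_counts)

  windows <- window_scan(bundle$genomes$chrom_lengths, counts, tissue = tissue,
                         min_reads = min_reads, threshold = threshold)
  features <- feature_scan(bundle$annotation, counts, tissue = tissue,
                           min_reads = min_reads, threshold = threshold)
  reconciled <- reconcile_scans(windows, features, bundle$annotation)
  splicing <- poe_splicing_scan(features, windows, bundle$annotation)

  candidates <- features[features$call %in% significant_calls, , drop = FALSE]
  strong <- candidates[!is.na(candidates$bias) &
                         candidates$bias >= strong_bias, , drop = FALSE]
  sig_w <- windows[windows$call %in% significant_calls, , drop = FALSE]
  clusters <- NULL
  if (nrow(sig_w)) {
    genes_df <- candidate_gene_spans(candidates)
    clusters <- cluster_stats(sig_w, genes_df, bundle$annotation)
  }

  profiled <- sum(features$r_mat_a + features$r_pat_a >= min_reads &
                    features$r_mat_b + features$r_pat_b >= min_reads)
  conservation <- attr(features, "conservation")
  summary <- list(
    tissue = tissue,
    library_totals = attr(counts, "library_totals"),
    norm_constant = attr(counts, "norm_constant"),
    n_snps_with_reads = vapply(counts, nrow, integer(1)),
    n_windows = nrow(windows),
    n_features = nrow(features),
    n_profiled_features = profiled,
    calls_features = table(features$call),
    calls_windows = table(windows$call),
    n_candidates = nrow(candidates),
    n_strong_candidates = nrow(strong),
    n_splicing_candidates = nrow(splicing),
    conservation = conservation,
    conservation_ok = all(vapply(conservation, function(x) {
      x[["exon"]] + x[["intron"]] + x[["intergenic"]] == x[["total"]]
    }, logical(1))),
    min_reads = min_reads, threshold = threshold, strong_bias = strong_bias
  )

  res <- structure(
    list(
      tissue = tissue, preprocess = preprocess, assign = assign_tallies,
      counts = counts, windows = windows, features = features,
      reconciled = reconciled, splicing = splicing, clusters = clusters,
      candidates = candidates, strong_candidates = strong,
      truth = bundle$truth, summary = summary
    ),
    class = "imprint_scan"
  )
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

candidate_gene_spans <- function(candidates) {
  g <- candidates[!is.na(candidates$gene_id), , drop = FALSE]
  if (!nrow(g)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  sp <- lapply(split(g, g$gene_id), function(x) {
    data.frame(gene_id = x$gene_id[1], chrom = x$chrom[1],
               start = min(x$start), end = max(x$end),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, sp)
  rownames(out) <- NULL
  out
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res$features, file.path(out_dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$candidates, file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$strong_candidates,
                     file.path(out_dir, "candidates_strong.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$splicing, file.path(out_dir, "splicing_candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sig_w <- res$windows[res$windows$call %in% significant_calls, , drop = FALSE]
  write_bed_windows(sig_w, file.path(out_dir, "significant_windows.bed"))
  s <- res$summary
  s$calls_features <- as.list(s$calls_features)
  s$calls_windows <- as.list(s$calls_windows)
  s$conservation <- lapply(s$conservation, as.list)
  s$preprocess <- lapply(res$preprocess, as.list)
  s$assign <- lapply(res$assign, as.list)
  jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.imprint_scan <- function(x, ...) {
  s <- x$summary
  cat(sprintf("imprint_scan of %s (reciprocal crosses)\n", x$tissue))
  cat(sprintf("  library totals: A_mother %d, B_mother %d (C = %.3g)\n",
              s$library_totals[["A_mother"]], s$library_totals[["B_mother"]],
              s$norm_constant))
  cat(sprintf("  features profiled (>=%d reads both crosses): %d of %d\n",
              s$min_reads, s$n_profiled_features, s$n_features))
  tb <- s$calls_features
  tb <- tb[tb > 0]
  cat("  feature calls:", paste(sprintf("%s %d", names(tb), tb), collapse = ", "), "\n")
  cat(sprintf("  candidates: %d (%d with bias >= %.2f); splicing candidates: %d\n",
              s$n_candidates, s$n_strong_candidates, s$strong_bias,
              s$n_splicing_candidates))
  cat(sprintf("  conservation (exon+intron+intergenic == total): %s\n",
              if (isTRUE(s$conservation_ok)) "ok" else "VIOLATED"))
  invisible(x)
}

#' @export
summary.imprint_scan <- function(object, ...) {
  print(object)
  if (!is.null(object$clusters)) print(object$clusters)
  if (!is.null(object$reconciled)) {
    s <- object$reconciled$summary
    cat("  reconciliation:",
        paste(sprintf("%s %d", names(s), s), collapse = ", "), "\n")
  }
  invisible(object$summary)
}

#' Compare pipeline calls with the simulator's planted truth
#'
#' Per truth class: how many planted loci were recovered with the expected
#' call (sensitivity), plus the false-positive rate among biallelic loci
#' and the number of subspecies loci miscalled as imprinted. A planted
#' locus counts as recovered when any feature unit of its gene (or the
#' intergenic unit containing it) carries the expected call;
#' `poe_splicing` loci are checked against the splicing screen.
#'
#' @param result an `imprint_scan` object with its bundle `truth` attached.
#' @param truth optional truth table overriding `result$truth`.
#' @return list of class `recovery_stats`: per-class data.frame and the
#'   headline rates.
#' @export
recovery_stats <- function(result, truth = NULL) {
  if (is.null(truth)) truth <- result$truth
  stopifnot(!is.null(truth))
  truth <- truth[truth$testable, , drop = FALSE]
  feats <- result$features
  call_of <- function(fid, tr) {
    rows <- feats[!is.na(feats$gene_id) & feats$gene_id == fid, , drop = FALSE]
    if (!nrow(rows)) {
      # intergenic transcript: the unit(s) overlapping its span
      ig <- feats[feats$kind == "intergenic", , drop = FALSE]
      rows <- ig[ig$chrom == tr$chrom & ig$start <= tr$end & ig$end >= tr$start, ,
                 drop = FALSE]
    }
    as.character(rows$call)
  }
  expected_call <- c(
    maternal_imprint = "maternal_imprint",
    paternal_imprint = "paternal_imprint",
    subspecies_a_bias = "subspecies_a_bias",
    subspecies_b_bias = "subspecies_b_bias",
    biallelic = "unbiased",
    low_coverage = "low_coverage"
  )
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    cls <- tr$truth_class
    if (cls == "poe_splicing") {
      hit <- tr$feature_id %in% result$splicing$gene_id
      mis <- FALSE
    } else {
      calls <- call_of(tr$feature_id, tr)
      hit <- expected_call[[cls]] %in% calls
      mis <- any(calls %in% significant_calls) &&
        !cls %in% c("maternal_imprint", "paternal_imprint")
    }
    data.frame(feature_id = tr$feature_id, truth_class = cls,
               recovered = hit, miscalled_imprinted = mis,
               stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, rows)
  per_class <- do.call(rbind, lapply(split(per_locus, per_locus$truth_class),
                                     function(x) {
    data.frame(truth_class = x$truth_class[1], n = nrow(x),
               recovered = sum(x$recovered),
               sensitivity = mean(x$recovered),
               stringsAsFactors = FALSE)
  }))
  rownames(per_class) <- NULL
  bial <- per_locus[per_locus$truth_class == "biallelic", , drop = FALSE]
  subsp <- per_locus[per_locus$truth_class %in%
                       c("subspecies_a_bias", "subspecies_b_bias"), , drop = FALSE]
  structure(
    list(
      per_locus = per_locus, per_class = per_class,
      fp_rate_biallelic = if (nrow(bial)) mean(bial$miscalled_imprinted) else NA_real_,
      n_subspecies_called_imprinted = sum(subsp$miscalled_imprinted)
    ),
    class = "recovery_stats"
  )
}

#' @export
print.recovery_stats <- function(x, ...) {
  cat("recovery_stats:\n")
  print(x$per_class, row.names = FALSE)
  cat(sprintf("  biallelic FP rate: %.4f; subspecies loci called imprinted: %d\n",
              x$fp_rate_biallelic, x$n_subspecies_called_imprinted))
  invisible(x)
}
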