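test_that("window tiling covers the genome with 2x overlap and no slivers", {
  w <- tile_windows(c(chr1 = 3000))
  expect_equal(nrow(w), 5)
  expect_equal(w$start, c(0, 500, 1000, 1500, 2000))
  expect_equal(w$end, c(1000, 1500, 2000, 2500, 3000))
  expect_equal(nrow(tile_windows(c(chr1 = 1000))), 1)
  expect_equal(tile_windows(c(chr1 = 1000))$end, 1000)
  # interior positions are covered by exactly two windows
  w <- tile_windows(c(chr1 = 3000))
  for (p in c(500, 1234, 2499)) {
    expect_equal(sum(w$start <= p & p < w$end), 2)
  }
  # a 200 bp tail is absorbed by the previous window
  w2 <- tile_windows(c(chr1 = 1200))
  expect_equal(nrow(w2), 2)
  expect_equal(w2$end, c(1000, 1200))
})

mk_counts <- function(df_a, df_b) {
  attr(df_a, "cross_direction") <- "A_mother"
  attr(df_b, "cross_direction") <- "B_mother"
  list(A_mother = df_a, B_mother = df_b)
}

test_that("windows below the 10-read floor are low_coverage, others classified", {
  cnt <- function(mat, pat) {
    data.frame(chrom = "chr1", pos = 500L, r_mat = mat, r_pat = pat,
               r_mat_raw = mat, r_pat_raw = pat, stringsAsFactors = FALSE)
  }
  # 9 reads in one cross, unremarkable in the other: not tested
  ws <- window_scan(c(chr1 = 1000), mk_counts(cnt(9L, 0L), cnt(6L, 3L)),
                    "endosperm")
  expect_equal(as.character(ws$call), "low_coverage")
  # planted mono-allelic maternal window at depth 100 in both crosses
  ws <- window_scan(c(chr1 = 1000), mk_counts(cnt(100L, 0L), cnt(100L, 0L)),
                    "endosperm")
  expect_equal(as.character(ws$call), "maternal_imprint")
  expect_equal(ws$bias, 1)
})

test_that("interior SNP reads are counted by exactly two windows", {
  set.seed(44)
  pos <- sort(sample(600:9400, 40))
  cnt <- data.frame(chrom = "chr1", pos = pos,
                    r_mat = rpois(40, 20), r_pat = rpois(40, 10),
                    stringsAsFactors = FALSE)
  ws <- window_scan(c(chr1 = 10000), mk_counts(cnt, cnt), "endosperm")
  expect_equal(sum(ws$r_mat_a + ws$r_pat_a),
               2 * sum(cnt$r_mat + cnt$r_pat))
})

test_that("scan results do not depend on SNP input order", {
  b <- quick_bundle(seed = 17, adaptor_frac = 0)
  counts <- normalize_between_crosses(lapply(
    c(A_mother = "A_mother", B_mother = "B_mother"),
    function(cr) aggregate_counts(assign_reads(b$reads[[cr]], b$genomes, cr))
  ))
  shuf <- lapply(counts, function(x) x[sample(nrow(x)), ])
  ws1 <- window_scan(b$genomes$chrom_lengths, counts, "endosperm")
  ws2 <- window_scan(b$genomes$chrom_lengths, shuf, "endosperm")
  expect_equal(ws1, ws2)
  fs1 <- feature_scan(b$annotation, counts, "endosperm")
  fs2 <- feature_scan(b$annotation, shuf, "endosperm")
  expect_equal(fs1$call, fs2$call)
  expect_equal(fs1$r_mat_a, fs2$r_mat_a)
})

test_that("exon/intron/intergenic partition conserves every SNP read", {
  b <- quick_bundle(seed = 19, n_intergenic_maternal = 2L)
  res <- run_pipeline(b)
  for (cr in c("A_mother", "B_mother")) {
    cons <- res$summary$conservation[[cr]]
    expect_equal(cons[["exon"]] + cons[["intron"]] + cons[["intergenic"]],
                 cons[["total"]])
    x <- res$counts[[cr]]
    expect_equal(cons[["total"]], sum(x$r_mat + x$r_pat))
  }
})

test_that("intron structure is derived as the gaps between exons", {
  g <- build_genome_pair(1, 3000, 0, seed = 1)
  ann <- GenomicRanges::GRanges(
    "chr01",
    IRanges::IRanges(c(101, 101, 101, 301, 601), c(700, 200, 150, 400, 700)),
    strand = "+",
    type = c("gene", "mRNA", "exon", "exon", "exon"),
    ID = c("g1", "g1.1", "g1.1.exon1", "g1.1.exon2", "g1.1.exon3"),
    Parent = c(NA, "g1", "g1.1", "g1.1", "g1.1"),
    gene_id = "g1"
  )
  GenomeInfoDb::seqlengths(ann) <- c(chr01 = 3000)
  units <- build_feature_units(ann)
  introns <- units$grl[[which(units$meta$kind == "intron")]]
  expect_equal(GenomicRanges::start(introns), c(151, 401))
  expect_equal(GenomicRanges::end(introns), c(300, 600))
})

test_that("isoforms with identical SNP support are collapsed and compound annotated", {
  b <- quick_bundle(seed = 29, isoform_prob = 1)
  counts <- normalize_between_crosses(lapply(
    c(A_mother = "A_mother", B_mother = "B_mother"),
    function(cr) aggregate_counts(assign_reads(
      preprocess_reads(b$reads[[cr]], "endosperm",
                       adaptor = b$config$adaptor)$reads,
      b$genomes, cr))
  ))
  fs <- feature_scan(b$annotation, counts, "endosperm")
  comp <- fs[fs$compound, , drop = FALSE]
  expect_gt(nrow(comp), 0)
  expect_true(all(grepl(";", comp$unit_id)))
  # collapsed isoforms appear only once
  iso_ids <- unlist(strsplit(fs$unit_id[fs$kind == "cdna_isoform"], ";"))
  expect_false(any(duplicated(iso_ids)))
})

test_that("planted intergenic maternal transcripts are recovered as intergenic units", {
  b <- quick_bundle(seed = 23, n_intergenic_maternal = 2L,
                    depth_median = 60, depth_sdlog = 0)
  res <- run_pipeline(b)
  ig_truth <- b$truth[startsWith(b$truth$feature_id, "igtx") & b$truth$testable, ]
  ig_calls <- res$features[res$features$kind == "intergenic", ]
  for (i in seq_len(nrow(ig_truth))) {
    hit <- ig_calls[ig_calls$chrom == ig_truth$chrom[i] &
                      ig_calls$start <= ig_truth$end[i] &
                      ig_calls$end >= ig_truth$start[i], ]
    expect_true("maternal_imprint" %in% as.character(hit$call))
  }
})

test_that("reconciliation labels windows by their feature support", {
  win <- data.frame(
    chrom = "chr01", start = c(100, 5000), end = c(1100, 6000),
    call = factor(c("maternal_imprint", "maternal_imprint"),
                  levels = levels(imprint_calls(1, 1, 1, 1, "embryo")$call)),
    stringsAsFactors = FALSE
  )
  feat <- data.frame(
    unit_id = "g1.1", kind = "cdna_isoform", gene_id = "g1",
    chrom = "chr01", start = 101, end = 700,
    call = factor("maternal_imprint",
                  levels = levels(win$call)),
    stringsAsFactors = FALSE
  )
  ann <- GenomicRanges::GRanges(
    "chr01", IRanges::IRanges(101, 700), strand = "+",
    type = "gene", ID = "g1", Parent = NA_character_, gene_id = "g1"
  )
  rec <- reconcile_scans(win, feat, ann)
  expect_equal(rec$windows$overlap, c("overlaps_candidate_feature", "intergenic"))
  expect_equal(rec$features$n_support_windows, 1)
  expect_equal(unname(rec$summary["n_window_intergenic"]), 1)
})

test_that("opposite parental bias in introns and exons flags a splicing candidate", {
  # one gene: paternal exonic reads, maternal intronic reads; a concordant
  # gene next to it must not be flagged
  g <- build_genome_pair(1, 6000, 0, seed = 2)
  ann <- GenomicRanges::GRanges(
    "chr01",
    IRanges::IRanges(c(101, 101, 101, 901, 2001, 2001, 2001),
                     c(1500, 1500, 800, 1500, 2900, 2900, 2900)),
    strand = "+",
    type = c("gene", "mRNA", "exon", "exon", "gene", "mRNA", "exon"),
    ID = c("g1", "g1.1", "g1.1.e1", "g1.1.e2", "g2", "g2.1", "g2.1.e1"),
    Parent = c(NA, "g1", "g1.1", "g1.1", NA, "g2", "g2.1"),
    gene_id = c("g1", "g1", "g1", "g1", "g2", "g2", "g2")
  )
  GenomeInfoDb::seqlengths(ann) <- c(chr01 = 6000)
  cnt <- function(ex_mat, ex_pat, in_mat, in_pat, g2_mat, g2_pat) {
    data.frame(chrom = "chr01", pos = c(500L, 850L, 2500L),
               r_mat = c(ex_mat, in_mat, g2_mat),
               r_pat = c(ex_pat, in_pat, g2_pat), stringsAsFactors = FALSE)
  }
  counts <- mk_counts(cnt(5L, 95L, 90L, 10L, 95L, 5L),
                      cnt(8L, 92L, 88L, 12L, 93L, 7L))
  fs <- feature_scan(ann, counts, "endosperm")
  sc <- poe_splicing_scan(fs, NULL, ann)
  expect_equal(sc$gene_id, "g1")
  expect_match(sc$maternal_parts, "introns")
  expect_match(sc$paternal_parts, "exons")
  # windows fully inside the gene may also contribute parts
  ws <- window_scan(c(chr01 = 6000), counts, "endosperm")
  sc2 <- poe_splicing_scan(fs, ws, ann)
  expect_equal(sc2$gene_id, "g1")
})
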