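# A hand-built 300 bp genome pair: SNPs at 60, 64 (close pair, so reads can
# span two SNPs), 150 and 220; positions 101-140 duplicated at 241-280 in
# both haplotypes so reads from that block multi-hit.
build_fixture <- function() {
  a <- rand_seq(300, seed = 77)
  substr(a, 241, 280) <- substr(a, 101, 140)
  b <- a
  snp_pos <- c(60L, 64L, 150L, 220L)
  for (p in snp_pos) {
    ref <- substr(a, p, p)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    b <- substitute_base(b, p, alt)
  }
  make_genome_pair(a, b)
}

test_that("a clean single-SNP read is assigned the right origin and allele", {
  g <- build_fixture()
  read_a <- substring(as.character(g$seq_a[[1]]), 200, 235) # covers SNP 220 only
  asA <- assign_reads(c(r1 = read_a), g, "A_mother")
  expect_equal(asA$status, "assigned")
  expect_equal(asA$pos, 220L)
  expect_equal(asA$allele, "A")
  expect_equal(asA$origin, "maternal")
  # the same allele is paternal in the reciprocal cross
  asB <- assign_reads(c(r1 = read_a), g, "B_mother")
  expect_equal(asB$origin, "paternal")
  # a read carrying the other subspecies allele
  read_b <- substring(as.character(g$seq_b[[1]]), 200, 235)
  expect_equal(assign_reads(c(r1 = read_b), g, "A_mother")$origin, "paternal")
})

test_that("assignment is strand-symmetric", {
  g <- build_fixture()
  read <- substring(as.character(g$seq_a[[1]]), 130, 165) # covers SNP 150
  fwd <- assign_reads(c(r = read), g, "A_mother")
  rev <- assign_reads(c(r = revcomp(read)), g, "A_mother")
  expect_equal(fwd$status, "assigned")
  expect_equal(fwd[, c("pos", "allele", "origin")],
               rev[, c("pos", "allele", "origin")])
  expect_equal(fwd$strand, "+")
  expect_equal(rev$strand, "-")
})

test_that("reads spanning two reported SNPs are rejected as multi_snp", {
  g <- build_fixture()
  read <- substring(as.character(g$seq_a[[1]]), 40, 75) # covers SNPs 60 and 64
  expect_equal(assign_reads(c(r = read), g, "A_mother")$status, "multi_snp")
})

test_that("reads from duplicated sequence are rejected as multi_hit", {
  g <- build_fixture()
  read <- substring(as.character(g$seq_a[[1]]), 103, 138) # inside duplicated block
  expect_equal(assign_reads(c(r = read), g, "A_mother")$status, "multi_hit")
})

test_that("reads covering no SNP match both genomes and are rejected", {
  g <- build_fixture()
  read <- substring(as.character(g$seq_a[[1]]), 1, 36) # before the first SNP
  expect_equal(assign_reads(c(r = read), g, "A_mother")$status,
               "zero_or_multi_mismatch")
})

test_that("a mismatch not at a reported SNP is rejected as such", {
  # haplotypes differ at 150 but the SNP table does not report it
  a <- rand_seq(300, seed = 78)
  b <- substitute_base(a, 150, setdiff(c("A", "C", "G", "T"),
                                       substr(a, 150, 150))[1])
  g <- make_genome_pair(a, b, snps = data.frame(
    chrom = character(), pos = integer(), allele_a = character(),
    allele_b = character(), stringsAsFactors = FALSE
  ))
  read <- substring(a, 130, 165)
  expect_equal(assign_reads(c(r = read), g, "A_mother")$status,
               "mismatch_not_snp")
})

test_that("unmappable reads and reads with N are no_hit", {
  g <- build_fixture()
  expect_equal(assign_reads(c(r = rand_seq(36, seed = 500)), g, "A_mother")$status,
               "no_hit")
  read <- substring(as.character(g$seq_a[[1]]), 200, 235)
  read_n <- paste0("N", substr(read, 2, 36))
  expect_equal(assign_reads(c(r = read_n), g, "A_mother")$status, "no_hit")
})

test_that("every simulated read lands in exactly one accept/reject bucket and assigned origins match the simulator truth", {
  b <- quick_bundle(seed = 13, adaptor_frac = 0)
  for (cr in c("A_mother", "B_mother")) {
    asg <- assign_reads(b$reads[[cr]], b$genomes, cr)
    expect_equal(sum(table(asg$status)), length(b$reads[[cr]]))
    expect_false(any(is.na(asg$status)))
    hit <- asg[asg$status == "assigned", ]
    truth <- b$read_info[[cr]][match(hit$id, b$read_info[[cr]]$id), ]
    expect_equal(hit$origin, truth$origin)
    expect_equal(hit$allele, truth$allele)
    expect_equal(hit$pos, truth$pos)
  }
})

test_that("aggregation counts reads per SNP and ignores input order", {
  asg <- data.frame(
    id = sprintf("r%d", 1:6),
    status = c(rep("assigned", 5), "no_hit"),
    chrom = "chr1", pos = c(10L, 10L, 10L, 10L, 10L, NA),
    strand = "+",
    allele = c("A", "A", "A", "B", "B", NA),
    origin = c("maternal", "maternal", "maternal", "paternal", "paternal", NA),
    stringsAsFactors = FALSE
  )
  cnt <- aggregate_counts(asg)
  expect_equal(cnt$r_mat_raw, 3L)
  expect_equal(cnt$r_pat_raw, 2L)
  shuffled <- aggregate_counts(asg[sample(nrow(asg)), ])
  expect_equal(cnt, shuffled)
  empty <- aggregate_counts(asg[asg$status == "none", ])
  expect_equal(nrow(empty), 0)
})

test_that("between-cross normalization follows the RPM x C rule", {
  mk <- function(mat, pat, cr) {
    x <- data.frame(chrom = "chr1", pos = seq_along(mat) * 100L,
                    r_mat_raw = mat, r_pat_raw = pat, stringsAsFactors = FALSE)
    attr(x, "cross_direction") <- cr
    x
  }
  # equal library totals leave counts unchanged
  eq <- normalize_between_crosses(list(
    A_mother = mk(c(30L, 20L), c(10L, 40L), "A_mother"),
    B_mother = mk(c(25L, 25L), c(25L, 25L), "B_mother")
  ))
  expect_equal(eq$A_mother$r_mat, c(30L, 20L))
  expect_equal(eq$A_mother$r_pat, c(10L, 40L))
  # library totals 4e6 and 2e6: C = 3, so 10 raw reads become 15
  un <- normalize_between_crosses(list(
    A_mother = mk(4000000L, 0L, "A_mother"),
    B_mother = mk(c(10L, 1999990L), c(0L, 0L), "B_mother")
  ))
  expect_equal(attr(un, "norm_constant"), 3)
  expect_equal(un$B_mother$r_mat[1], 15L)
  expect_equal(un$A_mother$r_pat, 0L)
  expect_error(normalize_between_crosses(list(
    A_mother = mk(0L, 0L, "A_mother"), B_mother = mk(1L, 0L, "B_mother")
  )), "zero library total")
})

test_that("normalization preserves per-SNP parental fractions up to rounding", {
  set.seed(6)
  mk <- function(n, cr, lambda) {
    x <- data.frame(chrom = "chr1", pos = seq_len(n) * 50L,
                    r_mat_raw = rpois(n, lambda), r_pat_raw = rpois(n, lambda / 2),
                    stringsAsFactors = FALSE)
    x <- x[x$r_mat_raw + x$r_pat_raw > 0, ]
    attr(x, "cross_direction") <- cr
    x
  }
  nn <- normalize_between_crosses(list(A_mother = mk(150, "A_mother", 40),
                                       B_mother = mk(150, "B_mother", 25)))
  for (cr in c("A_mother", "B_mother")) {
    x <- nn[[cr]]
    tot_n <- x$r_mat + x$r_pat
    ok <- tot_n > 0
    f_raw <- x$r_mat_raw / (x$r_mat_raw + x$r_pat_raw)
    f_norm <- x$r_mat / tot_n
    expect_true(all(abs(f_norm - f_raw)[ok] <= 1 / tot_n[ok] + 1e-12))
  }
})
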