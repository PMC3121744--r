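#' Expected maternal fraction of reads for a tissue
#'
#' The triploid endosperm carries two maternal and one paternal genome copy,
#' so under unbiased expression 2/3 of allele-informative reads are expected
#' to be maternal; the diploid embryo expects 1/2.
#'
#' @param tissue `"endosperm"` or `"embryo"`.
#' @return A single number, 2/3 or 1/2.
#' @export
maternal_fraction <- function(tissue = c("endosperm", "embryo")) {
  tissue <- match.arg(tissue)
  if (tissue == "endosperm") 2 / 3 else 1 / 2
}

#' Expected maternal and paternal read counts
#'
#' Proportions a total read count into the expected maternal:paternal
#' contributions for the tissue (2:1 in endosperm, 1:1 in embryo). Values are
#' real-valued and unrounded.
#'
#' @param r_total total (normalized) SNP read count; may be a vector, all > 0.
#' @inheritParams maternal_fraction
#' @return List with numeric components `mat` and `pat`.
#' @examples
#' expected_counts(300, "endosperm") # mat 200, pat 100
#' @export
expected_counts <- function(r_total, tissue = c("endosperm", "embryo")) {
  tissue <- match.arg(tissue)
  if (!is.numeric(r_total) || any(r_total <= 0)) {
    stop("r_total must be positive")
  }
  f <- maternal_fraction(tissue)
  list(mat = f * r_total, pat = (1 - f) * r_total)
}

#' Parental expression bias
#'
#' The bias of a feature is the fraction of its SNP reads attributed to each
#' parent: `b_mat = r_mat / (r_mat + r_pat)`. The bias reported for a call is
#' the fraction in the favored direction.
#'
#' @param r_mat,r_pat maternal and paternal (normalized) read counts;
#'   vectors of equal length, `r_mat + r_pat > 0`.
#' @return List with numeric components `b_mat` and `b_pat` summing to 1.
#' @export
bias_statistic <- function(r_mat, r_pat) {
  tot <- r_mat + r_pat
  if (any(tot <= 0)) stop("r_mat + r_pat must be positive")
  if (any(r_mat < 0) || any(r_pat < 0)) stop("counts must be non-negative")
  b <- r_mat / tot
  list(b_mat = b, b_pat = 1 - b)
}

#' Convert a chi-square statistic (df = 1) to -log10 P
#'
#' Computed in log space (`pchisq(log.p = TRUE)`) so that very large
#' statistics do not underflow to `-log10(0)`.
#'
#' @param chi2 non-negative chi-square statistic(s), 1 degree of freedom.
#' @return `-log10` of the upper-tail probability; 0 when `chi2 = 0`.
#' @export
neglog10p_from_chi2 <- function(chi2) {
  -stats::pchisq(chi2, df = 1, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' Pearson chi-square test of allelic counts against the tissue baseline
#'
#' Tests observed maternal/paternal read counts against the expected
#' 2:1 (endosperm) or 1:1 (embryo) split with a plain Pearson chi-square
#' statistic on the two categories (df = 1, no continuity correction).
#'
#' @inheritParams bias_statistic
#' @inheritParams maternal_fraction
#' @return List with numeric components `chi2` and `neglog10p`.
#' @examples
#' chi2_test(200, 100, "endosperm") # chi2 0: observed equals expected
#' @export
chi2_test <- function(r_mat, r_pat, tissue = c("endosperm", "embryo")) {
  tissue <- match.arg(tissue)
  tot <- r_mat + r_pat
  if (any(tot < 1)) stop("r_mat + r_pat must be at least 1")
  e <- expected_counts(tot, tissue)
  chi2 <- (r_mat - e$mat)^2 / e$mat + (r_pat - e$pat)^2 / e$pat
  list(chi2 = chi2, neglog10p = neglog10p_from_chi2(chi2))
}

#' Per-cross bias test for one feature
#'
#' Bundles counts, expected counts, bias fractions and the chi-square
#' significance for one feature in one cross.
#'
#' @inheritParams chi2_test
#' @return An object of class `bias_test`: a list with fields `r_mat`,
#'   `r_pat`, `r_total`, `expected_mat`, `b_mat`, `b_pat`, `chi2`,
#'   `neglog10p`, `direction` (`"maternal"`, `"paternal"` or `"none"`) and
#'   `tissue`.
#' @export
bias_test <- function(r_mat, r_pat, tissue = c("endosperm", "embryo")) {
  tissue <- match.arg(tissue)
  tot <- r_mat + r_pat
  if (length(tot) != 1L) stop("bias_test is scalar; see imprint_calls()")
  b <- bias_statistic(r_mat, r_pat)
  ct <- chi2_test(r_mat, r_pat, tissue)
  f <- maternal_fraction(tissue)
  dir <- if (b$b_mat > f) "maternal" else if (b$b_mat < f) "paternal" else "none"
  structure(
    list(
      r_mat = r_mat, r_pat = r_pat, r_total = tot,
      expected_mat = f * tot,
      b_mat = b$b_mat, b_pat = b$b_pat,
      chi2 = ct$chi2, neglog10p = ct$neglog10p,
      direction = dir, tissue = tissue
    ),
    class = "bias_test"
  )
}

#' @export
print.bias_test <- function(x, ...) {
  cat(sprintf(
    "bias_test (%s): %d mat / %d pat, b_mat = %.3f, chi2 = %.2f, -log10 P = %.2f (%s)\n",
    x$tissue, round(x$r_mat), round(x$r_pat), x$b_mat, x$chi2, x$neglog10p,
    x$direction
  ))
  invisible(x)
}

imprint_call_levels <- c(
  "maternal_imprint", "paternal_imprint",
  "subspecies_a_bias", "subspecies_b_bias",
  "unbiased", "low_coverage", "one_cross_candidate", "discordant"
)

#' Classify features from paired reciprocal-cross bias tests (vectorized)
#'
#' Applies the reciprocal-cross concordance rule to aligned count vectors
#' from the two crosses (subspecies A as mother, and subspecies B as mother):
#'
#' * A feature is maternally or paternally imprinted when both crosses are
#'   individually significant (`neglog10p >= threshold`) with the same
#'   parent-of-origin direction.
#' * When both crosses are significant but the direction flips with the
#'   cross, the same subspecies *allele* is favored in both, which is an
#'   allelic (subspecies) effect, not imprinting: `subspecies_a_bias` when
#'   allele A is favored, `subspecies_b_bias` when allele B is.
#' * A feature with fewer than `min_reads` normalized reads in one cross is
#'   a `one_cross_candidate` if the covered cross is significant, otherwise
#'   `low_coverage`; below `min_reads` in both crosses it is `low_coverage`.
#' * Everything else profiled in both crosses is `unbiased` (or `discordant`
#'   if significant in both crosses yet matching neither pattern).
#'
#' Combined bias and significance follow the minimum rule: both are taken
#' from the LESS significant cross, so the combined `neglog10p` is the
#' minimum of the two crosses and the combined bias is the favored-direction
#' read fraction of that same cross.
#'
#' @param r_mat_a,r_pat_a normalized maternal/paternal counts where
#'   subspecies A is the mother.
#' @param r_mat_b,r_pat_b counts where subspecies B is the mother.
#' @inheritParams maternal_fraction
#' @param min_reads minimum normalized reads per cross for a feature to be
#'   profiled (default 10).
#' @param threshold significance cutoff on `-log10 P` (default 1.3, i.e.
#'   P = 0.05); ties count as significant.
#' @return A data.frame with per-cross statistics (`b_mat_a`, `neglog10p_a`,
#'   `dir_a`, and the `_b` counterparts), the `call` (factor), and the
#'   combined `bias` and `neglog10p`.
#' @export
imprint_calls <- function(r_mat_a, r_pat_a, r_mat_b, r_pat_b,
                          tissue = c("endosperm", "embryo"),
                          min_reads = 10, threshold = 1.3) {
  tissue <- match.arg(tissue)
  n <- length(r_mat_a)
  stopifnot(
    length(r_pat_a) == n, length(r_mat_b) == n, length(r_pat_b) == n
  )
  f <- maternal_fraction(tissue)
  stat1 <- function(m, p) {
    tot <- m + p
    b <- ifelse(tot > 0, m / tot, NA_real_)
    e_mat <- f * tot
    chi2 <- ifelse(tot > 0, (m - e_mat)^2 / e_mat + (p - (tot - e_mat))^2 / (tot - e_mat), NA_real_)
    nlp <- ifelse(tot > 0, neglog10p_from_chi2(chi2), NA_real_)
    dir <- rep("none", length(m))
    dir[!is.na(b) & b > f] <- "maternal"
    dir[!is.na(b) & b < f] <- "paternal"
    list(tot = tot, b = b, chi2 = chi2, nlp = nlp, dir = dir)
  }
  a <- stat1(r_mat_a, r_pat_a)
  b <- stat1(r_mat_b, r_pat_b)

  sig_a <- !is.na(a$nlp) & a$nlp >= threshold
  sig_b <- !is.na(b$nlp) & b$nlp >= threshold
  low_a <- a$tot < min_reads
  low_b <- b$tot < min_reads

  call <- rep("unbiased", n)
  both_sig <- sig_a & sig_b
  call[both_sig] <- "discordant"
  call[both_sig & a$dir == "maternal" & b$dir == "maternal"] <- "maternal_imprint"
  call[both_sig & a$dir == "paternal" & b$dir == "paternal"] <- "paternal_imprint"
  # direction flips with the cross => the same subspecies allele is favored:
  # allele A is the maternal allele only when A is the mother.
  call[both_sig & a$dir == "maternal" & b$dir == "paternal"] <- "subspecies_a_bias"
  call[both_sig & a$dir == "paternal" & b$dir == "maternal"] <- "subspecies_b_bias"
  # coverage rules override significance-based calls
  call[(low_a & !low_b & !sig_b) | (low_b & !low_a & !sig_a)] <- "low_coverage"
  call[(low_a & !low_b & sig_b) | (low_b & !low_a & sig_a)] <- "one_cross_candidate"
  call[low_a & low_b] <- "low_coverage"

  # combined values from the less significant cross (minimum rule)
  bias_fav_a <- pmax(a$b, 1 - a$b)
  bias_fav_b <- pmax(b$b, 1 - b$b)
  use_a <- !is.na(a$nlp) & !is.na(b$nlp) & a$nlp <= b$nlp
  use_a[is.na(b$nlp)] <- TRUE
  use_a[is.na(a$nlp)] <- FALSE
  combined_nlp <- ifelse(use_a, a$nlp, b$nlp)
  combined_bias <- ifelse(use_a, bias_fav_a, bias_fav_b)

  data.frame(
    r_mat_a = r_mat_a, r_pat_a = r_pat_a,
    r_mat_b = r_mat_b, r_pat_b = r_pat_b,
    b_mat_a = a$b, chi2_a = a$chi2, neglog10p_a = a$nlp, dir_a = a$dir,
    b_mat_b = b$b, chi2_b = b$chi2, neglog10p_b = b$nlp, dir_b = b$dir,
    call = factor(call, levels = imprint_call_levels),
    bias = combined_bias, neglog10p = combined_nlp,
    stringsAsFactors = FALSE
  )
}

# supplementary BH-adjusted column over the combined P values; the calls
# themselves use the fixed per-feature threshold
add_bh_column <- function(df) {
  p <- 10^(-df$neglog10p)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  df$q_value <- q
  df
}

#' Classify one feature from its two per-cross bias tests
#'
#' Scalar wrapper around [imprint_calls()] matching the two reciprocal
#' crosses: `test_a` from the cross with subspecies A as mother, `test_b`
#' from the reciprocal cross.
#'
#' @param test_a,test_b [bias_test()] objects on normalized counts, same
#'   tissue.
#' @inheritParams imprint_calls
#' @return An object of class `imprint_call`: list with `call`, combined
#'   `bias` and `neglog10p`, and the two tests.
#' @export
classify_feature <- function(test_a, test_b, min_reads = 10, threshold = 1.3) {
  stopifnot(inherits(test_a, "bias_test"), inherits(test_b, "bias_test"))
  if (!identical(test_a$tissue, test_b$tissue)) {
    stop("the two crosses must come from the same tissue")
  }
  row <- imprint_calls(
    test_a$r_mat, test_a$r_pat, test_b$r_mat, test_b$r_pat,
    tissue = test_a$tissue, min_reads = min_reads, threshold = threshold
  )
  structure(
    list(
      call = as.character(row$call),
      bias = row$bias, neglog10p = row$neglog10p,
      test_a = test_a, test_b = test_b
    ),
    class = "imprint_call"
  )
}

#' @export
print.imprint_call <- function(x, ...) {
  cat(sprintf(
    "imprint_call: %s (combined bias %.2f, -log10 P %.2f)\n",
    x$call, x$bias, x$neglog10p
  ))
  invisible(x)
}
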