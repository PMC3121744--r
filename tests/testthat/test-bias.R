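test_that("expected counts split the total by the tissue ploidy ratio", {
  e <- expected_counts(300, "endosperm")
  expect_equal(e$mat, 200)
  expect_equal(e$pat, 100)
  e <- expected_counts(100, "embryo")
  expect_equal(e$mat, 50)
  expect_equal(e$pat, 50)
  e <- expected_counts(100, "endosperm")
  expect_equal(e$mat, 66.667, tolerance = 1e-4)
  expect_equal(e$pat, 33.333, tolerance = 1e-4)
  expect_error(expected_counts(0, "endosperm"), "positive")
})

test_that("bias statistic is the favored-parent read fraction", {
  expect_equal(bias_statistic(548, 0)$b_mat, 1.00)
  expect_equal(bias_statistic(200, 100)$b_mat, 0.667, tolerance = 1e-3)
  expect_equal(bias_statistic(66, 34)$b_pat, 0.34)
  b <- bias_statistic(c(10, 5), c(30, 5))
  expect_equal(b$b_mat + b$b_pat, c(1, 1))
  expect_error(bias_statistic(0, 0))
})

test_that("chi-square matches the normal-tail closed form and never underflows", {
  ct <- chi2_test(200, 100, "endosperm")
  expect_equal(ct$chi2, 0)
  expect_equal(ct$neglog10p, 0)
  ct <- chi2_test(100, 0, "endosperm")
  expect_equal(ct$chi2, 50)
  # df = 1 survival equals erfc(sqrt(x/2)) = 2 * pnorm(-sqrt(x))
  expect_equal(ct$neglog10p, -log10(2 * pnorm(-sqrt(50))), tolerance = 1e-10)
  # embryo 60:40 against 1:1
  ct <- chi2_test(60, 40, "embryo")
  expect_equal(ct$chi2, (60 - 50)^2 / 50 + (40 - 50)^2 / 50)
  # huge statistics stay finite in log space
  big <- neglog10p_from_chi2(1e4)
  expect_true(is.finite(big) && big > 2000)
})

test_that("the significance cutoff corresponds to P = 0.05", {
  expect_equal(neglog10p_from_chi2(qchisq(0.95, df = 1)), -log10(0.05),
               tolerance = 1e-10)
  expect_equal(round(-log10(0.05), 2), 1.30)
})

test_that("concordant significant bias in both crosses is an imprint call", {
  mm <- classify_feature(bias_test(95, 5, "endosperm"),
                         bias_test(90, 10, "endosperm"))
  expect_equal(mm$call, "maternal_imprint")
  expect_equal(mm$neglog10p, min(mm$test_a$neglog10p, mm$test_b$neglog10p))
  pp <- classify_feature(bias_test(5, 95, "endosperm"),
                         bias_test(10, 90, "endosperm"))
  expect_equal(pp$call, "paternal_imprint")
  # combined values come from the less significant cross
  expect_equal(mm$bias, 0.9)
})

test_that("direction flipping with the cross is a subspecies call", {
  # allele A favored: maternal when A is mother, paternal when B is mother
  sa <- classify_feature(bias_test(90, 10, "endosperm"),
                         bias_test(10, 90, "endosperm"))
  expect_equal(sa$call, "subspecies_a_bias")
  sb <- classify_feature(bias_test(5, 95, "endosperm"),
                         bias_test(95, 5, "endosperm"))
  expect_equal(sb$call, "subspecies_b_bias")
})

test_that("coverage rules yield low_coverage and one_cross_candidate", {
  # 6 normalized reads in one cross, clear signal in the other
  oc <- classify_feature(bias_test(95, 5, "endosperm"),
                         bias_test(6, 0, "endosperm"))
  expect_equal(oc$call, "one_cross_candidate")
  lc <- classify_feature(bias_test(4, 2, "endosperm"),
                         bias_test(3, 1, "endosperm"))
  expect_equal(lc$call, "low_coverage")
  # low in one cross, present but unremarkable in the other
  lc2 <- classify_feature(bias_test(5, 1, "endosperm"),
                          bias_test(40, 20, "endosperm"))
  expect_equal(lc2$call, "low_coverage")
  ub <- classify_feature(bias_test(40, 20, "endosperm"),
                         bias_test(41, 19, "endosperm"))
  expect_equal(ub$call, "unbiased")
})

test_that("a feature exactly at the threshold counts as significant", {
  nlp <- chi2_test(25, 5, "endosperm")$neglog10p
  at <- imprint_calls(25, 5, 25, 5, "endosperm", threshold = nlp)
  expect_equal(as.character(at$call), "maternal_imprint")
  above <- imprint_calls(25, 5, 25, 5, "endosperm", threshold = nlp + 1e-9)
  expect_equal(as.character(above$call), "unbiased")
})

test_that("combined evidence is never more significant than either cross", {
  set.seed(42)
  m_a <- rbinom(200, 60, 0.7); m_b <- rbinom(200, 80, 0.6)
  calls <- imprint_calls(m_a, 60 - m_a, m_b, 80 - m_b, "endosperm")
  expect_true(all(calls$neglog10p <= calls$neglog10p_a + 1e-12))
  expect_true(all(calls$neglog10p <= calls$neglog10p_b + 1e-12))
  expect_equal(calls$neglog10p, pmin(calls$neglog10p_a, calls$neglog10p_b))
})

test_that("swapping parental labels mirrors the calls (embryo, 1:1)", {
  set.seed(7)
  tot <- rep(80, 300)
  m_a <- rbinom(300, tot, runif(300, 0.1, 0.9))
  m_b <- rbinom(300, tot, runif(300, 0.1, 0.9))
  orig <- imprint_calls(m_a, tot - m_a, m_b, tot - m_b, "embryo")
  swap <- imprint_calls(tot - m_a, m_a, tot - m_b, m_b, "embryo")
  map <- c(maternal_imprint = "paternal_imprint",
           paternal_imprint = "maternal_imprint",
           subspecies_a_bias = "subspecies_b_bias",
           subspecies_b_bias = "subspecies_a_bias",
           unbiased = "unbiased", low_coverage = "low_coverage",
           one_cross_candidate = "one_cross_candidate",
           discordant = "discordant")
  expect_equal(as.character(swap$call), unname(map[as.character(orig$call)]))
  # subspecies-ness itself (an allelic property) is label-swap invariant
  sub <- c("subspecies_a_bias", "subspecies_b_bias")
  expect_equal(as.character(orig$call) %in% sub,
               as.character(swap$call) %in% sub)
})

test_that("null rejection rate per cross is near the nominal 5%", {
  set.seed(123)
  for (depth in c(30, 200)) {
    m <- rbinom(4000, depth, 2 / 3)
    nlp <- chi2_test(m, depth - m, "endosperm")$neglog10p
    rate <- mean(nlp >= 1.3)
    expect_gte(rate, 0.03)
    expect_lte(rate, 0.08)
  }
})

test_that("chi-square agrees with the exact binomial mid-P test at depth >= 100", {
  for (tot in c(100, 250, 600)) {
    for (m in 0:tot) {
      p_chi <- 10^(-chi2_test(m, tot - m, "endosperm")$neglog10p)
      expect_lt(abs(p_chi - binom_midp(m, tot, 2 / 3)), 0.01)
    }
  }
})
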