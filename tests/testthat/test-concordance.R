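test_that("2x2 tallies match a brute-force loop and drop unknowns", {
  set.seed(50)
  test <- sample(c("positive", "negative", NA), 50, replace = TRUE,
                 prob = c(0.3, 0.6, 0.1))
  ref <- sample(c("positive", "negative", NA), 50, replace = TRUE,
                prob = c(0.25, 0.65, 0.1))
  t <- build_table(test, ref)
  a <- b <- c_ <- d <- 0
  for (i in 1:50) {
    if (is.na(test[i]) || is.na(ref[i])) next
    tp <- test[i] == "positive"; rp <- ref[i] == "positive"
    if (tp && rp) a <- a + 1 else if (tp) b <- b + 1
    else if (rp) c_ <- c_ + 1 else d <- d + 1
  }
  expect_equal(c(t$a, t$b, t$c, t$d), c(a, b, c_, d))
  expect_equal(t$n + t$n_dropped, 50)
  expect_error(build_table(c(NA, NA), c("positive", NA)), "no samples")
  tt <- build_table(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(c(tt$b, tt$c), c(0, 0))
})

test_that("kappa reproduces the reconstructed assay comparisons", {
  # nCounter vs DNA-NGS for skipping: 5 both-positive, 3 nCounter-only,
  # 192 both-negative
  expect_equal(round(cohens_kappa(table2x2(5, 3, 0, 192)), 2), 0.76)
  # nCounter vs RT-PCR: 13 both-positive, 11 RT-PCR-only, 88 both-negative
  expect_equal(round(cohens_kappa(table2x2(13, 0, 11, 88)), 2), 0.65)
  expect_equal(cohens_kappa(table2x2(10, 0, 0, 10)), 1)
  # hand evaluation of the formula as an independent check
  po <- 101 / 112
  pe <- (13 * 24 + 99 * 88) / 112^2
  expect_equal(cohens_kappa(table2x2(13, 0, 11, 88)), (po - pe) / (1 - pe),
               tolerance = 1e-12)
})

test_that("kappa is bounded, symmetric, and matches resampled expectation", {
  set.seed(60)
  for (i in 1:25) {
    cells <- rmultinom(1, sample(20:200, 1), prob = runif(4, 0.05, 1))
    t <- table2x2(cells[1], cells[2], cells[3], cells[4])
    k <- cohens_kappa(t)
    if (is.na(k)) next
    expect_gte(k, -1); expect_lte(k, 1)
    # swapping test/reference transposes b and c: kappa unchanged
    expect_equal(cohens_kappa(table2x2(t$a, t$c, t$b, t$d)), k)
    if (k == 1) expect_equal(c(t$b, t$c), c(0, 0))
  }
  # Monte-Carlo expected agreement (independent raters with the observed
  # marginals) agrees with the analytic p_e
  t <- table2x2(12, 7, 4, 40)
  set.seed(61)
  p_test <- (t$a + t$b) / t$n
  p_ref <- (t$a + t$c) / t$n
  draws <- 1e5
  sim_agree <- mean((runif(draws) < p_test) == (runif(draws) < p_ref))
  pe <- ((t$a + t$b) * (t$a + t$c) + (t$c + t$d) * (t$b + t$d)) / t$n^2
  expect_equal(sim_agree, pe, tolerance = 0.01)
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  for (cells in list(c(5, 3, 0, 192), c(13, 0, 11, 88), c(12, 7, 4, 40))) {
    t <- table2x2(cells[1], cells[2], cells[3], cells[4])
    m <- matrix(c(t$a, t$c, t$b, t$d), 2)
    expect_equal(cohens_kappa(t), e1071::classAgreement(m)$kappa,
                 tolerance = 1e-10)
  }
})

test_that("Wilson intervals reproduce printed repeatability and RT-PCR CIs", {
  # 28 of 29 concordant repeats -> 96.6% (82.8-99.4)
  ci <- wilson_ci(28, 29)
  expect_equal(round(100 * unname(ci), 1), c(96.6, 82.8, 99.4))
  # 101 of 112 -> 90.2% (83.3-94.4)
  pa <- percent_agreement(table2x2(13, 0, 11, 88))
  expect_equal(round(100 * unname(pa), 1), c(90.2, 83.3, 94.4))
})

test_that("Wilson interval is valid and matches the score-test oracle", {
  cases <- rbind(c(28, 29), c(101, 112), c(0, 10), c(10, 10), c(1, 1),
                 c(3, 7), c(50, 100))
  for (i in seq_len(nrow(cases))) {
    k <- cases[i, 1]; n <- cases[i, 2]
    ci <- wilson_ci(k, n)
    expect_gte(ci["estimate"], ci["lower"])
    expect_lte(ci["estimate"], ci["upper"])
    expect_gte(ci["lower"], 0); expect_lte(ci["upper"], 1)
    if (k == n) expect_equal(unname(ci["upper"]), 1)
    if (k == 0) expect_equal(unname(ci["lower"]), 0)
    # oracle: the score interval from prop.test without continuity correction
    or <- suppressWarnings(prop.test(k, n, correct = FALSE)$conf.int)
    expect_equal(unname(ci[c("lower", "upper")]), as.numeric(or),
                 tolerance = 1e-10)
    # exact alternative matches binom.test
    cp <- clopper_pearson_ci(k, n)
    expect_equal(unname(cp[c("lower", "upper")]),
                 as.numeric(binom.test(k, n)$conf.int), tolerance = 1e-12)
  }
})

test_that("agreement percentages reproduce the FISH and NGS comparisons", {
  expect_equal(round(100 * percent_agreement(table2x2(5, 0, 3, 32))[["proportion"]], 1),
               92.5)  # 37 of 40 vs FISH MET/CEP7
  expect_equal(round(100 * percent_agreement(table2x2(13, 0, 2, 65))[["proportion"]], 1),
               97.5)  # 78 of 80 vs NGS amplification
})

test_that("sensitivity and specificity swap with orientation", {
  t <- table2x2(13, 0, 11, 88)
  ss <- sens_spec(t)
  expect_equal(unname(ss$sensitivity["estimate"]), 13 / 24)
  expect_equal(unname(ss$specificity["estimate"]), 1)
  # reversing the reference: NGS detected 5 of 8 nCounter positives
  t2 <- table2x2(5, 3, 0, 192)
  flipped <- table2x2(t2$a, t2$c, t2$b, t2$d)
  expect_equal(unname(sens_spec(flipped)$sensitivity["estimate"]), 5 / 8)
  # orientation swap exchanges the two proportions when the table is
  # transposed
  ss_f <- sens_spec(table2x2(t$a, t$c, t$b, t$d))
  expect_equal(unname(ss_f$sensitivity["estimate"]), 13 / 13)
  expect_equal(unname(ss_f$specificity["estimate"]), 88 / 99)
  # b = c = 0 gives perfect operating characteristics
  ss_p <- sens_spec(table2x2(4, 0, 0, 20))
  expect_equal(unname(ss_p$sensitivity["estimate"]), 1)
  expect_equal(unname(ss_p$specificity["estimate"]), 1)
})

test_that("the agreement report annotates qualitative kappa bands", {
  rep <- agreement_report(list(
    ngs_dex14 = table2x2(5, 3, 0, 192),
    rtpcr = table2x2(13, 0, 11, 88)))
  expect_equal(rep$kappa_band[rep$comparison == "ngs_dex14"], "substantial")
  expect_equal(rep$kappa_band[rep$comparison == "rtpcr"], "substantial")
  expect_equal(round(rep$agreement_pct, 1), c(98.5, 90.2))
  expect_equal(kappa_band(c(0.1, 0.3, 0.5, 0.7, 0.9)),
               c("slight", "fair", "moderate", "substantial",
                 "almost perfect"))
  expect_error(agreement_report(list()), ">= 1")
})
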