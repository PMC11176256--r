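test_that("allele frequency is the count ratio, with absent variants at 0", {
  expect_equal(allele_frequency(8, 1552226), 8 / 1552226)
  expect_equal(signif(allele_frequency(8, 1552226), 1), 5e-06)
  expect_equal(format_allele_frequency(allele_frequency(8, 1552226)),
               "5e-06")
  expect_equal(allele_frequency(0, 1e5), 0)
  expect_equal(allele_frequency(10, 20), 0.5)
  expect_error(allele_frequency(0, 0), "allele_number")
  expect_error(allele_frequency(5, 4), "allele_count")
})

test_that("variant records enforce their count invariants", {
  expect_error(variant_records("G", "c.1A>T", "K1N", "missense", 5, 4),
               "allele_count")
  expect_error(variant_records("G", "c.1A>T", "K1N", "missense", 3, 100,
                               homozygote_count = 2), "homozygote")
  expect_error(variant_records("G", "c.1A>T", "K1N", "nonsense_class",
                               1, 100), "consequence")
})

test_that("the qualifying filter keeps the five-variant worked example", {
  ex <- unc93b1_example_cohort()
  qual <- select_qualifying(ex$variants, filter_criteria(),
                            ex$damage_scores)
  expect_equal(nrow(qual), 5)
  expect_equal(qual$protein_change, ex$variants$protein_change)
})

test_that("frequency, consequence, and damage filters apply as stated", {
  v <- variant_records(
    gene = "G",
    coding_change = sprintf("c.%dA>T", 1:4),
    protein_change = c("A1T", "A2T", "A3T", "A4T"),
    consequence = c("synonymous", "missense", "missense", "missense"),
    allele_count = c(0L, 10L, 9L, 0L),
    allele_number = c(1000000L, 1000000L, 1000000L, 1000000L))
  qual <- select_qualifying(v, filter_criteria())
  # synonymous excluded at frequency 0; MAF exactly 1e-5 excluded (strict);
  # MAF 9e-6 and the absent variant retained
  expect_equal(qual$protein_change, c("A3T", "A4T"))

  # damage filter: threshold is inclusive; missing score errors loudly
  scores <- c("G:A3T" = 0.70, "G:A4T" = 0.69)
  qual2 <- select_qualifying(v, filter_criteria(), scores)
  expect_equal(qual2$protein_change, "A3T")
  expect_error(select_qualifying(v, filter_criteria(),
                                 c("G:A3T" = 0.9)), "A4T")
})

test_that("the qualifying filter is idempotent and order-preserving", {
  sim <- simulate_cohort(cohort_sim_spec(n_kindreds = 40,
                                         carrier_prob = 0.3, seed = 11))
  q1 <- select_qualifying(sim$variants, filter_criteria())
  q2 <- select_qualifying(q1, filter_criteria())
  expect_identical(q1, q2)
  expect_true(!is.unsorted(match(q1$id, sim$variants$id)))
})

test_that("carrier kindreds count once regardless of zygosity or variant count", {
  g <- matrix(0L, 4, 2, dimnames = list(paste0("K", 1:4), c("v1", "v2")))
  g["K1", "v1"] <- 2L          # homozygous: still one carrier
  g["K2", c("v1", "v2")] <- 1L # two distinct variants: still one carrier
  cc <- cohort_carrier_count(g)
  expect_equal(cc$k, 2L)
  expect_equal(cc$n, 4L)

  ex <- unc93b1_example_cohort()
  cc <- cohort_carrier_count(ex$genotypes)
  expect_equal(cc$k, 5L)
  expect_equal(cc$n, 63L)
  expect_equal(sprintf("%.1f%%", 100 * cc$carrier_freq), "7.9%")

  # zero qualifying variants is a valid degenerate input
  expect_equal(cohort_carrier_count(g[, 0, drop = FALSE])$k, 0L)
})

test_that("background carrier frequency follows the Hardy-Weinberg product form", {
  one <- variant_records("G", "c.1A>T", "A1T", "missense",
                         allele_count = 2000L, allele_number = 1000000L)
  # p = 0.002 is above the default MAF bound; relax it for the closed form
  crit <- filter_criteria(max_maf = 0.01)
  expect_equal(background_carrier_frequency(one, crit),
               2 * 0.002 * 0.998 + 0.002^2, tolerance = 1e-12)

  two <- variant_records("G", c("c.1A>T", "c.2A>T"), c("A1T", "A2T"),
                         "missense", allele_count = c(1L, 1L),
                         allele_number = 1000000L)
  p0 <- background_carrier_frequency(two, filter_criteria())
  ci <- 2 * 1e-6 * (1 - 1e-6) + 1e-12
  expect_equal(p0, 1 - (1 - ci)^2, tolerance = 1e-10)
  expect_equal(p0, 4e-6, tolerance = 1e-3)

  syn <- variant_records("G", "c.3A>T", "A3T", "synonymous", 1L, 1000000L)
  expect_warning(p_empty <- background_carrier_frequency(syn), "no qualifying")
  expect_equal(p_empty, 0)
})

test_that("exact binomial tail matches brute-force summation and closed forms", {
  expect_equal(burden_test(0, 50, 0.01)$p_value, 1)
  expect_equal(burden_test(20, 20, 0.5)$p_value, 0.5^20, tolerance = 1e-12)
  for (n in c(3, 17, 63, 128, 200)) {
    for (p0 in c(0.004, 0.05, 0.5, 0.9)) {
      for (k in unique(c(1, 2, ceiling(n / 3), n - 1, n))) {
        expected <- brute_binom_tail(k, n, p0)
        got <- burden_test(k, n, p0)$p_value
        expect_equal(got, expected, tolerance = 1e-10,
                     label = sprintf("tail(k=%d, n=%d, p=%g)", k, n, p0))
      }
    }
  }
})

test_that("burden p-value is monotone in k and in p0", {
  p_by_k <- vapply(0:20, function(k) burden_test(k, 63, 0.05)$p_value,
                   numeric(1))
  expect_true(all(diff(p_by_k) <= 1e-12))
  p_by_p0 <- vapply(c(0.001, 0.01, 0.05, 0.2, 0.5),
                    function(p0) burden_test(5, 63, p0)$p_value, numeric(1))
  expect_true(all(diff(p_by_p0) >= -1e-12))
})

test_that("burden fold enrichment and result invariants hold", {
  res <- burden_test(5, 63, 0.004)
  expect_equal(res$fold_enrichment, (5 / 63) / 0.004)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_error(burden_test(5, 63, 0), "p0")
  expect_error(burden_test(5, 63, 1), "p0")
  expect_error(burden_test(70, 63, 0.01), "k <= n")
  fis <- burden_test(5, 63, 0.004, method = "fisher",
                     background_carriers = 400, background_n = 100000)
  expect_true(fis$p_value > 0 && fis$p_value < 1)
  expect_output(print(res), "fold enrichment")
})
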