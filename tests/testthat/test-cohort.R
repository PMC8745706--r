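test_that("healthy-control summaries suggest the conservative threshold", {
  flat <- healthy_threshold_summary(c(1, 1, 1))
  expect_equal(flat$mean, 1)
  expect_equal(flat$sem, 0)

  # published healthy range: always floored at 2
  hc <- c(0.72, 0.95, 1.02, 1.10, 1.21, 1.33)
  s <- healthy_threshold_summary(hc)
  expect_equal(s$min, 0.72)
  expect_equal(s$max, 1.33)
  expect_equal(s$sem, stats::sd(hc) / sqrt(6), tolerance = 1e-12)
  expect_equal(s$suggested_threshold, 2)

  # a healthy max above 2 pushes the threshold up, never down
  expect_equal(healthy_threshold_summary(c(1, 2.34))$suggested_threshold,
               2.4)
  expect_error(healthy_threshold_summary(1.0), "at least 2")
})

test_that("Fisher exact p reproduces the published treatment associations", {
  p <- vapply(names(table4), function(g)
    fisher_exact_2x2(table4[[g]])$p_two_sided, numeric(1))
  expect_equal(round(p[["chemo"]], 2), 0.42)
  expect_equal(round(p[["chemo_and_enz_abi"]], 2), 0.56)
  # the Enz/Abi table is its margins' modal table: p is exactly 1
  expect_lte(abs(p[["enz_abi"]] - table4_printed_p[["enz_abi"]]), 0.01)
  # agreement with the stats::fisher.test route
  for (g in names(table4))
    expect_equal(fisher_exact_2x2(table4[[g]])$p_two_sided,
                 stats::fisher.test(table4[[g]])$p.value, tolerance = 1e-9)
})

test_that("Fisher exact equals the margin-enumeration oracle on small tables", {
  # exhaustive over all 2x2 tables with grand total <= 20
  worst <- 0
  for (n in 1:20) for (r1 in 0:n) for (c1 in 0:n) {
    lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
    for (a in lo:hi) {
      tab <- rbind(c(a, r1 - a), c(c1 - a, n - r1 - (c1 - a)))
      worst <- max(worst, abs(fisher_exact_2x2(tab)$p_two_sided -
                                oracle_fisher_p(tab)))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("Fisher p is invariant under transposition and row+column swap", {
  set.seed(5)
  for (i in 1:25) {
    tab <- matrix(stats::rpois(4, 6), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_2x2(tab)$p_two_sided
    expect_equal(fisher_exact_2x2(t(tab))$p_two_sided, p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1])$p_two_sided, p,
                 tolerance = 1e-12)
  }
  # degenerate cases
  expect_equal(fisher_exact_2x2(rbind(c(0, 0), c(5, 5)))$p_two_sided, 1)
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "all-zero")
  expect_true(is.infinite(fisher_exact_2x2(rbind(c(3, 0), c(2, 4)))$odds_ratio))
  or <- fisher_exact_2x2(rbind(c(5, 4), c(7, 14)))$odds_ratio
  expect_equal(or, 5 * 14 / (4 * 7), tolerance = 1e-12)
})

test_that("Mann-Whitney matches full permutation enumeration when exact", {
  res <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_identical(res$U, 0)
  expect_equal(res$p_two_sided, 0.1, tolerance = 1e-12)

  set.seed(9)
  for (i in 1:10) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    x <- sample(seq(1, 200, by = 0.5), na + nb)  # tie-free
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    res <- mann_whitney(a, b)
    expect_true(res$exact)
    expect_equal(res$p_two_sided, oracle_mw_p(a, b), tolerance = 1e-9)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("Mann-Whitney holds its size under the null and separates shifted groups", {
  set.seed(42)
  null_ok <- vapply(1:100, function(i) {
    a <- stats::rnorm(8); b <- stats::rnorm(8)
    mann_whitney(a, b)$p_two_sided > 0.05
  }, logical(1))
  expect_gte(mean(null_ok), 0.95)

  # well-separated amplified vs healthy CN distributions
  set.seed(1)
  amp <- stats::rlnorm(12, log(10), 0.5) + 2
  healthy <- stats::rnorm(12, 1, 0.1)
  expect_lt(mann_whitney(amp, healthy)$p_two_sided, 0.0005)
})

test_that("Pearson correlation handles identity, inversion and degenerate input", {
  x <- c(1, 3, 4, 7, 9.5)
  expect_equal(pearson_correlation(x, x)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson_correlation(x, rep(2, 5)), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "length >= 3")
})

test_that("treatment tables rebuild the published marginals from records", {
  cohort <- make_treatment_cohort()
  expect_identical(nrow(cohort), 30L)
  for (g in names(table4)) {
    tab <- build_table4(cohort, g)
    expect_equal(unname(tab), unname(table4[[g]]), ignore_attr = TRUE)
    expect_identical(sum(tab), 30L)  # counts conserved
  }
})

test_that("records with missing flags or discordant calls are excluded with warnings", {
  cohort <- make_treatment_cohort()
  cohort$chemo[1] <- NA
  expect_warning(tab <- build_table4(cohort, "chemo"),
                 "missing treatment")
  expect_identical(sum(tab), 29L)
  expect_identical(attr(tab, "n_excluded_missing"), 1L)

  cohort2 <- make_treatment_cohort()
  cohort2$cn_assay2[1] <- 1  # assay-1 high, assay-2 normal
  expect_warning(tab2 <- build_table4(cohort2, "chemo"), "discordant")
  expect_identical(sum(tab2), 29L)

  expect_error(build_table4(make_treatment_cohort()[0, ], "chemo"),
               "empty cohort")
  expect_error(cohort_record("H1", "male", "healthy", 1, 1, chemo = TRUE),
               "healthy records")
})
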