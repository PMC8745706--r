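test_that("the mutation-assay CN formula reproduces the published cell-line table", {
  for (i in seq_len(nrow(table2))) {
    r <- table2[i, ]
    res <- ar_cn_amp1(r$mt, r$wt, r$rpp30, mixture = r$mixture)
    expect_equal(res$ar_ref_ratio, (r$wt + r$mt) / r$rpp30,
                 tolerance = 1e-12)
    expect_equal(res$cn, 2 * (r$wt + r$mt) / r$rpp30, tolerance = 1e-12)
    # published ratios are printed to 2 dp (from unrounded raw data)
    expect_lt(abs(res$ar_ref_ratio - r$ratio), 0.011)
  }
  # no AR template at all
  expect_identical(ar_cn_amp1(0, 0, 50)$cn, 0)
  expect_error(ar_cn_amp1(10, 10, 0), "no reference signal")
})

test_that("the two-amplicon CN formula applies the MYM* hemizygosity rule", {
  for (i in seq_len(nrow(table3))) {
    r <- table3[i, ]
    res <- ar_cn_amp2(r$x1, r$x2, r$mym_star, r$tbp, sex = r$sex,
                      mym_is_star = TRUE)
    expect_identical(res$cn_display, r$cn_display)
  }
  # raw-reading path: male doubling is applied internally
  raw <- ar_cn_amp2(696, 709, 34.5, 54, sex = "male")
  star <- ar_cn_amp2(696, 709, 69, 54, sex = "male", mym_is_star = TRUE)
  expect_equal(raw$cn, star$cn, tolerance = 1e-12)
  # female samples use the raw reading, no doubling
  fem <- ar_cn_amp2(73, 72.6, 75, 73.1, sex = "female")
  expect_equal(fem$cn, 2 * 145.6 / 148.1, tolerance = 1e-12)

  expect_identical(ar_cn_amp2(0, 0, 30, 60, "male")$cn, 0)
  expect_error(ar_cn_amp2(10, 10, 0, 0, "male"), "no reference signal")
})

test_that("Chr X CN uses the raw MYM reading against TBP", {
  # normal male: raw MYM ~ half of TBP -> Chr X CN ~ 1
  expect_equal(chrx_cn(42.3, 87)$chrx_cn, 2 * 42.3 / 87, tolerance = 1e-12)
  expect_lt(chrx_cn(42.3, 87)$chrx_cn, 2)
  expect_identical(chrx_cn(0, 50)$chrx_cn, 0)
  # whole-X amplified patient: raw MYM at 2.15x TBP
  amp <- chrx_cn(2.15 * 87, 87)
  expect_equal(amp$chrx_cn, 4.30, tolerance = 1e-12)
  expect_true(amp$amplified)
  expect_error(chrx_cn(10, 0), "no reference signal")
  expect_warning(chrx_cn(50, 50, sex = "female"), "female")
})

test_that("T877A calls report mutant fraction and a droplet-count floor", {
  pure <- t877a_call(114, 0)
  expect_identical(pure$mutant_fraction, 1)
  expect_true(pure$detected)

  mix <- t877a_call(30.1, 16.2)
  expect_equal(mix$mutant_fraction, 30.1 / 46.3, tolerance = 1e-12)
  expect_equal(round(mix$mutant_fraction, 3), 0.650)

  wtonly <- t877a_call(0, 100)
  expect_identical(wtonly$mutant_fraction, 0)
  expect_false(wtonly$detected)

  none <- t877a_call(0, 0)
  expect_true(is.na(none$mutant_fraction))

  # the droplet floor gates detection when counts are available
  mt2 <- poisson_concentration(2, 20000, target = "MT")
  mt3 <- poisson_concentration(3, 20000, target = "MT")
  wt <- poisson_concentration(500, 20000, target = "WT")
  expect_false(t877a_call(mt2, wt)$detected)
  expect_true(t877a_call(mt3, wt)$detected)
})

test_that("amplification classification is boundary-inclusive at the threshold", {
  expect_false(classify_amplification(1.92))
  expect_true(classify_amplification(2.0))
  expect_true(classify_amplification(48.13))
  expect_false(classify_amplification(2.49, threshold = 2.5))
  expect_true(classify_amplification(2.5, threshold = 2.5))
})

test_that("CN is invariant under global concentration scaling", {
  set.seed(13)
  for (rep in 1:20) {
    k <- stats::runif(1, 0.01, 1000)
    mt <- stats::runif(1, 0, 50); wt <- stats::runif(1, 0, 800)
    rp <- stats::runif(1, 10, 300)
    expect_equal(ar_cn_amp1(k * mt, k * wt, k * rp)$cn,
                 ar_cn_amp1(mt, wt, rp)$cn, tolerance = 1e-9)
    x1 <- stats::runif(1, 0, 800); x2 <- stats::runif(1, 0, 800)
    mym <- stats::runif(1, 5, 200); tbp <- stats::runif(1, 5, 200)
    expect_equal(ar_cn_amp2(k * x1, k * x2, k * mym, k * tbp, "male")$cn,
                 ar_cn_amp2(x1, x2, mym, tbp, "male")$cn, tolerance = 1e-9)
    expect_equal(chrx_cn(k * mym, k * tbp)$chrx_cn,
                 chrx_cn(mym, tbp)$chrx_cn, tolerance = 1e-9)
  }
})

test_that("display rounding is half-up, integer for pure and 1 dp for low mixtures", {
  expect_identical(round_half_up(0.5), 1)
  expect_identical(round_half_up(2.5), 3)
  expect_identical(round_half_up(6.85, 1), 6.9)
  expect_identical(ar_cn_amp1(0, 198, 51.5)$cn_display, 8)
  expect_identical(ar_cn_amp1(20.4, 191, 61.7, mixture = TRUE)$cn_display,
                   6.9)
})

test_that("cross-validation reports concordance and relative difference", {
  amp_amp <- cross_validate(ar_cn_amp1(0, 721, 52.5),
                            ar_cn_amp2(696, 709, 69, 54, "male",
                                       mym_is_star = TRUE))
  expect_identical(amp_amp$status, "concordant-amplified")
  expect_lt(amp_amp$relative_difference, 0.25)

  nn <- cross_validate(ar_cn_amp1(0, 45.4, 90),
                       ar_cn_amp2(45.9, 42, 84.6, 87, "male",
                                  mym_is_star = TRUE))
  expect_identical(nn$status, "concordant-normal")

  dis <- cross_validate(ar_cn_amp1(0, 75, 100),   # cn 1.5
                        ar_cn_amp2(125, 125, 50, 100, "male"))  # cn 2.5
  expect_identical(dis$status, "discordant")
  expect_false(dis$concordant)
})
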