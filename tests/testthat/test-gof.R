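test_that("KS statistic matches closed forms and a brute-force oracle", {
  u01 <- noise_spec("uniform", a = 0, b = 1)
  expect_equal(ks_discrepancy(0.5, u01)$statistic, 0.5)
  expect_equal(ks_discrepancy(c(0.25, 0.75), u01)$statistic, 0.25)

  ref <- noise_spec("uniform", a = -1, b = 1)
  mags <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  signs <- expand.grid(rep(list(c(-1, 1)), 5))
  for (i in seq_len(nrow(signs))) {
    s <- mags * as.numeric(signs[i, ])
    expect_equal(ks_discrepancy(s, ref)$statistic,
                 oracle_ks(s, function(x) noise_cdf(ref, x)))
  }
})

test_that("KS against a discrete reference takes the sup over both limits", {
  ref <- noise_spec("poisson", lambda = 10)
  s <- noise_sample(ref, 200, seed = 5)
  # dense-grid approximation of sup |ECDF - F| over the real line
  grid <- seq(-1, max(s) + 2, by = 1e-3)
  Dgrid <- max(abs(vapply(grid, function(t) mean(s <= t), numeric(1)) -
                     noise_cdf(ref, grid)))
  expect_equal(ks_discrepancy(s, ref)$statistic, Dgrid, tolerance = 1e-6)
})

test_that("Anderson-Darling matches the n = 1 closed form and flags degeneracy", {
  ref <- noise_spec("uniform", a = 0, b = 1)
  res <- ad_discrepancy(0.5, ref)
  expect_equal(res$statistic, -1 + 2 * log(2), tolerance = 1e-12)
  expect_equal(res$z_score, res$statistic)  # n = 1
  expect_error(ad_discrepancy(c(-5, 2), ref), "degenerate")
  expect_message(ad_discrepancy(c(0, 0.5), ref), "clipped")
})

test_that("chi-squared matches a hand-summed statistic on fixed binnings", {
  ref <- noise_spec("uniform", a = 0, b = 1)
  # two equiprobable bins, observed 10/20, expected 15/15
  s <- c(seq(0.01, 0.49, length.out = 10), seq(0.51, 0.99, length.out = 20))
  res <- chi2_discrepancy(s, ref, n_bins = 2)
  expect_equal(res$statistic, oracle_chi2(c(10, 20), c(15, 15)))
  expect_equal(res$statistic, 10 / 3, tolerance = 1e-12)
  expect_equal(res$z_score, 1 / 9, tolerance = 1e-12)
  expect_equal(res$df, 1L)

  # balanced counts give a zero statistic and zero Z
  s0 <- c(seq(0.01, 0.49, length.out = 15), seq(0.51, 0.99, length.out = 15))
  expect_equal(chi2_discrepancy(s0, ref, n_bins = 2)$statistic, 0)
  expect_equal(chi2_discrepancy(s0, ref, n_bins = 2)$z_score, 0)

  # four equiprobable bins: oracle over the known expected counts
  s4 <- noise_sample(ref, 400, seed = 8)
  obs <- as.numeric(table(cut(s4, c(0, 0.25, 0.5, 0.75, 1))))
  expect_equal(chi2_discrepancy(s4, ref, n_bins = 4)$statistic,
               oracle_chi2(obs, rep(100, 4)))
})

test_that("chi-squared binning keeps every expected count at five or more", {
  ref <- noise_spec("poisson", lambda = 10)
  s <- noise_sample(ref, 120, seed = 3)
  res <- chi2_discrepancy(s, ref)
  expect_gte(res$df, 1L)
  expect_error(chi2_discrepancy(noise_sample(ref, 4, seed = 1), ref),
               "expected count")
})

test_that("gof_zscore dispatches and rejects unknown tests", {
  ref <- noise_spec("gaussian", mu = 0, sigma = 3)
  s <- noise_sample(ref, 300, seed = 13)
  expect_identical(gof_zscore(s, ref, "ks"), ks_discrepancy(s, ref)$z_score)
  expect_identical(gof_zscore(s, ref, "ad"), ad_discrepancy(s, ref)$z_score)
  expect_identical(gof_zscore(s, ref, "chi2"), chi2_discrepancy(s, ref)$z_score)
  expect_error(gof_zscore(s, ref, "cramer"), "unknown")
  expect_error(ks_discrepancy(numeric(0), ref), "non-empty")
})

test_that("Z scores shrink with sample size under the null for every family", {
  for (spec in study_noise_specs()) {
    for (tst in c("ks", "ad", "chi2")) {
      z_small <- stats::median(vapply(1:15, function(s) {
        gof_zscore(noise_sample(spec, 100, s), spec, tst)
      }, numeric(1)))
      z_large <- stats::median(vapply(1:15, function(s) {
        gof_zscore(noise_sample(spec, 10000, 500 + s), spec, tst)
      }, numeric(1)))
      expect_lt(z_large, z_small)
    }
  }
})

test_that("Z scores stay bounded away from zero under a wrong reference", {
  wrong <- noise_spec("gaussian", mu = 0, sigma = 3)
  src <- noise_spec("poisson", lambda = 10)
  for (tst in c("ks", "ad", "chi2")) {
    z_small <- stats::median(vapply(1:15, function(s) {
      gof_zscore(noise_sample(src, 100, s), wrong, tst)
    }, numeric(1)))
    z_large <- stats::median(vapply(1:15, function(s) {
      gof_zscore(noise_sample(src, 10000, s), wrong, tst)
    }, numeric(1)))
    expect_gte(z_large, 0.5 * z_small)
    expect_gt(z_large, 0.1)
  }
})

test_that("median Z grows with the size of a location shift", {
  ref <- noise_spec("gaussian", mu = 0, sigma = 3)
  med <- vapply(c(0, 1, 2), function(shift) {
    stats::median(vapply(1:25, function(s) {
      gof_zscore(noise_sample(ref, 500, s) + shift, ref, "ks")
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("KS agrees with the stats::ks.test oracle on continuous references", {
  ref <- noise_spec("gamma", shape = 3, scale = 2)
  s <- noise_sample(ref, 250, seed = 17)
  expect_equal(ks_discrepancy(s, ref)$statistic,
               unname(stats::ks.test(s, function(x) noise_cdf(ref, x))$statistic))
})

test_that("p-value Z mode is nonnegative and grows under a fixed alternative", {
  ref <- noise_spec("gaussian", mu = 0, sigma = 3)
  s_null <- noise_sample(ref, 1000, seed = 2)
  expect_gte(gof_zscore(s_null, ref, "ks", zscore_mode = "pvalue"), 0)
  z1 <- gof_zscore(noise_sample(ref, 300, 4) + 1, ref, "ks", "pvalue")
  z2 <- gof_zscore(noise_sample(ref, 3000, 4) + 1, ref, "ks", "pvalue")
  expect_gt(z2, z1)
})
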