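test_that("residual entropy matches closed forms and honours the floor", {
  # all residuals in one bin: raw H = 0, floored at 1/n
  h <- residual_entropy(rep(2, 8))
  expect_equal(as.numeric(h), 1 / 8)
  expect_true(attr(h, "floored"))

  # equal two-bin split
  expect_equal(residual_entropy(c(1, 1, 2, 2), bin_edges = c(0.5, 1.5, 2.5)),
               log(2))

  # uniform histogram over B bins hits the ln(B) ceiling
  B <- 5
  r <- rep(seq_len(B), each = 4)
  expect_equal(residual_entropy(r, bin_edges = seq(0.5, B + 0.5, by = 1)),
               log(B))

  expect_error(residual_entropy(c(1, NA)), "finite")
  expect_error(residual_entropy(numeric(0)), "non-empty")
  expect_error(residual_entropy(1:5, bin_edges = c(2, 1, 3)), "increasing")
  expect_error(residual_entropy(1:5, bin_edges = c(1.5, 4)), "cover")
})

test_that("entropy never exceeds log of the bin count", {
  for (s in 1:20) {
    r <- noise_sample(noise_spec("gamma", shape = 3, scale = 2), 200, s)
    B <- sample(2:30, 1)
    expect_lte(residual_entropy(r, n_bins = B), log(B) + 1e-12)
  }
})

test_that("residual summaries satisfy mse = variance + mean^2", {
  for (s in 1:25) {
    r <- noise_sample(noise_spec("poisson", lambda = 10), 150, s)
    sm <- residual_summary(r)
    expect_equal(sm$mse, sm$variance + mean(r)^2, tolerance = 1e-9)
  }
})

test_that("classic criteria match their closed forms", {
  expect_equal(classic_criterion("aic", list(n = 100, mse = 1), k = 3), 6)
  expect_equal(classic_criterion("bic", list(n = 50, variance = 1), k = 2),
               2 * log(50))
  expect_equal(classic_criterion("aic", list(n = 10, mse = exp(2)), k = 0), 20)
  expect_error(classic_criterion("aic", list(n = 10, mse = 0), k = 1),
               "degenerate")
  expect_error(classic_criterion("bic", list(n = 10, variance = 0), k = 1),
               "degenerate")
})

test_that("entropy criteria divide by H inside the log", {
  s1 <- list(n = 10, mse = 1, variance = 1, entropy = 1)
  expect_equal(entropy_criterion("aic", s1, k = 2),
               classic_criterion("aic", s1, k = 2))
  s2 <- list(n = 10, mse = 1, variance = 1, entropy = exp(-1))
  expect_equal(entropy_criterion("aic", s2, k = 1), 12)
  # doubling H lowers the criterion by n log 2
  s3 <- list(n = 10, mse = 1, variance = 1, entropy = 2 * exp(-1))
  expect_equal(entropy_criterion("aic", s2, k = 1) -
                 entropy_criterion("aic", s3, k = 1), 10 * log(2))
})

test_that("GF criteria multiply by (1 + Z^2) inside the log", {
  base <- list(n = 100, mse = 2, variance = 1.5, entropy = 0.8)
  s0 <- c(base, list(z_score = 0))
  expect_equal(gf_criterion("aic", s0, k = 4),
               entropy_criterion("aic", base, k = 4))
  s1 <- c(base, list(z_score = 1))
  expect_equal(gf_criterion("bic", s1, k = 4),
               entropy_criterion("bic", base, k = 4) + 100 * log(2))
  s3 <- c(base, list(z_score = 3))
  expect_equal(gf_criterion("aic", s3, k = 4),
               entropy_criterion("aic", base, k = 4) + 100 * log(10))
  expect_error(gf_criterion("aic", base, k = 4), "z_score")
})

test_that("likelihood-form criterion equals the residual form up to n(log 2pi + 1)", {
  r0 <- rnorm(10)
  r0 <- r0 / sqrt(mean(r0^2))  # rescale to mse = 1
  expect_equal(gaussian_loglik_criterion("aic", r0, k = 0),
               10 * (log(2 * pi) + 1))
  for (s in 1:20) {
    r <- noise_sample(noise_spec("gaussian", mu = 0, sigma = 3), 200, s)
    n <- length(r)
    sm <- residual_summary(r)
    expect_equal(
      gaussian_loglik_criterion("aic", r, k = 5) -
        classic_criterion("aic", sm, k = 5),
      n * (log(2 * pi) + 1),
      tolerance = 1e-9
    )
    # scaling residuals by c shifts the value by n log(c^2)
    expect_equal(
      gaussian_loglik_criterion("bic", 3 * r, k = 2) -
        gaussian_loglik_criterion("bic", r, k = 2),
      n * log(9),
      tolerance = 1e-9
    )
  }
})

test_that("criteria increase strictly with the parameter count", {
  r <- noise_sample(noise_spec("uniform"), 300, seed = 9)
  sm <- residual_summary(r, z_score = 0.2)
  for (kind in c("aic", "bic")) {
    for (f in list(classic_criterion, entropy_criterion, gf_criterion)) {
      vals <- vapply(0:5, function(k) f(kind, sm, k), numeric(1))
      expect_true(all(diff(vals) > 0))
    }
  }
})

test_that("a constant residual offset moves AIC but not BIC", {
  r <- noise_sample(noise_spec("gaussian", mu = 0, sigma = 3), 400, seed = 31)
  sm0 <- residual_summary(r)
  sm5 <- residual_summary(r + 5)
  expect_equal(classic_criterion("bic", sm5, k = 2),
               classic_criterion("bic", sm0, k = 2), tolerance = 1e-9)
  expect_gt(classic_criterion("aic", sm5, k = 2),
            classic_criterion("aic", sm0, k = 2))
})

test_that("criteria_table carries all six criteria and shared inputs", {
  ref <- noise_spec("poisson", lambda = 10)
  r <- noise_sample(ref, 250, seed = 12)
  tab <- criteria_table(r, k = 3, ref = ref, model_label = "Correct")
  expect_setequal(tab$criterion,
                  c("aic", "bic", "aic_h", "bic_h", "aic_gf", "bic_gf"))
  expect_equal(nrow(tab), 6L)
  expect_true(all(tab$n == 250 & tab$k == 3 & tab$model_label == "Correct"))
  expect_equal(length(unique(tab$z_score)), 1L)
  # deterministic: same inputs, same table
  expect_identical(tab, criteria_table(r, k = 3, ref = ref, model_label = "Correct"))
  # identical residuals, different k: every criterion differs by the penalty
  tab5 <- criteria_table(r, k = 5, ref = ref, model_label = "Correct")
  d <- tab5$value - tab$value
  expect_equal(d[tab$criterion %in% c("aic", "aic_h", "aic_gf")],
               rep(4, 3))
  expect_equal(d[tab$criterion %in% c("bic", "bic_h", "bic_gf")],
               rep(2 * log(250), 3))
})

test_that("GF criteria converge to the entropy criteria as n grows", {
  ref <- noise_spec("gaussian", mu = 0, sigma = 3)
  gap <- vapply(c(100, 1000, 10000), function(n) {
    mean(vapply(1:10, function(s) {
      tab <- criteria_table(noise_sample(ref, n, s), k = 1, ref = ref,
                            gof_test = "anderson_darling")
      abs(tab$value[tab$criterion == "aic_gf"] -
            tab$value[tab$criterion == "aic_h"])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(gap) < 0))
})
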