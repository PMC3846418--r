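test_that("the Beta posterior mean estimator matches hand-worked values", {
  expect_equal(unname(estimate_mu(make_counts(3, 10))[1, 1]), 4 / 12)
  # no data: prior mean of Beta(1, 1)
  expect_equal(unname(estimate_mu(make_counts(0, 0))[1, 1]), 1 / 2)
  # estimate never reaches 1 even when the feature is always present
  m <- unname(estimate_mu(make_counts(1000, 1000))[1, 1])
  expect_equal(m, 1001 / 1002)
  expect_lt(m, 1)
})

test_that("closed-form posterior mean agrees with numerical quadrature", {
  expect_equal(beta_posterior_oracle(3, 10, 1, 1), 1 / 3, tolerance = 1e-8)
  expect_equal(beta_posterior_oracle(0, 0, 2, 5), 2 / 7, tolerance = 1e-8)
  expect_equal(beta_posterior_oracle(5, 5, 2, 3), 0.7, tolerance = 1e-8)
  for (a in c(0.5, 2)) {
    for (b in c(1, 5)) {
      for (nc in c(1, 7, 23)) {
        nij <- nc %/% 2
        expect_equal(
          beta_posterior_oracle(nij, nc, a, b),
          unname(estimate_mu(make_counts(nij, nc), beta_hyper(a, b))[1, 1]),
          tolerance = 1e-8
        )
      }
    }
  }
})

test_that("present-feature posteriors match hand-worked toys in all three modes", {
  cnt <- toy_counts() # sizes (12, 8), presence (5, 3)
  prior <- empirical_prior(cnt)
  h <- beta_hyper(C = 2)

  # exact: Bayes inversion of mu = (6/14, 4/10) with prior (0.6, 0.4)
  xi_ex <- posterior_present_exact(cnt, h, prior)
  expect_equal(
    unname(xi_ex[1, 1]),
    (6 / 14 * 0.6) / (6 / 14 * 0.6 + 4 / 10 * 0.4)
  )
  expect_equal(unname(xi_ex[1, 1]), 0.6165, tolerance = 1e-4)

  # simplified: (N_ij + 1) / (N_j+ + 2)
  cnt2 <- make_counts(c(5, 3), c(30, 30))
  xi_s <- posterior_present_simplified(cnt2, h)
  expect_equal(unname(xi_s[, 1]), c(0.6, 0.4))
  xi_a <- posterior_present_simplified(make_counts(c(3, 1), c(30, 30)), beta_hyper(c(2, 1), 1))
  expect_equal(unname(xi_a[, 1]), c(5 / 7, 2 / 7))

  # never-present feature falls back to the smoothing mass alone
  xi0 <- posterior_present_simplified(make_counts(c(0, 0), c(10, 10)), h)
  expect_equal(unname(xi0[, 1]), c(0.5, 0.5))

  # identical classes with equal priors give 1/C; single class gives 1
  sym <- make_counts(c(4, 4), c(10, 10))
  expect_equal(unname(posterior_present_exact(sym, h, empirical_prior(sym))[, 1]), c(0.5, 0.5))
  one <- make_counts(3, 9)
  expect_equal(unname(posterior_present_exact(one, beta_hyper(C = 1), empirical_prior(one))[1, 1]), 1)
})

test_that("the LCMNB estimator is the simplified form with alpha = prior * K", {
  cnt <- make_counts(c(3, 1), c(20, 10))
  prior <- structure(list(probs = c(2 / 3, 1 / 3), mode = "empirical"), class = "fp_prior")
  xi <- posterior_present_lcmnb(cnt, prior, K = 3)
  expect_equal(unname(xi[, 1]), c(5 / 7, 2 / 7))
  expect_equal(xi, posterior_present_simplified(cnt, hyper_from_lcmnb(prior, 3)),
    tolerance = 1e-15
  )

  # uniform prior with K = C is plain add-one smoothing
  cntu <- random_counts(C = 3, L = 5)
  pru <- class_prior(cntu, "uniform")
  expect_equal(
    posterior_present_lcmnb(cntu, pru, K = 3),
    sweep(cntu$N_present + 1, 2, cntu$N_feat + 3, "/")
  )
  expect_error(posterior_present_lcmnb(cnt, prior, K = 0), class = "lapnb_input_error")
})

test_that("absent-feature posteriors match hand-worked toys", {
  cnt <- toy_counts()
  h <- beta_hyper(C = 2)
  nu_s <- posterior_absent_simplified(cnt, h)
  expect_equal(unname(nu_s[, 1]), c((12 - 6) / 10, (8 - 4) / 10))

  # feature absent everywhere
  cnt0 <- make_counts(c(0, 0), c(12, 8))
  nu0 <- posterior_absent_simplified(cnt0, h)
  expect_equal(unname(nu0[, 1]), c(11 / 18, 7 / 18))
  expect_equal(sum(nu0[, 1]), 1)

  # exact Bayes inversion of 1 - mu
  prior <- empirical_prior(cnt)
  nu_ex <- posterior_absent_exact(cnt, h, prior)
  expect_equal(
    unname(nu_ex[1, 1]),
    (8 / 14 * 0.6) / (8 / 14 * 0.6 + 6 / 10 * 0.4)
  )
  expect_equal(unname(nu_ex[1, 1]), 0.5882, tolerance = 1e-4)

  # identical classes, equal priors
  sym <- make_counts(c(4, 4), c(10, 10))
  expect_equal(unname(posterior_absent_exact(sym, h, empirical_prior(sym))[, 1]), c(0.5, 0.5))
})

test_that("degenerate features error in simplified mode but not exact mode", {
  # feature present in every class-1 compound forces a negative numerator
  cnt <- make_counts(c(12, 3), c(12, 8))
  h <- beta_hyper(C = 2)
  err <- expect_error(posterior_absent_simplified(cnt, h), class = "lapnb_degenerate_feature")
  expect_match(conditionMessage(err), "class 1, feature 1")
  expect_match(conditionMessage(err), "exact")

  nu_ex <- posterior_absent_exact(cnt, h, empirical_prior(cnt))
  expect_true(all(is.finite(nu_ex)) && all(nu_ex > 0))

  expect_error(fp_fit(degenerate_data(), mode = "simplified"),
    class = "lapnb_degenerate_feature"
  )
  expect_s3_class(fp_fit(degenerate_data(), mode = "exact"), "fp_model")
})

test_that("posterior columns sum to one in every populated mode", {
  set.seed(42)
  for (case in 1:60) {
    cnt <- random_counts(C = sample(2:4, 1), L = sample(3:8, 1))
    h <- beta_hyper(stats::runif(cnt$C, 0.3, 3), stats::runif(cnt$C, 0.3, 3), C = cnt$C)
    prior <- empirical_prior(cnt)
    K <- stats::runif(1, 0.5, 10)
    expect_cols_sum_to_one(posterior_present_exact(cnt, h, prior))
    expect_cols_sum_to_one(posterior_present_simplified(cnt, h))
    expect_cols_sum_to_one(posterior_present_lcmnb(cnt, prior, K))
    expect_cols_sum_to_one(posterior_absent_exact(cnt, h, prior))
    expect_cols_sum_to_one(posterior_absent_simplified(cnt, h))
  }
})

test_that("present-feature posterior strictly increases with the presence count", {
  h <- beta_hyper(C = 2)
  prior <- structure(list(probs = c(0.5, 0.5), mode = "uniform"), class = "fp_prior")
  for (mode in c("exact", "simplified", "lcmnb")) {
    prev <- -Inf
    for (nij in 0:10) {
      cnt <- make_counts(c(nij, 4), c(10, 10))
      xi <- switch(mode,
        exact = posterior_present_exact(cnt, h, prior),
        simplified = posterior_present_simplified(cnt, h),
        lcmnb = posterior_present_lcmnb(cnt, prior, K = 2)
      )
      expect_gt(xi[1, 1], prev)
      prev <- xi[1, 1]
    }
  }
})

test_that("simplified estimators converge to the exact ones as counts grow", {
  cnt <- toy_counts()
  h <- beta_hyper(C = 2)
  gap <- sapply(c(1, 10, 100), function(s) {
    cs <- scale_counts(cnt, s)
    prior <- empirical_prior(cs)
    c(
      xi = max(abs(
        posterior_present_exact(cs, h, prior) - posterior_present_simplified(cs, h)
      )),
      nu = max(abs(
        posterior_absent_exact(cs, h, prior) - posterior_absent_simplified(cs, h)
      ))
    )
  })
  expect_true(all(diff(gap["xi", ]) < 0))
  expect_true(all(diff(gap["nu", ]) < 0))
})
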