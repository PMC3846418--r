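# Inject hand-chosen posterior tables into a model skeleton so scorer
# arithmetic can be checked against direct evaluation.
fake_model <- function(xi, nu, probs, prior_mode = "uniform") {
  C <- nrow(xi)
  L <- ncol(xi)
  structure(
    list(
      counts = make_counts(matrix(1, C, L), rep(10, C)),
      hyper = beta_hyper(C = C),
      prior = structure(list(probs = probs, mode = prior_mode), class = "fp_prior"),
      mode = "exact", K = NULL,
      xi = xi, nu = nu,
      log_xi = log(xi), log_nu = if (is.null(nu)) NULL else log(nu),
      levels = paste0("class", seq_len(C)), L = L, C = C
    ),
    class = "fp_model"
  )
}

test_that("scorers reproduce direct log-space evaluation on tiny models", {
  # L = 1: D = ln xi - ln p, the absent sum empty and (L - 1) = 0
  m1 <- fake_model(
    xi = matrix(c(0.6, 0.4), 2, 1), nu = matrix(c(0.4, 0.6), 2, 1),
    probs = c(0.5, 0.5)
  )
  s <- score_snb(c(1), m1)
  expect_equal(unname(s[1, 1]), log(0.6) - log(0.5))
  expect_equal(unname(s[1, 1]), 0.1823, tolerance = 1e-3)

  # LCMNB on x = (1, 0): absent feature ignored entirely
  m2 <- fake_model(
    xi = matrix(c(0.6, 0.4, 0.4, 0.6), 2, 2), # class x feature
    nu = matrix(c(0.3, 0.7, 0.5, 0.5), 2, 2),
    probs = c(0.5, 0.5)
  )
  sl <- score_lcmnb(c(1, 0), m2)
  expect_equal(unname(sl[1, ]), c(log(0.6) - log(0.5), log(0.4) - log(0.5)))

  # uniform-prior reduction on x = (1, 0): ln xi_1 + ln nu_2
  su <- score_snb_uniform(c(1, 0), m2)
  expect_equal(unname(su[1, 1]), log(0.6) + log(0.5))
  expect_equal(unname(su[1, 1]), -1.204, tolerance = 1e-3)

  # all-ones fingerprint: absent sum vanishes
  sa <- score_snb(c(1, 1), m2)
  expect_equal(unname(sa[1, 1]), log(0.6) + log(0.4) - 2 * log(0.5))

  # all-zeros fingerprint under lcmnb: no discrimination, every class ties
  s0 <- score_lcmnb(c(0, 0), m2)
  expect_equal(unname(s0[1, 1]), unname(s0[1, 2]))
  expect_equal(unname(s0[1, 1]), log(2))
})

test_that("the naive Bernoulli log-likelihood oracle evaluates directly", {
  mu <- rbind(c(0.6, 0.3), c(0.2, 0.8))
  expect_equal(unname(likelihood_oracle(c(1, 0), mu)[1, ]),
    c(log(0.6) + log(0.7), log(0.2) + log(0.2)))
  expect_equal(unname(likelihood_oracle(1, matrix(0.6, 1, 1))[1, 1]), log(0.6))
  # uninformative model scores -L ln 2 for every class and fingerprint
  mu5 <- matrix(0.5, 3, 4)
  s <- likelihood_oracle(rbind(c(1, 1, 0, 0), c(0, 0, 0, 1)), mu5)
  expect_true(all(abs(s - (-4 * log(2))) < 1e-12))
})

test_that("uniform-prior scores differ from full scores by exactly L ln(1/C)", {
  d <- fp_simulate(class_sizes = c(25, 25), L = 9, preset = "separable", seed = 3)
  fit <- fp_fit(d, mode = "exact", prior = "uniform")
  gap <- score_snb(d, fit) - score_snb_uniform(d, fit)
  expect_equal(max(abs(gap - (-fit$L * log(1 / 2)))), 0, tolerance = 1e-10)

  fit_emp <- fp_fit(d, mode = "exact", prior = "empirical")
  expect_error(score_snb_uniform(d, fit_emp), class = "lapnb_mode_error")
})

test_that("full scores decompose into the present-only score plus the discarded term", {
  for (mode in c("exact", "simplified")) {
    d <- fp_simulate(class_sizes = c(200, 200), L = 12, preset = "absence_informative", seed = 9)
    fit <- fp_fit(d, mode = mode)
    snb <- score_snb(d, fit)
    lcm <- score_lcmnb(d, fit)
    del <- absent_term(d, fit)
    expect_lt(max(abs(snb - (lcm + del))), 1e-12 * max(1, max(abs(snb))))
  }
})

test_that("exact-mode scores equal the Bernoulli log-likelihood up to a class constant", {
  d <- fp_simulate(class_sizes = c(40, 30), L = 8, preset = "separable", seed = 21)
  fit <- fp_fit(d, mode = "exact", prior = "empirical")
  # exhaustive over all 2^8 fingerprints
  grid <- as.matrix(expand.grid(rep(list(0:1), 8)))
  colnames(grid) <- paste0("f", 1:8)
  snb <- score_snb(grid, fit)
  orc <- likelihood_oracle(grid, fit)
  shift <- snb - orc
  expect_lt(max(apply(shift, 1, function(r) max(r) - min(r))), 1e-10)
  expect_equal(apply(snb, 1, which.max), apply(orc, 1, which.max))
})

test_that("exact uniform-prior argmax equals the naive Bayes MAP class", {
  d <- fp_simulate(class_sizes = c(35, 35), L = 6, preset = "separable", seed = 13)
  fit <- fp_fit(d, mode = "exact", prior = "uniform")
  mu <- estimate_mu(fit$counts, fit$hyper)
  grid <- as.matrix(expand.grid(rep(list(0:1), 6)))
  colnames(grid) <- paste0("f", 1:6)
  snb <- score_snb(grid, fit)
  # posterior by direct computation: p(w|x) proportional to p(x|w) p(w)
  loglik <- likelihood_oracle(grid, mu)
  post <- sweep(loglik, 2, log(fit$prior$probs), "+")
  expect_equal(apply(snb, 1, which.max), apply(post, 1, which.max))
})

test_that("scores are equivariant under feature permutation", {
  d <- fp_simulate(class_sizes = c(20, 20), L = 10, preset = "separable", seed = 8)
  fit <- fp_fit(d, mode = "exact")
  perm <- sample(10)
  d_perm <- fp_data(d$x[, perm], labels = d$levels[d$labels], levels = d$levels)
  fit_perm <- fp_fit(d_perm, mode = "exact")
  expect_equal(unname(score_snb(d, fit)), unname(score_snb(d_perm, fit_perm)),
    tolerance = 1e-12
  )
})

test_that("prediction breaks ties deterministically to the lowest class and flags them", {
  m <- fake_model(
    xi = matrix(c(0.5, 0.5), 2, 1), nu = matrix(c(0.5, 0.5), 2, 1),
    probs = c(0.5, 0.5)
  )
  p <- predict(m, matrix(c(1, 0), 2, 1))
  expect_equal(p$class, c(1L, 1L))
  expect_true(all(p$tie))

  m3 <- fake_model(
    xi = matrix(c(0.2, 0.5, 0.3), 3, 1), nu = matrix(1 / 3, 3, 1),
    probs = rep(1 / 3, 3)
  )
  p3 <- predict(m3, matrix(1, 1, 1))
  expect_equal(p3$class, 2L)
  expect_false(p3$tie)
  expect_equal(p3$margin, log(0.5) - log(0.3))
})

test_that("lcmnb-mode models refuse full scoring and fall back in predict", {
  d <- fp_simulate(class_sizes = c(20, 20), L = 6, preset = "separable", seed = 4)
  fit <- fp_fit(d, mode = "lcmnb", K = 2)
  expect_error(score_snb(d, fit), class = "lapnb_mode_error")
  expect_error(absent_term(d, fit), class = "lapnb_mode_error")
  p <- predict(fit, d) # silently routed to the present-only scorer
  expect_equal(nrow(p), d$N)
})

test_that("posterior ranking adds the log prior back", {
  d <- fp_simulate(class_sizes = c(45, 15), L = 8, preset = "separable", seed = 17)
  fit <- fp_fit(d, mode = "exact", prior = "empirical")
  s <- score_snb(d, fit)
  post <- sweep(s, 2, log(fit$prior$probs), "+")
  p <- predict(fit, d, rank = "posterior")
  expect_equal(p$class, unname(apply(post, 1, which.max)))
})
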