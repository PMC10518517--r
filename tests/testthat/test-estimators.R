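test_that("Wald ratio and its delta-method SE", {
  w <- mr_wald_ratio(0.1, 0.01, 0.2, 0.05)
  expect_equal(w$theta, 2)
  expect_equal(w$se, 0.5)
  expect_equal(mr_wald_ratio(0.1, 0.01, 0, 0.05)$theta, 0)
  expect_error(mr_wald_ratio(0, 0.01, 0.2, 0.05), "undefined")
  # Second-order variance adds the exposure-error term.
  w2 <- mr_wald_ratio(0.1, 0.01, 0.2, 0.05, second_order = TRUE)
  expect_equal(w2$se, sqrt(0.05^2 / 0.1^2 + 0.2^2 * 0.01^2 / 0.1^4))
})

test_that("IVW closed form, heterogeneity attachment, and single-instrument fallback", {
  d <- make_harmonized_tbl(gamma = c(0.1, 0.2), Gamma = c(0.2, 0.4),
                           se_Gamma = 0.1)
  fit <- mr_ivw(d)
  expect_equal(fit$theta, (0.02 + 0.08) / (0.01 + 0.04))
  expect_equal(fit$theta, 2)
  expect_equal(fit$q_statistic, 0)
  expect_equal(fit$dispersion, 1) # floor applies when Q/(J-1) < 1
  expect_equal(fit$i_squared, 0)

  single <- make_harmonized_tbl(0.1, 0.2, se_Gamma = 0.05)
  expect_message(f1 <- mr_ivw(single), "Wald")
  wald <- mr_wald_ratio(0.1, 0.01, 0.2, 0.05)
  expect_equal(f1$theta, wald$theta)
  expect_equal(f1$se, wald$se)

  zero <- make_harmonized_tbl(c(0.1, 0.2, 0.3), Gamma = c(0, 0, 0))
  expect_equal(mr_ivw(zero)$theta, 0)
  expect_error(mr_ivw(make_harmonized_tbl(numeric(), numeric())), "Empty")
})

test_that("IVW and Egger match a weighted-least-squares oracle to 1e-10", {
  set.seed(101)
  for (i in 1:100) {
    J <- sample(3:8, 1)
    d <- make_harmonized_tbl(
      gamma = rnorm(J, 0.2, 0.1),
      Gamma = rnorm(J, 0.05, 0.1),
      se_gamma = runif(J, 0.005, 0.02),
      se_Gamma = runif(J, 0.02, 0.2)
    )
    d$gamma[d$gamma == 0] <- 0.01
    w <- 1 / d$se_Gamma^2
    ivw_lm <- stats::lm(Gamma ~ 0 + gamma, data = d, weights = w)
    expect_equal(mr_ivw(d)$theta, unname(coef(ivw_lm)), tolerance = 1e-10)
    # Egger after orienting all exposure effects positive.
    flip <- sign(d$gamma)
    do <- d
    do$gamma <- d$gamma * flip
    do$Gamma <- d$Gamma * flip
    egger_lm <- stats::lm(Gamma ~ gamma, data = do, weights = w)
    fit <- mr_egger(d)
    expect_equal(fit$theta, unname(coef(egger_lm)[2]), tolerance = 1e-10)
    expect_equal(fit$egger_intercept, unname(coef(egger_lm)[1]),
                 tolerance = 1e-10)
  }
})

test_that("Egger recovers an exactly collinear fixture and guards J < 3", {
  fit <- mr_egger(mr_fixture("egger_collinear"))
  expect_equal(fit$theta, 2, tolerance = 1e-12)
  expect_equal(fit$egger_intercept, 0.05, tolerance = 1e-12)
  expect_error(mr_egger(make_harmonized_tbl(c(0.1, 0.2), c(0.2, 0.4))),
               "at least 3")
})

test_that("Egger estimates are invariant to the sign orientation of any instrument", {
  set.seed(7)
  d <- make_harmonized_tbl(
    gamma = rnorm(6, 0.2, 0.05), Gamma = rnorm(6, 0.1, 0.05),
    se_Gamma = runif(6, 0.02, 0.1)
  )
  base <- mr_egger(d)
  for (j in c(1, 4, 6)) {
    dd <- d
    dd$gamma[j] <- -dd$gamma[j]
    dd$Gamma[j] <- -dd$Gamma[j]
    flipped <- mr_egger(dd)
    expect_equal(flipped$theta, base$theta)
    expect_equal(flipped$egger_intercept, base$egger_intercept)
    expect_equal(flipped$se, base$se)
  }
  # With a true zero intercept on a symmetric design, slope ~ IVW estimate.
  dsym <- make_harmonized_tbl(gamma = c(0.1, 0.2, 0.3),
                              Gamma = 2 * c(0.1, 0.2, 0.3),
                              se_Gamma = 0.1)
  expect_equal(mr_egger(dsym)$theta, mr_ivw(dsym)$theta, tolerance = 1e-8)
})

test_that("weighted median interpolates standardized cumulative weights", {
  d <- make_harmonized_tbl(gamma = c(1, 1, 1), Gamma = c(1, 2, 3),
                           se_Gamma = 1)
  fit <- mr_weighted_median(d, n_boot = 200, seed = 1)
  expect_equal(fit$theta, 2) # s = (1/6, 3/6, 5/6): 0.5 hits the middle

  const <- make_harmonized_tbl(gamma = c(0.1, 0.2, 0.4),
                               Gamma = 3 * c(0.1, 0.2, 0.4))
  cfit <- mr_weighted_median(const, n_boot = 100, seed = 1)
  expect_equal(cfit$theta, 3)
  expect_gt(cfit$se, 0)

  # Weights (10, 1, 1) on ratios (1, 2, 3): mass pulled below 2.
  dw <- make_harmonized_tbl(gamma = c(1, 1, 1), Gamma = c(1, 2, 3),
                            se_Gamma = c(sqrt(1 / 10), 1, 1))
  wfit <- mr_weighted_median(dw, n_boot = 100, seed = 1)
  expect_lt(wfit$theta, 2)
  # Independent oracle: direct interpolation trace.
  s <- (cumsum(c(10, 1, 1)) - c(10, 1, 1) / 2) / 12
  manual <- 1 + (2 - 1) * (0.5 - s[1]) / (s[2] - s[1])
  expect_equal(wfit$theta, manual)
  expect_error(mr_weighted_median(d[1:2, ]), "at least 3")
})

test_that("weighted median with equal weights equals the sample median for odd J", {
  set.seed(21)
  for (J in c(3, 5, 7)) {
    ratios <- sort(rnorm(J, 1, 0.5))
    d <- make_harmonized_tbl(gamma = rep(1, J), Gamma = ratios,
                             se_Gamma = 1)
    fit <- mr_weighted_median(d, n_boot = 50, seed = 2)
    expect_equal(fit$theta, median(ratios))
  }
})

test_that("weighted mode finds the dominant ratio cluster", {
  ratios <- c(1.0, 2.0, 2.0, 2.05, 3.0)
  d <- make_harmonized_tbl(gamma = rep(1, 5), Gamma = ratios, se_Gamma = 1)
  fit <- mr_weighted_mode(d, n_boot = 100, seed = 3)
  expect_equal(fit$theta, 2, tolerance = 0.25) # within a bandwidth

  const <- make_harmonized_tbl(gamma = c(1, 2, 4), Gamma = 2.5 * c(1, 2, 4))
  expect_equal(mr_weighted_mode(const, n_boot = 50, seed = 1)$theta, 2.5)

  # A dominant-weight instrument pulls the mode to its own ratio.
  dw <- make_harmonized_tbl(gamma = rep(1, 3), Gamma = c(1, 2, 3),
                            se_Gamma = c(1e-3, 1, 1))
  expect_equal(mr_weighted_mode(dw, n_boot = 50, seed = 1)$theta, 1,
               tolerance = 0.05)
  expect_error(mr_weighted_mode(d[1:2, ]), "at least 3")
})

test_that("Cochran's Q and I^2 follow the hand-computed forms", {
  const <- make_harmonized_tbl(gamma = c(1, 1, 1), Gamma = c(2, 2, 2))
  q0 <- mr_cochran_q(const)
  expect_equal(q0$q_statistic, 0)
  expect_equal(q0$i_squared, 0)

  # Ratios 1 and 3 with unit ratio variance: IVW = 2, Q = 2, I^2 = 0.5.
  d <- make_harmonized_tbl(gamma = c(1, 1), Gamma = c(1, 3), se_Gamma = 1)
  q <- mr_cochran_q(d)
  expect_equal(q$q_statistic, 2)
  expect_equal(q$df, 1)
  expect_equal(q$i_squared, 0.5)

  # Q < df clips I^2 at zero.
  mild <- make_harmonized_tbl(gamma = c(1, 1, 1), Gamma = c(2, 2.01, 1.99),
                              se_Gamma = 1)
  expect_equal(mr_cochran_q(mild)$i_squared, 0)
  expect_error(mr_cochran_q(d[1, ]), "at least 2")
})

test_that("leave-one-out returns J rows and isolates gross outliers", {
  const <- make_harmonized_tbl(gamma = c(0.1, 0.2, 0.3, 0.4),
                               Gamma = 2 * c(0.1, 0.2, 0.3, 0.4))
  loo <- mr_leave_one_out(const)
  expect_equal(nrow(loo), 4)
  expect_equal(loo$theta, rep(2, 4))

  d5 <- make_harmonized_tbl(gamma = rep(0.2, 5),
                            Gamma = c(0.1, 0.1, 0.1, 0.1, 0.5))
  loo5 <- mr_leave_one_out(d5)
  expect_equal(nrow(loo5), 5)
  full <- attr(loo5, "full")
  deltas <- abs(loo5$theta - full$theta)
  expect_equal(loo5$excluded_variant[which.max(deltas)], "rs5")
  expect_true(is.logical(attr(loo5, "all_same_side")))
  expect_error(mr_leave_one_out(const[1:2, ]), "at least 3")
})

test_that("funnel data pairs ratios with precisions and scores symmetry", {
  # Constructed +/- delta pairs around 2: symmetric by design.
  deltas <- c(0.1, 0.2, 0.3)
  d <- make_harmonized_tbl(gamma = rep(1, 6),
                           Gamma = 2 + c(deltas, -deltas), se_Gamma = 1)
  fd <- mr_funnel_data(d)
  expect_equal(nrow(fd), 6)
  expect_lt(abs(attr(fd, "symmetry_score")), 1)
  expect_equal(fd$precision, rep(1, 6))

  single <- mr_funnel_data(make_harmonized_tbl(0.1, 0.2))
  expect_equal(nrow(single), 1)
  expect_true(is.na(attr(single, "symmetry_score")))
})
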