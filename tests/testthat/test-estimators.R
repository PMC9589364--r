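test_that("single-instrument IVW reduces to the Wald ratio", {
  h <- make_instruments(beta_x = 0.5, beta_y = 0.10, se_y = 0.01)
  est <- mr_ivw(h)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.02)
  expect_equal(est$n_snps, 1L)
  expect_equal(est$odds_ratio, exp(0.2))
})

test_that("IVW equals the closed-form weighted mean of ratios", {
  h <- make_instruments(beta_x = c(0.3, 0.5), beta_y = c(0.09, 0.10),
                        se_y = c(0.02, 0.01))
  # weights (0.3/0.02)^2 = 225, (0.5/0.01)^2 = 2500; ratios 0.3, 0.2
  est <- mr_ivw(h, effects_model = "fixed")
  expect_equal(est$beta, 567.5 / 2725, tolerance = 1e-14)
  expect_equal(est$se, 1 / sqrt(2725))
})

test_that("homogeneous ratios collapse to that ratio with zero heterogeneity", {
  h <- make_instruments(beta_x = c(0.2, 0.4, 0.5), beta_y = c(0.06, 0.12, 0.15),
                        se_y = c(0.01, 0.02, 0.015))
  fixed <- mr_ivw(h, effects_model = "fixed")
  random <- mr_ivw(h, effects_model = "multiplicative_random")
  expect_equal(fixed$beta, 0.3)
  expect_equal(fixed$Q, 0, tolerance = 1e-20)
  expect_equal(fixed$I2, 0)
  expect_equal(fixed$se, random$se)
})

test_that("random-effects IVW shares the fixed point estimate with an SE never below it", {
  set.seed(9)
  for (i in 1:20) {
    n <- sample(3:15, 1)
    h <- make_instruments(beta_x = runif(n, 0.05, 0.4),
                          beta_y = rnorm(n, 0.05, 0.05),
                          se_y = runif(n, 0.005, 0.05))
    fixed <- mr_ivw(h, "fixed")
    random <- mr_ivw(h, "multiplicative_random")
    expect_equal(fixed$beta, random$beta)
    expect_gte(random$se, fixed$se)
    expect_equal(random$odds_ratio, exp(random$beta))
  }
})

test_that("Egger recovers an exact linear relationship exactly", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  h <- make_instruments(beta_x = bx, beta_y = 0.05 + 0.2 * bx,
                        se_y = rep(0.01, 4))
  est <- mr_egger(h)
  expect_equal(est$beta, 0.2, tolerance = 1e-12)
  expect_equal(est$egger_intercept, 0.05, tolerance = 1e-12)
  expect_equal(est$Q, 0, tolerance = 1e-16)
})

test_that("Egger is invariant to instrument orientation flips", {
  set.seed(12)
  h <- make_instruments(beta_x = runif(6, 0.1, 0.4),
                        beta_y = rnorm(6, 0.02, 0.03),
                        se_y = runif(6, 0.01, 0.03))
  base <- mr_egger(h)
  h2 <- h
  h2$beta_x[2] <- -h2$beta_x[2]
  h2$beta_y[2] <- -h2$beta_y[2]
  flipped <- mr_egger(h2)
  expect_equal(flipped$beta, base$beta)
  expect_equal(flipped$egger_intercept, base$egger_intercept)
  expect_equal(flipped$se, base$se)
})

test_that("Egger coefficients match a weighted lm fit", {
  set.seed(13)
  h <- make_instruments(beta_x = runif(8, 0.05, 0.5),
                        beta_y = rnorm(8, 0.03, 0.04),
                        se_y = runif(8, 0.01, 0.05))
  est <- mr_egger(h)
  fit <- lm(beta_y ~ beta_x, data = h, weights = 1 / h$se_y^2)
  expect_equal(est$beta, unname(coef(fit)["beta_x"]), tolerance = 1e-10)
  expect_equal(est$egger_intercept, unname(coef(fit)["(Intercept)"]),
               tolerance = 1e-10)
})

test_that("balanced pleiotropy leaves the Egger intercept centred on zero", {
  set.seed(14)
  reps <- 300
  intercepts <- vapply(seq_len(reps), function(i) {
    n <- 25
    bx <- runif(n, 0.1, 0.4)
    pleio <- rnorm(n, 0, 0.02)  # mean-zero direct effects
    by <- 0.2 * bx + pleio + rnorm(n, 0, 0.02)
    mr_egger(make_instruments(bx, by, rep(0.02, n)))$egger_intercept
  }, numeric(1))
  expect_lt(abs(mean(intercepts)), 3 * sd(intercepts) / sqrt(reps))
})

test_that("the weighted median interpolates the weighted ratio quantile", {
  h <- make_instruments(beta_x = c(1, 1, 1), beta_y = c(0.1, 0.2, 0.3),
                        se_y = c(1, 1, 1))
  est <- mr_weighted_median(h, n_boot = 50, seed = 3)
  expect_equal(est$beta, 0.2)
  set.seed(31)
  for (i in 1:15) {
    n <- sample(3:10, 1)
    bx <- runif(n, 0.1, 0.5)
    by <- rnorm(n, 0.06, 0.05)
    sy <- runif(n, 0.01, 0.05)
    est <- mr_weighted_median(make_instruments(bx, by, sy), n_boot = 20,
                              seed = i)
    expect_equal(est$beta, oracle_weighted_median(by / bx, (bx / sy)^2),
                 tolerance = 1e-12)
  }
})

test_that("degenerate ratio distributions give the common ratio and vanishing SE", {
  bx <- c(0.2, 0.3, 0.4)
  h <- make_instruments(beta_x = bx, beta_y = 0.25 * bx,
                        se_y = rep(1e-8, 3))
  est <- mr_weighted_median(h, n_boot = 200, seed = 5)
  expect_equal(est$beta, 0.25, tolerance = 1e-10)
  expect_lt(est$se, 1e-6)
})

test_that("the weighted median resists a 49% invalid-weight minority", {
  # 49% of weight at ratio 5, 51% at ratio 0.2
  bx <- rep(1, 100)
  by <- c(rep(5, 49), rep(0.2, 51))
  est <- mr_weighted_median(make_instruments(bx, by, rep(1, 100)),
                            n_boot = 20, seed = 7)
  expect_equal(est$beta, 0.2, tolerance = 0.05)
  expect_equal(oracle_weighted_median(by, rep(1, 100)), 0.2,
               tolerance = 0.05)
})

test_that("heterogeneity statistics follow their closed forms", {
  h <- make_instruments(beta_x = rep(0.3, 6), beta_y = rep(0.09, 6),
                        se_y = rep(0.01, 6))
  het <- heterogeneity(h, 0.3)
  expect_equal(unname(het[c("Q", "I2", "H")]), c(0, 0, 0))
  # Q = 10 with n = 6: I2 = 0.5, H = sqrt(2)
  expect_equal(max(0, (10 - 5) / 10), 0.5)
  expect_equal(sqrt(10 / 5), sqrt(2))
  h2 <- make_instruments(beta_x = c(1, 1), beta_y = c(0.1, 0.3),
                         se_y = c(0.1, 0.1))
  het2 <- heterogeneity(h2, 0.2)
  expect_equal(unname(het2[["Q"]]), 100 * 0.01 * 2)
  expect_equal(unname(het2[["H"]]), sqrt(2 / 1))
  expect_true(all(is.na(heterogeneity(h2[1, ], 0.2))))
})

test_that("degenerate inputs raise informative errors", {
  h <- make_instruments(beta_x = c(0, 0.2), beta_y = c(0.1, 0.1),
                        se_y = c(0.01, 0.01))
  expect_error(mr_ivw(h), "zero exposure effect")
  h2 <- make_instruments(beta_x = c(0.1, 0.2), beta_y = c(0.1, 0.1),
                         se_y = c(0.01, 0.01))
  expect_error(mr_egger(h2), "at least 3")
  expect_error(mr_weighted_median(h2, seed = 1), "at least 3")
  expect_error(mr_weighted_median(make_instruments(1, 1, 1)), "seed")
})

test_that("the tidy method table carries every estimator once", {
  set.seed(15)
  h <- make_instruments(beta_x = runif(6, 0.1, 0.4),
                        beta_y = rnorm(6, 0.05, 0.02),
                        se_y = runif(6, 0.01, 0.03))
  tab <- mr_all_methods(h, n_boot = 50, seed = 2)
  expect_equal(tab$method, c("ivw", "egger", "weighted_median"))
  expect_equal(tab$or, exp(tab$beta))
  expect_true(all(tab$nsnp == 6))
})
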