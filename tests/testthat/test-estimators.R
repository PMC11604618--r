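test_that("the Wald ratio divides betas with a first-order standard error", {
  est <- mr_wald_ratio(0.5, 0.05, 0.1, 0.02)
  expect_equal(est$beta, 0.2)
  expect_equal(est$se, 0.04)

  null_est <- mr_wald_ratio(0.5, 0.05, 0.0, 0.02)
  expect_equal(null_est$beta, 0)
  expect_equal(null_est$pvalue, 1)

  neg <- mr_wald_ratio(-0.4, 0.05, 0.2, 0.04)
  expect_equal(neg$beta, -0.5)
  expect_equal(neg$se, 0.04 / abs(-0.4))  # |.| convention
  expect_error(mr_wald_ratio(0, 0.05, 0.1, 0.02), class = "mr_domain_error")
})

test_that("IVW with one instrument reduces to the Wald ratio", {
  h <- make_h(0.5, 0.05, 0.1, 0.02)
  expect_equal(mr_ivw(h, mode = "fixed")$beta,
               mr_wald_ratio(0.5, 0.05, 0.1, 0.02)$beta)
  expect_equal(mr_ivw(h, mode = "fixed")$se,
               mr_wald_ratio(0.5, 0.05, 0.1, 0.02)$se)
  expect_error(mr_ivw(h, mode = "random"), class = "mr_arity_error")
})

test_that("IVW with equal Wald SEs averages the ratios", {
  # ratios {0.2, 0.3, 0.4}, each with Wald SE 0.1
  h <- make_h(rep(1, 3), 0.01, c(0.2, 0.3, 0.4), rep(0.1, 3))
  fe <- mr_ivw(h, mode = "fixed")
  expect_equal(fe$beta, 0.3)
  expect_equal(fe$se, sqrt(1 / 300))  # sum of weights = 3 * 100
})

test_that("IVW agrees with a weighted-regression oracle to 1e-10", {
  set.seed(31)
  h <- make_h(rnorm(8, 0.4, 0.1), 0.02, rnorm(8, 0.1, 0.05),
              runif(8, 0.02, 0.08))
  fe <- mr_ivw(h, mode = "fixed")
  orc <- oracle_ivw_fixed(h)
  expect_equal(fe$beta, orc$beta, tolerance = 1e-10)
  expect_equal(fe$se, orc$se, tolerance = 1e-10)
})

test_that("random-effects IVW never reports a smaller SE than fixed", {
  set.seed(7)
  for (rep in 1:20) {
    j <- sample(2:12, 1)
    h <- make_h(rnorm(j, 0.4, 0.1), 0.02,
                rnorm(j, 0.1, 0.2), runif(j, 0.02, 0.1))
    expect_gte(mr_ivw(h, "random")$se, mr_ivw(h, "fixed")$se)
  }
})

test_that("Egger recovers an exact line and matches the lm() oracle", {
  bx <- c(0.2, 0.3, 0.4, 0.5, 0.6)
  h <- make_h(bx, 0.02, 0.05 + 0.3 * bx, c(0.03, 0.05, 0.04, 0.06, 0.05))
  e <- mr_egger(h)
  expect_equal(e$slope$beta, 0.3, tolerance = 1e-12)
  expect_equal(e$intercept$estimate, 0.05, tolerance = 1e-12)

  set.seed(11)
  h2 <- make_h(rnorm(5, 0.4, 0.1), 0.02, rnorm(5, 0.1, 0.1),
               runif(5, 0.02, 0.08))
  e2 <- mr_egger(h2)
  orc <- oracle_egger(h2)
  expect_equal(e2$slope$beta, orc$slope, tolerance = 1e-10)
  expect_equal(e2$intercept$estimate, orc$intercept, tolerance = 1e-10)
  expect_equal(e2$slope$se, orc$se_slope, tolerance = 1e-10)
  expect_equal(e2$intercept$se, orc$se_intercept, tolerance = 1e-10)
})

test_that("with a zero intercept the Egger slope equals the IVW estimate", {
  bx <- c(0.2, 0.35, 0.5, 0.65)
  h <- make_h(bx, 0.02, 0.25 * bx, rep(0.04, 4))
  e <- mr_egger(h)
  expect_equal(e$intercept$estimate, 0, tolerance = 1e-12)
  expect_equal(e$slope$beta, mr_ivw(h, "fixed")$beta, tolerance = 1e-12)
})

test_that("Egger orients instruments to non-negative exposure effects", {
  bx <- c(0.2, -0.3, 0.4, -0.5, 0.6)
  by <- 0.05 * sign(bx) + 0.3 * bx
  h <- make_h(bx, 0.02, by, rep(0.04, 5))
  e <- mr_egger(h)
  expect_equal(e$slope$beta, 0.3, tolerance = 1e-12)
  expect_equal(e$intercept$estimate, 0.05, tolerance = 1e-12)
  expect_error(mr_egger(make_h(1:2 / 10, 0.02, 1:2 / 10, 0.04)),
               class = "mr_arity_error")
})

test_that("the weighted median interpolates the weighted ratio CDF", {
  # equal weights, odd J: the plain median
  h <- make_h(rep(1, 3), 1e-6, c(0.1, 0.2, 0.9), rep(0.05, 3))
  wm <- mr_weighted_median(h, n_boot = 100, seed = 1)
  expect_equal(wm$beta, 0.2)

  # unequal weights {0.7, 0.2, 0.1} on ratios {0.1, 0.5, 0.9}
  w_raw <- c(0.7, 0.2, 0.1)
  se_out <- 1 / sqrt(w_raw)  # beta_exp = 1 so Wald weights = w_raw
  h2 <- make_h(rep(1, 3), 1e-6, c(0.1, 0.5, 0.9), se_out)
  wm2 <- mr_weighted_median(h2, n_boot = 100, seed = 1)
  expect_equal(wm2$beta, oracle_weighted_median(c(0.1, 0.5, 0.9), w_raw),
               tolerance = 1e-12)

  set.seed(5)
  h3 <- make_h(rnorm(9, 0.5, 0.1), 0.02, rnorm(9, 0.15, 0.1),
               runif(9, 0.02, 0.1))
  wm3 <- mr_weighted_median(h3, n_boot = 100, seed = 2)
  r <- h3$beta_out / h3$beta_exp
  w <- (abs(h3$beta_exp) / h3$se_out)^2
  expect_equal(wm3$beta, oracle_weighted_median(r, w), tolerance = 1e-12)
})

test_that("identical ratios give a degenerate weighted median with tiny SE", {
  h <- make_h(rep(1, 4), 1e-8, rep(0.4, 4), rep(1e-8, 4))
  wm <- mr_weighted_median(h, n_boot = 200, seed = 3)
  expect_equal(wm$beta, 0.4)
  expect_lt(wm$se, 1e-6)
})

test_that("the mode estimator tracks the ratio cluster, not the outlier", {
  h <- make_h(rep(1, 4), 1e-6, c(0.30, 0.31, 0.29, 1.5), rep(0.05, 4))
  sm <- mr_mode(h, weighted = FALSE, n_boot = 100, seed = 1)
  expect_lt(abs(sm$beta - 0.30), 0.05)

  h2 <- make_h(rep(1, 3), 1e-6, rep(0.4, 3), rep(0.05, 3))
  degenerate <- mr_mode(h2, weighted = TRUE, n_boot = 100, seed = 1)
  expect_equal(degenerate$beta, 0.4)
  expect_equal(degenerate$se, 0)
})

test_that("the mode argmax matches a dense-grid brute-force oracle", {
  set.seed(13)
  h <- make_h(rnorm(8, 0.5, 0.1), 0.02, rnorm(8, 0.15, 0.08),
              runif(8, 0.02, 0.1))
  r <- h$beta_out / h$beta_exp
  se_w <- h$se_out / abs(h$beta_exp)
  bw <- 1 * 0.9 * min(sd(r), mad(r)) * length(r)^(-1 / 5)
  coarse_step <- (diff(range(r)) + 6 * bw) / 511
  for (weighted in c(TRUE, FALSE)) {
    est <- mr_mode(h, weighted = weighted, n_boot = 100, seed = 4)
    w <- if (weighted) 1 / se_w^2 else rep(1, length(r))
    expect_lt(abs(est$beta - oracle_mode(r, w, bw)), coarse_step)
  }
})

test_that("multivariable IVW solves the joint exposure/mediator regression", {
  bx <- c(0.2, 0.5, 0.3, 0.6, 0.4)
  bm <- c(0.5, 0.2, 0.6, 0.3, 0.1)
  h <- make_h(bx, 0.02, 0.2 * bx + 0.1 * bm, rep(0.04, 5),
              beta_med = bm, se_med = 0.03)
  mv <- mr_mvmr_ivw(h)
  expect_equal(mv$beta[mv$term == "exposure"], 0.2, tolerance = 1e-12)
  expect_equal(mv$beta[mv$term == "mediator"], 0.1, tolerance = 1e-12)

  set.seed(17)
  h2 <- make_h(rnorm(8, 0.4, 0.1), 0.02, rnorm(8, 0.1, 0.1),
               runif(8, 0.02, 0.08),
               beta_med = rnorm(8, 0.3, 0.1), se_med = 0.03)
  mv2 <- mr_mvmr_ivw(h2)
  orc <- oracle_mvmr(h2)
  expect_equal(mv2$beta, orc$coefs, tolerance = 1e-10)
  expect_equal(mv2$se, orc$ses, tolerance = 1e-10)
})

test_that("a null mediator column leaves the exposure coefficient univariable", {
  bx <- c(0.2, 0.5, 0.3, 0.6)
  h <- make_h(bx, 0.02, c(0.05, 0.11, 0.05, 0.13), rep(0.04, 4),
              beta_med = rep(0, 4), se_med = 0.03)
  mv <- mr_mvmr_ivw(h)
  expect_equal(mv$beta[mv$term == "exposure"], mr_ivw(h, "fixed")$beta,
               tolerance = 1e-12)
  expect_true(is.na(mv$beta[mv$term == "mediator"]))
})

test_that("collinear exposure and mediator columns are refused", {
  bx <- c(0.2, 0.5, 0.3, 0.6)
  h <- make_h(bx, 0.02, 0.2 * bx, rep(0.04, 4),
              beta_med = 2 * bx, se_med = 0.03)
  expect_error(mr_mvmr_ivw(h), class = "mr_collinearity_error")
})

test_that("odds-ratio conversion reproduces a published IVW row", {
  res <- to_odds_ratio(0.0971, 0.0439)
  expect_equal(round(res$or, 3), 1.102)
  expect_equal(round(res$ci_low, 3), 1.011)
  expect_equal(round(res$ci_high, 3), 1.201)

  null_or <- to_odds_ratio(0, 0.1)
  expect_equal(null_or$or, 1)
  expect_equal(null_or$ci_low * null_or$ci_high, 1, tolerance = 1e-12)

  expect_equal(beta_from_or(to_odds_ratio(0.37, 0.1)$or), 0.37)
})

test_that("estimates are equivariant to relabelling the effect allele", {
  set.seed(23)
  h <- make_h(rnorm(7, 0.4, 0.15), 0.02, rnorm(7, 0.12, 0.08),
              runif(7, 0.02, 0.08))
  flipped <- h
  flipped$beta_exp <- -flipped$beta_exp
  flipped$beta_out <- -flipped$beta_out
  expect_equal(mr_ivw(flipped, "random")$beta, mr_ivw(h, "random")$beta,
               tolerance = 1e-12)
  expect_equal(mr_egger(flipped)$slope$beta, mr_egger(h)$slope$beta,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(flipped, 50, seed = 1)$beta,
               mr_weighted_median(h, 50, seed = 1)$beta, tolerance = 1e-12)
  expect_equal(mr_mode(flipped, n_boot = 50, seed = 1)$beta,
               mr_mode(h, n_boot = 50, seed = 1)$beta, tolerance = 1e-12)
})

test_that("all estimators converge to the true effect as SEs shrink", {
  theta <- 0.25
  set.seed(41)
  gamma <- runif(30, 0.2, 0.6) * sample(c(-1, 1), 30, replace = TRUE)
  se <- 1e-4
  h <- make_h(rnorm(30, gamma, se), se, rnorm(30, theta * gamma, se),
              rep(se, 30))
  expect_lt(abs(mr_ivw(h, "random")$beta - theta), 1e-3)
  expect_lt(abs(mr_ivw(h, "fixed")$beta - theta), 1e-3)
  expect_lt(abs(mr_egger(h)$slope$beta - theta), 1e-3)
  expect_lt(abs(mr_weighted_median(h, 100, seed = 2)$beta - theta), 1e-3)
  expect_lt(abs(mr_mode(h, n_boot = 100, seed = 2)$beta - theta), 1e-3)
})
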