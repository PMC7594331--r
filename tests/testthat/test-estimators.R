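hrow <- function(bx, by, se_y, se_x = 0.01, rsid = "rs1") {
  data.frame(rsid = rsid, beta_exposure = bx, se_exposure = se_x,
             beta_outcome = by, se_outcome = se_y, stringsAsFactors = FALSE)
}

test_that("Wald ratio and delta-method SEs evaluate in closed form", {
  r <- wald_ratio(hrow(0.1, 0.02, 0.01))
  expect_equal(r$estimate, 0.2)
  expect_equal(r$se, 0.1)
  expect_equal(r$weight, r$se^-2)

  # unit exposure effect: ratio reduces to the outcome association
  r1 <- wald_ratio(hrow(1, 0.33, 0.05))
  expect_equal(r1$estimate, 0.33)
  expect_equal(r1$se, 0.05)

  r2 <- wald_ratio(hrow(0.1, 0.02, 0.01, se_x = 0.05), order = "second")
  expect_equal(r2$se, sqrt(0.01 + 0.01), tolerance = 1e-12)

  expect_error(wald_ratio(hrow(0, 0.02, 0.01, rsid = "rsZ")), "rsZ")
})

test_that("second-order delta SE matches a large Monte-Carlo SD for a strong instrument", {
  # strong instrument (z = 10) so the ratio's delta expansion is valid
  set.seed(2024)
  n <- 1e6
  bx_hat <- rnorm(n, 0.1, 0.01)
  by_hat <- rnorm(n, 0.02, 0.01)
  mc_sd <- sd(by_hat / bx_hat)
  delta <- wald_ratio(hrow(0.1, 0.02, 0.01, se_x = 0.01), order = "second")$se
  expect_lt(abs(mc_sd - delta) / mc_sd, 0.02)
})

test_that("IVW reproduces the closed form and degenerates to a single ratio", {
  r <- data.frame(rsid = c("a", "b"), estimate = c(0.1, 0.3),
                  se = 0.1, weight = 100)
  res <- ivw(r)
  expect_equal(res$estimate, 0.2)
  expect_equal(res$se, 0.1 / sqrt(2))
  expect_equal(res$q_stat, 2.0)
  expect_equal(res$q_pval, pchisq(2, 1, lower.tail = FALSE))

  one <- ivw(r[1, ])
  expect_equal(one$estimate, 0.1)
  expect_equal(one$se, 0.1)
  expect_true(is.na(one$q_stat))

  same <- ivw(data.frame(rsid = c("a", "b", "c"), estimate = 0.2,
                         se = c(0.1, 0.2, 0.3), weight = c(100, 25, 100 / 9)))
  expect_equal(same$q_stat, 0)
  expect_equal(same$q_pval, 1)

  expect_error(ivw(r[0, ]), "no ratios")
})

test_that("IVW agrees with a weighted-least-squares oracle on random sets", {
  for (seed in 1:5) {
    r <- random_ratios(7, seed = seed)
    res <- ivw(r)
    fit <- lm(estimate ~ 1, weights = r$weight, data = r)
    expect_equal(res$estimate, unname(coef(fit)), tolerance = 1e-12)
    # fixed-effects IVW = zero-intercept WLS of beta_y on beta_x with
    # first-order Wald weights
    h <- random_harmonized(7, seed = seed + 100)
    ratios <- wald_ratio(h)
    wls <- lm(beta_outcome ~ 0 + beta_exposure,
              weights = 1 / se_outcome^2, data = h)
    expect_equal(ivw(ratios)$estimate, unname(coef(wls)), tolerance = 1e-10)
  }
})

test_that("random-effects IVW inflates the SE only under excess heterogeneity", {
  r <- data.frame(rsid = letters[1:4], estimate = c(-0.5, 0, 0.5, 1),
                  se = 0.05, weight = 400)
  fixed <- ivw(r, model = "fixed")
  random <- ivw(r, model = "random_multiplicative")
  expect_equal(random$estimate, fixed$estimate)
  expect_equal(random$se, fixed$se * sqrt(fixed$q_stat / 3))

  calm <- data.frame(rsid = letters[1:4], estimate = c(0.1, 0.1, 0.1, 0.1001),
                     se = 0.05, weight = 400)
  expect_equal(ivw(calm, model = "random_multiplicative")$se,
               ivw(calm, model = "fixed")$se)  # max(1, .) floor
})

test_that("weighted median interpolates the cumulative-weight midpoints", {
  wm <- gdfmr:::weighted_median_point
  # equal weights, midpoints 1/6, 1/2, 5/6: exact hit at 1/2
  expect_equal(wm(c(0.1, 0.2, 0.9), rep(1, 3)), 0.2)
  # two equal weights, midpoints 0.25 and 0.75: interpolates halfway
  expect_equal(wm(c(0, 1), c(1, 1)), 0.5)
  # dominant weight pulls the estimate to that ratio
  expect_equal(wm(c(0.1, 0.9), c(0.001, 0.999)), 0.9, tolerance = 0.01)
  # unsorted input is sorted internally
  expect_equal(wm(c(0.9, 0.1, 0.2), rep(1, 3)), 0.2)
  # equal weights, odd count with an exact 0.5 midpoint: the sample median
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(wm(x, rep(2, 5)), median(x))
})

test_that("weighted_median guards its preconditions and is seed-reproducible", {
  r <- random_ratios(5, seed = 51)
  expect_error(weighted_median(r[1:2, ]), "at least 3")
  expect_error(weighted_median(r, n_boot = 50), "at least 100")
  a <- weighted_median(r, n_boot = 200, seed = 9)
  b <- weighted_median(r, n_boot = 200, seed = 9)
  expect_equal(a$se, b$se)
  expect_gt(a$se, 0)
  expect_equal(a$estimate,
               gdfmr:::weighted_median_point(r$estimate, r$weight))
})

test_that("MR-Egger recovers an exact linear relationship to machine precision", {
  bx <- c(0.1, 0.15, 0.2, 0.3, 0.4)
  a <- 0.05; b <- 0.25
  h <- data.frame(rsid = sprintf("rs%d", 1:5), beta_exposure = bx,
                  se_exposure = 0.01, beta_outcome = a + b * bx,
                  se_outcome = c(0.02, 0.03, 0.02, 0.04, 0.03))
  res <- mr_egger(h)
  expect_equal(res$estimate, b, tolerance = 1e-12)
  expect_equal(res$egger_intercept, a, tolerance = 1e-12)
  expect_true(is.finite(res$se) && res$se > 0)
  expect_true(is.finite(res$egger_intercept_se))
})

test_that("zero-intercept Egger equals fixed-effects IVW", {
  for (seed in 1:5) {
    h <- random_harmonized(6, seed = seed)
    h$beta_exposure <- abs(h$beta_exposure)
    res0 <- mr_egger(h, intercept = FALSE)
    res_ivw <- ivw(wald_ratio(h, order = "first"))
    expect_equal(res0$estimate, res_ivw$estimate, tolerance = 1e-10)
  }
})

test_that("Egger results are invariant to instrument orientation", {
  h <- random_harmonized(6, seed = 61)
  flipped <- h
  flipped$beta_exposure[2] <- -h$beta_exposure[2]
  flipped$beta_outcome[2] <- -h$beta_outcome[2]
  expect_equal(mr_egger(flipped), mr_egger(h))
})

test_that("Egger rejects degenerate inputs", {
  h <- random_harmonized(6, seed = 63)
  expect_error(mr_egger(h[1:2, ]), "at least 3")
  coll <- h
  coll$beta_exposure <- 0.2
  expect_error(mr_egger(coll), "collinear")
})

test_that("p-values and odds ratios convert as documented", {
  expect_equal(two_sided_p(0, 0.1), 1)
  expect_equal(two_sided_p(1.959964, 1), 0.05, tolerance = 1e-6)
  expect_error(two_sided_p(1, 0), "positive")

  or0 <- to_odds_ratio(0, 0.1)
  expect_equal(or0$odds_ratio, 1)
  expect_equal(or0$ci_low * or0$ci_high, 1, tolerance = 1e-12)
  or <- to_odds_ratio(0.2, 0.05, level = 0.9)
  expect_equal(or$ci_high, exp(0.2 + qnorm(0.95) * 0.05))
  expect_error(to_odds_ratio(0.2, 0.05, level = 1.5), "level")
})

test_that("every mr_result keeps OR = exp(estimate) and a valid CI", {
  r <- random_ratios(5, seed = 71)
  h <- random_harmonized(5, seed = 71)
  for (res in list(ivw(r), weighted_median(r, n_boot = 200, seed = 1),
                   mr_egger(h))) {
    expect_equal(res$odds_ratio, exp(res$estimate))
    expect_lt(res$ci_low, res$odds_ratio)
    expect_gt(res$ci_high, res$odds_ratio)
    expect_gt(res$pval, 0)
    expect_lte(res$pval, 1)
  }
})

test_that("rescaling the exposure divides every causal estimate by the factor", {
  h <- random_harmonized(6, seed = 81)
  for (c_factor in c(0.5, 2, 10)) {
    hs <- h
    hs$beta_exposure <- h$beta_exposure * c_factor
    hs$se_exposure <- h$se_exposure * c_factor
    r <- wald_ratio(h); rs <- wald_ratio(hs)
    expect_equal(ivw(rs)$estimate, ivw(r)$estimate / c_factor)
    expect_equal(gdfmr:::weighted_median_point(rs$estimate, rs$weight),
                 gdfmr:::weighted_median_point(r$estimate, r$weight) / c_factor)
    expect_equal(mr_egger(hs)$estimate, mr_egger(h)$estimate / c_factor)
  }
})

test_that("Q is non-negative and zero only for identical ratios", {
  for (seed in 1:10) {
    r <- random_ratios(6, seed = seed)
    q <- ivw(r)$q_stat
    expect_gte(q, 0)
    if (length(unique(r$estimate)) > 1) expect_gt(q, 0)
  }
})
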