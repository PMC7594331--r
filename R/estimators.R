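#' Two-sample MR estimators and diagnostics
#'
#' The causal effect of the exposure on a binary outcome is estimated on
#' the log-odds scale from harmonized per-SNP associations. Each SNP j
#' contributes a Wald ratio theta_j = beta_outcome_j / beta_exposure_j with
#' a delta-method standard error. Ratios are pooled by inverse-variance
#' weighting (IVW); the weighted-median and MR-Egger estimators relax the
#' assumption that every instrument is valid. Cochran's Q over the ratios
#' quantifies heterogeneity; the MR-Egger intercept tests for directional
#' horizontal pleiotropy. All p-values are two-sided normal; a t-based
#' switch is not offered because with a handful of instruments the field's
#' reference implementations report normal p-values.
#'
#' @name mr-estimators
NULL

mr_result <- function(method, estimate, se, n_snps, level = 0.95,
                      q_stat = NA_real_, q_pval = NA_real_,
                      egger_intercept = NA_real_,
                      egger_intercept_se = NA_real_,
                      egger_intercept_p = NA_real_) {
  or <- to_odds_ratio(estimate, se, level = level)
  structure(data.frame(method = method,
                       n_snps = as.integer(n_snps),
                       estimate = estimate, se = se,
                       pval = two_sided_p(estimate, se),
                       odds_ratio = or$odds_ratio,
                       ci_low = or$ci_low, ci_high = or$ci_high,
                       q_stat = q_stat, q_pval = q_pval,
                       egger_intercept = egger_intercept,
                       egger_intercept_se = egger_intercept_se,
                       egger_intercept_p = egger_intercept_p,
                       stringsAsFactors = FALSE),
            class = c("mr_result", "data.frame"))
}

#' Two-sided normal p-value
#'
#' `p = 2 * (1 - pnorm(|estimate / se|))`.
#'
#' @param estimate point estimate(s).
#' @param se standard error(s), all > 0.
#' @return p-value(s) in (0, 1].
#' @export
two_sided_p <- function(estimate, se) {
  if (any(is.na(se)) || any(se <= 0)) stop("se must be positive")
  2 * stats::pnorm(-abs(estimate / se))
}

#' Odds ratio with confidence interval from a log-odds estimate
#'
#' `OR = exp(estimate)`, CI `exp(estimate -/+ z * se)` with
#' `z = qnorm((1 + level) / 2)`.
#'
#' @param estimate log-odds estimate(s).
#' @param se standard error(s), all > 0.
#' @param level confidence level in (0, 1); default 0.95.
#' @return data.frame with `odds_ratio`, `ci_low`, `ci_high`.
#' @export
to_odds_ratio <- function(estimate, se, level = 0.95) {
  if (any(is.na(se)) || any(se <= 0)) stop("se must be positive")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  z <- stats::qnorm((1 + level) / 2)
  data.frame(odds_ratio = exp(estimate),
             ci_low = exp(estimate - z * se),
             ci_high = exp(estimate + z * se))
}

#' Per-SNP Wald ratios with delta-method standard errors
#'
#' The ratio is beta_outcome / beta_exposure. The first-order delta SE
#' propagates outcome noise only, `se_outcome / |beta_exposure|` — the
#' common two-sample default where instruments are strong. The
#' second-order SE also propagates exposure noise:
#' `sqrt(se_outcome^2 / beta_exposure^2 +
#'       beta_outcome^2 * se_exposure^2 / beta_exposure^4)`.
#'
#' @param h harmonized instruments: data.frame with `rsid`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome` (one or
#'   more rows).
#' @param order `"first"` (default) or `"second"`.
#' @return data.frame with `rsid`, `estimate`, `se`, `weight` (= se^-2).
#' @export
wald_ratio <- function(h, order = c("first", "second")) {
  order <- match.arg(order)
  needed <- c("rsid", "beta_exposure", "beta_outcome", "se_outcome")
  stopifnot(all(needed %in% names(h)))
  zero <- h$beta_exposure == 0
  if (any(zero)) {
    stop("beta_exposure is zero for: ", paste(h$rsid[zero], collapse = ", "))
  }
  estimate <- h$beta_outcome / h$beta_exposure
  se <- if (order == "first") {
    h$se_outcome / abs(h$beta_exposure)
  } else {
    sqrt(h$se_outcome^2 / h$beta_exposure^2 +
           h$beta_outcome^2 * h$se_exposure^2 / h$beta_exposure^4)
  }
  data.frame(rsid = h$rsid, estimate = estimate, se = se,
             weight = se^-2, stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted meta-analysis of Wald ratios
#'
#' Pooled estimate `sum(w * theta) / sum(w)` with weights `w = 1/se^2`.
#' Fixed-effects SE is `1/sqrt(sum(w))`; the multiplicative random-effects
#' model inflates it by `max(1, sqrt(Q / (L - 1)))`. Cochran's
#' `Q = sum(w * (theta - pooled)^2)` with a chi-squared test on L - 1
#' degrees of freedom (heterogeneity fields are `NA` for a single ratio).
#'
#' @param ratios data.frame from [wald_ratio()].
#' @param model `"fixed"` (default) or `"random_multiplicative"`.
#' @param level confidence level for the odds-ratio CI.
#' @return one-row `mr_result` with method `"IVW"`.
#' @export
ivw <- function(ratios, model = c("fixed", "random_multiplicative"),
                level = 0.95) {
  model <- match.arg(model)
  if (nrow(ratios) == 0) stop("no ratios to pool")
  w <- ratios$weight
  est <- sum(w * ratios$estimate) / sum(w)
  se <- 1 / sqrt(sum(w))
  L <- nrow(ratios)
  q_stat <- NA_real_; q_pval <- NA_real_
  if (L > 1) {
    q_stat <- sum(w * (ratios$estimate - est)^2)
    q_pval <- stats::pchisq(q_stat, df = L - 1, lower.tail = FALSE)
    if (model == "random_multiplicative") {
      se <- se * max(1, sqrt(q_stat / (L - 1)))
    }
  }
  mr_result("IVW", est, se, L, level = level,
            q_stat = q_stat, q_pval = q_pval)
}

# weighted 50th percentile of ratios: sort ascending, cumulative weight
# midpoints p_j = cumsum(w)/sum(w) - w_j/2, linear interpolation at 0.5
weighted_median_point <- function(estimate, weight) {
  o <- order(estimate)
  theta <- estimate[o]
  w <- weight[o] / sum(weight)
  p <- cumsum(w) - w / 2
  stats::approx(p, theta, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median estimator
#'
#' Consistent when valid instruments carry at least half the total weight.
#' The point estimate interpolates the inverse-variance-weighted 50th
#' percentile of the sorted Wald ratios; its SE is the standard deviation
#' of the estimate over parametric-bootstrap replicates drawing each ratio
#' from Normal(theta_j, se_j).
#'
#' @param ratios data.frame from [wald_ratio()]; at least 3 rows.
#' @param n_boot bootstrap replicates; at least 100, default 1000.
#' @param seed optional integer seed for the bootstrap.
#' @param level confidence level for the odds-ratio CI.
#' @return one-row `mr_result` with method `"weighted_median"`.
#' @export
weighted_median <- function(ratios, n_boot = 1000, seed = NULL,
                            level = 0.95) {
  if (nrow(ratios) < 3) {
    stop("weighted median needs at least 3 instruments; use ivw()")
  }
  if (n_boot < 100) stop("n_boot must be at least 100")
  est <- weighted_median_point(ratios$estimate, ratios$weight)
  if (!is.null(seed)) set.seed(seed)
  L <- nrow(ratios)
  boot <- vapply(seq_len(n_boot), function(i) {
    theta_star <- stats::rnorm(L, mean = ratios$estimate, sd = ratios$se)
    weighted_median_point(theta_star, ratios$weight)
  }, numeric(1))
  se <- stats::sd(boot)
  mr_result("weighted_median", est, se, L, level = level)
}

#' MR-Egger regression
#'
#' Instruments are first oriented so every exposure beta is positive (both
#' betas of a SNP negated where needed — estimates are invariant to this).
#' Outcome betas are then regressed on exposure betas by weighted least
#' squares with a free intercept and weights 1/se_outcome^2. The slope is
#' the pleiotropy-robust causal estimate under the InSIDE assumption; a
#' nonzero intercept indicates directional horizontal pleiotropy.
#' Standard errors use the model-free weights inflated by the
#' multiplicative overdispersion factor `max(1, sqrt(RSS_w / (L - 2)))`;
#' p-values are two-sided normal for both slope and intercept.
#'
#' With `intercept = FALSE` the regression is forced through the origin,
#' which reproduces the fixed-effects IVW estimate when first-order Wald
#' SEs are used (exposed for cross-checking, not reported as MR-Egger).
#'
#' @param h harmonized instruments (as for [wald_ratio()]); at least 3.
#' @param intercept fit a free intercept (default `TRUE`).
#' @param level confidence level for the odds-ratio CI.
#' @return one-row `mr_result` with method `"MR_Egger"` carrying
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_p`.
#' @export
mr_egger <- function(h, intercept = TRUE, level = 0.95) {
  if (nrow(h) < 3) stop("MR-Egger needs at least 3 instruments")
  flip <- sign(h$beta_exposure)
  if (any(flip == 0)) {
    stop("beta_exposure is zero for: ",
         paste(h$rsid[flip == 0], collapse = ", "))
  }
  bx <- h$beta_exposure * flip
  by <- h$beta_outcome * flip
  w <- 1 / h$se_outcome^2
  if (intercept && stats::sd(bx) < .Machine$double.eps^0.5 * mean(bx)) {
    stop("exposure betas are collinear after orientation; ",
         "MR-Egger fit is singular")
  }
  fit <- if (intercept) {
    stats::lm(by ~ bx, weights = w)
  } else {
    stats::lm(by ~ 0 + bx, weights = w)
  }
  L <- length(bx)
  df_resid <- L - ifelse(intercept, 2L, 1L)
  sigma <- sqrt(sum(w * stats::residuals(fit)^2) / df_resid)
  # SEs from (X'WX)^-1 directly so an exact fit (sigma = 0) stays finite
  X <- stats::model.matrix(fit)
  se_raw <- sqrt(diag(solve(crossprod(X, w * X))))
  names(se_raw) <- colnames(X)
  se_adj <- se_raw * max(1, sigma)
  coefs <- stats::coef(fit)
  if (intercept) {
    mr_result("MR_Egger", coefs[["bx"]], se_adj[["bx"]], L, level = level,
              egger_intercept = coefs[["(Intercept)"]],
              egger_intercept_se = se_adj[["(Intercept)"]],
              egger_intercept_p = two_sided_p(coefs[["(Intercept)"]],
                                              se_adj[["(Intercept)"]]))
  } else {
    mr_result("MR_Egger_no_intercept", coefs[["bx"]], se_adj[["bx"]], L,
              level = level)
  }
}
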