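# shared generators for the test suite; everything is built in code

random_sumstats <- function(n = 5, seed = NULL, trait = "trait",
                            allow_palindromic = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  if (allow_palindromic) pairs <- c(pairs, list(c("A", "T"), c("G", "C")))
  al <- pairs[sample.int(length(pairs), n, replace = TRUE)]
  beta <- rnorm(n, 0, 0.2)
  se <- runif(n, 0.01, 0.05)
  sumstats(data.frame(
    rsid = sprintf("rs%05d", sample.int(99999, n)),
    chr = "19",
    pos = sort(sample.int(1e7, n)),
    effect_allele = vapply(al, `[`, character(1), 1),
    other_allele = vapply(al, `[`, character(1), 2),
    eaf = runif(n, 0.05, 0.95),
    beta = beta,
    se = se,
    pval = 2 * pnorm(-abs(beta / se)),
    n = 1000L,
    stringsAsFactors = FALSE
  ), trait_name = trait)
}

random_ratios <- function(n = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  se <- runif(n, 0.05, 0.3)
  data.frame(rsid = sprintf("rs%d", seq_len(n)),
             estimate = rnorm(n, 0.1, 0.2),
             se = se, weight = se^-2, stringsAsFactors = FALSE)
}

random_harmonized <- function(n = 5, seed = NULL, theta = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  bx <- runif(n, 0.1, 0.4) * sample(c(-1, 1), n, replace = TRUE)
  se_x <- runif(n, 0.01, 0.03)
  se_y <- runif(n, 0.02, 0.06)
  data.frame(rsid = sprintf("rs%d", seq_len(n)),
             beta_exposure = bx, se_exposure = se_x,
             beta_outcome = theta * bx + rnorm(n, 0, se_y),
             se_outcome = se_y, stringsAsFactors = FALSE)
}

# independent greedy-pruning oracle: recompute pair coverage exhaustively
# at each step instead of masking rows incrementally
prune_oracle <- function(stats, ld, r2_threshold) {
  remaining <- stats$rsid[order(stats$pval, stats$rsid)]
  kept <- character()
  while (length(remaining) > 0) {
    lead <- remaining[1]
    kept <- c(kept, lead)
    remaining <- Filter(function(r) r != lead && ld[lead, r] < r2_threshold,
                        remaining)
  }
  sort(kept)
}
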