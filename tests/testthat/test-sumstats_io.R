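test_that("a well-formed file reads back in input order", {
  x <- random_sumstats(5, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(x, path)
  y <- read_sumstats(path, trait_name = attr(x, "trait_name"))
  expect_s3_class(y, "sumstats")
  expect_equal(y$rsid, x$rsid)
})

test_that("write -> read round-trips random sets field for field", {
  for (seed in 1:5) {
    x <- random_sumstats(8, seed = seed)
    if (seed %% 2 == 0) x$eaf[2] <- NA  # missing eaf stays missing, not 0
    path <- withr::local_tempfile(fileext = ".tsv")
    write_sumstats(x, path)
    y <- read_sumstats(path, trait_name = attr(x, "trait_name"))
    expect_equal(as.data.frame(y), as.data.frame(x), tolerance = 1e-12)
  }
})

test_that("comma-separated input is accepted", {
  x <- random_sumstats(4, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  y <- read_sumstats(path)
  expect_equal(y$beta, x$beta, tolerance = 1e-6)
})

test_that("column mapping renames file headers to the canonical schema", {
  x <- random_sumstats(3, seed = 5)
  df <- as.data.frame(x)
  names(df)[names(df) == "rsid"] <- "SNP"
  names(df)[names(df) == "effect_allele"] <- "A1"
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  y <- read_sumstats(path, column_map = c(SNP = "rsid", A1 = "effect_allele"))
  expect_equal(y$rsid, x$rsid)
})

test_that("structural problems are errors naming the offender", {
  x <- as.data.frame(random_sumstats(3, seed = 7))
  x$rsid <- c("rs1227731", "rs1227731", "rs99")
  expect_error(sumstats(x), "rs1227731")

  y <- as.data.frame(random_sumstats(3, seed = 7))
  y$se <- NULL
  expect_error(sumstats(y), "se")
})

test_that("row validation rejects exactly the invalid rows, never silently", {
  x <- as.data.frame(random_sumstats(5, seed = 9))
  x$se[2] <- -0.01             # non-positive SE
  x$pval[4] <- 0               # pval outside (0, 1]
  expect_error(sumstats(x), "non-positive")
  expect_warning(kept <- sumstats(x, drop_invalid = TRUE), "2 invalid")
  expect_equal(nrow(kept), 3)
  expect_equal(attr(kept, "n_rejected"), 2)
  expect_equal(kept$rsid, x$rsid[c(1, 3, 5)])
})

test_that("indel and multi-allelic records are rejected at read time", {
  x <- as.data.frame(random_sumstats(2, seed = 13))
  x$effect_allele[1] <- "AT"
  expect_error(sumstats(x), "single nucleotide")
})

test_that("LD matrix parses, validates range, symmetry and diagonal", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\trsA\trsB", "rsA\t1\t0.85", "rsB\t0.85\t1"), path)
  m <- read_ld_matrix(path)
  expect_equal(m["rsA", "rsB"], 0.85)

  writeLines(c("rsid\trsA\trsB", "rsA\t1\t1.2", "rsB\t1.2\t1"), path)
  expect_error(read_ld_matrix(path), "outside")

  writeLines(c("rsid\trsA\trsB", "rsA\t1\t0.3", "rsB\t0.9\t1"), path)
  expect_error(read_ld_matrix(path), "symmetric")

  writeLines(c("rsid\trsA\trsB", "rsA\t0.5\t0.3", "rsB\t0.3\t0.5"), path)
  expect_error(read_ld_matrix(path), "diagonal")
})

test_that("LD long form and square form agree, and writing round-trips", {
  long <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid_a\trsid_b\tr2", "rsA\trsB\t0.85"), long)
  m1 <- read_ld_matrix(long)
  expect_equal(m1["rsB", "rsA"], 0.85)
  expect_equal(diag(m1), c(rsA = 1, rsB = 1))

  square <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(m1, square)
  m2 <- read_ld_matrix(square)
  expect_equal(unclass(m2), unclass(m1))
})

test_that("results table renders one row per outcome at 3 decimals", {
  h <- random_harmonized(5, seed = 21)
  ratios <- wald_ratio(h)
  results <- rbind(
    cbind(outcome = "CES", as.data.frame(ivw(ratios)), status = "ok"),
    cbind(outcome = "CES", as.data.frame(weighted_median(ratios, seed = 1)),
          status = "ok"),
    cbind(outcome = "CES", as.data.frame(mr_egger(h)), status = "ok"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(results, path)
  grid <- read.delim(path)
  expect_equal(nrow(grid), 1)
  expect_equal(grid$ivw_estimate, round(results$estimate[1], 3))
  expect_equal(grid$wm_estimate, round(results$estimate[2], 3))
  expect_equal(grid$egger_intercept, round(results$egger_intercept[3], 3))
  expect_false(any(is.na(grid[, c("ivw_pval", "wm_pval", "egger_pval")])))

  expect_error(write_results_table(results[0, ], path), "no results")
})

test_that("negative Egger intercepts render with the sign, 3 decimals", {
  results <- rbind(
    cbind(outcome = "CES", as.data.frame(
      gdfmr:::mr_result("IVW", 0.091, 0.043, 5L)), status = "ok"),
    cbind(outcome = "CES", as.data.frame(
      gdfmr:::mr_result("MR_Egger", 0.154, 0.150, 5L,
                        egger_intercept = -0.017,
                        egger_intercept_se = -0.017 / qnorm(0.660 / 2),
                        egger_intercept_p = 0.660)), status = "ok"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(results, path)
  line <- strsplit(readLines(path)[2], "\t")[[1]]
  header <- strsplit(readLines(path)[1], "\t")[[1]]
  expect_equal(line[header == "egger_intercept"], "-0.017")
  expect_equal(line[header == "egger_intercept_p"], "0.660")

  # round-trip read reproduces every numeric cell at the written precision
  grid <- read.delim(path)
  expect_equal(grid$ivw_estimate, 0.091)
  expect_equal(grid$egger_estimate, 0.154)
})

test_that("exclusion lists support comments and blank lines", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# pleiotropy screen", "rs123", "", "rs456 # flagged"), path)
  expect_equal(read_exclusions(path), c("rs123", "rs456"))
})
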