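#' Full two-sample MR analysis across multiple outcomes
#'
#' Instruments are selected once on the exposure study and reused for every
#' outcome (the exposure GWAS does not change between outcomes);
#' harmonization is per-outcome. Each outcome then gets IVW,
#' weighted-median and MR-Egger estimates with Cochran Q and Egger
#' intercept diagnostics. A failure in one outcome never aborts the
#' others; the failed outcome is marked in the grid. Forest rows carry the
#' IVW estimate as the headline per-outcome result.
#'
#' @name mr-pipeline
NULL

#' Analysis configuration
#'
#' Inputs may be given as file paths (read with the package's readers) or
#' as in-memory objects; mixing is allowed.
#'
#' @param exposure exposure `sumstats` or path.
#' @param outcomes named list of outcome `sumstats` or paths; at least one.
#' @param ld `ld_matrix` or path.
#' @param exclusions character vector of rsIDs, path to an exclusion-list
#'   file, or `NULL`.
#' @param p_threshold genome-wide significance threshold; default 5e-8.
#' @param r2_threshold LD pruning boundary; default 0.8.
#' @param wald_order `"first"` or `"second"` delta-method SE.
#' @param ivw_model `"fixed"` or `"random_multiplicative"`.
#' @param n_boot weighted-median bootstrap replicates; default 1000.
#' @param seed integer seed for the bootstrap.
#' @param palindromes a [palindrome_policy()].
#' @param output_dir if non-`NULL`, results grid, forest rows, selection
#'   and harmonization reports and a JSON run manifest are written there.
#' @return an `mr_config` list.
#' @export
mr_config <- function(exposure, outcomes, ld, exclusions = NULL,
                      p_threshold = 5e-8, r2_threshold = 0.8,
                      wald_order = c("first", "second"),
                      ivw_model = c("fixed", "random_multiplicative"),
                      n_boot = 1000, seed = 1,
                      palindromes = palindrome_policy(),
                      output_dir = NULL) {
  if (length(outcomes) < 1) stop("at least one outcome is required")
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    stop("outcomes must be a named list")
  }
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold outside (0, 1)")
  if (r2_threshold < 0 || r2_threshold > 1) stop("r2_threshold outside [0, 1]")
  structure(list(exposure = exposure, outcomes = outcomes, ld = ld,
                 exclusions = exclusions,
                 p_threshold = p_threshold, r2_threshold = r2_threshold,
                 wald_order = match.arg(wald_order),
                 ivw_model = match.arg(ivw_model),
                 n_boot = n_boot, seed = seed,
                 palindromes = palindromes,
                 output_dir = output_dir),
            class = "mr_config")
}

resolve_input <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1) reader(x, ...) else x
}

#' Run the two-sample MR analysis
#'
#' @param config an [mr_config()].
#' @return list with `results` (long grid: one row per outcome and method,
#'   `NA`-filled rows with `status = "failed"` for outcomes that could not
#'   be analyzed), `selection` (a `selection_report`), `harmonization`
#'   (per-outcome action table), `forest` (per-outcome IVW odds ratios
#'   with CIs) and `log` (per-stage counts). No multiple-testing
#'   correction is applied across outcomes.
#' @export
run_mr <- function(config) {
  stopifnot(inherits(config, "mr_config"))
  exposure <- resolve_input(config$exposure, read_sumstats)
  ld <- resolve_input(config$ld, read_ld_matrix)
  exclusions <- if (is.null(config$exclusions)) character() else
    resolve_input(config$exclusions, read_exclusions)
  outcomes <- lapply(config$outcomes, resolve_input, reader = read_sumstats,
                     trait_type = "binary")

  sel <- select_instruments(exposure, ld, exclude = exclusions,
                            p_threshold = config$p_threshold,
                            r2_threshold = config$r2_threshold)
  log <- list(n_candidates = sel$report$n_input,
              n_instruments = length(sel$report$kept))

  grids <- list(); harm_reports <- list(); forest <- list()
  for (name in names(outcomes)) {
    res <- tryCatch(
      analyze_outcome(sel$stats, outcomes[[name]], name, config),
      error = function(e) {
        warning(sprintf("outcome %s failed: %s", name, conditionMessage(e)))
        list(grid = failed_row(name, conditionMessage(e)),
             harm = NULL, forest = NULL)
      })
    grids[[name]] <- res$grid
    if (!is.null(res$harm)) harm_reports[[name]] <- res$harm
    if (!is.null(res$forest)) forest[[name]] <- res$forest
  }
  results <- do.call(rbind, c(grids, list(make.row.names = FALSE)))
  harmonization <- if (length(harm_reports) > 0) {
    do.call(rbind, c(lapply(names(harm_reports), function(n) {
      cbind(outcome = n, harm_reports[[n]], stringsAsFactors = FALSE)
    }), list(make.row.names = FALSE)))
  } else NULL
  forest <- if (length(forest) > 0) {
    do.call(rbind, c(forest, list(make.row.names = FALSE)))
  } else NULL
  log$n_outcomes <- length(outcomes)
  log$n_failed <- length(unique(results$outcome[results$status == "failed"]))

  out <- list(results = results, selection = sel$report,
              harmonization = harmonization, forest = forest, log = log)
  if (!is.null(config$output_dir)) write_run_outputs(out, config)
  out
}

analyze_outcome <- function(instruments, outcome, name, config) {
  h <- harmonize_sets(instruments, outcome, policy = config$palindromes)
  if (nrow(h$harmonized) < 1) {
    stop("no instruments harmonized against outcome ", name)
  }
  ratios <- wald_ratio(h$harmonized, order = config$wald_order)
  res_ivw <- ivw(ratios, model = config$ivw_model)
  rows <- list(cbind(outcome = name, as.data.frame(res_ivw),
                     status = "ok", stringsAsFactors = FALSE))
  if (nrow(h$harmonized) >= 3) {
    res_wm <- weighted_median(ratios, n_boot = config$n_boot,
                              seed = config$seed)
    res_egger <- mr_egger(h$harmonized)
    rows <- c(rows, list(
      cbind(outcome = name, as.data.frame(res_wm), status = "ok",
            stringsAsFactors = FALSE),
      cbind(outcome = name, as.data.frame(res_egger), status = "ok",
            stringsAsFactors = FALSE)))
  } else {
    rows <- c(rows, list(
      na_method_row(name, "weighted_median", "not_applicable"),
      na_method_row(name, "MR_Egger", "not_applicable")))
  }
  grid <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  forest <- data.frame(outcome = name, method = "IVW",
                       odds_ratio = res_ivw$odds_ratio,
                       ci_low = res_ivw$ci_low, ci_high = res_ivw$ci_high,
                       pval = res_ivw$pval, stringsAsFactors = FALSE)
  list(grid = grid, harm = h$report, forest = forest)
}

grid_cols <- c("outcome", "method", "n_snps", "estimate", "se", "pval",
               "odds_ratio", "ci_low", "ci_high", "q_stat", "q_pval",
               "egger_intercept", "egger_intercept_se", "egger_intercept_p",
               "status")

na_method_row <- function(outcome, method, status) {
  row <- data.frame(outcome = outcome, method = method, n_snps = NA_integer_,
                    estimate = NA_real_, se = NA_real_, pval = NA_real_,
                    odds_ratio = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, q_stat = NA_real_, q_pval = NA_real_,
                    egger_intercept = NA_real_, egger_intercept_se = NA_real_,
                    egger_intercept_p = NA_real_, status = status,
                    stringsAsFactors = FALSE)
  row[, grid_cols]
}

failed_row <- function(outcome, message) {
  rows <- do.call(rbind, lapply(c("IVW", "weighted_median", "MR_Egger"),
                                function(m) na_method_row(outcome, m, "failed")))
  attr(rows, "failure_message") <- message
  rows
}

write_run_outputs <- function(out, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$output_dir, f)
  write_results_table(out$results, p("mr_results.tsv"))
  utils::write.table(as.data.frame(out$selection), p("selection_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(out$harmonization)) {
    utils::write.table(out$harmonization, p("harmonization_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$forest)) {
    utils::write.table(format_numeric(out$forest, 3), p("forest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(package = "gdfmr",
                   version = as.character(utils::packageVersion("gdfmr")),
                   seed = config$seed,
                   p_threshold = config$p_threshold,
                   r2_threshold = config$r2_threshold,
                   wald_order = config$wald_order,
                   ivw_model = config$ivw_model,
                   n_boot = config$n_boot,
                   multiple_testing_correction = "none",
                   outcomes = names(config$outcomes))
  jsonlite::write_json(manifest, p("run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}

format_numeric <- function(df, digits) {
  for (col in names(df)) {
    if (is.numeric(df[[col]]) && !is.integer(df[[col]])) {
      df[[col]] <- ifelse(is.na(df[[col]]), "",
                          formatC(df[[col]], format = "f", digits = digits))
    }
  }
  df
}

#' Write a Table-1-style results grid
#'
#' One row per outcome with estimate, SE and p for each of IVW,
#' weighted-median and MR-Egger, the Egger intercept and its p, and the
#' IVW odds ratio with 95% CI. Numbers are formatted to 3 decimals.
#'
#' @param results the long results grid from [run_mr()] (one row per
#'   outcome and method).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  if (is.null(results) || nrow(results) == 0) stop("no results to write")
  outcomes <- unique(results$outcome)
  pick <- function(oc, method, col) {
    v <- results[results$outcome == oc & results$method == method, col]
    if (length(v) == 0) NA_real_ else v[1]
  }
  wide <- do.call(rbind, lapply(outcomes, function(oc) {
    data.frame(outcome = oc,
               n_snps = pick(oc, "IVW", "n_snps"),
               ivw_estimate = pick(oc, "IVW", "estimate"),
               ivw_se = pick(oc, "IVW", "se"),
               ivw_pval = pick(oc, "IVW", "pval"),
               ivw_q = pick(oc, "IVW", "q_stat"),
               ivw_q_pval = pick(oc, "IVW", "q_pval"),
               wm_estimate = pick(oc, "weighted_median", "estimate"),
               wm_se = pick(oc, "weighted_median", "se"),
               wm_pval = pick(oc, "weighted_median", "pval"),
               egger_estimate = pick(oc, "MR_Egger", "estimate"),
               egger_se = pick(oc, "MR_Egger", "se"),
               egger_pval = pick(oc, "MR_Egger", "pval"),
               egger_intercept = pick(oc, "MR_Egger", "egger_intercept"),
               egger_intercept_p = pick(oc, "MR_Egger", "egger_intercept_p"),
               or = pick(oc, "IVW", "odds_ratio"),
               ci_low = pick(oc, "IVW", "ci_low"),
               ci_high = pick(oc, "IVW", "ci_high"),
               status = {
                 st <- results$status[results$outcome == oc]
                 if (any(st == "failed")) "failed" else "ok"
               },
               stringsAsFactors = FALSE)
  }))
  utils::write.table(format_numeric(wide, 3), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
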