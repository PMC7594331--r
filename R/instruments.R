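#' Genetic instrument selection
#'
#' Valid instruments for two-sample MR must be robustly associated with the
#' exposure, mutually independent, and free of known horizontal pleiotropy.
#' Selection composes three filters, in this order: a genome-wide
#' significance filter (keep p strictly below 5e-8), greedy LD pruning
#' (drop one of any pair at r-squared >= 0.8, keeping the smaller-p SNP),
#' and an offline exclusion list standing in for a pleiotropy database
#' screen. Every input SNP is accounted for in the selection report:
#' kept, dropped for p-value, dropped for LD (with the retained partner and
#' the r-squared that triggered removal), or dropped by exclusion.
#'
#' @name instrument-selection
NULL

new_selection_report <- function(n_input, kept = character(),
                                 dropped_pvalue = character(),
                                 dropped_ld = empty_ld_drops(),
                                 dropped_excluded = character(),
                                 unknown_exclusions = character()) {
  structure(list(n_input = n_input,
                 kept = kept,
                 dropped_pvalue = dropped_pvalue,
                 dropped_ld = dropped_ld,
                 dropped_excluded = dropped_excluded,
                 unknown_exclusions = unknown_exclusions),
            class = "selection_report")
}

empty_ld_drops <- function() {
  data.frame(rsid = character(), partner_rsid = character(),
             r2 = numeric(), stringsAsFactors = FALSE)
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("Instrument selection: %d candidates -> %d kept\n",
              x$n_input, length(x$kept)))
  cat(sprintf("  dropped (p-value):  %d %s\n", length(x$dropped_pvalue),
              paste(x$dropped_pvalue, collapse = " ")))
  cat(sprintf("  dropped (LD):       %d %s\n", nrow(x$dropped_ld),
              paste(x$dropped_ld$rsid, collapse = " ")))
  cat(sprintf("  dropped (excluded): %d %s\n", length(x$dropped_excluded),
              paste(x$dropped_excluded, collapse = " ")))
  if (length(x$unknown_exclusions) > 0) {
    cat(sprintf("  exclusion list rsids not in input: %d\n",
                length(x$unknown_exclusions)))
  }
  invisible(x)
}

#' Flatten a selection report to a table
#'
#' One row per input SNP with columns `rsid`, `stage` (`kept`, `pvalue`,
#' `ld`, `excluded`), `partner_rsid` and `r2` (LD drops only).
#'
#' @param x a `selection_report`.
#' @param ... unused.
#' @return a data.frame.
#' @export
as.data.frame.selection_report <- function(x, ...) {
  stage_df <- function(rsid, stage, partner = rep(NA_character_, length(rsid)),
                       r2 = rep(NA_real_, length(rsid))) {
    data.frame(rsid = rsid, stage = rep(stage, length(rsid)),
               partner_rsid = partner, r2 = r2, stringsAsFactors = FALSE)
  }
  rbind(stage_df(x$kept, "kept"),
        stage_df(x$dropped_pvalue, "pvalue"),
        stage_df(x$dropped_ld$rsid, "ld", x$dropped_ld$partner_rsid,
                 x$dropped_ld$r2),
        stage_df(x$dropped_excluded, "excluded"))
}

#' Genome-wide significance filter
#'
#' Keeps SNPs with p strictly below the threshold; a SNP at exactly the
#' threshold is dropped.
#'
#' @param stats a `sumstats` object.
#' @param threshold p-value threshold in (0, 1); default genome-wide 5e-8.
#' @return list with elements `stats` (filtered `sumstats`) and `report`
#'   (a `selection_report`).
#' @export
filter_genomewide <- function(stats, threshold = 5e-8) {
  stopifnot(inherits(stats, "sumstats"))
  if (nrow(stats) == 0) stop("empty summary-statistics set")
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)")
  }
  keep <- stats$pval < threshold
  report <- new_selection_report(n_input = nrow(stats),
                                 kept = stats$rsid[keep],
                                 dropped_pvalue = stats$rsid[!keep])
  list(stats = stats[keep, ], report = report)
}

#' Greedy LD pruning
#'
#' Repeatedly keeps the unprocessed SNP with the smallest p-value (ties
#' broken by lexicographic rsid) and drops every other unprocessed SNP with
#' r-squared at or above the threshold to it. No kept pair is at or above
#' the threshold; each drop records the retained partner and the r-squared.
#'
#' @param stats a `sumstats` object; every rsid must appear in `ld`.
#' @param ld an `ld_matrix`.
#' @param r2_threshold drop boundary; drop at r-squared >= this value.
#' @return list with elements `stats` and `report`.
#' @export
prune_ld <- function(stats, ld, r2_threshold = 0.8) {
  stopifnot(inherits(stats, "sumstats"), inherits(ld, "ld_matrix"))
  if (nrow(stats) == 0) stop("empty summary-statistics set")
  if (r2_threshold < 0 || r2_threshold > 1) {
    stop("r2_threshold must be in [0, 1]")
  }
  missing <- setdiff(stats$rsid, rownames(ld))
  if (length(missing) > 0) {
    stop("rsid(s) missing from LD matrix: ", paste(missing, collapse = ", "))
  }
  pending <- stats$rsid[order(stats$pval, stats$rsid)]
  kept <- character()
  drops <- empty_ld_drops()
  while (length(pending) > 0) {
    lead <- pending[1]
    pending <- pending[-1]
    kept <- c(kept, lead)
    if (length(pending) > 0) {
      r2 <- ld[lead, pending]
      hit <- r2 >= r2_threshold
      if (any(hit)) {
        drops <- rbind(drops, data.frame(rsid = pending[hit],
                                         partner_rsid = lead,
                                         r2 = unname(r2[hit]),
                                         stringsAsFactors = FALSE))
        pending <- pending[!hit]
      }
    }
  }
  keep <- stats$rsid %in% kept
  report <- new_selection_report(n_input = nrow(stats),
                                 kept = stats$rsid[keep],
                                 dropped_ld = drops)
  list(stats = stats[keep, ], report = report)
}

#' Apply a pleiotropy exclusion list
#'
#' Removes listed rsIDs. rsIDs in the list that are absent from the input
#' are ignored with a warning and counted in the report.
#'
#' @param stats a `sumstats` object.
#' @param exclude character vector of rsIDs to remove.
#' @return list with elements `stats` and `report`.
#' @export
apply_exclusions <- function(stats, exclude = character()) {
  stopifnot(inherits(stats, "sumstats"))
  exclude <- unique(as.character(exclude))
  unknown <- setdiff(exclude, stats$rsid)
  if (length(unknown) > 0) {
    warning(sprintf("%d exclusion-list rsid(s) not present in input: %s",
                    length(unknown), paste(unknown, collapse = ", ")))
  }
  keep <- !(stats$rsid %in% exclude)
  report <- new_selection_report(n_input = nrow(stats),
                                 kept = stats$rsid[keep],
                                 dropped_excluded = stats$rsid[!keep],
                                 unknown_exclusions = unknown)
  list(stats = stats[keep, ], report = report)
}

#' Select instruments: significance filter, LD pruning, exclusions
#'
#' Composes [filter_genomewide()], [prune_ld()] and [apply_exclusions()]
#' in that fixed order and aggregates the three stage reports. The
#' conservation invariant holds: every input rsID appears exactly once in
#' the kept set or one of the dropped lists.
#'
#' @param stats a `sumstats` object (exposure GWAS).
#' @param ld an `ld_matrix` covering all candidates surviving the p filter.
#' @param exclude optional rsID exclusion list.
#' @param p_threshold genome-wide significance threshold; default 5e-8.
#' @param r2_threshold LD pruning boundary; default 0.8.
#' @return list with elements `stats` (selected instruments) and `report`.
#' @export
select_instruments <- function(stats, ld, exclude = character(),
                               p_threshold = 5e-8, r2_threshold = 0.8) {
  s1 <- filter_genomewide(stats, threshold = p_threshold)
  if (nrow(s1$stats) == 0) {
    stop("no instruments remain after the p-value filter; ",
         "review the significance threshold")
  }
  s2 <- prune_ld(s1$stats, ld, r2_threshold = r2_threshold)
  s3 <- apply_exclusions(s2$stats, exclude)
  if (nrow(s3$stats) == 0) {
    stop("no instruments remain after selection; review the thresholds ",
         "and exclusion list")
  }
  report <- new_selection_report(
    n_input = nrow(stats),
    kept = s3$report$kept,
    dropped_pvalue = s1$report$dropped_pvalue,
    dropped_ld = s2$report$dropped_ld,
    dropped_excluded = s3$report$dropped_excluded,
    unknown_exclusions = s3$report$unknown_exclusions)
  list(stats = s3$stats, report = report)
}
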