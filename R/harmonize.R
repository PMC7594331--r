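#' Allele harmonization between exposure and outcome studies
#'
#' Two-sample MR combines per-SNP effects from two GWAS that may report
#' them against different effect alleles or opposite DNA strands. Before
#' estimation each SNP's outcome association is aligned to the exposure's
#' effect allele: if the outcome's alleles match, nothing changes; if they
#' are swapped, the outcome beta changes sign (and eaf becomes 1 - eaf);
#' if they are strand complements, they are complemented first and the same
#' rules applied. Palindromic SNPs (A/T or G/C) are their own complements,
#' so strand cannot be resolved from alleles alone; they are resolved by
#' comparing allele frequencies when both are available and informative
#' (outside the ambiguity window around 0.5), otherwise dropped.
#'
#' @name harmonization
NULL

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Palindromic-SNP handling policy
#'
#' @param mode `"frequency"` (default): resolve a palindromic SNP by
#'   effect-allele frequency when both studies report an eaf and both lie
#'   outside the ambiguity window, else drop; `"drop"`: always drop
#'   palindromic SNPs.
#' @param window frequencies in `[window, 1 - window]` are considered too
#'   close to 0.5 to call strand; default 0.42.
#' @return a `palindrome_policy` list.
#' @export
palindrome_policy <- function(mode = c("frequency", "drop"), window = 0.42) {
  mode <- match.arg(mode)
  if (window < 0 || window > 0.5) stop("window must be in [0, 0.5]")
  structure(list(mode = mode, window = window), class = "palindrome_policy")
}

#' Harmonize one SNP's outcome association to the exposure's effect allele
#'
#' @param exposure,outcome one-row `sumstats` (or plain data.frame) records
#'   for the same rsID.
#' @param policy a [palindrome_policy()].
#' @return one-row data.frame with columns `rsid`, `beta_exposure`,
#'   `se_exposure`, `eaf_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_outcome`, `action` (one of `unchanged`, `flipped`,
#'   `dropped_palindromic`, `dropped_mismatch`).
#' @export
harmonize_pair <- function(exposure, outcome, policy = palindrome_policy()) {
  if (nrow(exposure) != 1 || nrow(outcome) != 1) {
    stop("harmonize_pair expects single records")
  }
  if (exposure$rsid != outcome$rsid) {
    stop("rsid mismatch: ", exposure$rsid, " vs ", outcome$rsid)
  }
  ea_x <- exposure$effect_allele; oa_x <- exposure$other_allele
  ea_y <- outcome$effect_allele;  oa_y <- outcome$other_allele
  beta_y <- outcome$beta; eaf_y <- outcome$eaf

  result <- function(action, beta_out = beta_y, eaf_out = eaf_y) {
    data.frame(rsid = exposure$rsid,
               beta_exposure = exposure$beta, se_exposure = exposure$se,
               eaf_exposure = exposure$eaf,
               beta_outcome = beta_out, se_outcome = outcome$se,
               eaf_outcome = eaf_out,
               action = action, stringsAsFactors = FALSE)
  }

  if (is_palindromic(ea_x, oa_x)) {
    # palindrome: complementing is indistinguishable from swapping, so
    # alleles always "match"; orientation must come from frequency
    if (!setequal(c(ea_x, oa_x), c(ea_y, oa_y))) {
      return(result("dropped_mismatch"))
    }
    if (policy$mode == "drop") return(result("dropped_palindromic"))
    w <- policy$window
    eaf_x <- exposure$eaf
    informative <- function(f) !is.na(f) && (f < w || f > 1 - w)
    # compare frequencies of the exposure's effect allele in both studies
    f_y <- if (ea_y == ea_x) eaf_y else if (!is.na(eaf_y)) 1 - eaf_y else NA
    if (!informative(eaf_x) || !informative(f_y)) {
      return(result("dropped_palindromic"))
    }
    same_side <- (eaf_x < 0.5) == (f_y < 0.5)
    beta_aligned <- if (ea_y == ea_x) beta_y else -beta_y
    eaf_aligned <- f_y
    if (same_side) {
      if (ea_y == ea_x) return(result("unchanged"))
      return(result("flipped", beta_aligned, eaf_aligned))
    }
    # opposite sides: the outcome study reported the other strand, so the
    # correct alignment is the opposite of the letter alignment
    final_beta <- -beta_aligned
    final_eaf <- if (is.na(eaf_aligned)) NA else 1 - eaf_aligned
    action <- if (isTRUE(all.equal(final_beta, beta_y))) "unchanged" else "flipped"
    return(result(action, final_beta, final_eaf))
  }

  if (ea_y == ea_x && oa_y == oa_x) return(result("unchanged"))
  if (ea_y == oa_x && oa_y == ea_x) {
    return(result("flipped", -beta_y, if (is.na(eaf_y)) NA else 1 - eaf_y))
  }
  # try the complementary strand
  ea_c <- unname(COMPLEMENT[ea_y]); oa_c <- unname(COMPLEMENT[oa_y])
  if (ea_c == ea_x && oa_c == oa_x) return(result("unchanged"))
  if (ea_c == oa_x && oa_c == ea_x) {
    return(result("flipped", -beta_y, if (is.na(eaf_y)) NA else 1 - eaf_y))
  }
  result("dropped_mismatch")
}

#' Harmonize an instrument set against one outcome study
#'
#' Intersects by rsID, harmonizes each shared SNP with [harmonize_pair()],
#' and reports exposure SNPs missing from the outcome study. Actions
#' partition the input: every exposure rsID appears exactly once in the
#' harmonized table or the missing list.
#'
#' @param exposure_set,outcome_set `sumstats` objects.
#' @param policy a [palindrome_policy()].
#' @return list with `harmonized` (rows with action `unchanged`/`flipped`,
#'   ready for estimation), `report` (all per-SNP actions including drops)
#'   and `missing` (exposure rsIDs absent from the outcome set).
#' @export
harmonize_sets <- function(exposure_set, outcome_set,
                           policy = palindrome_policy()) {
  stopifnot(inherits(exposure_set, "sumstats"),
            inherits(outcome_set, "sumstats"))
  shared <- intersect(exposure_set$rsid, outcome_set$rsid)
  missing <- setdiff(exposure_set$rsid, outcome_set$rsid)
  if (length(shared) == 0) {
    stop("no shared rsids between exposure and outcome sets")
  }
  rows <- lapply(shared, function(id) {
    harmonize_pair(exposure_set[exposure_set$rsid == id, ],
                   outcome_set[outcome_set$rsid == id, ],
                   policy = policy)
  })
  report <- do.call(rbind, rows)
  harmonized <- report[report$action %in% c("unchanged", "flipped"), ,
                       drop = FALSE]
  rownames(harmonized) <- NULL
  list(harmonized = harmonized, report = report, missing = missing)
}
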