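#' GWAS summary-statistics containers and plain-text I/O
#'
#' A `sumstats` object is a data.frame of per-SNP association records from
#' one GWAS, with one row per SNP and the columns `rsid`, `chr`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' `beta` is the effect per copy of the effect allele, on the exposure's
#' measurement scale for a continuous trait or the log-odds scale for a
#' binary outcome. `eaf` and `n` may be missing (`NA`); everything else is
#' required. The trait name and type travel as attributes.
#'
#' @name sumstats
NULL

SUMSTATS_COLS <- c("rsid", "chr", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pval", "n")
REQUIRED_COLS <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pval")
VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a validated summary-statistics set
#'
#' @param df data.frame with at least the required columns `rsid`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval`; optional `chr`,
#'   `pos`, `eaf`, `n` (filled with `NA` when absent).
#' @param trait_name name of the measured trait (e.g. `"GDF15"`).
#' @param trait_type `"continuous"` or `"binary"`.
#' @param drop_invalid if `TRUE`, rows violating a row-level invariant are
#'   dropped with a warning reporting the count (retrievable via
#'   `attr(x, "n_rejected")`); if `FALSE` (default) any invalid row is an
#'   error. Rows are never silently discarded.
#' @return a `sumstats` data.frame, input row order preserved.
#' @export
sumstats <- function(df, trait_name = "trait",
                     trait_type = c("continuous", "binary"),
                     drop_invalid = FALSE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(REQUIRED_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in setdiff(SUMSTATS_COLS, names(df))) df[[col]] <- NA
  df <- df[, SUMSTATS_COLS, drop = FALSE]
  df$rsid <- as.character(df$rsid)
  df$chr <- as.character(df$chr)
  df$pos <- as.integer(df$pos)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- as.numeric(df[[col]])
  }

  dup <- unique(df$rsid[duplicated(df$rsid)])
  if (length(dup) > 0) {
    stop("duplicate rsid(s): ", paste(dup, collapse = ", "))
  }

  bad <- validate_sumstats_rows(df)
  n_rejected <- 0L
  if (any(bad != "")) {
    idx <- which(bad != "")
    msg <- paste0(df$rsid[idx], ": ", bad[idx])
    if (drop_invalid) {
      n_rejected <- length(idx)
      warning(sprintf("rejected %d invalid row(s): %s", n_rejected,
                      paste(msg, collapse = "; ")))
      df <- df[-idx, , drop = FALSE]
    } else {
      stop("invalid row(s): ", paste(msg, collapse = "; "))
    }
  }
  rownames(df) <- NULL
  structure(df,
            trait_name = trait_name,
            trait_type = trait_type,
            n_rejected = n_rejected,
            class = c("sumstats", "data.frame"))
}

# one message per row; "" when the row passes all invariants
validate_sumstats_rows <- function(df) {
  msg <- character(nrow(df))
  add <- function(cond, text) {
    cond[is.na(cond)] <- FALSE
    msg[cond] <<- ifelse(msg[cond] == "", text, paste(msg[cond], text, sep = ", "))
  }
  add(is.na(df$rsid) | df$rsid == "", "missing rsid")
  add(!(df$effect_allele %in% VALID_ALLELES), "effect_allele not a single nucleotide")
  add(!(df$other_allele %in% VALID_ALLELES), "other_allele not a single nucleotide")
  add(df$effect_allele == df$other_allele, "identical alleles")
  add(is.na(df$beta), "missing beta")
  add(is.na(df$se) | df$se <= 0, "non-positive or missing se")
  add(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "pval outside (0, 1]")
  add(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "eaf outside [0, 1]")
  add(!is.na(df$n) & df$n <= 0, "non-positive n")
  msg
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d SNPs\n",
              attr(x, "trait_name"), attr(x, "trait_type"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

# subsetting keeps the class and trait attributes
#' @export
`[.sumstats` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && identical(names(out), SUMSTATS_COLS)) {
    attr(out, "trait_name") <- attr(x, "trait_name")
    attr(out, "trait_type") <- attr(x, "trait_type")
    class(out) <- c("sumstats", "data.frame")
    rownames(out) <- NULL
  }
  out
}

#' Read GWAS summary statistics from a delimited file
#'
#' Canonical layout is tab-separated with a header; comma-separated files
#' are detected and accepted. Missing `eaf`/`n` are encoded as empty
#' fields, never 0. Positions are 1-based.
#'
#' @param path file path.
#' @param column_map optional named character vector mapping file column
#'   names to canonical names, e.g. `c(SNP = "rsid", A1 = "effect_allele")`.
#' @param trait_name,trait_type,drop_invalid passed to [sumstats()];
#'   `trait_name` defaults to the file name without extension.
#' @return a `sumstats` object, input row order preserved.
#' @export
read_sumstats <- function(path, column_map = NULL, trait_name = NULL,
                          trait_type = c("continuous", "binary"),
                          drop_invalid = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  if (!is.null(column_map)) {
    hit <- names(df) %in% names(column_map)
    names(df)[hit] <- unname(column_map[names(df)[hit]])
  }
  if (is.null(trait_name)) {
    trait_name <- sub("\\.[^.]*$", "", basename(path))
  }
  sumstats(df, trait_name = trait_name, trait_type = match.arg(trait_type),
           drop_invalid = drop_invalid)
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else if (grepl(",", header)) "," else "\t"
}

#' Write summary statistics as tab-separated text
#'
#' Missing `eaf`/`n` become empty fields. Round-trips through
#' [read_sumstats()] losslessly at full double precision.
#'
#' @param x a `sumstats` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  out <- as.data.frame(x)
  for (col in c("eaf", "beta", "se", "pval", "n")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         formatC(out[[col]], format = "g", digits = 17))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read an exclusion list of rsIDs
#'
#' One rsID per line; `#` starts a comment; blank lines ignored.
#'
#' @param path file path.
#' @return character vector of rsIDs.
#' @export
read_exclusions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[lines != ""]
}
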