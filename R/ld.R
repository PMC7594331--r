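#' Pairwise linkage-disequilibrium matrices
#'
#' An `ld_matrix` is a symmetric numeric matrix of squared allelic
#' correlations (r-squared) with rsID row and column names, unit diagonal
#' and all entries in [0, 1]. Correlated instruments carry redundant
#' information, so candidate SNP pairs at or above an r-squared threshold
#' are pruned before estimation.
#'
#' @name ld_matrix
NULL

LD_TOL <- 1e-6

#' Construct a validated LD matrix
#'
#' @param r2 square numeric matrix of squared correlations.
#' @param rsids rsID labels; defaults to `rownames(r2)`.
#' @return an `ld_matrix`.
#' @export
ld_matrix <- function(r2, rsids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (nrow(r2) != ncol(r2)) stop("LD matrix must be square")
  if (is.null(rsids) || length(rsids) != nrow(r2)) {
    stop("LD matrix needs one rsid label per row")
  }
  if (anyDuplicated(rsids)) stop("duplicate rsids in LD matrix")
  storage.mode(r2) <- "double"
  dimnames(r2) <- list(rsids, rsids)
  if (anyNA(r2)) stop("LD matrix contains missing values")
  if (any(r2 < -LD_TOL | r2 > 1 + LD_TOL)) {
    stop("r2 values outside [0, 1]")
  }
  if (any(abs(r2 - t(r2)) > LD_TOL)) stop("LD matrix is not symmetric")
  if (any(abs(diag(r2) - 1) > LD_TOL)) stop("LD matrix diagonal must be 1")
  r2[r2 < 0] <- 0
  r2[r2 > 1] <- 1
  r2 <- (r2 + t(r2)) / 2
  diag(r2) <- 1
  structure(r2, class = c("ld_matrix", "matrix", "array"))
}

#' Read an LD r-squared matrix
#'
#' Accepts either a labeled square tab-separated matrix (row names in the
#' first column, matching column names in the header) or the long
#' three-column form `rsid_a`, `rsid_b`, `r2` (unlisted pairs default to
#' r-squared 0). Asymmetries beyond 1e-6 are rejected.
#'
#' @param path file path.
#' @return an `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  long_form <- ncol(df) == 3 &&
    all(c("rsid_a", "rsid_b", "r2") %in% names(df))
  if (long_form) {
    rsids <- unique(c(df$rsid_a, df$rsid_b))
    m <- diag(1, length(rsids))
    dimnames(m) <- list(rsids, rsids)
    for (i in seq_len(nrow(df))) {
      a <- df$rsid_a[i]; b <- df$rsid_b[i]
      m[a, b] <- df$r2[i]
      m[b, a] <- df$r2[i]
    }
    return(ld_matrix(m))
  }
  rn <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) stop("LD matrix file is not square")
  if (!setequal(rn, colnames(m))) {
    stop("LD matrix row and column labels do not match")
  }
  rownames(m) <- rn
  m <- m[, rn, drop = FALSE]  # align column order to row order
  ld_matrix(m)
}

#' Write an LD matrix as labeled square TSV
#'
#' @param x an `ld_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(x, path) {
  stopifnot(inherits(x, "ld_matrix"))
  df <- data.frame(rsid = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
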