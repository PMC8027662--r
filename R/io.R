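#' Construct validated SNP-trait association records
#'
#' The unit of summary data: one SNP's effect estimate, standard error,
#' two-sided p-value, and sample size. When both `p` and the pair
#' (`beta_hat`, `se`) are supplied, `p` must agree with the 1-df
#' chi-square upper tail of the Wald statistic to 1e-6 relative
#' tolerance; when `p` is omitted it is computed from the Wald statistic.
#'
#' @param snp_id Character SNP identifier(s).
#' @param beta_hat Effect estimate(s).
#' @param se Standard error(s), `> 0`.
#' @param p Optional two-sided p-value(s) in (0, 1].
#' @param n Sample size(s), integer `>= 4` (so the Fisher-Z variance
#'   `1/(n-3)` is defined).
#' @return A `data.frame` with columns `snp`, `beta`, `se`, `p`, `n`.
#' @examples
#' assoc_summary("rs1", 0.5, 0.1, n = 1000)
#' @export
assoc_summary <- function(snp_id, beta_hat, se, p = NULL, n) {
  k <- length(snp_id)
  if (length(beta_hat) != k || length(se) != k || length(n) != k) {
    stop("all fields must have the same length")
  }
  if (any(!is.finite(se)) || any(se <= 0)) stop("'se' must be strictly positive")
  if (any(n < 4)) stop("'n' must be at least 4 (Fisher-Z variance 1/(n-3))")
  w <- wald_chisq(beta_hat, se)
  p_wald <- chisq_upper_p(w)
  if (is.null(p)) {
    p <- p_wald
  } else {
    if (any(p <= 0) || any(p > 1)) stop("'p' must lie in (0, 1]")
    rel <- abs(p - p_wald) / pmax(p_wald, .Machine$double.xmin)
    bad <- which(rel > 1e-6)
    if (length(bad)) {
      stop("p-value inconsistent with (beta/se)^2 at row(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  data.frame(snp = as.character(snp_id), beta = beta_hat, se = se,
             p = p, n = as.integer(n), stringsAsFactors = FALSE)
}

.ma_cols <- c("SNP", "A1", "A2", "freq", "b", "se", "p", "N")

#' Read a summary-statistics table
#'
#' Reads GWAS/eQTL summary statistics in either the GCTA-COJO `.ma`
#' dialect (whitespace-delimited columns `SNP A1 A2 freq b se p N`) or a
#' plain tab-delimited dialect with header columns `snp beta se p n`
#' (optional `a1 a2 freq`). Rows failing validation (non-positive
#' standard error, p outside (0, 1], sample size below 4, non-numeric
#' cells) are reported with their file line numbers; duplicate SNP ids
#' are fatal.
#'
#' @param path Path to the file; a header row is required.
#' @param dialect `"ma"` or `"tsv"`.
#' @return A `data.frame` of class `"summary_table"` with standardized
#'   columns `snp`, `beta`, `se`, `p`, `n` and, when present, `a1`,
#'   `a2`, `freq`; the dialect is kept in attribute `"dialect"`.
#' @examples
#' path <- system.file("extdata", "example_exposure.ma", package = "mrselect")
#' read_summary_table(path, "ma")
#' @export
read_summary_table <- function(path, dialect = c("ma", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = if (dialect == "ma") "" else "\t",
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  if (dialect == "ma") {
    missing_cols <- setdiff(tolower(.ma_cols), tolower(names(raw)))
    if (length(missing_cols)) {
      stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
    }
    idx <- match(tolower(.ma_cols), tolower(names(raw)))
    raw <- raw[idx]
    names(raw) <- c("snp", "a1", "a2", "freq", "beta", "se", "p", "n")
  } else {
    required <- c("snp", "beta", "se", "p", "n")
    missing_cols <- setdiff(required, tolower(names(raw)))
    if (length(missing_cols)) {
      stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
    }
    names(raw) <- tolower(names(raw))
    keep <- intersect(c("snp", "a1", "a2", "freq", "beta", "se", "p", "n"),
                      names(raw))
    raw <- raw[keep]
  }
  num_cols <- intersect(c("freq", "beta", "se", "p", "n"), names(raw))
  # data row i sits on file line i + 1 (header is line 1)
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(v) & !is.na(raw[[cl]]) & raw[[cl]] != "NA")
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' at line(s): %s", cl,
                   paste(bad + 1L, collapse = ", ")))
    }
    raw[[cl]] <- v
  }
  raw$n <- as.integer(raw$n)
  problems <- character(0)
  chk <- function(bad, what) {
    if (length(bad)) {
      problems <<- c(problems, sprintf("%s at line(s): %s", what,
                                       paste(bad + 1L, collapse = ", ")))
    }
  }
  chk(which(!is.finite(raw$se) | raw$se <= 0), "standard error must be > 0")
  chk(which(!is.finite(raw$p) | raw$p <= 0 | raw$p > 1), "p must lie in (0, 1]")
  chk(which(is.na(raw$n) | raw$n < 4), "sample size must be >= 4")
  if (anyDuplicated(raw$snp)) {
    problems <- c(problems, paste("duplicate SNP id(s):",
                                  paste(unique(raw$snp[duplicated(raw$snp)]),
                                        collapse = ", ")))
  }
  if (length(problems)) {
    stop("invalid summary table '", path, "':\n  ",
         paste(problems, collapse = "\n  "))
  }
  structure(raw, dialect = dialect, class = c("summary_table", "data.frame"))
}

#' Write a summary-statistics table
#'
#' Serializes a table read (or constructed) in one of the dialects of
#' [read_summary_table()]. Numeric cells are written with `as.character`
#' (up to 15 significant digits), so writing a table previously written
#' by this function reproduces the file byte-for-byte.
#'
#' @param x A `summary_table` or compatible `data.frame`.
#' @param path Output path.
#' @param dialect `"ma"` or `"tsv"`; defaults to the table's own dialect.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(x, path, dialect = NULL) {
  if (is.null(dialect)) dialect <- attr(x, "dialect")
  if (is.null(dialect)) dialect <- "tsv"
  dialect <- match.arg(dialect, c("ma", "tsv"))
  out <- as.data.frame(lapply(x, function(col) {
    if (is.numeric(col)) as.character(col) else as.character(col)
  }), stringsAsFactors = FALSE)
  if (dialect == "ma") {
    need <- c("snp", "a1", "a2", "freq", "beta", "se", "p", "n")
    if (!all(need %in% names(out))) {
      stop("the 'ma' dialect requires columns: ", paste(need, collapse = ", "))
    }
    out <- out[need]
    names(out) <- .ma_cols
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Absolute sample correlation implied by a Wald statistic at sample size n:
# inverse of the selection-floor relationship, used to move summary
# statistics onto the correlation/Fisher-Z scale.
wald_to_abs_corr <- function(w, n) {
  if (any(n < 3)) stop("'n' must be at least 3")
  1 / sqrt(1 + (n - 2) / pmax(w, .Machine$double.xmin))
}
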