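#' Rookery baseline table
#'
#' Container for the rookery side of a mixed stock analysis: per-rookery
#' haplotype sample counts, rookery sizes (nests per year) and, optionally,
#' per-destination ocean-current transport probabilities.
#'
#' @param X integer matrix of haplotype counts, one row per rookery, one
#'   column per haplotype.  Row names are rookery codes, column names are
#'   haplotype names.
#' @param N numeric vector of rookery sizes (nests/year), one per rookery;
#'   strictly positive.
#' @param p optional numeric matrix of transport probabilities, rookeries x
#'   mixed stocks, each entry in `[0, 1]`, row sums at most 1 (+ tolerance).
#'   Column names are mixed-stock codes.
#' @param tol tolerance allowed on transport-probability row sums.
#'
#' @return An object of class `baseline_table`: a list with elements
#'   `rookery_codes`, `haplotype_names`, `X`, `N` and `p` (`NULL` when
#'   transport probabilities are absent).
#' @seealso [mixed_table()], [read_baseline_table()], [harmonize()]
#' @export
baseline_table <- function(X, N, p = NULL, tol = 1e-6) {
  X <- as.matrix(X)
  if (is.null(rownames(X)) || is.null(colnames(X)))
    stop("baseline counts need rookery row names and haplotype column names")
  if (anyDuplicated(rownames(X)))
    stop("duplicated rookery codes: ",
         paste(unique(rownames(X)[duplicated(rownames(X))]), collapse = ", "))
  if (anyDuplicated(colnames(X)))
    stop("duplicated haplotype names in baseline table")
  storage.mode(X) <- "integer"
  if (anyNA(X) || any(X < 0))
    stop("baseline counts must be nonnegative integers")
  zero <- rowSums(X) == 0
  if (any(zero))
    stop("rookery with zero total baseline count: ",
         paste(rownames(X)[zero], collapse = ", "))
  N <- as.numeric(N)
  if (length(N) != nrow(X) || anyNA(N) || any(N <= 0))
    stop("rookery sizes N must be strictly positive, one per rookery")
  names(N) <- rownames(X)
  if (!is.null(p)) {
    p <- as.matrix(p)
    if (nrow(p) != nrow(X))
      stop("transport matrix p must have one row per rookery")
    if (is.null(colnames(p)))
      stop("transport matrix p needs mixed-stock column names")
    if (anyNA(p) || any(p < 0) || any(p > 1))
      stop("transport probabilities must lie in [0, 1]")
    bad <- rowSums(p) > 1 + tol
    if (any(bad))
      stop("transport probability row sum exceeds 1 for: ",
           paste(rownames(X)[bad], collapse = ", "))
    rownames(p) <- rownames(X)
  }
  structure(list(rookery_codes = rownames(X),
                 haplotype_names = colnames(X),
                 X = X, N = N, p = p),
            class = "baseline_table")
}

#' Mixed-stock table
#'
#' Per-site haplotype counts of individuals sampled from mixed aggregations
#' (here, oceanic dispersal-stage juveniles).
#'
#' @param Y integer matrix of haplotype counts, one row per mixed stock, one
#'   column per haplotype; row names are stock codes, column names haplotype
#'   names.
#' @return An object of class `mixed_table`: list with `stock_codes`,
#'   `haplotype_names` and `Y`.
#' @export
mixed_table <- function(Y) {
  Y <- as.matrix(Y)
  if (is.null(rownames(Y)) || is.null(colnames(Y)))
    stop("mixed counts need stock row names and haplotype column names")
  if (anyDuplicated(rownames(Y)))
    stop("duplicated mixed-stock codes")
  if (anyDuplicated(colnames(Y)))
    stop("duplicated haplotype names in mixed table")
  storage.mode(Y) <- "integer"
  if (anyNA(Y) || any(Y < 0))
    stop("mixed-stock counts must be nonnegative integers")
  zero <- rowSums(Y) == 0
  if (any(zero))
    stop("mixed stock with zero total count: ",
         paste(rownames(Y)[zero], collapse = ", "))
  structure(list(stock_codes = rownames(Y),
                 haplotype_names = colnames(Y),
                 Y = Y),
            class = "mixed_table")
}

#' @export
print.baseline_table <- function(x, ...) {
  cat(sprintf("baseline_table: %d rookeries x %d haplotypes (%d samples)\n",
              nrow(x$X), ncol(x$X), sum(x$X)))
  cat("  rookeries:", paste(x$rookery_codes, collapse = " "), "\n")
  cat(sprintf("  sizes (nests/yr): %.0f-%.0f; transport probabilities: %s\n",
              min(x$N), max(x$N),
              if (is.null(x$p)) "absent"
              else paste(colnames(x$p), collapse = ", ")))
  invisible(x)
}

#' @export
print.mixed_table <- function(x, ...) {
  cat(sprintf("mixed_table: %d stocks x %d haplotypes (%d individuals)\n",
              nrow(x$Y), ncol(x$Y), sum(x$Y)))
  cat("  stocks:", paste(x$stock_codes, collapse = " "), "\n")
  invisible(x)
}

# Autodetect comma vs tab on the header line.
.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (lengths(regmatches(header, gregexpr("\t", header))) > 0) "\t" else ","
}

#' Read a rookery baseline table
#'
#' Table dialect: delimited text (comma or tab, autodetected), one row per
#' rookery.  The first column holds the rookery code; the reserved header
#' `SIZE` holds rookery size (nests/year); headers of the form
#' `P_<stockcode>` hold transport probabilities to each sampled mixed stock;
#' every other column is a haplotype count.  Column order is preserved.
#'
#' @param path path to a delimited text file.
#' @return A [baseline_table()].
#' @export
read_baseline_table <- function(path) {
  sep <- .detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("baseline table needs a code column, a SIZE column and counts: ", path)
  codes <- as.character(df[[1L]])
  cols <- colnames(df)[-1L]
  if (!"SIZE" %in% cols)
    stop("baseline table is missing the reserved SIZE column: ", path)
  p_cols <- grep("^P_", cols, value = TRUE)
  hap_cols <- setdiff(cols, c("SIZE", p_cols))
  if (length(hap_cols) == 0L)
    stop("baseline table has no haplotype columns: ", path)
  X <- as.matrix(df[, hap_cols, drop = FALSE])
  rownames(X) <- codes
  if (any(X != round(X)))
    stop("non-integer haplotype count in baseline table: ", path)
  p <- NULL
  if (length(p_cols) > 0L) {
    p <- as.matrix(df[, p_cols, drop = FALSE])
    colnames(p) <- sub("^P_", "", p_cols)
  }
  baseline_table(X, N = df[["SIZE"]], p = p)
}

#' Write a rookery baseline table
#'
#' Inverse of [read_baseline_table()]; writes the documented dialect.
#'
#' @param x a [baseline_table()].
#' @param path output file path.
#' @param sep field separator, `","` or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_baseline_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "baseline_table"))
  df <- data.frame(rookery = x$rookery_codes, SIZE = x$N,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$p)) {
    pp <- as.data.frame(x$p)
    colnames(pp) <- paste0("P_", colnames(x$p))
    df <- cbind(df, pp)
  }
  df <- cbind(df, as.data.frame(x$X, check.names = FALSE))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a mixed-stock table
#'
#' Same dialect as [read_baseline_table()] but without the reserved
#' covariate columns: first column mixed-stock code, remaining columns
#' haplotype counts.
#'
#' @param path path to a delimited text file.
#' @return A [mixed_table()].
#' @export
read_mixed_table <- function(path) {
  sep <- .detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("mixed-stock table needs a code column plus counts: ", path)
  Y <- as.matrix(df[, -1L, drop = FALSE])
  rownames(Y) <- as.character(df[[1L]])
  if (any(Y != round(Y)))
    stop("non-integer haplotype count in mixed table: ", path)
  mixed_table(Y)
}

#' Write a mixed-stock table
#'
#' @param x a [mixed_table()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_mixed_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "mixed_table"))
  df <- cbind(data.frame(stock = x$stock_codes, stringsAsFactors = FALSE),
              as.data.frame(x$Y, check.names = FALSE))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
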