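#' Assign a query sequence to a named haplotype
#'
#' Compares a query control-region sequence against a reference set by
#' literal character identity after uppercasing and gap stripping.  Both
#' query and references are anchored at the shared 5' primer end, so the
#' overlap between a query and a reference is their common leading segment
#' (the shorter of the two lengths).  IUPAC ambiguity codes are treated as
#' ordinary distinct characters, never wildcards: named haplotypes are
#' defined by exact sequence.
#'
#' @param query nucleotide string (any case; may contain gap characters).
#' @param references a [hap_records()] data frame.
#' @param min_overlap minimum overlap (nt) required for a comparison to be
#'   meaningful; a query whose overlap with any reference falls below this
#'   is an error, not an orphan.
#' @return A list of class `hap_assignment` with elements `status` (one of
#'   `"match"`, `"ambiguous"`, `"orphan"`) and `names` (the matching
#'   reference name(s); empty for an orphan).
#' @export
match_haplotype <- function(query, references, min_overlap = 400L) {
  stopifnot(inherits(references, "hap_records"), length(query) == 1L)
  q <- .strip_gaps(toupper(trimws(query)))
  if (!.is_iupac(q)) stop("non-IUPAC character in query sequence")
  refs <- .strip_gaps(references$sequence)
  overlaps <- pmin(nchar(q), nchar(refs))
  if (any(overlaps < min_overlap))
    stop(sprintf("overlap below minimum (%d nt) with reference(s): %s",
                 min_overlap,
                 paste(references$name[overlaps < min_overlap],
                       collapse = ", ")))
  hit <- substr(refs, 1L, overlaps) == substr(q, 1L, overlaps)
  names <- references$name[hit]
  status <- if (length(names) == 0L) "orphan"
            else if (length(names) == 1L) "match" else "ambiguous"
  structure(list(status = status, names = names), class = "hap_assignment")
}

#' @export
print.hap_assignment <- function(x, ...) {
  cat("haplotype assignment:", x$status,
      if (length(x$names)) paste0("(", paste(x$names, collapse = ", "), ")"),
      "\n")
  invisible(x)
}

#' Collapse haplotypes into short-fragment classes
#'
#' Truncates each (long-fragment) sequence to a shared window and groups
#' names whose truncated sequences are identical, emulating the loss of
#' resolution when long-fragment haplotypes are matched against the ~500-bp
#' fragments that dominate the rookery literature.  Class labels are the
#' lexicographically smallest member name, so the partition is
#' deterministic.
#'
#' @param records a [hap_records()] data frame.
#' @param window half-open 0-based interval `c(start, end)` on the aligned
#'   fragment; the default `c(0, 490)` keeps the first 490 positions.
#' @return A named list of character vectors: one element per class, the
#'   element name being the class label and the value the member haplotype
#'   names (in input order).
#' @export
collapse_to_short_classes <- function(records, window = c(0L, 490L)) {
  stopifnot(inherits(records, "hap_records"),
            length(window) == 2L, window[1L] >= 0L, window[2L] > window[1L])
  seqs <- .strip_gaps(records$sequence)
  too_short <- nchar(seqs) < window[2L]
  if (any(too_short))
    stop("record(s) shorter than the truncation window: ",
         paste(records$name[too_short], collapse = ", "))
  trunc <- substr(seqs, window[1L] + 1L, window[2L])
  groups <- split(records$name, factor(trunc, levels = unique(trunc)))
  labels <- vapply(groups, function(g) sort(g)[1L], "")
  names(groups) <- labels
  groups[order(labels)]
}

#' Harmonize baseline and mixed tables onto one haplotype axis
#'
#' Sums counts of same-class haplotypes (per a partition such as the one
#' from [collapse_to_short_classes()]) and aligns both tables on a single
#' shared haplotype axis in a single order (baseline class order, i.e. the
#' order of first appearance in the baseline table).  Total counts are
#' conserved exactly.  A mixed-stock haplotype whose class is absent from
#' every baseline after collapsing has no defined likelihood in the mixed
#' stock model; by default this is a hard error, optionally such orphan
#' columns are dropped with a warning.
#'
#' @param baseline a [baseline_table()].
#' @param mixed a [mixed_table()].
#' @param classes named list partitioning haplotype names into classes
#'   (names = class labels), or `NULL` for the identity partition.
#' @param orphans `"error"` (default) or `"drop"`.
#' @return A list with elements `baseline` and `mixed`, harmonized, plus
#'   `dropped` (character vector of dropped orphan haplotype classes).
#' @export
harmonize <- function(baseline, mixed, classes = NULL,
                      orphans = c("error", "drop")) {
  stopifnot(inherits(baseline, "baseline_table"),
            inherits(mixed, "mixed_table"))
  orphans <- match.arg(orphans)
  all_names <- union(baseline$haplotype_names, mixed$haplotype_names)
  if (is.null(classes))
    classes <- setNames(as.list(all_names), all_names)
  member2class <- setNames(rep(names(classes), lengths(classes)),
                           unlist(classes))
  missing <- setdiff(all_names, names(member2class))
  if (length(missing) > 0L)
    stop("haplotype(s) not covered by the class partition: ",
         paste(missing, collapse = ", "))

  collapse <- function(mat) {
    cls <- member2class[colnames(mat)]
    t(rowsum(t(mat), group = cls, reorder = FALSE))
  }
  Xc <- collapse(baseline$X)
  Yc <- collapse(mixed$Y)

  base_present <- colnames(Xc)[colSums(Xc) > 0]
  orphan_cls <- setdiff(colnames(Yc)[colSums(Yc) > 0], base_present)
  if (length(orphan_cls) > 0L) {
    if (orphans == "error")
      stop("orphan haplotype(s) absent from every baseline: ",
           paste(orphan_cls, collapse = ", "))
    warning("dropping orphan haplotype(s) absent from every baseline: ",
            paste(orphan_cls, collapse = ", "))
    Yc <- Yc[, setdiff(colnames(Yc), orphan_cls), drop = FALSE]
  }
  axis <- colnames(Xc)  # baseline class order defines the shared axis
  Y_aligned <- matrix(0L, nrow(Yc), length(axis),
                      dimnames = list(rownames(Yc), axis))
  keep <- intersect(colnames(Yc), axis)
  Y_aligned[, keep] <- Yc[, keep]
  list(baseline = baseline_table(Xc, baseline$N, baseline$p),
       mixed = mixed_table(Y_aligned),
       dropped = orphan_cls)
}
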