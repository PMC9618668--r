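#' Construct a set of haplotype records
#'
#' A haplotype record ties a haplotype name to its defining control-region
#' sequence plus optional metadata: species code, fragment class
#' (`"long"` for the ~800/950-bp fragments, `"short"` for the ~500-bp or
#' shorter literature fragments) and alternate names (synonyms).
#'
#' @param name character vector of haplotype names; unique within the set.
#' @param sequence character vector of nucleotide sequences (IUPAC alphabet;
#'   gap characters `-` and `.` are tolerated and ignored for identity).
#' @param species optional character vector of species codes (e.g. `"Cm"`).
#' @param fragment_class optional; `"long"`, `"short"` or `NA`.  When `NA`
#'   it is inferred from the gap-stripped length via `short_max`/`long_min`.
#' @param synonyms optional list of character vectors of alternate names.
#' @param short_max,long_min length thresholds (nt) used to infer the
#'   fragment class: at most `short_max` is short, above `long_min` is long.
#' @return A `data.frame` of class `hap_records` with columns `name`,
#'   `sequence`, `species`, `fragment_class` and a list column `synonyms`.
#' @export
hap_records <- function(name, sequence, species = NA_character_,
                        fragment_class = NA_character_, synonyms = NULL,
                        short_max = 500L, long_min = 700L) {
  name <- as.character(name)
  sequence <- toupper(trimws(as.character(sequence)))
  if (length(name) != length(sequence))
    stop("name and sequence lengths differ")
  if (anyDuplicated(name))
    stop("duplicate haplotype name: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  ok <- .is_iupac(sequence)
  if (!all(ok))
    stop("non-IUPAC character in sequence of: ",
         paste(name[!ok], collapse = ", "))
  if (any(nchar(.strip_gaps(sequence)) == 0L))
    stop("empty sequence (after gap stripping) for: ",
         paste(name[nchar(.strip_gaps(sequence)) == 0L], collapse = ", "))
  species <- rep_len(as.character(species), length(name))
  fragment_class <- rep_len(as.character(fragment_class), length(name))
  len <- nchar(.strip_gaps(sequence))
  infer <- is.na(fragment_class)
  fragment_class[infer] <- ifelse(len[infer] <= short_max, "short",
                                  ifelse(len[infer] > long_min, "long",
                                         NA_character_))
  bad <- !is.na(fragment_class) & !fragment_class %in% c("long", "short")
  if (any(bad))
    stop("fragment_class must be 'long' or 'short': ",
         paste(name[bad], collapse = ", "))
  if (is.null(synonyms)) synonyms <- rep(list(character(0)), length(name))
  out <- data.frame(name = name, sequence = sequence, species = species,
                    fragment_class = fragment_class,
                    stringsAsFactors = FALSE)
  out$synonyms <- synonyms
  class(out) <- c("hap_records", "data.frame")
  out
}

# Line-level FASTA sanity check so errors can name the offending line;
# Biostrings does the actual parsing afterwards.
.validate_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonblank[1L]]), ">"))
    stop(sprintf("malformed FASTA (line %d does not start a record): %s",
                 nonblank[1L], path))
  for (i in nonblank) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">")) next
    if (!.is_iupac(ln))
      stop(sprintf("non-IUPAC character on line %d of %s", i, path))
  }
  invisible(TRUE)
}

#' Read haplotype reference sequences from FASTA
#'
#' Headers may carry metadata fields after a configurable delimiter:
#' `>name<delim>species<delim>fragment_class`.  Sequences are uppercased and
#' terminal whitespace is stripped; gap characters are kept as read.
#'
#' @param path path to a FASTA file.
#' @param meta_delim single-character delimiter separating header fields
#'   (default `"|"`).
#' @return A [hap_records()] data frame.
#' @export
read_hap_fasta <- function(path, meta_delim = "|") {
  .validate_fasta_lines(path)
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  fields <- strsplit(headers, meta_delim, fixed = TRUE)
  nm <- trimws(vapply(fields, `[`, "", 1L))
  if (anyDuplicated(nm))
    stop("duplicate haplotype name in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sp <- trimws(vapply(fields, function(f) if (length(f) >= 2L) f[2L]
                      else NA_character_, ""))
  fc <- trimws(vapply(fields, function(f) if (length(f) >= 3L) f[3L]
                      else NA_character_, ""))
  hap_records(name = nm, sequence = as.character(set),
              species = sp, fragment_class = fc)
}

#' Write haplotype records to FASTA
#'
#' @param records a [hap_records()] data frame.
#' @param path output path.
#' @param meta_delim delimiter for header metadata fields; species and
#'   fragment class are written when present.
#' @return `path`, invisibly.
#' @export
write_hap_fasta <- function(records, path, meta_delim = "|") {
  stopifnot(inherits(records, "hap_records"))
  hdr <- records$name
  has_sp <- !is.na(records$species)
  has_fc <- !is.na(records$fragment_class)
  extra <- ifelse(has_sp | has_fc,
                  paste0(meta_delim, ifelse(has_sp, records$species, "")),
                  "")
  extra <- ifelse(has_fc,
                  paste0(extra, meta_delim, records$fragment_class),
                  extra)
  out <- character(2L * nrow(records))
  out[c(TRUE, FALSE)] <- paste0(">", hdr, extra)
  out[c(FALSE, TRUE)] <- records$sequence
  writeLines(out, path)
  invisible(path)
}
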