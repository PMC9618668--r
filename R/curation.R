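#' @name curation
#' @title Haplotype registry curation
#'
#' @description Utilities for curating a global registry of named
#' control-region haplotypes assembled from the literature: merging
#' redundantly named identical sequences, disambiguating name collisions,
#' binning reported life stages into five standard categories, and
#' reporting species x life-stage (x ocean basin) cells with no data.
NULL

.LIFE_STAGE_BINS <- c("dispersal-stage juvenile",
                      "post-dispersal juvenile",
                      "mixed juvenile/adult",
                      "in-water adult",
                      "rookery")

.OCEAN_BASINS <- c("Atlantic", "Mediterranean", "Indian", "Pacific")

# controlled vocabulary -> bin; matching is case-insensitive on the
# trimmed term.  Strandings are assumed to occur near foraging sites,
# hence map to the in-water adult bin.
.LIFE_STAGE_VOCAB <- c(
  "dispersal-stage juvenile" = "dispersal-stage juvenile",
  "dispersal stage"          = "dispersal-stage juvenile",
  "oceanic juvenile"         = "dispersal-stage juvenile",
  "post-hatchling"           = "dispersal-stage juvenile",
  "lost years"               = "dispersal-stage juvenile",
  "post-dispersal juvenile"  = "post-dispersal juvenile",
  "neritic juvenile"         = "post-dispersal juvenile",
  "coastal juvenile"         = "post-dispersal juvenile",
  "juvenile foraging"        = "post-dispersal juvenile",
  "mixed juvenile/adult"     = "mixed juvenile/adult",
  "mixed foraging aggregation" = "mixed juvenile/adult",
  "juvenile/adult foraging"  = "mixed juvenile/adult",
  "in-water adult"           = "in-water adult",
  "foraging adult"           = "in-water adult",
  "adult foraging"           = "in-water adult",
  "stranding"                = "in-water adult",
  "stranding near foraging site" = "in-water adult",
  "bycatch"                  = "in-water adult",
  "rookery"                  = "rookery",
  "nesting female"           = "rookery",
  "nesting"                  = "rookery",
  "nesting beach"            = "rookery",
  "egg"                      = "rookery",
  "hatchling"                = "rookery")

#' Bin a reported life stage into one of five categories
#'
#' Maps a raw life-stage description (controlled vocabulary) onto the five
#' bins used for gap analysis: dispersal-stage juvenile, post-dispersal
#' juvenile, mixed post-dispersal juvenile/in-water adult, in-water adult,
#' rookery (nesting female, egg and/or hatchling samples).
#'
#' @param term character vector of raw stage descriptions.
#' @return character vector of bin names.
#' @export
bin_life_stage <- function(term) {
  key <- tolower(trimws(term))
  out <- .LIFE_STAGE_VOCAB[key]
  bad <- is.na(out)
  if (any(bad))
    stop("life stage term(s) outside the controlled vocabulary: ",
         paste(unique(term[bad]), collapse = ", "))
  unname(out)
}

.normalize_basins <- function(basins) {
  # Indo-Pacific granularity: recorded as both Indian and Pacific
  basins <- unlist(lapply(basins, function(b) {
    if (tolower(b) == "indo-pacific") c("Indian", "Pacific") else b
  }))
  bad <- !basins %in% .OCEAN_BASINS
  if (any(bad))
    stop("unknown ocean basin(s): ", paste(unique(basins[bad]), collapse = ", "))
  sort(unique(basins))
}

#' Construct a haplotype registry
#'
#' @param name,sequence,species as in [hap_records()].
#' @param author character vector: last name of the publishing author
#'   (used for name disambiguation).
#' @param year integer publication year.
#' @param basins list of character vectors; each a subset of Atlantic,
#'   Mediterranean, Indian, Pacific (`"Indo-Pacific"` is recorded as both
#'   Indian and Pacific).
#' @param life_stages list of character vectors of raw stage terms or bin
#'   names (binned via [bin_life_stage()]).
#' @param citation free-text source citations.
#' @return A data frame of class `hap_registry` with list columns
#'   `basins`, `life_stages` and `synonyms`.
#' @export
hap_registry <- function(name, sequence, species, author = NA_character_,
                         year = NA_integer_, basins = NULL,
                         life_stages = NULL, citation = NA_character_) {
  n <- length(name)
  name <- as.character(name)
  sequence <- toupper(trimws(as.character(sequence)))
  # duplicate names are allowed here: resolving them is what dedupe() and
  # disambiguate() are for
  ok <- .is_iupac(sequence)
  if (!all(ok))
    stop("non-IUPAC character in sequence of: ",
         paste(name[!ok], collapse = ", "))
  if (any(nchar(.strip_gaps(sequence)) == 0L))
    stop("empty sequence for: ",
         paste(name[nchar(.strip_gaps(sequence)) == 0L], collapse = ", "))
  if (is.null(basins)) basins <- rep(list(character(0)), n)
  if (is.null(life_stages)) life_stages <- rep(list(character(0)), n)
  out <- data.frame(name = name, sequence = sequence,
                    species = rep_len(as.character(species), n),
                    author = rep_len(as.character(author), n),
                    year = rep_len(as.integer(year), n),
                    citation = rep_len(as.character(citation), n),
                    stringsAsFactors = FALSE)
  out$basins <- lapply(basins, .normalize_basins)
  out$life_stages <- lapply(life_stages, function(s)
    if (length(s) == 0L) character(0) else sort(unique(bin_life_stage(s))))
  out$synonyms <- rep(list(character(0)), n)
  class(out) <- c("hap_registry", "data.frame")
  out
}

# nomenclature prefix = leading non-digit part of a name, e.g. "Cm-A"
.name_prefix <- function(name) sub("[0-9].*$", "", name)

.canonical_name <- function(names, years, species_prefixes) {
  # prefer the species' dominant nomenclature prefix, then earliest
  # publication year, then lexicographic
  tab <- sort(table(species_prefixes), decreasing = TRUE)
  dominant <- names(tab)[tab == max(tab)][1L]
  pref <- .name_prefix(names) == dominant
  years[is.na(years)] <- .Machine$integer.max
  ord <- order(!pref, years, names)
  names[ord][1L]
}

#' Merge identically sequenced haplotypes under one canonical name
#'
#' Within each species, records whose gap-stripped sequences are identical
#' are merged into one curated haplotype; the retained name is chosen by a
#' deterministic rule (dominant nomenclature prefix for the species, then
#' earliest publication year, then lexicographic) and the other names
#' become synonyms.  Basin and life-stage metadata are unioned.  Merge
#' events are reported via `message()`.
#'
#' @param registry a [hap_registry()].
#' @return A list with `records` (curated `hap_registry`) and
#'   `synonym_map` (named character vector, merged name -> canonical name).
#' @export
dedupe <- function(registry) {
  stopifnot(inherits(registry, "hap_registry"))
  key <- paste(registry$species, .strip_gaps(toupper(registry$sequence)),
               sep = "\r")
  groups <- split(seq_len(nrow(registry)), factor(key, levels = unique(key)))
  prefixes <- split(.name_prefix(registry$name), registry$species)
  keep <- integer(0)
  syn_map <- character(0)
  out <- registry[0, ]
  for (g in groups) {
    canon <- .canonical_name(registry$name[g], registry$year[g],
                             prefixes[[registry$species[g[1L]]]])
    i <- g[match(canon, registry$name[g])]
    rec <- registry[i, ]
    others <- setdiff(registry$name[g], canon)
    rec$synonyms <- list(sort(unique(c(registry$synonyms[[i]], others,
                                       unlist(registry$synonyms[g])))))
    rec$basins <- list(sort(unique(unlist(registry$basins[g]))))
    rec$life_stages <- list(sort(unique(unlist(registry$life_stages[g]))))
    cits <- unique(registry$citation[g])
    rec$citation <- paste(cits[!is.na(cits)], collapse = "; ")
    if (length(others) > 0L) {
      message("dedupe: merged ", paste(others, collapse = ", "),
              " into ", canon)
      syn_map[others] <- canon
    }
    out <- rbind(out, rec)
  }
  rownames(out) <- NULL
  class(out) <- c("hap_registry", "data.frame")
  list(records = out, synonym_map = syn_map)
}

#' Resolve name collisions between distinct sequences
#'
#' When two distinct sequences carry the same name, each colliding record
#' is renamed by appending `_<author>`.  A collision between distinct
#' sequences published by the same author cannot be resolved and is an
#' error.
#'
#' @param registry a [hap_registry()].
#' @return The registry with collision-free names.
#' @export
disambiguate <- function(registry) {
  stopifnot(inherits(registry, "hap_registry"))
  for (pass in 1:5) {
    seqs_all <- .strip_gaps(toupper(registry$sequence))
    dup_names <- unique(registry$name[duplicated(registry$name)])
    changed <- FALSE
    for (nm in dup_names) {
      idx <- which(registry$name == nm)
      seqs <- seqs_all[idx]
      if (length(unique(seqs)) == 1L) next  # identical sequences: dedupe's job
      authors <- registry$author[idx]
      if (anyDuplicated(authors[!duplicated(seqs)]))
        stop("cannot disambiguate '", nm, "': distinct sequences share an ",
             "author")
      registry$name[idx] <- paste0(nm, "_", authors)
      changed <- TRUE
    }
    if (!changed) break
  }
  # only identical-sequence duplicates (dedupe's job) may remain
  left <- registry$name[duplicated(registry$name)]
  for (nm in unique(left)) {
    s <- .strip_gaps(toupper(registry$sequence[registry$name == nm]))
    if (length(unique(s)) > 1L)
      stop("could not resolve name collision for '", nm, "'")
  }
  registry
}

#' Distinct-haplotype presence counts by species, basin and life stage
#'
#' @param registry a curated [hap_registry()].
#' @return A 3-d array species x basin x life-stage of distinct-haplotype
#'   counts, with attribute `species_totals` (distinct haplotypes per
#'   species).
#' @export
presence_matrix <- function(registry) {
  stopifnot(inherits(registry, "hap_registry"))
  species <- sort(unique(registry$species))
  arr <- array(0L, dim = c(length(species), length(.OCEAN_BASINS),
                           length(.LIFE_STAGE_BINS)),
               dimnames = list(species = species, basin = .OCEAN_BASINS,
                               life_stage = .LIFE_STAGE_BINS))
  for (i in seq_len(nrow(registry))) {
    sp <- registry$species[i]
    for (b in registry$basins[[i]])
      for (s in registry$life_stages[[i]])
        arr[sp, b, s] <- arr[sp, b, s] + 1L
  }
  attr(arr, "species_totals") <- vapply(split(registry$name,
                                              registry$species),
                                        function(x) length(unique(x)), 0L)
  arr
}

#' Report empty species x life-stage (x basin) cells
#'
#' Lists the combinations for which the registry holds no haplotype at
#' all -- the sampling gaps.  Deterministically sorted.
#'
#' @param registry a curated [hap_registry()].
#' @param by_basin include the ocean basin axis (default `FALSE`:
#'   gaps per species and life stage across all basins).
#' @return A data frame with columns `species`, `life_stage` and, when
#'   `by_basin`, `basin`; zero rows when every cell is filled.
#' @export
gap_report <- function(registry, by_basin = FALSE) {
  stopifnot(inherits(registry, "hap_registry"))
  species <- sort(unique(registry$species))
  if (by_basin) {
    cells <- expand.grid(species = species, basin = .OCEAN_BASINS,
                         life_stage = .LIFE_STAGE_BINS,
                         stringsAsFactors = FALSE)
    seen <- unique(do.call(rbind, lapply(seq_len(nrow(registry)), function(i)
      expand.grid(species = registry$species[i],
                  basin = registry$basins[[i]],
                  life_stage = registry$life_stages[[i]],
                  stringsAsFactors = FALSE))))
  } else {
    cells <- expand.grid(species = species, life_stage = .LIFE_STAGE_BINS,
                         stringsAsFactors = FALSE)
    seen <- unique(do.call(rbind, lapply(seq_len(nrow(registry)), function(i)
      if (length(registry$life_stages[[i]]) == 0L) NULL else
        data.frame(species = registry$species[i],
                   life_stage = registry$life_stages[[i]],
                   stringsAsFactors = FALSE))))
  }
  key <- function(df) do.call(paste, c(df, sep = "\r"))
  out <- cells[!key(cells) %in% key(seen), , drop = FALSE]
  out <- out[do.call(order, out), , drop = FALSE]
  rownames(out) <- NULL
  out
}
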