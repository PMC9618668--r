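# Deterministic builders for synthetic sequence fixtures.

rand_dna <- function(n, len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# Synthetic stand-ins for the EiA23 short-fragment family: seven hawksbill
# haplotypes identical over the first 490 positions (the short-fragment
# window) but distinct in the long-fragment tail, plus one unrelated
# haplotype.  The sequences are synthetic; only the indistinguishability
# structure is modelled.
make_eia23_family <- function() {
  core <- rand_dna(1, 490, seed = 4923)
  tails <- rand_dna(7, 310, seed = 4924)
  fam <- c("EiA23", "EiA24", "EiA39", "EiA41", "EiA42", "EiA43", "EiA83")
  other <- rand_dna(1, 800, seed = 4925)
  hap_records(name = c(fam, "EiA1"),
              sequence = c(paste0(core, tails), other),
              species = "Ei")
}

# small harmonizable table pair
toy_tables <- function() {
  X <- matrix(c(10L, 0L, 2L,
                0L, 8L, 1L), 2, 3, byrow = TRUE,
              dimnames = list(c("AA", "BB"), c("h1", "h2", "h3")))
  Y <- matrix(c(3L, 4L, 1L), 1, 3,
              dimnames = list(c("S1"), c("h1", "h2", "h3")))
  list(baseline = baseline_table(X, N = c(100, 200)),
       mixed = mixed_table(Y))
}

# random baseline/mixed pair on a shared haplotype axis (may include
# all-zero baseline columns only when allow_orphans)
random_tables <- function(R = 3, M = 2, H = 4, allow_orphans = FALSE) {
  repeat {
    X <- matrix(rpois(R * H, 2), R, H,
                dimnames = list(sprintf("R%d", 1:R), sprintf("h%d", 1:H)))
    Y <- matrix(rpois(M * H, 1), M, H,
                dimnames = list(sprintf("S%d", 1:M), sprintf("h%d", 1:H)))
    storage.mode(X) <- "integer"; storage.mode(Y) <- "integer"
    if (any(rowSums(X) == 0) || any(rowSums(Y) == 0)) next
    if (!allow_orphans && any(colSums(Y) > 0 & colSums(X) == 0)) next
    return(list(baseline = baseline_table(X, N = runif(R, 10, 1000)),
                mixed = mixed_table(Y)))
  }
}

# random partition of a set of names into classes
random_partition <- function(names) {
  k <- sample(seq_along(names), 1)
  grp <- sample(seq_len(k), length(names), replace = TRUE)
  split(names, grp)
}
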