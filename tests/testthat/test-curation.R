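reg_from <- function(name, sequence, species = "Cm", author = NA, year = NA,
                     basins = NULL, stages = NULL) {
  hap_registry(name, sequence, species, author = author, year = year,
               basins = basins, life_stages = stages)
}

test_that("identical sequences merge under the canonical-name rule", {
  set.seed(60)
  s <- rand_dna(1, 600)
  reg <- reg_from(c("Cm-A1.1", "CmA77", "Cm-A2.1"),
                  c(s, s, rand_dna(1, 600)),
                  author = c("Smith", "Jones", "Lee"),
                  year = c(1998L, 2005L, 2001L))
  out <- suppressMessages(dedupe(reg))
  expect_equal(nrow(out$records), 2L)
  # dominant prefix "Cm-A" (2 of 3 names) wins over the odd one out
  expect_true("Cm-A1.1" %in% out$records$name)
  expect_equal(out$records$synonyms[[which(out$records$name == "Cm-A1.1")]],
               "CmA77")
  expect_equal(unname(out$synonym_map["CmA77"]), "Cm-A1.1")

  # all-distinct sequences: output equals input
  set.seed(61)
  reg2 <- reg_from(sprintf("Cm-A%d.1", 1:5), rand_dna(5, 600))
  out2 <- dedupe(reg2)
  expect_equal(out2$records$name, reg2$name)
  expect_equal(length(out2$synonym_map), 0L)
})

test_that("dedupe recovers a planted duplicate structure and is idempotent", {
  set.seed(62)
  base <- rand_dna(6, 500)                 # 6 true haplotypes
  copies <- c(1:6, sample(6, 14, replace = TRUE))  # 20 published names
  reg <- reg_from(sprintf("Ei%02d", 1:20), base[copies], species = "Ei",
                  year = sample(1990:2020, 20, replace = TRUE))
  out <- suppressMessages(dedupe(reg))
  expect_equal(nrow(out$records), 6L)
  # recovered groups equal the planted partition
  planted <- split(reg$name, copies)
  got <- lapply(seq_len(nrow(out$records)), function(i)
    sort(c(out$records$name[i], out$records$synonyms[[i]])))
  key <- function(gs) sort(vapply(gs, function(g) paste(sort(g),
                                                        collapse = ","), ""))
  expect_equal(unname(key(got)), unname(key(planted)))
  # distinct-sequence count conserved
  expect_equal(length(unique(out$records$sequence)),
               length(unique(reg$sequence)))
  # idempotence
  again <- dedupe(out$records)
  expect_equal(again$records$name, out$records$name)
  expect_equal(again$records$sequence, out$records$sequence)
  expect_equal(length(again$synonym_map), 0L)
})

test_that("name collisions across distinct sequences get author suffixes", {
  set.seed(63)
  reg <- reg_from(c("X1", "X1"), rand_dna(2, 500),
                  author = c("Abreu", "Bolker"))
  out <- disambiguate(reg)
  expect_setequal(out$name, c("X1_Abreu", "X1_Bolker"))

  # no collisions: identity
  reg2 <- reg_from(c("A1", "B1"), rand_dna(2, 500), author = c("X", "Y"))
  expect_equal(disambiguate(reg2)$name, c("A1", "B1"))

  # same author, distinct sequences: unresolvable
  reg3 <- reg_from(c("Z1", "Z1"), rand_dna(2, 500),
                   author = c("Same", "Same"))
  expect_error(disambiguate(reg3), "cannot disambiguate")
})

test_that("disambiguation leaves no duplicate names across 500 fuzz cases", {
  set.seed(64)
  authors <- c("Ab", "Bo", "Ca", "Du", "El", "Fi", "Gu", "Ha")
  for (case in 1:500) {
    n <- sample(2:8, 1)
    nm <- sample(sprintf("N%d", 1:4), n, replace = TRUE)
    # one author per name occurrence, unique within each name group
    au <- ave(nm, nm, FUN = function(x) sample(authors, length(x)))
    reg <- reg_from(nm, rand_dna(n, 120), author = au)
    out <- disambiguate(reg)
    # all remaining duplicates must be identical sequences
    dup <- out$name[duplicated(out$name)]
    for (d in dup)
      expect_equal(length(unique(out$sequence[out$name == d])), 1L)
    expect_equal(anyDuplicated(paste(out$name, out$sequence)), 0L)
  }
})

test_that("life stages bin into the five categories", {
  expect_equal(bin_life_stage("nesting female"), "rookery")
  expect_equal(bin_life_stage("Hatchling"), "rookery")
  expect_equal(bin_life_stage("stranding near foraging site"),
               "in-water adult")
  expect_equal(bin_life_stage("oceanic juvenile"), "dispersal-stage juvenile")
  expect_equal(bin_life_stage("neritic juvenile"), "post-dispersal juvenile")
  expect_equal(bin_life_stage("mixed foraging aggregation"),
               "mixed juvenile/adult")
  # bin names map to themselves
  expect_equal(bin_life_stage("in-water adult"), "in-water adult")
  expect_error(bin_life_stage("larval"), "larval")
})

test_that("gap report finds exactly the planted empty cells", {
  set.seed(65)
  stages <- c("dispersal-stage juvenile", "post-dispersal juvenile",
              "mixed juvenile/adult", "in-water adult", "rookery")
  # species Cm covers everything; Lk and Dc lack dispersal-stage data
  reg <- reg_from(
    name = sprintf("q%d", 1:7),
    sequence = rand_dna(7, 400),
    species = c(rep("Cm", 5), "Lk", "Dc"),
    basins = c(rep(list("Atlantic"), 7)),
    stages = c(as.list(stages), list(stages[-1]), list(stages[-1])))
  gr <- gap_report(reg)
  expect_equal(nrow(gr), 2L)
  expect_setequal(gr$species, c("Lk", "Dc"))
  expect_true(all(gr$life_stage == "dispersal-stage juvenile"))

  # fully covered registry: empty report
  full <- reg_from(sprintf("f%d", 1:5), rand_dna(5, 400), species = "Cm",
                   basins = rep(list(c("Atlantic", "Mediterranean",
                                       "Indian", "Pacific")), 5),
                   stages = as.list(stages))
  expect_equal(nrow(gap_report(full)), 0L)
  # by-basin report is deterministic and covers the full grid
  grb <- gap_report(reg, by_basin = TRUE)
  expect_true(all(c("species", "basin", "life_stage") %in% names(grb)))
  expect_equal(grb, grb[do.call(order, grb), ], ignore_attr = TRUE)
})

test_that("presence matrix marginals agree with the registry", {
  set.seed(66)
  reg <- reg_from(sprintf("p%d", 1:6), rand_dna(6, 400),
                  species = c("Cm", "Cm", "Ei", "Ei", "Ei", "Dc"),
                  basins = list("Atlantic", "Indo-Pacific", "Atlantic",
                                "Pacific", "Indian", "Atlantic"),
                  stages = list("rookery", "rookery", "nesting",
                                "stranding", "oceanic juvenile", "rookery"))
  pm <- presence_matrix(reg)
  expect_equal(attr(pm, "species_totals")[["Cm"]], 2L)
  # Indo-Pacific recorded in both Indian and Pacific
  expect_equal(pm["Cm", "Indian", "rookery"], 1L)
  expect_equal(pm["Cm", "Pacific", "rookery"], 1L)
  expect_equal(pm["Cm", "Atlantic", "rookery"], 1L)
  expect_equal(sum(pm["Dc", , ]), 1L)
  expect_true(all(pm >= 0))
})
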