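test_that("exact-identity queries are assigned to their haplotype", {
  set.seed(77)
  refs <- hap_records(name = c("Cm-A1.1", "Cm-A3.1", "Cm-A5.1"),
                      sequence = rand_dna(3, 800), species = "Cm")
  a <- match_haplotype(refs$sequence[2], refs)
  expect_equal(a$status, "match")
  expect_equal(a$names, "Cm-A3.1")

  # lowercase and gap characters are immaterial
  messy <- paste0("--", tolower(refs$sequence[2]), ".")
  expect_equal(match_haplotype(messy, refs)$names, "Cm-A3.1")

  # one substitution anywhere makes an orphan
  q <- refs$sequence[1]
  substr(q, 400, 400) <- setdiff(c("A", "C", "G", "T"),
                                 substr(q, 400, 400))[1]
  expect_equal(match_haplotype(q, refs)$status, "orphan")
})

test_that("a short-fragment query hits the whole EiA23 family", {
  refs <- make_eia23_family()
  short_query <- substr(refs$sequence[1], 1, 490)
  a <- match_haplotype(short_query, refs)
  expect_equal(a$status, "ambiguous")
  expect_setequal(a$names, c("EiA23", "EiA24", "EiA39", "EiA41", "EiA42",
                             "EiA43", "EiA83"))
  # full-length query resolves uniquely
  expect_equal(match_haplotype(refs$sequence[3], refs)$names, "EiA39")
})

test_that("insufficient overlap is an error, not an orphan", {
  set.seed(78)
  refs <- hap_records(name = c("A", "B"), sequence = rand_dna(2, 800))
  expect_error(match_haplotype(substr(refs$sequence[1], 1, 200), refs),
               "overlap below minimum")
  expect_equal(match_haplotype(substr(refs$sequence[1], 1, 200), refs,
                               min_overlap = 100)$names, "A")
})

test_that("collapse groups identical truncations and labels deterministically", {
  refs <- make_eia23_family()
  cls <- collapse_to_short_classes(refs)
  expect_equal(sort(names(cls)), c("EiA1", "EiA23"))
  expect_setequal(cls$EiA23, c("EiA23", "EiA24", "EiA39", "EiA41", "EiA42",
                               "EiA43", "EiA83"))
  expect_equal(cls$EiA1, "EiA1")

  # all-distinct truncations give singletons
  set.seed(79)
  dis <- hap_records(name = sprintf("D%02d", 1:8), sequence = rand_dna(8, 600))
  expect_equal(lengths(collapse_to_short_classes(dis)),
               setNames(rep(1L, 8), sort(dis$name)))

  short <- hap_records(name = "S", sequence = rand_dna(1, 450))
  expect_error(collapse_to_short_classes(short), "shorter than.*S")
})

test_that("collapse equals brute-force pairwise truncation comparison", {
  set.seed(80)
  # 100 records built from 30 distinct truncation cores -> planted classes
  cores <- rand_dna(30, 490)
  pick <- sample(30, 100, replace = TRUE)
  recs <- hap_records(name = sprintf("Hp%03d", 1:100),
                      sequence = paste0(cores[pick], rand_dna(100, 200)))
  cls <- collapse_to_short_classes(recs)
  # O(n^2) oracle
  tr <- substr(recs$sequence, 1, 490)
  eq <- outer(tr, tr, "==")
  oracle <- unique(apply(eq, 1, function(row) sort(recs$name[row]),
                         simplify = FALSE))
  key <- function(groups) sort(vapply(groups, function(g)
    paste(sort(g), collapse = ","), character(1)))
  expect_equal(unname(key(cls)), unname(key(oracle)))
  # true partition: disjoint and covering
  expect_equal(unname(sort(unlist(cls))), sort(recs$name))
})

test_that("harmonize merges same-class columns and conserves totals", {
  tt <- toy_tables()
  cls <- list(h1 = c("h1", "h3"), h2 = "h2")
  h <- harmonize(tt$baseline, tt$mixed, cls)
  expect_equal(h$baseline$X[, "h1"],
               tt$baseline$X[, "h1"] + tt$baseline$X[, "h3"])
  expect_equal(sum(h$baseline$X), sum(tt$baseline$X))
  expect_equal(sum(h$mixed$Y), sum(tt$mixed$Y))
  expect_equal(h$baseline$haplotype_names, h$mixed$haplotype_names)

  # identity partition changes nothing but (possibly) ordering
  h0 <- harmonize(tt$baseline, tt$mixed)
  expect_equal(h0$baseline$X, tt$baseline$X)
  expect_equal(h0$mixed$Y, tt$mixed$Y)
})

test_that("harmonize conserves every row total across random systems", {
  set.seed(81)
  for (i in 1:200) {
    tt <- random_tables(R = sample(2:4, 1), M = sample(1:3, 1),
                        H = sample(2:6, 1))
    cls <- random_partition(tt$baseline$haplotype_names)
    h <- harmonize(tt$baseline, tt$mixed, cls)
    expect_equal(unname(rowSums(h$baseline$X)),
                 unname(rowSums(tt$baseline$X)))
    expect_equal(unname(rowSums(h$mixed$Y)), unname(rowSums(tt$mixed$Y)))
  }
})

test_that("orphan haplotypes are a hard error unless dropping is requested", {
  X <- matrix(c(5L, 5L), 1, 2, dimnames = list("A", c("h1", "h2")))
  Y <- matrix(c(2L, 1L, 3L), 1, 3,
              dimnames = list("S", c("h1", "h2", "h9")))
  b <- baseline_table(X, N = 10)
  m <- mixed_table(Y)
  expect_error(harmonize(b, m), "orphan.*h9")
  expect_warning(h <- harmonize(b, m, orphans = "drop"), "dropping.*h9")
  expect_equal(h$dropped, "h9")
  expect_false("h9" %in% h$mixed$haplotype_names)
  expect_equal(sum(h$mixed$Y), 3L)
})
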