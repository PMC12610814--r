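test_that("default genetic code has the expected family structure", {
  code <- genetic_code()
  expect_equal(nrow(code), 64)
  expect_setequal(stop_codons(code), c("UAA", "UAG", "UGA"))
  expect_equal(length(analyzable_codons(code)), 59)
  expect_false(any(c("AUG", "UGG", "UAA", "UAG", "UGA") %in%
                     analyzable_codons(code)))
  census <- table(vapply(split(code$deg[code$aa != "Stop"],
                               code$aa[code$aa != "Stop"]),
                         unique, 0L))
  expect_equal(census[["1"]], 2) # Met, Trp
  expect_equal(census[["2"]], 9)
  expect_equal(census[["3"]], 1) # Ile
  expect_equal(census[["4"]], 5)
  expect_equal(census[["6"]], 3) # Leu, Ser, Arg
  expect_error(genetic_code(99), "unknown translation table")
})

test_that("codon counting matches forced examples and excludes stops", {
  ct <- count_codons(c(g = "ATGGCTTAA"))
  v <- counts_as_vector(ct)
  expect_equal(unname(v[c("AUG", "GCU")]), c(1L, 1L))
  expect_equal(sum(v), 2L) # terminal stop excluded
  ct2 <- counts_as_vector(count_codons(c(g = "ATGTTATTATTGTAA")))
  expect_equal(unname(ct2[c("AUG", "UUA", "UUG")]), c(1L, 2L, 1L))
  # headless fragment mode: no start/stop requirements at counting level
  frag <- strrep("GCTGCA", 1000)
  v3 <- counts_as_vector(count_codons(c(g = frag)))
  expect_equal(unname(v3[c("GCU", "GCA")]), c(1000L, 1000L))
  expect_equal(sum(v3), 2000L)
})

test_that("counting agrees with a brute-force scan on random sequences", {
  set.seed(41)
  for (rep in 1:20) {
    seq <- paste(sample(c("A", "C", "G", "T"), 3 * sample(10:200, 1),
                        replace = TRUE), collapse = "")
    v <- counts_as_vector(count_codons(c(g = seq)))
    oracle <- oracle_count_codons(seq)
    expect_equal(v[names(oracle)], oracle[names(oracle)],
                 ignore_attr = FALSE)
    expect_equal(sum(v), sum(oracle))
  }
})

test_that("ambiguity-containing triplets are skipped and reported", {
  ct <- count_codons(c(g = "ATGNNTGCTTAA"))
  expect_equal(sum(ct$count), 2L) # AUG + GCU; NNT skipped, UAA terminal
  expect_equal(attr(ct, "skipped")$n_skipped, 1L)
  expect_error(count_codons(c(bad = "ATGG")), "frame")
})

test_that("terminal stop handling is configurable", {
  with_stop <- count_codons(c(g = "ATGGCTTAA"), remove_terminal_stop = FALSE)
  expect_equal(sum(with_stop$count), 3L)
  expect_equal(counts_as_vector(with_stop)[["UAA"]], 1L)
})

test_that("positional composition matches forced examples and identities", {
  pc <- positional_composition(c(g = "GAGGAG"))
  expect_equal(pc$gc1, 1)
  expect_equal(pc$gc2, 0)
  expect_equal(pc$gc3, 1)
  expect_equal(pc$gc, 2 / 3)
  expect_equal(pc$gc12, 0.5)
  pc2 <- positional_composition(c(g = "ATTATT"))
  expect_equal(pc2$gc, 0)
  expect_equal(pc2$a3, 0) # third positions are T,T
  expect_equal(pc2$t3, 1)
  # fractions normalize; GC arithmetic identity
  set.seed(7)
  for (rep in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 3 * sample(5:100, 1),
                        replace = TRUE), collapse = "")
    pc <- positional_composition(c(g = seq), remove_terminal_stop = FALSE)
    expect_equal(pc$a + pc$t + pc$g + pc$c, 1)
    expect_equal(pc$a3 + pc$t3 + pc$g3 + pc$c3, 1)
    expect_equal(pc$gc, (pc$gc1 + pc$gc2 + pc$gc3) / 3)
    expect_equal(pc$gc12, (pc$gc1 + pc$gc2) / 2)
  }
  expect_error(positional_composition(character(0)), "data frame|no codons")
})
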