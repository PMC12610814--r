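test_that("RSCU matches forced and hand-computed examples", {
  # equal counts in every family -> RSCU exactly 1 for all 59 codons
  r <- rscu(uniform_counts(100))
  expect_equal(nrow(r), 59)
  expect_equal(r$rscu, rep(1, 59))
  # Leu counts (4,2,0,0,0,0): zero-sub X = (4,2,.5,.5,.5,.5), mean 8/6
  r2 <- rscu(make_counts(UUA = 4, UUG = 2))
  leu <- r2[r2$aa == "Leu", ]
  expect_equal(leu$rscu[leu$codon == "UUA"], 3)
  expect_equal(leu$rscu[leu$codon == "UUG"], 1.5)
  expect_true(all(leu$zero_substituted[!leu$codon %in% c("UUA", "UUG")]))
  # a family entirely unobserved gets RSCU 1 by symmetry of the substitution
  ala <- r2[r2$aa == "Ala", ]
  expect_equal(ala$rscu, rep(1, 4))
  expect_error(rscu(tibble::tibble()), "empty")
})

test_that("RSCU family sums equal degeneracies on arbitrary inputs", {
  for (seed in 1:15) {
    r <- rscu(random_counts(seed))
    sums <- tapply(r$rscu, r$aa, sum)
    degs <- tapply(r$codon, r$aa, length)
    expect_equal(as.numeric(sums), as.numeric(degs), tolerance = 1e-12)
    expect_true(all(r$rscu >= 0))
  }
})

test_that("SCUO matches entropy hand-computations and bounds", {
  # 2-fold family used as (1,0): H = 0, SCUO_i = 1
  s1 <- scuo(make_counts(UUU = 5), by_family = TRUE)
  expect_equal(s1$scuo[s1$aa == "Phe"], 1)
  # used equally: H = H_max = 1, SCUO_i = 0
  s2 <- scuo(make_counts(UUU = 5, UUC = 5), by_family = TRUE)
  expect_equal(s2$scuo[s2$aa == "Phe"], 0)
  # p = (0.75, 0.25): H = 0.8113, SCUO_i = 0.1887
  s3 <- scuo(make_counts(UUU = 3, UUC = 1), by_family = TRUE)
  expect_equal(s3$scuo[s3$aa == "Phe"], 1 + 0.75 * log2(0.75) +
                 0.25 * log2(0.25), tolerance = 1e-12)
  expect_equal(round(s3$scuo[s3$aa == "Phe"], 4), 0.1887)
  # gene value averages only observed families, stays in [0, 1]
  for (seed in 16:25) {
    s <- scuo(random_counts(seed))$scuo
    expect_true(s >= 0 && s <= 1)
  }
  expect_warning(s0 <- scuo(make_counts(AUG = 3)), "undefined")
  expect_true(is.na(s0$scuo))
})

test_that("family homozygosity matches direct arithmetic", {
  expect_equal(family_homozygosity(c(3, 1)), 0.5)
  expect_equal(family_homozygosity(c(2, 2)), 1 / 3)
  expect_equal(family_homozygosity(c(1000, 0)), 1)
  expect_true(is.na(family_homozygosity(c(1, 0))))
})

test_that("observed ENC hits the closed-form extremes", {
  # one codon per amino acid -> 20 exactly
  expect_equal(enc_observed(one_codon_counts(100))$enc, 20)
  # equal usage in every family -> raw estimate slightly above 61, capped
  e <- enc_observed(uniform_counts(100))
  expect_equal(e$enc, 61)
  expect_gt(e$enc_raw, 61)
  # raw value from Wright's estimator: 2 + sum_k N_k / Fbar_k
  expect_equal(e$enc_raw,
               2 + 9 * 199 / 99 + 299 / 99 + 5 * 399 / 99 + 3 * 599 / 99,
               tolerance = 1e-12)
})

test_that("missing 3-fold class is imputed, other missing classes flag ENC", {
  # all families present except Ile -> imputed F3 = (F2 + F4)/2
  counts <- uniform_counts(50)
  counts$count[counts$aa == "Ile"] <- 0L
  e <- enc_observed(counts)
  expect_true(e$defined)
  expect_true(e$enc >= 20 && e$enc <= 61)
  # drop all 6-fold families -> undefined
  counts2 <- uniform_counts(50)
  counts2$count[counts2$deg == 6] <- 0L
  e2 <- enc_observed(counts2)
  expect_false(e2$defined)
  expect_true(is.na(e2$enc))
})

test_that("expected ENC curve evaluates and is symmetric about 0.5", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  gc3 <- seq(0.05, 0.45, by = 0.05)
  expect_equal(enc_expected(0.5 + gc3) - enc_expected(0.5 - gc3),
               2 * gc3, tolerance = 1e-12) # symmetric up to the linear term
  expect_error(enc_expected(1.2), "0, 1")
})

test_that("CAI follows the Sharp-Li construction and MILC is its complement", {
  # gene using each family's reference-maximal codon -> CAI = 1
  ref <- make_counts(UUU = 9, UUC = 1, GGU = 8, GGC = 1, GGA = 1, GGG = 1)
  gene <- make_counts(UUU = 5, GGU = 7)
  expect_equal(cai(gene, reference = ref)$cai, 1)
  # two-codon gene with w = (1, 0.25) -> geometric mean 0.5
  ref2 <- make_counts(UUU = 8, UUC = 2) # RSCU (1.6, 0.4); w = (1, 0.25)
  gene2 <- make_counts(UUU = 1, UUC = 1)
  expect_equal(cai(gene2, reference = ref2)$cai, 0.5)
  # reference = the gene itself with uniform usage -> CAI = 1
  u <- uniform_counts(10)
  expect_equal(cai(u, reference = u)$cai, 1)
  expect_equal(cai(u)$cai, 1) # default reference is the pooled input
  # MILC = 1 - CAI exactly
  res <- cai(random_counts(3))
  expect_identical(res$milc, 1 - res$cai)
  expect_equal(milc(1), 0)
  expect_equal(milc(0.3), 0.7)
  expect_error(cai(u, reference = tibble::tibble()), "reference")
})
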