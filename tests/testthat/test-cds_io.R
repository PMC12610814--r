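test_that("FASTA round trip preserves records and ids", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">geneA some description", "ATGGCTTAA",
               ">geneB", "ATGTTATAA"), path)
  seqs <- read_cds(path)
  expect_equal(seqs$gene, c("geneA", "geneB"))
  expect_equal(seqs$sequence, c("ATGGCTTAA", "ATGTTATAA"))
  out <- withr::local_tempfile(fileext = ".fasta")
  write_cds_fasta(seqs, out)
  expect_equal(read_cds(out)$sequence, seqs$sequence)
})

test_that("GenBank CDS extraction handles strand and joins", {
  # minus-strand CDS over the full record: revcomp("TTACATCAT") = ATGATGTAA
  path <- withr::local_tempfile(fileext = ".gb")
  write_toy_genbank(path, "TOY1", "TTACATCAT",
                    list(list(location = "complement(1..9)", gene = "m1")))
  seqs <- read_cds(path)
  expect_equal(seqs$sequence, "ATGATGTAA")
  expect_equal(seqs$gene_name, "m1")

  # join(1..3,7..9) concatenates exons in order
  path2 <- withr::local_tempfile(fileext = ".gb")
  write_toy_genbank(path2, "TOY2", "ATGCCCTAA",
                    list(list(location = "join(1..3,7..9)", gene = "j1")))
  expect_equal(read_cds(path2)$sequence, "ATGTAA")

  # complement(join(...)) reads segments in reverse order
  path3 <- withr::local_tempfile(fileext = ".gb")
  write_toy_genbank(path3, "TOY3", "TTAGGGCAT",
                    list(list(location = "complement(join(1..3,7..9))")))
  expect_equal(read_cds(path3)$sequence, "ATGTAA")

  # unresolvable locations are skipped with a warning, not fatal
  path4 <- withr::local_tempfile(fileext = ".gb")
  write_toy_genbank(path4, "TOY4", "ATGAAATAAATGTAA",
                    list(list(location = "1..9"),
                         list(location = "OTHER.1:1..6")))
  expect_warning(seqs4 <- read_cds(path4), "unresolvable")
  expect_equal(nrow(seqs4), 1)
})

test_that("filter chain attributes each rejection to its first failing rule", {
  clean <- cds_from_codons("AUG", rep("GCU", 98), "UAA") # 300 nt
  seqs <- tibble::tibble(
    gene = c("short", "dup_a", "dup_b", "badstart", "nostop", "clean"),
    sequence = c(
      cds_from_codons("AUG", rep("GCU", 97), "UAA"),          # 297 nt
      clean, clean,                                            # exact dup pair
      cds_from_codons("GUG", rep("GCU", 98), "UAA"),           # GTG start
      cds_from_codons("AUG", rep("GCU", 99)),                  # no stop
      cds_from_codons("AUG", rep("GCA", 98), "UAA")
    )
  )
  kept <- filter_cds(seqs)
  expect_setequal(kept$gene, c("dup_a", "clean"))
  rep_tbl <- tidy(filter_report(kept))
  reasons <- stats::setNames(rep_tbl$reason, rep_tbl$gene)
  expect_equal(unname(reasons[c("short", "dup_b", "badstart", "nostop")]),
               c("length", "duplicate", "start", "terminal_stop"))
  g <- glance(filter_report(kept))
  expect_equal(g$n_input, 6)
  expect_equal(g$n_retained, 2)
})

test_that("internal stops and frame failures are caught", {
  seqs <- tibble::tibble(
    gene = c("internal", "frame"),
    sequence = c(
      cds_from_codons("AUG", rep("GCU", 50), "UAA", rep("GCU", 48), "UAA"),
      paste0(cds_from_codons("AUG", rep("GCU", 99), "UAA"), "A")
    )
  )
  kept <- filter_cds(seqs)
  expect_equal(nrow(kept), 0)
  rep_tbl <- tidy(filter_report(kept))
  expect_equal(rep_tbl$reason, c("internal_stop", "frame"))
})

test_that("filtering is idempotent and keeps first duplicate occurrence", {
  set.seed(13)
  seqs <- generate_cds_set(usage_regime("uniform", n_genes = 12, seed = 5))
  seqs$sequence[7] <- seqs$sequence[2] # inject a duplicate
  once <- filter_cds(seqs)
  twice <- filter_cds(once)
  expect_equal(once$gene, twice$gene)
  expect_equal(once$sequence, twice$sequence)
  expect_true("gene002" %in% once$gene)
  expect_false("gene007" %in% once$gene)
})

test_that("empty input filters to empty output with zero counts", {
  empty <- tibble::tibble(gene = character(0), sequence = character(0))
  kept <- filter_cds(empty)
  expect_equal(nrow(kept), 0)
  expect_equal(glance(filter_report(kept))$n_input, 0)
  expect_equal(glance(filter_report(kept))$n_retained, 0)
})

test_that("gene-name deduplication mode is available", {
  seqs <- tibble::tibble(
    gene = c("a", "b"), gene_name = c("psbA", "psbA"),
    sequence = c(cds_from_codons("AUG", rep("GCU", 98), "UAA"),
                 cds_from_codons("AUG", rep("GCA", 98), "UAA"))
  )
  expect_equal(nrow(filter_cds(seqs)), 2)
  expect_equal(filter_cds(seqs, dedup = "gene_name")$gene, "a")
})
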