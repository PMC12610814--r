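# Fixture builders shared across test files. All fixtures are built in code.

# Full 64-row count table from a named codon -> count vector (RNA alphabet).
make_counts <- function(..., gene = "g") {
  given <- c(...)
  code <- genetic_code()
  counts <- stats::setNames(rep(0L, nrow(code)), code$codon)
  if (length(given)) counts[names(given)] <- as.integer(given)
  tibble::tibble(
    gene = gene, codon = code$codon, aa = code$aa, deg = code$deg,
    analyzable = code$analyzable, count = unname(counts)
  )
}

# Count table with `n` on every sense codon (0 for stops).
uniform_counts <- function(n = 100L, gene = "g") {
  code <- genetic_code()
  tibble::tibble(
    gene = gene, codon = code$codon, aa = code$aa, deg = code$deg,
    analyzable = code$analyzable,
    count = ifelse(code$aa == "Stop", 0L, as.integer(n))
  )
}

# One codon per amino acid used `n` times: maximal bias.
one_codon_counts <- function(n = 100L, gene = "g") {
  code <- genetic_code()
  first <- !duplicated(code$aa)
  tibble::tibble(
    gene = gene, codon = code$codon, aa = code$aa, deg = code$deg,
    analyzable = code$analyzable,
    count = ifelse(code$aa != "Stop" & first, as.integer(n), 0L)
  )
}

# Random small count table (some zeros), deterministic given seed.
random_counts <- function(seed, gene = "g", max_count = 12L) {
  set.seed(seed)
  code <- genetic_code()
  counts <- sample(0:max_count, nrow(code), replace = TRUE)
  counts[code$aa == "Stop"] <- 0L
  tibble::tibble(
    gene = gene, codon = code$codon, aa = code$aa, deg = code$deg,
    analyzable = code$analyzable, count = as.integer(counts)
  )
}

# DNA coding sequence built from RNA codons (no implicit start/stop added).
cds_from_codons <- function(...) {
  paste(chartr("U", "T", c(...)), collapse = "")
}

# Minimal GenBank flat file writer for parser tests.
write_toy_genbank <- function(path, acc, seq_dna, features) {
  lines <- c(
    sprintf("LOCUS       %s %d bp    DNA", acc, nchar(seq_dna)),
    sprintf("VERSION     %s", acc),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(seq_dna))
  )
  for (f in features) {
    lines <- c(lines, sprintf("     CDS             %s", f$location))
    if (!is.null(f$gene)) {
      lines <- c(lines, sprintf('                     /gene="%s"', f$gene))
    }
  }
  lines <- c(lines, "ORIGIN")
  chunks <- substring(tolower(seq_dna), seq(1, nchar(seq_dna), 60),
                      pmin(seq(1, nchar(seq_dna), 60) + 59, nchar(seq_dna)))
  for (i in seq_along(chunks)) {
    lines <- c(lines, sprintf("%9d %s", (i - 1) * 60 + 1, chunks[i]))
  }
  writeLines(c(lines, "//"), path)
  path
}
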