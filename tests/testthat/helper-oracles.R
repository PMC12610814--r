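# Independent straight-from-formula oracles. Deliberately naive loops, no
# shared code with the package implementation.

oracle_families <- function() {
  code <- genetic_code()
  fams <- split(code$codon, code$aa)
  fams[["Stop"]] <- NULL
  fams[vapply(fams, length, 0L) > 1]
}

# counts: named codon -> count vector. Returns named RSCU over the 59 codons.
oracle_rscu <- function(counts, zero_sub = 0.5) {
  out <- numeric(0)
  for (fam in oracle_families()) {
    x <- numeric(length(fam))
    for (j in seq_along(fam)) {
      x[j] <- if (is.na(counts[fam[j]]) || counts[fam[j]] == 0) zero_sub
      else counts[fam[j]]
    }
    n_i <- length(fam)
    expected <- sum(x) / n_i
    for (j in seq_along(fam)) out[fam[j]] <- x[j] / expected
  }
  out
}

oracle_scuo <- function(counts) {
  vals <- numeric(0)
  for (fam in oracle_families()) {
    x <- counts[fam]
    x[is.na(x)] <- 0
    n <- sum(x)
    if (n == 0) next
    h <- 0
    for (j in seq_along(fam)) {
      p <- x[[j]] / n
      if (p > 0) h <- h - p * log2(p)
    }
    vals <- c(vals, 1 - h / log2(length(fam)))
  }
  if (length(vals) == 0) return(NA_real_)
  sum(vals) / length(vals)
}

oracle_fhat <- function(x) {
  n <- sum(x)
  if (n < 2) return(NA_real_)
  s <- 0
  for (j in seq_along(x)) s <- s + (x[[j]] / n)^2
  (n * s - 1) / (n - 1)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# Brute-force triplet scan used as the counting oracle.
oracle_count_codons <- function(seq_dna, drop_terminal_stop = TRUE) {
  seq_rna <- chartr("T", "U", toupper(seq_dna))
  out <- new.env()
  k <- nchar(seq_rna) / 3
  stops <- c("UAA", "UAG", "UGA")
  for (i in seq_len(k)) {
    codon <- substr(seq_rna, 3 * i - 2, 3 * i)
    if (drop_terminal_stop && i == k && codon %in% stops) next
    if (grepl("[^ACGU]", codon)) next
    prev <- mget(codon, envir = out, ifnotfound = 0L)[[1]]
    assign(codon, prev + 1L, envir = out)
  }
  unlist(as.list(out))
}

counts_as_vector <- function(tab) stats::setNames(tab$count, tab$codon)
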