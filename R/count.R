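# Codon counting and positional nucleotide composition.

# Coerce supported inputs (tibble with gene/sequence, named character vector,
# Biostrings::DNAStringSet) to the canonical CDS tibble.
as_cds_tbl <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    x <- tibble::tibble(gene = ids, sequence = unname(x))
  }
  if (!is.data.frame(x) || !all(c("gene", "sequence") %in% names(x))) {
    stop("expected a data frame with columns `gene` and `sequence`",
         call. = FALSE)
  }
  tibble::as_tibble(x) |>
    dplyr::mutate(gene = as.character(.data$gene),
                  sequence = toupper(as.character(.data$sequence)))
}

split_triplets <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

#' Count codons in coding sequences
#'
#' Scans each in-frame sequence triplet by triplet and tallies the 64 codons.
#' Sequences are read as DNA but codons are reported in the RNA alphabet
#' (UUA, GCU, ...). Triplets containing ambiguity letters (N, R, ...) are
#' excluded from all counts and tallied in the `skipped` attribute. The
#' terminal triplet, when it is a stop codon, is excluded by default: stop
#' codons encode no amino acid and would otherwise contaminate third-position
#' composition.
#'
#' @param x Coding sequences: a data frame with columns `gene` and
#'   `sequence`, a named character vector, or a `DNAStringSet`.
#' @param code A [genetic_code()] table.
#' @param remove_terminal_stop Drop the final triplet when it is a stop
#'   codon (default `TRUE`).
#' @return A tibble with one row per gene x codon (all 64 codons, zero
#'   filled): columns `gene`, `codon`, `aa`, `deg`, `analyzable`, `count`.
#'   Attribute `skipped` is a tibble of per-gene ambiguous-triplet counts.
#' @examples
#' count_codons(c(g1 = "ATGGCTTAA"))
#' @export
count_codons <- function(x, code = genetic_code(), remove_terminal_stop = TRUE) {
  seqs <- as_cds_tbl(x)
  bad_frame <- seqs$gene[nchar(seqs$sequence) %% 3L != 0L]
  if (length(bad_frame) > 0) {
    stop("sequence length not divisible by 3 (frame error): ",
         paste(bad_frame, collapse = ", "), call. = FALSE)
  }
  stops <- stop_codons(code)
  per_gene <- purrr::map2(seqs$gene, seqs$sequence, function(gene, seq) {
    trip <- rna_codon(split_triplets(seq))
    if (remove_terminal_stop && length(trip) > 0 &&
        trip[length(trip)] %in% stops) {
      trip <- trip[-length(trip)]
    }
    keep <- trip %in% code$codon
    counts <- table(factor(trip[keep], levels = code$codon))
    list(counts = as.integer(counts), skipped = sum(!keep))
  })
  out <- tidyr::crossing(gene = seqs$gene, codon = code$codon) |>
    dplyr::arrange(match(.data$gene, seqs$gene), match(.data$codon, code$codon))
  counts_vec <- unlist(purrr::map(per_gene, "counts"))
  out$count <- if (is.null(counts_vec)) integer(0) else counts_vec
  out <- dplyr::left_join(
    out,
    dplyr::select(tibble::as_tibble(code), "codon", "aa", "deg", "analyzable"),
    by = "codon"
  ) |>
    dplyr::select("gene", "codon", "aa", "deg", "analyzable", "count")
  attr(out, "skipped") <- tibble::tibble(
    gene = seqs$gene,
    n_skipped = purrr::map_int(per_gene, "skipped")
  )
  out
}

#' Pool per-gene codon counts
#'
#' Sums counts across genes into a single table, e.g. to compute RSCU on a
#' whole gene set or an expression library.
#'
#' @param counts A [count_codons()] tibble.
#' @param source Label for the pooled pseudo-gene (default `"pooled"`).
#' @return A codon count tibble with a single `gene` level.
#' @export
pool_counts <- function(counts, source = "pooled") {
  counts |>
    dplyr::summarise(count = sum(.data$count),
                     .by = c("codon", "aa", "deg", "analyzable")) |>
    dplyr::mutate(gene = source, .before = 1)
}

#' Positional nucleotide composition
#'
#' Computes, per gene, the overall and third-position base fractions and the
#' GC content at each codon position (GC1, GC2, GC3), their position-1/2 mean
#' (GC12) and the overall GC. All values are fractions in \[0, 1\]; terminal
#' stop codons are excluded by default (see [count_codons()]), so GC equals
#' (GC1 + GC2 + GC3) / 3 exactly.
#'
#' @inheritParams count_codons
#' @param x Coding sequences (as in [count_codons()]) or an already computed
#'   codon count tibble.
#' @return A tibble with one row per gene: `gene`, `n_codons`, overall
#'   fractions `a`, `t`, `g`, `c`, third-position fractions `a3`, `t3`,
#'   `g3`, `c3`, and `gc1`, `gc2`, `gc3`, `gc12`, `gc`.
#' @examples
#' positional_composition(c(g = "GCGGCG"))
#' @export
positional_composition <- function(x, code = genetic_code(),
                                   remove_terminal_stop = TRUE) {
  counts <- if (is.data.frame(x) && all(c("codon", "count") %in% names(x))) {
    x
  } else {
    count_codons(x, code, remove_terminal_stop = remove_terminal_stop)
  }
  if (nrow(counts) == 0 || sum(counts$count) == 0) {
    stop("no codons counted: composition undefined", call. = FALSE)
  }
  pos <- counts |>
    dplyr::mutate(
      b1 = substr(.data$codon, 1, 1),
      b2 = substr(.data$codon, 2, 2),
      b3 = substr(.data$codon, 3, 3)
    )
  out <- pos |>
    dplyr::summarise(
      n_codons = sum(.data$count),
      a3 = sum(.data$count[.data$b3 == "A"]) / .data$n_codons,
      t3 = sum(.data$count[.data$b3 == "U"]) / .data$n_codons,
      g3 = sum(.data$count[.data$b3 == "G"]) / .data$n_codons,
      c3 = sum(.data$count[.data$b3 == "C"]) / .data$n_codons,
      a = (sum(.data$count[.data$b1 == "A"]) + sum(.data$count[.data$b2 == "A"]) +
             sum(.data$count[.data$b3 == "A"])) / (3 * .data$n_codons),
      t = (sum(.data$count[.data$b1 == "U"]) + sum(.data$count[.data$b2 == "U"]) +
             sum(.data$count[.data$b3 == "U"])) / (3 * .data$n_codons),
      g = (sum(.data$count[.data$b1 == "G"]) + sum(.data$count[.data$b2 == "G"]) +
             sum(.data$count[.data$b3 == "G"])) / (3 * .data$n_codons),
      c = (sum(.data$count[.data$b1 == "C"]) + sum(.data$count[.data$b2 == "C"]) +
             sum(.data$count[.data$b3 == "C"])) / (3 * .data$n_codons),
      gc1 = sum(.data$count[.data$b1 %in% c("G", "C")]) / .data$n_codons,
      gc2 = sum(.data$count[.data$b2 %in% c("G", "C")]) / .data$n_codons,
      gc3 = sum(.data$count[.data$b3 %in% c("G", "C")]) / .data$n_codons,
      .by = "gene"
    ) |>
    dplyr::mutate(
      gc12 = (.data$gc1 + .data$gc2) / 2,
      gc = (.data$gc1 + .data$gc2 + .data$gc3) / 3
    ) |>
    dplyr::select("gene", "n_codons", "a", "t", "g", "c",
                  "a3", "t3", "g3", "c3",
                  "gc1", "gc2", "gc3", "gc12", "gc")
  if (any(out$n_codons == 0)) {
    stop("gene with zero counted codons: composition undefined (",
         paste(out$gene[out$n_codons == 0], collapse = ", "), ")",
         call. = FALSE)
  }
  out
}
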