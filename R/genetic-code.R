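# Genetic code tables and codon/amino-acid family structure.

# NCBI translation strings, codon order: base1 slowest, bases ordered U,C,A,G.
.ncbi_code_strings <- c(
  "1"  = "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
  "11" = "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"
)

.aa_three <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Stop"
)

#' Genetic code table
#'
#' Builds the codon table for an NCBI translation table as a tibble, one row
#' per codon in the RNA alphabet, with its amino acid and the degeneracy
#' (family size) of that amino acid. The default is table 11, the
#' bacterial/archaeal/plant-plastid code used for chloroplast CDS annotation;
#' its codon-to-amino-acid map coincides with the standard code, so under it
#' 59 of the 64 codons are "analyzable" for synonymous usage: all codons
#' minus the single-codon families AUG (Met) and UGG (Trp) and the three
#' stops UAA, UAG, UGA.
#'
#' @param id NCBI translation table identifier; `11` (plastid, default) and
#'   `1` (standard) are provided.
#' @return A tibble with columns `codon` (RNA alphabet), `aa` (three-letter
#'   amino-acid name, `"Stop"` for terminators), `deg` (number of synonymous
#'   codons for that amino acid) and `analyzable` (logical: multi-codon,
#'   non-stop family).
#' @examples
#' code <- genetic_code()
#' sum(code$analyzable) # 59
#' @export
genetic_code <- function(id = 11) {
  id <- as.character(id)
  if (!id %in% names(.ncbi_code_strings)) {
    stop("unknown translation table id: ", id, call. = FALSE)
  }
  bases <- c("U", "C", "A", "G")
  grid <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE)
  codon <- paste0(grid$b1, grid$b2, grid$b3)
  aa1 <- strsplit(.ncbi_code_strings[[id]], "")[[1]]
  aa <- unname(.aa_three[aa1])
  tab <- tibble::tibble(codon = codon, aa = aa)
  tab <- dplyr::arrange(tab, .data$aa, .data$codon)
  tab <- dplyr::mutate(tab, deg = dplyr::n(), .by = "aa")
  tab <- dplyr::mutate(
    tab,
    analyzable = .data$aa != "Stop" & .data$deg > 1L
  )
  attr(tab, "code_id") <- id
  class(tab) <- c("genetic_code", class(tab))
  tab
}

#' Stop codons of a genetic code
#' @param code A [genetic_code()] tibble.
#' @return Character vector of stop codons in the RNA alphabet.
#' @export
stop_codons <- function(code = genetic_code()) {
  code$codon[code$aa == "Stop"]
}

#' Analyzable codons of a genetic code
#'
#' The codons informative about synonymous usage: members of multi-codon,
#' non-stop amino-acid families (59 under the default table).
#' @inheritParams stop_codons
#' @return Character vector of codons in the RNA alphabet.
#' @export
analyzable_codons <- function(code = genetic_code()) {
  code$codon[code$analyzable]
}

# DNA-alphabet view of a codon vector (U -> T), used when matching sequences.
dna_codon <- function(codon) chartr("U", "T", codon)

rna_codon <- function(codon) chartr("T", "U", codon)
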