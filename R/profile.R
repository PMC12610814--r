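# One-stop per-gene codon-usage profile.

#' Per-gene codon usage profile
#'
#' Runs the whole per-gene battery on a set of coding sequences: positional
#' composition (GC1/GC2/GC3/GC12/GC), SCUO, observed and expected ENC with
#' the ENC-ratio, CAI and its expression-proxy complement, and the PR2
#' coordinates `x = G3/(G3+C3)`, `y = A3/(A3+T3)`.
#'
#' @param seqs Coding sequences (anything [count_codons()] accepts), e.g.
#'   the output of [filter_cds()] or [generate_cds_set()].
#' @param code A [genetic_code()] table.
#' @param cai_reference Reference usage for [cai()]; default is the pooled
#'   input itself.
#' @param zero_sub Zero-count substitution used inside RSCU/CAI.
#' @return A `cub_profile` tibble, one row per gene, carrying the codon
#'   count table as attribute `"counts"` (retrieved with [profile_counts()]).
#' @examples
#' prof <- cub_profile(generate_cds_set(usage_regime("uniform", n_genes = 5)))
#' prof[, c("gene", "gc3", "enc_obs", "scuo")]
#' @export
cub_profile <- function(seqs, code = genetic_code(), cai_reference = NULL,
                        zero_sub = 0.5) {
  counts <- if (is.data.frame(seqs) && all(c("codon", "count") %in% names(seqs))) {
    seqs
  } else {
    count_codons(seqs, code)
  }
  comp <- positional_composition(counts, code)
  out <- comp |>
    dplyr::left_join(scuo(counts), by = "gene") |>
    dplyr::left_join(
      dplyr::rename(enc_observed(counts), enc_obs = "enc",
                    enc_defined = "defined"),
      by = "gene"
    ) |>
    dplyr::left_join(cai(counts, reference = cai_reference,
                         zero_sub = zero_sub),
                     by = "gene") |>
    dplyr::mutate(
      enc_exp = enc_expected(.data$gc3),
      enc_ratio = (.data$enc_exp - .data$enc_obs) / .data$enc_exp,
      pr2_x = ifelse(.data$g3 + .data$c3 > 0,
                     .data$g3 / (.data$g3 + .data$c3), NA_real_),
      pr2_y = ifelse(.data$a3 + .data$t3 > 0,
                     .data$a3 / (.data$a3 + .data$t3), NA_real_)
    )
  attr(out, "counts") <- counts
  class(out) <- c("cub_profile", class(out))
  out
}

#' Codon counts behind a profile
#' @param profiles A [cub_profile()] tibble.
#' @return The codon count tibble the profile was computed from.
#' @export
profile_counts <- function(profiles) attr(profiles, "counts")
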