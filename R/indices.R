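# Per-gene codon-usage bias indices: RSCU, SCUO, Wright's ENC, CAI.

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU is the ratio of a codon's observed count to the count expected if
#' all synonymous codons of its amino acid were used equally:
#' `RSCU_ij = X_ij / ((1/n_i) * sum_j X_ij)` for the j-th codon of family i
#' with degeneracy `n_i`. A value of 1 means no preference. Any zero count
#' is replaced by 0.5 before the computation (the conventional
#' zero-substitution, flagged per codon), which preserves the family-sum
#' identity `sum_j RSCU_ij = n_i`. Single-codon families (Met, Trp) and
#' stop codons are excluded, leaving the 59 analyzable codons.
#'
#' @param counts A codon count tibble from [count_codons()] or
#'   [pool_counts()] (any number of genes; RSCU is computed per gene).
#' @param zero_sub Value substituted for zero counts (default 0.5).
#' @return A tibble with columns `gene`, `aa`, `codon`, `count`, `rscu`,
#'   `zero_substituted`, 59 rows per gene, ordered by amino acid then codon.
#' @examples
#' rscu(pool_counts(count_codons(c(g = "ATGTTATTATTGTAA"))))
#' @export
rscu <- function(counts, zero_sub = 0.5) {
  if (!is.data.frame(counts) || nrow(counts) == 0) {
    stop("empty codon count table", call. = FALSE)
  }
  counts |>
    dplyr::filter(.data$analyzable) |>
    dplyr::mutate(
      zero_substituted = .data$count == 0,
      x = ifelse(.data$zero_substituted, zero_sub, .data$count),
      rscu = .data$x / mean(.data$x),
      .by = c("gene", "aa")
    ) |>
    dplyr::select("gene", "aa", "codon", "count", "rscu",
                  "zero_substituted") |>
    dplyr::arrange(match(.data$gene, unique(counts$gene)), .data$aa,
                   .data$codon)
}

#' Synonymous codon usage order (SCUO)
#'
#' SCUO measures how ordered (non-random) synonymous codon use is within
#' each amino-acid family via Shannon entropy: `H_i = -sum_j p_ij log2 p_ij`
#' over the family's codon usage frequencies, and
#' `SCUO_i = 1 - H_i / log2(n_i)`. 0 means uniform (random) use, 1 means a
#' single codon carries the whole family. The gene-level value is the
#' unweighted mean of `SCUO_i` over multi-codon families with at least one
#' observation; families with zero usage are excluded from the average.
#'
#' @inheritParams rscu
#' @param by_family Return the per-family table instead of the per-gene
#'   summary.
#' @return With `by_family = FALSE` (default) a tibble `gene`, `scuo`,
#'   `n_families`; genes with no observed multi-codon family get `NA` and a
#'   warning. With `by_family = TRUE` a tibble `gene`, `aa`, `deg`, `n`,
#'   `h`, `scuo`.
#' @export
scuo <- function(counts, by_family = FALSE) {
  fam <- counts |>
    dplyr::filter(.data$analyzable) |>
    dplyr::summarise(
      deg = .data$deg[1],
      n = sum(.data$count),
      h = {
        p <- .data$count / sum(.data$count)
        p <- p[p > 0]
        if (length(p) == 0) NA_real_ else -sum(p * log2(p))
      },
      .by = c("gene", "aa")
    ) |>
    dplyr::mutate(scuo = 1 - .data$h / log2(.data$deg))
  if (by_family) return(fam)
  out <- fam |>
    dplyr::summarise(
      scuo = mean(.data$scuo[.data$n > 0]),
      n_families = sum(.data$n > 0),
      .by = "gene"
    )
  if (any(out$n_families == 0)) {
    warning("gene(s) with no observed multi-codon family: SCUO undefined (",
            paste(out$gene[out$n_families == 0], collapse = ", "), ")",
            call. = FALSE)
    out$scuo[out$n_families == 0] <- NA_real_
  }
  out
}

#' Codon homozygosity of one synonymous family
#'
#' Wright-style unbiased homozygosity estimate for a family with observed
#' codon counts `x`: with `n = sum(x)` and `p_j = x_j / n`,
#' `F = (n * sum(p_j^2) - 1) / (n - 1)`. Families with `n < 2` are unusable
#' and return `NA`.
#'
#' @param x Integer vector of codon counts within one family.
#' @return The homozygosity estimate, or `NA` when `n < 2`.
#' @examples
#' family_homozygosity(c(3, 1)) # 0.5
#' @export
family_homozygosity <- function(x) {
  n <- sum(x)
  if (n < 2) return(NA_real_)
  p <- x / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Observed effective number of codons (ENC)
#'
#' Wright's estimator of the effective number of codons: per-family
#' homozygosities `F` are averaged within degeneracy classes and combined as
#' `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` (2 single-codon amino acids, nine
#' 2-fold, one 3-fold, five 4-fold and three 6-fold families under the
#' default code). 20 means one codon per amino acid (extreme bias); 61 means
#' fully even use. Families with fewer than 2 codons observed or `F = 0` are
#' unusable; a missing 3-fold class is imputed as `(F2 + F4)/2`, any other
#' empty class leaves ENC undefined for that gene. Finite-sample estimates
#' can exceed 61, so the reported value is capped into \[20, 61\]; the raw
#' value is kept alongside.
#'
#' @inheritParams rscu
#' @return A tibble `gene`, `enc` (capped), `enc_raw`, `defined`.
#' @export
enc_observed <- function(counts) {
  fam <- counts |>
    dplyr::filter(.data$analyzable) |>
    dplyr::summarise(
      deg = .data$deg[1],
      n = sum(.data$count),
      f = family_homozygosity(.data$count),
      .by = c("gene", "aa")
    ) |>
    dplyr::mutate(usable = !is.na(.data$f) & .data$f > 0)
  class_sizes <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)
  per_gene <- fam |>
    dplyr::summarise(
      f2 = mean(.data$f[.data$usable & .data$deg == 2]),
      f3 = mean(.data$f[.data$usable & .data$deg == 3]),
      f4 = mean(.data$f[.data$usable & .data$deg == 4]),
      f6 = mean(.data$f[.data$usable & .data$deg == 6]),
      .by = "gene"
    ) |>
    dplyr::mutate(
      f3 = ifelse(is.nan(.data$f3) & !is.nan(.data$f2) & !is.nan(.data$f4),
                  (.data$f2 + .data$f4) / 2, .data$f3),
      defined = !is.nan(.data$f2) & !is.nan(.data$f3) & !is.nan(.data$f4) &
        !is.nan(.data$f6),
      enc_raw = ifelse(
        .data$defined,
        2 + class_sizes[["2"]] / .data$f2 + class_sizes[["3"]] / .data$f3 +
          class_sizes[["4"]] / .data$f4 + class_sizes[["6"]] / .data$f6,
        NA_real_
      ),
      enc = pmin(pmax(.data$enc_raw, 20), 61)
    )
  dplyr::select(per_gene, "gene", "enc", "enc_raw", "defined")
}

#' Expected ENC under mutation alone
#'
#' The null ENC expected from third-position GC content when composition is
#' the only force: `ENC = 2 + GC3 + 29 / (GC3^2 + (1 - GC3)^2)`. Symmetric
#' about GC3 = 0.5, where it peaks at 60.5.
#'
#' @param gc3 Third-position GC fraction(s) in \[0, 1\].
#' @return Numeric vector of expected ENC values (not capped).
#' @examples
#' enc_expected(c(0, 0.5, 1)) # 31, 60.5, 32
#' @export
enc_expected <- function(gc3) {
  if (any(is.na(gc3)) || any(gc3 < 0 | gc3 > 1)) {
    stop("gc3 must lie in [0, 1]", call. = FALSE)
  }
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' Codon adaptation index (CAI) and its MILC complement
#'
#' Sharp & Li's CAI: from a reference codon-usage set, the relative
#' adaptiveness of codon j in family i is `w_ij = RSCU_ij / max_j RSCU_ij`
#' (the reference's zero-substitution keeps every `w > 0`); a gene's CAI is
#' the count-weighted geometric mean of `w` over its analyzable codons,
#' in (0, 1]. The companion expression proxy reported here as `milc` is the
#' complement `1 - CAI` (the convention adopted by this analysis; note this
#' is not the Supek-Vlahovicek MILC statistic). Higher values of this proxy
#' are read as higher expression.
#'
#' @inheritParams rscu
#' @param reference Reference usage: `NULL` (default) pools `counts` itself;
#'   otherwise a codon count tibble (pooled internally) or an [rscu()] table
#'   with a single gene level.
#' @return A tibble `gene`, `cai`, `milc`.
#' @export
cai <- function(counts, reference = NULL, zero_sub = 0.5) {
  ref_rscu <- if (is.null(reference)) {
    rscu(pool_counts(counts), zero_sub = zero_sub)
  } else if (is.data.frame(reference) && "rscu" %in% names(reference)) {
    if (length(unique(reference$gene)) != 1) {
      stop("reference RSCU table must have a single gene level", call. = FALSE)
    }
    reference
  } else if (is.data.frame(reference) && nrow(reference) > 0) {
    rscu(pool_counts(reference), zero_sub = zero_sub)
  } else {
    stop("empty or invalid CAI reference", call. = FALSE)
  }
  w_tab <- ref_rscu |>
    dplyr::mutate(w = .data$rscu / max(.data$rscu), .by = "aa") |>
    dplyr::select("codon", "w")
  counts |>
    dplyr::filter(.data$analyzable) |>
    dplyr::left_join(w_tab, by = "codon") |>
    dplyr::summarise(
      cai = exp(sum(.data$count * log(.data$w)) / sum(.data$count)),
      .by = "gene"
    ) |>
    dplyr::mutate(milc = milc(.data$cai))
}

#' Expression proxy from CAI
#'
#' The complement `1 - CAI`, used here as a gene-expression proxy (higher
#' means more highly expressed). This is a deliberate, documented
#' idiosyncrasy of the analysis this package implements; it is not the
#' Supek-Vlahovicek MILC statistic.
#'
#' @param cai CAI value(s) in (0, 1].
#' @return `1 - cai`.
#' @export
milc <- function(cai) 1 - cai
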