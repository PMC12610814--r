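# High/low-expression libraries and optimal-codon identification.

#' Build high/low-expression gene libraries
#'
#' Ranks genes by an expression proxy (default: the `milc` column of the
#' profile, i.e. 1 - CAI) and takes the top and bottom tails. Tail size is
#' `max(min_genes, ceiling(fraction * n))`; ties in the metric are broken by
#' gene identifier so the construction is deterministic.
#'
#' @param profiles A [cub_profile()] tibble.
#' @param metric Name of the profile column to rank by (default `"milc"`,
#'   higher = more expressed).
#' @param fraction Proportion of genes per tail (default 0.1).
#' @param min_genes Minimum genes per tail (default 5).
#' @return An `expression_libraries` object: `$high` and `$low` (gene id
#'   vectors, disjoint), `$metric`, `$fraction`, `$n_per_tail`, `$ranking`
#'   (the ranked tibble). `tidy()` returns a `gene`/`library` tibble.
#' @export
build_libraries <- function(profiles, metric = "milc", fraction = 0.1,
                            min_genes = 5) {
  if (!metric %in% names(profiles)) {
    stop("unknown ranking metric: ", metric, call. = FALSE)
  }
  n <- nrow(profiles)
  n_tail <- max(min_genes, ceiling(fraction * n))
  if (n < 2 * n_tail) {
    stop("need at least ", 2 * n_tail, " genes for ", n_tail,
         "-gene high/low libraries (have ", n, ")", call. = FALSE)
  }
  ranking <- profiles |>
    dplyr::select("gene", value = dplyr::all_of(metric)) |>
    dplyr::arrange(dplyr::desc(.data$value), .data$gene)
  if (length(unique(ranking$value)) == 1) {
    warning("all genes have identical `", metric,
            "`: tails are id-ordered and arbitrary", call. = FALSE)
  }
  structure(
    list(
      high = ranking$gene[seq_len(n_tail)],
      low = rev(ranking$gene)[seq_len(n_tail)],
      metric = metric,
      fraction = fraction,
      n_per_tail = n_tail,
      ranking = ranking
    ),
    class = "expression_libraries"
  )
}

#' @export
print.expression_libraries <- function(x, ...) {
  cat("Expression libraries by `", x$metric, "`: ", x$n_per_tail,
      " genes per tail\n", sep = "")
  cat("  high:", paste(x$high, collapse = ", "), "\n")
  cat("  low: ", paste(x$low, collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.expression_libraries <- function(x, ...) {
  tibble::tibble(
    gene = c(x$high, x$low),
    library = rep(c("high", "low"), each = x$n_per_tail)
  )
}

#' Identify optimal codons from high/low-expression libraries
#'
#' Pools codon counts within each library, computes RSCU on each pool, and
#' flags as optimal every codon with `delta_rscu = RSCU_high - RSCU_low >=
#' delta_min` and `RSCU_high >= rscu_min`. Star tiers follow the usual
#' convention: `*` for delta >= 0.08, `**` >= 0.3, `***` >= 0.5.
#'
#' @param counts A codon count tibble covering the library genes (e.g.
#'   [profile_counts()] of the profile the libraries were built from).
#' @param libraries An [build_libraries()] object, or a list with `high`
#'   and `low` gene-id vectors.
#' @param delta_min Minimum RSCU difference (default 0.08).
#' @param rscu_min Minimum high-library RSCU (default 1).
#' @param zero_sub Zero-count substitution inside RSCU.
#' @return A tibble `aa`, `codon`, `rscu_high`, `rscu_low`, `delta_rscu`,
#'   `tier`, ordered by amino acid then codon; zero rows when no codon
#'   passes.
#' @export
optimal_codons <- function(counts, libraries, delta_min = 0.08,
                           rscu_min = 1, zero_sub = 0.5) {
  if (length(libraries$high) == 0 || length(libraries$low) == 0) {
    stop("both libraries must be non-empty", call. = FALSE)
  }
  pool_of <- function(genes, label) {
    pool_counts(dplyr::filter(counts, .data$gene %in% genes), source = label)
  }
  hi <- rscu(pool_of(libraries$high, "high"), zero_sub = zero_sub)
  lo <- rscu(pool_of(libraries$low, "low"), zero_sub = zero_sub)
  hi |>
    dplyr::select("aa", "codon", rscu_high = "rscu") |>
    dplyr::left_join(dplyr::select(lo, "codon", rscu_low = "rscu"),
                     by = "codon") |>
    dplyr::mutate(delta_rscu = .data$rscu_high - .data$rscu_low) |>
    dplyr::filter(.data$delta_rscu >= delta_min,
                  .data$rscu_high >= rscu_min) |>
    dplyr::mutate(
      tier = dplyr::case_when(
        .data$delta_rscu >= 0.5 ~ "***",
        .data$delta_rscu >= 0.3 ~ "**",
        TRUE ~ "*"
      )
    ) |>
    dplyr::arrange(.data$aa, .data$codon)
}
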