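# Mutation-vs-selection diagnostics: ENC-plot classification, PR2 points,
# neutrality regression, correlation tables.

#' ENC-plot classification
#'
#' Compares each gene's observed ENC with the ENC expected from its GC3
#' alone via the ratio `(expected - observed) / expected`. Genes whose ratio
#' falls inside the window (default \[-0.05, 0.05\]) sit on the null curve
#' and are read as mutation-driven; genes outside it deviate enough that
#' selection is invoked. Genes with undefined observed ENC are excluded and
#' reported.
#'
#' @param profiles A [cub_profile()] tibble.
#' @param window Half-width of the mutation window on the ENC-ratio
#'   (default 0.05).
#' @param enc_threshold ENC value above which bias is called weak
#'   (default 45).
#' @return An `enc_plot` object: `$genes` (per-gene tibble with
#'   `classification`), `$n_inside`, `$n_outside`, `$frac_inside`,
#'   `$frac_outside`, `$n_high_enc`, `$n_undefined`, `$window`,
#'   `$enc_threshold`. `tidy()` returns the per-gene table, `glance()` the
#'   counts.
#' @export
enc_plot <- function(profiles, window = 0.05, enc_threshold = 45) {
  genes <- profiles |>
    dplyr::select("gene", "gc3", "enc_obs", "enc_exp", "enc_ratio",
                  "enc_defined")
  defined <- dplyr::filter(genes, .data$enc_defined)
  if (nrow(defined) == 0) {
    stop("no gene with defined observed ENC", call. = FALSE)
  }
  defined <- dplyr::mutate(
    defined,
    classification = ifelse(abs(.data$enc_ratio) <= window,
                            "inside", "outside")
  )
  n_in <- sum(defined$classification == "inside")
  n_out <- sum(defined$classification == "outside")
  structure(
    list(
      genes = defined,
      n_inside = n_in,
      n_outside = n_out,
      frac_inside = n_in / nrow(defined),
      frac_outside = n_out / nrow(defined),
      n_high_enc = sum(defined$enc_obs > enc_threshold),
      n_undefined = sum(!genes$enc_defined),
      window = window,
      enc_threshold = enc_threshold
    ),
    class = "enc_plot"
  )
}

#' @export
print.enc_plot <- function(x, ...) {
  cat("ENC-plot classification (window ±", x$window, ")\n", sep = "")
  cat("  inside (mutation-driven): ", x$n_inside,
      sprintf(" (%.2f%%)", 100 * x$frac_inside), "\n", sep = "")
  cat("  outside (selection):      ", x$n_outside,
      sprintf(" (%.2f%%)", 100 * x$frac_outside), "\n", sep = "")
  cat("  ENC > ", x$enc_threshold, ": ", x$n_high_enc, " genes\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.enc_plot <- function(x, ...) x$genes

#' @exportS3Method generics::glance
glance.enc_plot <- function(x, ...) {
  tibble::tibble(
    n_inside = x$n_inside, n_outside = x$n_outside,
    frac_inside = x$frac_inside, frac_outside = x$frac_outside,
    n_high_enc = x$n_high_enc, n_undefined = x$n_undefined,
    window = x$window, enc_threshold = x$enc_threshold
  )
}

#' Parity-rule-2 (PR2) points
#'
#' Per-gene third-position base skew: `x = G3/(G3+C3)` against
#' `y = A3/(A3+T3)`. The center (0.5, 0.5) corresponds to A = T and G = C at
#' third positions, the expectation under mutation alone; displacement marks
#' the direction and extent of bias. Genes are assigned to quadrants around
#' the center; a gene with a zero denominator is flagged undefined on that
#' axis.
#'
#' @param profiles A [cub_profile()] tibble.
#' @param category Optional two-column data frame (`gene`, `category`) used
#'   to label functional classes.
#' @return A tibble `gene`, `pr2_x`, `pr2_y`, `quadrant` (e.g.
#'   `"lower_right"`, `"center"` when exactly central, `"undefined"` when an
#'   axis is undefined), plus `category` when supplied.
#' @export
pr2_points <- function(profiles, category = NULL) {
  out <- profiles |>
    dplyr::select("gene", "pr2_x", "pr2_y") |>
    dplyr::mutate(
      quadrant = dplyr::case_when(
        is.na(.data$pr2_x) | is.na(.data$pr2_y) ~ "undefined",
        .data$pr2_x == 0.5 & .data$pr2_y == 0.5 ~ "center",
        .data$pr2_y >= 0.5 & .data$pr2_x >= 0.5 ~ "upper_right",
        .data$pr2_y >= 0.5 & .data$pr2_x < 0.5 ~ "upper_left",
        .data$pr2_y < 0.5 & .data$pr2_x >= 0.5 ~ "lower_right",
        TRUE ~ "lower_left"
      )
    )
  if (!is.null(category)) {
    out <- dplyr::left_join(out, tibble::as_tibble(category), by = "gene")
  }
  out
}

#' Neutrality-plot regression
#'
#' Regresses GC12 (mean GC at codon positions 1-2) on GC3 across genes and
#' reports the OLS slope and the Pearson correlation. A slope near 1 with a
#' significant correlation indicates that mutation pressure moves all three
#' positions together; a slope near 0 indicates selection constrains
#' positions 1-2 independently of third-position drift. Genes exactly on
#' the y = x diagonal count as above it.
#'
#' @param profiles A [cub_profile()] tibble (needs >= 3 genes).
#' @return A `neutrality_fit` object wrapping the `lm` fit; `tidy()` gives
#'   the coefficient table, `glance()` the slope, intercept, Pearson r and
#'   p, and the diagonal census.
#' @export
neutrality <- function(profiles) {
  dat <- dplyr::select(profiles, "gene", "gc3", "gc12")
  if (nrow(dat) < 3) stop("neutrality analysis needs >= 3 genes",
                          call. = FALSE)
  if (length(unique(dat$gc3)) < 2) {
    stop("all GC3 values identical: slope undefined", call. = FALSE)
  }
  fit <- stats::lm(gc12 ~ gc3, data = dat)
  ct <- stats::cor.test(dat$gc3, dat$gc12)
  structure(
    list(
      data = dat,
      fit = fit,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r = unname(ct$estimate),
      p_value = ct$p.value,
      n_below_diagonal = sum(dat$gc12 < dat$gc3),
      n_genes = nrow(dat)
    ),
    class = "neutrality_fit"
  )
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(
    "Neutrality plot: slope %.3f, intercept %.3f, r %.3f (p %.3g), %d/%d genes below the diagonal\n",
    x$slope, x$intercept, x$r, x$p_value, x$n_below_diagonal, x$n_genes))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.neutrality_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = s[, "Estimate"],
    std_error = s[, "Std. Error"],
    statistic = s[, "t value"],
    p_value = s[, "Pr(>|t|)"]
  )
}

#' @exportS3Method generics::glance
glance.neutrality_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r = x$r, p_value = x$p_value,
    n_below_diagonal = x$n_below_diagonal, n_genes = x$n_genes
  )
}

#' Pearson correlation table across genes
#'
#' Correlates, across genes, every profile variable in `rows` with every
#' variable in `cols` (Pearson r, two-tailed p from the exact t transform
#' with n - 2 degrees of freedom) and stars significance at 0.05 / 0.01.
#' Typical uses: overall base content (a, t, g, c, gc) against
#' third-position content (a3, t3, g3, c3, gc3), or SCUO against
#' composition. No multiple-testing correction is applied.
#'
#' @param profiles A [cub_profile()] tibble (needs >= 3 genes).
#' @param rows,cols Character vectors of profile column names.
#' @return A tibble `row`, `col`, `r`, `p_value`, `stars` (`""`, `"*"`,
#'   `"**"`), `n`. Zero-variance variables yield `NA` with a warning.
#' @export
correlation_table <- function(profiles,
                              rows = c("a", "t", "g", "c", "gc"),
                              cols = c("a3", "t3", "g3", "c3", "gc3")) {
  missing_vars <- setdiff(c(rows, cols), names(profiles))
  if (length(missing_vars) > 0) {
    stop("unknown profile variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  if (nrow(profiles) < 3) stop("correlation table needs >= 3 genes",
                               call. = FALSE)
  pairs <- tidyr::crossing(row = rows, col = cols) |>
    dplyr::arrange(match(.data$row, rows), match(.data$col, cols))
  res <- purrr::pmap(pairs, function(row, col) {
    x <- profiles[[row]]
    y <- profiles[[col]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero-variance variable in pair (", row, ", ", col,
              "): correlation undefined", call. = FALSE)
      return(tibble::tibble(r = NA_real_, p_value = NA_real_,
                            n = length(x)))
    }
    ct <- stats::cor.test(x, y)
    tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                   n = length(x))
  })
  dplyr::bind_cols(pairs, dplyr::bind_rows(res)) |>
    dplyr::mutate(
      stars = dplyr::case_when(
        is.na(.data$p_value) ~ NA_character_,
        .data$p_value < 0.01 ~ "**",
        .data$p_value < 0.05 ~ "*",
        TRUE ~ ""
      )
    )
}
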