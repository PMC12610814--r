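# End-to-end orchestration: profile one taxon, compare several.

write_tsv_out <- function(x, dir, name) {
  readr::write_tsv(x, file.path(dir, name))
}

#' Profile one taxon end to end
#'
#' Reads (or accepts) a taxon's coding sequences, applies the quality
#' filters, computes the per-gene profile and all diagnostics, identifies
#' optimal codons, and writes the full table/figure set to `outdir`:
#' `filter_report.tsv`, `profiles.tsv`, `rscu.tsv`,
#' `correlation_composition.tsv`, `correlation_scuo.tsv`, `enc_genes.tsv`,
#' `pr2.tsv`, `neutrality.tsv`, `optimal_codons.tsv` and PDF plots. All
#' thresholds default to the conventional values (300 bp minimum length,
#' +/-0.05 ENC window, ENC > 45 weak-bias cut, 0.08 minimum delta-RSCU) and
#' are echoed into `run_config.json`.
#'
#' @param input A path (FASTA or GenBank) or a CDS tibble.
#' @param outdir Output directory, created if needed; `NULL` skips writing.
#' @param format Input format for paths (see [read_cds()]).
#' @param min_len,dedup Filter settings (see [filter_cds()]).
#' @param code A [genetic_code()] table.
#' @param cai_reference Reference for [cai()] (default: the taxon itself).
#' @param library_metric,library_fraction,library_min_genes Settings for
#'   [build_libraries()].
#' @param enc_window,enc_threshold Settings for [enc_plot()].
#' @param delta_min ΔRSCU threshold for [optimal_codons()].
#' @param category Optional gene -> functional-category table for PR2.
#' @param write_plots Also write PDF figures (default `TRUE` when `outdir`
#'   is set).
#' @return A list with `seqs`, `filter_report`, `profiles`, `rscu`,
#'   `enc`, `pr2`, `neutrality`, `correlations`, `libraries`,
#'   `optimal_codons`, invisibly when `outdir` is set.
#' @export
run_species <- function(input, outdir = NULL,
                        format = c("auto", "fasta", "genbank"),
                        min_len = 300, dedup = TRUE,
                        code = genetic_code(), cai_reference = NULL,
                        library_metric = "milc", library_fraction = 0.1,
                        library_min_genes = 5,
                        enc_window = 0.05, enc_threshold = 45,
                        delta_min = 0.08, category = NULL,
                        write_plots = !is.null(outdir)) {
  format <- match.arg(format)
  seqs <- if (is.character(input) && length(input) == 1) {
    if (!file.exists(input)) {
      stop("input file not found: ", input, call. = FALSE)
    }
    read_cds(input, format)
  } else {
    as_cds_tbl(input)
  }
  retained <- filter_cds(seqs, min_len = min_len, dedup = dedup, code = code)
  report <- filter_report(retained)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_out(tidy(report), outdir, "filter_report.tsv")
  }
  if (nrow(retained) == 0) {
    stop("no sequence survived filtering; see filter_report.tsv",
         call. = FALSE)
  }
  profiles <- cub_profile(retained, code = code,
                          cai_reference = cai_reference)
  rscu_tab <- rscu(profile_counts(profiles))
  enc_res <- enc_plot(profiles, window = enc_window,
                      enc_threshold = enc_threshold)
  pr2 <- pr2_points(profiles, category = category)
  neut <- neutrality(profiles)
  cor_comp <- correlation_table(profiles)
  cor_scuo <- correlation_table(
    profiles, rows = "scuo",
    cols = c("a", "t", "g", "c", "gc", "a3", "t3", "g3", "c3", "gc3"))
  libs <- build_libraries(profiles, metric = library_metric,
                          fraction = library_fraction,
                          min_genes = library_min_genes)
  opt <- optimal_codons(profile_counts(profiles), libs,
                        delta_min = delta_min)
  out <- list(seqs = retained, filter_report = report, profiles = profiles,
              rscu = rscu_tab, enc = enc_res, pr2 = pr2, neutrality = neut,
              correlations = list(composition = cor_comp, scuo = cor_scuo),
              libraries = libs, optimal_codons = opt)
  if (is.null(outdir)) return(out)
  write_tsv_out(dplyr::select(profiles, !dplyr::any_of("sequence")),
                outdir, "profiles.tsv")
  write_tsv_out(rscu_tab, outdir, "rscu.tsv")
  write_tsv_out(cor_comp, outdir, "correlation_composition.tsv")
  write_tsv_out(cor_scuo, outdir, "correlation_scuo.tsv")
  write_tsv_out(tidy(enc_res), outdir, "enc_genes.tsv")
  write_tsv_out(pr2, outdir, "pr2.tsv")
  write_tsv_out(glance(neut), outdir, "neutrality.tsv")
  write_tsv_out(opt, outdir, "optimal_codons.tsv")
  jsonlite::write_json(
    list(min_len = min_len, dedup = dedup,
         code_id = attr(code, "code_id"),
         library_metric = library_metric,
         library_fraction = library_fraction,
         library_min_genes = library_min_genes,
         enc_window = enc_window, enc_threshold = enc_threshold,
         delta_min = delta_min),
    file.path(outdir, "run_config.json"), auto_unbox = TRUE)
  if (write_plots) {
    ggplot2::ggsave(file.path(outdir, "enc_plot.pdf"), plot_enc(enc_res),
                    width = 6, height = 5)
    ggplot2::ggsave(file.path(outdir, "enc_ratio.pdf"),
                    plot_enc_ratio(enc_res), width = 6, height = 5)
    ggplot2::ggsave(file.path(outdir, "pr2.pdf"), plot_pr2(pr2),
                    width = 6, height = 5)
    ggplot2::ggsave(file.path(outdir, "neutrality.pdf"),
                    plot_neutrality(neut), width = 6, height = 5)
  }
  invisible(out)
}

#' Compare taxa on pooled RSCU
#'
#' Builds the codons x taxa RSCU matrix over >= 2 taxa, clusters the taxa
#' (Euclidean distance, average linkage by default), and reports the codons
#' over-represented (RSCU > `overrep_threshold`) in every taxon. Inputs may
#' be file paths or CDS tibbles; each taxon is filtered with the same
#' settings before pooling.
#'
#' @param inputs Named list of per-taxon inputs (paths or CDS tibbles).
#' @param outdir Output directory; `NULL` skips writing.
#' @inheritParams run_species
#' @param distance,linkage Clustering settings (see [cluster_taxa()]).
#' @param overrep_threshold Shared over-representation cut (default 1.6).
#' @return A list with `matrix`, `tree`, `newick`, `shared_overrepresented`,
#'   `distance_matrix`, invisibly when `outdir` is set.
#' @export
run_compare <- function(inputs, outdir = NULL,
                        format = c("auto", "fasta", "genbank"),
                        min_len = 300, dedup = TRUE, code = genetic_code(),
                        distance = "euclidean", linkage = "average",
                        overrep_threshold = 1.6) {
  format <- match.arg(format)
  if (length(inputs) < 2) stop("run_compare needs >= 2 taxa", call. = FALSE)
  if (is.null(names(inputs)) || any(names(inputs) == "")) {
    stop("`inputs` must be a fully named list of taxa", call. = FALSE)
  }
  taxa <- purrr::map(inputs, function(x) {
    seqs <- if (is.character(x) && length(x) == 1) read_cds(x, format)
    else as_cds_tbl(x)
    filter_cds(seqs, min_len = min_len, dedup = dedup, code = code)
  })
  m <- rscu_matrix(taxa, code = code)
  tree <- cluster_taxa(m, distance = distance, linkage = linkage)
  shared <- shared_overrepresented(m, threshold = overrep_threshold)
  dmat <- as.matrix(stats::dist(t(m)))
  out <- list(matrix = m, tree = tree, newick = write_newick(tree),
              shared_overrepresented = shared, distance_matrix = dmat)
  if (is.null(outdir)) return(out)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  mat_tbl <- tibble::as_tibble(m, rownames = "codon") |>
    dplyr::mutate(aa = attr(m, "aa"), .after = "codon")
  write_tsv_out(mat_tbl, outdir, "rscu_matrix.tsv")
  write_tsv_out(tibble::as_tibble(dmat, rownames = "taxon"), outdir,
                "distance_matrix.tsv")
  writeLines(out$newick, file.path(outdir, "rscu_tree.nwk"))
  writeLines(shared, file.path(outdir, "shared_overrepresented.txt"))
  invisible(out)
}
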