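#!/usr/bin/env Rscript

# Integration run over the five grass plastome accessions. These snapshots
# are not bundled with the package (they are genome-scale downloads); point
# this script at a directory of local GenBank flat files:
#
#   Rscript scripts/accession-integration.R /path/to/genbank_dir [outdir]
#
# Expected files (GenBank flat format, one per accession):
#   ON422331.1.gb  (x Triticosecale sp.)
#   NC_021760.1.gb (Triticum monococcum)
#   NC_024814.1.gb (Triticum turgidum)
#   KC912694.1.gb  (Triticum aestivum)
#   NC_021761.1.gb (Secale cereale)
#
# Reference values reported for these accessions, for side-by-side reading
# of the output: retained CDS 52/54/49/52/51; mean ENC 47.31/47.66/47.05/
# 47.45/47.31; ENC > 45 counts 42/45/40/43/41; neutrality slopes
# 0.15/0.22/0.29/0.25/0.22; overall GC 38.78-39.16%; codons with RSCU > 1.6
# in every taxon: UUA, GCU, ACU, AGA, UCU; triticale clustering inside the
# Triticum clade.

suppressPackageStartupMessages(library(plastcub))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: accession-integration.R <genbank_dir> [outdir]")
gb_dir <- args[1]
outdir <- if (length(args) >= 2) args[2] else "accession_results"

taxa <- c(
  triticale   = "ON422331.1",
  monococcum  = "NC_021760.1",
  turgidum    = "NC_024814.1",
  aestivum    = "KC912694.1",
  secale      = "NC_021761.1"
)

paths <- file.path(gb_dir, paste0(taxa, ".gb"))
names(paths) <- names(taxa)
missing <- paths[!file.exists(paths)]
if (length(missing)) stop("missing snapshots: ", paste(missing, collapse = ", "))

summaries <- list()
for (nm in names(paths)) {
  res <- run_species(paths[[nm]], outdir = file.path(outdir, nm),
                     write_plots = FALSE)
  prof <- res$profiles
  ct <- res$correlations$composition
  summaries[[nm]] <- data.frame(
    taxon = nm,
    n_retained = glance(res$filter_report)$n_retained,
    mean_enc = mean(prof$enc_obs, na.rm = TRUE),
    n_enc_gt45 = glance(res$enc)$n_high_enc,
    n_inside = glance(res$enc)$n_inside,
    slope = glance(res$neutrality)$slope,
    r_a_a3 = ct$r[ct$row == "a" & ct$col == "a3"],
    mean_gc_pct = 100 * mean(prof$gc),
    mean_scuo = mean(prof$scuo, na.rm = TRUE),
    n_optimal = nrow(res$optimal_codons)
  )
}
summary_tbl <- do.call(rbind, summaries)
print(summary_tbl, digits = 4)
write.table(summary_tbl, file.path(outdir, "summary.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

cmp <- run_compare(as.list(paths), outdir = file.path(outdir, "compare"))
cat("shared over-represented codons (RSCU > 1.6):",
    paste(cmp$shared_overrepresented, collapse = ", "), "\n")
cat("RSCU tree:", cmp$newick, "\n")
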