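# Reading CDS from FASTA / GenBank flat files and the QC filter chain.

revcomp_dna <- function(seq) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", seq), "")[[1]]),
        collapse = "")
}

# Parse a GenBank feature location into segments (start, end, complement).
# Supports a..b, single positions, join(), complement(), nesting, and
# partial-end markers (< >). Remote references (accession:range) return NULL.
parse_gb_location <- function(loc) {
  loc <- gsub("[[:space:]<>]", "", loc)
  if (grepl(":", loc, fixed = TRUE)) return(NULL)
  parse1 <- function(s, comp) {
    if (startsWith(s, "complement(")) {
      inner <- substr(s, 12L, nchar(s) - 1L)
      return(parse1(inner, !comp))
    }
    if (startsWith(s, "join(") || startsWith(s, "order(")) {
      inner <- sub("^[a-z]+\\(", "", s)
      inner <- substr(inner, 1L, nchar(inner) - 1L)
      parts <- character()
      depth <- 0L; last <- 1L
      chars <- strsplit(inner, "")[[1]]
      for (i in seq_along(chars)) {
        if (chars[i] == "(") depth <- depth + 1L
        if (chars[i] == ")") depth <- depth - 1L
        if (chars[i] == "," && depth == 0L) {
          parts <- c(parts, substr(inner, last, i - 1L))
          last <- i + 1L
        }
      }
      parts <- c(parts, substr(inner, last, nchar(inner)))
      segs <- lapply(parts, parse1, comp = comp)
      if (any(vapply(segs, is.null, TRUE))) return(NULL)
      segs <- do.call(rbind, segs)
      # complement(join(...)) reads segments in reverse order
      if (comp) segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
      return(segs)
    }
    m <- regmatches(s, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", s))[[1]]
    if (length(m) == 0) return(NULL)
    start <- as.integer(m[2])
    end <- if (m[4] == "") start else as.integer(m[4])
    data.frame(start = start, end = end, comp = comp)
  }
  parse1(loc, FALSE)
}

extract_gb_feature <- function(origin, segs) {
  pieces <- vapply(seq_len(nrow(segs)), function(i) {
    s <- substr(origin, segs$start[i], segs$end[i])
    if (segs$comp[i]) revcomp_dna(s) else s
  }, character(1))
  paste(pieces, collapse = "")
}

read_genbank_cds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec_starts <- grep("^LOCUS", lines)
  if (length(rec_starts) == 0) {
    stop("not a GenBank flat file (no LOCUS line): ", path, call. = FALSE)
  }
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))
  recs <- purrr::map2(rec_starts, rec_ends, function(s, e) lines[s:e])
  out <- purrr::map(recs, function(rl) {
    acc_line <- grep("^(VERSION|ACCESSION|LOCUS)", rl, value = TRUE)
    acc <- strsplit(trimws(acc_line[1]), "[[:space:]]+")[[1]][2]
    ori_i <- grep("^ORIGIN", rl)
    if (length(ori_i) == 0) return(NULL)
    seq_lines <- rl[(ori_i[1] + 1L):length(rl)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    origin <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    feat_i <- grep("^FEATURES", rl)
    if (length(feat_i) == 0) return(NULL)
    feat <- rl[(feat_i[1] + 1L):(ori_i[1] - 1L)]
    # feature keys sit at column 6; qualifiers/continuations at column 22
    key_i <- grep("^     \\S", feat)
    if (length(key_i) == 0) return(NULL)
    key_end <- c(key_i[-1] - 1L, length(feat))
    cds <- purrr::map2(key_i, key_end, function(s, e) {
      block <- feat[s:e]
      key <- sub("^\\s+", "", block[1])
      if (!startsWith(key, "CDS")) return(NULL)
      # location may continue over lines until the first qualifier
      qual_i <- grep("^\\s+/", block)
      loc_end <- if (length(qual_i)) qual_i[1] - 1L else length(block)
      loc <- paste(gsub("^\\s*CDS\\s*|\\s", "", block[1:loc_end]),
                   collapse = "")
      gene <- NA_character_
      gm <- grep('^\\s+/gene="', block, value = TRUE)
      if (length(gm)) gene <- sub('^\\s+/gene="([^"]*)".*$', "\\1", gm[1])
      segs <- parse_gb_location(loc)
      if (is.null(segs)) {
        warning("skipping CDS with unresolvable location `", loc,
                "` in record ", acc, call. = FALSE)
        return(NULL)
      }
      if (any(segs$end > nchar(origin)) || any(segs$start < 1)) {
        warning("skipping CDS with out-of-range coordinates `", loc,
                "` in record ", acc, call. = FALSE)
        return(NULL)
      }
      tibble::tibble(gene_name = gene,
                     sequence = extract_gb_feature(origin, segs))
    })
    cds <- dplyr::bind_rows(cds)
    if (nrow(cds) == 0) return(NULL)
    cds |>
      dplyr::mutate(
        gene = paste0(acc, "|",
                      dplyr::coalesce(.data$gene_name,
                                      paste0("CDS", dplyr::row_number()))),
        .before = 1
      )
  })
  dplyr::bind_rows(out)
}

#' Read coding sequences
#'
#' Reads CDS either from a multi-FASTA of pre-extracted coding sequences or
#' from a GenBank flat file, in which case annotated CDS features are
#' extracted with strand and join handling (minus-strand features are
#' reverse-complemented; joined exons are concatenated in order;
#' `complement(join(...))` reads segments in reverse order).
#'
#' @param path Path to the input file.
#' @param format `"auto"` (by extension/content), `"fasta"` or `"genbank"`.
#' @return A tibble of coding sequences with columns `gene` (identifier),
#'   `gene_name` (annotated gene symbol, may be `NA`), `sequence` (DNA,
#'   upper case) and `source_file`.
#' @export
read_cds <- function(path, format = c("auto", "fasta", "genbank")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^LOCUS", first)) "genbank" else "fasta"
  }
  out <- if (format == "fasta") {
    set <- Biostrings::readDNAStringSet(path)
    tibble::tibble(
      gene = sub("\\s.*$", "", names(set)),
      gene_name = NA_character_,
      sequence = unname(as.character(set))
    )
  } else {
    read_genbank_cds(path)
  }
  if (is.null(out) || nrow(out) == 0) {
    stop("no coding sequences found in ", path, call. = FALSE)
  }
  out |>
    dplyr::mutate(sequence = toupper(.data$sequence),
                  source_file = path) |>
    dplyr::select("gene", "gene_name", "sequence", "source_file")
}

#' Write coding sequences as FASTA
#' @param seqs A CDS tibble (columns `gene`, `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(seqs, path) {
  seqs <- as_cds_tbl(seqs)
  set <- Biostrings::DNAStringSet(stats::setNames(seqs$sequence, seqs$gene))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Quality-filter coding sequences
#'
#' Applies the standard CDS quality chain used for codon-usage work, in a
#' fixed order so every rejected sequence is attributed to its first failing
#' rule: reading frame (length divisible by 3), minimum length, duplicate
#' removal, ATG start, terminal stop codon, internal stop codons.
#'
#' @param seqs A CDS tibble (see [read_cds()]) or anything [count_codons()]
#'   accepts.
#' @param min_len Minimum length in nucleotides (default 300).
#' @param require_atg Require the first codon to be ATG.
#' @param require_terminal_stop Require the final codon to be a stop codon
#'   of `code` ("abnormal termination" otherwise).
#' @param forbid_internal_stop Reject sequences with a stop codon at any
#'   non-terminal position.
#' @param dedup `TRUE`/"sequence" removes exact nucleotide duplicates
#'   (first occurrence kept), `"gene_name"` deduplicates on the annotated
#'   gene symbol, `FALSE`/"none" keeps everything.
#' @param code A [genetic_code()] table supplying the stop codons.
#' @return The retained tibble; the per-sequence report is attached as the
#'   `"filter_report"` attribute and available via [filter_report()].
#' @export
filter_cds <- function(seqs, min_len = 300, require_atg = TRUE,
                       require_terminal_stop = TRUE,
                       forbid_internal_stop = TRUE, dedup = TRUE,
                       code = genetic_code()) {
  seqs <- dplyr::as_tibble(as_cds_tbl(seqs))
  dedup_mode <- if (isTRUE(dedup)) "sequence"
  else if (identical(dedup, FALSE)) "none"
  else match.arg(dedup, c("sequence", "gene_name", "none"))
  stops_dna <- dna_codon(stop_codons(code))
  n <- nrow(seqs)
  reason <- rep(NA_character_, n)
  alive <- rep(TRUE, n)
  fail <- function(idx, why) {
    reason[idx] <<- why
    alive[idx] <<- FALSE
  }
  len <- nchar(seqs$sequence)
  fail(which(alive & len %% 3L != 0L), "frame")
  fail(which(alive & len < min_len), "length")
  if (dedup_mode != "none" && any(alive)) {
    key <- switch(dedup_mode,
                  sequence = seqs$sequence,
                  gene_name = if ("gene_name" %in% names(seqs))
                    seqs$gene_name else seqs$gene)
    dup <- rep(FALSE, n)
    dup[alive] <- duplicated(key[alive])
    fail(which(alive & dup), "duplicate")
  }
  if (require_atg) {
    fail(which(alive & substr(seqs$sequence, 1, 3) != "ATG"), "start")
  }
  if (require_terminal_stop) {
    last <- substr(seqs$sequence, len - 2L, len)
    fail(which(alive & !(last %in% stops_dna)), "terminal_stop")
  }
  if (forbid_internal_stop) {
    has_internal <- vapply(seqs$sequence[alive], function(s) {
      trip <- split_triplets(s)
      k <- length(trip)
      k > 1 && any(trip[-k] %in% stops_dna)
    }, logical(1), USE.NAMES = FALSE)
    fail(which(alive)[has_internal], "internal_stop")
  }
  report <- structure(
    list(
      per_sequence = tibble::tibble(gene = seqs$gene, retained = alive,
                                    reason = reason),
      n_input = n,
      n_after_frame = sum(!reason %in% "frame"),
      n_after_length = sum(!reason %in% c("frame", "length")),
      n_after_dedup = sum(!reason %in% c("frame", "length", "duplicate")),
      n_after_start = sum(!reason %in% c("frame", "length", "duplicate",
                                         "start")),
      n_after_stop = sum(!reason %in% c("frame", "length", "duplicate",
                                        "start", "terminal_stop")),
      n_retained = sum(alive)
    ),
    class = "filter_report"
  )
  out <- seqs[alive, , drop = FALSE]
  attr(out, "filter_report") <- report
  out
}

#' Retrieve the filter report of a filtered CDS set
#' @param x The tibble returned by [filter_cds()].
#' @return A `filter_report` object.
#' @export
filter_report <- function(x) attr(x, "filter_report")

#' @export
print.filter_report <- function(x, ...) {
  cat("CDS filter report: ", x$n_retained, "/", x$n_input, " retained\n",
      sep = "")
  rej <- dplyr::filter(x$per_sequence, !.data$retained)
  if (nrow(rej) > 0) {
    tab <- table(rej$reason)
    for (r in names(tab)) cat("  rejected (", r, "): ", tab[[r]], "\n",
                              sep = "")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.filter_report <- function(x, ...) x$per_sequence

#' @exportS3Method generics::glance
glance.filter_report <- function(x, ...) {
  tibble::tibble(
    n_input = x$n_input, n_after_frame = x$n_after_frame,
    n_after_length = x$n_after_length, n_after_dedup = x$n_after_dedup,
    n_after_start = x$n_after_start, n_after_stop = x$n_after_stop,
    n_retained = x$n_retained
  )
}
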