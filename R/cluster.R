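# Codons-x-taxa RSCU matrix and RSCU-based hierarchical clustering.

#' RSCU matrix across taxa
#'
#' Pools each taxon's coding sequences and assembles the 59 analyzable
#' codons x taxa matrix of RSCU values, the input to cross-taxon clustering
#' and to shared over-represented-codon censuses. Rows are ordered by amino
#' acid then codon; columns by taxon name.
#'
#' @param taxa A named list: one element per taxon, each either a CDS tibble
#'   (anything [count_codons()] accepts) or an already pooled codon count
#'   tibble.
#' @param code A [genetic_code()] table.
#' @param zero_sub Zero-count substitution inside RSCU.
#' @return A numeric matrix (codons x taxa) with an `aa` attribute giving
#'   the amino acid of each row.
#' @export
rscu_matrix <- function(taxa, code = genetic_code(), zero_sub = 0.5) {
  if (length(taxa) < 2) stop("need >= 2 taxa", call. = FALSE)
  if (is.null(names(taxa)) || anyDuplicated(names(taxa))) {
    stop("`taxa` must be a uniquely named list", call. = FALSE)
  }
  taxa <- taxa[order(names(taxa))]
  cols <- purrr::imap(taxa, function(x, name) {
    counts <- if (is.data.frame(x) && all(c("codon", "count") %in% names(x))) {
      x
    } else {
      count_codons(x, code)
    }
    if (sum(counts$count) == 0) {
      stop("taxon `", name, "` has an empty CDS set", call. = FALSE)
    }
    r <- rscu(pool_counts(counts, source = name), zero_sub = zero_sub)
    stats::setNames(r$rscu, r$codon)
  })
  template <- rscu(pool_counts(count_codons(
    c(x = "ATGTAA"), code), source = "t"), zero_sub = zero_sub)
  codons <- template$codon
  m <- vapply(cols, function(v) v[codons], numeric(length(codons)))
  rownames(m) <- codons
  attr(m, "aa") <- template$aa
  m
}

#' Codons over-represented in every taxon
#'
#' @param m An [rscu_matrix()].
#' @param threshold RSCU above which a codon counts as over-represented
#'   (default 1.6).
#' @return Character vector of codons with RSCU > `threshold` in all taxa.
#' @export
shared_overrepresented <- function(m, threshold = 1.6) {
  rownames(m)[apply(m > threshold, 1, all)]
}

#' Cluster taxa on their RSCU profiles
#'
#' Agglomerative hierarchical clustering of the taxon columns of an RSCU
#' matrix (default: Euclidean distance, average linkage/UPGMA), returned as
#' an `ape::phylo` tree serializable to Newick. Columns are ordered by
#' taxon name first, so equal-distance merges resolve deterministically.
#'
#' @param m An [rscu_matrix()].
#' @param distance `"euclidean"` (default) or `"correlation"`
#'   (1 - Pearson r between columns).
#' @param linkage An `stats::hclust` method: `"average"` (default),
#'   `"complete"`, `"ward.D2"`, ...
#' @return An object of class `rscu_tree` and `phylo`; write it with
#'   [write_newick()] or `ape::write.tree()`. The underlying `hclust` fit is
#'   attached as attribute `"hclust"`.
#' @export
cluster_taxa <- function(m, distance = c("euclidean", "correlation"),
                         linkage = "average") {
  distance <- match.arg(distance)
  m <- m[, order(colnames(m)), drop = FALSE]
  d <- if (distance == "euclidean") {
    stats::dist(t(m))
  } else {
    stats::as.dist(1 - stats::cor(m))
  }
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(as.matrix(d)), arr.ind = TRUE)[1, ]
    stop("non-finite distance between taxa `", colnames(m)[bad[1]],
         "` and `", colnames(m)[bad[2]], "`", call. = FALSE)
  }
  hc <- stats::hclust(d, method = linkage)
  tree <- ape::as.phylo(hc)
  attr(tree, "hclust") <- hc
  class(tree) <- c("rscu_tree", class(tree))
  tree
}

#' Write a taxon tree as Newick
#' @param tree A tree from [cluster_taxa()] (any `phylo`).
#' @param path Output file; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  class(tree) <- "phylo"
  if (is.null(path)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = path)
  invisible(ape::write.tree(tree))
}
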