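#' Harvest one gene across a taxon panel
#'
#' Reading-direction CDSs of a protein-coding gene from each genome;
#' taxa lacking the gene are omitted with a warning.
#'
#' @param genomes list of [mito_genome()] objects.
#' @param gene gene name.
#' @param fasta_path optional path: write the set as FASTA.
#' @return named character vector of sequences.
#' @export
harvest_gene <- function(genomes, gene, fasta_path = NULL) {
  have <- vapply(genomes, function(g) gene %in% g$features$name, logical(1L))
  if (any(!have))
    warning(sum(!have), " genome(s) lack ", gene, "; omitted")
  out <- stats::setNames(
    vapply(genomes[have], function(g) extract_gene_sequence(g, gene),
           character(1L)),
    vapply(genomes[have], function(g) g$taxon, character(1L)))
  if (!is.null(fasta_path)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(out), fasta_path)
  }
  out
}

# named character vector of equal-length strings -> character matrix
alignment_matrix <- function(alignment) {
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L)
    stop("alignment is not rectangular")
  t(vapply(alignment, function(s) seq_chars(s), character(lens[1L])))
}

#' Filter alignment columns by gap/ambiguity content
#'
#' A documented, transparent column filter applied before concatenation:
#' removes columns whose gap fraction exceeds `max_gap_frac` (default 0)
#' and, optionally, any column containing an ambiguity code (N).  The log
#' of removed column indices is attached so the filtering is auditable.
#'
#' @param alignment named character vector of equal-length sequences.
#' @param max_gap_frac maximum tolerated fraction of gap characters
#'   (`-`) per column.
#' @param drop_ambiguous also remove columns containing N.
#' @return filtered alignment (same names) with attribute
#'   `removed_columns` (integer indices in the input coordinates).
#' @export
filter_columns <- function(alignment, max_gap_frac = 0,
                           drop_ambiguous = FALSE) {
  m <- alignment_matrix(toupper(alignment))
  gap_frac <- colMeans(m == "-")
  bad <- gap_frac > max_gap_frac
  if (drop_ambiguous) bad <- bad | apply(m == "N", 2L, any)
  if (all(bad)) stop("no columns survive filtering")
  kept <- m[, !bad, drop = FALSE]
  out <- stats::setNames(apply(kept, 1L, paste, collapse = ""),
                         rownames(m))
  attr(out, "removed_columns") <- which(bad)
  out
}

#' Concatenate per-gene alignments into a partitioned supermatrix
#'
#' Genes are concatenated in a fixed order (alphabetical: atp6, atp8,
#' cox1, cox2, cox3, cytb, nad1, nad2, nad3, nad4, nad4l, nad5, nad6, or
#' the order given); taxa missing from a gene are filled with gaps and
#' flagged.  Per-gene lengths are trimmed to codon multiples before
#' filtering so frame is preserved.  The result records per-gene column
#' ranges (charsets) that tile the matrix.
#'
#' @param gene_alignments named list of named character vectors (gene ->
#'   taxon -> aligned sequence).
#' @param taxa optional taxon order; defaults to the union in first-seen
#'   order.
#' @param trim_to_codon trim each gene to a multiple of 3 first.
#' @param max_gap_frac,drop_ambiguous passed to [filter_columns()].
#' @return `supermatrix`: list with `taxa`, `sequences` (named vector),
#'   `charsets` (data.frame gene/start/end), `filter_log`,
#'   `missing` (gene x taxon fills).
#' @export
concatenate_genes <- function(gene_alignments, taxa = NULL,
                              trim_to_codon = TRUE, max_gap_frac = 1,
                              drop_ambiguous = FALSE) {
  genes <- names(gene_alignments)
  if (is.null(genes)) stop("gene_alignments must be named")
  genes <- sort(genes)
  if (is.null(taxa))
    taxa <- unique(unlist(lapply(gene_alignments, names)))
  if (anyDuplicated(taxa)) stop("duplicate taxon names")
  pieces <- list(); charsets <- list(); filter_log <- list()
  missing <- list()
  at <- 0L
  for (g in genes) {
    aln <- gene_alignments[[g]]
    if (trim_to_codon) {
      len <- min(nchar(aln)) %/% 3L * 3L
      aln <- vapply(aln, substr, character(1L), start = 1L, stop = len)
    }
    if (max_gap_frac < 1) {
      aln <- filter_columns(aln, max_gap_frac, drop_ambiguous)
      filter_log[[g]] <- attr(aln, "removed_columns")
    } else filter_log[[g]] <- integer(0L)
    len <- nchar(aln[[1L]])
    absent <- setdiff(taxa, names(aln))
    if (length(absent)) {
      missing[[g]] <- absent
      aln[absent] <- paste(rep("-", len), collapse = "")
    }
    pieces[[g]] <- unname(aln[taxa])
    charsets[[g]] <- data.frame(gene = g, start = at + 1L, end = at + len,
                                stringsAsFactors = FALSE)
    at <- at + len
  }
  seqs <- stats::setNames(do.call(paste0, pieces), taxa)
  structure(list(taxa = taxa, sequences = seqs,
                 charsets = do.call(rbind, c(charsets,
                                             make.row.names = FALSE)),
                 filter_log = filter_log, missing = missing),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("<supermatrix> ", length(x$taxa), " taxa x ",
      nchar(x$sequences[[1L]]), " columns, ", nrow(x$charsets),
      " partitions\n", sep = "")
  invisible(x)
}

#' Export a supermatrix
#'
#' NEXUS output includes a `sets` block with one `charset` line per gene
#' for partitioned analysis in external inference programs; PHYLIP output
#' is relaxed (name, space, sequence).
#'
#' @param sm a [concatenate_genes()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_nexus <- function(sm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nt <- length(sm$taxa); nc <- nchar(sm$sequences[[1L]])
  writeLines("#NEXUS", con)
  writeLines("begin data;", con)
  writeLines(sprintf("  dimensions ntax=%d nchar=%d;", nt, nc), con)
  writeLines("  format datatype=dna missing=? gap=-;", con)
  writeLines("  matrix", con)
  nm <- gsub("[^A-Za-z0-9_.]", "_", sm$taxa)
  w <- max(nchar(nm)) + 2L
  for (i in seq_len(nt))
    writeLines(sprintf("    %-*s%s", w, nm[i], sm$sequences[[i]]), con)
  writeLines("  ;", con)
  writeLines("end;", con)
  writeLines("begin sets;", con)
  for (i in seq_len(nrow(sm$charsets)))
    writeLines(sprintf("  charset %s = %d-%d;", sm$charsets$gene[i],
                       sm$charsets$start[i], sm$charsets$end[i]), con)
  writeLines("end;", con)
  invisible(path)
}

#' @rdname write_nexus
#' @export
write_phylip <- function(sm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", length(sm$taxa),
                     nchar(sm$sequences[[1L]])), con)
  nm <- gsub("[^A-Za-z0-9_.]", "_", sm$taxa)
  for (i in seq_along(sm$taxa))
    writeLines(paste(nm[i], sm$sequences[[i]]), con)
  invisible(path)
}

#' @rdname write_nexus
#' @export
write_fasta_matrix <- function(sm, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sm$sequences), path)
  invisible(path)
}
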