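#' Construct an annotated mitogenome record
#'
#' The central container of the package: a (usually circular) nucleotide
#' sequence plus an ordered, strand-aware gene feature table.  Coordinates
#' are 1-based inclusive in GenBank convention; a feature with `end <
#' start` wraps across the origin of the circle.  Strands are labelled
#' `"J"` (majority strand, GenBank `+`) and `"N"` (minority strand, `-`).
#'
#' @param taxon species name.
#' @param sequence nucleotide string over A, C, G, T, N (J-strand).
#' @param features data.frame with columns `name`, `kind` (one of `PCG`,
#'   `tRNA`, `rRNA`, `control_region`), `start`, `end`, `strand`
#'   (`J`/`N`) and optionally `note`.
#' @param accession optional identifier.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return An object of class `mito_genome`.
#' @export
mito_genome <- function(taxon, sequence, features,
                        accession = NA_character_, topology = "circular") {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", sequence))
    stop("sequence contains characters outside A,C,G,T,N")
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  needed <- c("name", "kind", "start", "end", "strand")
  if (nrow(features) == 0L)
    features <- data.frame(name = character(), kind = character(),
                           start = integer(), end = integer(),
                           strand = character(), note = character(),
                           stringsAsFactors = FALSE)
  if (!all(needed %in% names(features)))
    stop("features must have columns ", paste(needed, collapse = ", "))
  if (is.null(features$note)) features$note <- ""
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  n <- nchar(sequence)
  if (nrow(features)) {
    if (any(features$start < 1L | features$start > n |
            features$end < 1L | features$end > n))
      stop("feature coordinates outside genome of length ", n)
    if (!all(features$kind %in%
             c("PCG", "tRNA", "rRNA", "control_region")))
      stop("unknown feature kind")
    if (!all(features$strand %in% c("J", "N")))
      stop("strand must be 'J' or 'N'")
    if (anyDuplicated(features[, c("name", "start")]))
      stop("duplicate (name, start) feature")
  }
  structure(list(taxon = taxon, accession = accession,
                 sequence = sequence, topology = topology,
                 features = features[, c("name", "kind", "start", "end",
                                         "strand", "note")]),
            class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat("<mito_genome> ", x$taxon,
      if (!is.na(x$accession)) paste0(" [", x$accession, "]"), "\n",
      "  ", nchar(x$sequence), " bp, ", x$topology, ", ",
      nrow(x$features), " features (",
      sum(x$features$kind == "PCG"), " PCG, ",
      sum(x$features$kind == "tRNA"), " tRNA, ",
      sum(x$features$kind == "rRNA"), " rRNA, ",
      sum(x$features$kind == "control_region"), " CR)\n", sep = "")
  invisible(x)
}

# feature length on the circle
feature_lengths <- function(genome) {
  f <- genome$features
  n <- nchar(genome$sequence)
  mapply(circular_length, f$start, f$end, MoreArgs = list(genome_length = n))
}

# ---- gene-name normalization -----------------------------------------------

gene_synonyms <- function() {
  if (!is.null(.mitocomp_cache$synonyms)) return(.mitocomp_cache$synonyms)
  path <- system.file("extdata", "gene_synonyms.tsv", package = "mitocomp",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  .mitocomp_cache$synonyms <- tab
  tab
}

#' Normalize a gene label to the package's canonical names
#'
#' Maps annotation variants (COX1/COI/cox1, ND2, CYTB/cob, 16S, D-loop ...)
#' to canonical labels (cox1, nad2, cytb, rrnL, CR ...) via the shipped
#' synonym table.  Unmappable names are returned verbatim with `NA` kind
#' and a warning.
#'
#' @param name gene label as found in an annotation.
#' @return list with elements `name` and `kind` (`NA` if unmapped).
#' @export
normalize_gene_name <- function(name) {
  syn <- gene_synonyms()
  key <- tolower(trimws(gsub("[_]", " ", name)))
  hit <- match(key, syn$synonym)
  if (is.na(hit)) {
    warning("unmappable gene name kept verbatim: ", name)
    return(list(name = name, kind = NA_character_))
  }
  list(name = syn$name[hit], kind = syn$kind[hit])
}

# ---- sequence extraction ---------------------------------------------------

#' Extract a gene's sequence in reading direction
#'
#' For a J-strand feature this is the genomic slice (wrapping the origin
#' when `end < start`); for an N-strand feature, its reverse complement.
#'
#' @param genome a [mito_genome()].
#' @param feature a feature name (character), a row index, or a one-row
#'   data.frame taken from `genome$features`.
#' @return character scalar nucleotide sequence in reading direction.
#' @export
extract_gene_sequence <- function(genome, feature) {
  f <- resolve_feature(genome, feature)
  s <- circular_slice(genome$sequence, f$start, f$end)
  if (f$strand == "N") revcomp(s) else s
}

resolve_feature <- function(genome, feature) {
  ft <- genome$features
  if (is.character(feature) && length(feature) == 1L) {
    i <- which(ft$name == feature)
    if (length(i) == 0L) stop("no feature named ", feature)
    if (length(i) > 1L) stop("feature name ", feature, " is ambiguous")
    ft[i, ]
  } else if (is.numeric(feature)) {
    ft[as.integer(feature), ]
  } else {
    as.data.frame(feature, stringsAsFactors = FALSE)
  }
}

# ---- feature table TSV -----------------------------------------------------

#' Write / read the FASTA + feature-table representation
#'
#' A lossless plain-text alternative to GenBank: the sequence as FASTA and
#' the features as a TSV with fixed column order
#' `taxon, name, kind, start, end, strand`.
#'
#' @param genome a [mito_genome()].
#' @param tsv_path path of the feature table.
#' @param fasta_path path of the FASTA file (written/read alongside).
#' @return `write_feature_table()` returns the paths invisibly;
#'   `read_feature_table()` returns a [mito_genome()].
#' @export
write_feature_table <- function(genome, tsv_path, fasta_path = NULL) {
  f <- genome$features
  out <- data.frame(taxon = rep(genome$taxon, nrow(f)),
                    name = f$name, kind = f$kind, start = f$start,
                    end = f$end, strand = f$strand,
                    stringsAsFactors = FALSE)
  utils::write.table(out, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(fasta_path)) {
    dna <- Biostrings::DNAStringSet(stats::setNames(genome$sequence,
                                                    genome$taxon))
    Biostrings::writeXStringSet(dna, fasta_path)
  }
  invisible(c(tsv = tsv_path, fasta = fasta_path))
}

#' @rdname write_feature_table
#' @param taxon optional taxon override (defaults to the FASTA record name).
#' @param accession optional accession carried into the record.
#' @export
read_feature_table <- function(fasta_path, tsv_path,
                               taxon = NULL, accession = NA_character_) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dna) != 1L) stop("expected exactly one FASTA record")
  tab <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  if (nrow(tab) && anyDuplicated(tab[, c("name", "start")]))
    stop("duplicate (name, start) rows in feature table")
  if (is.null(taxon))
    taxon <- if (nrow(tab)) tab$taxon[1L] else names(dna)[1L]
  mito_genome(taxon = taxon, sequence = as.character(dna[[1L]]),
              features = tab[, c("name", "kind", "start", "end", "strand")],
              accession = accession)
}

# ---- GenBank flat file -----------------------------------------------------

genbank_feature_key <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                         control_region = "D-loop")

genbank_location <- function(start, end, strand, genome_length) {
  loc <- if (end >= start) paste0(start, "..", end)
         else paste0("join(", start, "..", genome_length, ",1..", end, ")")
  if (strand == "N") paste0("complement(", loc, ")") else loc
}

#' Write a mitogenome as a GenBank flat file
#'
#' Emits LOCUS/DEFINITION/ACCESSION headers, a feature table (CDS, tRNA,
#' rRNA, D-loop keys with `/gene` qualifiers, `complement()` for N-strand
#' features and origin-spanning `join()` locations) and the ORIGIN block.
#'
#' @param genome a [mito_genome()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_genbank <- function(genome, path) {
  n <- nchar(genome$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  locus_name <- if (!is.na(genome$accession)) genome$accession
                else gsub("[^A-Za-z0-9]", "_", genome$taxon)
  writeLines(sprintf("LOCUS       %-17s %d bp    DNA     %s INV",
                     locus_name, n,
                     if (genome$topology == "circular") "circular" else "linear "),
             con)
  writeLines(paste0("DEFINITION  ", genome$taxon,
                    " mitochondrion, complete genome."), con)
  if (!is.na(genome$accession))
    writeLines(paste0("ACCESSION   ", genome$accession), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  writeLines(sprintf("                     /organism=\"%s\"", genome$taxon), con)
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    key <- genbank_feature_key[[f$kind[i]]]
    loc <- genbank_location(f$start[i], f$end[i], f$strand[i], n)
    writeLines(sprintf("     %-15s %s", key, loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$name[i]), con)
    if (nzchar(f$note[i]))
      writeLines(sprintf("                     /note=\"%s\"", f$note[i]), con)
  }
  writeLines("ORIGIN", con)
  lower <- tolower(genome$sequence)
  starts <- seq(1L, n, by = 60L)
  for (s in starts) {
    block <- substr(lower, s, min(s + 59L, n))
    tens <- substring(block, seq(1L, nchar(block), 10L),
                      pmin(seq(10L, nchar(block) + 9L, 10L), nchar(block)))
    writeLines(sprintf("%9d %s", s, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

parse_genbank_location <- function(loc, genome_length) {
  strand <- "J"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1L]]
    rng <- lapply(parts, function(p)
      as.integer(strsplit(gsub("[<>]", "", p), "..", fixed = TRUE)[[1L]]))
    # origin-spanning join: first segment must end at the genome end,
    # second must start at 1; encoded as end < start
    start <- rng[[1L]][1L]
    end <- rng[[length(rng)]][2L]
  } else {
    x <- as.integer(strsplit(gsub("[<>]", "", loc), "..", fixed = TRUE)[[1L]])
    start <- x[1L]; end <- x[2L]
  }
  list(start = start, end = end, strand = strand)
}

#' Read a GenBank flat file into a mitogenome record
#'
#' Parses the ORIGIN sequence and CDS/tRNA/rRNA/D-loop/misc_feature
#' entries.  Gene names are normalized via the shipped synonym table
#' (COX1/COI to cox1, ND2 to nad2, 16S to rrnL, ...); `complement()`
#' locations map to strand `N` and origin-spanning `join()` locations to
#' `end < start`.  Features whose name cannot be mapped keep their
#' verbatim name with the kind inferred from the feature key (warning).
#'
#' @param path GenBank flat file.
#' @return a [mito_genome()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) == 0L)
    stop("GenBank parse error: no ORIGIN block in ", path)
  seq_lines <- lines[(origin_at[1L] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^acgtnACGTN]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("GenBank parse error: empty ORIGIN")

  taxon <- NA_character_; accession <- NA_character_
  def <- grep("^DEFINITION", lines, value = TRUE)
  if (length(def))
    taxon <- trimws(sub(" mitochondrion.*$", "",
                        sub("^DEFINITION\\s+", "", def[1L])))
  org <- grep("/organism=", lines, value = TRUE)
  if (length(org))
    taxon <- sub("^.*/organism=\"([^\"]*)\".*$", "\\1", org[1L])
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc)) accession <- trimws(sub("^ACCESSION\\s+", "", acc[1L]))
  circular <- any(grepl("^LOCUS.*circular", lines))

  feat_start <- grep("^FEATURES", lines)
  rows <- list()
  if (length(feat_start)) {
    block <- lines[(feat_start[1L] + 1L):(origin_at[1L] - 1L)]
    # a feature line has a key in columns 6-20
    is_feat <- grepl("^     \\S", block)
    idx <- which(is_feat)
    for (k in seq_along(idx)) {
      i <- idx[k]
      key <- trimws(substr(block[i], 1L, 20L))
      j_end <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
      body <- block[i:j_end]
      loc <- trimws(substr(body[1L], 21L, nchar(body[1L])))
      # location may continue on following lines until a qualifier starts
      extra <- body[-1L]
      qual_at <- grep("^\\s+/", extra)
      if (length(extra) && (!length(qual_at) || qual_at[1L] > 1L)) {
        upto <- if (length(qual_at)) qual_at[1L] - 1L else length(extra)
        loc <- paste0(loc, paste(trimws(extra[seq_len(upto)]), collapse = ""))
      }
      if (!key %in% c("CDS", "tRNA", "rRNA", "D-loop", "misc_feature"))
        next
      gene <- sub("^.*/gene=\"([^\"]*)\".*$", "\\1",
                  grep("/gene=", body, value = TRUE)[1L])
      if (is.na(gene)) {
        prod <- grep("/product=", body, value = TRUE)
        gene <- if (length(prod))
          sub("^.*/product=\"([^\"]*)\".*$", "\\1", prod[1L])
        else key
      }
      kind_from_key <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                              "D-loop" = "control_region",
                              misc_feature = "control_region")
      nm <- normalize_gene_name(gene)
      if (is.na(nm$kind)) nm$kind <- kind_from_key
      pl <- parse_genbank_location(loc, nchar(sequence))
      rows[[length(rows) + 1L]] <-
        data.frame(name = nm$name, kind = nm$kind, start = pl$start,
                   end = pl$end, strand = pl$strand,
                   stringsAsFactors = FALSE)
    }
  }
  features <- if (length(rows)) do.call(rbind, rows)
              else data.frame(name = character(), kind = character(),
                              start = integer(), end = integer(),
                              strand = character(), stringsAsFactors = FALSE)
  mito_genome(taxon = taxon, sequence = sequence, features = features,
              accession = accession,
              topology = if (circular) "circular" else "linear")
}
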