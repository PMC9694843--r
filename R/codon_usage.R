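#' Split a coding sequence into codons and trailing remnant
#'
#' Mitochondrial CDSs frequently end on an incomplete stop codon (T or TA,
#' completed to TAA by polyadenylation of the transcript), so a CDS length
#' need not be a multiple of three.
#'
#' @param cds reading-direction nucleotide string, length >= 3.
#' @return list with `codons` (character vector of triplets) and
#'   `remnant` (trailing 1-2 nt, `""` when length is divisible by 3).
#' @export
#' @examples
#' split_codons("ATGAAAT")   # codons ATG, AAA; remnant "T"
split_codons <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) < 3L) stop("CDS shorter than one codon")
  chunk_codons(cds)
}

#' Classify the start and stop codon of a CDS
#'
#' The start codon is the first triplet, reported verbatim (unusual starts
#' such as CGA, TTG, AAA, AAG, GTG are never "corrected").  The stop is
#' the final triplet when it is a stop under the chosen genetic code; a
#' trailing remnant of `"T"` or `"TA"` is classified as an incomplete
#' stop; anything else is flagged as a non-stop terminus and reported
#' verbatim.  Internal stop codons raise a warning (suspect annotation),
#' not an error.
#'
#' @param cds reading-direction nucleotide string, length >= 6.
#' @param gene gene label carried into the result.
#' @param table_id NCBI translation table (default 5, invertebrate mito).
#' @return list (`codon_call`): `gene`, `start_codon`, `stop_codon`,
#'   `is_canonical_start` (ATN), `is_incomplete_stop`, `is_nonstop_terminal`.
#' @export
classify_start_stop <- function(cds, gene = NA_character_, table_id = 5L) {
  cds <- toupper(cds)
  if (nchar(cds) < 6L) stop("CDS shorter than two codons")
  sc <- split_codons(cds)
  stops <- stop_codons(table_id)
  start <- sc$codons[1L]
  last <- sc$codons[length(sc$codons)]
  incomplete <- FALSE; nonstop <- FALSE
  if (nzchar(sc$remnant)) {
    if (sc$remnant %in% c("T", "TA")) {
      stop_codon <- sc$remnant
      incomplete <- TRUE
      interior <- sc$codons[-1L]
    } else {
      stop_codon <- sc$remnant
      nonstop <- TRUE
      interior <- sc$codons[-1L]
    }
  } else if (last %in% stops) {
    stop_codon <- last
    interior <- sc$codons[-c(1L, length(sc$codons))]
  } else {
    stop_codon <- last
    nonstop <- TRUE
    interior <- sc$codons[-c(1L, length(sc$codons))]
  }
  if (any(interior %in% stops))
    warning("internal stop codon(s) in ", gene, " - suspect annotation")
  list(gene = gene, start_codon = start, stop_codon = stop_codon,
       is_canonical_start = start %in% c("ATA", "ATT", "ATG", "ATC"),
       is_incomplete_stop = incomplete,
       is_nonstop_terminal = nonstop)
}

#' Count codons across protein-coding genes
#'
#' Counts sense-codon usage over one or more reading-direction CDSs.
#' Recognized stop codons at the CDS terminus and incomplete 1-2 nt
#' remnants are excluded; internal codons are counted verbatim.
#'
#' @param cds_set character vector of reading-direction CDSs.
#' @param table_id NCBI translation table.
#' @return named integer vector over the sense codons of the code.
#' @export
count_codons <- function(cds_set, table_id = 5L) {
  sense <- sense_codons(table_id)
  stops <- stop_codons(table_id)
  counts <- stats::setNames(integer(length(sense)), sense)
  for (cds in cds_set) {
    sc <- split_codons(cds)
    cod <- sc$codons
    if (length(cod) && !nzchar(sc$remnant) && cod[length(cod)] %in% stops)
      cod <- cod[-length(cod)]
    cod <- cod[cod %in% sense]   # drops internal stops / ambiguous codons
    t <- table(cod)
    counts[names(t)] <- counts[names(t)] + as.integer(t)
  }
  counts
}

#' Relative synonymous codon usage
#'
#' RSCU of codon c is its count divided by the mean count of its
#' synonymous family; 1 means no bias.  Families follow the amino acids of
#' the chosen code with leucine split into `leu1` (CTN) / `leu2` (TTA,
#' TTG) and serine into `ser1` (AGN) / `ser2` (TCN).  Within every family
#' with non-zero total, RSCU sums to the family size.
#'
#' @param counts named codon counts over sense codons (see
#'   [count_codons()]).
#' @param table_id NCBI translation table.
#' @return `codon_usage_table`: data.frame with columns `codon`, `family`,
#'   `count`, `rscu` (`NA` for families with zero total), plus attribute
#'   `aa_freq`.
#' @export
#' @examples
#' cnt <- count_codons("ATGAAATAA")
#' rscu(cnt)[rscu(cnt)$count > 0, ]
rscu <- function(counts, table_id = 5L) {
  fam <- codon_families(table_id)
  bad <- setdiff(names(counts), names(fam))
  if (length(bad))
    stop("counts contain non-sense codons: ", paste(bad, collapse = ", "))
  counts <- counts[names(fam)[names(fam) %in% names(counts)]]
  fams <- fam[names(counts)]
  fam_tot <- tapply(counts, fams, sum)
  fam_size <- table(fams)
  out <- data.frame(codon = names(counts), family = unname(fams),
                    count = as.integer(counts), stringsAsFactors = FALSE)
  mean_cnt <- as.numeric(fam_tot[out$family]) /
    as.integer(fam_size[out$family])
  out$rscu <- as.numeric(ifelse(fam_tot[out$family] > 0,
                                out$count / mean_cnt, NA_real_))
  aa <- tapply(out$count, out$family, sum)
  attr(out, "aa_freq") <- aa
  class(out) <- c("codon_usage_table", "data.frame")
  out
}

#' Amino-acid usage across protein-coding genes
#'
#' Translates all PCGs of a genome (or a supplied CDS set) under the
#' chosen code and counts residues; terminal stops and incomplete stop
#' remnants are excluded.
#'
#' @param x a [mito_genome()] or a character vector of CDSs.
#' @param table_id NCBI translation table.
#' @return named integer vector of residue counts (one-letter codes).
#' @export
amino_acid_usage <- function(x, table_id = 5L) {
  cds_set <- if (inherits(x, "mito_genome")) harvest_pcgs(x) else x
  code <- genetic_code(table_id)
  res <- integer(0)
  for (cds in cds_set) {
    sc <- split_codons(cds)
    cod <- sc$codons
    aa <- unname(code[cod])
    aa <- aa[!is.na(aa) & aa != "*"]
    t <- table(aa)
    for (a in names(t)) res[a] <- (if (a %in% names(res)) res[[a]] else 0L) +
        as.integer(t[[a]])
  }
  res[order(names(res))]
}

# all PCG sequences of a genome in reading direction, named by gene
harvest_pcgs <- function(genome) {
  idx <- which(genome$features$kind == "PCG")
  stats::setNames(
    vapply(idx, function(i) extract_gene_sequence(genome, i), character(1L)),
    genome$features$name[idx])
}

#' Per-genome codon report (start/stop matrix + RSCU)
#'
#' @param genomes list of [mito_genome()] objects.
#' @param table_id NCBI translation table.
#' @return list with `start_stop` (data.frame: species x PCG, entries
#'   "start/stop") and `rscu_long` (long-format data.frame: species,
#'   codon, family, count, rscu).
#' @export
codon_report <- function(genomes, table_id = 5L) {
  pcg_order <- c("nad2", "cox1", "cox2", "atp8", "atp6", "cox3", "nad3",
                 "nad5", "nad4", "nad4l", "nad6", "cytb", "nad1")
  ss_rows <- list(); rscu_rows <- list()
  for (g in genomes) {
    cds <- harvest_pcgs(g)
    calls <- lapply(names(cds), function(nm)
      classify_start_stop(cds[[nm]], nm, table_id))
    names(calls) <- names(cds)
    row <- vapply(pcg_order, function(nm) {
      if (!nm %in% names(calls)) return(NA_character_)
      paste0(calls[[nm]]$start_codon, "/", calls[[nm]]$stop_codon)
    }, character(1L))
    ss_rows[[g$taxon]] <- as.data.frame(as.list(row),
                                        stringsAsFactors = FALSE)
    ru <- rscu(count_codons(cds, table_id), table_id)
    ru$species <- g$taxon
    rscu_rows[[g$taxon]] <- ru[, c("species", "codon", "family",
                                   "count", "rscu")]
  }
  ss <- do.call(rbind, ss_rows)
  ss <- cbind(species = rownames(ss), ss)
  rownames(ss) <- NULL
  list(start_stop = ss, rscu_long = do.call(rbind, c(rscu_rows,
                                                     make.row.names = FALSE)))
}
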