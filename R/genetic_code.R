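#' Genetic code tables
#'
#' Codon-to-amino-acid maps keyed by NCBI translation table number, shipped
#' as an editable TSV (`inst/extdata/genetic_codes.tsv`).  Table 5, the
#' invertebrate mitochondrial code, is the package default: ATA = Met,
#' TGA = Trp and AGA/AGG = Ser, with TAA/TAG the only stops.
#'
#' @param table_id NCBI translation table number (1, 2 or 5 shipped).
#' @return Named character vector mapping all 64 codons to one-letter
#'   amino-acid codes, with `"*"` for stop codons.
#' @export
#' @examples
#' gc5 <- genetic_code(5)
#' gc5[c("ATA", "TGA", "AGA")]
genetic_code <- function(table_id = 5L) {
  key <- paste0("code", table_id)
  if (!is.null(.mitocomp_cache[[key]])) return(.mitocomp_cache[[key]])
  path <- system.file("extdata", "genetic_codes.tsv", package = "mitocomp",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab <- tab[tab$table_id == table_id, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("genetic code table ", table_id, " not shipped")
  code <- stats::setNames(tab$aa, tab$codon)
  stopifnot(length(code) == 64L)
  .mitocomp_cache[[key]] <- code
  code
}

# sense (non-stop) codons of a code
sense_codons <- function(table_id = 5L) {
  code <- genetic_code(table_id)
  names(code)[code != "*"]
}

stop_codons <- function(table_id = 5L) {
  code <- genetic_code(table_id)
  names(code)[code == "*"]
}

#' Translate an in-frame coding sequence
#'
#' @param cds character scalar, reading-direction nucleotide sequence; a
#'   trailing 1-2 nt remnant (incomplete stop codon) is ignored.
#' @param table_id NCBI translation table number.
#' @param strip_stop drop a single terminal stop residue if present.
#' @return character scalar of one-letter amino-acid codes (`*` marks
#'   internal stops unless stripped at the terminus).
#' @export
translate_cds <- function(cds, table_id = 5L, strip_stop = TRUE) {
  code <- genetic_code(table_id)
  cc <- chunk_codons(toupper(cds))$codons
  aa <- unname(code[cc])
  if (anyNA(aa))
    stop("non-ACGT codon(s): ", paste(cc[is.na(aa)], collapse = ", "))
  if (strip_stop && length(aa) && aa[length(aa)] == "*")
    aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

#' Synonymous-family map for RSCU reporting
#'
#' Families are amino acids under the chosen code, except that leucine is
#' split into `leu1` (CTN) and `leu2` (TTA/TTG) and serine into `ser1`
#' (AGN codons) and `ser2` (TCN), matching the conventional mitochondrial
#' RSCU reporting labels.
#'
#' @param table_id NCBI translation table number.
#' @return Named character vector: sense codon -> family label.
#' @export
codon_families <- function(table_id = 5L) {
  key <- paste0("fam", table_id)
  if (!is.null(.mitocomp_cache[[key]])) return(.mitocomp_cache[[key]])
  code <- genetic_code(table_id)
  sense <- names(code)[code != "*"]
  aa3 <- c(A = "ala", R = "arg", N = "asn", D = "asp", C = "cys", Q = "gln",
           E = "glu", G = "gly", H = "his", I = "ile", L = "leu", K = "lys",
           M = "met", F = "phe", P = "pro", S = "ser", T = "thr", W = "trp",
           Y = "tyr", V = "val")
  fam <- unname(aa3[code[sense]])
  names(fam) <- sense
  is_leu <- fam == "leu"
  fam[is_leu & startsWith(names(fam), "CT")] <- "leu1"
  fam[is_leu & startsWith(names(fam), "TT")] <- "leu2"
  is_ser <- fam == "ser"
  fam[is_ser & startsWith(names(fam), "AG")] <- "ser1"
  fam[is_ser & startsWith(names(fam), "TC")] <- "ser2"
  .mitocomp_cache[[key]] <- fam
  fam
}
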