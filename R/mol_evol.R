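#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' For each of the three codon positions, the fraction of the three
#' possible point mutations that are synonymous; mutations creating stop
#' codons are excluded from the denominator, so synonymous + nonsynonymous
#' sites always total 3 per sense codon.
#'
#' @param codon sense codon (3-mer) under the chosen code.
#' @param table_id NCBI translation table (default 5).
#' @return named numeric vector `c(syn, nonsyn)`.
#' @export
#' @examples
#' ng86_sites("TGG")  # Trp under code 5: third-position syn fraction 1/3
ng86_sites <- function(codon, table_id = 5L) {
  codon <- toupper(codon)
  code <- genetic_code(table_id)
  if (is.na(code[codon])) stop("not a codon: ", codon)
  if (code[[codon]] == "*") stop("stop codon has no NG86 sites: ", codon)
  key <- paste0("sites", table_id)
  if (is.null(.mitocomp_cache[[key]]))
    .mitocomp_cache[[key]] <- new.env(parent = emptyenv())
  env <- .mitocomp_cache[[key]]
  if (!is.null(env[[codon]])) return(env[[codon]])
  aa <- code[[codon]]
  bases <- c("A", "C", "G", "T")
  syn <- 0
  for (pos in 1:3) {
    orig <- substr(codon, pos, pos)
    muts <- vapply(setdiff(bases, orig), function(b) {
      m <- codon; substr(m, pos, pos) <- b; m
    }, character(1L))
    aas <- code[muts]
    keep <- aas != "*"
    if (any(keep)) syn <- syn + sum(aas[keep] == aa) / sum(keep)
  }
  out <- c(syn = syn, nonsyn = 3 - syn)
  env[[codon]] <- out
  out
}

# average synonymous/nonsynonymous differences between two sense codons:
# all minimal mutational pathways, equal weighting, paths through stop
# codons excluded.  Returns c(syn, nonsyn, paths); paths = 0 when every
# pathway crosses a stop (codon pair must then be excluded).
ng86_path_diffs <- function(c1, c2, table_id = 5L) {
  key <- paste0("paths", table_id)
  if (is.null(.mitocomp_cache[[key]]))
    .mitocomp_cache[[key]] <- new.env(parent = emptyenv())
  env <- .mitocomp_cache[[key]]
  pk <- paste0(c1, c2)
  if (!is.null(env[[pk]])) return(env[[pk]])
  code <- genetic_code(table_id)
  d <- which(seq_chars(c1) != seq_chars(c2))
  out <- if (length(d) == 0L) c(syn = 0, nonsyn = 0, paths = 1)
  else {
    perms <- if (length(d) == 1L) list(d)
      else if (length(d) == 2L) list(d, rev(d))
      else list(d[c(1,2,3)], d[c(1,3,2)], d[c(2,1,3)],
                d[c(2,3,1)], d[c(3,1,2)], d[c(3,2,1)])
    tot_s <- 0; tot_n <- 0; ok <- 0L
    for (p in perms) {
      cur <- c1; s <- 0L; n <- 0L; valid <- TRUE
      for (pos in p) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(c2, pos, pos)
        if (code[[nxt]] == "*") { valid <- FALSE; break }
        if (code[[nxt]] == code[[cur]]) s <- s + 1L else n <- n + 1L
        cur <- nxt
      }
      if (valid) { tot_s <- tot_s + s; tot_n <- tot_n + n; ok <- ok + 1L }
    }
    if (ok == 0L) c(syn = 0, nonsyn = 0, paths = 0)
    else c(syn = tot_s / ok, nonsyn = tot_n / ok, paths = ok)
  }
  env[[pk]] <- out
  out
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Codon-based counting with equal-weight averaging over minimal
#' mutational pathways (pathways through stop codons excluded) and
#' Jukes-Cantor correction d = -(3/4) ln(1 - (4/3) p) of the proportions
#' of synonymous and nonsynonymous differences.  Codons containing
#' alignment gaps, N, or stops (including pairs whose every pathway
#' crosses a stop) are excluded.
#'
#' @param cdsA,cdsB aligned reading-direction coding sequences of equal
#'   length (a trailing 1-2 nt remnant is trimmed).
#' @param table_id NCBI translation table.
#' @param labelA,labelB taxon labels carried into the result.
#' @param gene gene label.
#' @return `pairwise_divergence` list: `Ka`, `Ks`, `omega` (`NA` when
#'   Ks = 0), `ka_defined`, `ks_defined`, `saturated_s`, `saturated_n`,
#'   `syn_sites`, `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`,
#'   `codons_used`.
#' @export
pairwise_kaks <- function(cdsA, cdsB, table_id = 5L,
                          labelA = "A", labelB = "B", gene = NA_character_) {
  cdsA <- toupper(cdsA); cdsB <- toupper(cdsB)
  nA <- nchar(cdsA) - nchar(cdsA) %% 3L
  nB <- nchar(cdsB) - nchar(cdsB) %% 3L
  if (nA != nB) stop("aligned CDS lengths differ after remnant trimming")
  ca <- chunk_codons(substr(cdsA, 1L, nA))$codons
  cb <- chunk_codons(substr(cdsB, 1L, nB))$codons
  code <- genetic_code(table_id)
  S <- 0; N <- 0; Sd <- 0; Nd <- 0; used <- 0L
  for (i in seq_along(ca)) {
    a <- ca[i]; b <- cb[i]
    if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b)) next
    if (code[[a]] == "*" || code[[b]] == "*") next
    pd <- ng86_path_diffs(a, b, table_id)
    if (pd[["paths"]] == 0) next
    sa <- ng86_sites(a, table_id); sb <- ng86_sites(b, table_id)
    S <- S + (sa[["syn"]] + sb[["syn"]]) / 2
    N <- N + (sa[["nonsyn"]] + sb[["nonsyn"]]) / 2
    Sd <- Sd + pd[["syn"]]; Nd <- Nd + pd[["nonsyn"]]
    used <- used + 1L
  }
  jc <- function(p) if (p < 3 / 4) -3 / 4 * log(1 - 4 / 3 * p) else NA_real_
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  Ks <- if (!is.na(ps)) jc(ps) else NA_real_
  Ka <- if (!is.na(pn)) jc(pn) else NA_real_
  omega <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  structure(list(gene = gene, taxonA = labelA, taxonB = labelB,
                 Ka = Ka, Ks = Ks, omega = omega,
                 ka_defined = !is.na(Ka), ks_defined = !is.na(Ks) && Ks > 0,
                 saturated_s = !is.na(ps) && ps >= 3 / 4,
                 saturated_n = !is.na(pn) && pn >= 3 / 4,
                 syn_sites = S, nonsyn_sites = N,
                 syn_diffs = Sd, nonsyn_diffs = Nd, codons_used = used),
            class = "pairwise_divergence")
}

#' Ka/Ks panel for one gene across a taxon set
#'
#' Computes [pairwise_kaks()] over all unordered taxon pairs (or against a
#' single reference taxon) and summarizes.  Sequences of unequal length
#' are truncated to the shortest, frame-preserving (a simple
#' reading-frame alignment; supply externally aligned sequences for
#' indel-containing data).
#'
#' @param genomes list of [mito_genome()] objects, or a named character
#'   vector of reading-direction CDSs.
#' @param gene PCG name (ignored when `genomes` is a CDS vector).
#' @param reference optional taxon name: compare all taxa against it only.
#' @param table_id NCBI translation table.
#' @return list: `gene`, `pairs` (data.frame per pair), `mean_ka`,
#'   `mean_ks`, `mean_omega` (means over defined, unsaturated pairs),
#'   `n_pairs`.
#' @export
gene_panel_kaks <- function(genomes, gene = NA_character_, reference = NULL,
                            table_id = 5L) {
  cds <- if (is.character(genomes)) genomes
  else {
    have <- vapply(genomes, function(g) gene %in% g$features$name,
                   logical(1L))
    if (any(!have))
      warning(sum(!have), " genome(s) lack ", gene, "; omitted")
    stats::setNames(
      lapply(genomes[have], function(g) extract_gene_sequence(g, gene)),
      vapply(genomes[have], function(g) g$taxon, character(1L)))
  }
  cds <- unlist(cds)
  if (length(cds) < 2L)
    return(list(gene = gene, pairs = NULL, mean_ka = NA_real_,
                mean_ks = NA_real_, mean_omega = NA_real_, n_pairs = 0L))
  minlen <- min(nchar(cds)); minlen <- minlen - minlen %% 3L
  cds <- vapply(cds, substr, character(1L), start = 1L, stop = minlen)
  taxa <- names(cds)
  pairs <- if (is.null(reference)) utils::combn(taxa, 2L, simplify = FALSE)
  else lapply(setdiff(taxa, reference), function(t) c(reference, t))
  rows <- lapply(pairs, function(p) {
    r <- pairwise_kaks(cds[[p[1L]]], cds[[p[2L]]], table_id,
                       p[1L], p[2L], gene)
    data.frame(gene = gene, taxonA = p[1L], taxonB = p[2L], Ka = r$Ka,
               Ks = r$Ks, omega = r$omega, saturated = r$saturated_s ||
                 r$saturated_n, codons_used = r$codons_used,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- !tab$saturated
  list(gene = gene, pairs = tab,
       mean_ka = mean(tab$Ka[ok], na.rm = TRUE),
       mean_ks = mean(tab$Ks[ok], na.rm = TRUE),
       mean_omega = mean(tab$omega[ok], na.rm = TRUE),
       n_pairs = nrow(tab))
}

#' Tamura-Nei (1993) distance between two aligned sequences
#'
#' Closed-form TN93 distance distinguishing purine transitions (A-G,
#' proportion P1), pyrimidine transitions (C-T, proportion P2) and
#' transversions (proportion Q), with base frequencies averaged over the
#' two sequences.  Sites containing gaps or ambiguity codes are excluded
#' pairwise.  When any logarithm argument is non-positive the distance is
#' flagged saturated/undefined.
#'
#' @param seqA,seqB aligned nucleotide strings of equal length.
#' @param labelA,labelB taxon labels.
#' @return `pairwise_divergence` list: `tn93`, `p_transition` (P1 + P2),
#'   `p_transversion` (Q), `p_distance`, `sites_used`, `defined`.
#' @export
tn93_distance <- function(seqA, seqB, labelA = "A", labelB = "B") {
  a <- seq_chars(toupper(seqA)); b <- seq_chars(toupper(seqB))
  if (length(a) != length(b)) stop("aligned sequences of unequal length")
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n == 0L) stop("no comparable sites")
  diff <- a != b
  pair <- paste0(pmin(a, b), pmax(a, b))
  P1 <- sum(diff & pair == "AG") / n
  P2 <- sum(diff & pair == "CT") / n
  Q <- sum(diff & !(pair %in% c("AG", "CT"))) / n
  freq <- (table(factor(a, levels = c("A", "C", "G", "T"))) +
             table(factor(b, levels = c("A", "C", "G", "T")))) / (2 * n)
  gA <- freq[["A"]]; gC <- freq[["C"]]; gG <- freq[["G"]]; gT <- freq[["T"]]
  gR <- gA + gG; gY <- gC + gT
  w1 <- 1 - gR * P1 / (2 * gA * gG) - Q / (2 * gR)
  w2 <- 1 - gY * P2 / (2 * gC * gT) - Q / (2 * gY)
  w3 <- 1 - Q / (2 * gR * gY)
  defined <- is.finite(w1) && is.finite(w2) && is.finite(w3) &&
    w1 > 0 && w2 > 0 && w3 > 0
  d <- if (defined)
    -(2 * gA * gG / gR) * log(w1) - (2 * gC * gT / gY) * log(w2) -
      2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY) * log(w3)
  else NA_real_
  structure(list(taxonA = labelA, taxonB = labelB, tn93 = d,
                 p_transition = P1 + P2, p_transversion = Q,
                 p_distance = P1 + P2 + Q, sites_used = n,
                 defined = defined),
            class = "pairwise_divergence")
}

#' Substitution-saturation table for a multi-taxon alignment
#'
#' Per unordered taxon pair: transition proportion s, transversion
#' proportion v, and the TN93 distance; plus least-squares fits of s and v
#' on the distance (with Pearson correlations) over the pairs where the
#' distance is defined, supporting the usual linearity check for
#' saturation.  Saturated (undefined-distance) pairs are excluded from
#' the regression and reported in `flagged`.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences (>= 2 taxa).
#' @return list: `table` (data.frame `taxonA`, `taxonB`, `s`, `v`,
#'   `tn93`, `defined`), `fit_s`, `fit_v` (each: slope, intercept,
#'   pearson_r), `flagged` (rows with undefined distance).
#' @export
saturation_table <- function(alignment) {
  stopifnot(length(alignment) >= 2L, !is.null(names(alignment)))
  pairs <- utils::combn(names(alignment), 2L, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    r <- tn93_distance(alignment[[p[1L]]], alignment[[p[2L]]],
                       p[1L], p[2L])
    data.frame(taxonA = p[1L], taxonB = p[2L], s = r$p_transition,
               v = r$p_transversion, tn93 = r$tn93, defined = r$defined,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$defined
  fit <- function(y) {
    if (sum(ok) < 3L || stats::var(tab$tn93[ok]) == 0)
      return(list(slope = NA_real_, intercept = NA_real_,
                  pearson_r = NA_real_))
    m <- stats::lm(y[ok] ~ tab$tn93[ok])
    list(slope = unname(stats::coef(m)[2L]),
         intercept = unname(stats::coef(m)[1L]),
         pearson_r = stats::cor(tab$tn93[ok], y[ok]))
  }
  list(table = tab, fit_s = fit(tab$s), fit_v = fit(tab$v),
       flagged = tab[!ok, , drop = FALSE])
}
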