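#' Base composition and strand skews of a sequence
#'
#' Counts A, C, G, T (N excluded from all percentages and skews, but
#' counted in `length`), and computes A+T / G+C content together with the
#' strand-asymmetry skews
#' \deqn{AT\mathrm{-skew} = (A - T)/(A + T), \qquad
#'       GC\mathrm{-skew} = (G - C)/(G + C).}
#' A skew whose denominator is zero is returned as `NA` with
#' `at_skew_defined`/`gc_skew_defined` set to `FALSE`.
#'
#' @param seq nucleotide string over A,C,G,T,N.
#' @param label region identifier carried into the summary.
#' @return An object of class `composition_summary`: a list with counts,
#'   percentages, `at_content`, `gc_content`, `at_skew`, `gc_skew`,
#'   `length` (bp including N) and `n_count`.
#' @export
#' @examples
#' base_composition("GGGC")$gc_skew   # (3 - 1)/4 = 0.5
base_composition <- function(seq, label = "region") {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("empty sequence")
  seq <- toupper(seq)
  tab <- table(factor(seq_chars(seq), levels = c("A", "C", "G", "T", "N")))
  cnt <- as.integer(tab[c("A", "C", "G", "T")])
  names(cnt) <- c("A", "C", "G", "T")
  nN <- as.integer(tab[["N"]])
  tot <- sum(cnt)
  pct <- if (tot > 0) 100 * cnt / tot else rep(NA_real_, 4L)
  at_den <- cnt[["A"]] + cnt[["T"]]
  gc_den <- cnt[["G"]] + cnt[["C"]]
  structure(list(
    label = label,
    counts = cnt,
    pct = pct,
    at_content = if (tot > 0) pct[["A"]] + pct[["T"]] else NA_real_,
    gc_content = if (tot > 0) pct[["G"]] + pct[["C"]] else NA_real_,
    at_skew = if (at_den > 0) (cnt[["A"]] - cnt[["T"]]) / at_den else NA_real_,
    gc_skew = if (gc_den > 0) (cnt[["G"]] - cnt[["C"]]) / gc_den else NA_real_,
    at_skew_defined = at_den > 0,
    gc_skew_defined = gc_den > 0,
    length = nchar(seq),
    n_count = nN,
    all_n = tot == 0L
  ), class = "composition_summary")
}

#' @export
print.composition_summary <- function(x, ...) {
  cat(sprintf("<composition> %s: %d bp, AT %.1f%%, AT-skew %s, GC-skew %s\n",
              x$label, x$length,
              x$at_content,
              ifelse(x$at_skew_defined, sprintf("%.3f", x$at_skew), "undef"),
              ifelse(x$gc_skew_defined, sprintf("%.3f", x$gc_skew), "undef")))
  invisible(x)
}

#' Whole-genome and strand-partitioned PCG composition
#'
#' Returns composition summaries for (i) the whole genome on the J-strand
#' reference sequence, (ii) the concatenated J-strand protein-coding genes
#' and (iii) the concatenated N-strand protein-coding genes, both in
#' reading direction.  A strand with no PCGs is omitted with a warning.
#'
#' @param genome a [mito_genome()].
#' @return named list of `composition_summary` objects
#'   (`genome`, `pcg_J`, `pcg_N`).
#' @export
strand_class_composition <- function(genome) {
  out <- list(genome = base_composition(genome$sequence,
                                        paste0(genome$taxon, " genome")))
  f <- genome$features
  for (st in c("J", "N")) {
    idx <- which(f$kind == "PCG" & f$strand == st)
    if (length(idx) == 0L) {
      warning("no PCGs on strand ", st, " in ", genome$taxon)
      next
    }
    cat_seq <- paste(vapply(idx, function(i)
      extract_gene_sequence(genome, i), character(1L)), collapse = "")
    s <- base_composition(cat_seq, paste0(genome$taxon, " PCG-", st))
    s$n_genes <- length(idx)
    out[[paste0("pcg_", st)]] <- s
  }
  out
}

#' Composition report table across genomes
#'
#' One row per genome in the conventional mitogenome-paper layout:
#' Size (bp), T%, C%, A%, G%, AT%, GC%, GT% (= G% + T%), AT skew, GC skew.
#' Percentages are rounded to one decimal and skews to three decimals in
#' the `*_r` display columns; unrounded values are kept alongside.
#'
#' @param genomes list of [mito_genome()] objects.
#' @return data.frame, one row per genome.
#' @export
composition_table <- function(genomes) {
  stopifnot(length(genomes) >= 1L)
  rows <- lapply(genomes, function(g) {
    s <- base_composition(g$sequence, g$taxon)
    data.frame(
      species = g$taxon,
      size_bp = s$length,
      T_pct = s$pct[["T"]], C_pct = s$pct[["C"]],
      A_pct = s$pct[["A"]], G_pct = s$pct[["G"]],
      AT_pct = s$at_content, GC_pct = s$gc_content,
      GT_pct = s$pct[["G"]] + s$pct[["T"]],
      AT_skew = s$at_skew, GC_skew = s$gc_skew,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  pctcols <- c("T_pct", "C_pct", "A_pct", "G_pct", "AT_pct", "GC_pct", "GT_pct")
  for (cc in pctcols) out[[paste0(cc, "_r")]] <- round(out[[cc]], 1)
  out$AT_skew_r <- round(out$AT_skew, 3)
  out$GC_skew_r <- round(out$GC_skew, 3)
  rownames(out) <- NULL
  out
}

#' Skews implied by printed composition percentages
#'
#' Convenience for checking published composition tables: computes AT- and
#' GC-skew from percentage values (as printed, e.g. A = 39.8, T = 39.1)
#' rather than from raw counts.
#'
#' @param A,C,G,T base percentages.
#' @return list with `at_skew` and `gc_skew`.
#' @export
skews_from_percentages <- function(A, C, G, T) {
  list(at_skew = (A - T) / (A + T), gc_skew = (G - C) / (G + C))
}
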