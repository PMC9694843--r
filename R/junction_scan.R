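#' Scan gene junctions of a circular genome
#'
#' Walks adjacent feature pairs in genomic order around the circle
#' (control regions included as features) and reports, for every pair,
#' whether the genes overlap, abut, or are separated by an intergenic
#' spacer.  Overlaps are computed on genomic coordinates irrespective of
#' strand (tRNA overlaps routinely span opposite strands); overlap and
#' spacer sequences are reported on the J-strand.  A feature fully nested
#' inside its predecessor is reported as an overlap of the inner length,
#' with a warning.
#'
#' @param genome a [mito_genome()].
#' @return `junction_report` data.frame: `taxon`, `upstream`,
#'   `downstream`, `relation` (`overlap`/`abutting`/`spacer`), `length`,
#'   `sequence`, `circular_wrap`.
#' @export
scan_junctions <- function(genome) {
  f <- genome$features
  empty <- data.frame(taxon = character(), upstream = character(),
                      downstream = character(), relation = character(),
                      length = integer(), sequence = character(),
                      circular_wrap = logical(), stringsAsFactors = FALSE)
  class(empty) <- c("junction_report", "data.frame")
  if (nrow(f) < 2L) return(empty)
  L <- nchar(genome$sequence)
  len <- feature_lengths(genome)
  o <- order(f$start, -len)
  f <- f[o, ]; len <- len[o]
  end_u <- f$start + len - 1L          # unrolled end coordinate
  n <- nrow(f)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    j <- if (i < n) i + 1L else 1L
    nxt_start <- if (i < n) f$start[j] else f$start[j] + L
    nxt_end <- if (i < n) end_u[j] else end_u[j] + L
    gap <- nxt_start - end_u[i] - 1L
    wrap <- i == n || end_u[i] > L
    if (nxt_end <= end_u[i]) {         # nested feature
      warning("feature ", f$name[j], " nested inside ", f$name[i],
              " in ", genome$taxon)
      relation <- "overlap"; olen <- len[j]
      sq <- circ_span(genome$sequence, nxt_start, nxt_end, L)
    } else if (gap < 0L) {
      relation <- "overlap"; olen <- -gap
      sq <- circ_span(genome$sequence, nxt_start, end_u[i], L)
    } else if (gap == 0L) {
      relation <- "abutting"; olen <- 0L; sq <- ""
    } else {
      relation <- "spacer"; olen <- gap
      sq <- circ_span(genome$sequence, end_u[i] + 1L, nxt_start - 1L, L)
    }
    rows[[i]] <- data.frame(taxon = genome$taxon, upstream = f$name[i],
                            downstream = f$name[j], relation = relation,
                            length = olen, sequence = sq,
                            circular_wrap = wrap, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("junction_report", "data.frame")
  out
}

# J-strand slice given unrolled coordinates on a circle of length L
circ_span <- function(seq, from, to, L) {
  a <- ((from - 1L) %% L) + 1L
  b <- ((to - 1L) %% L) + 1L
  circular_slice(seq, a, b)
}

#' Conserved junction motifs across taxa
#'
#' Groups the junction sequences of every gene pair that is adjacent in at
#' least one genome.  A junction is universal when all input genomes have
#' that adjacency with an identical sequence (and relation); otherwise the
#' modal sequence is reported as the motif with its supporting taxa.
#'
#' @param genomes list of [mito_genome()] objects (>= 2).
#' @return data.frame: `upstream`, `downstream`, `relation`, `motif`,
#'   `length`, `n_adjacent` (genomes with the adjacency),
#'   `n_supporting` (genomes sharing the modal sequence),
#'   `taxa_supporting` (comma-separated), `is_universal`.
#' @export
conserved_junctions <- function(genomes) {
  stopifnot(length(genomes) >= 2L)
  ntax <- length(genomes)
  all_j <- do.call(rbind, lapply(genomes, scan_junctions))
  key <- paste(all_j$upstream, all_j$downstream, sep = "|")
  rows <- lapply(split(all_j, key), function(d) {
    tab <- sort(table(d$sequence), decreasing = TRUE)
    motif <- names(tab)[1L]
    sup <- d$taxon[d$sequence == motif]
    data.frame(upstream = d$upstream[1L], downstream = d$downstream[1L],
               relation = d$relation[which(d$sequence == motif)[1L]],
               motif = motif, length = nchar(motif),
               n_adjacent = nrow(d), n_supporting = length(sup),
               taxa_supporting = paste(sup, collapse = ","),
               is_universal = nrow(d) == ntax && length(sup) == ntax &&
                 length(unique(d$relation)) == 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(-out$is_universal, -out$n_supporting, out$upstream), ]
}

#' Spacer length and composition profile for one gene pair
#'
#' @param genomes list of [mito_genome()] objects.
#' @param gene_pair character vector of length 2: upstream and downstream
#'   gene in genomic order.
#' @return list: `per_taxon` data.frame (`taxon`, `relation`, `length`,
#'   `at_content`), `min_length`, `max_length`.
#' @export
spacer_profile <- function(genomes, gene_pair) {
  stopifnot(length(gene_pair) == 2L)
  rows <- list()
  for (g in genomes) {
    j <- scan_junctions(g)
    hit <- j[j$upstream == gene_pair[1L] & j$downstream == gene_pair[2L], ]
    if (nrow(hit) == 0L) next
    at <- if (nchar(hit$sequence[1L]) > 0)
      base_composition(hit$sequence[1L])$at_content else NA_real_
    rows[[length(rows) + 1L]] <-
      data.frame(taxon = g$taxon, relation = hit$relation[1L],
                 length = hit$length[1L], at_content = at,
                 stringsAsFactors = FALSE)
  }
  per <- if (length(rows)) do.call(rbind, rows)
         else data.frame(taxon = character(), relation = character(),
                         length = integer(), at_content = numeric(),
                         stringsAsFactors = FALSE)
  list(per_taxon = per,
       min_length = if (nrow(per)) min(per$length) else NA_integer_,
       max_length = if (nrow(per)) max(per$length) else NA_integer_)
}

#' Locate (unannotated) control regions
#'
#' Scans the circle for stretches not covered by any tRNA/rRNA/PCG
#' feature of at least `min_len` bp and reports them with their flanking
#' genes.  The canonical lepidopteran control region is flanked by rrnS
#' and trnM; any other hit is flagged supernumerary.  Annotated
#' control-region features are ignored for the coverage computation, so
#' the function works whether or not the CR is annotated.
#'
#' @param genome a [mito_genome()].
#' @param min_len minimum stretch length in bp (default 200, safely above
#'   ordinary intergenic spacers).
#' @return data.frame: `start`, `end`, `length`, `upstream`,
#'   `downstream`, `canonical`.
#' @export
locate_control_regions <- function(genome, min_len = 200L) {
  g2 <- genome
  g2$features <- g2$features[g2$features$kind != "control_region", ,
                             drop = FALSE]
  j <- scan_junctions(g2)
  hits <- j[j$relation == "spacer" & j$length >= min_len, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(start = integer(), end = integer(), length = integer(),
                      upstream = character(), downstream = character(),
                      canonical = logical(), stringsAsFactors = FALSE))
  f <- g2$features
  L <- nchar(genome$sequence)
  res <- lapply(seq_len(nrow(hits)), function(i) {
    up <- hits$upstream[i]
    fe <- f[f$name == up, ][1L, ]
    s <- (fe$end %% L) + 1L
    e <- ((s + hits$length[i] - 2L) %% L) + 1L
    data.frame(start = s, end = e, length = hits$length[i],
               upstream = up, downstream = hits$downstream[i],
               canonical = setequal(c(up, hits$downstream[i]),
                                    c("rrnS", "trnM")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Search a junction motif anywhere in a genome
#'
#' Some conserved "intergenic" motifs partially lie inside the 3' end of a
#' neighbouring gene; this reports every J-strand occurrence of a motif
#' with the features it intersects, keeping such motif-in-gene hits
#' separate from pure spacer calls.
#'
#' @param genome a [mito_genome()].
#' @param motif nucleotide string.
#' @return data.frame: `start`, `end`, `inside_features`
#'   (comma-separated feature names overlapped, `""` if fully intergenic).
#' @export
find_junction_motif <- function(genome, motif) {
  L <- nchar(genome$sequence)
  doubled <- paste0(genome$sequence,
                    substr(genome$sequence, 1L, nchar(motif) - 1L))
  starts <- gregexpr(motif, doubled, fixed = TRUE)[[1L]]
  if (starts[1L] == -1L)
    return(data.frame(start = integer(), end = integer(),
                      inside_features = character(), stringsAsFactors = FALSE))
  f <- genome$features
  len <- feature_lengths(genome)
  end_u <- f$start + len - 1L
  res <- lapply(as.integer(starts), function(s) {
    e <- s + nchar(motif) - 1L
    hit <- f$name[f$start <= e & end_u >= s |
                    (f$start <= e - L & end_u >= s - L)]
    data.frame(start = ((s - 1L) %% L) + 1L, end = ((e - 1L) %% L) + 1L,
               inside_features = paste(unique(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
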