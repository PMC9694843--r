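#' Reference mitochondrial gene orders
#'
#' Signed circular gene orders shipped as references:
#' `ancestral_insect` (the plesiomorphic arrangement with the
#' trnI-trnQ-trnM block), `lepidoptera_typical` (the moth/butterfly
#' rearrangement trnM-trnI-trnQ) and `chironomid_variant`
#' (trnI-trnM-trnQ).  Strand `J`/`N` follows the majority/minority
#' convention; the control region is the token `CR`.
#'
#' @param template one of `"ancestral_insect"`, `"lepidoptera_typical"`,
#'   `"chironomid_variant"`.
#' @return data.frame with columns `name`, `kind`, `strand` in genomic
#'   order around the circle.
#' @export
gene_order_template <- function(template = "lepidoptera_typical") {
  core <- list(
    # name, kind, strand -- shared downstream block (nad2 .. CR)
    c("nad2", "PCG", "J"), c("trnW", "tRNA", "J"), c("trnC", "tRNA", "N"),
    c("trnY", "tRNA", "N"), c("cox1", "PCG", "J"), c("trnL2", "tRNA", "J"),
    c("cox2", "PCG", "J"), c("trnK", "tRNA", "J"), c("trnD", "tRNA", "J"),
    c("atp8", "PCG", "J"), c("atp6", "PCG", "J"), c("cox3", "PCG", "J"),
    c("trnG", "tRNA", "J"), c("nad3", "PCG", "J"), c("trnA", "tRNA", "J"),
    c("trnR", "tRNA", "J"), c("trnN", "tRNA", "J"), c("trnS1", "tRNA", "J"),
    c("trnE", "tRNA", "J"), c("trnF", "tRNA", "N"), c("nad5", "PCG", "N"),
    c("trnH", "tRNA", "N"), c("nad4", "PCG", "N"), c("nad4l", "PCG", "N"),
    c("trnT", "tRNA", "J"), c("trnP", "tRNA", "N"), c("nad6", "PCG", "J"),
    c("cytb", "PCG", "J"), c("trnS2", "tRNA", "J"), c("nad1", "PCG", "N"),
    c("trnL1", "tRNA", "N"), c("rrnL", "rRNA", "N"), c("trnV", "tRNA", "N"),
    c("rrnS", "rRNA", "N"), c("CR", "control_region", "J"))
  head_block <- switch(
    template,
    ancestral_insect = list(c("trnI", "tRNA", "J"), c("trnQ", "tRNA", "N"),
                            c("trnM", "tRNA", "J")),
    lepidoptera_typical = list(c("trnM", "tRNA", "J"), c("trnI", "tRNA", "J"),
                               c("trnQ", "tRNA", "N")),
    chironomid_variant = list(c("trnI", "tRNA", "J"), c("trnM", "tRNA", "J"),
                              c("trnQ", "tRNA", "N")),
    stop("unknown template: ", template))
  m <- do.call(rbind, c(head_block, core))
  data.frame(name = m[, 1L], kind = m[, 2L], strand = m[, 3L],
             stringsAsFactors = FALSE)
}

#' Signed gene order of an annotated genome
#'
#' Features sorted by genomic position (ties: longer feature first) give a
#' circular signed order, canonically rotated to start at an anchor gene
#' (default cox1) in J-strand orientation: if the anchor lies on the N
#' strand the whole order is reflected (reversed with all strands flipped)
#' so comparisons are orientation-free.
#'
#' @param genome a [mito_genome()].
#' @param anchor anchor gene name; if absent, the lexicographically
#'   smallest gene is used with a warning.
#' @return `gene_order` object: list with `taxon` and `order`
#'   (data.frame `name`, `strand`).
#' @export
order_string <- function(genome, anchor = "cox1") {
  f <- genome$features
  stopifnot(nrow(f) > 0L)
  len <- feature_lengths(genome)
  f <- f[order(f$start, -len), ]
  ord <- data.frame(name = ifelse(f$kind == "control_region", "CR", f$name),
                    strand = f$strand, stringsAsFactors = FALSE)
  make_gene_order(ord, genome$taxon, anchor)
}

# canonicalize a name/strand data.frame into a gene_order
make_gene_order <- function(ord, taxon, anchor = "cox1") {
  if (!anchor %in% ord$name) {
    anchor <- sort(ord$name)[1L]
    warning("anchor gene missing; falling back to ", anchor)
  }
  i <- which(ord$name == anchor)[1L]
  n <- nrow(ord)
  idx <- ((i - 1L + seq_len(n) - 1L) %% n) + 1L
  ord <- ord[idx, , drop = FALSE]
  if (ord$strand[1L] == "N") {      # reflect so the anchor reads on J
    ord <- ord[c(1L, rev(seq_len(n)[-1L])), , drop = FALSE]
    ord$strand <- ifelse(ord$strand == "J", "N", "J")
  }
  rownames(ord) <- NULL
  structure(list(taxon = taxon, order = ord), class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  tok <- paste0(ifelse(x$order$strand == "N", "-", ""), x$order$name)
  cat("<gene_order> ", x$taxon, " (", nrow(x$order), " genes)\n  ",
      paste(tok, collapse = " "), "\n", sep = "")
  invisible(x)
}

# circular signed adjacency set; each adjacency is canonicalized so that
# traversing the circle in either direction yields the same token:
# (x,sx) -> (y,sy)  ==  (y, flip sy) -> (x, flip sx)
adjacency_set <- function(ord, include_cr = FALSE) {
  o <- ord$order
  if (!include_cr) o <- o[o$name != "CR", , drop = FALSE]
  n <- nrow(o)
  if (n < 2L) return(character(0L))
  nxt <- c(seq_len(n)[-1L], 1L)
  flip <- function(s) ifelse(s == "J", "N", "J")
  fwd <- paste0(o$name, ":", o$strand, ">", o$name[nxt], ":", o$strand[nxt])
  rev_ <- paste0(o$name[nxt], ":", flip(o$strand[nxt]), ">",
                 o$name, ":", flip(o$strand))
  pmin(fwd, rev_)
}

#' Compare two signed gene orders
#'
#' Orders are compared on their circular signed adjacency sets (no
#' inversion-distance computation): the breakpoint count is the number of
#' adjacencies of `a` absent from `b`.  Control-region tokens are
#' excluded by default because CR position varies.  Genes present in only
#' one order are dropped pairwise with a warning.
#'
#' @param a,b `gene_order` objects.
#' @param include_cr include CR tokens in the adjacency comparison.
#' @return list: `identical` (logical), `breakpoints` (count),
#'   `differing_blocks` (list of character vectors: maximal runs of `a`
#'   spanned by unshared adjacencies).
#' @export
compare_orders <- function(a, b, include_cr = FALSE) {
  ga <- setdiff(a$order$name, "CR"); gb <- setdiff(b$order$name, "CR")
  common <- intersect(ga, gb)
  if (length(common) == 0L) stop("disjoint gene sets")
  if (!setequal(ga, gb)) {
    warning("gene sets differ; comparing the ", length(common),
            " shared genes")
    a <- make_gene_order(a$order[a$order$name %in% c(common, "CR"), ],
                         a$taxon, anchor = common[1L])
    b <- make_gene_order(b$order[b$order$name %in% c(common, "CR"), ],
                         b$taxon, anchor = common[1L])
  }
  sa <- adjacency_set(a, include_cr)
  sb <- adjacency_set(b, include_cr)
  broken <- !(sa %in% sb)
  # map broken adjacencies of `a` back onto runs of its gene list
  o <- a$order
  if (!include_cr) o <- o[o$name != "CR", , drop = FALSE]
  n <- nrow(o)
  in_block <- logical(n)
  nxt <- c(seq_len(n)[-1L], 1L)
  for (k in which(broken)) { in_block[k] <- TRUE; in_block[nxt[k]] <- TRUE }
  blocks <- list()
  if (any(in_block)) {
    r <- rle(in_block)
    pos <- cumsum(c(1L, r$lengths))
    for (j in seq_along(r$values)) {
      if (!r$values[j]) next
      blocks[[length(blocks) + 1L]] <-
        o$name[pos[j]:(pos[j] + r$lengths[j] - 1L)]
    }
    # merge first/last blocks across the circular seam
    if (length(blocks) > 1L && in_block[1L] && in_block[n]) {
      blocks[[1L]] <- c(blocks[[length(blocks)]], blocks[[1L]])
      blocks[[length(blocks)]] <- NULL
    }
  }
  list(identical = !any(broken) && length(sa) == length(sb),
       breakpoints = sum(broken),
       differing_blocks = blocks)
}

#' Classify a genome's gene order against shipped references
#'
#' @param genome a [mito_genome()] (or a `gene_order`).
#' @param references named list of `gene_order` objects; defaults to the
#'   three shipped templates.
#' @return list: `best` (reference name with fewest breakpoints; ties
#'   broken alphabetically), `tie` (logical), `breakpoints` (named
#'   vector), `diff` (the [compare_orders()] result for the best match).
#' @export
classify_against_references <- function(genome, references = NULL) {
  ord <- if (inherits(genome, "gene_order")) genome else order_string(genome)
  if (is.null(references)) {
    references <- lapply(
      c(ancestral_insect = "ancestral_insect",
        lepidoptera_typical = "lepidoptera_typical",
        chironomid_variant = "chironomid_variant"),
      function(t) {
        tpl <- gene_order_template(t)
        make_gene_order(tpl[, c("name", "strand")], t)
      })
  }
  bp <- vapply(references, function(r)
    compare_orders(ord, r)$breakpoints, integer(1L))
  best <- names(bp)[order(bp, names(bp))][1L]   # ties broken alphabetically
  list(best = best, tie = sum(bp == min(bp)) > 1L, breakpoints = bp,
       diff = compare_orders(ord, references[[best]]))
}
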