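# Synthetic annotated mitogenomes with machine-checkable ground truth.
# Every planted property (gene order, junction motifs, start/stop codons,
# composition targets) is recorded in a truth object that
# validate_truth() re-checks against the emitted genome.

# run expr under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

default_pcg_lengths <- c(
  nad2 = 1020L, cox1 = 1536L, cox2 = 684L, atp8 = 162L, atp6 = 678L,
  cox3 = 786L, nad3 = 354L, nad5 = 1734L, nad4 = 1341L, nad4l = 291L,
  nad6 = 531L, cytb = 1137L, nad1 = 936L)

default_startstop_plan <- function() {
  list(nad2 = c("ATT", "TAA"), cox1 = c("CGA", "TAA"), cox2 = c("ATG", "T"),
       atp8 = c("ATT", "TAA"), atp6 = c("ATG", "TAA"), cox3 = c("ATG", "TAA"),
       nad3 = c("ATT", "TAA"), nad5 = c("ATT", "TAA"), nad4 = c("ATG", "TA"),
       nad4l = c("ATG", "TAA"), nad6 = c("ATA", "TAA"),
       cytb = c("ATG", "TAA"), nad1 = c("ATG", "TAG"))
}

#' Default junction plan emulating the conserved moth junction structure
#'
#' Three conserved gene overlaps (cox1/trnL2 "TCTAA", atp8/atp6
#' "ATGATAA", trnW/trnC "AAGCCTTA"), the conserved trnS2/nad1 intergenic
#' motif "ATACTAA", a long variable trnQ/nad2 spacer (48-87 bp), and
#' short random spacers elsewhere.
#'
#' @return named list keyed `"upstream|downstream"`; each entry has
#'   `relation`, and `length`/`motif` or `length_range`, plus `conserved`.
#' @export
default_junction_plan <- function() {
  list(
    `cox1|trnL2` = list(relation = "overlap", motif = "TCTAA",
                        conserved = TRUE),
    `atp8|atp6` = list(relation = "overlap", motif = "ATGATAA",
                       conserved = TRUE),
    `trnW|trnC` = list(relation = "overlap", motif = "AAGCCTTA",
                       conserved = TRUE),
    `trnS2|nad1` = list(relation = "spacer", motif = "ATACTAA",
                        conserved = TRUE),
    `trnQ|nad2` = list(relation = "spacer", length_range = c(48L, 87L),
                       conserved = FALSE),
    `CR|trnM` = list(relation = "abutting", conserved = TRUE))
}

#' Specification of a synthetic mitogenome
#'
#' @param taxon taxon name.
#' @param template gene-order template (see [gene_order_template()]).
#' @param at_content target A+T percentage of the J-strand (50-95).
#' @param at_skew,gc_skew target strand skews, in (-1, 1).
#' @param junction_plan named junction plan; defaults to
#'   [default_junction_plan()]; unlisted adjacencies get a random spacer
#'   with length drawn from `default_spacer_range`.
#' @param startstop_plan named list PCG -> c(start codon, stop: "TAA",
#'   "TAG", "TA" or "T").
#' @param pcg_lengths named PCG lengths in bp (complete-stop basis;
#'   incomplete stops shorten the CDS accordingly).
#' @param cr_length control-region length in bp.
#' @param extra_crs list of `list(after = gene, length = bp)` entries for
#'   supernumerary control regions.
#' @param annotate_cr keep control regions in the feature table (set
#'   `FALSE` to leave them unannotated for CR-inference tests).
#' @param default_spacer_range length range for unplanned junctions.
#' @param seed integer RNG seed.
#' @return `genome_spec` list.
#' @export
genome_spec <- function(taxon = "Synthetica exempli",
                        template = "lepidoptera_typical",
                        at_content = 80, at_skew = 0.0, gc_skew = -0.2,
                        junction_plan = default_junction_plan(),
                        startstop_plan = default_startstop_plan(),
                        pcg_lengths = default_pcg_lengths,
                        cr_length = 350L,
                        extra_crs = list(),
                        annotate_cr = TRUE,
                        default_spacer_range = c(0L, 10L),
                        seed = 1L) {
  stopifnot(at_content >= 50, at_content <= 95,
            abs(at_skew) < 1, abs(gc_skew) < 1,
            all(names(default_pcg_lengths) %in% names(pcg_lengths)),
            all(names(startstop_plan) %in% names(default_pcg_lengths)))
  structure(list(taxon = taxon, template = template,
                 at_content = at_content, at_skew = at_skew,
                 gc_skew = gc_skew, junction_plan = junction_plan,
                 startstop_plan = startstop_plan,
                 pcg_lengths = pcg_lengths, cr_length = cr_length,
                 extra_crs = extra_crs, annotate_cr = annotate_cr,
                 default_spacer_range = as.integer(default_spacer_range),
                 seed = as.integer(seed)),
            class = "genome_spec")
}

# Codon-by-codon sampling rejects stop codons, which tilts the realized
# composition away from the target (stops are A+T-rich).  This computes
# tilted base probabilities whose stop-conditioned codon composition
# matches the target probabilities (fixed-point iteration).
adjust_probs_for_stops <- function(probs, table_id = 5L) {
  stops <- stop_codons(table_id)
  bases <- names(probs)
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  keep <- !(codons %in% stops)
  counts <- vapply(bases, function(b) vapply(codons, function(cc)
    sum(seq_chars(cc) == b), numeric(1L)), numeric(length(codons)))
  realized <- function(p) {
    w <- apply(counts, 1L, function(k) prod(p^k))
    w[!keep] <- 0
    w <- w / sum(w)
    colSums(w * counts) / 3
  }
  p <- probs
  for (it in 1:25) {
    f <- realized(p)
    p <- p * probs / f
    p <- p / sum(p)
    if (max(abs(f - probs)) < 1e-9) break
  }
  p
}

# generate one feature sequence in reading direction under constraints.
# jprefix/jsuffix are J-strand constraints at the feature's genomic ends.
gen_feature_seq <- function(length, strand, kind, probs,
                            jprefix = "", jsuffix = "",
                            start_codon = NULL, stop_str = NULL,
                            table_id = 5L, name = "?") {
  rprobs <- if (strand == "N")
    c(A = probs[["T"]], C = probs[["G"]], G = probs[["C"]], T = probs[["A"]])
  else probs
  mask <- rep(NA_character_, length)
  put <- function(mask, at, str) {
    ch <- seq_chars(str)
    idx <- at + seq_along(ch) - 1L
    clash <- !is.na(mask[idx]) & mask[idx] != ch
    if (any(clash))
      stop("infeasible constraints on ", name, ": conflicting bases")
    mask[idx] <- ch
    mask
  }
  if (strand == "J") {
    if (nzchar(jprefix)) mask <- put(mask, 1L, jprefix)
    if (nzchar(jsuffix)) mask <- put(mask, length - nchar(jsuffix) + 1L,
                                     jsuffix)
  } else {
    if (nzchar(jsuffix)) mask <- put(mask, 1L, revcomp(jsuffix))
    if (nzchar(jprefix)) mask <- put(mask, length - nchar(jprefix) + 1L,
                                     revcomp(jprefix))
  }
  if (kind == "PCG") {
    stopifnot(!is.null(start_codon), !is.null(stop_str))
    mask <- put(mask, 1L, start_codon)
    mask <- put(mask, length - nchar(stop_str) + 1L, stop_str)
    stops <- stop_codons(table_id)
    cprobs <- adjust_probs_for_stops(rprobs, table_id)
    n_codons <- (length - nchar(stop_str)) %/% 3L
    if ((length - nchar(stop_str)) %% 3L != 0L)
      stop("infeasible: CDS body of ", name, " not a codon multiple")
    out <- character(length)
    for (k in seq_len(n_codons)) {
      idx <- (k - 1L) * 3L + 1:3
      fixed <- mask[idx]
      for (try in 1:200) {
        cand <- ifelse(is.na(fixed),
                       sample(names(cprobs), 3L, replace = TRUE,
                              prob = cprobs), fixed)
        codon <- paste(cand, collapse = "")
        if (k == 1L || !(codon %in% stops)) break
        if (try == 200L)
          stop("infeasible: constrained stop codon inside ", name)
      }
      out[idx] <- cand
    }
    tail_idx <- n_codons * 3L + seq_len(nchar(stop_str))
    out[tail_idx] <- mask[tail_idx]
    paste(out, collapse = "")
  } else {
    free <- is.na(mask)
    mask[free] <- sample(names(rprobs), sum(free), replace = TRUE,
                         prob = rprobs)
    paste(mask, collapse = "")
  }
}

# resolve the feature order (template + CR insertions) of a spec
spec_feature_order <- function(spec) {
  ord <- gene_order_template(spec$template)
  for (cr in spec$extra_crs) {
    at <- which(ord$name == cr$after)
    if (length(at) != 1L) stop("extra CR anchor not found: ", cr$after)
    ins <- data.frame(name = paste0("CR", 1L + sum(grepl("^CR", ord$name))),
                      kind = "control_region", strand = "J",
                      stringsAsFactors = FALSE)
    ord <- rbind(ord[seq_len(at), ], ins,
                 ord[seq(at + 1L, nrow(ord)), ])
  }
  rownames(ord) <- NULL
  ord
}

#' Generate a synthetic annotated mitogenome
#'
#' Deterministic given the spec's seed.  The genome satisfies its plan
#' exactly: gene order per template, junction motifs placed verbatim,
#' start/stop codons as planned, PCG interiors free of in-frame stops
#' under the invertebrate mitochondrial code, and J-strand composition
#' within about one percentage point of the targets (declared in the
#' truth record).  tRNA and rRNA genes are random sequences of realistic
#' length (tRNA 60-75 bp, rRNA ~780/~1350 bp); no secondary structure is
#' modelled.
#'
#' @param spec a [genome_spec()].
#' @return list with `genome` (a [mito_genome()]) and `truth` (planted
#'   properties; see [validate_truth()]).
#' @export
make_genome <- function(spec) {
  with_local_seed(spec$seed, make_genome_impl(spec))
}

make_genome_impl <- function(spec) {
  ord <- spec_feature_order(spec)
  n <- nrow(ord)
  probs <- base_probs(spec$at_content, spec$at_skew, spec$gc_skew)
  # feature lengths
  lens <- integer(n)
  for (i in seq_len(n)) {
    lens[i] <- switch(ord$kind[i],
      PCG = {
        g <- ord$name[i]
        stop_str <- spec$startstop_plan[[g]][2L]
        spec$pcg_lengths[[g]] - 3L + nchar(stop_str)
      },
      tRNA = sample(60:75, 1L),
      rRNA = if (ord$name[i] == "rrnL") sample(1300:1400, 1L)
             else sample(750:800, 1L),
      control_region = spec$cr_length)
    if (ord$kind[i] == "control_region" && ord$name[i] != "CR") {
      # supernumerary CR: look its length up by insertion order
      k <- as.integer(sub("^CR", "", ord$name[i])) - 1L
      lens[i] <- spec$extra_crs[[k]]$length
    }
  }
  # resolve the junction plan around the circle
  jplan <- vector("list", n)
  for (i in seq_len(n)) {
    j <- if (i < n) i + 1L else 1L
    key <- paste0(ord$name[i], "|", ord$name[j])
    p <- spec$junction_plan[[key]]
    if (is.null(p)) {
      rng <- spec$default_spacer_range
      len <- sample(rng[1L]:rng[2L], 1L)
      p <- if (len == 0L) list(relation = "abutting")
           else list(relation = "spacer", length = len)
    }
    if (p$relation %in% c("overlap", "spacer")) {
      if (!is.null(p$motif)) p[["length"]] <- nchar(p$motif)
      if (is.null(p[["length"]]))
        p[["length"]] <- sample(p[["length_range"]][1L]:p[["length_range"]][2L], 1L)
      if (is.null(p$motif) && p$relation == "spacer")
        p$sequence <- random_seq(p[["length"]], probs)
      if (!is.null(p$motif)) p$sequence <- p$motif
    } else p[["length"]] <- 0L
    if (p$relation == "overlap") {
      if (i == n)
        stop("infeasible junction plan: overlap across the origin")
      if (p[["length"]] >= min(lens[i], lens[j]))
        stop("infeasible junction plan: overlap of ", p[["length"]],
             " bp exceeds gene length at ", key)
      if (is.null(p$motif)) stop("overlaps require an explicit motif")
    }
    jplan[[i]] <- c(p, list(upstream = ord$name[i],
                            downstream = ord$name[j]))
  }
  # per-feature J-strand end constraints from overlaps
  jpref <- rep("", n); jsuf <- rep("", n)
  for (i in seq_len(n)) {
    p <- jplan[[i]]
    if (p$relation == "overlap") {
      jsuf[i] <- p$motif
      jpref[i %% n + 1L] <- p$motif
    }
  }
  # generate feature sequences (reading direction) and their J-strand form
  jrep <- character(n)
  for (i in seq_len(n)) {
    g <- ord$name[i]
    sseq <- gen_feature_seq(
      lens[i], ord$strand[i], ord$kind[i], probs,
      jprefix = jpref[i], jsuffix = jsuf[i],
      start_codon = if (ord$kind[i] == "PCG") spec$startstop_plan[[g]][1L],
      stop_str = if (ord$kind[i] == "PCG") spec$startstop_plan[[g]][2L],
      name = g)
    jrep[i] <- if (ord$strand[i] == "N") revcomp(sseq) else sseq
  }
  # assemble around the circle
  pieces <- character(0L)
  starts <- integer(n); ends <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    if (i == 1L) {
      starts[i] <- 1L
      pieces <- jrep[i]; pos <- lens[i]
    } else {
      p <- jplan[[i - 1L]]
      if (p$relation == "spacer") {
        pieces <- c(pieces, p$sequence); pos <- pos + p[["length"]]
        starts[i] <- pos + 1L
        pieces <- c(pieces, jrep[i]); pos <- pos + lens[i]
      } else if (p$relation == "abutting") {
        starts[i] <- pos + 1L
        pieces <- c(pieces, jrep[i]); pos <- pos + lens[i]
      } else {                       # overlap: shared bases emitted once
        k <- p[["length"]]
        starts[i] <- pos - k + 1L
        pieces <- c(pieces, substr(jrep[i], k + 1L, lens[i]))
        pos <- pos + lens[i] - k
      }
    }
    ends[i] <- starts[i] + lens[i] - 1L
  }
  pwrap <- jplan[[n]]
  if (pwrap$relation == "spacer") {
    pieces <- c(pieces, pwrap$sequence); pos <- pos + pwrap[["length"]]
  }
  sequence <- paste(pieces, collapse = "")
  features <- data.frame(name = ord$name, kind = ord$kind,
                         start = starts, end = ends, strand = ord$strand,
                         note = "", stringsAsFactors = FALSE)
  truth_junctions <- do.call(rbind, lapply(jplan, function(p)
    data.frame(upstream = p$upstream, downstream = p$downstream,
               relation = p$relation, length = p[["length"]],
               sequence = if (p$relation == "abutting") "" else p$sequence,
               conserved = isTRUE(p$conserved), stringsAsFactors = FALSE)))
  truth <- list(taxon = spec$taxon, seed = spec$seed,
                template = spec$template, order = ord,
                junctions = truth_junctions,
                start_stop = spec$startstop_plan,
                at_content = spec$at_content, at_skew = spec$at_skew,
                gc_skew = spec$gc_skew, composition_tol = 1.0,
                annotate_cr = spec$annotate_cr,
                feature_lengths = stats::setNames(lens, ord$name))
  if (!spec$annotate_cr)
    features <- features[features$kind != "control_region", , drop = FALSE]
  genome <- mito_genome(taxon = spec$taxon, sequence = sequence,
                        features = features)
  list(genome = genome, truth = truth)
}

#' Re-check a synthetic genome against its truth record
#'
#' Verifies that the emitted genome carries every planted property:
#' feature order, planned junction relations/lengths/sequences, start and
#' stop codons, stop-free PCG interiors, and the composition targets
#' within the declared tolerance.
#'
#' @param genome a [mito_genome()] from [make_genome()].
#' @param truth its truth record.
#' @return `TRUE` invisibly; stops with a message on any violation.
#' @export
validate_truth <- function(genome, truth) {
  if (truth$annotate_cr) {
    stopifnot(identical(genome$features$name, truth$order$name))
    j <- scan_junctions(genome)
    for (k in seq_len(nrow(truth$junctions))) {
      tr <- truth$junctions[k, ]
      hit <- j[j$upstream == tr$upstream & j$downstream == tr$downstream, ]
      if (nrow(hit) != 1L || hit$relation != tr$relation ||
          hit$length != tr$length ||
          (tr$relation != "abutting" && hit$sequence != tr$sequence))
        stop("junction mismatch at ", tr$upstream, "|", tr$downstream)
    }
  }
  for (g in names(truth$start_stop)) {
    call <- classify_start_stop(extract_gene_sequence(genome, g), g)
    if (call$start_codon != truth$start_stop[[g]][1L] ||
        call$stop_codon != truth$start_stop[[g]][2L])
      stop("start/stop mismatch at ", g)
  }
  comp <- base_composition(genome$sequence)
  if (abs(comp$at_content - truth$at_content) > truth$composition_tol)
    stop("A+T content off target: ", round(comp$at_content, 2))
  invisible(TRUE)
}

#' Generate a clade of synthetic mitogenomes
#'
#' Taxa share the base spec's planned (conserved) junction motifs and
#' start/stop codons; free sequence, unplanned spacers, tRNA/rRNA lengths
#' and ranged spacer lengths vary per taxon.  With `divergence` supplied,
#' protein-coding genes are derived from the base genome by sampling
#' synonymous and nonsynonymous events (Poisson, stop-rejecting) so that
#' per-gene Ka/Ks has known truth; other features are mutated at the
#' synonymous rate.  `motif_variants` plants controlled deviations, e.g.
#' one taxon's trnS2/nad1 motif mutated.
#'
#' @param n number of taxa (>= 2).
#' @param base_spec a [genome_spec()].
#' @param taxa optional taxon names.
#' @param divergence `NULL` (independent genomes) or
#'   `list(ks_branch =, omega = named per-PCG vector)`; `ks_branch` may be
#'   a vector of per-taxon branch lengths (recycled to `n`).
#' @param motif_variants list of `list(taxon = index, junction = "up|down",
#'   motif = "...")` overrides.
#' @return list with `genomes` (list of [mito_genome()]) and `truths`.
#' @export
make_clade <- function(n, base_spec, taxa = NULL, divergence = NULL,
                       motif_variants = list()) {
  stopifnot(n >= 2L)
  if (is.null(taxa))
    taxa <- sprintf("%s %02d", base_spec$taxon, seq_len(n))
  with_local_seed(base_spec$seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n + 1L)
    if (is.null(divergence)) {
      out <- lapply(seq_len(n), function(i) {
        sp <- base_spec
        sp$taxon <- taxa[i]
        sp$seed <- seeds[i]
        sp$junction_plan <- apply_motif_variants(sp$junction_plan,
                                                 motif_variants, i)
        make_genome(sp)
      })
    } else {
      base_sp <- base_spec
      base_sp$seed <- seeds[n + 1L]
      base <- make_genome(base_sp)
      ksv <- rep_len(divergence$ks_branch, n)   # per-taxon branch lengths
      out <- lapply(seq_len(n), function(i) {
        set.seed(seeds[i])
        div_i <- divergence
        div_i$ks_branch <- ksv[i]
        derive_taxon(base, base_sp, taxa[i], div_i,
                     apply_motif_variants(base_sp$junction_plan,
                                          motif_variants, i))
      })
    }
    list(genomes = lapply(out, `[[`, "genome"),
         truths = lapply(out, `[[`, "truth"))
  })
}

apply_motif_variants <- function(plan, variants, taxon_index) {
  for (v in variants) {
    if (v$taxon != taxon_index) next
    key <- v$junction
    if (is.null(plan[[key]])) stop("no planned junction ", key)
    plan[[key]]$motif <- v$motif
    plan[[key]]$conserved <- FALSE
  }
  plan
}

# derive one taxon from a base synthetic genome under per-gene Ka/Ks
derive_taxon <- function(base, base_spec, taxon, divergence, plan) {
  ord <- base$truth$order
  n <- nrow(ord)
  probs <- base_probs(base_spec$at_content, base_spec$at_skew,
                      base_spec$gc_skew)
  ks <- divergence$ks_branch
  omega <- divergence$omega
  jrep <- character(n)
  for (i in seq_len(n)) {
    g <- ord$name[i]
    rseq <- extract_gene_sequence_by_index(base$genome, base$truth, i)
    rprobs <- if (ord$strand[i] == "N")
      c(A = probs[["T"]], C = probs[["G"]], G = probs[["C"]],
        T = probs[["A"]])
    else probs
    if (ord$kind[i] == "PCG" && ks > 0) {
      om <- if (g %in% names(omega)) omega[[g]] else 0.2
      body <- substr(rseq, 1L, nchar(rseq) - nchar(rseq) %% 3L)
      protect <- protected_positions(nchar(body), i, n, ord, base$truth)
      sites <- codon_site_totals(body)
      nsyn <- stats::rpois(1L, ks * sites[["syn"]])
      nnon <- stats::rpois(1L, ks * om * sites[["nonsyn"]])
      body <- mutate_cds(body, nsyn, nnon, protect, probs = rprobs)
      rseq <- paste0(body, substr(rseq, nchar(body) + 1L, nchar(rseq)))
    } else if (ord$kind[i] != "PCG" && ks > 0) {
      protect <- protected_positions(nchar(rseq), i, n, ord, base$truth)
      rseq <- mutate_neutral(rseq, ks, protect, rprobs)
    }
    jrep[i] <- if (ord$strand[i] == "N") revcomp(rseq) else rseq
  }
  reassemble_clade_taxon(base, base_spec, taxon, jrep, plan, probs)
}

# reading-direction sequence of the i-th planned feature of a synthetic
# genome (requires the control region to be annotated)
extract_gene_sequence_by_index <- function(genome, truth, i) {
  f <- genome$features
  row <- which(f$name == truth$order$name[i])
  stopifnot(length(row) == 1L)
  extract_gene_sequence(genome, row[1L])
}

# positions of a feature's reading-direction sequence that carry planted
# constraints (junction motifs, PCG start/stop) and must not mutate
protected_positions <- function(len, i, n, ord, truth) {
  prot <- logical(len)
  jn <- truth$junctions
  up <- jn[jn$downstream == ord$name[i] & jn$relation == "overlap", ]
  dn <- jn[jn$upstream == ord$name[i] & jn$relation == "overlap", ]
  kpre <- if (nrow(up)) up[["length"]][1L] else 0L   # J-strand prefix
  ksuf <- if (nrow(dn)) dn$length[1L] else 0L   # J-strand suffix
  if (ord$strand[i] == "N") { tmp <- kpre; kpre <- ksuf; ksuf <- tmp }
  if (kpre > 0L) prot[seq_len(kpre)] <- TRUE
  if (ksuf > 0L) prot[len - seq_len(ksuf) + 1L] <- TRUE
  if (ord$kind[i] == "PCG") {
    prot[1:3] <- TRUE
    stop_len <- nchar(truth$start_stop[[ord$name[i]]][2L])
    prot[len - seq_len(stop_len) + 1L] <- TRUE
  }
  prot
}

codon_site_totals <- function(cds, table_id = 5L) {
  cc <- chunk_codons(cds)$codons
  stops <- stop_codons(table_id)
  cc <- cc[!cc %in% stops]
  s <- vapply(cc, function(c) ng86_sites(c, table_id)[["syn"]], numeric(1L))
  c(syn = sum(s), nonsyn = 3 * length(cc) - sum(s))
}

# apply n_syn synonymous and n_nonsyn nonsynonymous single-nucleotide
# events, rejecting stop-creating changes and protected positions
mutate_cds <- function(cds, n_syn, n_nonsyn, protect = NULL,
                       table_id = 5L, probs = NULL) {
  code <- genetic_code(table_id)
  ch <- seq_chars(cds)
  nc <- length(ch) %/% 3L
  if (is.null(protect)) protect <- logical(length(ch))
  types <- sample(c(rep("s", n_syn), rep("n", n_nonsyn)))
  bases <- c("A", "C", "G", "T")
  for (ty in types) {
    for (try in 1:5000) {
      i <- sample.int(nc, 1L)
      p <- sample.int(3L, 1L)
      pos <- (i - 1L) * 3L + p
      if (protect[pos]) next
      cur <- paste(ch[(i - 1L) * 3L + 1:3], collapse = "")
      if (code[[cur]] == "*") next
      alt <- setdiff(bases, ch[pos])
      b <- if (is.null(probs)) sample(alt, 1L)
           else sample(alt, 1L, prob = probs[alt])
      new <- cur
      substr(new, p, p) <- b
      if (code[[new]] == "*") next
      is_syn <- code[[new]] == code[[cur]]
      if ((ty == "s") != is_syn) next
      ch[pos] <- b
      break
    }
  }
  paste(ch, collapse = "")
}

# per-site neutral mutation of a non-coding feature at rate mu
mutate_neutral <- function(seq, mu, protect, probs) {
  ch <- seq_chars(seq)
  hit <- stats::runif(length(ch)) < mu & !protect
  if (any(hit))
    ch[hit] <- sample(names(probs), sum(hit), replace = TRUE, prob = probs)
  paste(ch, collapse = "")
}

# rebuild a derived taxon's circle with fresh junction draws
reassemble_clade_taxon <- function(base, base_spec, taxon, jrep, plan,
                                   probs) {
  sp <- base_spec
  sp$taxon <- taxon
  sp$junction_plan <- plan
  ord <- base$truth$order
  n <- nrow(ord)
  lens <- nchar(jrep)
  jplan <- vector("list", n)
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    key <- paste0(ord$name[i], "|", ord$name[j])
    p <- plan[[key]]
    base_j <- base$truth$junctions[i, ]
    if (is.null(p)) {
      # unplanned junction: redraw a short spacer
      rng <- sp$default_spacer_range
      len <- sample(rng[1L]:rng[2L], 1L)
      p <- if (len == 0L) list(relation = "abutting", length = 0L)
           else list(relation = "spacer", length = len,
                     sequence = random_seq(len, probs))
    } else {
      if (!is.null(p$motif)) { p[["length"]] <- nchar(p$motif); p$sequence <- p$motif }
      if (is.null(p[["length"]]) && !is.null(p[["length_range"]]))
        p[["length"]] <- sample(p[["length_range"]][1L]:p[["length_range"]][2L], 1L)
      if (p$relation == "spacer" && is.null(p$sequence))
        p$sequence <- random_seq(p[["length"]], probs)
      if (p$relation == "abutting") p[["length"]] <- 0L
    }
    p$conserved <- isTRUE(p$conserved)
    jplan[[i]] <- c(p, list(upstream = ord$name[i],
                            downstream = ord$name[j]))
  }
  # overlap motifs may differ from the base (motif variants): force ends
  for (i in seq_len(n)) {
    p <- jplan[[i]]
    if (p$relation != "overlap") next
    j <- i %% n + 1L
    m <- p$motif; k <- nchar(m)
    jrep[i] <- paste0(substr(jrep[i], 1L, lens[i] - k), m)
    jrep[j] <- paste0(m, substr(jrep[j], k + 1L, lens[j]))
  }
  pieces <- character(0L); starts <- integer(n); ends <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    if (i == 1L) { starts[i] <- 1L; pieces <- jrep[i]; pos <- lens[i] }
    else {
      p <- jplan[[i - 1L]]
      if (p$relation == "spacer") {
        pieces <- c(pieces, p$sequence); pos <- pos + p[["length"]]
        starts[i] <- pos + 1L; pieces <- c(pieces, jrep[i])
        pos <- pos + lens[i]
      } else if (p$relation == "abutting") {
        starts[i] <- pos + 1L; pieces <- c(pieces, jrep[i])
        pos <- pos + lens[i]
      } else {
        k <- p[["length"]]
        starts[i] <- pos - k + 1L
        pieces <- c(pieces, substr(jrep[i], k + 1L, lens[i]))
        pos <- pos + lens[i] - k
      }
    }
    ends[i] <- starts[i] + lens[i] - 1L
  }
  if (jplan[[n]]$relation == "spacer")
    pieces <- c(pieces, jplan[[n]]$sequence)
  sequence <- paste(pieces, collapse = "")
  features <- data.frame(name = ord$name, kind = ord$kind, start = starts,
                         end = ends, strand = ord$strand, note = "",
                         stringsAsFactors = FALSE)
  truth <- base$truth
  truth$taxon <- taxon
  truth$junctions <- do.call(rbind, lapply(jplan, function(p)
    data.frame(upstream = p$upstream, downstream = p$downstream,
               relation = p$relation, length = p[["length"]],
               sequence = if (p$relation == "abutting") "" else p$sequence,
               conserved = isTRUE(p$conserved), stringsAsFactors = FALSE)))
  truth$feature_lengths <- stats::setNames(lens, ord$name)
  # mutational pressure pulls diverged taxa slightly off the base
  # composition target; the declared tolerance is wider accordingly
  truth$composition_tol <- 2.0
  if (!sp$annotate_cr)
    features <- features[features$kind != "control_region", , drop = FALSE]
  list(genome = mito_genome(taxon = taxon, sequence = sequence,
                            features = features),
       truth = truth)
}

#' Simulate diverged codon sequence pairs with known Ka/Ks truth
#'
#' An ancestral in-frame sequence is sampled over the sense codons of the
#' invertebrate mitochondrial code; a descendant is derived by applying
#' Poisson numbers of synonymous and nonsynonymous single-nucleotide
#' events (expected counts `ks * synonymous sites` and
#' `ka * nonsynonymous sites`), rejecting stop-creating changes.
#'
#' @param n_codons sequence length in codons.
#' @param ks,ka true synonymous / nonsynonymous rates (events per site).
#' @param replicates number of pairs.
#' @param seed RNG seed.
#' @param at_content A+T percentage used when sampling the ancestor.
#' @param table_id NCBI translation table.
#' @return list of replicates, each with `ancestor`, `derived`,
#'   `events_syn`, `events_nonsyn`, `true_ks`, `true_ka`, `true_omega`.
#' @export
evolve_codons <- function(n_codons, ks, ka, replicates = 1L, seed = 1L,
                          at_content = 70, table_id = 5L) {
  sense <- sense_codons(table_id)
  probs <- base_probs(at_content, 0, 0)
  codon_w <- vapply(sense, function(cc)
    prod(probs[seq_chars(cc)]), numeric(1L))
  with_local_seed(seed, lapply(seq_len(replicates), function(r) {
    anc <- paste(sample(sense, n_codons, replace = TRUE, prob = codon_w),
                 collapse = "")
    sites <- codon_site_totals(anc, table_id)
    nsyn <- stats::rpois(1L, ks * sites[["syn"]])
    nnon <- stats::rpois(1L, ka * sites[["nonsyn"]])
    der <- mutate_cds(anc, nsyn, nnon, table_id = table_id)
    list(ancestor = anc, derived = der, events_syn = nsyn,
         events_nonsyn = nnon, true_ks = ks, true_ka = ka,
         true_omega = if (ks > 0) ka / ks else NA_real_)
  }))
}

#' Simulate aligned pairs under the TN93 substitution model
#'
#' Continuous-time TN93 simulation (via phangorn's sequence simulator on a
#' two-taxon tree) with separate purine/pyrimidine transition rates and
#' unequal base frequencies; branch lengths are scaled so the true
#' expected distance between the pair equals `d`.
#'
#' @param n_sites alignment length.
#' @param d true expected substitutions per site between the two taxa.
#' @param kappa1,kappa2 purine (A-G) and pyrimidine (C-T) transition rate
#'   multipliers relative to transversions.
#' @param base_freqs frequencies in A, C, G, T order.
#' @param replicates number of pairs.
#' @param seed RNG seed.
#' @return list of replicates, each a named character vector of two
#'   aligned sequences with attribute `true_d`.
#' @export
evolve_tn93 <- function(n_sites, d, kappa1 = 4, kappa2 = 8,
                        base_freqs = c(0.35, 0.12, 0.13, 0.40),
                        replicates = 1L, seed = 1L) {
  tree <- ape::read.tree(text = sprintf("(A:%f,B:%f);", d / 2, d / 2))
  Q <- c(1, kappa1, 1, 1, kappa2, 1)   # ac, ag, at, cg, ct, gt
  with_local_seed(seed, lapply(seq_len(replicates), function(r) {
    sim <- phangorn::simSeq(tree, l = n_sites, Q = Q, bf = base_freqs,
                            type = "DNA")
    m <- toupper(as.character(sim))
    out <- stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m))
    attr(out, "true_d") <- d
    out
  }))
}
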