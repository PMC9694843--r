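# Shared fixtures and independent oracles for the test suite.

# internal helpers used by fixtures
seq_chars <- mitocomp:::seq_chars
make_gene_order <- mitocomp:::make_gene_order
`%||%` <- function(a, b) if (is.null(a)) b else a

# small hand-built genome: explicit sequence + features
toy_genome <- function(sequence, features, taxon = "Toyus exemplaris") {
  mito_genome(taxon = taxon, sequence = sequence, features = features)
}

expect_genome_equal <- function(a, b) {
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$taxon, b$taxon)
  expect_equal(a$features[, c("name", "kind", "start", "end", "strand")],
               b$features[, c("name", "kind", "start", "end", "strand")])
}

# rotate a circular genome's origin to old position `shift + 1`
rotate_genome <- function(genome, shift) {
  L <- nchar(genome$sequence)
  shift <- shift %% L
  seq2 <- paste0(substr(genome$sequence, shift + 1L, L),
                 substr(genome$sequence, 1L, shift))
  f <- genome$features
  mv <- function(p) ((p - shift - 1L) %% L) + 1L
  f$start <- mv(f$start); f$end <- mv(f$end)
  mito_genome(genome$taxon, seq2, f)
}

# --- independent NG86 pathway oracle (recursive DFS, written separately
#     from the package's permutation-based implementation) ---------------
oracle_ng86_diffs <- function(c1, c2, code = genetic_code(5)) {
  walk <- function(cur) {
    d <- which(seq_chars(cur) != seq_chars(c2))
    if (length(d) == 0L) return(list(c(s = 0, n = 0)))
    res <- list()
    for (pos in d) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (code[[nxt]] == "*") next
      step_syn <- code[[nxt]] == code[[cur]]
      for (tl in walk(nxt))
        res[[length(res) + 1L]] <- c(s = step_syn + tl[["s"]],
                                     n = (!step_syn) + tl[["n"]])
    }
    res
  }
  paths <- walk(c1)
  if (length(paths) == 0L) return(c(syn = 0, nonsyn = 0, paths = 0))
  m <- do.call(rbind, paths)
  c(syn = mean(m[, "s"]), nonsyn = mean(m[, "n"]), paths = nrow(m))
}

# --- independent circular-adjacency breakpoint oracle -------------------
oracle_breakpoints <- function(ord_a, ord_b) {
  adj <- function(o) {
    n <- nrow(o)
    keys <- character(n)
    for (i in seq_len(n)) {
      j <- i %% n + 1L
      f <- paste0(o$name[i], o$strand[i], "->", o$name[j], o$strand[j])
      g <- paste0(o$name[j], chartr("JN", "NJ", o$strand[j]), "->",
                  o$name[i], chartr("JN", "NJ", o$strand[i]))
      keys[i] <- min(f, g)
    }
    keys
  }
  sum(!(adj(ord_a) %in% adj(ord_b)))
}

# random signed circular order over k genes
random_order <- function(k, taxon = "rnd") {
  nm <- paste0("g", sample(k))
  make_gene_order(data.frame(name = nm,
                             strand = sample(c("J", "N"), k, TRUE),
                             stringsAsFactors = FALSE),
                  taxon, anchor = "g1")
}

# Kimura two-parameter distance (closed form) for the TN93 limit check
k2p_distance <- function(P, Q) {
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}
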