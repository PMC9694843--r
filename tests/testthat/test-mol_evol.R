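test_that("NG86 site fractions conserve 3 sites per sense codon", {
  for (codon in mitocomp:::sense_codons(5)) {
    s <- ng86_sites(codon)
    expect_equal(unname(s[["syn"]] + s[["nonsyn"]]), 3)
    expect_gte(s[["syn"]], 0)
  }
  # Trp (TGG) under code 5: only TGA at position 3 is synonymous
  expect_equal(unname(ng86_sites("TGG")[["syn"]]), 1 / 3)
  # four-fold third position: all three changes synonymous
  expect_gte(unname(ng86_sites("GGG")[["syn"]]), 1)
  expect_error(ng86_sites("TAA"), "stop")
})

test_that("NG86 pathway averaging equals the brute-force oracle", {
  sense <- mitocomp:::sense_codons(5)
  code <- genetic_code(5)
  checked <- 0L
  for (c1 in sense) {
    for (c2 in sense) {
      nd <- sum(seq_chars(c1) != seq_chars(c2))
      if (nd == 0L || nd > 2L) next
      mine <- mitocomp:::ng86_path_diffs(c1, c2)
      orac <- oracle_ng86_diffs(c1, c2, code)
      expect_equal(unname(mine[["syn"]]), unname(orac[["syn"]]))
      expect_equal(unname(mine[["nonsyn"]]), unname(orac[["nonsyn"]]))
      expect_equal(unname(mine[["paths"]]), unname(orac[["paths"]]))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 1500L)
})

test_that("a single synonymous change gives the hand-derived Ks", {
  # AAA CCC GGG vs AAA CCC GGA: one third-position synonymous change.
  # Per-sequence synonymous sites: 1/3 (Lys) + 1 (Pro) + 1 (Gly) = 7/3,
  # so ps = 3/7 and Ks = -(3/4) ln(1 - 4/3 * 3/7) = (3/4) ln(7/3).
  r <- pairwise_kaks("AAACCCGGG", "AAACCCGGA")
  expect_equal(r$Ks, 0.75 * log(7 / 3))
  expect_equal(r$Ka, 0)
  expect_equal(r$syn_sites, 7 / 3)
  expect_equal(r$syn_diffs, 1)
})

test_that("identical sequences give zero divergence, omega undefined", {
  cds <- strrep("ATGAAACCCGGGTTT", 20)
  r <- pairwise_kaks(cds, cds)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_true(is.na(r$omega))
  expect_false(r$ks_defined)
})

test_that("gap and N codons are excluded pairwise", {
  r <- pairwise_kaks("ATGAAANNNGGG", "ATGAAACCCGGG")
  expect_identical(r$codons_used, 3L)
  r2 <- pairwise_kaks("ATG---AAAGGG", "ATGCCCAAAGGG")
  expect_identical(r2$codons_used, 3L)
})

test_that("simulated purifying selection yields omega below one", {
  reps <- evolve_codons(300, ks = 0.2, ka = 0.02, replicates = 12,
                        seed = 7)
  om <- vapply(reps, function(r)
    pairwise_kaks(r$ancestor, r$derived)$omega, numeric(1))
  expect_true(all(om < 1))
  expect_lt(abs(mean(om) - 0.1), 0.05)
})

test_that("gene panels rank planted high- and low-omega genes", {
  om <- c(atp8 = 0.5, nad5 = 0.3, cox1 = 0.05, cytb = 0.12)
  cl <- make_clade(6, genome_spec(seed = 108),
                   divergence = list(ks_branch = 0.15, omega = om))
  means <- vapply(names(om), function(g)
    gene_panel_kaks(cl$genomes, g)$mean_omega, numeric(1))
  expect_identical(names(which.max(means)), "atp8")
  expect_identical(names(which.min(means)), "cox1")
  # a panel of identical genomes is all-zero
  g <- cl$genomes[[1]]
  r0 <- gene_panel_kaks(list(g, g), "cox1")
  expect_equal(r0$mean_ka, 0)
  expect_equal(r0$mean_ks, 0)
  # two genomes: the summary is the single pair
  r2 <- gene_panel_kaks(cl$genomes[1:2], "cox1")
  expect_identical(r2$n_pairs, 1L)
  expect_equal(r2$mean_omega, r2$pairs$omega[1])
})

test_that("TN93 distance is zero for identical sequences and exceeds p", {
  s <- strrep("ACGT", 100)
  expect_equal(tn93_distance(s, s)$tn93, 0)
  set.seed(9)
  for (r in 1:10) {
    p <- evolve_tn93(2000, d = runif(1, 0.02, 0.4), replicates = 1,
                     seed = r)[[1]]
    est <- tn93_distance(p[[1]], p[[2]])
    if (est$defined) expect_gte(est$tn93, est$p_distance)
  }
})

test_that("TN93 reduces to Kimura 2P when frequencies are balanced", {
  # balanced construction: every substitution class applied in
  # complementary pairs so both sequences keep frequencies exactly 1/4
  a <- rep(c("A", "C", "G", "T"), each = 100)
  b <- a
  swap <- function(b, from, to, k) {
    i <- which(a == from & b == from)[seq_len(k)]
    b[i] <- to
    b
  }
  b <- swap(b, "A", "G", 20); b <- swap(b, "G", "A", 20)  # P1 = 0.1
  b <- swap(b, "C", "T", 20); b <- swap(b, "T", "C", 20)  # P2 = 0.1
  b <- swap(b, "A", "C", 10); b <- swap(b, "C", "A", 10)  # Q  = 0.1
  b <- swap(b, "G", "T", 10); b <- swap(b, "T", "G", 10)
  r <- tn93_distance(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_equal(r$p_transition, 0.2)
  expect_equal(r$p_transversion, 0.1)
  expect_lt(abs(r$tn93 - k2p_distance(0.2, 0.1)), 1e-9)
})

test_that("TN93 agrees with an independent implementation", {
  for (s in 1:3) {
    p <- evolve_tn93(4000, d = 0.15, replicates = 1, seed = s)[[1]]
    mine <- tn93_distance(p[[1]], p[[2]])$tn93
    m <- rbind(seq_chars(tolower(p[[1]])), seq_chars(tolower(p[[2]])))
    rownames(m) <- c("A", "B")
    ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "TN93"))
    expect_lt(abs(mine - ref), 1e-12)
  }
})

test_that("TN93 simulation recovery hits the stated accuracy", {
  p <- evolve_tn93(10000, d = 0.1, replicates = 1, seed = 12)[[1]]
  expect_lt(abs(tn93_distance(p[[1]], p[[2]])$tn93 - 0.1), 0.01)
})

test_that("saturated pairs are flagged, not silently numeric", {
  set.seed(10)
  a <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  r <- tn93_distance(a, b)
  aln <- c(t1 = a, t2 = b, t3 = a)
  sat <- saturation_table(aln)
  expect_identical(nrow(sat$table), 3L)
  if (!r$defined) expect_gte(nrow(sat$flagged), 1L)
  # identical taxa row is exactly zero
  z <- sat$table[sat$table$taxonA == "t1" & sat$table$taxonB == "t3", ]
  expect_equal(unname(unlist(z[, c("s", "v", "tn93")])), c(0, 0, 0))
})

test_that("transitions track distance linearly at low divergence", {
  tree <- ape::read.tree(
    text = "(t1:0.01,t2:0.04,t3:0.08,t4:0.12,t5:0.16);")
  set.seed(14)
  sim <- phangorn::simSeq(tree, l = 3000, Q = c(1, 4, 1, 1, 8, 1),
                          bf = c(0.35, 0.12, 0.13, 0.40), type = "DNA")
  m <- toupper(as.character(sim))
  aln <- setNames(apply(m, 1, paste, collapse = ""), rownames(m))
  sat <- saturation_table(aln)
  expect_true(all(sat$table$defined))
  expect_gt(sat$fit_s$pearson_r, 0.95)
  expect_true(all(sat$table$s + sat$table$v <= 1))
})
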