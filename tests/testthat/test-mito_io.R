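test_that("gene extraction follows strand and circular coordinates", {
  f <- data.frame(name = c("a", "b", "w"), kind = "tRNA",
                  start = c(1L, 1L, 5L), end = c(3L, 3L, 2L),
                  strand = c("J", "N", "J"), stringsAsFactors = FALSE)
  g <- toy_genome("ATGCCC", f[1, ])
  expect_identical(extract_gene_sequence(g, 1L), "ATG")
  g2 <- toy_genome("ATGCCC", f[2, ])
  expect_identical(extract_gene_sequence(g2, 1L), "CAT")
  # wrap across the origin (1-based inclusive): positions 5,6,1,2
  g3 <- toy_genome("ATGCCC", f[3, ])
  expect_identical(extract_gene_sequence(g3, 1L), "CCAT")
  expect_error(mitocomp:::circular_slice("ATGCCC", 0L, 3L), "outside")
})

test_that("N-strand extraction is the reverse complement of the J slice", {
  set.seed(11)
  for (r in 1:10) {
    L <- sample(50:120, 1)
    s <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
    st <- sample(L, 1); en <- sample(L, 1)   # may wrap
    fJ <- data.frame(name = "x", kind = "tRNA", start = st, end = en,
                     strand = "J", stringsAsFactors = FALSE)
    fN <- fJ; fN$strand <- "N"
    expect_identical(
      extract_gene_sequence(toy_genome(s, fN), 1L),
      revcomp(extract_gene_sequence(toy_genome(s, fJ), 1L)))
  }
})

test_that("GenBank write/read round-trips synthetic genomes", {
  g <- make_genome(genome_spec(seed = 21))$genome
  g$accession <- "SYN000001"
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  g2 <- read_genbank(path)
  expect_genome_equal(g, g2)
  expect_identical(g2$accession, "SYN000001")
  expect_identical(g2$topology, "circular")
})

test_that("GenBank complement and origin-spanning locations parse", {
  f <- data.frame(name = c("trnQ", "cox1"), kind = c("tRNA", "PCG"),
                  start = c(100L, 180L), end = c(160L, 20L),
                  strand = c("N", "J"), stringsAsFactors = FALSE)
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  g <- toy_genome(s, f)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  txt <- readLines(path)
  expect_true(any(grepl("complement\\(100..160\\)", txt)))
  expect_true(any(grepl("join\\(180..200,1..20\\)", txt)))
  g2 <- read_genbank(path)
  expect_genome_equal(g, g2)
})

test_that("missing ORIGIN is a parse error", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 10 bp", "FEATURES", "//"), path)
  expect_error(read_genbank(path), "ORIGIN")
})

test_that("feature table TSV round-trips and rejects duplicates", {
  g <- make_genome(genome_spec(seed = 22))$genome
  tsv <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_feature_table(g, tsv, fa)
  g2 <- read_feature_table(fa, tsv)
  expect_genome_equal(g, g2)
  tab <- utils::read.delim(tsv)
  expect_identical(names(tab), c("taxon", "name", "kind", "start", "end",
                                 "strand"))
  tab2 <- rbind(tab, tab[1, ])
  utils::write.table(tab2, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_feature_table(fa, tsv), "duplicate")
})

test_that("an empty feature table yields a valid genome and empty scans", {
  g <- toy_genome("ACGTACGTAA", data.frame())
  expect_identical(nrow(g$features), 0L)
  expect_identical(nrow(scan_junctions(g)), 0L)
})

test_that("gene names normalize through the synonym table", {
  expect_identical(normalize_gene_name("COI")$name, "cox1")
  expect_identical(normalize_gene_name("ND2")$name, "nad2")
  expect_identical(normalize_gene_name("cob")$name, "cytb")
  expect_identical(normalize_gene_name("16S")$name, "rrnL")
  expect_identical(normalize_gene_name("D-loop")$kind, "control_region")
  expect_warning(out <- normalize_gene_name("mystery_orf"), "unmappable")
  expect_identical(out$name, "mystery_orf")
  expect_true(is.na(out$kind))
})

test_that("feature length accounting closes the circle", {
  for (seed in c(31, 32)) {
    res <- make_genome(genome_spec(seed = seed))
    g <- res$genome
    j <- scan_junctions(g)
    total <- sum(mitocomp:::feature_lengths(g)) +
      sum(j$length[j$relation == "spacer"]) -
      sum(j$length[j$relation == "overlap"])
    expect_identical(as.integer(total), nchar(g$sequence))
  }
})
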