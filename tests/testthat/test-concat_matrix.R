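test_that("harvested genes round-trip through FASTA", {
  cl <- make_clade(3, genome_spec(seed = 111))
  fa <- withr::local_tempfile(fileext = ".fasta")
  cds <- harvest_gene(cl$genomes, "cox1", fasta_path = fa)
  expect_length(cds, 3L)
  back <- Biostrings::readDNAStringSet(fa)
  expect_identical(unname(as.character(back)), unname(cds))
  expect_identical(cds[[1]],
                   extract_gene_sequence(cl$genomes[[1]], "cox1"))
  # a taxon lacking the gene is omitted with a warning
  g2 <- cl$genomes[[2]]
  g2$features <- g2$features[g2$features$name != "cox1", ]
  expect_warning(cds2 <- harvest_gene(list(cl$genomes[[1]], g2), "cox1"),
                 "lack")
  expect_length(cds2, 1L)
})

test_that("column filtering removes exactly the gapped columns", {
  aln <- c(a = "ATGCCC", b = "ATGCCC", c = "ATGCCC")
  expect_identical(unname(unclass(filter_columns(aln))[1:3]), unname(aln))
  aln2 <- c(a = "ATGCCC", b = "AT-CCC", c = "ATGCCC")
  f <- filter_columns(aln2)
  expect_identical(unname(f[["a"]]), "ATCCC")
  expect_identical(attr(f, "removed_columns"), 3L)
  # random alignment: output length equals the gapless-column count
  set.seed(15)
  m <- matrix(sample(c("A", "C", "G", "T"), 5 * 60, TRUE), nrow = 5)
  gapcols <- sample(60, 6)
  for (cc in gapcols) m[sample(5, 1), cc] <- "-"
  aln3 <- setNames(apply(m, 1, paste, collapse = ""), paste0("t", 1:5))
  f3 <- filter_columns(aln3)
  expect_identical(nchar(f3[[1]]), 60L - length(unique(gapcols)))
  # idempotence
  f3b <- filter_columns(f3)
  expect_identical(unname(unclass(f3b)[1:5]), unname(unclass(f3)[1:5]))
  expect_error(filter_columns(c(a = "---", b = "A--")), "survive")
})

test_that("concatenation builds a tiling partitioned supermatrix", {
  cl <- make_clade(5, genome_spec(seed = 112))
  pcgs <- names(mitocomp:::default_pcg_lengths)
  alns <- lapply(pcgs, function(g) {
    a <- harvest_gene(cl$genomes, g)
    len <- min(nchar(a)) %/% 3L * 3L
    vapply(a, substr, character(1L), 1L, len)
  })
  names(alns) <- pcgs
  sm <- concatenate_genes(alns)
  expect_identical(nrow(sm$charsets), 13L)
  expect_identical(sm$charsets$start[1], 1L)
  expect_identical(sm$charsets$gene, sort(pcgs))
  expect_true(all(sm$charsets$start[-1] == head(sm$charsets$end, -1) + 1L))
  expect_identical(sm$charsets$end[13], nchar(sm$sequences[[1]]))
  expect_identical(sum(sm$charsets$end - sm$charsets$start + 1L),
                   nchar(sm$sequences[[1]]))
  # single gene: the matrix is that alignment
  sm1 <- concatenate_genes(alns["cox1"])
  expect_identical(unname(sm1$sequences), unname(alns$cox1))
  # duplicate taxon names are rejected
  expect_error(concatenate_genes(alns, taxa = rep("x", 2)), "duplicate")
})

test_that("a taxon missing from one gene is gap-filled and flagged", {
  aln <- list(g1 = c(a = "ATGAAA", b = "ATGAAA"),
              g2 = c(a = "CCCGGG"))
  sm <- concatenate_genes(aln)
  expect_identical(sm$missing$g2, "b")
  expect_identical(substr(sm$sequences[["b"]], 7, 12), "------")
})

test_that("NEXUS export re-reads with the expected dimensions", {
  cl <- make_clade(4, genome_spec(seed = 113))
  alns <- list(cox1 = harvest_gene(cl$genomes, "cox1"),
               nad3 = harvest_gene(cl$genomes, "nad3"))
  sm <- concatenate_genes(alns)
  nex <- withr::local_tempfile(fileext = ".nex")
  write_nexus(sm, nex)
  back <- ape::read.nexus.data(nex)
  expect_length(back, 4L)
  expect_identical(length(back[[1]]), nchar(sm$sequences[[1]]))
  expect_true(any(grepl("charset cox1 = 1-", readLines(nex))))
  phy <- withr::local_tempfile(fileext = ".phy")
  write_phylip(sm, phy)
  first <- readLines(phy, n = 1)
  expect_identical(first, paste(4, nchar(sm$sequences[[1]])))
})
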