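test_that("skew formulas and undefined denominators behave", {
  s <- base_composition("AATT")
  expect_equal(s$at_skew, 0)
  expect_false(s$gc_skew_defined)
  expect_true(is.na(s$gc_skew))
  expect_equal(base_composition("GGGC")$gc_skew, 0.5)
  expect_error(base_composition(""), "empty")
  expect_true(base_composition("NNNN")$all_n)
})

test_that("published moth base percentages reproduce the printed skews", {
  # counts in the printed proportions of a 78.9% A+T moth genome
  seqZ <- paste0(strrep("A", 398), strrep("T", 391), strrep("C", 132),
                 strrep("G", 79))
  expect_equal(round(base_composition(seqZ)$at_skew, 3), 0.009)
  seqH <- paste0(strrep("A", 406), strrep("T", 410), strrep("C", 111),
                 strrep("G", 73))
  expect_equal(round(base_composition(seqH)$at_skew, 3), -0.005)
  # the one moth with more G than C has a positive GC skew
  seqL <- paste0(strrep("A", 398), strrep("T", 414), strrep("C", 79),
                 strrep("G", 109))
  expect_gt(base_composition(seqL)$gc_skew, 0)
})

test_that("skews are antisymmetric under reverse complement and bounded", {
  set.seed(42)
  for (r in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, TRUE,
                      prob = runif(4)), collapse = "")
    a <- base_composition(s); b <- base_composition(revcomp(s))
    expect_equal(b$at_skew, -a$at_skew)
    expect_equal(b$gc_skew, -a$gc_skew)
    expect_true(abs(a$at_skew) <= 1 && abs(a$gc_skew) <= 1)
  }
})

test_that("composition of a concatenation pools per-gene counts", {
  set.seed(43)
  parts <- replicate(5, paste(sample(c("A", "C", "G", "T", "N"), 120, TRUE),
                              collapse = ""))
  whole <- base_composition(paste(parts, collapse = ""))
  counts <- Reduce(`+`, lapply(parts, function(p) base_composition(p)$counts))
  expect_identical(whole$counts, counts)
  expect_equal(whole$at_skew,
               (counts[["A"]] - counts[["T"]]) / (counts[["A"]] + counts[["T"]]))
})

test_that("N bases are excluded from denominators but kept in length", {
  s <- base_composition("AANN")
  expect_identical(s$length, 4L)
  expect_identical(s$n_count, 2L)
  expect_equal(s$pct[["A"]], 100)
})

test_that("strand-partitioned PCG composition matches the strand layout", {
  res <- make_genome(genome_spec(seed = 51))
  sc <- strand_class_composition(res$genome)
  expect_named(sc, c("genome", "pcg_J", "pcg_N"))
  expect_identical(sc$pcg_J$n_genes, 9L)
  expect_identical(sc$pcg_N$n_genes, 4L)
  # generator targets recovered on the genome-wide sequence
  expect_lt(abs(sc$genome$at_content - 80), 1)
  # a genome with all PCGs on J yields two summaries and a warning
  f <- data.frame(name = c("cox1", "cox2"), kind = "PCG",
                  start = c(1L, 40L), end = c(30L, 90L), strand = "J",
                  stringsAsFactors = FALSE)
  set.seed(1)
  g <- toy_genome(paste(sample(c("A", "C", "G", "T"), 100, TRUE),
                        collapse = ""), f)
  expect_warning(sc2 <- strand_class_composition(g), "strand N")
  expect_named(sc2, c("genome", "pcg_J"))
})

test_that("the composition table keeps its internal identities", {
  genomes <- lapply(c(61, 62), function(s)
    make_genome(genome_spec(seed = s, at_content = 78))$genome)
  tab <- composition_table(genomes)
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$AT_pct + tab$GC_pct, c(100, 100))
  expect_equal(tab$GT_pct, tab$G_pct + tab$T_pct)
  expect_equal(tab$AT_skew_r, round(tab$AT_skew, 3))
})

test_that("generator composition targets are recovered", {
  res <- make_genome(genome_spec(seed = 71, at_content = 81.7))
  at <- base_composition(res$genome$sequence)$at_content
  expect_true(at >= 80.7 && at <= 82.7)
  res2 <- make_genome(genome_spec(seed = 72, gc_skew = -0.25))
  expect_lt(base_composition(res2$genome$sequence)$gc_skew, -0.2)
})
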