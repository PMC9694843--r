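mk_feats <- function(starts, ends, names = NULL, strands = "J") {
  data.frame(name = names %||% paste0("g", seq_along(starts)),
             kind = "tRNA", start = starts, end = ends,
             strand = strands, stringsAsFactors = FALSE)
}

test_that("overlap, abutting and spacer relations are detected", {
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  j <- scan_junctions(toy_genome(s, mk_feats(c(1, 8), c(10, 20))))
  expect_identical(j$relation[1], "overlap")
  expect_identical(j$length[1], 3L)
  expect_identical(j$sequence[1], substr(s, 8, 10))
  j2 <- scan_junctions(toy_genome(s, mk_feats(c(1, 11), c(10, 20))))
  expect_identical(j2$relation[1], "abutting")
  expect_identical(j2$length[1], 0L)
  j3 <- scan_junctions(toy_genome(s, mk_feats(c(1, 15), c(10, 20))))
  expect_identical(j3$relation[1], "spacer")
  expect_identical(j3$sequence[1], substr(s, 11, 14))
  # nested feature reported as an overlap of the inner length, with warning
  expect_warning(
    j4 <- scan_junctions(toy_genome(s, mk_feats(c(1, 5), c(20, 9)))),
    "nested")
  expect_identical(j4$length[1], 5L)
})

test_that("planted junction motifs are recovered verbatim", {
  res <- make_genome(genome_spec(seed = 91))
  j <- scan_junctions(res$genome)
  get <- function(up, dn) j[j$upstream == up & j$downstream == dn, ]
  expect_identical(get("atp8", "atp6")$sequence, "ATGATAA")
  expect_identical(get("atp8", "atp6")$length, 7L)
  expect_identical(get("cox1", "trnL2")$sequence, "TCTAA")
  expect_identical(get("trnW", "trnC")$sequence, "AAGCCTTA")
  expect_identical(get("trnS2", "nad1")$relation, "spacer")
  expect_identical(get("trnS2", "nad1")$sequence, "ATACTAA")
})

test_that("junction scanning is invariant under origin rotation", {
  res <- make_genome(genome_spec(seed = 92))
  j0 <- scan_junctions(res$genome)
  for (shift in c(137, 9000)) {
    jr <- scan_junctions(rotate_genome(res$genome, shift))
    key <- function(d) d[order(d$upstream, d$downstream),
                         c("upstream", "downstream", "relation", "length",
                           "sequence")]
    k0 <- key(j0); kr <- key(jr)
    rownames(k0) <- rownames(kr) <- NULL
    expect_equal(k0, kr)
  }
})

test_that("motifs conserved across a clade are flagged universal", {
  base <- genome_spec(seed = 93)
  cl <- make_clade(6, base)
  cons <- conserved_junctions(cl$genomes)
  u <- cons[cons$is_universal, ]
  expect_identical(sum(u$relation == "overlap"), 3L)
  expect_identical(sum(u$relation == "spacer"), 1L)
  expect_setequal(u$motif[u$relation == "overlap"],
                  c("TCTAA", "ATGATAA", "AAGCCTTA"))
  expect_identical(u$motif[u$relation == "spacer"], "ATACTAA")
  # a single mutated taxon breaks universality
  cl2 <- make_clade(6, base, motif_variants = list(
    list(taxon = 6, junction = "trnS2|nad1", motif = "TTACTAA")))
  cons2 <- conserved_junctions(cl2$genomes)
  row <- cons2[cons2$upstream == "trnS2" & cons2$downstream == "nad1", ]
  expect_false(row$is_universal)
  expect_identical(row$n_supporting, 5L)
  expect_identical(row$motif, "ATACTAA")
})

test_that("spacer profiles recover planted length ranges and composition", {
  cl <- make_clade(8, genome_spec(seed = 94))
  pr <- spacer_profile(cl$genomes, c("trnQ", "nad2"))
  expect_identical(nrow(pr$per_taxon), 8L)
  expect_gte(pr$min_length, 48L)
  expect_lte(pr$max_length, 87L)
  # planted high-AT spacer is recovered exactly
  plan <- default_junction_plan()
  plan[["trnG|nad3"]] <- list(relation = "spacer",
                              motif = "AATTATAATTGTAATTATAT",
                              conserved = TRUE)
  res <- make_genome(genome_spec(seed = 95, junction_plan = plan))
  pr2 <- spacer_profile(list(res$genome), c("trnG", "nad3"))
  expect_equal(pr2$per_taxon$at_content, 95)
  # absent pair gives an empty profile
  expect_identical(nrow(spacer_profile(cl$genomes,
                                       c("cox1", "nad5"))$per_taxon), 0L)
})

test_that("control regions are located from unannotated gaps", {
  g1 <- make_genome(genome_spec(seed = 96, cr_length = 400,
                                annotate_cr = FALSE))$genome
  cr <- locate_control_regions(g1)
  expect_identical(nrow(cr), 1L)
  expect_true(cr$canonical)
  expect_gte(cr$length, 400L)
  expect_setequal(c(cr$upstream, cr$downstream), c("rrnS", "trnM"))
  # dual-CR genome: a second unannotated stretch between rrnL and trnV
  g2 <- make_genome(genome_spec(seed = 97, annotate_cr = FALSE,
                                extra_crs = list(list(after = "rrnL",
                                                      length = 300))))$genome
  cr2 <- locate_control_regions(g2)
  expect_identical(nrow(cr2), 2L)
  expect_identical(sum(cr2$canonical), 1L)
  expect_true(any(cr2$upstream == "rrnL" | cr2$downstream == "rrnL"))
  # fully tiled toy genome: no hits
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  g3 <- toy_genome(s, mk_feats(c(1, 301), c(300, 600),
                               names = c("rrnS", "trnM")))
  expect_identical(nrow(locate_control_regions(g3)), 0L)
})

test_that("motif search reports hits inside genes separately", {
  res <- make_genome(genome_spec(seed = 98))
  hits <- find_junction_motif(res$genome, "ATGATAA")
  expect_gte(nrow(hits), 1L)
  expect_true(any(grepl("atp8", hits$inside_features) &
                    grepl("atp6", hits$inside_features)))
})
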