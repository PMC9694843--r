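# mitocomp

Comparative analysis of annotated animal mitochondrial genomes, aimed at
the standard workflow of insect (especially lepidopteran) mitogenomics
papers: base composition and strand skews, codon usage under the
invertebrate mitochondrial genetic code, gene-junction conservation,
gene-order rearrangement, selective-constraint estimation, and
substitution-saturation diagnostics, ending in a partitioned supermatrix
ready for external phylogenetic inference.

## What it computes

For a panel of annotated mitogenomes (GenBank flat files, or FASTA plus a
feature table), `mitocomp` produces:

* **Composition and skews** — per-genome and per-strand-class base
  percentages, A+T content, and the strand-asymmetry statistics
  AT-skew = (A − T)/(A + T), GC-skew = (G − C)/(G + C).
* **Codon usage** — start/stop codon matrices (unusual starts reported
  verbatim, incomplete stops T/TA recognized), RSCU
  (RSCU_c = n_c / mean count of c's synonymous family, with the leu1/leu2
  and ser1/ser2 reporting split), and amino-acid usage under NCBI
  translation table 5.
* **Junction structure** — per-adjacent-pair overlap/spacer/abutting
  calls on the circular genome with J-strand sequences, cross-taxon
  conserved-motif detection, spacer length/composition profiles, and
  control-region localization from unannotated gaps.
* **Gene order** — signed circular orders anchored at cox1, breakpoint
  distances on the signed adjacency set, and classification against the
  ancestral-insect, typical-lepidopteran and chironomid-variant
  reference arrangements.
* **Molecular evolution** — pairwise Ka/Ks by the Nei–Gojobori (1986)
  pathway-counting method with Jukes–Cantor correction, and Tamura–Nei
  (1993) distances with transition/transversion proportions for
  saturation assessment.
* **Supermatrix export** — per-gene harvesting, a transparent logged
  column filter, and concatenation with charset partitions in
  NEXUS/PHYLIP/FASTA.

A seeded synthetic-mitogenome generator (`make_genome()`, `make_clade()`,
`evolve_codons()`, `evolve_tn93()`) produces annotated genomes and
divergence scenarios with machine-checkable ground truth, so the entire
pipeline is testable offline.

## Worked example

```r
library(mitocomp)

res <- make_genome(genome_spec(taxon = "Synthetica exempli", seed = 42))
g <- res$genome
g
#> <mito_genome> Synthetica exempli
#>   15303 bp, circular, 38 features (13 PCG, 22 tRNA, 2 rRNA, 1 CR)

base_composition(g$sequence, "whole genome")
#> <composition> whole genome: 15303 bp, AT 80.0%, AT-skew -0.011, GC-skew -0.206

j <- scan_junctions(g)
j[j$upstream == "atp8", c("upstream", "downstream", "relation", "length", "sequence")]
#>  upstream downstream relation length sequence
#>      atp8       atp6  overlap      7  ATGATAA

classify_against_references(g)$breakpoints
#>    ancestral_insect lepidoptera_typical  chironomid_variant
#>                   3                   0                   3

rep <- evolve_codons(500, ks = 0.2, ka = 0.02, replicates = 1, seed = 7)[[1]]
k <- pairwise_kaks(rep$ancestor, rep$derived)
sprintf("Ka = %.4f  Ks = %.4f  Ka/Ks = %.3f", k$Ka, k$Ks, k$omega)
#> [1] "Ka = 0.0184  Ks = 0.2204  Ka/Ks = 0.084"
```

Reading the output: the generated genome carries the typical lepidopteran
gene order (zero breakpoints against that reference; the three
breakpoints against the ancestral order are exactly the
trnM-trnI-trnQ rearrangement), the conserved 7-bp atp8/atp6 overlap
"ATGATAA", ~80% A+T with a negative GC skew, and a codon pair simulated
under strong purifying selection recovers Ka/Ks ≈ 0.1.

`run_all(genomes, out_dir)` executes every stage over a genome panel and
writes the full report bundle (composition table, start/stop matrix,
RSCU, junction and conserved-motif tables, gene-order classification,
Ka/Ks panels, saturation table, partitioned NEXUS matrix, and a run log).

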