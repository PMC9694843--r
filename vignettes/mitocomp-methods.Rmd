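---
title: "Comparative mitogenomics with mitocomp: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## Scope and the data model

Insect mitochondrial genomes are circular molecules of roughly 14-16 kb
carrying a nearly invariant inventory of 37 genes — 13 protein-coding
genes (PCGs), 22 tRNAs, 2 rRNAs — plus at least one A+T-rich control
region (CR). Comparative studies of such genomes revolve around a small
set of standard statistics: strand-asymmetry skews of base composition,
relative synonymous codon usage (RSCU) under the invertebrate
mitochondrial genetic code, start/stop codon inventories (including the
incomplete stops completed by transcript polyadenylation), the overlap
and spacer structure of gene junctions, tRNA gene-order rearrangements
relative to the ancestral insect arrangement, pairwise Ka/Ks as an index
of selective constraint, and substitution-saturation diagnostics before
tree inference. `mitocomp` implements this suite as a tested pipeline
over annotated genomes; it deliberately does *not* assemble or annotate
reads, align sequences, or run tree inference — those belong to external
tools whose inputs this package prepares.

The central record is the `mito_genome`: a J-strand (majority-strand)
nucleotide sequence plus an ordered feature table in GenBank convention —
1-based inclusive coordinates, `end < start` encoding a feature that wraps
the origin of the circle, and strands labelled J/N for the GenBank +/-.
Records come from GenBank flat files (`read_genbank()`), from FASTA plus
a tab-separated feature table (`read_feature_table()`), or from the
synthetic generator. Gene labels are normalized through an editable
synonym table shipped in `extdata` (COX1/COI → cox1, ND2 → nad2, 16S →
rrnL, D-loop → CR, ...), because deposited annotations vary widely in
naming.

## Composition and skews

For counts of the four bases, the strand skews are

$$\mathrm{AT\,skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\,skew} = \frac{G - C}{G + C}.$$

`base_composition()` excludes N from every denominator while still
reporting full sequence length; a zero denominator yields an explicit
undefined flag rather than NaN. Whole-genome values are computed on the
J-strand sequence as deposited, which is the convention of published
composition tables; `strand_class_composition()` additionally reports
the concatenated J-strand and N-strand PCG sets in reading direction.
Report rounding (one decimal for percentages, three for skews) is applied
only in display columns — comparisons in tests always use unrounded
values. The GT% column that composition tables in this field often carry
is reproduced as G% + T%, the identity the printed values satisfy.

## Codon usage under genetic code 5

The invertebrate mitochondrial code (NCBI table 5: ATA = Met, TGA = Trp,
AGA/AGG = Ser; TAA/TAG the only stops, hence 62 sense codons) is shipped
as data keyed by NCBI table number, with tables 1 and 2 included for
cross-checks. Start codons are reported verbatim — published tables list
CGA, TTG, AAA, AAG and GTG starts literally, so no "correction" toward
ATN is ever applied. A CDS whose length leaves a trailing `T` or `TA` is
classified as an incomplete stop; any other non-stop terminus is flagged
and reported verbatim. Incomplete-stop remnants are excluded from codon
counts: they are not codons.

RSCU for codon $c$ in synonymous family $F$ is
$\mathrm{RSCU}_c = n_c / \overline{n}_F$, so each family sums to its
size. Families follow the amino acids of the code with the conventional
reporting split of leucine into leu1 (CTN) and leu2 (TTA/TTG) and serine
into ser1 (AGN) and ser2 (TCN). One published account of moth codon
preference lists "leu2 (UAA)" among preferred codons; UAA is a stop
codon, and the accompanying figure lists UUA — `mitocomp` treats this as
a typo for UUA and reports UUA (TTA in DNA alphabet) for the leu2 family.
RSCU defaults to concatenated PCGs per genome, with a per-gene option.

## Junction structure and control regions

`scan_junctions()` walks adjacent features around the circle (ties at a
shared start position are broken longest-first) and classifies each pair
as overlap, abutting, or spacer. Overlaps are computed on genomic
coordinates irrespective of strand — the classic trnW/trnC overlap spans
opposite-strand genes — and all junction sequences are reported on the
J-strand. A feature nested inside its neighbour is reported as an
overlap of the inner length with a warning rather than an error, since
real annotations occasionally contain such cases.
`conserved_junctions()` marks a junction universal only when every input
genome has the adjacency with an identical sequence; the modal sequence
and its supporting taxa are reported otherwise, so a single mutated taxon
(e.g. a TTACTAA variant of the common ATACTAA trnS2/nad1 spacer) breaks
universality but remains visible with 16/17 support.

Control-region localization treats annotated CR features as ordinary
junction participants; separately, `locate_control_regions()` infers
unannotated CRs as gaps of at least `min_len` bp between non-CR
features. The default `min_len = 200` is a deliberate design choice: the
largest ordinary intergenic spacer reported in the moth panels this
package targets is 87 bp, so 200 bp cleanly separates CRs from spacers
while catching even short supernumerary CRs. The hit flanked by rrnS and
trnM is classified canonical (the lepidopteran CR position); anything
else is supernumerary, covering dual-CR genomes. Conserved motifs that
partially lie inside a neighbouring gene's 3' end are a known annotation
ambiguity; `find_junction_motif()` reports such motif-in-gene hits as a
separate category from pure spacer calls.

## Gene order

`order_string()` produces a signed circular gene order canonically
rotated to an anchor (cox1) and reflected so the anchor reads on the
J-strand; control regions appear as `CR` tokens. Orders are compared on
the circular *signed adjacency set*: each adjacency is stored in an
orientation-independent canonical form, and the breakpoint count is the
number of adjacencies of one order absent from the other. This is
adjacency-level only — no inversion or DCJ distance is computed, because
the claims this supports (the lepidopteran trnM-trnI-trnQ block vs the
ancestral trnI-trnQ-trnM, and the chironomid trnI-trnM-trnQ variant) are
adjacency-level claims. CR tokens are excluded from breakpoint counting
by default since CR position varies; a flag re-includes them. Three
reference orders ship with the package; classification returns the
reference with the fewest breakpoints, ties broken alphabetically and
flagged.

## Ka/Ks by Nei-Gojobori (1986)

The published analyses this package reproduces computed Ka/Ks "using
DnaSP", without naming the estimator; `mitocomp` fixes the method to
NG86 — DnaSP's classic counting method — because it is fully specifiable
and reproducible without the external program. Per sense codon, each
position contributes the fraction of its three possible point mutations
that are synonymous, with mutations creating stops excluded from the
denominator, so synonymous + nonsynonymous sites are exactly 3 per codon.
Differences between codon pairs are averaged with equal weight over all
minimal mutational pathways that avoid stop codons; codon pairs whose
every pathway crosses a stop are excluded with a warning, as are codons
containing gaps or N. The proportions $p_S = S_d/S$ and $p_N = N_d/N$
(sites averaged over the two sequences) receive the Jukes-Cantor
correction $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, which is undefined
at $p \ge 3/4$ — such pairs are flagged saturated rather than silently
dropped or clamped. An undefined ratio (Ks = 0) is reported as a flag,
never as infinity. The implementation is verified against an independent
brute-force pathway-enumeration oracle over every codon pair differing at
up to two positions.

Gene panels default to means over all unordered taxon pairs; a
reference-taxon mode is available. Sequences of unequal length are
truncated to the shortest frame-preserving length — a simple
reading-frame alignment suitable for the indel-free CDSs the generator
produces; indel-containing data should be externally aligned first.

## TN93 distance and saturation

The Tamura-Nei (1993) distance distinguishes purine transitions
($P_1$: A↔G), pyrimidine transitions ($P_2$: C↔T) and transversions
($Q$), with base frequencies averaged over the two sequences (the
pairwise convention of standard distance implementations, rather than
alignment-wide frequencies):

$$d = -\frac{2 g_A g_G}{g_R}\ln w_1 - \frac{2 g_C g_T}{g_Y}\ln w_2
      - 2\Big(g_R g_Y - \frac{g_A g_G g_Y}{g_R} - \frac{g_C g_T g_R}{g_Y}\Big)\ln w_3$$

with $w_1 = 1 - \frac{g_R P_1}{2 g_A g_G} - \frac{Q}{2 g_R}$,
$w_2 = 1 - \frac{g_Y P_2}{2 g_C g_T} - \frac{Q}{2 g_Y}$,
$w_3 = 1 - \frac{Q}{2 g_R g_Y}$, $g_R = g_A + g_G$, $g_Y = g_C + g_T$.
Any non-positive logarithm argument flags the pair saturated/undefined.
With balanced frequencies the formula reduces to Kimura 2P and
Jukes-Cantor limits, which the tests verify to $10^{-9}$ on exactly
constructed alignments; agreement with an independent implementation
(`ape::dist.dna`) is verified to $10^{-12}$ on simulated pairs.
`saturation_table()` emits the per-pair transition/transversion
proportions and TN93 distances plus least-squares fits of $s$ and $v$ on
$d$ — the usual linearity check that substitution saturation has not
eroded signal — excluding flagged pairs from the regression and
reporting them separately.

## Supermatrix preparation

`harvest_gene()` extracts per-taxon CDSs; `concatenate_genes()` builds a
partitioned matrix with per-gene charsets that tile its length, written
as NEXUS (with a `sets` block for partitioned analysis), relaxed PHYLIP,
or FASTA. The column filter applied before concatenation is a
deliberately simple, fully logged rule — remove columns whose gap
fraction exceeds a threshold (default 0) and optionally columns
containing N. It is a documented stand-in for heuristic alignment-
trimming tools, not a clone of them: its entire behaviour is auditable
from the removed-column log it attaches. Since no concatenation order is
canonical in the field's publications, genes are concatenated in fixed
alphabetical order and the order is recorded in the charsets, so any
downstream partitioned analysis is unambiguous.

## The synthetic-mitogenome generator

Every pipeline stage is testable without downloads because
`make_genome()` builds annotated genomes with declared ground truth. The
generator emulates the observed structure of moth mitogenomes: the
lepidopteran gene order (or the ancestral/chironomid templates), a 37-gene
inventory plus CR, A+T content in the 76-82% range with negative GC skew,
the three conserved junction overlaps (cox1/trnL2 "TCTAA", atp8/atp6
"ATGATAA", trnW/trnC "AAGCCTTA") and the conserved trnS2/nad1 spacer
"ATACTAA", a variable 48-87 bp trnQ/nad2 spacer, and per-PCG start/stop
plans including incomplete stops. Sequence is sampled i.i.d. from base
probabilities derived from the composition targets; junction motifs and
start/stop codons are placed first as hard constraints, and PCG interiors
are sampled codon-wise with stop codons rejected. Because stop rejection
alone would tilt PCG composition away from target (stops are A+T-rich),
codon sampling uses probabilities tilted by a fixed-point iteration so
that the stop-conditioned composition matches the target; across seeds
the realized A+T content is unbiased with a standard deviation near
0.25 percentage points, well inside the declared ±1-point tolerance.
N-strand genes are sampled under complement-swapped probabilities so the
J-strand composition matches targets genome-wide.

What the generator does *not* model: tRNA cloverleaf or rRNA secondary
structure (tRNA/rRNA genes are random sequences of realistic lengths —
60-75 bp and ~780/~1350 bp), CR tandem repeats, codon-position-specific
composition, and among-site rate variation. Passing tests therefore
demonstrate correctness of the statistics on sequences with realistic
composition and annotation structure, not robustness to every property of
real data (annotation errors, indels, heterogeneous rates).

`make_clade()` produces taxon panels in two modes. Independent mode
regenerates each taxon from its own seed while honouring the shared
junction plan, which is exactly what conservation scanning needs;
divergence mode derives each taxon from a common base genome by sampling
Poisson numbers of synonymous and nonsynonymous events per PCG (expected
counts `ks_branch * syn_sites` and `ks_branch * omega_g * nonsyn_sites`,
stop-creating changes rejected, constraint positions protected), giving
per-gene Ka/Ks with known truth; `ks_branch` may vary per taxon to grade
pairwise distances. Mutational pressure pulls diverged taxa slightly off
the base composition target, so their truth records declare a wider
(±2-point) tolerance. `evolve_codons()` and `evolve_tn93()` provide
sequence-level divergence scenarios; the TN93 simulator runs a
continuous-time chain via phangorn's simulator on a two-taxon tree with
branch lengths summing to the true distance, keeping the simulation
machinery independent of the package's own estimator. All generation is
deterministic given the spec seed, and `validate_truth()` re-checks every
planted property against the emitted genome.

Default problem sizes used by the test-suite and acceptance script —
17-taxon clades for conservation patterns, 100 replicates of 500 codons
for Ka/Ks recovery, 10 kb alignments for TN93 recovery — were chosen as
the smallest sizes at which the sampling error of each statistic is
comfortably below the tolerance being checked.

## Numerical and degenerate-input conventions

* Skews with zero denominators, JC corrections at $p \ge 3/4$, TN93 with
  non-positive log arguments, and omega with Ks = 0 are all *flagged*,
  never returned as NaN/Inf in tables.
* Empty feature tables are valid genomes; scans return empty reports.
* Adjacency ties (features sharing a start) order longest-first.
* The canonical rotation anchor (cox1) falls back to the
  lexicographically smallest gene with a warning when absent.
* An annotated CDS with internal stops draws a warning (suspect
  annotation), not an error; genomes are taken as annotated.

## Known limitations

The package trusts its input annotations; it does not adjudicate dubious
gene models. The simple reading-frame alignment is only valid for
equal-length, indel-free CDS sets; anything else requires external
alignment. The column filter is not a substitute for block-based
trimming heuristics when alignments are noisy. Breakpoint counts measure
adjacency disruption only and are not a rearrangement-event distance.
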