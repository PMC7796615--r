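---
title: "plastidflow: models, thresholds and simulator design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{plastidflow: models, thresholds and simulator design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidflow)
```

`plastidflow` analyses the relationship between plastome rearrangements and
plastid gene expression: strand-specific transcription profiling, TPM-based
ortholog expression correlation, synteny-block rearrangement distances,
strand-aware C-to-U editing detection, and the correlation-of-correlations
association statistics — all exercisable end to end on synthetic plastomes
with simulated stranded reads. This vignette records the models, the
tunable parameters that matter, the numerical choices, and what the
synthetic world does and does not establish.

## Coordinate and strand conventions

Internally every coordinate is 0-based half-open on the plus strand; GFF3's
1-based inclusive convention is converted only at the I/O boundary, so
windowing and codon arithmetic never carry an off-by-one. Plastomes are
circular: a feature spanning the origin is stored with an "unrolled" end
beyond the genome length and flagged `wraps_origin`. The read simulator,
by contrast, emits only non-wrapping fragments (a desk-scale
simplification, see Limitations); circularity is fully honoured where it is
load-bearing — in the signed-permutation representation used by the
rearrangement distances.

Strand-specific libraries follow the dUTP convention (`fr-firststrand`):
the first read of a pair aligns antisense to the transcript. `read_sam()`
therefore assigns a record's transcript strand from its pair-order and
mapping-strand flags; both mates of a proper pair always receive the same
transcript strand, and this invariant is tested.

## Coverage profiling

Coverage is the number of reads whose aligned (CIGAR `M`) segments cover a
base, kept separately per transcript strand. For plotting-scale profiles
the per-base vector is summarized in non-overlapping windows (default
100 bp, final partial window retained) and transformed with

$$ s_w = \frac{\log_{10}(\bar c_w + 1)}{\log_{10}(c_{max} + 1)} $$

where $\bar c_w$ is the window mean and $c_{max}$ the maximum window value
of that strand's vector. Three choices here were genuinely open and are
fixed as follows: the window statistic is the *mean* per-base count
(scale-consistent with "read counts per base"; sum or max would change
only the normalizing constant's interpretation), the maximum is taken *per
strand and per dataset* (each profile is normalized to its own peak —
without this the transform's "maximum coverage" is undefined), and a base
counts as transcribed at `min_cov = 1` read. Transformed scores are bounded
in [0, 1], monotone in raw coverage, and satisfy the endpoint identities
$s(0) = 0$, $s(c_{max}) = 1$, and $s = 1/2$ when
$\bar c_w = 9, c_{max} = 99$.

## Expression

A read is assigned to a CDS when at least 50% of its aligned length
overlaps it; among qualifying CDSs it goes to the largest overlap (exact
ties are counted in both and flagged). With non-overlapping CDSs separated
by spacers, a read can qualify for at most one gene, so the rule is
unambiguous in practice. Reads are *sense* when their transcript strand
equals the CDS strand; only sense counts enter TPM,

$$ \mathrm{TPM}_g = 10^6 \cdot \frac{c_g / l_g}{\sum_h c_h / l_h}, $$

while antisense counts are reported alongside. Between-species correlation
of ortholog expression uses Pearson on `log10(TPM + 1)` by default: plastid
expression spans orders of magnitude (psbA and rbcL dominate), and on the
raw scale those two genes alone would fix the coefficient. A raw-TPM option
exists.

## Rearrangement distances

Orthologous gene orders are reduced to the genes present exactly once in
every species. A syntenic block is a maximal run of such genes whose
oriented adjacencies are conserved in all species; each species is then a
circular signed permutation of blocks. Representing each block by head/tail
extremities makes both distances automatically invariant to rotation and
reflection of the circle (tested property):

* **breakpoint distance** — the number of oriented adjacencies of one
  genome absent from the other; a single inversion breaks two adjacencies.
* **DCJ distance** — for circular unichromosomal genomes the minimal
  double-cut-and-join event count has the closed form $d = N - C$, with
  $N$ blocks and $C$ cycles in the adjacency graph. One inversion is one
  DCJ event.

How "rearrangement counts" between real plastomes were originally tallied
is not specified anywhere precise enough to reimplement, so the package
defines PR = DCJ by default (the standard minimal-event count covering
inversions) and reports breakpoint distance alongside. DCJ is validated
exhaustively against a breadth-first search over adjacency matchings for
all signed circular permutations of up to 5 blocks, and the metric
properties plus the sandwich $b/2 \le d_{DCJ} \le b$ are tested on random
instances.

## C-to-U editing

Editing is read out strictly per transcript strand: a `+`-transcript site
is a plus-strand C whose covering `+` reads show T; a `−`-transcript site
is a plus-strand G (a C on the transcript) whose covering `−` reads show
plus-strand A. A site is called when

* informative coverage $n = n_{edited} + n_{unedited} \ge 50$,
* editing fraction $n_{edited}/n \ge 0.1$, and
* the one-sided exact binomial tail $P(X \ge n_{edited} \mid n,
  \varepsilon) \le 10^{-6}$.

The original detection used a proprietary variant caller whose p-value
model is not published; the exact binomial test against a configurable
per-base error rate $\varepsilon$ (default 0.001, roughly Q30) is
transparent, testable, and plays the same thresholding role. "Editing
efficiency" is the fraction $n_{edited}/n$ (the reading consistent with
statements like "efficiency less than 50%"); the literal edited:unedited
ratio is reported as an auxiliary column. Bases other than the C-like and
T-like states at a site are excluded from $n$.

Classification translates the affected codon before and after C→U with the
plastid/bacterial genetic code (table 11): same amino acid → silent,
different → non-silent; a site inside a CDS on the opposite transcript
strand is antisense (sense takes priority in overlaps); outside all CDSs,
noncoding — reported but excluded from the three biological categories.
CDSs whose length is not a multiple of 3 cannot be frame-classified; such
sites keep an `NA` category with a warning rather than aborting the run.

Cross-species shared/specific status aligns orthologous CDSs codon-aware:
translate, globally align amino acids (BLOSUM62, affine gaps, opening 10 /
extension 0.5), back-map to nucleotide columns. Multiple species use a star
alignment around the longest sequence; two sites share a column iff they
map to the same centre coordinate with the same strand class. A full
progressive MSA would be more general, but for plastid orthologs (few,
short indels) the star projection is exact in practice and keeps the
pairwise scores verifiable against a brute-force dynamic program, which the
tests do.

## Association statistics

The pair table holds, for each of the $S(S-1)/2$ unordered species pairs,
the ortholog expression correlation $r_{expr}$, the rearrangement count PR
and the patristic distance (sum of branch lengths on the tip-to-tip path).
The headline analysis applies the plain Pearson test with the exact t
transform, $t = r\sqrt{n-2}/\sqrt{1-r^2}$ with $n-2$ df, two-sided, to
PR ~ distance and PR ~ $r_{expr}$. These pairwise values are not
independent — the package reproduces the plain test deliberately because it
*is* the study design being implemented, and additionally exposes a Mantel
permutation test (label permutations of one matrix, add-one estimator,
identity shuffles redrawn) as the robustness companion. No multiple-testing
correction is applied by default. Two analytic anchors tie the
implementation to printed results: $p(r{=}0.375, n{=}15) \approx 0.167$ and
$p(r{=}-0.626, n{=}15) \approx 0.013$.

## The synthetic world

The simulator states one world and the tests measure the pipeline against
it; none of its parameters are adjusted to make tests pass.

* **Genome.** `n_genes` CDSs (default 24) in `n_operons` contiguous
  same-strand operons (default 8), gene lengths uniform over 300–1500 bp
  rounded to codons (the typical plastid CDS range: many ribosomal-protein
  genes at 300–500 bp, psbA ≈ 1.1 kb, rbcL ≈ 1.4 kb), spacers 60–200 bp,
  random sequence. Per-operon transcription rates are log-normal
  (sdlog = 1), reproducing the orders-of-magnitude spread between
  photosystem genes and lowly expressed CDSs.
* **Transcription.** The transcript pool is the model's deterministic
  expectation: each unit emits its primary transcript at rate
  $r(1-p)$ plus geometric read-through extensions into the next $m$
  downstream units at $r p^m (1-p)$ (read-through probability $p$, default
  0.2 — a free parameter, no quantitative rate is published — capped at one
  lap with the tail mass absorbed in the last extension). A tiling of
  low-weight fragments on both strands (rate `antisense_rate` = 0.02
  relative to the mean operon rate) models pervasive antisense/intergenic
  transcription, so combined-strand coverage support is the whole genome by
  construction. Randomness enters only at read sampling, which makes the
  manifest quantities (expected per-gene counts under the 50% rule,
  expected per-base coverage) exact closed forms.
* **Reads.** Constant fragment length (default 180 bp), reads 100 bp,
  proper dUTP pairs with correct FLAGs, per-base errors at
  $\varepsilon$ = 0.001. Injected C-to-U edits flip the base independently
  per covering fragment with probability equal to the site's efficiency.
* **Inversions.** Endpoints are midpoints of distinct intergenic spacers
  paired in coordinate order, so inversions are endpoint-disjoint, contain
  whole genes, and induce a well-defined block permutation; $k$ such
  inversions are recovered as DCJ distance exactly $k$.
* **Coupled study.** For the headline-recovery experiment a chain of
  species is produced by successive inversions (2 per speciation step,
  giving pairwise PR in the single digits, comparable to real conifer
  pairs); under the coupled scenario each inversion perturbs the
  log10-expression of the genes it relocates (sd 0.6, against a
  between-gene baseline sd of 0.8 and measurement noise sd 0.1 — effect
  sizes fixed a priori as "relocation rescales a gene's transcription by
  roughly 2–4-fold"), so expression divergence accumulates with
  rearrangement count. Under the uncoupled null every species instead
  receives one independent, exchangeable perturbation of matched
  magnitude, so $r_{expr}$ carries no information about PR; the null
  rejection rate of the plain Pearson test stays near nominal despite the
  shared-species dependence between pairs, and this calibration is itself
  an acceptance test. TPM tables come from Poisson count sampling at depth
  2×10⁵, so the statistics are exercised through the package's own
  counting and correlation modules. Read-level sampling is deliberately
  skipped here: the tested statistic is downstream of counts, and 120
  seeded read simulations would dominate the suite's runtime without
  changing what is measured.

## Numerical and degenerate-input choices

* Zero-variance correlation input raises an explicit undefined-correlation
  error rather than returning NA; $|r| = 1$ yields p = 0 flagged
  `degenerate`.
* An all-zero count vector yields all-zero TPM (the 10⁶ normalization
  applies only when any count is positive).
* Window transform with an all-zero strand returns all-zero scores.
* Mantel permutations redraw identity shuffles (an identity draw carries no
  information and would bias p upward at small $S$); p uses the add-one
  estimator, bounded below by $1/(n_{perm}+1)$.
* All RNG flows through explicit seeds; derived per-stage seeds stay below
  2³¹; same config ⇒ byte-identical outputs (tested).

## What a green test establishes — and what it does not

The synthetic world contains the features the methods must cope with
(stranded polycistrons, read-through, antisense background, partial
editing, rearranged gene orders) but not everything real data brings: no
indels or spliced alignments (CIGAR `N` is rejected as out of scope), no
quality-score structure or position-dependent error profiles, a single
fragment length rather than an insert-size distribution, no rRNA/tRNA
loci, no IR-mediated isomerization, and uniform nucleotide composition.
Consequently the suite establishes correctness of the statistics and
transforms *given aligned reads*, not robustness to alignment artefacts.
Fragment sampling within transcript intervals also reproduces the real
end bias of RNA-seq — terminal genes of a transcription unit lose up to a
fragment length of read placements — which is why TPM rank recovery is
validated against the manifest at realistic CDS lengths rather than
asserted as exact.

## Known limitations

* Read simulation is linear: fragments never span the origin, and
  read-through extension truncates at the sequence end instead of wrapping.
* An operon split by an inversion keeps its old rate in both derived
  transcription units; promoter-loss effects on the downstream half are
  not modelled (this is conservative for the coupled study: it weakens,
  never fabricates, the rearrangement–expression coupling).
* The star alignment projects all species onto the centre sequence; sites
  falling in centre-relative insertions cannot be shared.
* `find_synteny_blocks()` requires single-copy genes in all species;
  duplicated genes (IR copies, dispersed repeats) are excluded from
  anchoring by design.
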