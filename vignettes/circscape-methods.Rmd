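---
title: "Methods: circRNA characterization from back-splice junction calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circRNA characterization from back-splice junction calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and rationale

`circscape` characterizes plant circular RNAs (circRNAs) downstream of
back-splice junction detection. It deliberately does **not** detect
circRNAs from raw reads: tools such as CIRIquant and find_circ do that
well, and their call tables — chromosome, junction coordinates, strand,
junction-read counts per sample — are this package's input. Everything
after that point is covered: consensus filtering across two callers,
classification against a gene annotation, conservation scoring,
flanking-intron repeat and DNA-methylation characterization, expression
quantification with differential testing, and assembly of a
circRNA–miRNA–mRNA sponge network.

All internal coordinates are 0-based half-open. GFF3 (1-based closed) and
BED (0-based half-open) are converted exactly once, on ingest or on
write; a single convention eliminates the off-by-one class of bugs.
A circRNA is identified throughout by the key
`"chrom:start|end:strand"`.

# Consensus filtering

Back-splice callers disagree substantially, so the high-confidence set is
the **intersection** of the two callers' keys, filtered further by:

* genomic span ≤ 10 kb (very long spans are nearly always artifacts of
  mis-paired junctions);
* maximum per-sample junction-read support ≥ 2, **inclusive**. Junction
  support distributions are dominated by sites seen in exactly two reads;
  an exclusive "> 2" rule would discard the mode of the distribution, so
  the inclusive reading is used and the threshold is exposed as a
  parameter.

Per-sample reads from the two callers are merged by taking the
**maximum**, not the sum: both callers counted the same physical reads,
and summing would double-count. Keys must match exactly; there is no
fuzzy ±1 junction matching (a `boundary_tol` flag exists in the
classifier for imprecise callers, defaulting to 0).

"Length" in the 10 kb rule means genomic span. Intronic and intergenic
circles have no splice model, so a spliced length is undefined for them;
using the span applies one rule uniformly.

# Classification

Each consensus circle is assigned exactly one type by a first-match
cascade against collapsed gene models:

1. **exonic** — both junction ends lie on or within exons of one
   same-strand gene;
2. **intronic** — the circle lies entirely inside one intron of a
   same-strand gene;
3. **antisense** — the circle overlaps annotation only on the opposite
   strand;
4. **intergenic** — no gene overlap.

The priority ordering mirrors both the biogenesis expectation (exon
circularization dominates in plants) and standard practice. A circle that
touches a same-strand gene without satisfying rules 1–2 (e.g. a junction
end in mid-intron with the other end in an exon) falls through to
intergenic with no parental gene; such calls do not arise from the
synthetic generator and are rare in practice, but the behavior is a
documented limitation rather than a fifth type.

Multi-transcript genes are collapsed to the transcript with the largest
total exon length (ties: larger span, then transcript id) — annotations
rarely say which isoform templates a circle, and the longest chain is the
most permissive host for junction matching. The parental gene of a circle
compatible with two same-strand genes is the one covering the larger
fraction of the circle, ties broken lexicographically. "Antisense" is
defined by any opposite-strand overlap, not by junction ends on the
antisense gene's exons; the stricter reading would reclassify a handful
of calls as intergenic and is not what callers report.

Flanking introns of an exonic circle are the introns of the parental gene
immediately upstream and downstream of the circularized exon block.

# Conservation

Two complementary routes score conservation against a user-supplied
subject database (e.g. a PlantcircBase-style per-species FASTA export).

**Junction-anchored alignment.** The junction sequence joins the last
`min(100, L)` bases of the circle to its first `min(100, L)` bases —
the sequence a read crossing the back-splice junction traverses. For
minus-strand circles the circle is reverse-complemented first, so the
junction is always in transcript orientation; for circles shorter than
100 bp both segments are the entire circle, i.e. the junction sequence
walks the circle twice around the joint. Alignment is word-seeded
(default word 11) gapped local alignment with match +1, mismatch −2, gap
open −5, gap extend −2 (a gap of length *g* costs 5 + 2*g*), and hits are
thresholded at a Karlin–Altschul E-value of 1e−5 with K = 0.711,
λ = 1.37 — constants stated so results are reproducible bit for bit. A
hit only counts as *conserved* when the aligned query span extends
across both junction-adjacent bases: similarity of one flank alone
tests linear-sequence similarity, not conservation of the circle joint.

**k-mer profiles.** Alignment-free similarity uses the vector of all
4^k k-mer counts, length-normalized to counts per kb and z-scored per
component against a background set. k defaults to 6: 4096 components keep
the profile dense at the 200 bp junction-sequence scale while remaining
informative; k is a parameter. The standardization background is the
union of query and subject sequences in the comparison — a choice that
makes the score depend only on the data at hand rather than on an
external corpus. Components with zero background variance are set to 0.
Two profiles are compared by Pearson correlation; a query is conserved
when some subject exceeds r > 0.2, **strictly** — r equal to the cutoff
is not conserved. Zero-variance profiles yield NaN with an `undefined`
flag rather than a silent 0.

# Flanking-intron features

Comparisons are always against a background of genes with no detected
circRNA, sampled uniformly without replacement to the size of the
foreground set, deterministically given a seed.

* **Repeat fraction** of an interval is the base-pair fraction covered by
  the union of overlapping repeat intervals (overlaps merged first, so a
  nested repeat cannot push the fraction past 1).
* **Weighted methylation** of an interval is Σ methylated reads /
  Σ total reads over its covered cytosines — read counts pooled, not
  per-site means averaged, so deeply covered cytosines carry more weight
  and the measure is additive over disjoint intervals. Sequence contexts
  (CpG/CHG/CHH) are pooled by default; per-context filtering is a
  parameter.
* The **metagene profile** scales each interval body to 20 bins plus
  2000 bp flanks split into 10 bins per side (all three are parameters,
  not claims), pooling read counts across intervals per bin. Intervals
  are treated as unstranded.
* **Group comparisons** use a two-sided Welch t-test, by default on
  log10-transformed values for length-like features. Welch is preferred
  over the pooled-variance Student test because group variances of
  length data are not plausibly equal; the pooled test is available via
  `var_equal = TRUE`, and a Mann–Whitney p-value is always reported
  alongside as a robustness column. Non-positive values under the log
  transform are shifted by +1 with a warning.

The "random intron background" for repeat and methylation comparisons is
the introns of the sampled no-circRNA genes, not arbitrary genomic
windows — arbitrary windows would confound intron-ness with
circularization.

# Expression and differential expression

circRNA abundance is **RPB**: junction reads per billion clean reads,
`reads / (clean_reads / 1e9)`. Expression classes are low (< 100),
medium (100–500) and high (> 500) RPB; the published bin edges leave
(500, 501) unassigned, and since RPB is continuous the gap is closed as
"high > 500". Gene abundance is standard FPKM.

The differential test is written for junction-read counts: low,
overdispersed, few replicates. Counts are scaled to the geometric-mean
library size; a common negative-binomial dispersion is estimated by the
method of moments on the normalized counts (floored at 1e−4); each
feature is then tested by a **two-sided exact NB test on the group
sums** (a sum of n iid NB(μ, φ) variables is NB(nμ, φ/n)): conditional
on the total, the p-value sums the probabilities of all splits no more
likely than the observed one. With a single replicate per group the test
falls back to a Poisson (conditional binomial) exact test with a
warning. log2 fold changes use a pseudocount of 0.5 on the normalized
scale. Benjamini–Hochberg adjustment is applied across features.

Significance calls use |log2FC| > 1 with raw p ≤ 0.05 for circRNAs (the
low counts make adjusted-p calls needlessly conservative at typical
circRNA depth) and BH-adjusted p ≤ 0.05 with fold ≥ 2 for genes; both
are parameters. Timecourse designs are analyzed as each treatment
timepoint versus the reference, combined per feature by the smallest
p-value. In a held-out check against the edgeR exact test at a fixed
common dispersion the p-values agree to Spearman ρ > 0.99; edgeR is used
only as a cross-check in the test suite, never as the implementation.

Functional enrichment is the flat one-sided hypergeometric
(upper-tail) test per term with BH adjustment; the term map is taken as
given, with no ontology-graph propagation.

# miRNA sites and the sponge network

Target prediction slides the reverse complement of the mature miRNA
along the target, allowing at most one gap. Per aligned position,
numbered from the miRNA 5′ end: match 0, G:U wobble 0.5, mismatch 1.0,
gap 2.0, all doubled at positions 2–13 (the seed-critical region). A site
is reported when the summed expectation is ≤ 5.0, with at most 4
mismatches and no run of more than 2 consecutive mismatches in the seed
region. These are the published default constants of the plant
small-RNA target-prediction tools this scheme follows; all are exposed
as parameters. Expectation 0 occurs iff every position pairs, and any
single edit away from perfect complementarity increases it.

circRNA sites are predicted on the **circular junction sequence**, so
sites spanning the back-splice joint — invisible to any linear scan —
are detectable; site detection on the junction sequence is a strict
superset of detection on the two flanks separately. mRNA sites are
predicted on the full spliced transcript (the data rarely resolve CDS
vs UTR binding for plant miRNAs, which cleave coding regions freely).
Sponge edges do not require the binding site to overlap the junction
itself — anywhere on the junction sequence counts.

The network keeps circ–miRNA edges whose circRNA is differentially
expressed and miRNA–mRNA edges whose mRNA is differentially expressed,
then prunes miRNAs lacking either edge type. The result is tripartite by
construction; multiple sites on one pair collapse to the best (lowest)
expectation. Export is a plain edge list plus node attribute table,
loadable by any graph viewer.

# The synthetic-data generator

`simulate_bundle()` emits a complete input bundle with planted ground
truth, so every stage is testable with no external data. What it
emulates, and its defaults:

* a compact two-chromosome genome (2 × 220 kb) with ~50 non-overlapping
  multi-exon genes (3–7 exons of 120–400 bp, introns 300–1500 bp);
* planted circRNAs of all four types — 28 exonic, 8 intronic, 3
  intergenic, 1 antisense — constructed to satisfy the classification
  cascade unambiguously (exonic circles sit exactly on exon boundaries
  of interior exon blocks, so flanking introns always exist);
* two caller tables sharing `round(overlap_fraction × n_circ)` keys
  (default overlap 1) plus caller-specific decoy calls;
* junction reads drawn negative-binomially (mean 60, dispersion 0.1),
  because downstream differential analysis presumes overdispersed
  counts; 5 timepoints × 3 replicates, with the first timepoint as the
  untreated reference, mirroring a chilling timecourse (0 h, 6 h, 12 h,
  24 h, 7 d);
* planted 4-fold changes on 8 circRNAs (five up, three down) and 12
  genes, applied at every treatment timepoint;
* repeat intervals of class LTR (the dominant class in plant flanking
  introns) covering 35% of circ-flanking introns versus 8% of background
  introns, with occasional LINE/DNA intervals in the background for
  class-breakdown realism;
* a per-cytosine methylation track: true cytosine positions of the
  generated genome, coverage ~ Poisson(20), per-site levels ~ Beta
  around 0.65 in circ-flanking introns versus 0.25 elsewhere,
  methylated reads ~ Binomial(coverage, level) — exactly the inputs the
  weighted-level estimator consumes;
* 8 random 21-nt miRNAs and 5 sponge triples whose miRNA reverse
  complements are embedded verbatim across the back-splice junction of
  a DE circRNA (half before, half after the joint) and inside an exon
  of a DE target gene;
* a conservation subject set: mutated copies (5% substitutions) of six
  planted junction sequences under fictitious species labels, plus
  unrelated random sequences.

Everything is deterministic given the seed — two runs produce
byte-identical files — and a seed is mandatory; there is no silent
default. What the generator does **not** emulate: read-level errors and
mapping ambiguity, isoform complexity, correlated methylation along a
chromosome, genuine phylogenetic divergence, and realistic genome-scale
repeat landscapes. Passing tests on this bundle therefore demonstrate
correctness of the analysis logic under its stated statistical model,
not performance on real libraries.

Problem sizes in the tests (a ~40-circle bundle, 2000-feature
calibration simulations, 1000-interval oracle checks) were chosen as the
smallest sizes at which the statistical assertions are stable across
seeds.

# Numerical choices and degenerate inputs

* Jaccard overlap of two empty call sets is undefined; it is reported as
  0 with a warning flag rather than NaN.
* Zero-variance k-mer profiles and uncovered intervals yield NaN with an
  explicit flag.
* The exact NB test enumerates the full conditional distribution; for
  totals above 20 000 the enumeration is restricted to a 1e−14 quantile
  window, which changes p-values by less than the enumeration's own
  floating-point noise.
* Dispersion estimates are floored at 1e−4 to keep the NB well-defined
  for underdispersed features.
* `consensus_filter` is idempotent, and its output size always equals
  the intersection size minus length and support failures.
* Report generation is deterministic given (inputs, config, seed);
  re-running `run_all()` with the same configuration reproduces the
  JSON report byte for byte.

# Known limitations

* No isoform-resolved internal structure of circles: lengths are genomic
  spans.
* No reverse-complement pairing analysis of flanking introns (rarely
  observed in plants, and no standard procedure exists).
* No RNA secondary-structure or degradome support in target prediction.
* The alignment conservation route is not a general BLAST replacement;
  it is tuned to 200 bp junction sequences.
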