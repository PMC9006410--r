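---
title: "lncScout: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncScout: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncScout)
```

# Scope

lncScout re-implements, as a tested and reusable pipeline, the downstream
computational analysis of a two-state insect brain RNA-seq study design:
novel long non-coding RNA (lncRNA) discovery from assembled transcript
models, differential expression between a virgin and a mated reproductive
state, lncRNA:mRNA co-expression networks, and RNA:DNA:DNA triplex target
prediction. Upstream read processing (trimming, alignment, assembly,
quantification) is out of scope: the pipeline starts from a reference
annotation (GTF), assembled transcript models (GTF), genome sequence
(FASTA) and per-library count tables.

Because the package is exercised on synthetic data, every stage has a
ground truth, and the test suite asserts recovery of planted structure as
well as exact agreement of each computational kernel with an independent
naive re-implementation.

# Transcript classification

Assembled transcripts are compared with the reference annotation and
assigned a single-letter class code in the gffcompare tradition. The
subset of the code alphabet needed for lncRNA discovery is implemented:
`=` (identical exon chain), `o` (any exonic overlap), `i` (contained in a
single reference intron), `y` (a reference transcript contained in a
query intron), `p` (a possible run-on fragment starting within 2,000 bp
downstream of a reference end, strand-aware) and `u` (intergenic).

Three choices were genuinely open and are fixed as follows:

* **Precedence** is `=`, `o`, `i`, `y`, `p`, `u`. Exonic overlap always
  disqualifies a candidate, which matches the intent of the downstream
  filter: only transcripts from non-coding loci should survive.
* **Strand for codes `i`/`y`** is ignored by default
  (`strandAwareIntron = FALSE`): an intronic transcript on either strand
  is a candidate regulatory RNA, and assembly strand assignment of
  single-exon fragments is unreliable. The behaviour is a flag.
* **Unstranded queries** (`*`) are evaluated on both strands and receive
  the most "overlapping" code under the precedence order.

Candidates keep codes `i`, `y`, `p`, `u` with a spliced (exonic, not
genomic-span) length of at least 200 nt; the bound is inclusive, following
the "minimum length of 200 nt" convention for lncRNAs.

# Coding potential

The coding-probability model follows the CPAT design: a logistic
regression on four sequence features.

1. **Longest ORF length** (nt). ORFs run ATG to stop (stop included) on
   the three sense-strand frames; assembled transcripts are taken to be
   strand-resolved, so the reverse strand is not scanned.
2. **ORF coverage**: ORF length divided by transcript length.
3. **Fickett TESTCODE**: positional periodicity (max/min + 1 of the
   per-phase counts of each base) and base composition, converted through
   the published lookup tables and weighted.
4. **Hexamer usage bias**: mean log-ratio of in-frame (step 3) hexamer
   frequencies between a coding and a noncoding training set, with
   additive smoothing.

The regression is fit by iteratively reweighted least squares on
internally standardised features (convergence when the largest
coefficient change is below 1e-8, at most 100 iterations); coefficients
are reported on the original scale. Perfect separation — common when the
composition gap is large — triggers a ridge penalty of 1e-4 on the
standardised features and is flagged in the model metadata.

The probability cutoff is calibrated by evaluating every observed score
as a threshold ("coding if probability >= t") and maximising accuracy,
ties resolved toward the smallest threshold; ROC points and the trapezoid
AUC are reported. On perfectly separated synthetic training sets the
calibrated cutoff can sit next to 1; this is expected, and an external
cutoff can be supplied instead (`runPipeline(cutoff = ...)`), mirroring
the use of a benchmark-derived threshold.

Candidates below the cutoff are still discarded when they contain a
complete ORF of at least 100 codons (peptide length, stop excluded,
inclusive bound — the conventional minimum of ORF-calling tools; a
literal "any ORF" rule would discard nearly every transcript) or when
they appear in a user-supplied table of precomputed homology hits. No
homology search is run by the package: the filter logic, not the search,
is the modelled step.

# Differential expression

The DE stage is a deliberately compact negative-binomial Wald pipeline,
accepted by its operating characteristics rather than by numerical
equality with any specific tool:

* **Prefilter**: keep genes with nonzero counts in at least 3 samples of
  at least one group. The underlying verbal rule ("zero read counts in
  less than 3 samples") is grammatically ambiguous; this reading keeps
  genes that are reliably observed somewhere and is recorded as an
  interpretation, not as the original intent.
* **Size factors**: median-of-ratios against the per-gene geometric mean.
* **Dispersion**: method-of-moments on normalised counts with the group
  effect removed, floored at 1e-8, then shrunk halfway in log space
  toward a log-linear mean-dispersion trend. The 50/50 shrinkage is
  geometric (log-space) because dispersions act multiplicatively.
* **Wald test**: per-gene NB log-link model with the group coefficient,
  fit by IRLS with the dispersion fixed, vectorised across genes (all
  genes share the design). Non-converged genes get `NA` p-values and a
  flag. log2 fold change is mated versus virgin.
* **BH-FDR** via the standard step-up procedure; calls use
  |log2FC| >= 1 (inclusive) and FDR < 0.01 (strict).

Technical runs are treated as samples for testing — the convention of the
emulated design, which quantified 32 libraries as 16 per group — but are
averaged per biological replicate before the z-transform and
average-linkage hierarchical clustering of DE genes. The test suite
checks the size factors and the fixed-dispersion Wald fit against DESeq2
as an independent reference implementation, and checks power (>= 90% at
|log2FC| = 2, baseMean >= 100, dispersion 0.1, n = 16/group), empirical
FDR (<= 5%) and the null call rate (<= 2% at FDR < 0.01).

A caveat worth stating: when the 16 libraries per group are 4 biological
replicates x 4 technical runs, they are block-correlated, and nominal
p-values computed at n = 16 (Wald or Spearman) are anticonservative.
That is an artifact of the treat-technical-runs-as-samples convention
itself, so the operating characteristics above are measured on designs
with 16 independent libraries per group, while the end-to-end synthetic
study keeps the 4 x 4 hierarchy.

# Co-regulation networks

All DE-lncRNA x DE-mRNA pairs are tested within each group's samples
separately with Spearman's correlation (average ranks for ties; Pearson
on ranks; two-sided p from the t approximation with n - 2 degrees of
freedom, exact permutation enumeration available for n <= 8). Edges
require |rho| > 0.8 and p < 0.01, both strict, as printed thresholds;
no multiple-testing correction is applied to edge p-values by default —
a faithful but liberal convention — and a BH flag is available
(`buildNetwork(adjust = TRUE)`). Retained edges carry their sign, are
cross-tabulated by DE direction into per-group category proportions, and
can be reduced to per-node ego networks.

# Triplex prediction

The triplex stage predicts RNA:DNA:DNA interactions under Hoogsteen
base-pairing rules: pyrimidine motif (U.A, C.G; parallel), purine motif
(A.A, G.G; antiparallel) and mixed motif (U.A, G.G; both orientations),
with both DNA strands considered as candidate purine strands. A match is
a maximal ungapped TFO/TTS segment satisfying all of: length >= 15 nt
(the length parameter is read as a lower bound — a maximum-length reading
would forbid nearly all reported triplexes), error rate strictly below
20% (a 15-mer admits at most 2 errors), at most 3 consecutive errors
(reading "constitutive errors" as consecutive), and guanine fraction of
the purine strand of at least 20% (inclusive). `N` never matches and
counts as non-G/non-A in content fractions. Maximality means no one-base
extension on either side stays within the constraints; matches are
deduplicated by (TFO, TTS, motif, orientation).

The scan kernel is implemented in C++ (per-diagonal prefix sums with a
run-of-errors pruning bound); the test suite holds it to exact set
equality with a naive pure-R enumerator over all windows of all
diagonals. TTS intervals can be lifted to genome coordinates, annotated
with the exon/intron/flank feature of a chosen gene (numbered in
transcript orientation, so "intron1" is the first intron of the mRNA),
and merged into clusters (overlap-or-adjacent within a gap parameter)
that report member counts and the GA fraction of the merged interval on
its majority purine strand.

# The synthetic study generator

`simulateStudy()` produces every pipeline input with ground truth:

* **Genome and annotation**: 4 scaffolds of 400 kb; 40 reference mRNAs
  (3-6 exons, codon-biased ORF of >= 120 codons embedded in UTRs) and 20
  reference lncRNAs (2-3 exons, ORF-free uniform-composition sequence).
  Coding sequence uses a first-order codon-bias model whose strength is a
  config knob; the composition gap is what makes the coding-potential
  model learnable, and synthetic noncoding sequence is more uniform than
  real intergenic sequence, so the learnability results say the model
  machinery works, not that real-data accuracy will match.
* **Novel plants**: single-exon class-i (inside an mRNA intron), class-p
  (50-1,500 bp downstream, strand-aware), class-u (>= 2.5 kb from any
  reference) and exon-overlapping decoys, plus two-exon class-y plants
  whose intron wraps a compact reference gene. Class-y transcripts cannot
  be single-exon by definition of the code, so the "novel lncRNAs are
  monoexonic" property holds for every other cohort. Planted i/y/p/u
  transcripts receive ORF-free sequence written into the genome; decoys
  keep the underlying (partly coding) sequence, as real assembly
  artifacts over coding loci would.
* **Counts**: a Gamma-Poisson hierarchy. Each biological replicate draws
  a latent expression `lambda ~ Gamma(1/alpha, alpha * mu)` per gene (the
  marginal is NB with mean `mu`, dispersion `alpha`); each technical run
  is a Poisson resample of `s * lambda` with a per-library size factor
  `s ~ U(0.7, 1.4)`. The design is 2 groups x 4 biological x 4 technical
  = 32 libraries. Planted fold changes multiply the mated mean by
  `2^log2FC` (default magnitude 2).
* **Correlated pairs**: planted DEL:DEG pairs draw their latent
  expression from a shared Gaussian copula per library. The target is the
  Spearman correlation of the resulting counts, so the copula Pearson
  correlation is set to `2 sin(pi rho / 6)` (the normal-score map)
  inflated by a first-order correction for Poisson counting noise,
  `sqrt(prod(1 + 1/(alpha mu)))`, capped at 0.999. Exact NB Spearman
  targeting is analytically awkward; this calibration reaches the target
  to within a few hundredths for well-expressed genes and is validated
  empirically. For weakly expressed genes (mu near the Poisson-noise
  regime) the cap binds and the realised correlation falls below target,
  which is why the retention checks plant their focal pair at mean 400 —
  the expression regime of the focal transcripts such networks are
  reported for.
* **Triplex plant**: a GA tract (40 nt, purity 1.0 by default) written
  into the first intron of a plus-strand host mRNA, and its
  pyrimidine-motif parallel TFO written into the middle of a chosen
  novel lncRNA; impure tract positions get a guaranteed-mismatching base
  so that purity maps directly onto the match error rate. The host mRNA
  is planted as repressed in the mated state with a strong negative
  copula link to the lncRNA, mirroring the repressive-triplex hypothesis
  the pipeline is meant to surface.

Everything is deterministic given the seed; the problem sizes above keep
a full synthetic study plus a complete pipeline run around a minute on a
single CPU, and the acceptance checks (2,000-gene DE designs, 10-50
seeds, 500 oracle scan pairs) within a few minutes each.

# What the pipeline reports

`runPipeline()` executes classify, codepot, de, corr and triplex in
order, writing each stage's TSV before the next starts, plus a JSON run
report with parameter echoes and per-stage counts (kept + rejected =
input at every stage). The triplex stage scans, for each mated DEL, the
loci of its negatively correlated DEG partners — retained edges plus the
top-3 most anti-correlated DEGs, a shortlist that does not let a
borderline edge p-value hide a strong repressive target.
`evaluateAgainstTruth()` scores any synthetic run: identification
sensitivity/precision, DE sensitivity/precision, planted-pair recall and
planted-tract recovery, with `NA` where a rate is undefined.

# Known limitations

* The class-code alphabet is the subset needed here; codes such as `c`,
  `j`, `e`, `s`, `x` are not assigned.
* The DE pipeline has no Cox-Reid dispersion estimation, shrinkage of
  fold changes, outlier handling or multi-factor designs.
* Edge p-values are raw by default (see above).
* The simulated genome has no repeats, GC heterogeneity or splice-site
  motifs; decoy coding potential comes only from overlapping planted
  ORFs.
* Triplex scoring is purely combinatorial (length - errors); no
  thermodynamics.
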