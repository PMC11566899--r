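---
title: "Methods: models, synthetic worlds and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, synthetic worlds and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`islandmeth` re-implements, as a tested package, the analysis chain of a
whole-blood WGBS study of an outbred mammalian cohort: site-level
quality control and β computation, de novo CpG-island (CGI) detection,
breed-DMR and methylation-variability calling, feature/repeat
enrichment, and a sequence-only embedding of CGI DNA. This vignette
records the models, the assumptions behind the defaults, and the design
choices made where the underlying description was genuinely open. It
states no empirical result that the test suite does not itself compute.

## Coordinates and formats

All internal coordinates are 0-based, half-open (`[start, end)`), the
BED convention; the single 1-based surface is the methylation count
table dialect (a 5-column TSV: chrom, 1-based position of the cytosine,
strand, methylated count, total count), chosen as the least common
denominator of allc/CX-report styles. A site absent from a sample's file
means *no data*; it is never encoded as `0/0`. Readers reject rows with
`meth > total` and name the offending line.

## Site-level processing

A CpG site is the strand pair (forward C at *p*, reverse C at *p*+1);
`collapse_strands()` sums the pair's counts at *p*, and a site covered
on one strand keeps that strand's counts. β = meth/total per cell.

The depth filter retains a site iff `10 <= total <= 500` in **every**
sample and every sample has data. Both bounds are read as strict
removals outside the closed interval ("fewer than 10", "more than
500"). Whether the ceiling applied per sample or to summed depth was
ambiguous in the usual phrasing of the rule; per-sample was chosen for
consistency with the presence filter. SNP masking removes a CpG if a
variant hits *either* base of the dinucleotide: a variant at the G
corrupts the reverse-strand call just as one at the C corrupts the
forward call. Spearman correlations use average ranks; a zero-variance
sample yields `NA` with a warning rather than a fabricated value.

Gene meta-profiles rescale each gene body to 100 bins with 2 kb flanks
in 40 bins each (methylation transitions concentrate within ~2 kb of
gene ends); minus-strand genes are mirrored so bin 0 is always 5′.
Genes shorter than the bin count are skipped with a warning rather than
up-sampled.

## CGI detection

Two printed criteria sets are bundled: Gardiner–Garden–Frommer
(GC > 0.5, CpG O/E > 0.6, length > 200 bp; all strict) and Takai–Jones
(GC ≥ 0.55, O/E ≥ 0.65, length ≥ 500 bp; all inclusive). The detection
*algorithm* behind public CGI tracks is not printed anywhere usable, so
the package defines a deterministic, oracle-checkable scan:

1. slide a window of the minimum admissible length in 1 bp steps;
   windows meeting all thresholds (and containing no N) are seeds;
2. merge overlapping/adjacent seeds;
3. greedily trim each merged region until it qualifies — removing the
   end whose removal raises the CpG O/E more, ties trimming the 3′
   end — falling back to the leftmost qualifying seed window if greedy
   trimming bottoms out;
4. extend 1 bp at a time within the merged region while the island
   keeps qualifying (side raising O/E more first; ties extend 5′).

Outputs are disjoint, each satisfies its criteria (re-asserted in
tests), and each is maximal under 1 bp extension within its seed
region. The test suite proves equivalence against a naive
quadratic-time re-implementation on hundreds of random sequences.

One consequence worth stating plainly: composition criteria are not
base-sharp. A pure-CpG run flanked by AT sequence yields an island
*wider* than the run, because mixed windows still clear GC > 0.5. Tests
therefore assert coverage and maximality bounds, not exact planted
boundaries, and externally produced CGI BED files can be supplied
wherever detection would be used. UCSC-style post-processing
refinements are deliberately not replicated.

CGI methylation classes follow the printed thresholds on the island
mean of per-site mean β: unmethylated `[0, 0.1)`, low `[0.1, 0.5]`,
high `(0.5, 1]`; islands with no filtered CpGs are flagged unscorable
rather than silently classified.

## DMRs and variable regions

Breed DMCs come from a per-site one-way fixed-effects ANOVA
(F = inter-breed over intra-breed variance) with BH-FDR `q < 0.05`
(strict). The merge rule "merged if ≤ 100 bp" is read as *chaining*:
consecutive significant sites at most 100 bp apart (inclusive) belong
to one region, because regions longer than 100 bp are plainly expected
downstream; regions need ≥ 5 members. DMRs are usually stated as a
"minimum of five" sites but variability regions as "more than five";
both are implemented as ≥ 5 behind one `min_count` parameter. Degenerate ANOVA
sites (zero within-group variance with non-zero between) are assigned
p = 0 and flagged, never dropped silently.

Variable regions take the top 1% of across-sample SDs (sample SD,
n−1). The threshold is a plain order statistic — the k-th largest SD
with k = ⌈0.01·n⌉, no interpolation — so the printed cut of any real
dataset is data-specific and not a constant of the method. Region-level
sex/breed ANOVA and age Spearman tests run on the per-sample mean β
over member CpGs (the region-mean reading; per-CpG aggregation was the
other candidate), with BH applied *per test family* across regions and
association flagged at adjusted p < 0.01.

Injury-style case/control testing is a per-site logistic regression
(outcome ~ β + covariates, e.g. age) with a Wald test on the β
coefficient. Separated or non-converged fits are flagged and excluded
from FDR rather than given fake p-values. The Wald test is asymptotic:
at a cohort of ~19 it is visibly conservative (its null p-values fail
KS uniformity), which is a property of the test, not a bug; the
calibration criterion therefore runs the null at n = 100 where the
asymptotics hold, and the conservatism at small n is the reason the
package reports, rather than hides, the flag counts.

## Enrichment

Feature enrichment of high-SD CpGs uses the analytic exact binomial
with background proportion p₀ = (eligible sites in feature)/(eligible
sites) — the infinite-resampling limit of "compare to random CpG
sets" — with a seeded Monte-Carlo mode available for fidelity.
Sidedness was not printed; the two-sided doubled-smaller-tail (capped
at 1) is used, with the direction reported. Repeat-subfamily enrichment
within CGI classes is one-tailed (upper) binomial per (subfamily,
class), BH-adjusted jointly, after omitting subfamilies overlapping
fewer than `min_regions` (default 100) CGIs; overlap means ≥ 1 bp, not
base-pair fractions. Gene-set tests are exact hypergeometric upper
tails over user-supplied two-column (set, gene) annotation — no
database downloads.

## The synthetic world

The generator's defaults state one world, chosen once: a CpG-depleted
background at GC 0.41 (a typical mammalian genome-wide GC) with 0.01
CpG/bp (O/E ≈ 0.24), islands of 500–1500 bp at GC ≥ 0.65 and O/E ≥
0.75, high global methylation (background β 0.8) with unmethylated
islands (β 0.05) and 30% of islands planted methylated — echoing the
observation that composition-defined islands include a substantial
methylated fraction. The cohort is 3 + 3 + 13 samples across three
breeds, ages 3–14 years, at 70× intended depth; depth is
negative-binomial (overdispersion 0.05) so the <10/>500 filters trigger
naturally, and counts are beta-binomial (precision 50) because real
WGBS is overdispersed relative to binomial. Island sequences are built
at fixed base composition with CpG counts steered by
composition-preserving swaps, so realized GC is exact and realized O/E
sits just above target. All randomness flows from one seed through
named substreams (genome, counts, annotations, metadata), so any stage
can be regenerated independently and byte-identically.

What the generator does **not** emulate: read-level artifacts,
bisulfite conversion failure, alignment bias, chromosome-scale
composition structure, linkage between SNPs, or realistic repeat
sequence content (repeats are labeled intervals, not sequence models).
A green planted-truth test therefore establishes that the statistics
recover effects of the stated size under the stated noise — not that
the pipeline is robust to artifacts it never saw.

## Sequence embedding

The tokenizer is native merge-based BPE over A/C/G/T with the most
frequent adjacent pair merged until the vocabulary is full or no pair
repeats; equal-frequency ties take the lexicographically smallest
(left, right) string pair, which makes training deterministic across
platforms (the usual tools do not specify this). Tokenization applies
merges in recorded order and is lossless by construction (asserted over
thousands of random sequences). Sequences exceeding 512 tokens are
dropped — strictly "more than", so exactly-512 is kept.

The encoder is a pre-LayerNorm bidirectional transformer (learned
absolute positions, multi-head dot-product attention, ReLU feed-forward
blocks) trained on masked-token cross-entropy only — no next-sentence
objective, hence no CLS/SEP tokens, and pooling is the arithmetic mean
of final-layer token vectors. Masking selects 15% of positions
uniformly; all selected positions become `[MASK]` (the simpler reading
of "randomly masked"), with the BERT 80/10/10 convention behind a flag.
Optimization is Adam (1e-3) with gradient accumulation over 8-sequence
batches. The full-scale configuration (768 dims, vocab 8192) is
expressible; the desk-scale default (2 layers, 4 heads, 64 dims, vocab
512, 20 epochs) trains the 600-sequence acceptance corpus on one CPU in
minutes. The entire forward/backward pass is hand-written R matrix
algebra and is verified against finite-difference gradients in the test
suite. Training is deterministic given the config seed.

t-SNE is the exact O(n²) algorithm (perplexity bisection, early
exaggeration ×12 for the first quarter of iterations, momentum
0.5→0.8), deterministic given its seed, and adequate for the corpus
sizes embedded here. Class separation is scored on full-dimensional
embeddings: mean silhouette between the unmethylated and high classes
(low excluded and reported separately) and a stratified 5-fold
linear-probe AUC. The probe is a ridge-regularized least-squares linear
scorer rather than an iteratively fitted logistic model, because
embeddings of separable classes make maximum-likelihood logistic
regression diverge; the AUC of a linear scorer is the quantity of
interest and is well-defined either way.

## Numerical and degenerate-input conventions

- BH-FDR is the exact step-up formula, verified against a quadratic
  from-the-definition oracle and `p.adjust` to 1e-12.
- Exact binomial/hypergeometric tails are verified against term-wise
  log-space summation to 1e-10 up to n = 1000.
- ANOVA uses sums of squares with a relative 1e-12 tolerance for
  zero-variance detection; k = 2 reproduces the pooled-variance t² to
  1e-10.
- Empty inputs (no sequences, no SNPs, no qualifying windows, empty
  BED) return typed empty results, not errors; impossible states
  (`total = 0` at a non-missing cell, meth > total, start ≥ end) are
  typed errors distinguishing configuration from data problems, which
  the CLI maps to exit codes 2 and 3.

## Limitations

No smoothing-based DMR calling (BSmooth/metilene style), no mixed
models or cell-composition deconvolution, no non-CpG methylation, no
imputation. The CGI detector is a defined interpretation of the printed
composition criteria, not a reproduction of any browser track's exact
coordinates. The MLM is CPU-scale: it demonstrates and tests the
method; it is not a pretrained resource.
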