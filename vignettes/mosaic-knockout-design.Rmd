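---
title: "Methods: modeling knockout penetrance in mosaic F0 embryos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling knockout penetrance in mosaic F0 embryos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicKO)
```

## The problem

Injecting Cas9/gRNA ribonucleoprotein into an early embryo produces a
mosaic F0 animal: each cell repairs its double-strand break independently,
so the animal is a patchwork of repair genotypes. A cell only loses
protein function completely when *both* alleles carry frame-disrupting
(frameshift) indels; cells with at least one in-frame indel, one
unedited allele, or no edit at all can retain function and dilute the
phenotype. `mosaicKO` implements the quantitative machinery for reasoning
about — and designing around — this dilution: a cell-level model of the
mosaic, the bookkeeping rules for comparing predicted and observed
editing-outcome spectra, a guide scanning/scoring pipeline, synthetic-data
generators with known ground truth, and an image-based phenotype score.

## The mosaic model

Each cell carries two alleles. An allele is edited with probability $e$
(the guide's per-allele on-target efficiency) and, if edited, acquires a
frameshift outcome with probability $f$ (the guide's frameshift
frequency). Alleles and cells are independent. The per-cell class
probabilities are closed-form:

| class | probability |
|---|---|
| biallelic frameshift (complete KO) | $(ef)^2$ |
| biallelic edited, $\ge$1 in-frame allele | $e^2(1-f^2)$ |
| monoallelic edited | $2e(1-e)$ |
| unedited | $(1-e)^2$ |

The knockout score of a guide is $\mathrm{KO} = f^2$ (reported on a 0-100
scale), the biallelic-frameshift probability at full efficiency. The
square is the entire story: $f = 0.80$ gives only 64% complete-KO cells,
and the ratio $\mathrm{KO}/f = f$ shows the penalty grows as $f$ falls.

```{r}
biallelic_frameshift_prob(e = 1, f = 0.80)
expected_mosaic(e = 0.75, f = 0.80)$fractions
```

Three modeling choices deserve flagging. *Efficiency is per allele*, with
alleles independent; published accounts of mosaic editing do not always
distinguish per-allele from per-cell efficiency, but the per-allele
reading reproduces every worked value at $e = 1$ and yields the clean
partition above. *Cells are independent*: no clonal/lineage structure is
modelled, mirroring the schematic 100-cell mosaic; real embryos edited at
the 2-16-cell stage have clonal patches, so finite-embryo variance is
understated for late-injection designs. *The "biallelic with in-frame"
class* includes every biallelic-edited cell that is not biallelic
frameshift, i.e. frameshift/in-frame heterozygous cells count as
function-retaining.

`simulate_mosaic()` is the stochastic counterpart (seeded, cell-by-cell,
optionally sampling a full outcome distribution per edited allele instead
of a Bernoulli $f$); `expected_mosaic()` is the closed form the simulation
is tested against.

## From a population prior to "what does a random guide buy me?"

Given a distribution of $f$ across candidate target sites — an empirical
histogram from genome-scale predictions, or a parametric stand-in —
`transform_prior()` pushes it through $f \mapsto (ef)^2$ to get the
distribution of the complete-KO cell fraction. Two modes exist: the
analytic pushforward (infinite cells) and a finite-cell mode that mixes
$\mathrm{Binomial}(n, (ef)^2)/n$ over the prior, with $n = 100$ as the
conventional schematic mosaic size. `tail_probability()` reports mass at
or **above** a threshold (inclusive boundary, so a point mass exactly at
the threshold counts). On a uniform prior with $e = 1$ the tail above 0.8
has the closed form $1 - \sqrt{0.8} \approx 0.1056$, which the discretized
transform (10,000 equal-mass atoms at bin midpoints) reproduces to three
decimals — the resolution/accuracy trade-off behind the default atom
count.

## Comparing predicted and observed spectra

Predicted and observed indel spectra come from different tools with
different conventions, so the harness fixes a common currency first.

**Canonical outcome keys.** A deletion flanked by microhomology has
several equivalent coordinate representations. Deletions are left-aligned
within their sequence context before keying, so shifted representations of
the same product collapse to one class. Coordinates are 0-based offsets
from the cut site, which sits 3 bp 5' of the PAM (between protospacer
positions 17 and 18).

**Observed-side filter.** Wildtype reads and insertions longer than 1 bp
are removed and the residual mutant frequencies renormalized to 1
(`normalize_observed()`); outcome predictors model templated +1 insertions
but not the long-insertion tail, so the comparison is restricted to the
classes both sides can express. The +1-only rule is applied to both sides
by default — predictor exports that do contain multi-nucleotide insertions
lose them at curation, which keeps the class universes identical.

**99%-cumulative curation.** Comparisons run over all +1 insertions plus
deletions up to the length $L^\*$ at which the reference prediction's
cumulative probability (accumulated over +1 insertions, then deletions by
increasing length) first exceeds 0.99 (`curate_to_reference_classes()`).
This prevents rare large deletions from dominating Pearson correlations
through a cloud of near-zero points.

**Correlations.** Per guide, Pearson $r$ over the zero-filled vectors on
the sorted union of keys; pooled, a single Pearson over the concatenation
of all guides' matched pairs (not an average of per-guide $r$); and a
per-guide cumulative-frameshift correlation with one point per guide.
$p$-values are the two-sided $t$-transform of $r$, uncorrected — these are
descriptive concordance measures, not a multiple-testing screen. Matched
vectors include zero-filled classes from *both* sides by default; since
the observed side is curated to the prediction's class universe, the union
is in practice the predicted support plus observed classes inside $L^\*$,
and results are labelled by the harness mode.

**Underpowered guides.** A per-guide $r$ is only reported when at least 3
matched classes exist and the observation carries at least 500 reads
(when depth is known); panels report mean ± SD of $r$ over powered guides
and surface the exclusion count. Few-embryo Sanger-deconvolution data
fails these gates readily — an embryo edited at a late stage contains few
discrete repair events, so its spectrum is a small-sample draw, not the
outcome probability vector.

**Deconvolution averaging.** Per-embryo spectra are averaged
arithmetically per class across at least 3 embryos (classes absent from
an embryo count as zero), restricted to +1 insertions and deletions
$\le 20$ bp, and renormalized.

## Predictors

**Activity.** On-target activity is a linear regression over
position-specific 1- and 2-mer indicators in a 35-nt window (6-nt 5'
flank, 20-nt protospacer, NGG PAM, 6-nt 3' flank), the feature set of
in-vivo activity models for T7-transcribed guides. Coefficients load from
CSV; the repository ships a synthetic coefficient fixture for tests
because published coefficient tables are distributed as supplementary
material under their own terms. The linear predictor maps to 0-100 by a
*fixed* affine rescaling declared with the model (defaults: linear
predictor in [0, 1] maps to [0, 100], clipped) — never by data-driven
min/max, so scores cannot drift between runs.

**Editing outcomes.** The outcome-predictor contract is: 80-nt context
centred on the cut in, a normalized `outcome_dist` out. Exports from
trained models (InDelphi-style, Lindel/FORECasT-style genotype strings, or
this package's native tables) are ingested by `load_predictions()` with
the dialect always stated, never sniffed. The built-in
`predict_outcomes_mh()` is a deterministic microhomology heuristic
honoring the same contract: it enumerates every deletion up to 30 bp
spanning the cut, collapses microhomology-equivalent candidates, weights
each by $e^{-\Delta L}(1+\mu)^\gamma$ ($\Delta = 0.2$ per bp,
$\gamma = 1.5$ by default, $\mu$ the flanking-repeat length), and adds
four +1 insertion channels with the base matching the nucleotide 5' of the
cut up-weighted 3x (templated insertion). It exists so the pipeline runs
and can be tested without external model weights; it claims no numeric
agreement with any trained predictor.

**MMEJ fraction.** The mass in deletions with $\mu \ge \mu_{\min}$,
default $\mu_{\min} = 2$ nt. Published pipelines do not state the
threshold their "fraction of MMEJ repair" uses, so it is an explicit
parameter rather than a constant.

## Guide design

`scan_targets()` enumerates all 20-nt+NGG sites on both strands of each
CDS record, keeping sites whose context windows fit inside the record,
with deterministic (position, strand) ordering. Guides are scanned across
the *entire* CDS of each record, not a window near the start. The T7
filter keeps protospacers beginning GG (the canonical +GG requirement for
T7 transcription); GA starts are accepted under an option since in
practice many labs tolerate them. Per gene, `classify_per_gene()` flags
exactly one highest- and one lowest-KO-score guide, breaking ties by
higher activity score, then 5'-most cut position, then strand — a total
order, so flags are invariant to row order. `quadrant_report()` counts
threshold crossings at the conventional demarcations (KO > 75,
activity > 50, MMEJ > 90%). Genome-scale runs stream record by record
with append-only CSV output, keeping memory flat in gene count.

## The synthetic-data generator

Everything the pipeline consumes can be generated with known ground
truth: random CDS FASTA (`gen_cds`), per-guide true outcome spectra
(`gen_truth`), deep amplicon observations (`gen_amplicon_table`),
distorted mock predictions (`gen_prediction_table`), and few-embryo
deconvolution-style tables (`gen_ice_tables`).

What the generator emulates, and the defaults chosen for it:

* **Guide-to-guide diversity.** `gen_truth` draws heuristic parameters
  per guide: length decay $0.2\,e^{U(-0.25, 0.25)}$ (repair physics,
  roughly shared across sites), microhomology reward $U(1, 6)$ (the
  precision axis: high values give spectra dominated by one strong
  microhomology deletion, whose frame then pins $f$ near 0 or 1), and
  insertion weight $0.3\,e^{U(-2, 2.5)}$ (the insertion-fraction axis).
  These were calibrated once against what a realistic multi-guide panel
  looks like — cumulative frameshift frequencies spanning roughly
  0.4-1.0, peaked spectra with top-class frequencies up to ~0.5,
  insertion fractions up to ~0.4 — and against the design requirement
  that deep-read (1e5) zero-distortion recovery through the full harness
  stay above $r = 0.999$ per guide.
* **Amplicon sequencing** is one multinomial draw: wildtype with
  probability $1 - e$, mutant classes with probability $e$ times the
  truth. No sequencing-error, PCR-bias or alignment-artifact model — a
  deliberate non-goal, so passing recovery tests says the *bookkeeping*
  is faithful, not that real pipelines are unbiased.
* **Prediction distortion** is multiplicative log-normal noise followed
  by renormalization (simplex-safe; distortion 0 is an exact copy), a
  single knob for "how wrong is the predictor".
* **Few-embryo tables** are built from a small number of discrete repair
  draws (cells, two alleles each), not read-level noise, reproducing the
  mechanism by which low-mosaicism embryos underpower spectrum
  comparisons: at 4 cells per embryo the between-embryo frameshift SD is
  several-fold that at 64 cells.

Because real data differ in exactly the ways the generator omits
(sequencing artifacts, clonal structure, predictor-specific biases),
green recovery tests validate the harness and its rules, not any claim
about in-vivo editing.

## Pigment phenotype score

Pre-cropped 8-bit grayscale eye images (conventionally 365x365) are
masked by inclusive intensity thresholding in [1, 30] — the semantics of
an ImageJ-style `setThreshold(1, 30)` on a black background — and the
masked count is normalized as $(\mathrm{max\_ref} - \mathrm{count}) /
\mathrm{max\_ref}$ against the most pigmented reference eye. `max_ref` is
a required argument, not auto-detected, so adding images to a batch never
silently rescales earlier scores; counts above `max_ref` clip to 0 with a
message. RGB inputs convert by the standard luminance weights
(0.299, 0.587, 0.114) — the original tool-specific 8-bit conversion is
not documented, so the standard weights are used and stated.

## Numerical choices

* Ingested third-party tables may sum to 100% only to printing precision:
  tolerance 0.1 percentage points with renormalization (warned beyond
  it); internal conservation checks use 1e-9, and
  `cumulative_frameshift()` rejects inputs off the simplex by more than
  1e-6.
* Frequencies are written with 17 significant digits so table round-trips
  are bit-exact.
* All stochastic components take explicit integer seeds; panel generators
  derive per-guide sub-seeds from the master seed so guides are
  independent but jointly reproducible.
* Degenerate inputs error early with named guides: empty mutant signal
  after filtering, reference mass below the curation threshold, fewer
  than 3 embryos, fewer than 3 guides for frameshift concordance.

## Problem sizes

The test suite and analysis scripts run at: 28-guide panels with 1e5
reads per amplicon (panel experiments), 1e5-cell Monte-Carlo mosaics,
10,000-atom priors, 40-gene design runs, and 365x365 synthetic images —
sizes chosen so the full suite completes in about a minute while keeping
Monte-Carlo standard errors well inside the asserted tolerances.

## Known limitations

* The built-in outcome predictor is a structural stand-in; analyses of
  real guides should ingest tables from a trained predictor.
* No off-target assessment anywhere in the pipeline.
* No clonal structure in the mosaic model (see above).
* Exon-level biology — NMD escape, reading-frame restoration by exon
  skipping, translation reinitiation — is outside the model: $f$ is a
  sequence-local quantity.
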