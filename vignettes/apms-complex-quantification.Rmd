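---
title: "Quantifying affinity-purified protein complexes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying affinity-purified protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmsquant)
```

## The analysis problem

Affinity purification followed by mass spectrometry (AP-MS) identifies the
proteins that co-purify with a bait protein. When the purified material is
first resolved on a blue-native gel (BN-PAGE), each gel band is a distinct
native assembly of the bait — here, the neuronal K⁺/Cl⁻ co-transporter
Kcc2, which runs as ~300, ~600 and ~800 kDa species — and every band is
analysed as its own AP-MS experiment with bait and non-immune IgG control
replicates. The computational task is to turn peptide-spectrum matches
(PSMs) into per-protein abundances, separate true partners from bead
background, characterise the composition of each band, draw the
interaction network, and localize phosphosites on the bait.

`apmsquant` implements that pipeline end to end, together with a
synthetic-data generator that plants a known ground truth so every stage
can be tested quantitatively.

## Quantification: the SI_GI statistic

The package quantifies a protein in a sample by its *spectral index
normalized to global intensity*:

$$\mathrm{SI}(p, s) = \sum_{\substack{\text{PSMs of } s\\ \text{peptide unique to } p}} I,
\qquad
\mathrm{SI_{GI}}(p, s) = \frac{\mathrm{SI}(p, s)}{\sum_{\text{all PSMs of } s} I}$$

with $I$ the summed MS2 fragment intensity of a PSM. Two choices deserve
emphasis because the statistic's name alone does not pin them down:

* **No protein-length normalization.** A related statistic (SIN) divides
  by peptide count or protein length; "normalized to global intensity"
  is implemented literally as the within-sample share of summed
  intensity, nothing else.
* **Shared peptides** (mapping to more than one protein) contribute to
  the *denominator* — the global intensity is a property of the sample —
  but to no protein's numerator, so nothing is counted twice.

Proteins supported by fewer than two distinct peptides are unreliable
one-hit identifications; their SI_GI is set to zero and flagged. The
peptide count is pooled across a band's replicates by default
(`min_peptide_scope = "band"`), since detection evidence accumulates over
repeats of the same band; per-sample zeroing is available.

Consequences that the tests verify: per-sample SI_GI values sum to exactly
1 when every PSM maps uniquely and all proteins clear the peptide floor;
the statistic is invariant to rescaling a sample's intensities; raising
one protein's intensities strictly lowers every other protein's share.

## Enrichment: Welch test plus replicate consistency

For each band, every protein's bait SI_GI vector is compared to its IgG
control vector with a two-sided Welch (unequal-variance) t-test, filling
missing detections with zero — absence from a control run *is* evidence
of enrichment, and the all-proteins-by-all-samples matrix implies the
zero fill. A protein is **significant** when p < α (default 0.05,
uncorrected) *and* its bait mean exceeds its control mean; it is
**consistent** when detected in every bait replicate. Only
significant-and-consistent proteins move forward.

Why no multiple-testing correction by default: the all-replicates filter
is the de-facto false-discovery control in this design; an optional
Benjamini–Hochberg mode (`p_adjust = "BH"`) is exposed for users who want
explicit FDR control. Both α and the adjustment are logged in the run
report.

Degenerate proteins whose bait and control vectors both have zero
variance cannot be tested; identical means give p = 1, differing means
give p = 0 with a `degenerate` flag so downstream review can find them.

A note on calibration: Welch's test with four replicates is mildly
*conservative* on right-skewed data. On the generator's null world —
protein values that sum ~20 peptides with stable response factors and
~30% replicate noise — the measured type-I error at p < 0.05 is ≈0.04–0.05,
and the acceptance suite checks it against the binomial sampling band.
On a single raw log-normal draw per sample it would drop to ≈0.02; that
is a property of the t-statistic under skew at n = 4, not of this
implementation (which matches `stats::t.test` to 10⁻¹⁰).

## Composition: z-transform and PCA

The SI_GI sub-matrix of significant proteins (union over bands by
default) is standardized per protein across the 12 band-replicate
samples, dropping zero-variance proteins, and decomposed by SVD with the
samples as observations. Standardizing within protein — not within
sample — is what makes the loadings readable as per-protein
contributions to each component. A deterministic sign convention (the
largest-magnitude loading of each component is made positive) keeps
output bit-identical across runs. Variance explained per component is
reported in percent and sums to 100 over all retained components;
retaining all components reconstructs the input exactly, which the tests
assert at 10⁻⁸.

## Networks: trace filter and evidence assembly

Partners whose abundance is a small fraction of the bait's are treated as
trace binders: protein *p* survives iff
$\mathrm{SI_{GI}}(p) \ge f \cdot \mathrm{SI_{GI}}(\text{bait})$ with
*f* = 0.02 — the 2% cutoff, identical to removing proteins more than
50-fold below the bait (1/0.02 = 50). The two published phrasings of this
rule differ on whether a protein at exactly 2% stays; the boundary is a
config flag, inclusive by default (retained at exactly 2%).

Known interactions come from an *offline* evidence table in the STRING
`protein.links.detailed` dialect, filtered on the **experimental**
channel at a minimum score of 700 ("high confidence, direct experimental
association"); live database queries are deliberately out of scope so
runs are reproducible against a pinned file. The band network contains
one node per trace survivor (diameter scaled linearly in SI_GI up to the
most abundant protein), every evidence edge among survivors, and one
imputed bait edge per non-bait node — the bait interaction is what the
purification itself demonstrated. When a protein→term table is supplied,
each node is annotated with its top-scoring functional term.

## Phosphosite localization: the A-score

Phosphopeptide spectra are scored by the ambiguity-score algorithm.
For a peptide with *k* phospho groups and a set of candidate S/T/Y
acceptors, every placement (isoform) is evaluated against the spectrum
reduced to its *d* most intense peaks per 100 m/z window, *d* = 1..10:
with *n* theoretical singly-charged b/y ions and *m* of them matched
within ±0.05 Da, the depth-*d* score is
$-10\log_{10} P(X \ge m),\; X \sim \mathrm{Binomial}(n, d/100)$,
and isoforms are ranked by a fixed depth-weighted sum
(weights 0.5, 0.75, 1, 1, 1, 1, 0.75, 0.5, 0.25, 0.25). The A-score of
the winning placement is the score difference between the top two
isoforms computed on their *site-determining ions* only — the ions whose
m/z differ between the placements — at the peak depth where the full
peptide scores separate most (ties resolved toward the lower depth).
Confidence maps to percent as $100(1 - 10^{-A/10})$: A = 15 → ≈96.8%
(the >90% band), A > 19 → >99%.

Design choices where the published algorithm is silent:

* **Single-candidate peptides** are unambiguous; they receive a sentinel
  A of 1000 so the >19 banding applies uniformly.
* **Per-site scores for multi-site peptides**: each site of the winning
  isoform is scored against the best-ranked isoform *not* containing
  that site.
* **Composite sites.** When the nearest competitor places the phospho on
  an *adjacent* residue and the pairwise A-score is below the ambiguity
  threshold (default 15), the pair is reported as one composite site
  ("S25/26" style). Its confidence band uses the A-score against the
  best isoform containing *neither* residue — the phospho group is
  confidently localized to the residue pair even when the neighbours
  cannot be told apart — and the sentinel when no such isoform exists.
* **Counting unit**: each qualifying PSM is one detection, so counts
  across four experiments can exceed four.
* Fragment matching uses singly charged b/y ions, no neutral losses,
  ±0.05 Da (high-resolution HCD); these are config fields.

Site coordinates are reported on the protein and, after subtracting a
configurable signal-peptide offset, on the mature-sequence numbering
used in the literature for this transporter.

## The synthetic world

`simulation_design()` states the simulated experiment; the generators
are pure functions of it. Defaults, and why:

| Parameter | Default | Rationale |
|---|---|---|
| bands × replicates | 3 × (4 bait + 4 IgG) | the BN-PAGE study design |
| `n_partners`, `n_background` | 24, 60 | desk-scale versions of per-band partner sets and bead background |
| `bait_abundance_fold` | 10 | bait ~10× its most abundant partner, as observed for a bait-dominated band |
| `bait_enrichment_fold` | 8 | bait-condition multiplier for bait and planted partners |
| `intensity_logmean`, `intensity_logsd` | 12, 1 | log-normal peptide response factors: peptides ionize with orders-of-magnitude spread |
| `replicate_logsd` | 0.3 | ~30% replicate CV, typical of label-free quantification |
| `dropout_prob` | 0.1 | peptide-level missingness |
| phospho | 200 spectra, 20 noise peaks / 100 m/z | planted-site spectra: all true-isoform ions at high intensity plus uniform noise |

Two structural choices matter more than any single number. First, the
log-normal sdlog 1 spread is assigned to *peptide response factors*,
drawn once per peptide and held fixed across samples, with a separate
30% replicate noise; treating the full spread as independent
per-replicate noise would give ~130% replicate CVs, which real label-free
data do not show and which no 4-vs-4 test could power through. Second, a
protein's expected total signal is independent of its length (its
abundance is split across its observable peptides, capped at 30), so
planted abundance — not sequence length — drives SI_GI.

What the generator does *not* emulate: chromatography and retention
time, charge-state and missed-cleavage diversity, correlated
contaminant structure across runs, isotope envelopes, and neutral-loss
fragments. A green test therefore establishes that the statistics and
algorithms behave as specified on data with the stated structure — not
that the pipeline is robust to every artefact of a real instrument.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive throughout; I and L are distinct
  letters during peptide mapping (search output is database-resolved).
* Binomial tails are evaluated in log space, so scores for dozens of
  matched ions at depth 1 do not underflow.
* Peak-depth reduction breaks intensity ties toward the lower m/z;
  windows are `[0, 100), [100, 200), …`.
* Input q-value filtering defaults to 0.01 and is configurable — the
  upstream search's quality-control cutoff is not standardized.
* Table writers emit fixed-format numbers, so identical inputs produce
  byte-identical artifacts; PSM tables round-trip numeric fields exactly.

## Known limitations

* The enrichment model tests each band independently; it does not borrow
  strength across bands or model protein-level FDR.
* Phospho localization covers single- and multi-phospho placements of one
  modification type; other PTMs, charge-2 fragments and neutral losses
  are out of scope.
* Two acceptance checks compare against downloadable reference artifacts
  (the bait's UniProt entry; the study's deposited z-matrix). They run
  only when the user supplies those files under
  `inst/extdata/reference/`; in offline environments they report as
  failing with an explanatory message rather than being skipped.
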