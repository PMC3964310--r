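---
title: "Hybrid specificity and stability profiling of AP-MS interactomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid specificity and stability profiling of AP-MS interactomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmstability)
```

## The problem

Affinity purification followed by mass spectrometry (AP-MS) identifies the
proteins co-isolated with a tagged bait, but a raw prey list conflates three
very different things: genuinely specific interactors, the background that
sticks to beads, antibody and tag in any purification, and extrinsic
contaminants introduced during sample handling. Label-free spectral counting
against negative-control purifications can separate specific from
non-specific, but says nothing about how *stable* a specific interaction is
— whether the partner is a constitutive complex subunit or a transcription
factor touching the complex in rapid equilibrium.

`apmstability` implements a hybrid workflow that answers both questions and
joins the answers per prey:

1. **Specificity** — a per-bait probabilistic score from spectral counts in
   bait versus control runs (a SAINT-style mixture model), calibrated
   against a reference interaction list with ROC-like curves;
2. **Stability** — an I-DIRT SILAC measurement: bait-expressing cells grown
   in light medium are mixed 1:1 with heavy-labelled wild-type cells
   *before* lysis, so a partner that exchanges during the purification
   equilibrates toward a 50:50 isotope mixture while a stable, in-vivo
   partner stays light;
3. **Integration** — a quadrant classification of each prey
   (stable / dynamic / rescued / contaminant / nonspecific), plus
   downstream summaries: hierarchical clustering of interaction profiles,
   NSAF-based enrichment indices, and a network export.

Everything runs end-to-end on synthetic data from the package's own
generator, so every stage is testable without any external download.

## The specificity model

For one bait, each prey's spectral count $k$ in a bait run is modelled as a
two-component Poisson mixture,

$$P(k) = \pi \, \mathrm{Pois}(k;\lambda_T) + (1-\pi) \, \mathrm{Pois}(k;\lambda_F),$$

where $\lambda_F$ is the prey's background rate and $\lambda_T$ its rate
when specifically enriched. The per-replicate interaction probability
(iProb) is the posterior of the specific component,

$$p(k) \;=\; \frac{\pi\,\mathrm{Pois}(k;\lambda_T)}
{\pi\,\mathrm{Pois}(k;\lambda_T) + (1-\pi)\,\mathrm{Pois}(k;\lambda_F)},$$

and the final bait–prey score is the **mean of the two highest** replicate
probabilities (the single probability if only one replicate exists). This
two-highest rule rewards reproducibility across biological replicates while
tolerating one weak run.

Parameter choices, all exposed in `saint_config()`:

* `pi_true = 0.1` — prior probability that an observed prey is specific. A
  prey whose counts are equally likely under both components therefore
  scores exactly 0.1, far below any pass threshold.
* `pseudocount = 0.1` — rate estimates are smoothed means,
  $\lambda_F = (\sum_{\text{ctrl}} k + 0.1)/n_{\text{ctrl}}$ and
  $\lambda_T = (\sum_{\text{bait}} k + 0.1)/n_{\text{rep}}$, keeping both
  rates strictly positive.
* `minfold = 1`, `min_separation = 1e-6` — $\lambda_T$ is floored at
  $\lambda_F \cdot \text{minfold} + 10^{-6}$. Without the floor, a prey
  *depleted* in bait runs would paradoxically score above the prior at low
  counts; with it, uninformative preys converge to the prior.
* Normalized counts are rounded to the nearest integer before the Poisson
  mass is evaluated (normalization produces non-integral counts; the
  Poisson needs integers).

Modelling is strictly per bait: $\lambda_T$ uses only that bait's
replicates, so adding or removing another bait's runs never changes a
score. Preys observed only in control runs are not scored — they cannot be
interactions of the bait. This scorer is a transparent, desk-scale model in
the spirit of spectral-count interaction scoring tools; it is fully
specified here and makes no attempt at numeric parity with any external
scoring binary.

### Thresholds and calibration

`threshold_policy()` applies a default pass threshold of 0.75
(`score >= t`), with per-bait overrides — the shipped defaults mirror a
design where promiscuous, high-background baits get 0.90 and one divergent
bait a strict `> 0.95`. A manual-include list retains well-established
low-abundance interactors below threshold, flagged `manual`. For
calibration, `roc_like_curve()` sweeps the threshold and reports *approximate*
true/false-positive rates by membership in a reference interaction list;
"approximate" because absence from a curated database does not prove
non-interaction. Scored-but-unlisted preys count only against the FP rate;
the recovery column divides by *all* reference pairs for the bait, so it
measures how much of the known interactome the screen retrieves.

## The stability model

Each SILAC peptide pair gives light/heavy intensities $(L, H)$. The raw
odds $L/H$ are divided by the input normalizer — the realized light:heavy
mixing ratio, estimated as the median over input-sample proteins (each
needing $\ge 2$ peptides) of their median peptide odds — and converted back
to a fraction:

$$\text{fraction} = \frac{(L/H)/m}{1 + (L/H)/m}.$$

Correcting in odds space is the only order in which a mis-mixed input
restores the expected 0.5 for a fully exchanging prey. Per protein, the
I-DIRT ratio is the **median** of its peptide fractions, requiring at least
two quantified peptides; medians are used at both levels for robustness to
outlier peptides. Limits are exact: $H = 0$ gives fraction 1, $L = 0$
gives 0, and a peptide with both channels empty is skipped with a warning.
Peptides mapping to more than one protein are dropped — protein-group
disambiguation is the upstream search engine's job.

One orientation note: the ratio is reported as the *light* fraction,
$L/(L+H)$. With the bait-expressing population in light medium, only the
light fraction reaches 1.0 for a stable, in-vivo-specific partner; a
heavy-fraction convention would invert the scale.

## The quadrant classification

`classify_profile()` joins the two measurements per prey and applies, in
order (defaults in `profile_thresholds()`):

| rule (in order) | category |
|---|---|
| score < 0.10 and ratio $\ge 1 - 10^{-6}$ | contaminant |
| score below pass and ratio $\ge$ 0.80 | rescued |
| score passes and ratio $\ge$ 0.80 | stable |
| score passes and ratio < 0.80 | dynamic |
| score below pass | nonspecific |
| ratio missing, score passes | unquantified |

The 0.80 stable/dynamic boundary is the working boundary of the study
design this package implements (NCoR-complex members sat above 0.8 with
their direct partner and near 0.5 with indirect ones); it is configurable.
The contaminant signature — near-zero specificity with a *maximal* light
ratio — identifies extrinsic, environmentally introduced proteins, which
are only ever in the natural (light) isotope state; the `= 1.0` comparison
is applied within a $10^{-6}$ floating-point tolerance. The *rescued*
category mitigates false negatives: a low-abundance partner that fails the
spectral-count threshold but is unambiguously label-pure is kept, mirroring
known interactions recovered this way in practice.

A design decision worth stating: a prey quantified by I-DIRT but never
scored (never observed in the bait's label-free runs) is treated as having
**zero** specificity evidence, not missing. This makes the classifier total
and sends light-saturated, never-enriched proteins to `contaminant` rather
than to an undefined state. Conversely a specific prey undetected in I-DIRT
(common for sub-stoichiometric partners) is retained as `unquantified`
rather than discarded.

## Downstream summaries

* **Clustering** — `cluster_matrix()` clusters $\log_2(x+1)$-transformed
  counts of passing preys under the Pearson correlation distance
  $d = 1 - r$ with average linkage, for both preys and runs. The $+1$
  offset keeps zeros finite (the transform is otherwise undefined at 0);
  bait self-counts are zeroed upstream so the bait's own huge signal cannot
  drive the tree. Zero-variance profiles have no defined correlation; their
  distance is set to 1 with a warning. Ties are broken deterministically by
  input order, and dendrograms export as Newick.
* **Enrichment** — NSAF$_i$ = $(k_i/L_i)/\sum_j (k_j/L_j)$ length-normalizes
  spectral counts and rescales them to sum to 1; dividing by a cellular
  abundance estimate (PAX-style) and anchoring a chosen reference protein
  at exactly 1 yields an enrichment index that highlights preys enriched by
  the purification far beyond their cellular levels. Per-prey counts are
  replicate means, a robust single value.
* **Network** — passing, non-contaminant profiles become bait–prey edges
  (weight $\log_2(\text{mean count}+1)$, known/novel flag, category), with
  SIF and TSV outputs for standard viewers.

## The synthetic-data generator

`sim_config()` fixes the simulated study design; the defaults are the
conditions under which the package's claims are tested:

* 3 baits $\times$ 3 biological replicates vs 7 control runs;
* 50 specific preys per bait at $\lambda_T = 15$ counts/run, a 5-protein
  complex shared by the first two baits, and 450 background preys with
  per-prey rates uniform on $(0.02, 0.5)$ — the same rates in bait and
  control runs;
* exchange fractions $f \in \{0, 1\}$ alternating over specific preys, 20
  peptides per prey (100 in convergence checks), lognormal channel noise
  $\sigma = 0.2$, an equal-amount mix (`mixing_imbalance = 1`), and a
  30-protein input sample;
* 10 light-only contaminants at 6 counts/run in controls and 1 count/run in
  bait purifications — control isolations are dominated by ambient
  background, whereas bait runs are dominated by the specific complex, so
  environmental contaminants are proportionally and absolutely lower there;
* protein lengths uniform on 100–2000 aa, cellular abundances lognormal.

The SILAC model sets a prey's expected light fraction to $1 - f/2$: with
equal light/heavy pools, the exchanged portion $f$ re-equilibrates to
50:50 while the rest stays light, so $f{=}1$ gives 0.5 and $f{=}0$ gives
exactly 1.0 (the heavy channel is exactly zero at $f{=}0$, so the limit is
exact, not asymptotic). Counts are Poisson by default, matching the scoring
model; a negative-binomial `overdispersion` option exists purely for
robustness experiments. A seed is mandatory and identical configurations
produce byte-identical files.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: protein-dependent detectability and saturation of
spectral counts, overdispersion beyond Poisson (by default), correlated
backgrounds between runs, peptide-level missingness structure,
arginine-to-proline label conversion, and protein-group ambiguity beyond
simple shared peptides. Claims about real instruments need real data.

### Why synthetic runs are scored without total-count rescaling

`normalize_counts()` multiplies a bait's counts by
(mean control total)/(mean bait total), equalizing group mean totals — the
right correction when runs differ in global efficiency or input amount. The
generator simulates no such artifact: background rates are identical across
runs by construction, so the ideal scale factor is 1, while the planted
specific signal makes bait totals several-fold higher than control totals.
Rescaling synthetic bait runs therefore *distorts* the generative rates
(and discards information when scaled counts are rounded for the Poisson
mass). The analysis scripts and end-to-end checks consequently score the
synthetic matrix as-is (`saint$normalize: false` in the pipeline config),
while the normalization operation itself is verified by its own invariants
(equalized mean totals to $10^{-9}$, rank preservation within runs). For
real data, where run totals drift for uninteresting reasons, the default
`saint$normalize: true` applies the correction before scoring.

## Orchestration and reproducibility

`run_pipeline()` drives all stages from one nested configuration (R list or
YAML), writes every stage's tables under one output directory, and records
an md5 digest per output file in `manifest.tsv`. With `resume = TRUE` a
stage whose recorded outputs all exist with matching digests is skipped; a
mismatching digest stops with a dependency error rather than silently
overwriting. All randomness flows from the single `seed`, and fixed seeds
give identical manifests across runs.

Problem sizes used throughout the shipped analyses and tests — ~600 preys,
16 runs, 60 quantified proteins per I-DIRT experiment, 20–100 peptides per
protein — were chosen as representative of a single-bait-family AP-MS
study; each driver script completes in seconds.

## Known limitations

* The Poisson mixture is a deliberately transparent surrogate for
  spectral-count interaction scoring; it has no MCMC machinery, no
  semi-supervised background pooling across baits, and no intensity-based
  variant, and its scores should not be expected to match any external
  implementation numerically.
* With `pi_true = 0.1`, an uninformative prey scores exactly at the 0.10
  contaminant boundary; the contaminant call therefore requires genuine
  depletion in bait runs (as the generator's contaminants have), not mere
  equality.
* The false-positive rate in calibration is an approximation by database
  absence.
* Quadrant boundaries (0.80; 0.10/1.0) are working conventions, exposed in
  configuration, not biological constants.
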