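---
title: "Scoring microRNA target sites with a calibrated support-vector regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring microRNA target sites with a calibrated support-vector regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirsvr)
```

## The problem and the model

MicroRNAs guide the RISC complex to 3' UTR sites that are partially
complementary to the microRNA, with the seed region (positions 2–7 from
the microRNA 5' end) as the primary determinant of recognition.  A
perfect seed match is neither necessary nor sufficient for repression:
sites with a single G:U wobble or mismatch in the seed can be effective,
and many perfect matches do nothing.  This package therefore treats
target prediction as a two-stage problem:

1. **Site discovery.**  A seed-weighted Smith–Waterman alignment between
   the reverse of the microRNA and the UTR finds candidate duplexes.
   Pair scores are +5 for Watson–Crick, +1 for G:U, −3 for a mismatch;
   affine gaps cost −9 to open and −4 to extend; positions 2–8 of the
   microRNA carry a 4-fold weight so that alignments strongly favour 5'
   pairing.  The first 5' base and last two 3' bases of the microRNA are
   excluded from alignment.  Alignments scoring at least 120 are kept;
   the seed rule then keeps either only canonical sites (perfect
   Watson–Crick 6-mer at positions 2–7) or additionally sites with
   exactly one G:U or mismatch — never a gap — in the seed.

2. **Downregulation scoring.**  Each site is represented by a fixed
   35-dimensional feature vector (seed-match bits for positions 2–8, the
   A1-anchor bit, a position-9 match bit, the 3'-supplementary pairing
   count at positions 12–17, the distance-weighted AU context of 30-base
   flanks, 21 local-accessibility values, the seed-block conservation,
   UTR length and relative site position).  A linear nu-SVR
   (epsilon-insensitive loss, `C = 0.1`, `nu = 0.5`, libsvm via
   \pkg{e1071}) regresses the observed log expression change after
   microRNA transfection on these features, using only genes with a
   single site for the transfected microRNA.  Raw scores are then passed
   through a sigmoid transfer function
   `t(x) = -c / (1 + exp(a(-x) + b))`, fitted by nonlinear least squares
   against the responses of five-fold cross-validation scores, so that
   calibrated scores live on the expression scale, are additive across
   the sites of a gene, and a fixed cutoff (−0.1 by default) has a
   stable meaning across microRNAs.

## Parameters that matter

| parameter | default | units / range | why |
|---|---|---|---|
| `score_cutoff` | 120 | alignment score | a lone perfect 6-mer seed (6 × 5 × 4) reaches exactly 120, so canonical sites always pass |
| `gap_open`, `gap_extend` | −9, −4 | score | classic miRanda-style affine penalties |
| `seed_scale` | 4 | multiplier | applied to pair *and gap* scores at positions 2–8 (see below) |
| `C`, `nu` | 0.1, 0.5 | libsvm | deployed scorer settings; `nu` bounds the fraction of points outside the epsilon tube |
| `flank` | 30 | nt | AU-context window, weights 1/(offset+1) |
| `u`, `L`, span | 8, 40, 160 | nt | accessibility: unpaired-window length, maximum pair span, folded region around the site |
| cutoff | −0.1 | calibrated score | default reporting threshold |

Two scoring conventions deserve a note:

* **Seed gaps.**  The seed weight multiplies gap penalties inside the
  seed span as well as pair scores.  Without this, the dynamic program
  can fake a contiguous seed by bulging out a UTR base (a −9 gap beats a
  −12 weighted mismatch), producing sites whose "perfect" seed is split
  across a bulge.  Seed contiguity is additionally verified from the
  pairing coordinates: a site whose seed partners are non-contiguous is
  classified non-canonical and counts a violation.
* **Population standard deviation.**  The feature scaler uses the
  divisor-`n` (population) convention, so a two-point column `(0, 2)`
  standardizes to exactly `(−1, +1)`.  The same convention is used when
  Z-transforming responses per experiment.

## Accessibility

RNAplfold-style unpaired probabilities are computed from a McCaskill
partition function over nested secondary structures under a simplified
base-pair energy model: one stabilizing energy per pair type (−3 G:C,
−2 A:U, −1 G:U at `kT = 1`), a minimum hairpin loop of 3, and a pair
span capped at `L = 40`, evaluated on a 160-base region centred on the
site.  These defaults give the three pair types well-separated Boltzmann
weights while keeping the model exactly enumerable, so the kernel is
verified against exhaustive structure enumeration to 1e-9 relative
tolerance.  Full Turner nearest-neighbour thermodynamics is deliberately
out of scope; externally computed RNAplfold tables can be imported with
`load_accessibility()` and used in place of the built-in model.  The
feature extractor reads windows at site-relative positions −20..+20
averaged over two bases (21 values); positions beyond the profile are
clamped to the nearest computed window and flagged.

## What the synthetic data emulates

`simulate_transfection()` builds one transfection experiment end to end:
random microRNAs; UTRs (600 nt by default) carrying 0–2 planted sites
per gene (25/60/15%), with a seed-class mix of
8mer/7mer-m8/7mer-A1/6mer/non-canonical = 30/20/15/15/20%, random
3'-supplementary pairing (0–6 pairs), flank AU fractions in 0.15–0.85
and per-site conservation levels; per-gene conservation tracks; and an
expression table.  Backgrounds are screened so no accidental perfect
seed match survives outside planted footprints, which makes
plant-and-recover tests exact; a no-screening mode restores full
realism.  The expected log expression change of a gene is the sum of its
sites' contributions — the linear signal `<w*, x>` of each site's
standardized features passed through a known sigmoid — plus Gaussian
noise (sd 0.3 by default), and an independent log-normal
control-intensity column lets the above-median expression filter be
exercised.  The default true sigmoid `(a = −1.2, b = 1, c = 2.5)` places
a typical single site on the weak shoulder (expected change ≈ −0.7 log
units, strong sites to −2.5), reflecting that most genes with a seed
match are only mildly repressed.  `generate_site_features()` is a
feature-level companion used for model-scale recovery experiments
(n = 2000–3000) where folding every site would be wasteful.

What passing these tests does *not* show: the generator draws features
close to the model family the scorer assumes (linear-in-features signal
through a monotone transfer), so recovery results certify the machinery,
not biological accuracy on real transfection data; real microarray
noise, probe effects, off-target transfection responses and 3'
UTR-isoform heterogeneity are not modelled.

## Numerical choices and edge cases

* Overlapping alignment hits are resolved greedily best-score-first
  (ties toward the 5' end); reported footprints never share a base.
  The score cutoff is applied before the seed-violation filter.
* A mismatch violation at seed position 2 sits at the terminal column of
  the alignment and is trimmed by any optimal local alignment, so the
  recovered footprint ends one base early; the generator records this.
* The A1 anchor is read directly from the UTR base 3' of the footprint
  (site abutting the UTR end ⇒ no anchor), since position 1 never
  aligns.
* Sigmoid fitting tries four documented starting points covering both
  monotonicity branches and keeps the converged fit with the smallest
  residual sum of squares; near-ties are broken toward the branch whose
  direction matches the observed score–response association, because a
  calibration that inverts the ranking is semantically wrong even when
  its residual error is marginally smaller.  If no start converges, a
  deterministic grid over slopes and centres (amplitude solved in closed
  form) is polished by the optimizer.  Fits with non-positive amplitude
  are rejected.  Convergence tolerance is 1e-8.
* Because calibrated scores lie in `(−c, 0)` while Z-transformed
  responses are mean-centred, the top score bins saturate toward 0 when
  the response carries a large mean shift; calibration is therefore best
  interpreted on the per-experiment log-change scale, where "no effect"
  is genuinely 0.  This saturation is visible as a flattening in
  `plot(fit)` and is a property of the published transfer family, not a
  fitting failure.
* Cross-validation folds are a deterministic polynomial hash of the gene
  identifier mixed with a seed, so repeated runs reproduce byte-identical
  artifacts.
* Model artifacts serialize numerics as C17 `%.17g` strings inside
  JSON, which round-trips IEEE doubles exactly: a reloaded model
  rescored on the same sites is bit-identical.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic
data: alignment oracles on 100 random pairs up to 12 nt against an
exhaustive-search optimum; the accessibility kernel on 100 random
sequences up to 25 nt against exhaustive Boltzmann sums; plant-and-
recover on 200 sites across all seed classes; model recovery at
n = 500 (noiseless) and n = 2000/1000 train/test (noise sd 0.3); and a
300-gene sequence-level pipeline.  These sizes make the whole suite run
in about a minute while leaving every statistical check far from its
decision boundary.

## Known limitations

* The alignment reports one optimal footprint per region; suboptimal
  overlapping duplex conformations are not enumerated.
* The accessibility model ignores dangling ends, coaxial stacking and
  pseudoknots, and approximates RNAplfold's sliding-window averaging by
  one partition function on the 160-base region.
* The published scorer's exact weights are not reproducible here — the
  original training microarrays are external data — so the package ships
  the estimator, not the frozen model.
* Training pools all experiments into one regression; per-experiment
  weighting is not implemented.
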