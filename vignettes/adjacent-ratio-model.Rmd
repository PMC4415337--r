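---
title: "Predicting tandem mass spectra from adjacent y-ion intensity ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting tandem mass spectra from adjacent y-ion intensity ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specsim)
```

## The model

Database-search and de novo peptide identification both compare experimental
MS/MS spectra against theoretical spectra, and both benefit when the
theoretical spectrum carries realistic fragment *intensities* rather than
uniform stick heights. Under the mobile-proton picture of peptide
fragmentation, the intensity of a y ion depends on the residues flanking its
cleavage site and, more weakly, on remote residues. Because remote residues
affect neighbouring ions almost equally, they cancel in the *ratio* of
adjacent ions, which is what makes a closed-form model possible. specsim
models, for a doubly charged tryptic peptide of length $n$ and its singly
charged y ions $y_1,\dots,y_{n-1}$,

$$
\ln\frac{I(y_i)}{I(y_{i+1})}
 = \beta\,(E_i - E_{i+1})
 + G(A_i, c_i) - G(A_{i+1}, c_{i+1}),
$$

where

* $E_i$ is a **cleavage energy** assembled additively from short-range
  residue terms $\Delta(x,d)$ — residue $x$ at offset $d$ from the N-terminal
  flank of the $y_i$ site — plus terminus terms. Ordinary residues are felt
  over offsets $-2 \le d \le 1$ (four neighbouring residues); lysine and
  arginine, which sequester the mobile proton, act over the wider window
  $-8 \le d \le 5$; the C terminus contributes $\Delta(\mathrm{Cterm}, d_C)$
  for site-to-terminus distances $d_C \le 10$; and the N-terminus distance is
  bucketed into five levels via $s = \lceil 5\,d_N / n \rceil$ (clamped to
  $\ge 1$).
* $G(A, c) = \ln(F(A) + D(A, c))$ combines the probabilities of the two
  fragmentation channels attached to the residue $A$ immediately N-terminal
  to the cleavage site: the dominant b/y amide-bond pathway $F$ and the
  diketopiperazine cyclisation pathway $D$. The latter matters only where
  the two N-terminal residues can cyclise, so the site class $c$ is
  *penultimate* for the $y_{n-1}$ site and *interior* everywhere else.
  $F$ and $D$ enter only through their sum, so they are not separately
  identifiable from intensity ratios and only $G$ is stored.

Anchoring $\ln I(y_{n-1}) = 0$ and accumulating the ratios reconstructs the
whole y series (the anchor is immaterial after the base peak is rescaled to
100); per-ion isotope envelopes then yield the full theoretical peak list.

### Conventions the model fixes

Several details are genuinely open choices; specsim fixes them once:

* **Site indexing.** The $y_i$ cleavage site lies between residues $n-i$ and
  $n-i+1$ (1-based). Offsets count from the N-terminal flanking residue, so
  $d \in \{-2,\dots,1\}$ spans exactly four residues around the bond.
* **One delta per residue.** A K or R inside the narrow core window
  contributes its K/R-specific $\Delta$ only — no double counting.
* **Truncation.** Window positions falling outside the peptide are simply
  omitted; there is no padding residue.
* **Mass convention.** Monoisotopic residue masses at five-decimal
  precision, stored in a single table; fragments are singly charged y ions
  only, matching the doubly-charged-precursor scope.
* **Isotopes.** An averagine-style Poisson envelope with rate
  $\lambda = 5.5\times10^{-4}$ per Da of fragment mass (roughly the ^13^C
  abundance times the average carbon count per Da), three peaks by default,
  spaced 1.00335 Da.
* **CID vs HCD** differ only through their parameter sets, never through
  code paths.

## Identifiability and the training gauge

The ratio model is linear in its parameters, and training is
ridge-regularised least squares on observed log ratios. Linearity exposes
exact null directions that the likelihood cannot see, so the trainer
estimates a canonical representative:

* $\beta$ multiplies every $\Delta$, so it is absorbed: $\beta \equiv 1$.
* $\Delta(x, 0)$ attaches to exactly the residue whose $G$ term enters the
  same ratio, so the offset-0 deltas are perfectly confounded with $G$; they
  are absorbed into both $G$ classes and pinned to 0. (This confound is easy
  to miss: it removes a twenty-dimensional null space, which rank checks on
  the design confirm.)
* A common shift of all five N-terminus levels cancels in every ratio
  difference; level 1 is pinned to 0.
* A common shift of every $G$ entry cancels; $G(\mathrm{G},\text{interior})$
  is pinned to 0.
* $\Delta(\mathrm{Cterm}, 0)$ can never occur — the C-terminal offset of the
  $y_i$ site equals $i \ge 1$ — and is pinned to 0.
* The near-null common shifts of $\Delta(\cdot, d)$ at the remaining core
  offsets $d \in \{-2,-1,1\}$ (they cancel except at window truncation) are
  fixed by sum-to-zero constraints over the 20 residues.

That leaves 130 free parameters out of 156. The synthetic-data generator
projects its ground truth onto this same gauge before any spectrum is
generated, which is what makes *exact* recovery a meaningful test: fitting
noiseless data recovers every free parameter to machine precision.

With `ridge = 0` the fit refuses rank-deficient designs rather than
returning an arbitrary pseudo-inverse solution; small training sets (fewer
than roughly 150 peptides, where some penultimate-class residues may never
occur in first position) should pass a small ridge such as `1e-6`.

Training responses are extracted by matching each theoretical monoisotopic y
m/z to the nearest experimental peak within a tolerance (default 0.5 Da for
ion-trap CID; 0.02 Da suits HCD), with distance ties going to the higher
intensity; a ratio is kept only when both matched peaks reach 1% of the base
peak, so detector-floor noise never enters the regression. Isotope peaks are
not folded back in during training — the monoisotopic grid is the simplest
consistent inverse of the prediction.

## Scoring and re-ranking

Agreement between a predicted and an experimental spectrum is quantified
three ways:

* **Pearson CC** over the y-ion index grid (length $n-1$), with unmatched
  ions carrying experimental intensity 0. The grid reading, rather than
  binned m/z, matches a theoretical spectrum that consists of y ions.
  A zero-variance vector would make the correlation undefined; it is
  returned as 0 with a `degenerate` flag so downstream score arithmetic
  stays finite.
* **Square-root spectral similarity**
  $\sum_m \sqrt{I^1_m I^2_m} / \sqrt{(\sum_m I^1_m)(\sum_m I^2_m)}$ over
  1 Da m/z bins — bounded in $[0,1]$ by Cauchy–Schwarz, symmetric, and
  invariant to rescaling either spectrum.
* **Shared-peak count** by greedy nearest-first one-to-one matching. Greedy
  is reproducible and optimal in the generic case; on adversarial spacings
  it can fall one pair short of the maximum matching, and greedy's value is
  the contract.

PSMs from SEQUEST are re-scored as $X_{corr} + 5\,\Delta C_n + 5\,CC$ and
from X!Tandem as $\#SharedPeaks \cdot \sqrt{S_T} \cdot CC + S_T$. FDR is
estimated by the decoy-count method, $FDR = FP/(TP+FP)$, with the decoy
count proxying $FP$ and accepted targets playing $TP+FP$; no factor-of-two
concatenated-database correction is applied. Ties are broken decoys-first
(the conservative order), and a cumulative minimum from the strict end makes
the reported q-like curve monotone so "PSMs at FDR $q$" is well defined.

The engine-only baseline against which re-ranking is compared is the
combined score with the CC term removed ($X_{corr} + 5\,\Delta C_n$ for
SEQUEST, $S_T$ for X!Tandem). This choice makes an exact invariant hold:
a constant, fully uninformative CC cannot change the accepted count at any
threshold.

## What the synthetic generator emulates — and what it does not

`generate_pairs()` / `generate_dataset()` draw uniform-composition tryptic
peptides (lengths 7–20, C-terminal K/R), sample gauge-canonical ground-truth
parameters ($\Delta \sim N(0, 0.5)$, $G \sim N(0,1)$), predict each
spectrum, and only then corrupt it: multiplicative log-normal intensity
noise (default $\sigma = 0.3$), peak dropout (default 10%), m/z jitter
(0.01 Da), and uniform-m/z junk peaks at 5% of the base peak. Because noise
is injected strictly after prediction, the generator and the trainer share
no path that would make recovery circular. Everything is byte-reproducible
under a seed.

The log-normal choice has a useful closed consequence: an observed log ratio
is the difference of two independent noise terms, so training residuals
should show RMS $\approx \sqrt{2}\,\sigma$ — a calibration the tests check
(and the fits reproduce: measured residual RMS ≈ 0.42 at $\sigma = 0.3$).

`generate_psm_benchmark()` adds a decoy-laden PSM table: decoy rows carry
shuffled-peptide labels (C-terminal residue kept, preserving tryptic
character) against the original peptide's spectrum; engine scores come from
overlapping normals (xcorr-like: targets $N(3,1)$, decoys $N(1.5,1)$). The
`cc_signal` knob is the probability that a target's spectrum really was
generated from its own peptide. At `cc_signal = 1` the recomputed CC
separates targets from decoys and re-ranking roughly doubles the accepted
PSMs at FDR 1% on the default benchmark. At `cc_signal = 0` every spectrum
is unrelated to its label and CC becomes exchangeable noise between targets
and decoys — note that this *degrades* the combined ranking rather than
leaving it unchanged, because a noisy score component always blurs the
target/decoy separation; only a *constant* CC leaves accepted counts exactly
invariant.

What the generator does not emulate: real instrument noise physics,
b/a/neutral-loss ion series, chimeric spectra, modified residues, or
realistic peptide composition. Passing the recovery and re-ranking tests
therefore demonstrates that the estimator and pipeline are correct and
well-calibrated for data generated by the model class — not that the model
attains any particular accuracy on real instrument data, which would require
annotated spectral libraries.

## Numerical choices and problem sizes

* Fitting assembles a sparse design (one row per observed ratio, one column
  per free parameter) and solves by QR; `ridge > 0` is implemented by row
  augmentation, keeping the same solver and an explicit rank check at
  `ridge = 0`.
* Predicted peaks closer than $10^{-4}$ Da are merged by summing before the
  final sort; spectra are renormalised to base peak 100 (the normalisation
  is a display convention — every score used downstream is scale-free).
* The validation suite uses 500 noiseless and 2,000 noisy training pairs for
  parameter recovery, 1,000 draws for the energy-oracle equivalence, and a
  1,000-PSM benchmark for the re-ranking lift; these sizes give tight Monte
  Carlo bands while keeping a full run on one CPU in a few minutes.
* All randomness flows through explicit seeds (`withr::with_seed`), and the
  file writers use fixed numeric formats, so every dataset, fit and
  re-ranking is byte-reproducible.

## Known limitations

* y-series only, singly charged fragments, doubly charged precursors,
  unmodified peptides. b ions and neutral losses are out of scope.
* The penultimate site class gives the diketopiperazine channel positional
  effect only at $y_{n-1}$; any milder position dependence elsewhere is
  absorbed into the residue terms.
* The square-root similarity is computed on fixed-width bins; peaks
  straddling a bin boundary within tolerance of each other do not match.
  The Pearson CC path, which matches by distance, does not share this
  artefact.
* Engine-native result formats (pepXML, sqt) are not parsed; PSMs enter
  through a documented TSV schema and conversion is the caller's
  responsibility.
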