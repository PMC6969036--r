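---
title: "Charge-based design of ultra-stable cytoplasmic antibodies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge-based design of ultra-stable cytoplasmic antibodies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standr)
```

## The problem and the model

Single-chain antibody fragments expressed in the cytoplasm cannot form
their stabilising disulfide bonds and frequently aggregate. Empirically,
the property that separates stable from aggregation-prone intrabodies is
not the net charge at pH 7.4 — the quantity most charge-engineering
heuristics use — but a low isoelectric point together with a strong net
negative charge *at pH 6.6*, the acidic end of the physiological
cytoplasmic range. Constructs satisfying both are designated STANDs
(ultra-stable cytoplasmic antibodies), and the practical route to them is
fusion of strongly acidic peptide tags (s3Flag at the N-terminus, HA at
the C-terminus) rather than mutagenesis of the antibody itself.

standr's charge model is the isolated-residue Henderson–Hasselbalch sum.
Each ionizable group contributes its protonation-state expectation:

$$Z(\mathrm{pH}) = \sum_{\text{basic}} \frac{1}{1+10^{\mathrm{pH}-pK_a}}
  \;-\; \sum_{\text{acidic}} \frac{1}{1+10^{pK_a-\mathrm{pH}}}$$

over the side chains D, E, H, C, Y, K, R and, when the terminus is free,
the α-amine and α-carboxyl. Every group is treated as isolated: there are
no structural pKa shifts, no temperature correction, and no electrostatic
coupling. That is knowingly wrong for a folded protein, but it is the
convention under which the designation thresholds were established, and it
makes the model a strict, monotone function of sequence composition —
which is what a screening heuristic needs.

Two useful consequences follow. First, $Z$ is strictly decreasing in pH
for any peptide with at least one ionizable group, so the isoelectric
point (the unique root of $Z$) can be found by plain bisection with a
guaranteed bracket on pH [0, 14]; `isoelectric_point()` uses tolerance
$10^{-3}$ pH. Second, charge is exactly additive over concatenation when
termini are excluded, which is what makes tag-fusion design compositional:
internal junctions contribute nothing, and only the outermost termini
carry the terminal groups. `build_fusion()` enforces exactly that.

## The pKa set and its calibration

No single "correct" isolated-residue pKa table exists; published tools
differ by a few tenths of a unit per group. The package default
(`pka_default()`) is D/E 4.4, H 6.5, C 8.5, Y 10.0, K 10.0, R 12.0,
N-terminus 8.0, C-terminus 3.1, chosen because it reproduces the three
published tag anchors used for calibration — s3Flag net charge −7.0 e at
pH 7.4, s3Flag pI 4.48, HA pI 3.53 — within ±0.15:

```{r}
calibrate_pka(pka_default())
```

It also reproduces the published HA net charge of −2.2 e, at pH 7.4 with
both termini free (computed value −2.21). The set is a plain parameter:
any `pka_set()` can be substituted, serialized with `write_pka()`, and
every screening report echoes the set's name so results remain
attributable. `calibrate_pka()` exists to catch silent drift if the
default is ever edited.

## Designation thresholds and ranking

The designation rule in `stand_criteria()` is pI ≤ 5.5 **and**
charge ≤ −6 e at pH 6.6 (inclusive on both boundaries). The published
work establishes a continuous correlation between charge and aggregation
rather than a sharp cut-off, so these numbers are inferred from the gap
between its successful constructs (fusion pIs 4.48–5.08, charges −6.1 to
−7.1 e at pH 6.6) and its failures (an s3Flag-only fusion at −5.2 e still
aggregated in ~8% of cells); treat them as a starting point, not a law.
Both thresholds and the criterion pH are arguments. The designation is
monotone by construction: making a construct more acidic can never revoke
it.

`suggest_tag_combinations()` enumerates ordered tag subsets (at most two
per terminus) and ranks by charge at the criterion pH, breaking ties by pI
and then id. Charge ranks first because it is the directly engineered
quantity; pI, which correlates more strongly with aggregation across
panels, serves as the tie-breaker and is always reported alongside. Note
that exhaustive enumeration will happily propose the same acidic tag at
both termini when that maximises negative charge; whether such a construct
is practical (e.g. for antibody detection) is a wet-lab decision the
ranking does not make.

The report pH set {6.6, 7.03, 7.4} spans the cytoplasmic range; 7.03 is
reported for completeness only and never enters designation.

## Aggregation statistics

Aggregation is measured as the percentage of transfected cells bearing
visible intrabody aggregates, counted over at least 100 cells per dish;
`aggregation_summary()` flags dishes below that count and reports
per-construct means with SEM (sample SD, $n-1$ denominator, over
replicate dishes). The charge–aggregation association is summarised by
the sample Pearson correlation with the exact t transform
$t = r\sqrt{n-2}/\sqrt{1-r^2}$, two-tailed — two-tailed because it
reproduces the published panel p-values from their $(r, n)$ pairs:

```{r}
r_to_p(0.6168, 17)   # charge at pH 6.6 vs aggregation, published P = 0.008179
r_to_p(0.8392, 17)   # pI vs aggregation, published P = 0.000025
```

A seeded permutation test on $|r|$ is available for small panels where
the t approximation deserves a check. Correlations use per-construct mean
rates (one point per construct), and the *signed* charge: a positive r
means less-negative constructs aggregate more.

## The two validation fits

**Saturation binding.** ELISA responses, after subtraction of
carrier-only control wells (`specific_binding()`, negative differences
clipped to zero with a warning), are fit to the Hill–Langmuir form
$B = B_\max c/(K_d+c)$ with the Hill coefficient fixed at 1 and no
weighting. Replicate wells are pooled as extra points. The optimizer is
Levenberg–Marquardt (`minpack.lm::nlsLM`) from $B_{\max,0}=\max B$,
$K_{d,0}=\mathrm{median}(c)$. A fit is reported non-converged when the
optimizer fails, when the fitted $K_d$ lies far beyond the measured
concentration range (saturation never approached — the regime where only
the initial slope $B_\max/K_d$ is identified), or when the $K_d$ standard
error exceeds the estimate.

**Thermal unfolding.** Isothermal heating in the presence of a
hydrophobicity-sensing dye yields a rising fluorescence time course. The
half-life is fit with the same rectangular-hyperbola form transplanted to
the time domain, $F(t) = F_0 + (F_\max-F_0)\,t/(t_{1/2}+t)$, with a
baseline $F_0$ because raw fluorescence has nonzero background. Constant
or declining traces are rejected with a diagnostic rather than fit.

Both fits are deterministic given the data; noiseless round-trips through
the generators recover the generating parameters to $10^{-6}$ relative,
and under 2% Gaussian noise the median relative $K_d$ error across 200
seeded replicates stays below 10%.

## What the synthetic generators emulate — and what they do not

The generators exist so that every analysis path is testable end-to-end
with no external data:

- `simulate_scfv_set()` draws panels (default $n=17$, matching a typical
  screening panel) from a miniature VH–linker–VL framework with three
  CDR-like variable windows sampled from a residue-frequency model, fused
  with s3Flag/HA by default.
- `simulate_aggregation_data()` makes the charge–aggregation link explicit:
  true rate $= \mathrm{clip}(a + b\,Z_{6.6} + \varepsilon,\,0,\,100)$,
  discretised into three binomial replicate counts over 200 cells. The
  defaults $a=38$%, $b=+3$% per e, $\sigma=3$% were chosen once so that a
  default panel (charges roughly −14 to −7 e) spans ~0–20% aggregation
  with a clearly positive signed-charge correlation, echoing the published
  panel's structure (strongly negative constructs near zero aggregation);
  clipping at 0 is reached for the most negative constructs, as in real
  panels.
- The assay-curve generators add Gaussian noise (a stated fraction of
  $B_\max$ or $F_\max$) to the exact model curves.

All generators are pure functions of their arguments and a single integer
seed, restore the caller's RNG state, and emit data satisfying the
consuming functions' input contracts by construction.

What they do **not** emulate: real CDR sequence statistics, any physical
aggregation mechanism (the linear charge–rate model is a statistical
stand-in, not biophysics), plate effects or heteroscedastic assay noise,
and expression-level differences. Passing the round-trip tests therefore
demonstrates the correctness of the computations, not the biological
validity of the charge–stability rule — that validation is experimental.

## Numerical choices and edge cases

- Bisection tolerance $10^{-3}$ pH; reported pIs are conventionally
  rounded to 2 decimals, full precision is returned.
- A peptide with no ionizable groups, or one whose charge never changes
  sign on [0, 14], has no pI; this raises a dedicated
  `standr_pi_undefined` condition, which screening converts to a warning
  and `is_stand = FALSE`.
- Unknown residue letters are rejected with the offending position;
  a lenient mode maps the IUPAC ambiguity letters to non-ionizable with a
  recorded warning. Silent miscounting is never allowed.
- Boundary behaviour: at pH 0/14 the charge approaches the basic/acidic
  group counts, but groups whose pKa lies within ~2 units of the boundary
  (notably arginine at the alkaline end) are still visibly incomplete
  there; tests of the limit property account for this.
- Fits: tolerances $10^{-12}$ (ftol/ptol), 500 iterations; parameter
  positivity is checked on the estimates rather than imposed as hard
  optimizer bounds, and violations are reported as non-convergence with a
  diagnostic.
- Problem sizes used in the self-tests — panels of 17 constructs, 8-point
  dilution series, 21-point time courses, 200-replicate noise studies,
  100-peptide property sweeps — mirror the scale of the corresponding
  experiments while keeping the full suite fast.

## Known limitations

- The isolated-residue model ignores folding; computed pIs for folded
  scFvs are systematically approximate. This is intrinsic to the method,
  not an implementation gap.
- The designation thresholds are calibrated to one family of published
  constructs; other scaffolds may need different cut-offs.
- The package predicts no absolute aggregation percentage — only the
  screening quantities (charge, pI) that correlate with it.
- Tag junctions default to direct concatenation; vendor cloning scars must
  be supplied explicitly as linker segments if charge-relevant (they
  rarely are, being typically Gly/Ser).
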