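---
title: "Methods: tRNA recognition, kinetics and melting-curve analysis in nsun6kit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tRNA recognition, kinetics and melting-curve analysis in nsun6kit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nsun6kit)
```

# Scope

NSun6 enzymes install 5-methylcytosine at position 72 (m⁵C72) of tRNA, the
3′-strand cytosine of the last acceptor-stem base pair. The archaeal enzyme
(from the hyperthermophile *Pyrococcus horikoshii*, here "PhNSun6") and the
human enzyme ("hNSun6") read different identity elements from the acceptor
end of the tRNA and consequently methylate disjoint substrate sets.
`nsun6kit` provides the desk-scale machinery to study that specificity:

* a deterministic cloverleaf parser with canonical numbering,
* a rule-based substrate classifier for both enzymes,
* a constraint-driven synthetic tRNA generator,
* simulation and double-reciprocal fitting of steady-state methylation
  kinetics, and
* simulation and first-derivative analysis of two-state UV melting curves.

# The cloverleaf model and parser

## Numbering convention

Canonical tRNA numbering is used throughout: acceptor stem pairs 1:72
through 7:66, discriminator base 73, CCA terminus 74–76, D-stem pairs
10:25 through 13:22, anticodon stem 27:43 through 31:39 with the anticodon
at 34–36, T-stem 49:65 through 53:61. Variable-region residues receive no
canonical numbers, and Sprinzl insertion codes (17a, e-positions) are not
implemented; no coordinate used by the recognition rules requires them.
Internally, sequence indices are 1-based inclusive (the R convention); all
user-facing coordinates are canonical positions.

## Parsing strategy

`parse_cloverleaf()` is a 3′-anchored template parse, not a thermodynamic
folder:

1. **CCA and discriminator.** If the sequence ends in CCA, the
   discriminator is the 4th residue from the 3′ end; otherwise the last
   residue, with `cca_present = FALSE` (this path is what makes the
   ΔCCA mutant analysable rather than an error).
2. **Acceptor stem.** The 7 residues 5′ of the discriminator are paired
   against residues 1–7. At least 5 of the 7 pairs must be Watson–Crick or
   wobble (G:U/U:G), otherwise parsing fails. The permissive threshold
   lets single mutated or mismatched pairs (e.g. the 2:71 swap mutants)
   parse normally.
3. **Anticodon arm.** A 5-bp stem with a 7-nt loop is sought in the
   central window. Candidates are scored by (valid pairs, anticodon-loop
   flank convention — U at loop position 2 and a purine at position 6,
   i.e. the near-universal U33/R37 signature — then Watson–Crick pairs).
   Ties among top-scoring candidates are broken by overall cloverleaf
   consistency: the candidate that leaves the best D-stem upstream
   (preferring a 4-bp stem with a canonical 7–11 nt D-loop) wins, then the
   5′-most. The consistency tie-break exists because on GC-rich random
   sequence a chance all-Watson–Crick hairpin occasionally appears away
   from the true arm; judging candidates jointly with the rest of the
   cloverleaf removes that ambiguity.
4. **T arm.** Fixed position: the 5-bp stem + 7-nt loop immediately
   preceding the acceptor 3′ strand.
5. **D arm.** The best 3–4 bp stem between position 9 and the anticodon
   arm, preferring 4 bp, then a stem 3′ end exactly one residue before the
   anticodon arm (the canonical position-26 spacing), then the 5′-most
   start, and only then pair count. Position, not pairing quality, leads
   these tie-breaks: the D-arm of a canonical tRNA is where the template
   says it is, and preferring better-paired decoys would mis-number
   wobble-containing D-stem mutants.

The parse is deterministic: identical input yields identical annotation.
A 3-bp D-stem reports pairs 10:25–12:23 and leaves 13:22 out of the
position map; `element_profile()` reports missing positions as
unpaired/absent rather than erroring.

One genuine ambiguity is refused at generation time rather than papered
over: a CCA-less tRNA whose final residues (71=C, 72=C, 73=A) happen to
spell "CCA" cannot be distinguished from a CCA-terminated tRNA by any
3′-anchored rule, so `generate_scaffold()` raises an infeasible-constraint
error for that combination.

# Recognition rule sets

A `rule_set` constrains the identity-element profile: CCA presence, the
residue at the target site 72, the discriminator 73, and ordered base
pairs at 2:71, 3:70 and the D-stem positions. The built-ins encode what
the methylation assays established:

* **PhNSun6 (archaeal):** CCA required, C72, N73 ∈ {U, G}, 2:71 = C:G.
  Pair 3:70 and the D-stem are deliberately unconstrained — swapping them
  does not abolish methylation.
* **hNSun6 (human):** CCA required, C72, N73 = U strictly, 2:71 = G:C.
  The published element set for the human enzyme also involves 3:70 and
  D-stem contacts; their exact allowed values are not needed to reproduce
  any panel outcome here, so they are representable in the `rule_set`
  schema but left unconstrained by default rather than invented.

Pairs are compared as ordered (5′, 3′) tuples, so C2:G71 and G2:C71 are
different elements — this single comparison is what makes the archaeal and
human substrate sets disjoint. Classification is a conjunction: a tRNA is
a substrate iff every constrained element matches, and every failure is
reported with observed versus required values. Verdicts are binary;
quantitative differences between substrates (e.g. turnover 4.30 vs 3.04
per minute) belong to the kinetics module, not the classifier.

Two extrapolations are flagged rather than hidden. The seven G73
substrates are encoded with C2:G71, which the assays imply but do not
print member-by-member. G2:U71-bearing tRNAs (which exist in the genome)
are rejected by the archaeal rule set; their true status is untested.

# Synthetic tRNA scaffolds

`generate_scaffold()` builds sequences with fixed canonical geometry:
7-bp acceptor stem, 2-nt linker (U8, purine 9), 4-bp D-stem with 9-nt
D-loop, 5-bp anticodon stem with 7-nt loop (U33/R37, anticodon settable),
a 4-nt variable region (14-nt unstructured for type-II/serine scaffolds),
5-bp T-stem with 7-nt loop carrying the T54-Ψ55-C56 motif, discriminator
and optional CCA — 76 nt for type I, 86 nt for type II. Constrained
positions are set exactly; free stem pairs are Watson–Crick with the G:C
proportion at `gc_content_target` (default 0.7, emulating
hyperthermophile tRNAs); free loop residues are uniform. Everything is
deterministic given the seed, and panel mutants are produced by applying
the named mutation operations to the parsed wild-type scaffold, never by
resampling — so a mutant differs from its wild type at exactly the
mutated positions.

What the generator does **not** emulate: true genomic *P. horikoshii*
sequences (none are printed in full anywhere we could take them from),
natural variation in D-loop and variable-arm lengths, modified
nucleosides (m⁵C72 is treated as a label, not a sequence change), and
intron-containing or mitochondrial tRNAs. Passing classification tests on
generated scaffolds therefore demonstrates that the rules and the parser
are mutually consistent and reproduce the published truth tables — not
that the parser handles every natural tRNA gene.

# Steady-state kinetics

Initial velocities follow v = k~cat~·[E]·[S]/(K~m~ + [S]) with
concentrations in μM internally (enzyme accepted in nM at the interface).
The default assay design mirrors the published protocol: 100 nM enzyme
and S ∈ {0.1, 0.25, 0.5, 1, 2.5, 5, 10, 40} μM, with progress curves
sampled at 2–8 min.

Estimation is by **unweighted ordinary least squares on double
reciprocals** (Lineweaver–Burk): 1/v regressed on 1/[S], V~max~ =
1/intercept, K~m~ = slope/intercept, k~cat~ = V~max~/[E]. This is exactly
the published fitting procedure, and fidelity to it is the point: the
transform's well-known noise bias (reciprocal errors blow up at low [S])
is accepted rather than corrected. A direct Levenberg–Marquardt fit of
the untransformed rates ships as an internal cross-check
(`nsun6kit:::fit_mm_nls`) and agrees with the double-reciprocal route
exactly on noiseless data; it is an oracle for testing, not an
alternative estimator.

The simulation noise model is multiplicative Gaussian on rates (relative
sd, redrawn when a draw would be non-positive), chosen because
scintillation-count errors scale with signal and no error model is
published. Under 5% relative noise and 500 replicates the median
recovered K~m~ and k~cat~ stay within 10% of the generating values at the
default design — the double-reciprocal bias is real but modest at this
noise level.

```{r}
fit <- fit_lineweaver_burk(simulate_initial_rates(mm_params(4.30, 0.43)))
coef(fit)
```

# Two-state melting curves

The unfolded fraction follows the van't Hoff form

$$\theta(T) = \frac{1}{1 + \exp\!\big(\tfrac{\Delta H_{vH}}{R}
  (\tfrac{1}{T} - \tfrac{1}{T_m})\big)}$$

with temperatures in kelvin, a single temperature-independent enthalpy
(default 250 kJ/mol, a typical tRNA unfolding cooperativity) and linear
folded/unfolded baselines (defaults flat at 0.25 and 0.30 AU, matching a
scan started at A260 ≈ 0.2–0.3). Absorbance interpolates the baselines by
θ, plus optional additive Gaussian noise. The default grid is 25–95 °C at
0.1 °C; the instrument cadence (1 °C/min heating, one sample per degree)
is exercised in tests as the coarse-grid case.

## The derivative readout

T~m~ is determined from the first derivative of the melting curve. One
numerical subtlety drives the implementation: the van't Hoff sigmoid is
symmetric in 1/T, not in T, so the peak of dA/dT sits *below* the true
midpoint by approximately 4R²T~m~³/ΔH² — about 0.17 °C at 250 kJ/mol,
larger for broader transitions. `estimate_tm()` therefore differentiates
with respect to inverse absolute temperature by default
(`method = "dinvT"`): the peak of dA/d(1/T) coincides exactly with the
midpoint, the estimator recovers noiseless curves to well within grid
resolution, and it remains invariant to affine rescaling of the
absorbance axis. The plain dA/dT readout is available as
`method = "dT"` for comparison with instrument software that reports it.

The pipeline is: centered moving-average smoothing of the trace
(`smooth_window`, default 5 points — keep small for clean curves, widen
to ~2 °C for noisy instrument traces), central differences, the same
smoothing applied to the derivative, then a least-squares parabola fitted
over a window of ±`peak_halfwidth` (default 7.5 °C) around the maximum,
with the window symmetric in 1/T and re-centred on the vertex. The vertex
of a symmetric window around a symmetric peak is unbiased, and averaging
over the whole transition makes the estimate far more noise-tolerant than
a 3-point interpolation of the argmax. A derivative maximum at the scan
edge raises a boundary-peak error (truncated transition) instead of
returning a guess.

Reported T~m~ values are rounded to 0.1 °C (`print()` and `delta_tm()`);
internal values keep full precision. ΔT~m~ is modified minus unmodified.

```{r}
est <- estimate_tm(simulate_melting_curve(melt_curve_model(66.3)))
est
```

# Numerical choices and degenerate inputs

* Double-reciprocal fitting requires ≥4 distinct positive substrate
  concentrations and strictly positive rates; a non-positive intercept is
  a singular-fit error, not a silent negative K~m~.
* `estimate_initial_rate()` needs ≥3 time points inside its window and is
  exact on noiseless linear phases.
* `estimate_tm()` requires ≥20 grid points and an odd smoothing window.
* Unparseable tRNAs in a panel scan are reported as non-substrates with a
  parse-failure violation; they never abort the run.
* Every stochastic operation takes an explicit seed and restores the
  global RNG state; unseeded calls draw from the global generator.

# Problem sizes

The shipped tests and the reproduction report run entirely at desk scale:
panels of 3–23 generated tRNAs, 8-point rate datasets with 500-replicate
noise studies, 701-point melting curves with 200-replicate noise studies,
and exhaustive enumeration of 4 × 16 × 2 × 2 identity-element
combinations. Everything completes in well under a minute on one CPU.

# Known limitations

* The parser is a template matcher for canonical (and type-II) cytosolic
  tRNAs; it does not fold thermodynamically and will mis-handle
  non-canonical geometries (mitochondrial, truncated, intron-containing).
* The human rule set is reduced to the constraints needed here; a scan of
  human tRNAs against it will over-accept sequences that the real enzyme
  rejects via D-stem contacts.
* Kinetics ignores SAM co-substrate dependence, product inhibition and
  thermal inactivation; temperature is metadata only.
* Thermal analysis is strictly two-state with temperature-independent
  enthalpy; multi-transition unfolding, Mg²⁺ dependence and hysteresis
  are out of scope, and ΔH~vH~ is an input, never fitted.
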