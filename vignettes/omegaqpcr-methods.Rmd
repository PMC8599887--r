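---
title: "Measuring absolute telomere length with circularizable probes: models and design choices"
author: "omegaqpcr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring absolute telomere length with circularizable probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omegaqpcr)
```

## The measurement model

Human telomeres are tandem `(TTAGGG)n` tracts. The assay this package
models measures their absolute length by saturating the tract with
circularizable (padlock-style) probes: each probe's 5'- and 3'-terminal
arms hybridize to adjacent positions on the G-rich strand so the two ends
abut, a ligase seals probes whose junction bases are correctly paired, and
only the resulting circles support qPCR amplification. The number of
circularized probes is therefore directly proportional to the length of
telomere they tiled.

Two constants turn a circle count into base pairs. Each circularized probe
hybridizes a footprint of 32 bases, and where two probes abut their
stem-loops additionally occlude target sequence, for 48 bp of telomere
consumed per probe. With $N_{cp}$ circularized probes,

$$\mathrm{TL} = 48\,(N_{cp} - 1) + 32 .$$

`tlFromCount()` implements this formula and `tileProbes()` is its exact
inverse image, the saturating probe count $\lfloor (L-32)/48 \rfloor + 1$
for a tract of length $L$. The pair are mutual inverses on the lattice
$\{48(N-1)+32\}$; off-lattice lengths quantize downward by less than one
occlusion width, which is the assay's intrinsic resolution (and matches the
replicate spreads seen in validation work: one probe's occlusion for a
1.6 kb target, one stem-loop for a 0.8 kb target).

The footprint and occlusion constants are held in a `ProbeGeometry` object
rather than derived from the probe's segmentation. The printed account of
the probe describes 16-base arms (32 hybridized bases) with 7-base
stem-loops, numbers that do not quite agree with each other or with the
only segmentation consistent with the published 88-mer (17 + 14 arm bases);
the quantification formula, not the segmentation, is authoritative for
length, so the geometry constants default to 32 and 48 and are configurable
independently of the sequence.

## Probe architecture and junction discrimination

`buildProbe()` concatenates five segments 5'→3': the 5' arm, the
reverse-primer binding region (reverse complement of the reverse primer),
the forward primer, the hydrolysis-probe binding region, and the 3' arm.
The default segments reconstruct the published 88-mer telomeric probe
byte-for-byte, and `linearizeToORF()` returns its cyclic rotation starting
at the forward primer — the linear "ORF" form used to build standard
curves, which amplifies like a circle because both primer sites flank the
amplicon.

Ligation requires correct Watson–Crick pairing at the nick.
`checkLigationJunction()` aligns the junction-spanning stretch (3' arm
followed by 5' arm) against a target window at the complementarity-
maximizing offset (ties resolve to the designed phase) and applies two
rules:

* **junction rule** — both target bases spanning the nick (the `TA` of
  `GGGTTAGGG` for the default probe) must pair; a single mismatch at either
  base aborts ligation outright;
* **hybridization premise** — each arm may carry at most two mismatches at
  the chosen alignment. Padlock arms of 14–17 nt tolerate essentially no
  mismatches at a 16 °C ligation, and without this premise a 7-mer
  subtelomeric variant repeat (`TTXAGGG`) could slip phase until its two
  junction bases happened to pair while the arms were only half
  hybridized — a physically meaningless alignment.

The two rules together reproduce the designed discrimination: canonical
windows ligate at every repeat phase, any single substitution at a
junction-covered base is rejected, and variant-repeat windows are rejected
for every concrete variant base.

`armMeltingTemperature()` supports arm design for non-default targets with
a nearest-neighbor duplex Tm (unified 1998 parameter set with an entropic
salt correction; the 1986 parameter set is available as an independent
cross-check). The values are advisory only — the assay fixes hybridization
empirically with a slow 55→16 °C ramp, and no stem-loop folding or
cross-dimer screening is modeled (deliberately out of scope).

## From quantification cycles to copies

Two calibration routes coexist, because their published forms are not
exactly consistent with one another:

* `fitStandardCurve()` fits Cq against log10(copies) by least squares and
  derives the amplification efficiency $10^{-1/\mathrm{slope}} - 1$
  (a slope of −3.3219 is perfect doubling; the published slope of −3.3649
  gives 98.2 %).
* `expCalibration()` carries the closed-form calibration
  $N_{cp} = 4\times10^{11} e^{-0.691\,C_q}$ with its published rounded
  constants. Note $0.691 \ne \ln 10 / 3.3649 = 0.684$: the rounding
  introduces up to ~1 % drift against a curve fitted to the same data,
  which is why fitting is preferred whenever calibration points exist. Both
  parameterizations agree within 1 % over Cq 10–35 when cross-fitted, and
  both are retained rather than reconciled.

Circle counts are carried as reals end to end and rounded only at final
bp reporting; the published worked example's totals are reproducible only
with unrounded intermediates. Non-detects are explicit (`NA`), never
encoded as zero, and `backgroundGate()` removes wells at or beyond the
negative-control band (Cq ≥ 40 by default) before quantification.
`quantifyTelomeres()` chains these steps for a batch, aggregates
replicates by mean Cq, and propagates the Cq spread to length by a
first-order delta method
($\mathrm{sd(TL)} \approx 48\,k\,N_{cp}\,\mathrm{sd}(C_q)$ under the
exponential calibration).

For the plasmid validation design, template copy numbers come from DNA
mass via `massToMolecules()`; for non-preset plasmids the
molecules-per-microgram constant is computed from total length at
650 g/mol/bp, which reproduces the published constants within 2 %.

## Mean telomere length per cell

A per-cell total telomere length only becomes a mean telomere length (MTL)
once the number of telomeres is known, which requires ploidy and
cell-cycle stage. `telomereCount()` counts two telomeres per chromosome
(so 47 chromosomes → 94 telomeres; 64 → 128) and doubles again in G2/M for
sister chromatids. Karyotype presets bracket aneuploid lines with
low/modal/high chromosome counts; `computeMTL()` reports all three
scenarios, ordered inversely to the count. The K-562 preset's implied
count (134) is not printed in primary sources and is flagged as
derived-from-karyotype in its model object.

Cell-cycle stage comes from a single-copy gene: its Cq, through a
pg-scale calibration (`fitScgCurve()`), estimates the cell's DNA content,
which is compared with the 6.6 pg diploid G1 reference. The G2 threshold
is not something the source work quantifies (it assumes G1 throughout), so
the call uses a configurable dead zone, default ratio 1.4–1.6 around 1.5:
below it G1, above it G2/M, inside it `ambiguous`, which downstream
counting refuses to resolve silently.

## TRF densitometry comparison

`trfMTL()` computes the cross-method comparator: mean telomere length from
a Southern-blot terminal-restriction-fragment lane. The lane's 1-D optical
density trace is calibrated against a marker ladder by a log-linear fit of
log10(length) on migration position (`fitMarkerCurve()`; a reciprocal-law
alternative is provided since the functional form is a convention, not a
measurement). Longer fragments bind proportionally more probe, so raw OD
over-weights long telomeres; the corrected mean is

$$\mathrm{MTL} = \frac{\sum_i OD_i}{\sum_i OD_i / L_i}$$

over background-subtracted bins. Background defaults to a constant
estimated from the profile tails (5 % of bins at each end), and bins
migrating outside the ladder span are excluded unless extrapolation is
explicitly requested — the top marker bounds trustworthy calibration.

`synthLane()` is the generator used to validate this estimator. It places
the six standard markers (23.13 … 2.02 kbp) at the positions an ideal
log-linear gel implies — not at equal spacings, which would make the
fitted calibration disagree with the generator's own bin mapping and bias
every recovery — then lays down a delta or log-normal fragment-length
distribution with OD proportional to fragment length, as on a real blot.
At zero noise the estimator recovers the distribution's number-mean length
exactly (log-normal case) or within one bin (delta case). Real blots
differ in ways the generator does not emulate: nonconstant background,
lane distortion, partial digestion and subtelomeric sequence in each
fragment; published lane-derived MTLs therefore serve as context, not as
desk-reproducible targets.

## The forward simulator

`simulateAssay()` closes the loop: given tract lengths (or an explicit
repeat-unit target whose junction fidelity is decided from sequence),
template copy numbers, ligation probabilities, Poisson background circles
and a calibration, it tiles, ligates, and maps circle counts to Cq by
inverting the calibration and adding Gaussian noise. Defaults mirror the
validation conditions: saturating tiling (the assay's slow ramp is
designed to approach saturation; a random-sequential-adsorption mode
exists for exploring sub-saturation, and provably never exceeds the
saturating count), ligation probability 1 at matched junctions with a 1 %
mismatch leak (discrimination minimizes, not eliminates, mis-ligation),
and the exponential calibration. Fewer than one circle is reported as a
non-detect, not an error — which also means sub-copy backgrounds appear as
non-detects rather than as very late Cq values (one circle corresponds to
Cq ≈ 38.7 under the default calibration).

`recoverAssay()` runs the quantification calculus on the simulated Cq
values. Its default divides the estimated circle count by the template
copy number *before* applying the occlusion formula (per-template
recovery), which makes noiseless recovery exact on the length lattice —
800 bp is the lattice point $48\cdot16+32$ and recovers exactly, while
1600 bp tiles to 33 probes and recovers as the lattice point 1568 bp. The
batch path in `quantifyTelomeres()` instead follows the published order
of operations (formula on the total count, then division), which differs
from per-template recovery by at most one occlusion width spread across
the copies. Both orders are deliberate and documented because they answer
slightly different questions: the former recovers a single template's
length, the latter reproduces the published worked example.

Problem sizes in the shipped tests were chosen to exercise every property
at desk scale: the lattice round trip runs over all counts up to $10^6$,
simulator recovery uses $10^3$–$3.6\times10^4$ template copies with 10
replicates, and synthetic lanes use 400 bins. The delta-method spread
prediction is verified at Cq noise 0.05–0.1 cycles with 10 replicates
under fixed seeds.

## What the synthetic generators do and do not show

Passing tests on simulated data demonstrate that the calculus is
self-consistent — tiling, calibration, recovery and the TRF estimator
invert each other under the model's own assumptions. They cannot
demonstrate wet-lab accuracy: hybridization saturation, ligase fidelity,
amplification efficiency drift and blot physics enter only through the
parameters exposed here (`pLigateMismatch`, `cqNoiseSd`,
`backgroundCircles`, OD noise), not from first principles. The published
replicate spreads (±19.6 and ±42.3 bp for the 0.8/1.6 kb validation
targets) imply a Cq noise scale the source never states, so the simulator
exposes noise as a free parameter rather than claiming to reproduce those
numbers.

## Numerical and degenerate-input conventions

* Zero circularized probes → length 0 with a warning; counts in (0, 1)
  extrapolate the formula below one footprint, floored at 0 bp.
* Cq values must be positive; non-detects are `NA` and must be gated, not
  converted.
* Ladders need ≥ 3 markers with strictly monotone length–position order;
  all-zero lane profiles are an error rather than a zero.
* Ties in junction alignment resolve to the smallest offset, i.e. the
  designed phase, making verdicts phase-consistent across repeat units.
* All stochastic components (simulator, synthetic lanes, fixtures) take
  explicit integer seeds and are bit-reproducible.
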