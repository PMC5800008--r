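---
title: "Methods: pentamer-based prediction of CpG methylation effects on DNA shape"
author: "methylShapeR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pentamer-based prediction of CpG methylation effects on DNA shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylShapeR)
```

## The model

Cytosine methylation at CpG dinucleotides places a methyl group at the
major-groove edge of both cytosines of the step.  Although the chemical
change is small, it perturbs the local helix geometry — base-pair step
rotations (Roll, helix twist), intra-base-pair propeller twist and the
width of the minor groove — and those perturbations are read out by
DNA-binding proteins.  Because experimentally solved structures containing
5-methylcytosine are rare, methylShapeR predicts these effects from
*pentamer query tables*: lookup tables that assign to every 5-mer sequence
context the mean shape features observed for that context across a large
pool of per-fragment shape records (in the original setting, mined from
all-atom simulations; here, either user-supplied record pools or the
package's synthetic generator).

Methylated DNA is written over a six-letter alphabet: `m` is
5-methylcytosine and `g` the guanine base-paired with an `m` on the
opposite strand.  The two letters are not independent: CpG methylation is
symmetric, so they occur only as the unit `mg`.  Two grammar modes follow
from this.  A full fragment must contain only complete `mg` units; a k-mer
window cut from a valid fragment may additionally begin with `g` (its `m`
lies before the window) or end with `m` (its `g` lies beyond it).  The
boundary letters carry real information: a window ending in `m` implies a
`g` — hence a G/5mC pair — at the first position past the window.

Tables are keyed on *canonical* pentamers: the lexicographic minimum of a
pentamer and its reverse complement under the fixed order
`A < C < G < T < g < m`.  The order itself is arbitrary, but it is part of
the serialized table format and therefore fixed and locale-independent
(comparison is performed on a digit transliteration).  Under the
methylation grammar there are 1024 unmethylated and 950 methylated
window-valid pentamers, collapsing to 512 + 475 = 987 canonical keys; no
odd-length DNA string equals its own reverse complement, so
canonicalization exactly halves each count.

## Mining and table building

A record pool stores, per fragment, the sequence, per-base-pair MGW (Å)
and ProT (degrees), and per-step Roll and HelT (degrees).  Mining slides a
5-bp window along each fragment and emits, under the window's canonical
key, the MGW/ProT at the central base pair and the Roll/HelT at the
window's steps 2–3 and 3–4.  When the canonical form is the reverse
complement of the observed window the two step slots are swapped; MGW and
ProT are strand-symmetric at the central base pair and left unchanged.
Table entries are plain means over all emitted occurrences, weighting
every occurrence equally rather than averaging per fragment first — with
balanced pools the two choices coincide, and occurrence-level pooling
keeps the estimator a simple mean with a known standard error
(σ/√n per key and slot).

Windows whose central base pair lies within `2 + margin` positions of a
fragment end are excluded; the default margin of 1 bp discards one
position beyond the geometric minimum, since terminal base pairs of
simulated fragments are affected by end fraying.  The margin is exposed as
a build option because the appropriate exclusion width depends on how the
records were produced.

## Profiles, Δshape and the step-assembly policy

`shapeProfile()` predicts features for an arbitrary sequence by querying
the table with the pentamer centred at each position: a sequence of length
N yields N − 4 defined MGW/ProT positions (3..N−2).  Steps are covered by
two pentamer windows — the step between s and s+1 receives the `roll34`
slot of the window centred at s and the `roll23` slot of the window
centred at s+1.  The table stores both slots but no assembly rule is
implied by the storage format, so the rule is an explicit policy: the
default averages the two contributions (the symmetric choice), the two
boundary steps necessarily use their single available contribution, and
`five_prime`/`three_prime` policies keep one designated slot for users who
prefer a single-window convention.  Profiles keep full-length axes with
`NA` at undefined entries so indices always align with input coordinates
(1-based in all reports).

`deltaShape()` is the positionwise difference between the profile of the
methylated sequence (queried against the methylation-aware table) and of
the unmethylated sequence (queried against the unmethylated table).  An
empty methylation specification returns an identically zero profile by
construction.

## Context-matched ΔMGW

A methylated pentamer ending in `m` was only ever observed, in any valid
training pool, followed by `g`; its unmethylated counterpart ending in `C`
was observed in front of all four bases.  Pentamer tables therefore build
an implied sixth-position context into methylated keys but not into
unmethylated ones, and the plain Δ estimate at such positions confounds
the methylation effect with a (weak) sixth-position shape dependency.
`contextMatchedDeltaMGW()` removes the confound by drawing the
unmethylated reference from CpG-context tables: hexamers ending in CG (256
keys) when one window boundary touches a CpG, heptamers with CG at both
flanks (64 keys) when both do.  Context-table keys are kept in pattern
orientation — opposite-strand occurrences are mapped in with positions
reversed, and a window matching in both orientations contributes to both
keys — so that "position 3 of the hexamer" always means the same thing.
When the full CpG lies inside the window there is no confound and the
plain pentamer reference is used.

This is the machinery behind `pbxHoxDeltaMGW()`: in the 12-bp Pbx-Hox
site pattern `NTGAYNNAYNNN`, a CpG at offset 9/10 lies fully inside the
pentamer window of the downstream AY adenine, while CpGs at offsets 6/7
and 10/11 touch the windows of the two AY adenines with a single base
pair, producing CG-ending hexamer contexts.  Minor-groove narrowing at
the AY positions is associated with enhanced binding, so a
methylation-induced widening there predicts suppressed binding.

## A-tract analysis

A-tracts (runs of ≥3 A/T base pairs without a TpA step) are rigid and
intrinsically narrow; an adjacent methylated CpG can amplify or relax the
narrowing depending on the A/T composition.  `atractAnalysis()` compares
paired methylated/unmethylated MGW samples at the tract's central
nucleotide with one-sided tests (alternative: methylation narrows the
groove), Wilcoxon signed-rank for the 3-bp series and paired t for the
4-bp series by default; both tests are available for either series.
Pairing is by fragment context — the two members of a pair share their
flanking sequence — which isolates the methylation effect from flank
variability.  All-zero paired differences carry no evidence for narrowing
and are reported as P = 1 (the generic tests reject such input).  Stars
follow the usual convention (`*` for 0.01 < P ≤ 0.05, `**` for
0.001 < P ≤ 0.01, `***` below).

## Shape-to-affinity modeling

DNase I cleavage preference is modelled on the hexamer around the
phosphate cleavage site (3 bp on either side).  Cleavage counts are
filtered at a minimum of 25 observations and converted to relative free
energies ΔΔG/RT = −ln(c/c̄); the reference c̄ is the mean retained count of
the variant class by default, with median or a named reference hexamer as
alternatives, since the appropriate normalization depends on how the
counts were preprocessed.  Energies are invariant under global count
rescaling.

Hexamers are featurized by wildcard padding: two `N`s on each side give
every position and step a pentamer-window value, with wildcard queries
averaging over all concrete flanks.  The layout — 6 MGW + 6 ProT + 5 Roll
+ 5 HelT = 22 features — is stored inside serialized models so that
featurization and prediction cannot silently disagree.

The elastic net minimizes ‖y − Xw − b‖² + λ₁‖w‖₁ + λ₂‖w‖₂² by cyclic
coordinate descent on internally standardized features, with coefficients
reported on the original scale.  Convergence is declared when no
coefficient moves by more than 1e-8 in a sweep; features are visited in
layout order, making the fit deterministic.  Zero-variance features are
dropped with a warning.  Default penalties are λ₁ = λ₂ = 0.01 — small
enough to leave a well-determined fit essentially unbiased while
regularizing degenerate designs — with seeded 5-fold cross-validation
(`cvAffinityModel()`) available when data-driven selection is wanted.
With both penalties zero the solution matches the normal equations (the
test suite verifies agreement to 1e-8 on well-conditioned designs, and
cross-checks the penalized path against an independent solver).

Because the model is affine, the methylation-induced energy shift is
predicted directly from Δshape features: ΔΔΔG/RT = W·Δx with no
intercept.  A negative Roll weight at the CpG step combined with the
methylation-induced Roll increase yields a negative ΔΔΔG — enhanced
cleavage — which is the sign logic the comparator tests assert.

For Pbx-Hox binding data, `methylationEffect()` computes
ΔΔΔG/RT = −ln(affinity_meth/affinity_unmeth) per paired site and groups by
CpG offset class; positive values mean suppressed binding.

## The synthetic generator

The generator stands in for mined simulation trajectories and defines the
conditions under which the pipeline is tested.

**Planted truth.**  Base values are drawn once per canonical context from
seeded distributions spanning typical B-DNA ranges: MGW ~ N(5.1, 0.3) Å
and ProT ~ N(−7, 3)° per canonical pentamer; Roll ~ N(1, 2.5)° and
HelT ~ N(34.3, 1.2)° per canonical *tetramer*.  Step features live at
tetramer resolution by design: the step between positions s and s+1 is
covered by two pentamer windows whose step slots describe the same
physical quantity, so independent per-pentamer step values would be
internally inconsistent — no record pool could reproduce them.  Defining
the step truth on the tetramer s−1..s+2 (the overlap of the two windows)
makes pools self-consistent: a zero-noise pool reproduces the planted
table exactly, which the test suite asserts to machine precision.

**Methylation effects** are applied deterministically on top of the
demethylated base value: Roll +6° at the mg step itself, ProT −5° when the
central base pair is m or g, HelT −2° when the mg step sits off-centre in
the tetramer (the CpG at pentamer position 1 or 3), and a small MGW term
(−0.1 Å default) plus a seeded per-key context jitter (sd 0.1 Å) standing
in for the subtle, context-dependent MGW response.  Effect sizes are
constants at their reported magnitudes; the spread observed across real
contexts (roughly ±1° around the Roll and ProT means) is represented only
by the MGW jitter, so recovered *mean* effects are sharper here than they
would be on real tables.

**Occurrence noise** is i.i.d. Gaussian per defined entry (default
σ = 0.5° / Å), the simplest stand-in for snapshot-averaged estimates; real
mined records have correlated, heteroscedastic errors that this does not
emulate.  Consequently, passing recovery tests demonstrate that the
mining/averaging/query machinery is correct and well-calibrated under
known noise — not that the tables would match experiment.

**Pool design** is a greedy cover: canonical pentamers are visited in
lexicographic order and fragments added (core = the pentamer completed to
fragment validity, 5–7 bp; 4-bp flanks with the right flank the reverse
complement of the left, rotating through four flank choices) until each
key has the requested number of minable occurrences.  Lexicographic
visiting order and fixed flank rotation make the design deterministic.
Incidental occurrences from flank–core junctions count toward coverage,
so a key may be covered in fewer fragments than requested flank
combinations.

**The sixth-position interaction** (`pos6Effect`, default 0) adds, at
record-simulation time, an MGW dependency on the base three positions
downstream of each window centre, mirrored on the opposite strand.  It is
the planted analogue of the confound that motivates the context tables:
with it enabled, the plain pentamer Δ estimate is biased by construction
while the context-matched estimate recovers the planted effect, which the
tests assert comparatively.  It defaults to zero so that exact zero-noise
recovery holds everywhere else.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on generated data:
full-universe pools at 100 occurrences per key and σ = 0.5 for parameter
recovery (the per-key tolerance 4σ/√n then admits ~6 × 10⁻⁵ misses per
slot, so ≥99% of 987 keys within tolerance is the expected outcome, not a
generous bound); 4096-hexamer cleavage tables at depth 2 × 10⁶ for the
DNase chain; 20 pairs per context at σ = 0.1 for the A-tract tests; 1000
random sequences for the strand-symmetry property.  These sizes keep a
full run in the order of a minute while leaving comfortable statistical
margins.

Other numerical conventions: undefined profile entries are `NA`, never
zero; serialized tables round to a fixed number of decimals (default 2,
matching the style of published shape tables) and round-trip within that
precision; missing-key policy defaults to a hard error at build time
(published tables are complete) and a soft `NA` at query time (small
synthetic pools need not be); coordinates are 1-based inclusive in
reports and 0-based half-open in BED input.

## Limitations

The package predicts intrinsic, protein-free shape; bound-state geometry
can differ.  Only symmetric CpG methylation is modelled — no
hemimethylation, CHG/CHH contexts, or hydroxymethylation.  Pentamer
windows cannot express dependencies beyond ±2 bp except through the
dedicated CpG-context tables.  The energy normalization (mean-count
reference) is a documented stand-in for dataset-specific preprocessing,
and the synthetic generator's Gaussian, context-constant effect model is
a deliberately simple emulation: conclusions about real methylated DNA
require tables mined from real structural ensembles.
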