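---
title: "Screening untargeted LC-MS data for iron-siderophore complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening untargeted LC-MS data for iron-siderophore complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(sideroscan)
```

## The screening model

A ferric siderophore complex in positive-mode LC-MS is identified by
three independent signatures, and `sideroscan` requires the first two
and reports the third:

**Iron isotopologue pattern.** Iron's natural isotopes place a
satellite peak 1.99533 Da *below* the monoisotopic ion (⁵⁴Fe vs ⁵⁶Fe)
at an abundance ratio of 0.0637 (5.845% / 91.754%). The screen accepts
an A−2 partner whose spacing is within 0.003 Da and whose intensity
ratio falls in `[0.02, 0.15]`. The window is roughly a factor 2.5
around the theoretical ratio: wide enough to absorb ion-counting noise
on a minor isotopologue, narrow enough to reject chlorine- and
bromine-type A+2 patterns read from the wrong side (a ³⁷Cl-anchored
feature shows the right spacing to within ~2 mDa but a ratio near 3).
⁵⁷Fe and ⁵⁸Fe (2.1%, 0.3%) are ignored in scoring; they add little
discrimination at realistic noise.

**Apo/holo exact-mass pairing.** Chelation of Fe(III) by a
tris-hydroxamate displaces three protons, so the neutral holo species
is M − 3H + Fe and its protonated ion sits exactly

$$\Delta m = m(^{56}\mathrm{Fe}) - 3\,m(\mathrm{H}) = 52.91146\ \mathrm{Da}$$

above the apo [M+H]⁺ ion, independent of M. Pairs are accepted within
0.003 Da of this offset and within ±2 min in retention time: the
complex survives acidic reversed-phase chromatography intact but
elutes at a shifted time, and the window must span that shift without
linking unrelated features across the gradient. Singly charged ions
are assumed throughout (the species of interest are observed as MH⁺);
the electron mass is ignored in protonation arithmetic, an error below
1 ppm above *m/z* 100, though the constant is kept available.

**MS/MS corroboration.** Candidate spectra are annotated against a
building-block library of hydroxamate fragments. Matching uses the
tolerance rule *5 ppm or 0.003 Da, whichever is larger* at the given
*m/z* — the same rule used for fragment matching in the network — and a
candidate is flagged "hydroxamate-consistent" when at least two
distinct blocks hit (a package choice; the underlying reasoning is
qualitative, and one shared fragment is weak evidence while two
independent blocks rarely co-occur by chance). The elemental formulas
behind the 131.0816 and 157.0609 fragments are inferred from the
measured masses (protonated C5H10N2O2 and C6H8N2O3, both within
0.2 mDa); their library entries carry an `inferred` provenance flag.

Before any of this, features present in the blank/control extract are
removed: a sample feature is dropped when a matched control feature
carries more than 0.01% of its area. The asymmetric threshold
deliberately removes medium-derived features aggressively — a genuine
secreted metabolite is essentially absent from an uninoculated
control, so even a trace in the blank marks a contaminant.

## Formula decomposition

Candidate elemental formulas for the apo neutral mass are enumerated
exhaustively over CHNOS with default bounds C ≤ 60, H ≤ 120, N ≤ 15,
O ≤ 25, S ≤ 5, within 5 ppm, and filtered to RDBE ∈ [0, 40]. The
bounds cover metabolites to ~1 kDa without exploding the search; the
implementation enumerates the heavy-element grid and solves the
hydrogen count from the residual mass, which a naive nested-loop
enumeration reproduces exactly (this equivalence is a test). Results
are ordered by |ppm error| with ties broken by the Hill-notation
string, so output is deterministic. At 5 ppm and 750 Da many formulas
tie within instrument accuracy; the screen therefore stores the full
candidate list per feature, and an optional H/C ratio filter
(0.2–3.1, off by default) is available to prune chemically implausible
extremes. Mass constants are hard-coded from the AME2020 atomic-mass
evaluation; an empty formula has mass 0 and a mass with no
decomposition returns an empty table, not an error.

## MS/MS hygiene and networking

Spectra are cleaned in two steps. A ubiquitous contaminant ion at
*m/z* 202.080 — present in every spectrum independent of precursor —
is removed within ±0.003 Da. Then a peak survives only if it ranks in
the top 5 by intensity among peaks within ±25 Da of itself *and*
reaches 0.1% of the base peak. The 50 Da window is implemented as a
sliding window centred on each peak rather than fixed bins: fixed bins
make survival depend on where a bin boundary happens to fall, while
the sliding rule is translation-invariant and idempotent (filtering
twice changes nothing, which is a test).

The network's **modified cosine** matches two fragments when their
*m/z* agree directly or when their difference equals the precursor
mass difference (so homologues such as CH₂ analogs align their
complement ions). Candidate pairs are reduced to a one-to-one
assignment greedily by descending intensity product; a pair satisfying
both the direct and the shifted condition is counted once. Intensities
are square-root transformed before the cosine (the convention of
feature-based molecular networking; configurable to raw). The greedy
assignment can in principle fall short of the optimal one-to-one
assignment; an exhaustive-assignment oracle in the test suite checks
that on random small spectra the greedy score equals the optimum in at
least 95% of cases and never exceeds it. Scores within 1e-12 of 1 are
snapped to exactly 1 so that self-similarity is 1.0 despite float
rounding. Empty spectra score 0 with 0 matches.

Edges require cosine ≥ 0.7 and ≥ 5 matched fragment ions. The
10-neighbour cap is applied symmetrically: an edge survives only if it
ranks within the top 10 by score for *both* endpoints (TopK
semantics). The wording "at most 10 neighbours per node" is ambiguous
between either-endpoint and both-endpoint pruning; the symmetric rule
guarantees the cap as a hard graph invariant, which the asymmetric one
does not. Ties are broken by score, then matched-ion count, then
lexicographic ids, so the network is reproducible. Positive- and
negative-mode features would be networked separately; the synthetic
data is positive-mode only.

## The synthetic scenario

`generate_scenario()` emulates the observation structure the screen
assumes, not an instrument. The default scenario plants five
siderophore families around the base neutral formula C33H62N6O13 at
offsets {0, −CH₂, +O, +CH₂+O, +2CH₂+O}. Only the base formula and the
CH₂/O relation pattern are fixed by design; the other four formulas
are instantiated from the relations and make no claim to match any
particular real compound. Each family contributes an apo [M+H]⁺
feature and a ferric-complex feature at exactly +52.91146 Da (before
noise), with the complex carrying 75% of the family's area
(`apo_fraction = 0.25` — the complex is the major fraction, the apo a
minor one; the exact split is unconstrained and this default simply
respects the inequality). Retention times are uniform over the 1.5–8
min gradient window and the complex is shifted by 0.2–0.5 min with
random sign, inside the ±2 min pairing window.

Decoys (24 by default) comprise plain organics, chlorine-pattern traps
and correct-spacing/wrong-ratio traps as described above; four decoys
are "blank-shared", reproduced in the control table at 50% of their
sample area, far above the 0.01% removal threshold. MS/MS spectra are
generated for each family apo (the building-block template plus noise
peaks plus the contaminant ion) and for plain decoys (random peaks
plus contaminant).

Noise model: peak areas are log-normal (σ = 0.1); isotopologue ratios
and MS/MS intensities carry relative Gaussian noise (σ = 0.05 by
default); the *m/z* error is a run-level calibration bias
(σ = 0.8 ppm) shared by all features plus per-feature jitter
(σ = 0.3 ppm), ≈ 1 ppm total, the behaviour of a well-calibrated
high-resolution instrument. The decomposition matters: mass
*differences* within a run (isotope spacings, the apo/holo offset)
cancel the shared bias and are far more accurate than absolute masses,
exactly as in real data, and the screen relies on differences. A purely
independent per-feature error of the same total magnitude would
misstate this and make the 0.003 Da pairing tolerance artificially
marginal at 800 Da.

What the generator does **not** emulate: chromatographic peak shapes
and co-elution artifacts, profile-mode spectra and centroiding errors,
ion suppression, multiply charged species, adducts other than H⁺ and
the ferric substitution, in-source fragmentation, and real fragmentation
chemistry beyond the planted building blocks. Passing the end-to-end
tests therefore shows the pipeline's logic is correct under its stated
assumptions — not that those assumptions hold for any given instrument
or matrix.

## Degenerate inputs and edge cases

Empty feature tables and empty spectra propagate to empty results with
exit status 0; malformed tables (missing columns, non-positive areas,
*m/z* outside the 80–1500 scan range) are schema errors. Feature
matching across runs (5 ppm, ±0.2 min, greedy nearest by ppm then RT)
matches each feature at most once. When several spectra share a
feature id the most intense is kept. In holo-only mode
(`require_apo = FALSE`) the apo neutral mass is inferred from the holo
ion by subtracting the ferric offset; by default both species are
required, since the co-occurrence of the pair is the second criterion.

## Problem sizes

The shipped tests run the default scenario (34 sample features, 21
spectra) across 20 seeds for the recall/false-positive property, 1,000
random spectrum pairs for the greedy-vs-optimal cosine comparison, and
full-bounds decompositions at 114.0681 and 750.4375 Da against the
nested-loop oracle — sizes chosen so the entire suite completes in
well under a minute while still exercising every code path.

## Known limitations

* Detection operates on feature tables with isotopologue envelopes (or
  co-eluting A−2 features), not on raw spectra; peak picking is out of
  scope.
* Negative ionization mode is carried through I/O but the apo/holo
  arithmetic is positive-mode only.
* MGF is the supported MS/MS interchange format; mzML is not read.
* Formula decomposition ranks purely by mass error; isotope-pattern
  scoring of decomposition candidates (beyond the A−2 screen) is not
  implemented.
* The building-block library covers ornithine-derived hydroxamate
  blocks; carboxylate and catecholate siderophores would need their
  own entries.
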