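---
title: "Methods: reactive-pose analysis of external-aldimine ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reactive-pose analysis of external-aldimine ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aldipose)
```

## Scientific model

PLP-dependent decarboxylases cleave the C&alpha;&ndash;COO&minus; bond of
an external aldimine: the Schiff base formed between the pyridoxal
5'-phosphate (PLP) cofactor and the substrate's amino group. Whether a
conformational snapshot of this intermediate is *reaction-competent* can
be summarized by four geometric descriptors measured between named
active-site atoms:

| descriptor | definition | units |
|---|---|---|
| `d1` | distance from the catalytic-lysine ammonium proton HZ to the substrate C&alpha; | &Aring; |
| `theta1` | angle HZ&ndash;C&alpha;&ndash;H99 (H99 is the aldimine proton on C&alpha;'s imine carbon side) | degrees |
| `chi1` | dihedral C50&ndash;N99&ndash;C&alpha;&ndash;C80, aligning the scissile C&alpha;&ndash;COO&minus; bond with the &pi; system of the Schiff base / pyridine ring | signed degrees |
| `d2` | distance from the pyridinium proton H1 to the glutamate carboxylate oxygen OE1 that protonates the pyridine nitrogen | &Aring; |

A frame is classified **reactive** when all four criteria hold with
*strict* inequalities. Two presets are provided:

- `reactiveCriteria("DAP")`: `d1 < 4.0`, `theta1 < 80`,
  `-120 < chi1 < -90`, `d2 < 2.0`;
- `reactiveCriteria("2-APA")`: the same except `-125 < chi1 < -75`.

The `chi1` windows are stated so that the catalytically ideal alignment
of &minus;90&deg; lies *inside* the window used for the engineered
substrate. Stereoelectronically, decarboxylation is fastest when the
scissile bond is perpendicular to the ring plane, i.e. `chi1` near
&minus;90&deg;; the windows are one-sided tolerances around that optimum,
not intervals that exclude it.

### Dihedral sign convention

`measureDihedral(a, b, c, d)` uses the IUPAC convention shared by
standard structural-biology toolchains: looking down the b&rarr;c axis, a
clockwise rotation of the far bond is positive, computed as
`atan2((n1 x n2) . u(b->c), n1 . n2)` with `n1 = (b-a) x (c-b)` and
`n2 = (c-b) x (d-c)`. Cis is 0&deg;, trans is 180&deg;, and the range is
(&minus;180, 180]. The convention was cross-checked against
`bio3d::torsion.xyz` on shared inputs.

## Atom roles instead of hard-coded indices

Structures arrive as multi-model PDB files (`readModels`, delegating
parsing to **bio3d** after validating model balance and per-model atom
composition). Descriptor code never addresses atoms by index; a
`RoleMap` binds each named role (HZ, CA, H99, C50, N99, C80, OE1, H1,
plus optional DISTAL_CA, LYS_NZ, the MC anchors and the PLP anchor set)
to a `(chain, resno, name)` selector, with `NA` as a wildcard. A selector
must resolve to exactly one atom; missing or ambiguous bindings raise
errors naming the role. Role maps round-trip through YAML
(`readRoleMap` / `writeRoleMap`).

```{r descriptors}
fr <- buildFragment(d1 = 3.0, theta1 = 60, chi1 = -100, d2 = 1.8)
rmap <- syntheticRoleMap()
unlist(poseDescriptors(fr, rmap))
classifyPose(poseDescriptors(fr, rmap), reactiveCriteria("DAP"))
```

`summarizeTrajectory` applies the classifier to every frame of an
ensemble using a vectorized descriptor path; its counts are
property-tested against brute-force per-frame classification, so the
fast path and the obvious path act as oracles for each other.

## Rotamer library construction

Covalent docking of an external aldimine needs a ligand rotamer library.
The generator starts from a template whose alignment dihedral `chi1` is
pre-set to &minus;90&deg; (it is an error if it is not) and draws
`nCandidates = 10,000` candidates by perturbing each of the three
rotatable heavy-atom side-chain dihedrals by an independent uniform angle
in &plusmn;30&deg;, leaving `chi1` and the PLP anchor atoms bit-identical
to the template.

Pruning visits candidates in ascending clash-energy order and greedily
retains a candidate iff

1. its distal C&alpha; lies within `distalCaMaxDev = 2.5` &Aring; of the
   template's, and
2. its heavy-atom RMSD (no superposition; the frames share the fixed PLP
   anchor) to *every* already-retained rotamer exceeds
   `uniquenessRmsdMin = 0.0050` &Aring;,

stopping at `libraryCap = 400` rotamers. With the default parameters the
cap binds (far more than 400 admissible, mutually distinct candidates
exist), so the retained size is exactly 400 for every seed &mdash; a
deterministic pipeline-level invariant that the acceptance tests verify
by brute force over all 79,800 retained pairs.

The clash energy is a deliberately simple soft-core score,
`sum(((r0 - d) / r0)^2)` over non-excluded heavy-atom pairs closer than
`r0 = 3.0` &Aring;, with 1&ndash;2 and 1&ndash;3 neighbours excluded via
the explicit bond list (`fragmentBonds`; bond *perception* is never
performed). It only has to produce a stable, physically sensible visiting
order for the greedy pruner, not a force-field energy. Ties in energy are
broken by candidate index, making pruning fully deterministic.

## Catalytic-lysine conformations

The catalytic lysine's ammonium group occupies three states: MC1
(hydrogen-bonded to the PLP phenolic oxygen; closest to C&alpha; and
reaction-competent), MC2 (toward an aspartate), MC3 (toward a distal
glutamate). `classifyLys` assigns the state of the NZ nitrogen by
nearest anchor distance, breaking exact ties in the order MC1 > MC2 >
MC3. `conformationProfile` tabulates state counts and mean `d1` per
state over a trajectory. Because MC1 keeps `d1` near 2.9 &Aring; while
MC3 sits beyond 4.8 &Aring;, the `d1 < 4.0` criterion passes essentially
always in MC1 and never in MC3 &mdash; the ordering the acceptance suite
asserts.

## Activity data and correlation

`loadActivityTable` reads a wide CSV of specific activities in mU/mg with
cells `"value (stderr)"` or `"n.a."` (below the 1 mU/mg detection limit)
into a long table; `loadKinetics` reads Michaelis&ndash;Menten parameters.
`foldRatio` forms kcat ratios between (variant, substrate) pairs.

```{r activity}
kin <- loadKinetics(system.file("extdata", "tmdapdc_kinetics.csv",
                                package = "aldipose"))
foldRatio(kin, c("E315T", "APA"), c("Wild-type", "DAP"))
```

`correlateWithActivity` merges per-variant reactive-pose statistics
(counts or fractions) with measured activities and computes the Pearson
correlation via `stats::cor` (re-implementing a standard statistic would
only add risk); non-detectable activities can be excluded, set to zero,
or set to the detection limit. `rankVariants` orders variants by reactive
count, then fraction, then label.

## Synthetic data generator

Every pipeline stage is testable offline because the generator works
*backwards* from descriptor values:

- `buildFragment(d1, theta1, chi1, d2)` places an 18-atom active-site
  fragment by internal-coordinate (NeRF) construction so that the
  measured descriptors equal the requested ones to machine precision
  (the round-trip is property-tested over 1,000 random parameter sets).
  The fragment is geometric, not a chemically complete aldimine: the
  pipeline consumes geometry, not chemistry.
- `simulateTrajectory(n, fraction, criteria)` emits exactly
  `round(n * fraction)` frames strictly inside every window and the rest
  strictly outside at least one. Sampling is *margin-respecting*
  (default 0.1 &Aring; / 2&deg;): jittered values are clamped so noise can
  never cross a threshold, hence truth labels are exact by construction.
  `jitterSd` is interpreted as &Aring; for the two distances and
  `10 * jitterSd` degrees for the two angles, reflecting the roughly
  tenfold scale difference between the units.
- `simulateLysEnsemble` co-generates MC states with state-conditional
  `d1` regimes (MC1 ~ N(2.9, 0.15) clamped to [2.5, 3.3]; MC2 uniform
  3.5&ndash;4.5; MC3 uniform 4.9&ndash;6.0 &Aring;).
- `simulatePanel` emulates a variant screen: per variant *i*, a
  trajectory with true fraction *f<sub>i</sub>* and a specific activity
  `a + b * f_i + N(0, noiseSd^2)`, defaults `a = 0`, `b = 700` mU/mg per
  unit fraction, `noiseSd = 200` mU/mg, which places the realized Pearson
  r in the 0.6&ndash;0.8 regime typical of pose-count/activity
  correlations. Negative activities are clamped at 0 and flagged. The
  truth table records fractions, counts and noise, so the pipeline's r
  can be checked against `pearsonR` on the truth table to 1e-12.

All generators take a `seed` and restore the caller's RNG state.

## Problem sizes used in the test suite

Where a test needs an ensemble or panel, its size (frames per
trajectory, variants per panel, number of replicate panels) is this
package's own choice, picked to keep the full suite around two minutes on
one CPU while leaving every assertion at full strength: the stochastic
panel test uses 200 seeded panels of 20 variants with 10 frames each (the
oracle equality it checks holds for any frame count), and the full-scale
rotamer run uses the real 10,000-candidate spec.

## Limitations

- No force fields, thermostats, or realistic protein environments; the
  synthetic ensembles are geometric constructions, not dynamics.
- The clash score is a visiting-order heuristic, not an energy model.
- Docking scores are consumed as data (`meanTopScores`); no docking is
  performed.
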