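---
title: "Fragment-based MicroED phasing: models and methods"
author: "microshred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-based MicroED phasing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(microshred)
```

This vignette explains the science behind `microshred`: the models the
package implements, the assumptions they carry, the parameters that
matter, and the choices made where the design was genuinely open.  The
package's tests and acceptance script compute every number referred to
here; the vignette states no result they do not.

## The problem

Microcrystal electron diffraction (MicroED) measures intensities
$I(hkl) = |F(hkl)|^2$ from three-dimensional protein nanocrystals
rotated continuously in an electron beam.  Limited stage tilt, preferred
crystal orientation on the grid and radiation damage mean a single
crystal rarely yields complete data; several crystals are scaled and
merged.  The phases of $F$ are lost.  When no close homologue of the
target exists, molecular replacement with a single model fails, but
*fragments* of a distant homologue — stripped to polyalanine so that
sequence-specific detail cannot mislead — can often be placed correctly.
A placed fragment supplies approximate phases; its quality is judged by
amplitude correlation and, when a reference exists, by the weighted mean
phase error (wMPE).

`microshred` implements this workflow at desk scale, with every stage
exercisable on synthetic data generated by the package itself.

## Diffraction core

Structure factors are computed by direct summation over atoms and
symmetry operators,

$$F(\mathbf h) = \sum_{s}\sum_{j} o_j\, f_j(s)\,
  e^{-B_j s^2} e^{2\pi i\, \mathbf h\cdot(R_s \mathbf x_j + \mathbf t_s)},
  \qquad s = \sin\theta/\lambda = \tfrac{1}{2d},$$

with neutral-atom elastic *electron* form factors in the standard
5-Gaussian parameterization $f(s) = \sum_i a_i e^{-b_i s^2}$ (H, C, N,
O, S, Ca).  Electrons scatter from the Coulomb potential, not the
electron density, so these coefficients differ qualitatively from the
X-ray case — the package deliberately has no X-ray fallback, and an
unknown element is an error.  Direct summation (no FFT) was chosen for
exactness at the problem sizes the package targets; the compiled kernel
makes it fast enough for grid searches.

The Debye–Waller convention is $e^{-Bs^2}$ with $s = 1/(2d)$, i.e.
$e^{-B\sin^2\theta/\lambda^2}$.  Space-group support is a hard-coded
operator table for P1, P2~1~, P2~1~2~1~2~1~, P4~3~2~1~2 and its
enantiomorph P4~1~2~1~2 — the groups needed for the simulator and the
targeted use cases.  Centric flags, epsilon factors, systematic
absences, allowed origin shifts and the polar-axis structure are all
derived from (or tabulated with) these operators; unsupported symbols
are rejected loudly rather than half-supported.

Normalized amplitudes use equal-count resolution shells in $s^2$:
$E^2(\mathbf h) = I / (\epsilon \langle I/\epsilon\rangle_{shell})$,
which enforces $\langle|E|^2\rangle = 1$ per shell by construction
(default 20 shells; non-positive shells merge with a neighbour).

The twinning L-test pairs each acentric reflection with close,
symmetry-unrelated neighbours ($l$ and $k$ offsets of 1 and 2, a
declared convention) and reports $\langle|L|\rangle$ and $\langle
L^2\rangle$ with the analytic references 1/2 and 1/3 (untwinned) versus
0.375 and 0.2 (perfect twin).

## Fragment generation

**Sequential ("shred") mode** walks every break-free chain segment with
windows of `sizeMin`–`sizeMax` residues (defaults 10–20) starting every
`step` residues (default 4), emitting either the extracted window or its
complement ("omit").  Chain breaks — a Cα–Cα step above 4.5 Å or a
numbering gap — restart the grid.  On an unbroken chain of length $L$
the library size is exactly $\sum_s (\lfloor (L-s)/step\rfloor + 1)$.

**Spherical mode** takes each residue's Cα as a centre, collects the
`nTarget` spatially nearest residues, discards contiguous runs shorter
than `minContig` (default 3) and deduplicates.  Neighbourhoods that fall
more than 10 residues short are grown by up to 10 extra neighbours, so
every emitted model is within ±10 residues of the target — mirroring
how compact-fragment libraries are sized in practice.  The target size
itself can be derived from the data with the expected-LLG criterion:
$eLLG(n) = \sum_{acentric}\sigma_A^4/2 + \sum_{centric}\sigma_A^4/4$
with $\sigma_A(s) = \sqrt{f_n}\, e^{-2\pi^2\,rmsd^2 s^2/3}$,
$f_n = n/N_{asu}$, $s = 1/d$; the smallest $n$ reaching the target
(default 30) is returned.

**The Shred-LLG descriptor.**  Each fragment is scored by the rotation
function at the clustered orientations of the whole template.  Scores
are z-scored *within each size group* (a 25-residue fragment cannot be
compared raw to a 15-residue one), and each residue receives the mean
z-score of all fragments containing it.  This aggregation — mean of
within-size z-scores — is this package's concrete reconstruction of a
descriptor whose published definition names the idea but not the
arithmetic; the within-group normalization makes the profile invariant
to affine rescaling of any single size group, which the tests assert.
From the profile, up to four models are built per rotation cluster by
four rules: local-maximum regions ("peaks", grown while values stay
within 75% of their peak), plateaus (runs of ≥6 residues within 10% of
the run maximum — a concrete stand-in for an otherwise unspecified
notion), residues above 75% of the profile maximum, and residues above
the smallest local-maximum height.  Duplicate residue sets and models
under 10 residues are dropped.

## Search

**Rotation function.**  Orientations are sampled on a uniform z-x-z
Euler grid (default 12°; steps above 30° are refused as meaningless).
For each rotation the fragment's molecular transform — the fragment as
an isolated molecule, equivalent to a large P1 box — is evaluated at
the data's scattering vectors, shell-normalized to $E^2-1$, and Pearson
correlated with the observed $E^2-1$.  This is a Patterson-correlation
style, translation-independent target: a documented simplification of
the maximum-likelihood rotation function.  Three practical points
matter:

* The correlation is computed on a *band-limited* slice of the data
  (default 10–3.5 Å).  The lowest-resolution terms are dominated by
  interference between symmetry-related molecules, which a single-copy
  transform cannot model; including them buries the signal.
* In space groups with rotational symmetry, the fast single-copy scan
  is followed by re-ranking of the top candidates (default 80) under a
  *symmetry-summed* ("locked") target: the squared transform is
  accumulated over all point-group images of the trial orientation
  before normalization, so the score sees every copy's self-vectors in
  the Patterson rather than one molecule's worth.  The single-copy
  target alone can be fooled by partial alignments with the wrong
  symmetry copy; the locked target discriminates these reliably but is
  eight-fold more expensive, hence the two-stage scheme.
* The top candidates (default 8–12) are then polished by local
  Nelder–Mead maximization, because at the high-resolution end the
  orientation peak is sharper than the grid.

For data with a rotational symmetry axis along *z* (the tetragonal
groups), the α range is reduced to $360°/n_z$; symmetry-equivalent
orientations score identically, which the clustering step then exploits
with a metric minimized over the point-group rotations (15° tolerance,
greedy in score order, ties broken by input order).

**Translation function.**  With the orientation fixed, the fragment
centroid scans the fundamental translation domain (the cell modulo
allowed origin shifts, polar axes pinned at 0) on a fractional grid
(default 1/24).  Each position is scored by the Pearson correlation of
$|F_{calc}|$ with $|F_{obs}|$, computed from per-symmetry-operator
partial structure factors so the grid scan costs one complex rotation
per operator per reflection.  TFZ is the Z-score of the best position
against the whole grid-score distribution — a grid-referenced analogue
of the conventional TFZ (which references random placements); the two
are ordinally comparable but not numerically identical.

**Packing filter and refinement.**  A placement is rejected when more
than 5% of its Cα atoms approach a symmetry copy or a previously
accepted placement closer than 3.0 Å (periodic images included).
Accepted placements are refined by derivative-free (Nelder–Mead)
maximization of the amplitude correlation over the six rigid-body
parameters; the refined score never falls below the input score.

**Likelihood score.**  Placements are also scored by a Rice-likelihood
gain: $\sum_h [\log P_{Rice}(E_o;\sigma_A E_c) - \log P_{Wilson}(E_o)]$
for acentrics, with the Woolfson (cosh) analogue for centrics, and
$\sigma_A$ from the same formula as the eLLG sizing.  The score is
exactly zero for the null model ($\sigma_A = 0$), increases with model
completeness, and ranks correct placements above random ones — the
contracts the tests check.  Its absolute values are not comparable to
any particular external program's LLG.

## Solution metrics

The weighted mean phase error is
$wMPE = \sum w|\Delta\phi|_{circ} / \sum w$, minimized over the allowed
origin shifts of the space group (the discrete table, plus numerical
refinement along polar axes) and optionally the enantiomorph flip
(phase negation).  Weights are the test set's figures of merit, or 1
when absent.  For model-derived phase sets the pipeline attaches
$\sigma_A$-based figures of merit — $m = I_1(X)/I_0(X)$ for acentrics,
$\tanh(X/2)$ for centrics, with $X = 2E_o\sigma_A E_c/(1-\sigma_A^2)$
— the expected cosine of the phase error of a partial model with
coordinate error.  This matters for interpretation: a 1 Å-r.m.s.d.
model's highest-resolution phases are close to random
($\sigma_A \to 0$), so the unweighted mean phase error of even a
well-placed fragment saturates toward the random limit, while the
FOM-weighted value reflects the information the phases actually carry.
Random phases give 90° in expectation; identity and origin-shifted
copies give 0°, which the acceptance checks assert at 10^4^
reflections.

Maps are synthesized by FFT after symmetry expansion to P1 and reported
in σ units (default grid spacing $d_{min}/3$).  Difference maps use
$2mF_o - F_c$ or $F_o - F_c$ coefficients on the model phases with an
overall linear scale fitted between $F_o$ and $F_c$; omit-map peak
heights are read off by trilinear interpolation at the feature position
(positions outside the cell wrap by lattice translation).

## Merging heuristics

Per-crystal scaling fits $(k, B)$ minimizing $\sum(I_{ref} - k\,
e^{-2Bs^2} I)^2$ against a reference crystal (linearized start, then
Nelder–Mead).  CC~1/2~ uses seeded random half-splits of each
reflection's observations — simple and reproducible; the seed is an
explicit argument everywhere it is used.  Damage trimming drops the
last frame of a series while doing so *strictly* increases CC~1/2~, up
to 6 frames; each crystal is trimmed independently from its own end.
Whether the original analyses assessed CC~1/2~ overall or in the outer
shell during trimming is not stated; overall is the default here, and
the shell table is available for the other choice.  Merging is
inverse-variance weighted; merge-set selection enumerates all non-empty
subsets (capped at 16 crystals), keeps those above the completeness
threshold (default 90%), and picks the smallest, breaking ties by
⟨I/σ⟩.

## The synthetic-data generator

The generator defines the package's study conditions; it is not a
tuning knob.  Defaults: a 60-residue ground truth in P4~3~2~1~2 with
cell 48 × 48 × 68 Å, 2.5 Å data, six crystals of ten frames with
70° wedges in seeded random orientations, 10% relative Gaussian
intensity noise, per-crystal scales in [0.7, 1.4] and relative B in
[0, 4] Å², no damage unless requested.  These numbers emulate the
texture of real multi-crystal MicroED reductions — wedge
incompleteness, modest per-crystal non-isomorphism in scale, noise at
the few-to-ten-percent level — at a size a desk machine can search
exhaustively.

The ground-truth fold is built from ideal backbone geometry (NeRF
internal-coordinate propagation; helices at φ = −57°, ψ = −47°) with
fixed inter-helix turn torsions chosen once for three properties:
compactness (radius of gyration ≈ 11–12 Å at 60 residues), absence of
steric clashes, and *distinctly non-parallel helix axes* (50–90°
crossing angles).  The last matters: a bundle of parallel helices has a
nearly cylindrically symmetric transform, which makes any rotation
about the bundle axis score almost equally in the rotation function —
realistic folds are not that degenerate, and a generator that produced
one would test the search against an artificial pathology rather than
the intended problem.  The fold is placed at the position maximizing
the closest symmetry contact (a deterministic grid search), with a
small seeded orientation perturbation; if a seeded orientation cannot
be packed at ≥3 Å contact, further seeded orientations are tried
deterministically before erroring with a cell-size hint.

Synthetic homologues are made by adding smoothly correlated
displacement fields (sums of low-frequency sinusoidal modes along the
chain) rescaled iteratively so the superposed Cα r.m.s.d. hits the
target within 5% — mimicking the long-wavelength coordinate differences
between real homologues, unlike independent per-atom noise.

Wedge membership is geometric: a reflection is observed when the
azimuth of its scattering vector about the rotation axis (in the
crystal's seeded orientation) falls inside the wedge, excluding a
missing cone about the crystal's c* when requested; the frame index is
the angular bin.  Damage multiplies intensities by
$e^{-rate\,(frame-onset)^+ s^2}$ — late frames fade from high
resolution inward, as radiation damage does.

**What the simulator does not model** — and hence what passing tests do
not establish about real data: dynamical (multi-beam) scattering,
absorption, partiality and integration error models, anisotropy,
detector effects, and charged-atom scattering factors.  The simulation
is kinematic by construction, so the recovery experiments validate the
search and scoring machinery, not robustness to the physics MicroED
practitioners worry about at the measurement stage.

## Numerical choices and degenerate inputs

* Correlations with zero variance on either side are defined as 0 (with
  a warning where the user should know).
* A degenerate translation-score distribution reports TFZ = 0 with a
  warning.
* Shell normalization merges non-positive shells with a neighbour.
* `dmin = dmax` reflection ranges yield an empty or single-shell set,
  not an error.
* Rotation-grid degeneracy at β = 0/180° is collapsed (γ fixed at 0).
* Superposition core-trimming (discard pairs >3 Å, refit, repeat) stops
  at a fixed point or 20 iterations; the 3 Å cutoff is a documented
  stand-in for the unspecified "core Cα" conventions of structure
  comparison tools, whose exact outlier rejection varies by program.
* All stochastic steps (simulation, CC~1/2~ splits, homologue modes)
  run through explicit seeds, and seeded helpers restore the caller's
  RNG state.

## Problem sizes

The package's own tests run the full study conditions once (60 residues,
~3,000 unique reflections, 117 fragments, one rotation grid of ~3,600
orientations with refinement) and scaled-down variants (30–40 residues,
3 crystals) everywhere else; these sizes were chosen so the complete
suite exercises every stage, including the end-to-end phase-recovery
experiment, in minutes on a single CPU.

## Known limitations

* Space-group coverage is the five tabulated groups.
* The rotation and translation targets are correlation-based
  simplifications; scores are comparable within a run, not to external
  maximum-likelihood engines.
* No bulk-solvent or anisotropy model in any scoring target.
* The translation search fixes polar axes at 0 (legitimate for the
  first fragment; a second fragment in a polar group would need the
  relative translation searched, which the current pipeline does not
  do).
* Density modification and autotracing are out of scope: the pipeline
  ends at scored placements and their phase sets.
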