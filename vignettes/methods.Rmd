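---
title: "Methods: quantifying cooperative homeodomain-DNA binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cooperative homeodomain-DNA binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdcoop)
```

# The scientific setting

Many homeodomain transcription factors recognize short A/T-rich motifs
(TAAT cores) that occur throughout a genome, yet they regulate specific
targets in vivo. One route to specificity is cooperative homodimer
binding: two homeodomains occupying two TAAT half-sites in head-to-tail
orientation separated by a fixed spacer (7 bp), where binding of the
first protomer bends the DNA and thereby creates a protein-protein
interface for the second. `hdcoop` implements the quantitative machinery
for studying this mechanism: DNA geometry and bend measurement,
structure comparison and interface analysis, trim-and-join dimer
modeling on n-bp spacers, one-site ITC thermodynamics, the tau
cooperativity statistic under a two-identical-site equilibrium, and
PWM-based spacer-composition analysis of selection libraries, plus
seeded generators that emulate each data type.

# Nucleic-acid geometry

## Frames and step parameters

Each base is least-squares superposed (proper rotations only) onto a
bundled standard-geometry base; the base-pair frame is the orthonormal
average of the sense frame and the complement-flipped antisense frame
(the flip is a 180 degree rotation about the pair's x-axis). Step
parameters (shift, slide, rise in Angstrom; tilt, roll, twist in
degrees) are extracted from the relative rotation and translation of
consecutive frames in the mid-step convention: the relative rotation is
factored as Rz(twist/2 - phi) Ry(Gamma) Rz(twist/2 + phi) with
Gamma^2 = tilt^2 + roll^2 and phi = atan2(tilt, roll), and the
translation is read in the half-way frame. The builder applies exactly
the inverse map, so `step_parameters(base_pair_frames(build_duplex(s,
steps)))` recovers any physical step table to 1e-6 - this mutual-inverse
property is the backbone of the test suite. Full reproduction of
axis-optimizing curvature analyses (which fit a global curvilinear axis)
is out of scope; the mid-step convention differs from them by a few
degrees at most on gently bent B-DNA, which is why the headline bend
tolerance used in validation is +/- 5 degrees.

Twist extraction keeps angles on the principal branch: the
(a - pi, b - pi, -Gamma) parameterization generates the same rotation,
and the degenerate Gamma -> 0 case is detected from the off-diagonal
norm rather than acos, which would otherwise inject ~0.1 degree noise.

## The duplex builder

`build_duplex()` places rigid standard-geometry nucleotides (base heavy
atoms, C1', one phosphate per residue, bridging O3') on the frame run.
Ideal B-form means twist 36.0 degrees, rise 3.38 Angstrom, everything
else zero. The phosphate sits at cylindrical radius 8.91 Angstrom,
azimuth 121 degrees, height 1.25 Angstrom in the pair frame - calibrated
once so that an ideal build reproduces canonical fiber-model geometry
(cross-strand P-P of ~11.6 Angstrom across the minor groove and ~17.1
across the major groove at the registers below). Bridging O3' atoms are
placed on the P(i)->P(i+1) segment 1.6 Angstrom from the downstream
phosphate, giving an exact O3'-P bond on any build and a well-defined
continuity criterion (1.3-1.9 Angstrom) for joined models.

The sequence-dependent step table
(`inst/extdata/bdna_step_params.tsv`) carries survey-style dinucleotide
means for twist, roll, rise, and a per-step propeller column; it is
strand-symmetric by construction and versioned as data, so an
alternative parameter set can be swapped in without touching code.

## Bend, grooves, shape

The global bend is the angle between the mean local helical axis (the
rotation axis of the frame-to-frame transform) over the first and last
`end_window` steps, after excluding `trim_ends` terminal pairs; the
defaults (window 4, trim 1) reflect that terminal pairs are the least
reliable part of a crystal model. Per-step bend angles localize kinks.
For a uniform superhelix all local axes coincide, so uniform-roll builds
report zero bend - the measure responds to localized curvature, which is
the geometry of interest here.

Groove widths follow the refined phosphate-phosphate convention:
cross-strand P-P distance minus 5.8 Angstrom (two phosphate van der
Waals radii), interpolated to base-pair levels. The registers (sense
level +1 / antisense level -1 for the minor groove; -2.5 / +2.5 for the
major) were fixed by the same fiber-geometry calibration as the
phosphate position. Depths are the distance from the defining P-P
midpoint to the base-pair origin. Levels lacking the needed phosphates
are flagged undefined rather than zero-filled, and shape features are
never extrapolated into the terminal positions.

`predict_shape()` is a deliberately simple, fully deterministic shape
predictor: it builds the sequence with the bundled table and measures
minor-groove width geometrically, reading propeller, roll and twist from
the table. It reproduces the qualitative contrasts that matter for the
spacer-flexibility analysis (A/T-rich runs have narrower minor grooves
and larger propeller magnitudes than G/C-rich runs) but it is not a
substitute for pentamer-trained shape models: it has no Monte-Carlo
ensemble averaging and no intra-base-pair degrees of freedom beyond the
table-driven propeller.

# Structure comparison and interfaces

Superposition is Kabsch SVD with the determinant correction (proper
rotations only), matching atoms by (chain, residue number, atom name)
through an optional chain-equivalence map; waters are excluded unless
asked for. Solvent-accessible surface area is Shrake-Rupley on a
deterministic golden-spiral point set, 960 points per atom by default
(an isolated sphere is then exact by construction, and rigid-motion
invariance holds to ~0.3%, the quadrature anisotropy; 5000 points
tighten this several-fold at linear cost). The bundled radii are
standard element values (C 1.70, N 1.55, O 1.52, P/S 1.80, H 1.20
Angstrom); unknown elements error unless a default is supplied. Probe
radius 1.4 Angstrom is the water convention.

Interface area is computed from three SASA evaluations and reported
primarily as half the total change, (SASA_A + SASA_B - SASA_AB)/2 - the
per-side "buries X Angstrom^2" usage - with the per-component losses
alongside, because published single numbers are ambiguous between the
two conventions. Contacts are residue pairs with any heavy-atom distance
at or below 4.5 Angstrom (a standard van der Waals contact cutoff;
configurable), and clashes use 2.2 Angstrom.

# Trim-and-join dimer modeling

`join_as_dimer()` realizes the modeling procedure as described: the
monomer complex is duplicated and the duplicate placed so the two TAAT
cores sit exactly spacer_bp base pairs apart on the same strand, reading
5'->3' (head-to-tail). In `preserve_bend` mode the placement superposes
a 2-base-pair overlap window of duplicate frames; the junction overlap
is taken at the *start* of the copy (copy frames 1-2 onto original
frames k+1, k+2, with k = 4 + spacer_bp), so the composite keeps the
original DNA through the junction and the copy's DNA - including its own
bend around its core - beyond it. Overlapping at the original's far end
instead would discard the duplicate's bend, defeating the construction's
purpose. In `ideal_b` mode the DNA is rebuilt as a straight ideal
duplex of the composite sequence and both protomers are docked by their
core frames - the "no bending" control.

Nothing inside either protomer or the retained DNA halves moves (the
placement is rigid; internal distances are preserved to machine
precision and tested to 1e-6), matching the principle that no
alterations are made beyond duplication, trimming and junction
rebuilding. Only the junction O3' is rebuilt, to the same 1.6 Angstrom
geometry the builder uses, and models failing the 1.3-1.9 Angstrom
continuity band are rejected at assessment. `trim_duplex()` refuses to
delete any nucleotide with heavy atoms within 4.5 Angstrom of protein,
so the protein-contacted footprint cannot be trimmed away silently.

The assessment reports the minimum inter-protomer heavy-atom distance,
clash count, per-protomer interface residue sets, and the Calpha-Calpha
distances between all four termini pairings (N-N, C-C, N-C, C-N) -
published "termini distance" statements rarely say which pairing is
meant, so all are available.

# ITC: one-site model and fit

The titration model is the standard perfusion-cell one-site treatment
with the macromolecule in the cell and the titrant in the syringe (here:
protein in the cell at ~10 uM, DNA duplex in the syringe at ~100 uM, one
1 ul pre-injection then nineteen 14 ul injections at 20 C). Totals after
each injection are diluted by the cumulative displaced volume
(Mt = M0 (1 - f/2)/(1 + f/2), Xt = X0 f/(1 + f/2), f = dV/V0); the
cumulative bound heat comes from the single-site quadratic with a
clamped discriminant, and the per-injection heat adds the half-weight
displaced-volume term. The cell working volume is taken as 1400 ul, the
nominal perfusion-cell volume of the instrument class; it cancels in
generator/fitter round trips. Note one consequence of the dilution
convention: past saturation the magnitude of the cumulative heat
*decreases* slightly (bound complex is displaced), so monotonicity holds
through the transition, not globally.

Fitting is Levenberg-Marquardt least squares on the normalized heats
over (log10 K, dH, n), with a deterministic multi-start over log-spaced
K when no start is given; the first injection is discarded by default
(the small pre-injection mixes syringe and cell contents). Derived
quantities satisfy their defining identities exactly: dG = -RT ln K with
R = 1.98720425e-3 kcal/(mol K), Kd(nM) = 1e9/K, -TdS = dG - dH, and the
Wiseman parameter c = K M n flags fits outside the reliable 1-1000
window. n counts DNA sites per protein and is expected near 1 in this
orientation. At very high c the transition approaches a step and K is
intrinsically ill-determined - the noisy-replicate bias test therefore
runs at c ~ 100.

# EMSA cooperativity: tau under the two-site model

The two-identical-site equilibrium uses per-site association k = 1/Kd
and cooperativity omega: [PD] = 2 k [P][D] and
[P2D] = omega k^2 [P]^2 [D]; free protein is solved by bracketed 1-D
root finding on the protein mass balance to 1e-12 relative tolerance.
With the statistical factor 2 on the monomer complex, the statistic
tau = 4 [P2D][D]/[PD]^2 equals omega identically and the
independent-sites baseline is exactly 1 - a property the suite checks
over a thousand random parameter draws. Equivalently tau = 4 Kd1/Kd2 in
macroscopic constants.

The background-normalized form subtracts the probe-only lane's monomer
and dimer signals before forming the ratio. Lanes whose corrected
monomer signal is non-positive are excluded with a reason rather than
clamped, because clamping at zero biases tau upward. Replicates are
aggregated as the mean of per-lane tau values (each lane is one
measurement), not as tau of summed signals. Gel densitometry is out of
scope: the interface is the band-intensity table (free, monomer, dimer
per lane at stated protein concentrations, probe 35 nM).

# Spacer-variant PWMs and composition analysis

The dimer site is TAAT + 7-nt spacer + TAAT; the protein contacts the
first two spacer nucleotides, so composition analysis uses spacer
positions 3-7 only. Spacer variants set the two variant bases to
probability 0.5 each at those five motif columns (7-11 of 15) and floor
the other two bases at the 0.001 pseudocount; all other columns are
untouched. Scanning is log-odds (base 2) against the background on both
strands; the default hit threshold is 80% of the matrix's maximum score
- published per-motif thresholds for the original scanning tool are not
available, so the threshold is an explicit, logged parameter. N bases
score as background. A sequence counts once per cycle regardless of hit
multiplicity.

For genomic or selected dimer sites, orientation is decided by the best
log-odds strand of the full dimer matrix, and the spacer G/C fraction is
computed over the analyzed positions. The empirical distribution is
compared to a Normal(0.5, 0.33) reference. Because the attainable
fractions have only six support points (0, 0.2, ..., 1), a
Kolmogorov-Smirnov statistic against the *continuous* normal would be
dominated by discreteness (it cannot drop below ~0.12 for any sample);
the reference is therefore integrated over the attainable-fraction bins
before the statistic is formed, which makes the composition-matched null
pass at the usual critical values while preserving full sensitivity to
A/T- versus G/C-skew. The reported p-value uses the asymptotic
Kolmogorov distribution and is conservative for discrete data.

# Synthetic data: what it emulates, and what it does not

All generators are pure functions of their seed.

* `gen_selex()` emulates selection rounds: cycle 0 is random background
  (26-mers) with 10% of reads carrying a TAAT-N7-TAAT site of uniform
  spacer composition; each cycle resamples with weight
  exp(strength x energy), energy being the normalized best PWM score
  plus a linear A/T-fraction bonus over the analyzed spacer (the minimal
  mechanism that produces composition-dependent enrichment without
  asserting an energy model). Strength 0 is an exact null. The defaults
  (strength 6, bonus weight 1) produce strict A/T enrichment across
  cycles 1-4 with A/T above G/C from cycle 2 - the qualitative shape of
  interest. No sequencing-error or read-quality realism is attempted.
* `gen_emsa()` draws band signals proportional to the equilibrium
  species with 10% multiplicative Gaussian noise (a visually plausible
  scatter; the value is arbitrary and documented as such) and an
  additive background on the shifted bands, where the background
  correction operates. Noise-free tables recover omega exactly through
  the full analysis path.
* `gen_itc()` wraps the one-site model with optional Gaussian heat
  noise.
* `gen_toy_complex()` builds a duplex with a single TAAT core bent by a
  prescribed roll (default 20 degrees) at the step three levels 5' of
  the core - upstream of the footprint, where a minor-groove-tracking
  arm would sit - plus a rigid, geometry-only protomer: a shell of
  pseudo-atoms (radius 11-13.5 Angstrom, +/-90 degrees around the
  major-groove face, covering core levels -2 to +6.8). The shell's
  extent was chosen once so that the modeling contrast manifests: with
  the 20 degree bend and a 7-bp spacer the protomers meet below the 4.5
  Angstrom contact cutoff without clashing, while straight DNA or an
  8-bp spacer keeps them apart. The protomer is not a protein model; it
  exists to exercise contact, clash and termini logic. Requested bends
  above 60 degrees are rejected as unphysical for a short duplex.

Consequently, passing tests demonstrate internal consistency of the
models and estimators under controlled conditions - identity of tau and
omega, parameter recovery, geometric invariants - not agreement with any
particular experimental dataset. Analyses of deposited crystal
structures run through exactly the same functions when such a file is
supplied (`options(hdcoop.deposited_structure = ...)`), but no
structure file ships with the package.

# Problem sizes and determinism

The shipped analysis uses 2000 reads per SELEX cycle, three replicate
4-lane EMSA tables per condition (12 protein lanes per pooled estimate),
the 20-injection titration protocol, and 18-bp toy duplexes - sizes
chosen so every stage is exact or statistically stable while the whole
workflow runs in minutes on a laptop. Every random draw flows from an
explicit integer seed; geometry and fitting are deterministic, and
repeated runs are bit-identical.

# Known limitations

* The bend measure is window-based and reports localized curvature;
  it is not an axis-optimizing curvature analysis, and smoothly
  superhelical DNA reports zero bend by design.
* The shape predictor is table-driven and rigid at the base-pair level;
  absolute groove widths carry the calibration's fiber-model idealization.
* The dimer modeler does no energy minimization, side-chain repacking,
  or heterodimer combinatorics, and flanking regions outside the modeled
  domain are not predicted.
* The ITC module fits one-site models only; multi-site or sequential
  schemes are out of scope.
* tau is an estimator computed from band intensities, not a fitted
  binding model; no Hill analysis or direct omega fit is attempted.
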