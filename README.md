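# hdcoop

Quantitative analysis of cooperative homeodomain-DNA binding on
head-to-tail dimer sites.

Homeodomain transcription factors bind short A/T-rich motifs (TAAT
cores) that are everywhere in a genome. One mechanism that sharpens
their specificity is cooperative homodimer binding: two homeodomains
occupy two TAAT half-sites in head-to-tail orientation, exactly 7 bp
apart, and the DNA bend induced by the first protomer creates the
protein-protein interface that recruits the second. `hdcoop` is a
toolkit for every quantitative step of studying that mechanism,
aimed at structural biologists and biochemists working on protein-DNA
cooperativity:

* **DNA geometry** - base-pair reference frames, rigid-body step
  parameters (shift, slide, rise, tilt, roll, twist; mid-step
  convention), B-DNA construction (ideal, sequence-dependent or explicit
  steps), helical-axis bend, groove profiles (P-P minus 5.8 A
  convention), and deterministic sequence-based shape features.
* **Structure comparison** - Kabsch superposition/RMSD, Shrake-Rupley
  solvent-accessible surface area, buried interface area
  ((SASA_A + SASA_B - SASA_AB)/2), residue contacts.
* **Dimer modeling** - the trim-and-join procedure: duplicate a monomer
  protein-DNA complex, trim terminal base pairs, and join head-to-tail
  on an n-bp spacer either preserving the monomer's DNA bend or on ideal
  straight B-DNA, then assess inter-protomer contacts, clashes and
  termini distances.
* **ITC** - one-site isotherm simulation and Levenberg-Marquardt
  fitting with the perfusion-cell dilution conventions, and the derived
  thermodynamics `dG = -RT ln K`, `Kd = 1e9/K` nM, `-TdS = dG - dH`,
  Wiseman `c = K M n`.
* **EMSA cooperativity** - the tau factor
  `tau = 4 [P2D][D] / [PD]^2` with background normalization, and the
  two-identical-site equilibrium (`[PD] = 2k[P][D]`,
  `[P2D] = omega k^2 [P]^2 [D]`) under which `tau = omega` exactly and
  independent sites give tau = 1.
* **Motif analysis** - A/T- and G/C-rich spacer-variant PWMs
  (probability 0.5/0.5 on the analyzed five spacer positions), two-strand
  log-odds scanning, per-cycle selection enrichment, and spacer G/C
  composition versus a Normal(0.5, 0.33) reference.
* **Synthetic data** - seeded generators for SELEX libraries, EMSA
  lane intensities, ITC isotherms and toy bent complexes, so the entire
  pipeline is testable offline.

## Worked example

Fit a one-site isotherm generated under the study's titration protocol
(protein 10 uM in the cell, DNA 100 uM in the syringe, one 1 ul then
nineteen 14 ul injections, 20 C):

```r
library(hdcoop)
iso <- one_site_heats(titration_protocol(), K = 6.8e7, dH = -5.4, n = 1.02)
fit_one_site(iso)
#> OneSiteFit: K 6.8e+07 /M (Kd 14.7 nM), dH -5.40 kcal/mol, n 1.020
#>   dG -10.51, -TdS -5.11 kcal/mol, c 694
```

The fitter recovers the generating constants exactly: a 14.7 nM
dissociation constant, with the free energy split into its enthalpic
(-5.4) and entropic (-5.1 kcal/mol) parts, at a Wiseman c inside the
reliable window.

Quantify cooperativity from a simulated gel-shift titration
(0/25/100/400 nM protein, 35 nM probe, omega = 38, 10% band noise):

```r
tb <- gen_emsa(seed = 7, omega = 38)
analyze_titration(tb)
#> TauResult: mean tau 45.9 (sd 7.84) over 3 lane(s)
```

Each protein lane yields one background-normalized tau; their mean
estimates the cooperativity factor omega (38 here; noise-free tables
recover it exactly).

Build and assess a bent 7-bp-spacer dimer model from a toy monomer
complex with the characteristic 20 degree bend:

```r
cx <- gen_toy_complex(bend_deg = 20)
assess_dimer(join_as_dimer(cx, spacer_bp = 7, bend_mode = "preserve_bend"))
#> DimerAssessment: min inter-protomer 3.85 A, 0 clash(es), 4+4 interface residues
#>   termini N-N 36.7, C-C 34.1 A
```

The two protomers touch (3.85 A < the 4.5 A contact cutoff) without
clashing; with straight DNA (`bend_mode = "ideal_b"`) or an 8-bp spacer
they separate - the geometric signature of bend-dependent cooperativity.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on synthetic data
and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R         # SELEX, EMSA, ITC, toy complexes
Rscript analysis/02_itc_thermodynamics.R    # one-site fits + derived columns
Rscript analysis/03_emsa_cooperativity.R    # pooled tau: 7-bp vs 8-bp spacer
Rscript analysis/04_selex_spacer_composition.R  # cycle enrichment + spacer G/C
Rscript analysis/05_dna_geometry.R          # bend, grooves, shape contrasts
Rscript analysis/06_dimer_models.R          # four dimer models + assessment
```

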