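---
title: "Methods: analysing ice-binding peptides on synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing ice-binding peptides on synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icebindr)
```

## Scope and design

`icebindr` re-implements, as a tested and reusable pipeline, the
computational analyses used to characterize a short cyclic ice-binding
peptide: the scaffold/mutant data model with residue-essentiality queries,
local bond-order classification of water phases, ice-front tracking and
growth-rate estimation, solvation-shell desolvation analysis and binding
detection, disulfide torsion analysis and torsion-hydration coupling,
cysteine C-beta redox classification with disulfide inference, conformer
ensemble ranking, and quantification of ice recrystallization inhibition
(IRI) from grain maps.

No production simulation data or experimental micrographs are distributed
with the package. Instead, every analysis input is generated by a
synthetic-system module with embedded ground truth: proton-disordered
hexagonal ice (ice Ih) lattices, random liquid boxes, kinematically
scripted growth/binding trajectories, conformer ensembles with planted
energy/RMSD structure, and Voronoi grain maps. Passing tests therefore
demonstrate that the *analyses* recover known answers on inputs with the
right geometric structure; they do not demonstrate thermodynamic realism of
the generators, and results on real MD trajectories will additionally
reflect force-field and sampling choices the generators do not model.

## The peptide data model

The canonical scaffold is a cyclic 14-mer with cysteines at positions 2, 3,
7 and 13, threonines at 4, 10 and 14, aspartate at 8, and a disulfide
bridge between Cys3 and Cys13 in the oxidized state. The six remaining
positions are not part of the data model; they are filled with glycine and
flagged as placeholders, and every structural analysis involving them is a
synthetic stand-in. We deliberately do not guess their identities.

A position is *essential* when some variant carrying exactly one
substitution there is inactive while the parent is active at the same
concentration. Multi-substitution variants (the all-Thr mutant, cysteine
pair mutants, scrambles) never enter the essentiality call, because a loss
of activity in them cannot be localized to one residue. The packaged
activity table encodes the qualitative outcome pattern of the mutational
experiments (parent active only when oxidized; Thr10, Thr14 and Asp8
single mutants inactive; Thr4 mutant active; the non-bridging Cys2/Cys7
pair dispensable); its numeric grain-area ratios are synthetic round
numbers, chosen only to be clearly on the right side of the activity
threshold. The threshold itself (ratio < 0.8 at 1 mg/mL) is a configurable
default: IRI activity is reported qualitatively in splat-assay practice,
and no universal numeric cutoff exists.

```{r}
essential_residues(packaged_activity_table(), 1)
```

## Water-phase classification

Each water molecule is assigned a local bond-order vector
$q_{3m}(i) = \frac{1}{N_b}\sum_j Y_{3m}(\hat r_{ij})$ over its four nearest
oxygen neighbours within 3.5 Å, and each neighbour bond the normalized
correlation
$c_{ij} = \mathrm{Re}\sum_m q_{3m}(i)\,q_{3m}^*(j) / (|q_3(i)||q_3(j)|)$.
On an ideal ice Ih lattice the three basal-plane bonds evaluate to
$c = -1$ (staggered) and the c-axis bond to $c = -0.11$ (eclipsed). Bonds
with $c \le -0.8$ are counted staggered and bonds with
$-0.35 \le c \le 0.25$ eclipsed; per-molecule counts then decide the label:
4 staggered = cubic ice, 3 staggered + 1 eclipsed = hexagonal ice,
4 eclipsed = clathrate, exactly 3 eclipsed = interfacial clathrate,
otherwise at least 2 staggered = interfacial ice, anything else liquid.
Molecules with fewer than four neighbours inside the cutoff are liquid by
fiat (surface/gas safety). All cutoffs are configurable via
`phase_cutoffs()`.

Two properties of this classifier family matter for interpretation:

* *Ice-like* means hexagonal + cubic + interfacial ice. This grouping backs
  the solvation census and front profile; whether interfacial ice should
  count is a configuration choice (`include_interfacial` in `ice_like()`),
  not a fact we attribute to any reference analysis.
* A disordered liquid necessarily scatters across the liquid *and*
  clathrate-like labels: the eclipsed band catches roughly half of random
  bonds, so three-or-four-of-four eclipsed arrangements are common. A
  random liquid box classifies as ~99% *non-ice* but only ~70-75% strict
  `LIQ`. Oracle checks on liquid systems therefore assert the non-ice
  fraction, which is also the bifurcation every downstream analysis uses.

## Synthetic systems

**Ice Ih lattices.** Oxygens sit on a lonsdaleite lattice expressed in an
orthorhombic cell of 8 molecules (hexagonal lattice constants a = 4.50 Å,
c = 7.34 Å by default, standard values for ice near 265 K). Protons are
assigned randomly one-per-bond and repaired to Bernal-Fowler validity (two
donated hydrogens per oxygen, one hydrogen per bond) by zero-temperature
Monte Carlo moves that shift a bond's hydrogen towards the
donor-deficient end when this does not increase the total squared defect;
defects random-walk and annihilate well within the default budget of 10^6
moves. An audit function re-checks the rules by brute force over all bonds.

**Scripted trajectories.** The growth/binding trajectories are kinematic,
not physical: the analyses, not the dynamics, are the implementable
content, and ground-truth recovery is the acceptance surface. Every water
molecule owns one lattice site of a slab-spanning ice Ih lattice. The
nominal front advances as $z_0 + v\,t$, slowing by a configurable factor
(default 0.1) after the scripted binding time. A molecule is *converted*
(sits on its site, thermal jitter $\sigma/3$) once the front passes its
conversion threshold; unconverted molecules sit at a disordered position
(site plus a uniform displacement of up to 2.2 Å per axis, redrawn every
frame - bulk liquid decorrelates far faster than the 1 ns frame spacing -
plus jitter $\sigma$). Conversion thresholds implement kinetic roughening at
constant flux: molecules convert one at a time in noisy order of site
height (random tie-breaking within $\pm c/4$), with thresholds placed on an
exactly uniform z grid. Without the staggering, whole crystal layers would
convert simultaneously and the tracked front would advance in c/2 steps,
aliasing the recovered growth rate at low velocities; without the uniform
threshold grid, the binomial scatter of the converted count would dominate
the replicate variance of slow fronts. With both, the converted count grows
strictly linearly with front position while the interface stays rough at
the layer scale. Two further generator choices matter:

* the initial front position gets a per-seed uniform phase offset in
  [0, c), so replicate averages are not biased by a shared lattice phase;
* the probe (a methyl carbon plus a C-S-S-C chain that realizes the
  scripted torsion schedule exactly) stays at bulk height, descends to the
  surface over a short final approach (default 2 ns), and from the binding
  time onward rides the *converted* surface - the 20th-highest converted
  site, i.e. the dense middle of the rough interface - at a contact height
  of 0.5 Å, emulating the methyl sitting in a surface pocket. Growth-axis
  metadata labels the exposed face as a synthetic stand-in for a primary
  prismatic front; no crystallographic fidelity is claimed.

The default desk-scale profile is 3-30 trajectories of 90 frames (1 ns
spacing) with ~580 waters in a 13.5 x 15.6 x 88 Å slab box, periodic in x/y
only. These sizes keep the full recovery grid (10 seeds x 3 velocities)
within minutes while leaving dozens of molecules per crystal layer.

**Ensembles and grain maps.** Conformer ensembles are built from a common
synthetic cyclic backbone with per-cluster displacement fields
(between-cluster RMSD), per-model noise (within-cluster RMSD), random
rigid-body placement and strictly increasing energies; a planted optimum
sits at the centre of the majority cluster of the low-energy shortlist
with the lowest energy, so the ranking has a known right answer. Grain
maps are Voronoi tessellations around uniform random seeds, whose mean
grain area is exactly (width x height)/n when all grains are kept.

## Trajectory analyses

**Front tracking.** The slab is binned along z (default 1.5 Å), the
ice-like fraction per bin is forced monotone (non-increasing away from the
ice side, suppressing single-bin noise and transient ice clusters in the
liquid), and the front is the linearly interpolated 0.5 crossing scanned
from the ice side. All-ice and all-liquid profiles return the boundary
value with a diagnostic. The growth-rate series is the centred finite
difference of a moving-average-smoothed front (default window 11 points),
with edges omitted rather than padded - smoothed values exist only where
the full window fits, and the same edge-omission convention applies to the
torsion series. Two front estimators ship: the profile 0.5-crossing
(`method = "crossing"`, localizes the interface within a bin) and an
integral estimator (`method = "count"`, total ice-like population divided
by the areal site density), whose frame-to-frame *changes* track front
displacement with much lower variance because interface-labelling offsets
cancel in differences. For scalar rate recovery `mean_growth_rate()` uses
the least-squares slope of the count-based series over a window; slow
fronts (0.1 Å/ns over tens of ns) are recovered to a few percent this way,
where a crossing-based pointwise derivative would be dominated by
interface noise.

**Census and binding.** The solvation census counts water oxygens within
5.4 Å (first minimum of a methane-water pair correlation; the right scale
for a methyl probe) of the probe atom, split ice-like vs rest. Binding is
the earliest time from which the ice-like count stays at or above k = 4
for at least 5 ns. Both defaults are justified by the recovery tests: on
scripted runs with sigma up to 0.3 Å they recover the scripted binding
time to within +/-2 frame intervals across seeds and velocities. The mean
liquid-shell occupancy of a methyl-sized probe in these synthetic systems
is ~15-20 waters; the corresponding production-simulation observable
(an average of 16 liquid waters) depends on an unstated shell cutoff and
is treated as non-reproducible at desk scale.

**Torsions and coupling.** Dihedrals follow the IUPAC sign convention
(cis = 0), validated against constructed geometries and an independent
implementation. The torsion-hydration map is a mass-1 2D histogram of
(torsion, shell count) over a time window, with presets for the full
pre-binding span and the last few ns before binding. Hydrogen bonds use
the standard geometric criterion (donor-acceptor <= 3.5 Å, H-donor-acceptor
angle <= 30 degrees), split by the acceptor's phase label. Distance PDFs
are histogram densities with integral 1 (default bin 0.2 Å). RMSD uses
Kabsch superposition with the determinant + 1 guard so reflections are
never introduced.

## NMR-side analyses

C-beta shifts below 32 ppm are called reduced, above 35 ppm oxidized, with
an indeterminate band between; the bands are literature-style defaults
around the clearly separated measured values (28.1 vs 38.8/42.1 ppm) and
are configurable. When exactly two cysteines are oxidized they are reported
as the inferred bridge.

"Lowest energy and RMSD" is ambiguous as a selection rule, and it is also
unstated whether reference RMSD means pairwise means or distance to the
lowest-energy model. We operationalize it as: shortlist the k = 10
lowest-energy models, compute all-pairs superposed RMSD, rank models by
energy and by mean RMSD to the rest of the shortlist, and select the
minimal rank sum, ties to the lower energy. Both component ranks and the
full RMSD matrix are emitted so any alternative rule can be audited.

## IRI quantification

The statistic is the mean grain area over all grains, relative to a
control - the field sometimes uses mean *largest* grain size instead, so
that choice is explicit and the per-grain areas are returned. Border
grains are excluded by default (partial grains bias areas down), but the
Voronoi recovery oracle keeps them, because only then is the tessellation
mean exactly (W x H)/n. Input is a pre-segmented label map; segmenting raw
micrographs is out of scope.

## Numerical choices and degenerate inputs

* Minimum-image convention on orthorhombic boxes only; slab axes are
  non-periodic and simply skip imaging.
* Fewer than 4 molecules: all liquid, with a message. Empty solvation
  shells in `clathrate_fraction()` report NA, never 0.
* Collinear torsion atoms yield NA for that frame.
* Degenerate q3 norms raise an error in `bond_correlation()`; inside the
  classifier such bonds count neither staggered nor eclipsed.
* Every stochastic operation takes an explicit seed and restores the RNG
  state; trajectory generation is bit-reproducible per seed.

## Known limitations

The generators do not model interfacial pre-ordering, density differences
between ice and water, molecular diffusion, or real conformational
dynamics; the liquid is a static disordered configuration with thermal
jitter. The headline observables of long production simulations (shell
occupancies, binding times of a diffusing peptide, NMR-model C-beta
spacings) are consequently demonstrated as *recoverable statistics* on
scripted ground truth, not reproduced values. The six placeholder residues
make any sequence-dependent structural conclusion about real peptides
impossible by construction - deliberately so.
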