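---
title: "Methods: chirality-aware analysis of mirror-image RNA aptamer complexes"
author: "spiegelmer package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chirality-aware analysis of mirror-image RNA aptamer complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Spiegelmers are aptamers built entirely from L-ribonucleotides, the
enantiomer of natural D-RNA. Because they are exact mirror images, every
chiral descriptor of their structure inverts: helices that are
right-handed in D-RNA are left-handed in L-RNA, and the sugar pucker
nomenclature (endo vs exo) swaps. Annotation software written for natural
nucleic acids computes torsions and puckers on the deposited coordinates
without regard to chirality, so its output must be corrected before it
can be reported in the standard vocabulary. This package computes those
descriptors with the chirality made explicit, and assembles around them
the analyses used to characterize an aptamer-protein complex: interface
areas and contacts, ion-site identification, rigid-body comparison
against related structures, and SPR binding kinetics.

# Geometry conventions

**Torsions.** `dihedral()` uses the IUPAC sign convention: looking along
the central bond, a clockwise rotation of the far bond relative to the
near bond is positive. Under this convention mirror-imaging a structure
negates every proper dihedral exactly; this is asserted in the test suite
at 1e-9 degrees on random quadruples and verified against an independent
plane-normal formula.

**Chirality detection.** A sugar is called D or L from the sign of the
triple product `(C3'-C4') x (O4'-C4') . (C5'-C4')` (positive for D). The
sign convention was calibrated once against ideal D-ribonucleotide
geometry; a second triad at C1' (with the glycosidic nitrogen) is
cross-checked when present, and any disagreement or a triple product
smaller than 0.1 A^3 yields "undetermined" rather than a guess.

**Glycosidic torsion.** chi is O4'-C1'-N9-C4 (purines) or O4'-C1'-N1-C2
(pyrimidines), computed on the coordinates as deposited. For L-residues
the chirality-corrected value is `-chi`, and the syn/anti call is made on
the corrected value with the standard boundary: syn iff chi_corrected in
(-90, 90]. The correction makes the call mirror-invariant, which is the
behaviour a chemist expects: a molecule and its mirror image have the
same base orientation relative to their own sugars.

**Pseudorotation.** The five endocyclic torsions nu0..nu4 give the phase
through the Altona-Sundaralingam relation
`tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72))`,
resolved with the two-argument arctangent, and the amplitude
`tau_m = nu2 / cos P`. Envelope labels come from ten 36-degree bins
starting with C3'-endo on [0, 36). For L-sugars the corrected label is
obtained by negating the torsions, equivalent to `P + 180`; this swaps
every endo label with its exo partner while D labels pass through
unchanged. Rings with `|tau_m| < 5` degrees are effectively planar and
labelled "undetermined". The synthetic ring generator uses the same
Altona-Sundaralingam convention (`nu_j = tau_m cos(P + 144 (j - 2))`, so
`nu2 = tau_m cos P`), which makes generator and analyzer exact inverses;
the test suite checks the round trip to within 1 degree across the whole
phase wheel.

**Helix handedness.** Handedness is read from the screw sense of the C1'
trace: with the helix axis (first principal component) oriented 5' to 3',
a positive mean azimuthal progression means right-handed. This
formulation is exact for any twist in (0, 60], is invariant under
traversal reversal, and strictly flips under mirroring. The mean virtual
C1' dihedral is also reported as a descriptive statistic; note that under
the IUPAC sign convention it is *negative* for right-handed nucleic-acid
helices at 30-36 degrees of twist, so its raw sign is not used as the
classifier. For short stacked-pair runs (a helix of only 2-3 pairs) the
same screw logic is applied to base-pair steps: the rotation of the
C1'-C1' pair vector about the local rise.

# Base pairing

Hydrogen bonds between bases are detected between donor and acceptor
heavy atoms (N/O) from per-base chemistry tables, within 2.4 A and a
configurable cutoff (default 3.5 A, a common crystallographic
convention); crystal structures carry no hydrogens so none are required.
Modified nucleotides (e.g. the 2'-methylseleno-uridine used for
anomalous phasing) are mapped to a parent base for pairing chemistry
while retaining their residue name.

A candidate pair must have at least two base-base hydrogen bonds,
near-coplanar bases (plane angle <= 35 degrees), an edge-on approach
(the inter-centroid vector within 35 degrees of both base planes), and a
vertical offset along the base normals of at most 2.5 A. The last two
gates reject stacked and diagonal neighbours, which can satisfy distance
criteria in tightly wound helices; real annotation tools apply the same
kind of vertical-separation criterion. The hydrogen-bond pattern is then
matched against dictionaries: canonical Watson-Crick G-C (three bonds)
and A-U (two), Hoogsteen-edge patterns (purine N7 plus O6/N6), and named
noncanonical types including the GG N7-N1 carbonyl-amino and
GA N3-amino amino-N1 pairs and the GU wobble (classified noncanonical so
the Watson-Crick tally stays strict). Valid but unmatched pairs are
"noncanonical / unclassified" - never dropped.

Strand orientation is parallel iff the local 5'->3' backbone directions
have a positive dot product. The direction is taken from the C1' chain
propagation (centred difference over neighbours) where neighbours exist,
falling back to the intra-residue C5'->C3' vector for isolated residues;
on idealized fixtures whose backbone connectivity is not enforced the
intra-residue vector alone can be dominated by its lateral component and
misread the strand sense, while the propagation direction is robust for
both fixtures and real chains.

Pseudoknots are crossings in the partner list: pairs (i, k) and (j, l)
with i < j < k < l. Detection is by direct enumeration and is tested
against an independently coded brute-force oracle on random pair sets.

# Interfaces

Solvent-accessible surface areas use the Shrake-Rupley construction with
a deterministic golden-angle spiral lattice (no random sampling - results
are exactly reproducible), a 1.4 A probe and 960 points per atom by
default. The radii table is a standard protein/nucleic-acid set in the
NACCESS/Chothia family, passed as configuration. Waters and ions are
excluded from interface areas by default (a flag includes them).
Invariance of the total area under rigid motion and mirroring is a
sampling property: the suite verifies it to 0.1% at 5000 points per atom,
the resolution used for those checks.

The interface area between two chain sets is the mean of the two sides'
buried areas, `(dA_a + dA_b)/2`, with `dA_X = sasa(X alone) - sasa(X in
complex)`; both per-side areas are always reported, and interface
residues are those burying more than 0.1 A^2. This buried-area-mean
convention is the one whose internal arithmetic matches published
per-side/interface triples from PISA-style analyses. Inter-chain hydrogen
bonds use the same 2.4-3.5 A heavy-atom window with residue chemistry
tables (backbone and side-chain donors/acceptors, ribose 2'-OH as donor
and acceptor, phosphate oxygens as acceptors). Salt bridges are
charged-group nitrogens (Arg, Lys, His) to phosphate or carboxylate
oxygens within 4.0 A, with atom pairs already counted as hydrogen bonds
excluded so the two tallies stay disjoint. Cation-pi contacts require the
cation centre (Arg CZ or Lys NZ) within 6.0 A of an aromatic ring
centroid and within 45 degrees of the ring normal (face-on approach).

# Ion sites

A coordination shell collects oxygen ligands (optionally nitrogen) within
3.2 A - wide enough to capture Rb-O-range contacts. Candidate identities
are scored by `|d_mean - d_ideal|` against a configurable table of ideal
ion-oxygen distances anchored at Sr-O 2.62 A and Rb-O 2.98 A, with Mg
2.07, Ca 2.39, Na 2.41, K 2.81 and Cs 3.07 from the same literature
family; ranking is ascending with ties broken by element name, and a
z-like score (`score/d_sd`) accompanies it when the shell spread is
positive. Shells with fewer than three ligands are scored but flagged
low-confidence. This distance scoring is a desk-scale analogue of the
restrained-refinement discrimination used in crystallographic practice;
the refinement itself is out of scope. A separate check reports whether
observed anomalous difference peak heights across sites are ordered
consistently with theoretical f'' values at the measurement wavelength -
an ordering statement only, no absolute scale is claimed.

# Superposition and epitope mapping

Kabsch superposition uses the SVD solution with the reflection branch
corrected, so the rotation is always proper; mirror images of chiral sets
therefore never superpose to zero, which the suite asserts on helix
fixtures. Results are cross-checked against the quaternion (Horn) method
to 1e-9 A. Atoms are paired by author numbering or by Needleman-Wunsch
global alignment (BLOSUM62, gap open/extend 10/0.5 via Biostrings), then
by atom name within matched residues; unpaired residues are dropped and
counted, never padded. Protein comparisons default to C-alpha selection
with all-atom available - published r.m.s.d. values do not always state
the selection, so both are reported where it matters. Epitope mapping is
restricted to the reference's contact positions and annotates
substitutions from a user-editable effect table seeded with mutational
binding results for the CCL2 epitope (R18K, V22K, H66Y neutral; S21P,
S63F, S63Y detrimental); the flags follow the table, not hard-coded
values.

# SPR kinetics

The binding model is 1:1 Langmuir with mass-transport limitation in the
algebraic-elimination form

```
dR/dt = (ka C (Rmax - R) - kd R) / (1 + ka (Rmax - R) / kt)
```

integrated through an association phase (constant injected concentration)
and a dissociation phase (C = 0) with adaptive-step lsoda at relative
tolerance 1e-8. The proprietary evaluation software used with Biacore
instruments does not document its exact mass-transport formulation; the
algebraic form above is the standard one and is adopted here. As
`kt -> infinity` the model reduces to the closed form
`R(t) = Req (1 - exp(-(ka C + kd) t))`; with the fixture kinetics
(`ka Rmax = 5e7`) the transport factor at `kt = 1e9` still perturbs the
curve by more than 0.1%, so the limit checks in the suite use
`kt = 1e11`, where agreement to 0.1% is comfortably met.

Global fitting shares ka, kd and Rmax (and optionally kt) across the
concentration series by Levenberg-Marquardt least squares on log-scale
parameters, with a data-driven start (terminal dissociation decay for kd,
maximum response for Rmax) plus an optional log-grid multistart over
ka in [1e3, 1e8] and kd in [1e-5, 1e-1]. The fit is deterministic for a
given configuration. Following instrument-software practice the
refractive-index (bulk) term is fixed at zero and kt is fixed at
1e7 RU/(M s) unless explicitly released. `Kd = kd/ka` holds exactly by
construction. Curves sharing one clock are integrated as a single vector
ODE inside the fit, which keeps the multistart affordable. Failed trial
integrations at extreme parameter values are caught and penalized (the
Fortran solver may print diagnostics; they are harmless).

Concentration presets mirror Biacore practice: the full injection series
(0.12-1000 nM with duplicates), a high-affinity window (<= 1.95 nM plus a
blank) used for tight binders, and a reduced-affinity window
(<= 62.5 nM). Generator defaults echo the wild-type-affinity scale
(ka = 1e6 1/(M s), kd = 1.32e-3 1/s, Kd = 1.32 nM, Rmax = 50 RU, 240 s
association and dissociation). Identifiability depends strongly on the
window: on the high-affinity subset alone (all concentrations within
1.5x Kd, transport-limited onset) ka is weakly determined and noisy
recovery is poor, which is expected, not a solver defect; the recovery
experiments therefore use the full series, where the suite requires the
median relative error of ka and kd across 20 noise seeds at 2% of Rmax
to stay within 5%. Double referencing subtracts the surface-control
curve and the mean of buffer blanks after linear-interpolation
resampling to the sample clock.

# The synthetic-data module

The generators produce geometrically honest but idealized objects:

* Sugar rings are closed by least squares with fixed bond lengths,
  softly restrained angles and strongly weighted target torsions
  (residual torsion error must be below 0.5 degrees or the builder
  errors). Exocyclic C5', O2', O3' are attached with D stereochemistry.
* Bases are planar fused regular polygons (bond ~1.38 A) with exocyclic
  donors/acceptors; base pairs are placed by a small rigid optimization
  that drives the designated donor-acceptor distances to 2.9 A with a
  soft clash floor at 2.8 A. The same machinery builds Watson-Crick
  duplexes and engineered Hoogsteen/noncanonical test pairs.
* Duplexes are assembled in a standard pair frame (glycosidic-N line
  along x, pair midpoint displaced 4 A off the axis) and propagated by
  twist 32.7 degrees and rise 2.81 A per step about z; any canonical
  right-handed parameterization would do, since acceptance rests on
  property tests, not fiber-diffraction fidelity. Single strands are
  seated with the base extending outward from the axis so stacked
  neighbours keep non-hydrogen-bonding separations.
* The mirror operator negates x - a single reflection rather than an
  inversion, chosen because any improper operation works and one
  reflection is simplest to audit. It is an exact involution, preserves
  all distances, and negates all dihedrals.
* Ion shells place water oxygens on octahedral axes or a deterministic
  spiral at prescribed distances. Sensorgram noise is Gaussian with a
  recorded seed; generation is bit-reproducible.

What the fixtures do **not** emulate: real backbone connectivity between
consecutive nucleotides (phosphodiester continuity is not enforced),
base-pair propeller/buckle, sequence-dependent stacking, crystallographic
disorder, or solvent structure. Passing the synthetic suite therefore
demonstrates the correctness of the geometric and statistical machinery,
not the ability to reproduce any particular deposited fold; the tests
that reproduce published numbers run against the deposited entries
themselves when local copies are supplied (see `pdb_entry_path()`).

# Problem sizes and determinism

The default test run uses desk-scale problems chosen to exercise every
code path: 6-10 nt helices, 20 pseudorotation phases, 100 random pair
sets for the crossing oracle, 5000 sphere points for the SASA invariance
checks, and 20 noise seeds for the kinetic recovery experiment (full
concentration series at 2 s sampling, single-start fits). All randomness
sits behind explicit seeds; `scripts/acceptance.R` derives every noise
stream from its `--seed` argument and reports each quantity with the
problem size used.

# Known limitations

* Backbone torsions alpha-zeta and suite classification are not
  computed.
* Base-pair annotation is dictionary-based, not a full 12-family
  geometric classification; pairs outside the dictionaries are labelled
  unclassified rather than typed.
* SASA is O(n * neighbours * points) in plain R - comfortable for
  complexes of a few thousand atoms, not for large assemblies.
* Symmetry expansion assumes orthogonal unit cells (sufficient for
  tetragonal/orthorhombic lattices, not oblique ones).
* Heterogeneous-ligand and bivalent-analyte SPR models are out of scope.
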