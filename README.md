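# spiegelmer

Chirality-aware structural analysis of mirror-image RNA aptamer
(Spiegelmer) complexes in R.

Spiegelmers are aptamers chemically synthesized from L-ribonucleotides —
the mirror image of natural D-RNA. They fold into mirror-image
architectures (left-handed helices where D-RNA is right-handed) and bind
natural L-protein targets such as the pro-inflammatory chemokine CCL2.
Standard nucleic-acid annotation tools silently assume D-chirality, so
their sugar-pucker and torsion output must be reinterpreted for L-RNA.
This package makes the chirality bookkeeping explicit and reproducible,
and bundles the biophysical analyses used to characterize an
aptamer-protein complex end to end:

* **Structure I/O** — PDB/mmCIF reading and writing (via bio3d), altloc
  collapsing, residue classification (protein / nucleotide incl. modified
  and L-forms / ion / water), rigid transforms and crystal-symmetry mates.
* **Chirality and torsions** — D/L detection from the signed volume of the
  sugar substituent triad; glycosidic torsion chi with syn/anti calls on
  the chirality-corrected angle; Altona–Sundaralingam pseudorotation
  (phase P, amplitude tau_m) with the endo/exo label inversion required
  for L-sugars.
* **Base pairing** — heavy-atom hydrogen-bond detection; dictionary
  classification into Watson–Crick, Hoogsteen and named noncanonical pairs
  (e.g. GG N7-N1 carbonyl-amino, GA N3-amino amino-N1, GU wobble); strand
  orientation; pseudoknot detection by crossing enumeration; helix
  handedness from the screw sense of the C1' trace.
* **Interfaces** — Shrake–Rupley solvent-accessible surface areas on a
  deterministic spiral lattice; buried-area interface metrics
  (`interface = (dA_a + dA_b) / 2`); inter-chain hydrogen bonds, salt
  bridges and cation–pi contacts.
* **Ion sites** — coordination-shell extraction and identity scoring
  against ideal ion–oxygen distances (e.g. Sr–O 2.62 Å vs Rb–O 2.98 Å),
  plus anomalous-peak/f'' ordering consistency checks.
* **Superposition** — Kabsch least-squares fitting (proper rotations
  only), atom pairing by author numbering or Needleman–Wunsch alignment,
  and epitope substitution mapping across chemokine homologs.
* **SPR kinetics** — simulation and global fitting of 1:1 Langmuir
  binding with mass-transport limitation,
  `dR/dt = (ka C (Rmax - R) - kd R) / (1 + ka (Rmax - R)/kt)`,
  with double referencing and concentration-series presets.
* **Synthetic data** — every fixture needed to exercise the pipeline is
  generated in code: ideal A-form helices and their exact mirror images,
  sugar rings built at prescribed pseudorotation states, engineered base
  pairs, toy complexes, ion shells, noisy sensorgrams.

## Worked example

```r
library(spiegelmer)

## a mirror-image (L) Watson-Crick duplex fixture
helix <- build_aform_helix("GCGCAU", duplex = TRUE, chirality = "L")
geo <- nucleotide_geometry(helix)
head(geo[, c("resno", "resid", "chirality", "glycosidic_class",
             "raw_pucker", "pucker")], 3)
#>   resno resid chirality glycosidic_class raw_pucker   pucker
#> 1     1     G         L             anti    C3'-exo C3'-endo
#> 2     2     C         L             anti    C3'-exo C3'-endo
#> 3     3     G         L             anti    C3'-exo C3'-endo

ss <- secondary_structure(helix)
table(ss$pairs$pair_type)   #> watson_crick: 6
ss$dot_bracket              #> "(((((())))))"
ss$helices[[1]]$handedness  #> "left"
```

The raw pucker label computed on the deposited coordinates is C3'-exo;
because the sugars are L, the chirality-corrected label (the one to
report) is C3'-endo — the endo/exo inversion that L-chirality demands.
The helix is left-handed, as expected for mirror-image RNA.

```r
## kinetic recovery from a noisy synthetic Biacore-style series
sg <- generate_sensorgrams(ka = 1e6, kd = 1.32e-3, Rmax = 50,
                           noise_sd = 0.5, seed = 1, dt = 2,
                           concentrations = spr_concentration_preset("full"))
global_fit(sg, multistart = 0)
#> 1:1 Langmuir fit (16 curves): ka 1e+06 1/(M s), kd 0.00133 1/s, Kd 1.32e-09 M
#> Rmax 50.0 RU, kt 1e+07 (fixed), SSE 1.04e+03 RU^2, converged: TRUE
```

The fitted dissociation constant (1.32 nM) matches the generating
parameters at the wild-type-affinity scale.

A one-command annotation run over a coordinate file:

```r
report <- run_pipeline(list(input = "complex.pdb",
                            stages = c("geometry", "pairs", "ions")))
write_report(report, "report.json")
```

or, from a shell, the thin wrapper `inst/scripts/annotate.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/annotate.R", package="spiegelmer"))')" \
  --input complex.pdb --stages geometry,pairs,ions --out report.json
```

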