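---
title: "Detecting intramolecular isopeptide bonds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intramolecular isopeptide bonds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isopeptider)
```

## The problem

Intramolecular isopeptide bonds cross-link a lysine side-chain NZ to the
side-chain acyl carbon of an asparagine or aspartate within one protein,
with a spatially adjacent aspartate or glutamate acting as the catalytic
residue. They are hallmarks of CnaA-like and CnaB-like β-sandwich domains
of Gram-positive pilins and adhesins, where they confer mechanical and
chemical stability. Because the cross-link is not part of standard
polypeptide chemistry, model-building software does not form it
automatically, and depositions with unmodeled or distorted bonds exist.
`isopeptider` detects candidate sites geometrically and scores them
probabilistically, so the decision is explainable: a site is called a bond
because its triad geometry matches curated examples closely (low RMSD) and
it is buried (low rASA).

## The detection model

**Template matching.** A template is the set of labeled side-chain atoms of
one known triad (Lys CB–CG–CD–CE–NZ; Asn CB–CG–OD1–ND2 or Asp
CB–CG–OD1–OD2; Glu CB–CG–CD–OE1–OE2), with its topology and a flank
sequence for homology exclusion. A match is an assignment of three distinct
target residues, type-matched strictly per role, such that *every* pairwise
inter-atom distance among the assigned atoms reproduces the template's
within `distance_tolerance`. Surviving assignments are scored by optimal
superposition RMSD (Kabsch, SVD form; proper rotations only) and reported
below `rmsd_cutoff`. The search walks residue roles depth-first with
pairwise-distance pruning; a brute-force enumerator over all triples
(`find_matches_brute()`) is exported as the reference implementation and
the test suite asserts exact hit-set equivalence on structures of up to 60
residues. Carboxylate oxygen labels (Asp OD1/OD2, Glu OE1/OE2) are
chemically arbitrary in deposited files, so both namings are tried and the
lower-RMSD one kept. Sites may span chains; reported chain identifiers make
that visible.

**Per-site reduction.** When several templates hit the same unordered
residue triple, only the lowest-RMSD hit survives; ties break on
lexicographic template id so reruns are reproducible. The retained
template's topology (CnaA-like / CnaB-like) is the site's topology call.

**Features and classification.** Two features enter a logistic regression:
the RMSD to the closest template, and the mean relative accessibility of
the triad. rASA uses Shrake–Rupley SASA (deterministic Fibonacci sphere
point set, 500 points per heavy atom, 1.4 Å water probe, whole-structure
context including heteroatom ligands as occluders, hydrogens ignored)
normalized by the Rost–Sander per-residue maxima. The mean over the three
residues is used because the reduction is symmetric and bounded; nothing
downstream depends on which triad member is most buried. The model is fit
by maximizing the L2-penalized likelihood with penalty ‖w‖²/(2C), C = 1,
intercept unpenalized, features unstandardized; the convention is recorded
in the model file so training and prediction cannot silently disagree. The
decision rule is strict: `is_bond` requires p *above* the threshold, so
p = 0.5 classifies negative at the default threshold of 0.5.

**Geometry quality control.** For predicted bonds only (the step is
optional), two kinds of flags are computed against a reference table of
curated bond geometries:

* the NZ–C(acyl) bond length Z-score, an outlier iff |Z| > 4 (strictly);
* the likelihoods of the three pseudo-dihedral pairs under 2-D Gaussian
  kernel density models, one per (topology × pair), an outlier iff the
  likelihood falls below the 5th percentile of the reference sample's own
  likelihoods — by construction about 5% of the reference flags itself.

The pseudo-dihedrals treat the isopeptide C–N bond as a peptide-bond
analogue along CD–CE–NZ–C(acyl)–CB–CA: pseudo-φ = CD–CE–NZ–C(acyl),
pseudo-ω = CE–NZ–C(acyl)–CB (torsion about the acyl C–N bond),
pseudo-ψ = NZ–C(acyl)–CB–CA. Glu acceptors would use CD as the acyl
carbon; in the three triad types shipped, the acceptor is always Asn or
Asp (acyl carbon CG) and Glu only appears in the catalytic role. A site
whose atoms are missing gets `NA` for the affected component, which is
skipped — never counted as an outlier. The overall flag is `outlier` iff
any available component flags.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `distance_tolerance` | 1.5 | Å | pairwise-distance slack defining a match; generous enough that planted triads with ≤ 0.5 Å coordinate noise are never pruned |
| `rmsd_cutoff` | 2.0 | Å | hit-reporting radius; far above the noise floor of true sites, so recall is limited by the classifier, not the search |
| `sasa_points` | 500 | points/atom | SASA discretization; the suite checks the isolated-atom analytic sphere within 2% and 500 → 2000-point drift below 0.02 rASA |
| probe radius | 1.4 | Å | standard water probe |
| `threshold` | 0.5 | probability | decision cut, strict inequality |
| Z-score cut | 4 | σ | bond-length outlier rule, strict inequality |
| KDE cutoff | 5th percentile | log-likelihood | outlier rule calibrated on the reference's own likelihoods |
| identity threshold | 30 | % | training/evaluation-mode exclusion, strictly above |

Flank identity uses optimal global alignment with BLOSUM62 and affine gaps
(open 10, extend 1); identity is identical aligned positions over
alignment length. The flank window is 20 residues upstream of the first
triad residue to 20 downstream of the last, in modeled-sequence space,
truncated at chain ends. Identity exclusion is applied only when
explicitly requested (`identity_exclusion`), i.e. in training/evaluation
runs — in plain prediction there is no self-matching to prevent.

## Numerical choices

* **Altloc resolution** keeps the highest-occupancy alternate per atom
  slot, ties broken by file order; waters are stripped; other heteroatoms
  are kept (they occlude) but never matched. Only model 1 of multi-model
  files is used; NMR ensembles are not averaged.
* **Sphere points** come from a golden-angle Fibonacci lattice, so SASA is
  bit-reproducible. The lattice is fixed in the laboratory frame, so
  rigid-body motion of the structure changes rASA only at the
  discretization level (below 0.5% relative at 2000 points).
* **KDE bandwidths** follow Scott's rule per dimension, n^(−1/6) times the
  *circular* standard deviation (recentre on the circular mean, wrap
  residuals). The plain standard deviation is meaningless for trans
  pseudo-ω samples straddling the ±180° cut, where it approaches 180°.
* **Angular wrap-around** is handled by mirroring samples within 20° of
  the cut across it (±360° copies) rather than by a full toroidal (von
  Mises) density — a documented approximation; the suite checks the
  density still integrates to 1 within 2% on a 1° grid for a
  cut-straddling fixture.
* **Kabsch RMSD** restricts to proper rotations (reflection-corrected
  SVD), so mirror images do not superpose; dihedral signs are
  chirality-sensitive and mirroring a structure negates all three
  pseudo-dihedrals exactly.
* **Degenerate inputs**: empty structures, unknown chains, single-class
  training data, too-few KDE samples (< 20), and residues without
  tabulated maxima raise errors naming the offender; missing atoms make
  quantities "unmeasurable" (`NA`), never silently zero.

## The synthetic generator: what it emulates, what it does not

All tests and the acceptance run are driven by `make_positive()`,
`make_negative()` and `make_corpus()`, which build structures from
standard internal coordinates (NeRF chaining):

* planted triads reproduce a requested bond length and pseudo-dihedral
  triple exactly (the construction is the inverse of the measurement);
* per-topology geometry differs the way the two domain classes differ in
  the literature — CnaA-like bonds are generated trans (pseudo-ω ≈ 180°),
  CnaB-like cis (pseudo-ω ≈ 0°) — with 8° angular spread and bond lengths
  N(1.33 Å, 0.02 Å), so the six KDE reference models are genuinely
  distinct;
* burial is emulated by a close-packed carbon lattice around the triad
  (contact ≈ van der Waals, spacing too tight for a 1.4 Å probe), because
  Shrake–Rupley occlusion is local — a distant hollow shell would not
  bury anything;
* decoys are self-avoiding random-walk chains carrying full Lys / Asn /
  Asp / Glu side chains (so the matcher has real candidates to reject)
  and are rejection-validated to contain no template hit;
* corpus templates are cut from held-out planted structures, including
  their true flank sequences, so identity exclusion can be exercised
  against the corpus.

The generator does **not** emulate crystallographic artifacts (alternate
conformations, partial occupancy, density fit), realistic protein packing
around the site, sequence–structure correlation, or homology between
decoys and positives. Passing the synthetic corpus therefore demonstrates
that the machinery — search, reduction, features, classification,
QC — works end to end under controlled geometry and noise; it does not
certify performance on deposited PDB entries, which depends on the quality
of the curated template set and reference geometries supplied.

For the same reason the bundled resources are explicitly synthetic: the
template library (`templates_synthetic/`), the geometry reference
(`geometry_reference_synthetic.tsv`) and the default classifier
(`model_synthetic.txt`, trained on the documented Gaussian fixture
corpus: positives RMSD ~ N(0.3, 0.1), rASA ~ N(0.1, 0.05); negatives
RMSD ~ N(1.5, 0.2), rASA ~ N(0.5, 0.1); 200 + 200, seed 7). They use the
same file schemas a user would produce from curated real bonds, so real
resources drop in via `--templates`, `--geometry-ref` and `--model`.

## Study conditions and problem sizes

The synthetic study conditions are fixed once: evaluation corpora use 20
planted bonds at σ = 0.2 Å isotropic coordinate noise among 50 decoys of
60 residues; search-equivalence checks run 25 structures of at most 60
residues; noise-monotonicity uses 100 replicates at σ ∈ {0, 0.1, 0.3,
0.5} Å; KDE calibration uses 500 reference rows per topology. These sizes
make every distributional check well-resolved while keeping the whole
suite a desk-scale computation.

## Classifier verification

The penalized fit is verified two ways: against an independent ridge
solver (glmnet with λ = 1/(nC), unstandardized — the optima agree to six
decimals), and by parameter recovery on data simulated from a known model
(w = (−4, −8), b = 3, n = 5000). With the default penalty the weight
vector is recovered within ±15%; the intercept, though unpenalized,
absorbs part of the weight shrinkage through correlation and recovers
within ±25% under these conditions. This is the expected behaviour of the
penalized estimator, not an optimisation failure.

## Known limitations

* mmCIF parsing covers the `atom_site` category as exposed by bio3d; exotic
  categories (anisotropic ADPs, multi-datablock files) are ignored.
* The angular KDE is planar with mirror augmentation, not toroidal; density
  leaks of order 1–2% remain possible far from the mirrored margin.
* rASA is computed on the full deposited assembly as given in the file;
  whether a biological-assembly context would be more appropriate is left
  to the user preparing the input.
* The bundled classifier and references are synthetic-fixture-derived and
  are stand-ins for curated resources, suitable for testing the machinery
  and as format documentation, not for annotating real depositions.
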