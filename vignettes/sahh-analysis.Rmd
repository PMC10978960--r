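---
title: "Substrate-preference analysis of SAH/SIH hydrolases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substrate-preference analysis of SAH/SIH hydrolases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sahhtools)
```

## The biological problem

S-adenosyl-L-homocysteine (SAH) is the by-product of every
SAM-dependent methylation and a potent feedback inhibitor of
methyltransferases, so cells must remove it. The canonical route is the
NAD⁺-dependent hydrolase SAHH, which reversibly cleaves SAH into
adenosine and L-homocysteine. In parts of the Euryarchaeota and in some
thermophilic bacteria an alternative salvage route exists: a deaminase
(DadD) first converts SAH to S-inosyl-L-homocysteine (SIH, hypoxanthine
in place of adenine), and the hydrolase then cleaves SIH into inosine
and homocysteine. Bacteria may instead degrade SAH in two steps via
MTAN/LuxS. Which route an organism uses is reflected in its hydrolase:
some family members prefer SAH, others prefer SIH, and the preference
is legible from the sequence.

`sahhtools` implements the analyses by which that preference is
assigned:

* **Sequence**: extraction and classification of the five-residue
  nucleobase-binding *fingerprint motif*, detection of a 40-residue
  catalytic-domain segment and of C-terminal shortening, and local
  homolog scans for DadD/MTAN feeding a pathway-route call.
* **Structure**: molecular-gate state (His-IN/His-OUT) with rotamer
  and peptide-plane-flip analysis, ligand hydrogen-bond enumeration,
  nucleobase tautomer inference, monovalent-cation detection, Kabsch
  superposition/RMSD and interdomain open/closed rotation angles.
* **Assay**: semi-quantitative conversion scoring of HPLC peak tables,
  per-enzyme preference calls and concordance with the motif rule.
* **Synthetic data**: generators for toy active sites, motif-planted
  sequences and noisy peak tables, so every stage is testable without
  any download.

## The fingerprint-motif rule

The motif spans five residues in the substrate-binding domain,
H-x-[E/T]-x-[K/E/Q], anchored on a catalytic His. Position 3 hydrogen
bonds the nucleobase N1; position 5 can contact the C6 substituent.
The classification rule acts on the anchors 1/3/5 only (the "x"
positions never contribute):

| anchors | class | predicted preference |
|---------|-------|----------------------|
| H.E.K   | HxExK | SIH-preferring |
| H.T.E   | HxTxE | SAH-preferring |
| H.T.Q   | HxTxQ | SAH-preferring |
| H.E.other | HxExX | unknown |
| anything else | other | unknown |
| anchor unaligned | undetermined | unknown |

A non-His anchor 1 always forces `unknown`: that His is required for
catalysis, so no preference statement is meaningful without it.

Motif positions are located by global alignment (BLOSUM62, affine gap
cost 11 open / 1 per residue — the standard protein setting) of the
query against an annotated reference, then reading the query columns
aligned to the reference motif span. Alignment is delegated to
`Biostrings::pairwiseAlignment`; its traceback is deterministic, so
identical inputs give identical motifs. The unit tests cross-check the
scores against an independent exhaustive-recursion oracle on short
sequences.

## Packaged reference data are synthetic stand-ins

The package ships reference sequences and an 18-enzyme study set as
**synthetic scaffolds**: deterministic pseudo-random backgrounds with
the family's landmark residues planted at their literature positions
(archaeal reference numbering: motif 55–59, catalytic Asp128, gate
His298/Phe299, His-OUT partner Glu302, C6-contact Asp348; the
crenarchaeal scaffold carries Thr53 via a 4-residue N-terminal
deletion, the Methanococcus-type scaffold Lys74 via a 15-residue
insertion). Real database sequences are not redistributed. Consequences
to keep in mind:

* Landmark mapping across these scaffolds is exact by construction;
  tests on them validate the *pipeline* (alignment transfer, motif
  extraction, classification), not the content of any database entry.
* The study-set motif groups (six HxExK members among the
  euryarchaeal/archaeal-type enzymes, HxTxE in Crenarchaeota, HxTxQ in
  bacteria/eukaryotes) were planted according to the published group
  membership; the packaged conversion symbols are the published assay
  categories, used as a fixed truth table.
* To analyse real enzymes, pass their FASTA to
  `annotate_sequences()`; the alignment-based extraction is exactly the
  same code path.

## Structure analyses

**Gate state.** The conserved His/Phe pair gates the substrate channel.
`d_gate` is the *minimum heavy-atom distance* between the His imidazole
ring atoms (CG, ND1, CD2, CE1, NE2) and the catalytic Asp carboxylate
oxygens; a ring-centroid–to–carboxylate-centroid distance is reported
alongside because printed literature distances do not always state
their convention. The call is

* `IN` when `d_gate <= 6.0` Å,
* `OUT` when `d_gate >= 8.0` Å **and** the His ring contacts the
  partner Glu carboxylate within the hydrogen-bond cutoff,
* `undetermined` otherwise (including missing side-chain atoms, with
  the reason recorded).

The 6/8 Å thresholds sit symmetrically between the family's His-IN
(~4.2 Å) and His-OUT (~10.4 Å) exemplars, leaving a deliberate
undetermined band rather than forcing borderline geometries; both are
configurable. Side-chain dihedrals χ1 (N-CA-CB-CG) and χ2
(CA-CB-CG-ND1) are binned coarsely at −60/+60/180° (`m`/`p`/`t`) to
express rotamer differences between His-IN states.

**Hydrogen bonds.** Donor–acceptor assignment needs hydrogens, which
2.0–2.6 Å crystal structures do not resolve, so the criterion is a pure
N/O/S heavy-atom distance cutoff (default 3.5 Å) with no angle term.
Water partners are excluded by default. Atom-name prime dialects
(O5'/O5*) are normalised. Enumeration equals a brute-force all-pairs
scan (tested), and results are monotone in the cutoff.

**Tautomer.** Hypoxanthine ligands (inosine/SIH) are called
*imino-hydroxy* when their O6 contacts at least one main-chain carbonyl
oxygen within the cutoff — an O···O=C contact only a protonated
(hydroxy) O6 can donate — and otherwise default to *amino-oxo*, the
dominant form in water. Adenine ligands are reported in the amino form,
with N6 main-chain contacts as supporting evidence.

**Superposition.** `superpose_kabsch()` is an SVD-based least-squares
rigid superposition with reflections excluded (determinant sign
correction); the test suite checks it against an independent
quaternion (Horn) formulation to 1e-6 Å on 100 seeded instances, plus
rigid-motion invariance. Chain pairing for asymmetric-unit RMSD goes
through sequence alignment, not author numbering, and uses Cα atoms
only.

**Interdomain rotation.** Ligand binding closes the enzyme by rotating
the substrate-binding domain ~18° against the cofactor-binding domain.
The angle is computed by superposing model B on model A over
cofactor-domain Cα, then reducing the residual Kabsch rotation of the
substrate domain to its axis–angle magnitude. The open/closed call
compares that angle with anchor values (0° = same state as the
reference model, 18° = the opposite state) inside a ±6° window;
everything else is undetermined. Domain boundaries are not universal
constants: the packaged intervals are implementer defaults recorded in
`reference_annotations.tsv` and fully configurable.

**Peptide flip.** Gate opening proceeds via a ~180° flip of the
His–Phe peptide plane. After superposing the local backbone (Cα of
His−2..Phe+2), the angle between the peptide-plane normals (plane
through Cα/C/O of the His and N of the Phe) is reported; a flip is
called at ≥120°, far above thermal librations and safely below the
ideal 180°.

**Cations.** Some mesophilic family members coordinate Na⁺/K⁺ at the
hinge element; thermostable archaeal ones do not. `detect_cation()`
reports Na/K het atoms within 6 Å (default) of the hinge residues with
their coordinating protein N/O atoms; an empty report *is* the absence
call.

**Altloc policy.** For each (chain, residue, atom name) the
highest-occupancy alternate conformer is kept, ties resolved towards
altloc "A".

## Assay scoring

Conversion is computed from response-corrected peak areas as converted
fraction of the substrate pool, with the free nucleobase side product
counting as converted substrate:

conversion % = 100 · (products + side products) / (substrate + products + side products).

Homocysteine-derived species are excluded from the denominator: they
are not UV-comparable with the nucleoside species at the detection
wavelength, and the published scoring is explicitly semi-quantitative.
Default response factors are 1 (equal molar absorptivity); per-analyte
factors can be supplied.

Categories follow the published thresholds: `+++` above 70 %, `++` for
30–70 %, `+` below 30 %, `-` below a noise floor. Because the printed
bounds are strict (">70 %", "<30 %"), the middle band is closed on both
ends: exactly 30 % and exactly 70 % are `++`. "No conversion" means
below a configurable 1 % noise floor, not exactly zero —
chromatographic baselines never are.

Per-enzyme preference compares the four category symbols (SAH/SIH ×
cleavage/synthesis) ordinally; a substrate strictly better in one
direction and not worse in the other is preferred, upgraded to
`SAH-only`/`SIH-only` when the other substrate shows no conversion at
all, with `inactive` and `both/no-preference` covering the rest.
Concordance counts an SIH-preferring motif prediction as confirmed by
an SIH-preferring assay call and an SAH-preferring prediction by an
SAH-preferring or SAH-only call; SAH-motif enzymes with measurable SIH
turnover keep an explanatory note, since the motif does not explain
residual SIH activity.

## Synthetic-data generators

`make_toy_site()` builds minimal active sites from idealised residue
geometry (standard bond lengths/angles placed by internal-coordinate
chaining). The controlled quantities — gate distance, His-OUT contact,
ND1–O5' distance, nucleobase C6 contact, cation distance — are exact by
construction and re-verified to 1e-6 Å before writing (PDB output then
rounds to 0.001 Å). Defaults reproduce the family's printed exemplar
geometries (His-IN 4.2 Å with a 2.7 Å Nδ1–O5' contact; His-OUT 10.4 Å
with a 2.7 Å Glu hydrogen bond). Chains can be duplicated under a
random rigid motion with optional isotropic Cα noise, giving ground
truth for chain-RMSD statistics (expected residual σ√3 for noise sd σ
per coordinate). Realism is limited to what the geometric classifiers
consume: no realistic folds, B-factors or density are simulated, so
passing tests demonstrate correctness of the measurements, not
robustness to disorder, alternate conformations beyond the altloc
policy, or model errors in real depositions.

`make_motif_sequences()` plants motif anchors on reference-derived or
random scaffolds with optional off-anchor substitutions, 40-residue
segment deletion and C-terminal truncation; `make_peak_table()` builds
peak tables whose noise-free score equals the requested conversion
exactly, with multiplicative per-peak noise. All generators are
deterministic under their seed and write ground-truth JSON sidecars.

## Numerical and design choices

* Distances in Å, residue indices 1-based, intervals closed.
* Gap model: a gap of length L costs open + L·extend (the convention of
  the alignment backend and of the test oracle alike).
* `segment40_present` requires ≥50 % non-gap query columns inside the
  annotated segment — robust to local misalignment at the segment
  edges.
* `thermophile_flag = (cterm_delta <= -15)` relative to the packaged
  long-C-terminus reference; a reported heuristic only, never used in
  preference prediction.
* Homolog presence: best local hit with ≥30 % identity and ≥70 %
  reference coverage — a conventional homology floor; no E-value
  statistics are computed.
* Chain-to-reference mapping requires ≥30 % alignment identity;
  landmark residues with unexpected amino acids warn rather than fail,
  so near-homolog structures can still be inspected.
* Degenerate superposition inputs (<3 points, collinear sets) are
  errors, not silent results.

## Problem sizes in the tests and acceptance script

The shipped checks run at desk scale: 100 six-point clouds for the
superposition oracle, 20 seeds × 5 gate distances (two chains each) for
gate recovery, 50 seeded trials per noise level for motif recovery, 200
noisy peak tables at σ = 2 %, seven constructed rotations in 2–40°, and
20 dimers for the noise/RMSD relation. These sizes give binomial/sampling
resolution well below the asserted margins while keeping the whole
suite in the low minutes.

`tests/testthat/test-acceptance.R` additionally contains reproduction
checks against deposited crystal structures (accessions fetched from
the RCSB file server at run time, with landmark annotation derived from
each chain's own sequence at the published author numbering). These
require network access and fail with a download error in offline
environments; all desk-scale checks are network-free.

## Known limitations

* The packaged reference and study sequences are synthetic stand-ins;
  conclusions about real database entries require supplying the real
  sequences.
* Hydrogen-bond detection has no angular term and treats every N/O/S
  pair as a candidate donor/acceptor.
* Tautomer inference rests on a single contact class (C6 substituent
  vs main-chain carbonyl) and reports evidence, not certainty.
* The open/closed call depends on configurable domain intervals; for
  renumbered or heavily gapped structures the interdomain angle is
  only as good as the interval mapping.
* No crystallographic validation (density fit, B-factors, Ramachandran)
  is performed or implied.
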