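# sahhtools

Substrate-preference annotation for the S-adenosyl-L-homocysteine
hydrolase (SAHH/SIHH) enzyme family, from sequence, structure and assay
data.

SAH, the by-product of every SAM-dependent methylation, is degraded
either directly by SAHH (SAH ⇌ adenosine + L-homocysteine) or — in a
subgroup of Euryarchaeota and related thermophilic bacteria — after
deamination by DadD to S-inosyl-L-homocysteine (SIH), which the
hydrolase then cleaves into inosine and homocysteine. Which route an
organism uses shows up in its hydrolase, and `sahhtools` implements the
analyses that read it out:

* **Fingerprint motif.** The five-residue nucleobase-binding signature
  H-x-[E/T]-x-[K/E/Q] is extracted by reference-anchored global
  alignment (BLOSUM62, affine gaps 11/1) and classified on its anchor
  positions 1/3/5: `HxExK` → SIH-preferring, `HxTxE`/`HxTxQ` →
  SAH-preferring, anything else (or a missing catalytic His) →
  unknown. Architecture features (a 40-residue catalytic-domain
  segment, C-terminal shortening, a thermophily heuristic) are read
  from the same alignments, and Smith–Waterman scans for DadD/MTAN
  homologues feed a deterministic SAH-degradation route call.
* **Active-site geometry.** From PDB/mmCIF coordinates: molecular-gate
  state per chain — His-IN when the gate-His imidazole sits within
  6 Å (minimum heavy-atom distance) of the catalytic Asp carboxylate,
  His-OUT when it swings ≥8 Å away and hydrogen-bonds the partner Glu —
  with χ1/χ2 rotamers and peptide-plane flip angles; ligand–protein
  hydrogen-bond enumeration (N/O/S, 3.5 Å, no angle term); nucleobase
  tautomer inference (imino-hydroxy vs amino-oxo from O6 main-chain
  carbonyl contacts); hinge cation detection; SVD Kabsch superposition
  with Cα asymmetric-unit RMSD; and the ~18° open/closed interdomain
  rotation angle.
* **Assay scoring.** HPLC peak tables → conversion percentages
  (response-corrected converted fraction of the substrate pool, the
  nucleobase side product counting as converted) → the published
  semi-quantitative categories (`+++` >70 %, `++` 30–70 %, `+` <30 %,
  `-` below the noise floor) → per-enzyme preference calls and
  concordance with the motif predictions.
* **Synthetic fixtures.** Generators for toy active sites with exact
  controlled geometry, motif-planted sequences and noisy peak tables,
  with ground-truth sidecars — the whole pipeline is testable offline.

The packaged reference and 18-enzyme study sequence sets are clearly
labelled **synthetic stand-ins**: pseudo-random scaffolds carrying the
family's landmark residues at their literature positions (see the
vignette `vignettes/sahh-analysis.Rmd`).

## Worked example

```r
library(sahhtools)

## sequence annotation of the packaged (synthetic) study set
study <- load_study_set()
rep <- annotate_sequences(study$sequences)
head(rep[, c("id", "motif", "motif_class", "predicted",
             "segment40_present", "cterm_delta")], 8)
#>       id motif motif_class      predicted segment40_present cterm_delta
#>  SacSAHH HSTVE       HxTxE SAH-preferring             FALSE         -25
#>  SsoSAHH HSTVE       HxTxE SAH-preferring             FALSE         -25
#>   McSAHH HSTVE       HxTxE SAH-preferring             FALSE         -25
#>   MeSAHH HSTVE       HxTxE SAH-preferring              TRUE           0
#>   MhSAHH HSTVE       HxTxE SAH-preferring              TRUE           0
#>   MiSAHH HSEVK       HxExK SIH-preferring             FALSE         -25
#>   MjSIHH HSEVK       HxExK SIH-preferring             FALSE         -25
#>  MmaSAHH HSEVK       HxExK SIH-preferring             FALSE         -25
```

Six of the eighteen enzymes carry the `HxExK` motif and are predicted
SIH-preferring; the crenarchaeal members class as `HxTxE`; archaeal
scaffolds lack the 40-residue segment and run 25 residues short at the
C-terminus (the thermophily heuristic).

```r
## gate-state calls on toy sites built at the family's exemplar
## geometries (His-IN 4.2 A; His-OUT 10.4 A with a 2.7 A Glu contact)
make_toy_site("site_in.pdb", d_gate = 4.2, ligand = "inosine",
              d_o5prime = 2.7, nucleobase_contact = TRUE)
make_toy_site("site_out.pdb", d_gate = 10.4, out_partner = TRUE)
annotate_structures(c("site_in.pdb", "site_out.pdb"),
                    ref = toy_site_annotation())
#>  structure_id gate_state d_gate d_out_partner d_his_o5prime rotamer      tautomer
#>       site_in         IN    4.2          20.0         2.699      mm imino_hydroxy
#>      site_out        OUT   10.4           2.7            NA      mm          <NA>

## assay preference from the four conversion categories of one enzyme
call_assay_preference(data.frame(
  enzyme_id = "PfuSAHH",
  substrate = c("SAH", "SAH", "SIH", "SIH"),
  direction = rep(c("cleavage", "synthesis"), 2),
  category = c("+", "++", "++", "+++")))
#> <preference_call_assay> PfuSAHH: SIH-preferring  [SAH +/++, SIH ++/+++]

## route inference: DadD plus an SIH-preferring hydrolase
infer_pathway("SIH-preferring", dadd_present = TRUE, mtan_present = FALSE)
#> <pathway_call> {SAHH_direct, deamination_SIH}
#>   note: SIH-preferring hydrolase retains SAH activity (dual function)
```

A thin command-line wrapper ships at
`inst/scripts/sahh_tools.R` (subcommands `annotate-seq`,
`annotate-structure`, `score-assay`, `make-fixtures`; exit codes 0 ok /
1 usage / 2 parse / 4 internal).

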