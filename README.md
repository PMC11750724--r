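# neovax

Design and immune monitoring of individualized mRNA neoantigen vaccines,
from somatic variant calls to concatamer construct sequences and from assay
tables to per-patient response reports.

Tumors carry private somatic mutations; a small fraction yield neoantigens
— mutant peptides presented on HLA that T cells can recognize. An
individualized neoantigen-specific immunotherapy (iNeST) encodes up to 20
such targets per patient on up to two messenger RNAs. `neovax` implements
the computational pipeline of such a program and the analytics of its
immune-monitoring assays, and ships a deterministic synthetic-cohort
generator so every stage runs and tests itself with no external data or
predictors.

## What the package computes

**Design** (`design_patient()`, `run_design()`):

* **Mutated peptide sequences (MPS).** For an amino acid substitution, the
  window of 13 residues N- and C-terminal of the changed residue(s)
  (truncated at protein ends: an interior SNV gives a 27-mer). For
  frameshift indels, the novel reading frame from the first changed residue
  to the next stop codon. Protein-changing germline variants in the window
  are incorporated when RNA phase evidence puts them in cis with the
  somatic mutation. Non-expressed, synonymous and nonsense records are
  filtered with recorded reasons.
* **Binding annotation.** All mutation-containing 8–11-mers × class I
  alleles (15-mers × DRB for class II) scored through a pluggable
  percentile-rank predictor interface; each variant keeps its best
  (minimum) rank. The bundled predictor is a deterministic keyed hash — no
  external tool is ever required.
* **Prioritization to ≤ 46 MPS** in tiers, RNA-expressed variants first:
  ≤ 5 indels by class I rank, ≤ 20 SNVs at ≥ 10 RPKM by rank, ≤ 20 SNVs at
  ≥ 1 RPKM by rank, further SNVs by expression to reach 46, then RNA-silent
  backfill.
* **Selection and assembly.** ≤ 20 targets by a composite score over
  class I/II binding, expression and DNA VAF (patients need ≥ 5 identified
  neoantigens to be eligible), split across ≤ 2 constructs of ≤ 10 targets,
  each assembled as `SEC + target1 + linker + ... + targetN + MITD` with
  30-nt Gly/Ser linkers and a deterministic reverse translation that
  round-trips through the standard genetic code.

**Monitoring** (`run_monitoring()`):

* **ELISpot response calling**: exact label-permutation positivity plus a
  minimum spot delta; de novo / amplified (≥ 2-fold) / preexisting-only
  classification against baseline; patient responder summaries and CD4/CD8
  phenotypes; overlapping 15-mer peptide pools with 11-residue overlap.
* **Multimer candidates**: peptide–HLA pairs with percentile rank < 5,
  top three by rank.
* **TCR tracking**: Jurkat reporter validation at a 2-fold luminescence
  cutoff; exact CDR3β matching in blood and tumor bulk repertoires;
  cumulative frequencies with per-neoantigen breakdowns; de novo vs
  preexisting status against baseline; biopsy overlap.

## Worked example

```r
library(neovax)

cohort <- generate_cohort(cohort_config(n_patients = 4, seed = 11))
patient <- cohort[[3]]
patient
#> <neovax_patient> P003
#>   proteome: 30 transcripts
#>   HLA: HLA-A*02:01, HLA-A*11:01, HLA-B*07:02, HLA-B*44:02, ... | HLA-DRB1*01:01, HLA-DRB1*04:01
#>   somatic variants: 51 (5 indels)
#>   immunogenic truth labels: 16

report <- design_patient(patient)
report$n_candidates          # 31 identified neoantigen candidates (20 dropped with reasons)
table(report$prioritized$tier)
#>     EXPR_FILL         INDEL   SNV_HI_EXPR   SNV_LO_EXPR VAF0_BACKFILL
#>             4             3             6            14             4
nrow(report$selected)        # 20 targets
report$constructs$RNA1
#> <neovax_construct> RNA1: 10 targets, 438 aa / 1314 nt

assays <- generate_assay_data(patient, report$selected$variant_id, seed = 11)
mon <- run_monitoring(report, assays$elispot, assays$repertoire, assays$jurkat)
mon$responder                # TRUE
mon$n_targets_positive       # 8 neoantigens with de novo or amplified responses
nrow(mon$specific_tcrs)      # 18 Jurkat-validated specific TCRs
mon$tracking$blood$cumulative   # 0.071 of circulating CD8 reads
mon$tracking$tumor$cumulative   # 0.0105 of tumor CD8 clonotype reads
sum(mon$tracking$baseline_status$status == "de_novo")  # 11 of 18 undetectable at baseline
```

The design report records every variant's fate (dropped reason, tier,
construct), the configuration hash and the seed, so reruns are
byte-identical. `write_patient_bundle()` / `run_design()` provide the same
flow through FASTA/VCF/TSV files on disk.

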