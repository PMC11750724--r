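---
title: "Designing and monitoring individualized neoantigen vaccines with neovax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and monitoring individualized neoantigen vaccines with neovax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neovax)
```

## The problem

Individualized neoantigen-specific immunotherapy (iNeST) encodes a
patient-specific set of tumor mutations on messenger RNA so that dendritic
cells present the mutant peptides and prime T cell responses. neovax
implements the computational backbone of such a program: it turns somatic
variant calls into mutated peptide sequences (MPS), prioritizes them with
HLA-binding and expression evidence, selects up to 20 targets, assembles
them into up to two concatamer mRNA constructs, and then analyzes the
downstream immune-monitoring assays — IFN-gamma ELISpot, peptide–HLA
multimer candidate selection, and bulk TCR-beta repertoire tracking.

Because patient-level clinical data of this kind are not redistributable,
the package ships
a first-class synthetic-cohort generator that emulates every input the
pipeline consumes. All tests and all reported numbers in this vignette are
computed on synthetic data.

## From variants to mutated peptide sequences

For an amino acid substitution the MPS is the window of 13 residues on each
side of the changed residue(s), truncated at the protein ends — so an
interior SNV yields a 27-mer with the mutation at position 14, and an
N-terminal substitution yields a 14-mer. For frameshift indels the MPS is
the novel reading frame from the first changed residue up to (and
excluding) the next stop codon, prefixed by up to 13 wild-type residues.
Both paths are implemented by applying the nucleotide edit to the coding
sequence, translating, and diffing against the wild-type protein; in-frame
indels fall out of the same diff as a 13 + altered-region + 13 window.
Degenerate frameshifts whose first novel codon is already a stop carry no
novel peptide and are dropped with reason `"null neo-ORF"`; frameshifts
with no downstream stop are truncated at the CDS end and flagged
`read_through`.

Protein-changing germline variants inside the window are incorporated when
their RNA phase evidence places them in cis with the somatic mutation.
RNA-read phasing has no standardized thresholds, so both are package
parameters: `min_phase_reads = 2` cis reads and `phase_fraction = 0.8` cis
fraction. The generator emits integer
cis/trans read counts rather than raw reads because the package starts
downstream of alignment.

Candidates on non-expressed transcripts and synonymous/nonsense records are
filtered with machine-readable reasons. The expression floor
(`expressed_min = 0.001` RPKM) means "RPKM is effectively zero"; it must
stay below the 1-RPKM prioritization threshold so that low-expression
candidates remain visible to the expression-fill and VAF-zero backfill
tiers. Start-loss and stop-loss variants are excluded with explicit
reasons; they produce no well-defined peptide window.

## Binding scores

Candidate epitopes are all 8–11-mers overlapping the mutated span crossed
with the patient's HLA class I alleles, and 15-mers against the DRB alleles
for class II. Scoring goes through a pluggable predictor interface whose
bundled implementation maps each (peptide, allele) pair deterministically
to a percentile rank in [0, 100) via a keyed hash — lower is stronger,
matching the percentile-rank convention of the common prediction servers.
Nothing in the package requires an external predictor; adapters to real
tools can implement the same interface. The "best consensus score" of a
variant is realized as the minimum percentile rank over all of its scored
candidates, following the percentile-rank convention in which lower means
stronger predicted binding.

## Prioritization and selection

Prioritization reduces annotated candidates to at most 46 MPS in a fixed
tier order, considering RNA-expressed variants (RNA VAF > 0) first:
up to 5 indel MPS by class I rank, up to 20 SNVs with RPKM >= 10 by class I
rank, up to 20 SNVs with RPKM >= 1 by class I rank, then remaining SNVs by
expression until 46; if the list is still short, RNA-silent candidates are
backfilled by class I rank and expression. Three decisions were genuinely
open:

* the expression thresholds are nested, so a strong >= 10 RPKM SNV that
  misses the HI tier on rank competes in the >= 1 RPKM tier rather than
  dropping out;
* ties break deterministically on (class I rank ascending, RPKM descending,
  variant id lexicographic);
* the backfill tier admits both SNV and indel candidates — any
  RNA-silent somatic mutation may rescue a short list — while the
  expression-fill tier is restricted to SNVs.

Final selection takes at most 20 targets by a composite score — a weighted
sum of normalized (100 − class I rank)/100, (100 − class II rank)/100,
log10(1 + RPKM) scaled to the input maximum, and DNA VAF, with default
weights 0.4/0.2/0.25/0.15. In practice this step combines an algorithmic
ranking with human review and no canonical weighting exists, so the weights
are a package decision, config-exposed and recorded in every design
report.
Patients need at least 5 identified neoantigens to be eligible.

## Construct assembly

Selected targets are split across up to two constructs of at most 10
targets each (alternating assignment in selection order, giving
ceiling/floor group sizes). Each construct fuses a 26-residue secretory
signal peptide (SEC), the targets joined by 30-nt glycine/serine linkers
encoding `GGSGGSGGSG`, and the 55-residue MHC class I trafficking domain
(MITD). Linkers sit between consecutive targets only; SEC and MITD are
direct-fused — the linkers exist to insulate neighboring targets from one
another, not to space the trafficking elements. Reverse translation uses
one fixed codon
per amino acid with no optimization — determinism and a guaranteed
translation round trip matter more here than codon usage, which is a
manufacturing concern out of scope. The 3' UTR vector element is recorded
verbatim as opaque metadata and deliberately not interpreted.

## ELISpot response calling

No standard positivity statistic exists for this assay, so the caller is a
package design: a well set is positive when an exact label-permutation test
of stimulated versus control replicates rejects at `alpha = 0.05` *and* the
mean spot-count difference is at least `min_spot_delta = 5`. The p-value
counts relabelings whose statistic strictly exceeds the observed one. With
duplicate wells the strict count is the only reading under which a clean
separation like {60, 55} vs {3, 5} can reject at 0.05 (the inclusive count
never falls below 1/6); on its own that reading is anti-conservative, which
is exactly what the delta floor compensates for. The acceptance suite
verifies the combined caller's false-positive responder rate stays within
alpha on 500 null synthetic patients.

A response is de novo if the baseline wells were negative and the
post-treatment wells positive; amplified if both were positive and the net
spot count rose at least twofold; a positive baseline without a twofold
rise is preexisting-only. The fold denominator is floored at 1 spot to
avoid division by near-zero baselines, and de novo calls bypass the fold
entirely. A patient is a responder when at least one encoded neoantigen is
de novo or amplified; per-target CD4/CD8 phenotypes come from the
post-IVS compartment calls.

Overlapping peptide pools tile each MPS with 15-mers stepping by 4 residues
(11-residue overlap); the final peptide is anchored to the sequence end
rather than synthesized short, so full coverage always holds and the last
overlap may exceed 11.

## Multimer candidates and TCR tracking

For multimer staining the package filters all scored class I pairs to
percentile rank < 5 and takes the top three by ascending rank with a
lexicographic tie-break. TCR candidates validate in the Jurkat reporter
when luminescence reaches twice the effectors-only control. Validated TCRs
are tracked in bulk repertoires by exact CDR3-beta amino acid match, with
V/J gene constraints applied only when both sides carry calls; frequencies
are computed within compartment (sorted blood CD8 vs tumor-infiltrating
clonotypes), and both blood and tumor cumulative frequencies are reported
with per-neoantigen breakdowns. "Undetectable at baseline" defaults to 0
reads, config-exposed because detection depends on sequencing depth.

## What the synthetic cohort emulates — and what it does not

The generator reproduces the *statistical shape* of the pipeline's inputs:
Poisson variant counts (default 40 SNVs + 4 indels expected per patient,
with a 20% low-burden subgroup at 5% of those rates so the 5-neoantigen
eligibility boundary is exercised), SNVs as literal single-nucleotide CDS
edits so synonymous/nonsense/missense consequences arise from the genetic
code at their natural rates, beta(2,3) allele fractions with a 15%
RNA-silent fraction, log-normal(1.5, 1.5) RPKM with a 10% non-expressed
atom, and germline variants with cis/trans phase read counts. Truth labels
plant a 71% responder fraction; within responders roughly half the
candidates are immunogenic with CD4/CD8 phenotypes at 59/26/15% and a 29%
preexisting fraction, mirroring the proportions reported for this class of
therapy. Planted repertoire quantities default to a 7.3% cumulative blood
frequency for specific clonotypes, a 1% tumor frequency, and an 84%
blood-to-tumor trafficking fraction at 50,000 reads per sample. The
per-patient variant-count distributions are free parameters — no public
per-patient table exists to calibrate them.

The generator does *not* emulate mutational signatures, read-level errors,
HLA haplotype frequencies, isoform structure, or assay plate effects.
Passing tests therefore demonstrate that the pipeline's logic is correct
and that planted truths are recovered under the stated noise models — not
that any particular clinical response rate would be reproduced on real
patients.

With `noise = 0` the assay generator emits deterministic expectations, and
the package recovers planted truth exactly: the acceptance suite checks
responder sets, de novo clonotype status and planted frequencies at zero
noise, and distributional recovery (binomial sampling error at the stated
read depth) at `noise = 1`.

## Numerical and reproducibility choices

All randomness derives from one integer seed; every patient and every
assay bundle uses a named substream (a keyed hash of the seed and the
label), so cohorts are byte-identical across runs and insensitive to
generation order. The bundled predictor is a pure function of (peptide,
allele, key). Problem sizes in the shipped tests — cohorts of 8–60
patients for module tests, 200 patients for the end-to-end run, 500 null
patients for the caller calibration, 1,000 random instances for the
prioritization property — were chosen so the whole suite completes in a
few minutes on a single core while keeping every boundary (tier caps,
eligibility, rank cutoff) saturated.

## Known limitations

* One canonical transcript per gene; isoform-aware windows are out of
  scope.
* The bundled predictor's ranks are uniform by construction and carry no
  biology; it exists to make the pipeline deterministic and testable, and
  real predictors plug in behind the same interface.
* The composite selection score stands in for what is, in a clinical
  program, an algorithm-plus-review-board process; its weights are a
  package choice.
* Clonotype identity is the CDR3-beta amino acid string (plus V/J when
  present); nucleotide-level clonotypes and single-cell V(D)J assembly are
  consumed, not produced.
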