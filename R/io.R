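# Patient bundle I/O: proteome/CDS FASTA, minimal somatic + germline VCF 4.2
# (one contig per transcript CDS, 1-based), expression TSV, HLA TSV.
# FASTA through Biostrings; VCF written as minimal v4.2 text and read back
# with vcfR.

#' Write a synthetic patient bundle to disk
#'
#' Emits `proteome.fasta`, `cds.fasta`, `somatic.vcf`, `germline.vcf`,
#' `expression.tsv`, `hla.tsv` and a `truth.tsv` sidecar (simulation truth,
#' not a pipeline input) into `dir`. Output is byte-deterministic for a
#' given patient object.
#'
#' @param patient A `neovax_patient`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_patient_bundle <- function(patient, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aa <- Biostrings::AAStringSet(patient$proteome)
  Biostrings::writeXStringSet(aa, file.path(dir, "proteome.fasta"))
  nt <- Biostrings::DNAStringSet(patient$cds)
  Biostrings::writeXStringSet(nt, file.path(dir, "cds.fasta"))
  write_somatic_vcf(patient$somatic_variants, patient$cds,
                    file.path(dir, "somatic.vcf"))
  write_germline_vcf(patient$germline_variants, patient$cds,
                     file.path(dir, "germline.vcf"))
  readr::write_tsv(patient$expression, file.path(dir, "expression.tsv"))
  hla <- tibble::tibble(
    class = c(rep("I", length(patient$hla_class1)),
              rep("DRB", length(patient$hla_drb))),
    allele = c(patient$hla_class1, patient$hla_drb)
  )
  readr::write_tsv(hla, file.path(dir, "hla.tsv"))
  readr::write_tsv(patient$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

vcf_header <- function(cds, info_lines) {
  c("##fileformat=VCFv4.2",
    "##source=neovax-synthetic",
    sprintf("##contig=<ID=%s,length=%d>", names(cds), nchar(cds)),
    info_lines,
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

write_somatic_vcf <- function(somatic, cds, path) {
  info_lines <- c(
    '##INFO=<ID=VAF_DNA,Number=1,Type=Float,Description="Variant allele frequency in tumor DNA">',
    '##INFO=<ID=VAF_RNA,Number=1,Type=Float,Description="Variant allele frequency in tumor RNA">',
    '##INFO=<ID=TRANSCRIPT,Number=1,Type=String,Description="Host transcript">',
    '##INFO=<ID=PROT_POS,Number=1,Type=Integer,Description="1-based position of first changed residue">',
    '##INFO=<ID=KIND,Number=1,Type=String,Description="SNV, insertion or deletion">'
  )
  body <- if (nrow(somatic) == 0) character(0) else {
    info <- sprintf("VAF_DNA=%s;VAF_RNA=%s;TRANSCRIPT=%s;PROT_POS=%d;KIND=%s",
                    format(somatic$vaf_dna, trim = TRUE, scientific = FALSE),
                    format(somatic$vaf_rna, trim = TRUE, scientific = FALSE),
                    somatic$transcript_id, somatic$protein_position,
                    somatic$kind)
    sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
            somatic$transcript_id, somatic$cds_pos, somatic$id,
            somatic$ref_nt, somatic$alt_nt, info)
  }
  writeLines(c(vcf_header(cds, info_lines), body), path)
}

write_germline_vcf <- function(germline, cds, path) {
  info_lines <- c(
    '##INFO=<ID=TRANSCRIPT,Number=1,Type=String,Description="Host transcript">',
    '##INFO=<ID=PROT_POS,Number=1,Type=Integer,Description="1-based residue position">',
    '##INFO=<ID=REF_AA,Number=1,Type=String,Description="Reference residue">',
    '##INFO=<ID=ALT_AA,Number=1,Type=String,Description="Alternate residue">',
    '##INFO=<ID=SOMATIC_ID,Number=1,Type=String,Description="Nearby somatic variant the phase evidence refers to">',
    '##INFO=<ID=CIS_READS,Number=1,Type=Integer,Description="RNA reads supporting cis phase">',
    '##INFO=<ID=TRANS_READS,Number=1,Type=Integer,Description="RNA reads supporting trans phase">'
  )
  body <- if (nrow(germline) == 0) character(0) else {
    # Codon-level REF/ALT so protein-level edits stay faithful in VCF.
    ref_codon <- vapply(seq_len(nrow(germline)), function(i) {
      s <- cds[[germline$transcript_id[i]]]
      p <- germline$protein_position[i]
      substr(s, 3L * (p - 1L) + 1L, 3L * p)
    }, character(1))
    alt_codon <- ifelse(germline$is_protein_changing,
                        unname(.CODON_OF[germline$alt_aa]), ref_codon)
    info <- sprintf(
      "TRANSCRIPT=%s;PROT_POS=%d;REF_AA=%s;ALT_AA=%s;SOMATIC_ID=%s;CIS_READS=%d;TRANS_READS=%d",
      germline$transcript_id, germline$protein_position, germline$ref_aa,
      germline$alt_aa, germline$somatic_id, germline$cis_reads,
      germline$trans_reads)
    sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s",
            germline$transcript_id, 3L * (germline$protein_position - 1L) + 1L,
            germline$id, ref_codon, alt_codon, info)
  }
  writeLines(c(vcf_header(cds, info_lines), body), path)
}

#' Read a patient bundle back from disk
#'
#' Inverse of [write_patient_bundle()] for the pipeline-facing inputs
#' (the truth sidecar is read only when present).
#'
#' @param dir Bundle directory.
#' @param patient_id Patient identifier; defaults to the directory name.
#' @return A `neovax_patient`.
#' @export
read_patient_bundle <- function(dir, patient_id = basename(dir)) {
  need <- c("proteome.fasta", "cds.fasta", "somatic.vcf", "germline.vcf",
            "expression.tsv", "hla.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    abort(paste0("patient bundle ", dir, " is missing: ",
                 paste(missing, collapse = ", ")),
          class = "neovax_parse_error")
  }
  aa <- Biostrings::readAAStringSet(file.path(dir, "proteome.fasta"))
  proteome <- setNames(as.character(aa), names(aa))
  nt <- Biostrings::readDNAStringSet(file.path(dir, "cds.fasta"))
  cds <- setNames(as.character(nt), names(nt))
  expression <- readr::read_tsv(file.path(dir, "expression.tsv"),
                                show_col_types = FALSE)
  hla <- readr::read_tsv(file.path(dir, "hla.tsv"), show_col_types = FALSE)
  somatic <- read_somatic_vcf(file.path(dir, "somatic.vcf"))
  somatic <- dplyr::left_join(somatic, expression, by = "transcript_id")
  germline <- read_germline_vcf(file.path(dir, "germline.vcf"))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    readr::read_tsv(truth_path, show_col_types = FALSE)
  } else NULL
  structure(list(
    patient_id = patient_id,
    proteome = proteome,
    cds = cds,
    hla_class1 = hla$allele[hla$class == "I"],
    hla_drb = hla$allele[hla$class == "DRB"],
    somatic_variants = somatic,
    germline_variants = germline,
    expression = expression,
    truth = truth
  ), class = "neovax_patient")
}

read_vcf_fix <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) {
                  abort(paste0("failed to parse VCF ", path, ": ",
                               conditionMessage(e)),
                        class = "neovax_parse_error")
                })
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  fix$INFO <- vcfR::getINFO(v)
  fix
}

info_field <- function(info, key) {
  m <- stringr::str_match(info, paste0("(?:^|;)", key, "=([^;]*)"))[, 2]
  m
}

#' Read a somatic variant VCF
#'
#' Expects the minimal schema written by [write_patient_bundle()]: INFO keys
#' `VAF_DNA`, `VAF_RNA`, `TRANSCRIPT`, `PROT_POS`, `KIND`.
#'
#' @param path VCF path.
#' @return Tibble of somatic variants.
#' @export
read_somatic_vcf <- function(path) {
  fix <- read_vcf_fix(path)
  if (nrow(fix) == 0) {
    out <- empty_variant_tbl()
    out$id <- character(0)
    return(out[, c("id", "kind", "transcript_id", "cds_pos", "ref_nt",
                   "alt_nt", "protein_position", "ref_aa", "alt_aa",
                   "consequence", "vaf_dna", "vaf_rna")])
  }
  kind <- info_field(fix$INFO, "KIND")
  tibble::tibble(
    id = fix$ID,
    kind = kind,
    transcript_id = info_field(fix$INFO, "TRANSCRIPT"),
    cds_pos = as.integer(fix$POS),
    ref_nt = fix$REF,
    alt_nt = fix$ALT,
    protein_position = as.integer(info_field(fix$INFO, "PROT_POS")),
    vaf_dna = as.numeric(info_field(fix$INFO, "VAF_DNA")),
    vaf_rna = as.numeric(info_field(fix$INFO, "VAF_RNA"))
  )
}

#' Read a germline variant VCF with phase evidence
#'
#' @param path VCF path.
#' @return Tibble of germline variants with cis/trans phase read counts.
#' @export
read_germline_vcf <- function(path) {
  fix <- read_vcf_fix(path)
  if (nrow(fix) == 0) {
    return(tibble::tibble(
      id = character(0), transcript_id = character(0),
      protein_position = integer(0), ref_aa = character(0),
      alt_aa = character(0), is_protein_changing = logical(0),
      somatic_id = character(0), cis_reads = integer(0),
      trans_reads = integer(0)))
  }
  ref_aa <- info_field(fix$INFO, "REF_AA")
  alt_aa <- info_field(fix$INFO, "ALT_AA")
  tibble::tibble(
    id = fix$ID,
    transcript_id = info_field(fix$INFO, "TRANSCRIPT"),
    protein_position = as.integer(info_field(fix$INFO, "PROT_POS")),
    ref_aa = ref_aa,
    alt_aa = alt_aa,
    is_protein_changing = ref_aa != alt_aa,
    somatic_id = info_field(fix$INFO, "SOMATIC_ID"),
    cis_reads = as.integer(info_field(fix$INFO, "CIS_READS")),
    trans_reads = as.integer(info_field(fix$INFO, "TRANS_READS"))
  )
}

#' Write a whole cohort of patient bundles
#'
#' @param cohort List of patients from [generate_cohort()].
#' @param dir Root directory; one subdirectory per patient id.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  for (p in cohort) write_patient_bundle(p, file.path(dir, p$patient_id))
  invisible(dir)
}
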