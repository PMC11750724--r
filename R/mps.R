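# Mutated peptide sequence (MPS) extraction: 13+13 windows around amino acid
# substitutions, novel reading frame to the next stop for frameshifts,
# germline phasing, and candidate filtering. Protein coordinates are 1-based
# inclusive throughout; MPS spans are 1-based within the MPS itself.

mps_record <- function(variant, sequence, span_start, span_end, source_kind,
                       flag = "") {
  tibble::tibble(
    variant_id = variant$id,
    transcript_id = variant$transcript_id,
    protein_position = variant$protein_position,
    kind = variant$kind,
    consequence = variant$consequence,
    source_kind = source_kind,
    sequence = sequence,
    span_start = span_start,
    span_end = span_end,
    incorporated_germline = "",
    flag = flag,
    rpkm = variant$rpkm %||% NA_real_,
    vaf_dna = variant$vaf_dna,
    vaf_rna = variant$vaf_rna,
    best_class1_rank = NA_real_,
    best_class2_rank = NA_real_
  )
}

#' Extract the mutated peptide sequence for an amino acid substitution
#'
#' Returns the window of 13 residues N-terminal and 13 residues C-terminal
#' of the changed residue(s), truncated at the protein ends. Multi-residue
#' substitutions (MNVs) are handled as one variant whose mutated span covers
#' all changed residues.
#'
#' @param variant One somatic variant (one-row tibble or named list) with
#'   `kind == "SNV"`, `protein_position`, `ref_aa`, `alt_aa`.
#' @param protein Wild-type protein sequence (string, no stop symbol).
#' @param flank Flank width in residues on each side (default 13).
#' @return One-row MPS tibble with `sequence` and 1-based `span_start`,
#'   `span_end` marking the mutated residues within it.
#' @export
extract_mps_snv <- function(variant, protein, flank = 13L) {
  variant <- as.list(variant)
  if (!identical(variant$kind, "SNV")) {
    abort("extract_mps_snv requires a SNV", class = "neovax_input_error")
  }
  p <- variant$protein_position
  lr <- nchar(variant$ref_aa)
  la <- nchar(variant$alt_aa)
  len <- nchar(protein)
  if (p < 1 || p + lr - 1L > len) {
    abort("protein_position outside protein", class = "neovax_input_error")
  }
  if (substr(protein, p, p + lr - 1L) != variant$ref_aa) {
    abort(sprintf("reference mismatch at %s:%d (expected %s, found %s)",
                  variant$transcript_id, p, variant$ref_aa,
                  substr(protein, p, p + lr - 1L)),
          class = "neovax_reference_mismatch")
  }
  mutant <- paste0(substr(protein, 1L, p - 1L), variant$alt_aa,
                   substr(protein, p + lr, len))
  left <- min(flank, p - 1L)
  right <- min(flank, nchar(mutant) - (p + la - 1L))
  sequence <- substr(mutant, p - left, p + la - 1L + right)
  mps_record(variant, sequence,
             span_start = left + 1L, span_end = left + la,
             source_kind = "SNV")
}

# First index at which two strings differ; length(min)+1 if one is a prefix
# of the other; 0 if identical.
first_diff <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n > 0) {
    av <- utf8ToInt(substr(a, 1L, n))
    bv <- utf8ToInt(substr(b, 1L, n))
    d <- which(av != bv)
    if (length(d) > 0) return(d[1])
  }
  if (nchar(a) == nchar(b)) 0L else n + 1L
}

#' Extract the mutated peptide sequence for an indel
#'
#' The nucleotide edit is applied to the coding sequence and the result
#' translated. For frameshifts the MPS is the novel reading frame from the
#' first changed residue to (exclusive) the first downstream stop, prefixed
#' by up to 13 wild-type residues; if no stop occurs before the CDS end the
#' sequence is truncated there and flagged `read_through`. A frameshift
#' whose first novel codon is already a stop yields an empty sequence
#' flagged `null_neo_ORF` (dropped downstream). In-frame indels are treated
#' as short substitutions: a 13 + altered-region + 13 window.
#'
#' @param variant One somatic variant with `kind` in
#'   `c("insertion", "deletion")`, VCF-style left-anchored `cds_pos`,
#'   `ref_nt`, `alt_nt`.
#' @param cds Wild-type coding sequence (string, includes terminal stop
#'   codon).
#' @param flank Flank width in residues (default 13).
#' @return One-row MPS tibble.
#' @export
extract_mps_frameshift <- function(variant, cds, flank = 13L) {
  variant <- as.list(variant)
  if (!variant$kind %in% c("insertion", "deletion", "frameshift")) {
    abort("extract_mps_frameshift requires an indel", class = "neovax_input_error")
  }
  pos <- variant$cds_pos
  ref <- variant$ref_nt
  alt <- variant$alt_nt
  if (substr(cds, pos, pos + nchar(ref) - 1L) != ref) {
    abort(sprintf("reference mismatch at %s:%d", variant$transcript_id, pos),
          class = "neovax_reference_mismatch")
  }
  mutated <- paste0(substr(cds, 1L, pos - 1L), alt,
                    substr(cds, pos + nchar(ref), nchar(cds)))
  wt_aa <- sub("\\*.*$", "", translate_nt(cds))
  mut_trans <- translate_nt(mutated)
  stop_at <- regexpr("*", mut_trans, fixed = TRUE)
  flag <- ""
  if (stop_at > 0) {
    mut_aa <- substr(mut_trans, 1L, stop_at - 1L)
  } else {
    mut_aa <- mut_trans
    flag <- "read_through"
    warn(paste0("no stop codon downstream of ", variant$id %||% "indel",
                "; sequence truncated at CDS end"))
  }
  d <- first_diff(wt_aa, mut_aa)
  frameshift <- (abs(nchar(ref) - nchar(alt)) %% 3L) != 0L
  if (d == 0L || d > nchar(mut_aa)) {
    # No novel residue before the stop: degenerate frameshift.
    return(mps_record(variant, "", span_start = 0L, span_end = 0L,
                      source_kind = "indel", flag = "null_neo_ORF"))
  }
  left <- min(flank, d - 1L)
  if (frameshift) {
    sequence <- substr(mut_aa, d - left, nchar(mut_aa))
    span_start <- left + 1L
    span_end <- nchar(sequence)
  } else {
    # Changed region: strip the longest common suffix (kept clear of the
    # first difference so a pure deletion still marks its junction residue).
    n_mut <- nchar(mut_aa)
    suffix <- 0L
    max_suffix <- n_mut - d
    wt_v <- utf8ToInt(wt_aa)
    mut_v <- utf8ToInt(mut_aa)
    while (suffix < max_suffix &&
           suffix < nchar(wt_aa) &&
           wt_v[nchar(wt_aa) - suffix] == mut_v[n_mut - suffix]) {
      suffix <- suffix + 1L
    }
    region_end <- n_mut - suffix
    right <- min(flank, n_mut - region_end)
    sequence <- substr(mut_aa, d - left, region_end + right)
    span_start <- left + 1L
    span_end <- left + (region_end - d + 1L)
  }
  rec <- mps_record(variant, sequence, span_start, span_end,
                    source_kind = "indel", flag = flag)
  rec$protein_position <- d  # first changed residue, from the translation diff
  rec
}

#' Incorporate in-phase germline variants into an MPS
#'
#' Protein-changing germline variants whose RNA phase evidence places them
#' in cis with the somatic mutation (`cis_reads >= min_phase_reads` and
#' `cis_reads / (cis_reads + trans_reads) >= phase_fraction`) are
#' substituted into the MPS window; their ids are recorded in
#' `incorporated_germline`. A germline edit colliding with the mutated span
#' is skipped with a warning (the somatic edit wins). Edits are applied in
#' position order.
#'
#' @param mps One-row MPS tibble from the extractors.
#' @param germline Tibble of germline variants with phase read counts.
#' @param min_phase_reads Minimum cis reads (default 2).
#' @param phase_fraction Minimum cis fraction (default 0.8).
#' @return The MPS with substitutions applied.
#' @export
phase_and_incorporate <- function(mps, germline,
                                  min_phase_reads = 2L,
                                  phase_fraction = 0.8) {
  if (is.na(mps$sequence) || nchar(mps$sequence) == 0 || nrow(germline) == 0) {
    return(mps)
  }
  win_start <- mps$protein_position - (mps$span_start - 1L)
  win_end <- win_start + nchar(mps$sequence) - 1L
  g <- germline[germline$transcript_id == mps$transcript_id &
                  germline$is_protein_changing &
                  germline$protein_position >= win_start &
                  germline$protein_position <= win_end, , drop = FALSE]
  if (nrow(g) == 0) return(mps)
  g <- g[order(g$protein_position), , drop = FALSE]
  seqc <- mps$sequence
  taken <- character(0)
  for (i in seq_len(nrow(g))) {
    tot <- g$cis_reads[i] + g$trans_reads[i]
    in_phase <- g$cis_reads[i] >= min_phase_reads &&
      tot > 0 && g$cis_reads[i] / tot >= phase_fraction
    if (!in_phase) next
    w <- g$protein_position[i] - win_start + 1L
    if (w >= mps$span_start && w <= mps$span_end) {
      warn(paste0("germline ", g$id[i],
                  " collides with the somatic edit; skipped"))
      next
    }
    if (substr(seqc, w, w) == g$ref_aa[i]) {
      substr(seqc, w, w) <- g$alt_aa[i]
      taken <- c(taken, g$id[i])
    }
  }
  mps$sequence <- seqc
  mps$incorporated_germline <- paste(taken, collapse = ",")
  mps
}

#' Filter MPS candidates, recording a reason for every drop
#'
#' Drops candidates on non-expressed transcripts (`rpkm < expressed_min`),
#' synonymous and nonsense records, start-loss/stop-loss variants and
#' frameshifts with an empty novel region. The partition is lossless:
#' `nrow(kept) + nrow(dropped) == nrow(candidates)`.
#'
#' @param candidates Candidate MPS tibble (one row per variant).
#' @param expressed_min RPKM below which a transcript counts as
#'   non-expressed (default 0.001).
#' @return List with `kept` and `dropped` tibbles; `dropped` carries a
#'   machine-readable `reason`.
#' @export
filter_candidates <- function(candidates, expressed_min = 0.001) {
  if (nrow(candidates) == 0) {
    return(list(kept = candidates,
                dropped = dplyr::mutate(candidates, reason = character(0))))
  }
  reason <- rep(NA_character_, nrow(candidates))
  take <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    ifelse(is.na(reason) & cond, why, reason)
  }
  reason <- take(candidates$consequence == "synonymous", "synonymous")
  reason <- take(candidates$consequence == "nonsense", "nonsense")
  reason <- take(candidates$consequence == "start_loss", "start-loss")
  reason <- take(candidates$consequence == "stop_loss", "stop-loss")
  reason <- take(is.na(candidates$rpkm) | candidates$rpkm < expressed_min,
                 "non-expressed")
  reason <- take(!is.na(candidates$flag) & candidates$flag == "null_neo_ORF",
                 "null neo-ORF")
  kept <- candidates[is.na(reason), , drop = FALSE]
  dropped <- candidates[!is.na(reason), , drop = FALSE]
  dropped$reason <- reason[!is.na(reason)]
  list(kept = kept, dropped = dropped)
}

# Recompute ref/alt residues and consequence from the CDS; used both on
# generated variants (idempotent) and on variants read back from VCF, where
# only nucleotide-level fields survive.
annotate_consequence <- function(somatic, cds) {
  if (nrow(somatic) == 0) {
    somatic$ref_aa <- character(0)
    somatic$alt_aa <- character(0)
    somatic$consequence <- character(0)
    return(somatic)
  }
  ref_aa <- character(nrow(somatic))
  alt_aa <- character(nrow(somatic))
  consequence <- character(nrow(somatic))
  for (i in seq_len(nrow(somatic))) {
    s <- cds[[somatic$transcript_id[i]]]
    if (somatic$kind[i] == "SNV") {
      ci <- (somatic$cds_pos[i] - 1L) %/% 3L + 1L
      ref_codon <- substr(s, 3L * (ci - 1L) + 1L, 3L * ci)
      alt_codon <- ref_codon
      substr(alt_codon, (somatic$cds_pos[i] - 1L) %% 3L + 1L,
             (somatic$cds_pos[i] - 1L) %% 3L + 1L) <- somatic$alt_nt[i]
      ref_aa[i] <- unname(Biostrings::GENETIC_CODE[ref_codon])
      alt_aa[i] <- unname(Biostrings::GENETIC_CODE[alt_codon])
      consequence[i] <- if (alt_aa[i] == ref_aa[i]) "synonymous"
        else if (alt_aa[i] == "*") "nonsense"
        else if (ci == 1L) "start_loss"
        else if (ref_aa[i] == "*") "stop_loss"
        else "missense"
    } else {
      ref_aa[i] <- ""
      alt_aa[i] <- ""
      fs <- (abs(nchar(somatic$ref_nt[i]) - nchar(somatic$alt_nt[i])) %% 3L) != 0L
      consequence[i] <- if (fs) "frameshift" else "inframe_indel"
    }
  }
  somatic$ref_aa <- ref_aa
  somatic$alt_aa <- alt_aa
  somatic$consequence <- consequence
  somatic
}

#' Extract, phase and filter all MPS candidates for a patient
#'
#' Runs the full first stage: consequence annotation, window extraction
#' (substitution or indel path), germline phasing and candidate filtering.
#'
#' @param patient A `neovax_patient` (generated or read from a bundle).
#' @param min_phase_reads,phase_fraction Phasing thresholds, see
#'   [phase_and_incorporate()].
#' @param expressed_min Expression floor, see [filter_candidates()].
#' @return List with `kept` and `dropped` candidate tibbles.
#' @export
extract_candidates <- function(patient, min_phase_reads = 2L,
                               phase_fraction = 0.8, expressed_min = 0.001) {
  somatic <- annotate_consequence(patient$somatic_variants, patient$cds)
  rows <- lapply(seq_len(nrow(somatic)), function(i) {
    v <- somatic[i, ]
    if (v$consequence == "missense") {
      mps <- extract_mps_snv(v, patient$proteome[[v$transcript_id]])
    } else if (v$consequence %in% c("frameshift", "inframe_indel")) {
      mps <- extract_mps_frameshift(v, patient$cds[[v$transcript_id]])
    } else {
      mps <- mps_record(v, NA_character_, NA_integer_, NA_integer_,
                        source_kind = if (v$kind == "SNV") "SNV" else "indel")
    }
    phase_and_incorporate(mps, patient$germline_variants,
                          min_phase_reads = min_phase_reads,
                          phase_fraction = phase_fraction)
  })
  candidates <- dplyr::bind_rows(rows)
  if (nrow(candidates) == 0) {
    candidates <- mps_record(
      list(id = character(0), transcript_id = character(0),
           protein_position = integer(0), kind = character(0),
           consequence = character(0), rpkm = numeric(0),
           vaf_dna = numeric(0), vaf_rna = numeric(0)),
      character(0), integer(0), integer(0), character(0))[0, ]
  }
  filter_candidates(candidates, expressed_min = expressed_min)
}
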