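#' Configuration for a synthetic patient cohort
#'
#' Bundles the generative parameters for [generate_cohort()]. Defaults emulate
#' the input structure the design pipeline assumes for a pretreated
#' solid-tumor cohort: tens of somatic SNVs and a handful of indels per
#' patient, log-normal transcript expression, beta-distributed allele
#' fractions with a configurable RNA-silent fraction, and truth labels that
#' designate a subset of candidates as genuinely immunogenic.
#'
#' @param n_patients Number of patients to generate.
#' @param seed Global integer seed; every patient draws from a named
#'   substream derived from it, so cohorts are reproducible and patients are
#'   independent of cohort ordering.
#' @param snv_rate Expected somatic SNVs per patient (Poisson mean).
#' @param indel_rate Expected somatic indels per patient (Poisson mean).
#' @param rpkm_lognormal_params Named vector `c(meanlog=, sdlog=)` of the
#'   log-normal RPKM distribution.
#' @param vaf_beta_params Named vector `c(a=, b=)` of the beta distribution
#'   for DNA and RNA variant allele fractions.
#' @param frac_rna_silent Probability that a variant's RNA VAF is exactly 0
#'   (expressed transcript but allele not observed in RNA).
#' @param n_proteins Toy proteome size (number of transcripts/proteins).
#' @param immunogenic_frac Within responder patients, probability that an
#'   eligible candidate is designated truly immunogenic.
#' @param preexisting_frac Probability that an immunogenic candidate has a
#'   baseline-detectable (preexisting) response.
#' @param responder_frac Fraction of patients with at least one immunogenic
#'   target.
#' @param low_burden_frac Fraction of patients drawn from a low-mutational-
#'   burden subgroup so candidate counts span the 5-neoantigen eligibility
#'   boundary.
#' @param low_burden_scale Multiplier applied to `snv_rate`/`indel_rate` for
#'   the low-burden subgroup.
#' @param frac_zero_rpkm Fraction of transcripts with RPKM exactly 0
#'   (non-expressed).
#' @param germline_prob Probability that a somatic variant has a nearby
#'   protein-changing germline variant with read-level phase evidence.
#' @param cds_length_range Length range (nt) of generated coding sequences;
#'   rounded to codons, with an enforced ATG start and single terminal stop.
#'
#' @return A `neovax_cohort_config` list.
#' @export
cohort_config <- function(n_patients = 10,
                          seed = 1,
                          snv_rate = 40,
                          indel_rate = 4,
                          rpkm_lognormal_params = c(meanlog = 1.5, sdlog = 1.5),
                          vaf_beta_params = c(a = 2, b = 3),
                          frac_rna_silent = 0.15,
                          n_proteins = 30,
                          immunogenic_frac = 0.5,
                          preexisting_frac = 0.29,
                          responder_frac = 0.71,
                          low_burden_frac = 0.2,
                          low_burden_scale = 0.05,
                          frac_zero_rpkm = 0.1,
                          germline_prob = 0.15,
                          cds_length_range = c(300, 3000)) {
  cfg <- list(
    n_patients = n_patients, seed = seed,
    snv_rate = snv_rate, indel_rate = indel_rate,
    rpkm_lognormal_params = rpkm_lognormal_params,
    vaf_beta_params = vaf_beta_params,
    frac_rna_silent = frac_rna_silent,
    n_proteins = n_proteins,
    immunogenic_frac = immunogenic_frac,
    preexisting_frac = preexisting_frac,
    responder_frac = responder_frac,
    low_burden_frac = low_burden_frac,
    low_burden_scale = low_burden_scale,
    frac_zero_rpkm = frac_zero_rpkm,
    germline_prob = germline_prob,
    cds_length_range = cds_length_range
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "neovax_cohort_config")
}

validate_cohort_config <- function(cfg) {
  chk <- function(ok, msg) {
    if (!isTRUE(ok)) abort(msg, class = "neovax_config_error")
  }
  chk(is.numeric(cfg$n_patients) && cfg$n_patients >= 1, "n_patients must be >= 1")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be a single number")
  for (r in c("snv_rate", "indel_rate")) {
    chk(is.numeric(cfg[[r]]) && cfg[[r]] >= 0, paste(r, "must be >= 0"))
  }
  for (p in c("frac_rna_silent", "immunogenic_frac", "preexisting_frac",
              "responder_frac", "low_burden_frac", "low_burden_scale",
              "frac_zero_rpkm", "germline_prob")) {
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1, paste(p, "must be in [0, 1]"))
  }
  chk(all(cfg$vaf_beta_params > 0), "vaf_beta_params must be positive")
  chk(length(cfg$rpkm_lognormal_params) == 2 && cfg$rpkm_lognormal_params[2] > 0,
      "rpkm_lognormal_params must be (meanlog, sdlog) with sdlog > 0")
  chk(cfg$n_proteins >= 1, "n_proteins must be >= 1")
  chk(length(cfg$cds_length_range) == 2 &&
        cfg$cds_length_range[1] >= 30 &&
        cfg$cds_length_range[2] >= cfg$cds_length_range[1],
      "cds_length_range must be an increasing pair >= 30 nt")
  invisible(cfg)
}

.HLA_CLASS1_POOL <- list(
  A = c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01", "HLA-A*11:01", "HLA-A*24:02"),
  B = c("HLA-B*07:02", "HLA-B*08:01", "HLA-B*15:01", "HLA-B*35:01", "HLA-B*44:02"),
  C = c("HLA-C*03:04", "HLA-C*04:01", "HLA-C*07:01", "HLA-C*07:02")
)
.HLA_DRB_POOL <- c("HLA-DRB1*01:01", "HLA-DRB1*03:01", "HLA-DRB1*04:01",
                   "HLA-DRB1*07:01", "HLA-DRB1*11:01", "HLA-DRB1*15:01")

#' Generate a deterministic synthetic cohort
#'
#' Each patient gets a toy proteome (random CDS with ATG start, no internal
#' stop, one terminal stop), an HLA class I + DRB genotype, somatic SNVs
#' generated as literal single-nucleotide CDS substitutions (so missense,
#' synonymous and nonsense consequences arise from the genetic code), somatic
#' indels (frameshift and in-frame), germline variants with cis/trans phase
#' read counts against a nearby somatic variant, per-transcript RPKM, and
#' truth labels marking which candidates are immunogenic (with CD4/CD8
#' phenotype) and preexisting.
#'
#' Identical `(config, seed)` yields identical cohorts; each patient uses a
#' named substream of the global seed.
#'
#' @param config A [cohort_config()].
#' @return List of `neovax_patient` objects.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  purrr::map(seq_len(config$n_patients), function(i) {
    pid <- sprintf("P%03d", i)
    generate_patient(pid, config, derive_seed(config$seed, paste0("patient/", pid)))
  })
}

# Single synthetic patient under an explicit seed.
generate_patient <- function(patient_id, config, seed) {
  withr::with_seed(seed, {
    np <- config$n_proteins
    codon_range <- pmax(2L, round(config$cds_length_range / 3))
    n_codons <- sample(seq(codon_range[1], codon_range[2]), np, replace = TRUE)
    tx_ids <- sprintf("TX%03d", seq_len(np))
    cds <- vapply(n_codons, function(k) {
      paste0("ATG",
             paste(sample(.SENSE_CODONS, k - 2L, replace = TRUE), collapse = ""),
             "TAA")
    }, character(1))
    names(cds) <- tx_ids
    proteome <- vapply(cds, function(s) sub("\\*$", "", translate_nt(s)), character(1))

    hla_class1 <- unique(unlist(lapply(.HLA_CLASS1_POOL, sample, size = 2)))
    hla_drb <- unique(sample(.HLA_DRB_POOL, 2))

    rp <- config$rpkm_lognormal_params
    rpkm <- round(rlnorm(np, meanlog = rp[[1]], sdlog = rp[[2]]), 3)
    rpkm[runif(np) < config$frac_zero_rpkm] <- 0
    expression <- tibble::tibble(transcript_id = tx_ids, rpkm = rpkm)

    mult <- if (runif(1) < config$low_burden_frac) config$low_burden_scale else 1
    n_snv <- rpois(1, config$snv_rate * mult)
    n_indel <- rpois(1, config$indel_rate * mult)

    snvs <- generate_snvs(n_snv, cds, config)
    indels <- generate_indels(n_indel, cds, config)
    somatic <- dplyr::bind_rows(snvs, indels)
    if (nrow(somatic) > 0) {
      somatic$id <- sprintf("%s_V%03d", patient_id, seq_len(nrow(somatic)))
      somatic <- dplyr::left_join(somatic, expression, by = "transcript_id")
    } else {
      somatic$id <- character(0)
      somatic$rpkm <- numeric(0)
    }
    somatic <- somatic[, c("id", "kind", "transcript_id", "cds_pos", "ref_nt",
                           "alt_nt", "protein_position", "ref_aa", "alt_aa",
                           "consequence", "vaf_dna", "vaf_rna", "rpkm")]

    germline <- generate_germline(somatic, proteome, patient_id, config)
    truth <- assign_truth(somatic, config)

    structure(list(
      patient_id = patient_id,
      proteome = proteome,
      cds = cds,
      hla_class1 = hla_class1,
      hla_drb = hla_drb,
      somatic_variants = somatic,
      germline_variants = germline,
      expression = expression,
      truth = truth
    ), class = "neovax_patient")
  })
}

# Somatic SNVs as literal single-nt substitutions in interior codons.
generate_snvs <- function(n, cds, config) {
  if (n == 0) return(empty_variant_tbl())
  vb <- config$vaf_beta_params
  rows <- lapply(seq_len(n), function(i) {
    tx <- sample(names(cds), 1)
    s <- cds[[tx]]
    k <- nchar(s) %/% 3L
    codon_idx <- sample(2:(k - 1L), 1)  # skip start and terminal stop codons
    off <- sample(0:2, 1)
    cds_pos <- 3L * (codon_idx - 1L) + 1L + off
    ref_nt <- substr(s, cds_pos, cds_pos)
    alt_nt <- sample(setdiff(c("A", "C", "G", "T"), ref_nt), 1)
    ref_codon <- substr(s, 3L * (codon_idx - 1L) + 1L, 3L * codon_idx)
    alt_codon <- ref_codon
    substr(alt_codon, off + 1L, off + 1L) <- alt_nt
    ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
    alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
    consequence <- if (alt_aa == ref_aa) "synonymous"
      else if (alt_aa == "*") "nonsense"
      else "missense"
    tibble::tibble(
      kind = "SNV", transcript_id = tx, cds_pos = cds_pos,
      ref_nt = ref_nt, alt_nt = alt_nt,
      protein_position = codon_idx, ref_aa = ref_aa, alt_aa = alt_aa,
      consequence = consequence,
      vaf_dna = round(rbeta(1, vb[[1]], vb[[2]]), 4),
      vaf_rna = if (runif(1) < config$frac_rna_silent) 0
                else round(rbeta(1, vb[[1]], vb[[2]]), 4)
    )
  })
  dplyr::bind_rows(rows)
}

# Somatic indels, left-anchored VCF style; 80% frameshift (1-2 nt), 20%
# in-frame 3-nt insertions.
generate_indels <- function(n, cds, config) {
  if (n == 0) return(empty_variant_tbl())
  vb <- config$vaf_beta_params
  rows <- lapply(seq_len(n), function(i) {
    tx <- sample(names(cds), 1)
    s <- cds[[tx]]
    L <- nchar(s)
    pos <- sample(6:(L - 90L), 1)  # anchor; leave room for a neo-ORF
    inframe <- runif(1) < 0.2
    if (inframe) {
      ins <- sample(setdiff(.SENSE_CODONS, "ATG"), 1)
      ref_nt <- substr(s, pos, pos)
      alt_nt <- paste0(ref_nt, ins)
      kind <- "insertion"
    } else if (runif(1) < 0.5) {
      d <- sample(1:2, 1)
      ref_nt <- substr(s, pos, pos + d)
      alt_nt <- substr(s, pos, pos)
      kind <- "deletion"
    } else {
      d <- sample(1:2, 1)
      ref_nt <- substr(s, pos, pos)
      alt_nt <- paste0(ref_nt, paste(sample(c("A", "C", "G", "T"), d,
                                            replace = TRUE), collapse = ""))
      kind <- "insertion"
    }
    fs <- (abs(nchar(ref_nt) - nchar(alt_nt)) %% 3L) != 0L
    tibble::tibble(
      kind = kind, transcript_id = tx, cds_pos = pos,
      ref_nt = ref_nt, alt_nt = alt_nt,
      protein_position = ((pos + 1L) - 1L) %/% 3L + 1L,
      ref_aa = "", alt_aa = "",
      consequence = if (fs) "frameshift" else "inframe_indel",
      vaf_dna = round(rbeta(1, vb[[1]], vb[[2]]), 4),
      vaf_rna = if (runif(1) < config$frac_rna_silent) 0
                else round(rbeta(1, vb[[1]], vb[[2]]), 4)
    )
  })
  dplyr::bind_rows(rows)
}

empty_variant_tbl <- function() {
  tibble::tibble(
    kind = character(0), transcript_id = character(0), cds_pos = integer(0),
    ref_nt = character(0), alt_nt = character(0),
    protein_position = integer(0), ref_aa = character(0),
    alt_aa = character(0), consequence = character(0),
    vaf_dna = numeric(0), vaf_rna = numeric(0)
  )
}

# Germline variants near somatic SNVs with cis/trans phase read counts.
generate_germline <- function(somatic, proteome, patient_id, config) {
  empty <- tibble::tibble(
    id = character(0), transcript_id = character(0),
    protein_position = integer(0), ref_aa = character(0),
    alt_aa = character(0), is_protein_changing = logical(0),
    somatic_id = character(0), cis_reads = integer(0), trans_reads = integer(0)
  )
  snvs <- somatic[somatic$kind == "SNV", , drop = FALSE]
  if (nrow(snvs) == 0) return(empty)
  rows <- list()
  for (i in seq_len(nrow(snvs))) {
    if (runif(1) >= config$germline_prob) next
    sv <- snvs[i, ]
    prot <- proteome[[sv$transcript_id]]
    gpos <- sv$protein_position + sample(c(-13:-1, 1:13), 1)
    if (gpos < 2 || gpos > nchar(prot)) next
    ref_aa <- substr(prot, gpos, gpos)
    changing <- runif(1) < 0.85
    alt_aa <- if (changing) sample(setdiff(.AA20, ref_aa), 1) else ref_aa
    in_phase <- runif(1) < 0.7
    rows[[length(rows) + 1L]] <- tibble::tibble(
      transcript_id = sv$transcript_id, protein_position = gpos,
      ref_aa = ref_aa, alt_aa = alt_aa, is_protein_changing = changing,
      somatic_id = sv$id,
      cis_reads = if (in_phase) sample(5:30, 1) else sample(0:1, 1),
      trans_reads = if (in_phase) sample(0:1, 1) else sample(5:30, 1)
    )
  }
  if (length(rows) == 0) return(empty)
  out <- dplyr::bind_rows(rows)
  out$id <- sprintf("%s_G%03d", patient_id, seq_len(nrow(out)))
  out[, c("id", "transcript_id", "protein_position", "ref_aa", "alt_aa",
          "is_protein_changing", "somatic_id", "cis_reads", "trans_reads")]
}

# Truth labels: immunogenic candidates exist only in responder patients and
# only on expressed, protein-changing variants with RNA VAF > 0.
assign_truth <- function(somatic, config) {
  eligible <- somatic$consequence %in% c("missense", "frameshift", "inframe_indel") &
    somatic$vaf_rna > 0 & somatic$rpkm > 0
  ids <- somatic$id[eligible]
  responder <- runif(1) < config$responder_frac
  immunogenic <- responder & (runif(length(ids)) < config$immunogenic_frac)
  if (responder && config$immunogenic_frac > 0 && length(ids) > 0 &&
      !any(immunogenic)) {
    immunogenic[1] <- TRUE
  }
  n_imm <- sum(immunogenic)
  phenotype <- rep("n/a", length(ids))
  phenotype[immunogenic] <- sample(c("CD4_only", "CD8_only", "CD4_and_CD8"),
                                   n_imm, replace = TRUE,
                                   prob = c(0.59, 0.26, 0.15))
  preexisting <- immunogenic & (runif(length(ids)) < config$preexisting_frac)
  tibble::tibble(
    variant_id = ids,
    immunogenic = immunogenic,
    phenotype = phenotype,
    preexisting = preexisting
  )
}

#' @export
print.neovax_patient <- function(x, ...) {
  cat("<neovax_patient> ", x$patient_id, "\n",
      "  proteome: ", length(x$proteome), " transcripts\n",
      "  HLA: ", paste(x$hla_class1, collapse = ", "), " | ",
      paste(x$hla_drb, collapse = ", "), "\n",
      "  somatic variants: ", nrow(x$somatic_variants),
      " (", sum(x$somatic_variants$kind != "SNV"), " indels)\n",
      "  immunogenic truth labels: ", sum(x$truth$immunogenic), "\n", sep = "")
  invisible(x)
}
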