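# Shared fixture builders. Sequences are constructed in code at test time;
# the codon map here is the test suite's own (wobble positions differ from
# the package's reverse-translation table on purpose).

.TEST_CODON <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
  Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
  L = "CTT", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
  S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT"
)

aa2nt <- function(aa) {
  paste(.TEST_CODON[strsplit(aa, "")[[1]]], collapse = "")
}

rand_protein <- function(n, seed) {
  withr::with_seed(seed, {
    paste(c("M", sample(names(.TEST_CODON), n - 1, replace = TRUE)),
          collapse = "")
  })
}

make_variant <- function(id = "V1", kind = "SNV", transcript_id = "TX001",
                         protein_position = 10L, ref_aa = "A", alt_aa = "W",
                         cds_pos = NA_integer_, ref_nt = NA_character_,
                         alt_nt = NA_character_, consequence = "missense",
                         vaf_dna = 0.4, vaf_rna = 0.3, rpkm = 20) {
  tibble::tibble(id = id, kind = kind, transcript_id = transcript_id,
                 cds_pos = cds_pos, ref_nt = ref_nt, alt_nt = alt_nt,
                 protein_position = protein_position, ref_aa = ref_aa,
                 alt_aa = alt_aa, consequence = consequence,
                 vaf_dna = vaf_dna, vaf_rna = vaf_rna, rpkm = rpkm)
}

make_mps <- function(sequence, span_start = 14L, span_end = 14L,
                     variant_id = "V1", source_kind = "SNV", rpkm = 20,
                     vaf_dna = 0.4, vaf_rna = 0.3,
                     best_class1_rank = NA_real_,
                     best_class2_rank = NA_real_) {
  tibble::tibble(
    variant_id = variant_id, transcript_id = "TX001",
    protein_position = 100L, kind = source_kind, consequence = "missense",
    source_kind = source_kind, sequence = sequence,
    span_start = as.integer(span_start), span_end = as.integer(span_end),
    incorporated_germline = "", flag = "", rpkm = rpkm, vaf_dna = vaf_dna,
    vaf_rna = vaf_rna, best_class1_rank = best_class1_rank,
    best_class2_rank = best_class2_rank
  )
}

# Cohorts are expensive enough to share across tests within a file run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, maker(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

small_cohort <- function() {
  cached("small_cohort", function() {
    generate_cohort(cohort_config(n_patients = 8, seed = 42))
  })
}

designed_patient <- function() {
  cached("designed_patient", function() {
    co <- small_cohort()
    for (p in co) {
      rep <- suppressWarnings(design_patient(p))
      if (rep$eligible && nrow(rep$selected) == 20 &&
          sum(p$truth$immunogenic) > 0) {
        return(list(patient = p, report = rep))
      }
    }
    stop("no suitable designed patient in fixture cohort")
  })
}

# Oversubscribed candidate set: every prioritization tier has surplus.
saturating_candidates <- function(seed = 60) {
  withr::with_seed(seed, {
    mk <- function(n, prefix, kind, rpkm_range, vaf_rna = 0.3) {
      tibble::tibble(
        variant_id = sprintf("%s%03d", prefix, seq_len(n)),
        source_kind = kind,
        sequence = replicate(n, paste(sample(c("A", "G", "L", "S", "V"), 27,
                                             TRUE), collapse = "")),
        span_start = 14L, span_end = 14L,
        rpkm = round(runif(n, rpkm_range[1], rpkm_range[2]), 2),
        vaf_rna = vaf_rna,
        vaf_dna = round(runif(n, 0.05, 0.9), 3),
        best_class1_rank = round(runif(n, 0, 60), 3),
        best_class2_rank = round(runif(n, 0, 100), 3))
    }
    dplyr::bind_rows(
      mk(10, "IND", "indel", c(2, 300)),
      mk(60, "HIS", "SNV", c(10, 500)),
      mk(60, "LOS", "SNV", c(1, 9.9)))
  })
}

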