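# CDR3-beta clonotype tracking across blood and tumor bulk repertoires:
# Jurkat reporter validation, exact junction matching (plus V/J when both
# sides carry gene calls), cumulative frequencies with per-neoantigen
# breakdowns, baseline de novo classification and biopsy overlap.

#' Jurkat reporter specificity call
#'
#' @param luminescence Reporter signal with antigen-loaded targets.
#' @param effectors_only Effectors-only control signal (> 0).
#' @param fold_threshold Validation cutoff (default 2).
#' @return List with `fold` and `validated`.
#' @export
jurkat_specificity_call <- function(luminescence, effectors_only,
                                    fold_threshold = 2) {
  if (any(effectors_only <= 0)) {
    abort("effectors-only control must be positive", class = "neovax_assay_error")
  }
  fold <- luminescence / effectors_only
  list(fold = fold, validated = fold >= fold_threshold)
}

# Frequencies within one repertoire sample (one compartment x timepoint).
sample_frequencies <- function(sample) {
  total <- sum(sample$duplicate_count)
  stopifnot(total > 0)
  sample$frequency <- sample$duplicate_count / total
  sample
}

#' Track specific TCRs in a bulk repertoire sample
#'
#' Matches on the exact CDR3-beta amino acid string; when both the specific
#' TCR and the repertoire row carry V and J gene calls these must match
#' too. Unmatched TCRs are reported with frequency 0.
#'
#' @param specific Tibble of specific TCRs (`tcr_id`, `junction_aa`,
#'   `specificity`, optional `v_call`/`j_call`).
#' @param sample One repertoire sample tibble (`junction_aa`,
#'   `duplicate_count`, optional `v_call`/`j_call`).
#' @return `specific` with `duplicate_count` and `frequency` columns.
#' @export
track_clonotypes <- function(specific, sample) {
  sample <- sample_frequencies(sample)
  count <- numeric(nrow(specific))
  freq <- numeric(nrow(specific))
  for (i in seq_len(nrow(specific))) {
    hit <- sample$junction_aa == specific$junction_aa[i]
    sv <- if ("v_call" %in% names(specific)) specific$v_call[i] else NA_character_
    sj <- if ("j_call" %in% names(specific)) specific$j_call[i] else NA_character_
    if (!is.na(sv) && "v_call" %in% names(sample)) {
      hit <- hit & (is.na(sample$v_call) | sample$v_call == sv)
    }
    if (!is.na(sj) && "j_call" %in% names(sample)) {
      hit <- hit & (is.na(sample$j_call) | sample$j_call == sj)
    }
    count[i] <- sum(sample$duplicate_count[hit])
    freq[i] <- sum(sample$frequency[hit])
  }
  out <- specific
  out$duplicate_count <- count
  out$frequency <- freq
  out
}

#' Cumulative frequency of specific TCRs in a sample
#'
#' Sum of matched clonotype frequencies, with a per-neoantigen breakdown
#' and counts of distinct detected TCRs and neoantigens.
#'
#' @inheritParams track_clonotypes
#' @return List with `cumulative`, `per_specificity` tibble, `n_tcrs`
#'   (distinct TCRs detected) and `n_neoantigens`.
#' @export
cumulative_frequency <- function(specific, sample) {
  tracked <- track_clonotypes(specific, sample)
  per <- dplyr::summarise(
    dplyr::group_by(tracked, specificity = .data$specificity),
    frequency = sum(.data$frequency),
    n_tcrs = sum(.data$frequency > 0), .groups = "drop")
  list(cumulative = sum(tracked$frequency),
       per_specificity = per,
       n_tcrs = sum(tracked$frequency > 0),
       n_neoantigens = sum(per$frequency > 0))
}

#' Classify specific TCRs as de novo or preexisting at baseline
#'
#' De novo: no matching reads (at most `detection_threshold`) in the
#' baseline sample. With `baseline_sample = NULL` every TCR is `unknown`.
#'
#' @inheritParams track_clonotypes
#' @param baseline_sample Baseline repertoire tibble or `NULL`.
#' @param detection_threshold Read count at or below which a TCR counts as
#'   undetectable (default 0).
#' @return `specific` with `baseline_count` and `status` columns.
#' @export
classify_baseline_status <- function(specific, baseline_sample,
                                     detection_threshold = 0) {
  out <- specific
  if (is.null(baseline_sample) || nrow(baseline_sample) == 0) {
    out$baseline_count <- NA_real_
    out$status <- "unknown"
    return(out)
  }
  tracked <- track_clonotypes(specific, baseline_sample)
  out$baseline_count <- tracked$duplicate_count
  out$status <- ifelse(tracked$duplicate_count <= detection_threshold,
                       "de_novo", "preexisting")
  out
}

#' Overlap of detected specific TCRs between two samples
#'
#' Jaccard index over the subsets of `specific` detected in each sample;
#' symmetric by construction.
#'
#' @param sample_a,sample_b Repertoire sample tibbles.
#' @param specific Specific TCR tibble.
#' @return List with `shared` tcr ids, `n_a`, `n_b`, `jaccard`.
#' @export
biopsy_overlap <- function(sample_a, sample_b, specific) {
  in_a <- track_clonotypes(specific, sample_a)
  in_b <- track_clonotypes(specific, sample_b)
  set_a <- specific$tcr_id[in_a$frequency > 0]
  set_b <- specific$tcr_id[in_b$frequency > 0]
  un <- union(set_a, set_b)
  list(shared = intersect(set_a, set_b),
       n_a = length(set_a), n_b = length(set_b),
       jaccard = if (length(un) == 0) NA_real_
                 else length(intersect(set_a, set_b)) / length(un))
}
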