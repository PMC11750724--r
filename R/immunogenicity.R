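# Immune-response analytics: overlapping-peptide (OLP) pool design, ELISpot
# positivity by an exact label-permutation test plus a minimum spot delta,
# response classification against baseline with a twofold rule, patient
# summaries, and peptide-HLA multimer candidate selection.

#' Design the overlapping 15-mer peptide pool for an MPS
#'
#' 15-mers advancing in steps of 4 residues (11-residue overlap); the final
#' peptide is anchored to the sequence end so coverage is complete, which
#' may overlap its predecessor by more than 11. Sequences shorter than the
#' peptide length yield a single full-sequence peptide.
#'
#' @param sequence MPS amino acid string (or a one-row MPS tibble).
#' @param target_id Identifier carried into the pool.
#' @param width Peptide length (default 15).
#' @param overlap Overlap between consecutive peptides (default 11).
#' @return A list with `target_id`, `peptides`, `starts`, `step`.
#' @export
make_olp_pool <- function(sequence, target_id = NULL, width = 15L,
                          overlap = 11L) {
  if (is.data.frame(sequence)) {
    target_id <- target_id %||% sequence$variant_id
    sequence <- sequence$sequence
  }
  L <- nchar(sequence)
  stopifnot(L >= 1)
  step <- width - overlap
  if (L <= width) {
    starts <- 1L
    peptides <- sequence
  } else {
    starts <- seq(1L, L - width, by = step)
    if (utils::tail(starts, 1) + width - 1L < L) {
      starts <- c(starts, L - width + 1L)
    }
    peptides <- substring(sequence, starts, starts + width - 1L)
  }
  list(target_id = target_id, peptides = peptides, starts = starts,
       step = step)
}

#' ELISpot positivity by exact permutation plus a spot-count floor
#'
#' A well set is positive when (a) the one-sided exact label-permutation
#' test of stimulated vs control replicates rejects at `alpha` -- the
#' p-value is the fraction of relabelings whose mean difference strictly
#' exceeds the observed one -- and (b) the observed mean difference is at
#' least `min_spot_delta` spots. The delta floor keeps the caller
#' conservative at the very small replicate counts typical of the assay.
#'
#' @param stimulated,control Non-negative replicate spot counts (>= 2 each).
#' @param alpha Test level (default 0.05).
#' @param min_spot_delta Minimum mean stimulated - control difference
#'   (default 5 spots).
#' @param positive_control Optional positive-control replicate counts; if
#'   all zero the assay has failed and no call is made.
#' @return List with `positive`, `p_value`, `delta`, `assay_failure`.
#' @export
call_positivity <- function(stimulated, control, alpha = 0.05,
                            min_spot_delta = 5, positive_control = NULL) {
  stopifnot(length(stimulated) >= 2, length(control) >= 2,
            all(stimulated >= 0), all(control >= 0))
  if (!is.null(positive_control) && all(positive_control == 0)) {
    return(list(positive = NA, p_value = NA_real_, delta = NA_real_,
                assay_failure = TRUE))
  }
  pooled <- c(stimulated, control)
  n_s <- length(stimulated)
  obs <- mean(stimulated) - mean(control)
  idx <- utils::combn(length(pooled), n_s)
  perm <- apply(idx, 2, function(j) mean(pooled[j]) - mean(pooled[-j]))
  p <- mean(perm > obs)
  list(positive = (p < alpha) && (obs >= min_spot_delta),
       p_value = p, delta = obs, assay_failure = FALSE)
}

#' Classify a target's response from baseline and post-treatment wells
#'
#' Positivity is called at both timepoints with [call_positivity()]. The
#' fold change is the post net spot count over the baseline net spot count
#' (floored to avoid near-zero denominators). A target responds when the
#' post-treatment wells are positive: de novo if baseline was negative,
#' amplified when baseline was positive and the fold change reaches
#' `fold_threshold`; a positive baseline that does not amplify is
#' `preexisting_only`.
#'
#' @param baseline,post Lists with `stimulated` and `control` replicate
#'   counts; `baseline` may be `NULL` (call flagged `no-baseline`).
#' @param fold_threshold Amplification threshold (default 2).
#' @param floor Denominator floor in spots (default 1).
#' @param alpha,min_spot_delta Passed to [call_positivity()].
#' @return List with `classification`, `fold_change`, `positive_at_baseline`,
#'   `positive_post`, `responded`, `flag`.
#' @export
call_response <- function(baseline, post, fold_threshold = 2, floor = 1,
                          alpha = 0.05, min_spot_delta = 5) {
  post_call <- call_positivity(post$stimulated, post$control,
                               alpha = alpha, min_spot_delta = min_spot_delta,
                               positive_control = post$positive_control)
  flag <- ""
  if (is.null(baseline)) {
    base_pos <- FALSE
    base_net <- NA_real_
    flag <- "no-baseline"
  } else {
    base_call <- call_positivity(baseline$stimulated, baseline$control,
                                 alpha = alpha,
                                 min_spot_delta = min_spot_delta,
                                 positive_control = baseline$positive_control)
    base_pos <- isTRUE(base_call$positive)
    base_net <- mean(baseline$stimulated) - mean(baseline$control)
  }
  post_net <- mean(post$stimulated) - mean(post$control)
  fold <- if (is.na(base_net)) NA_real_ else post_net / max(base_net, floor)
  post_pos <- isTRUE(post_call$positive)
  classification <- if (!post_pos && !base_pos) {
    "negative"
  } else if (post_pos && !base_pos) {
    "de_novo"
  } else if (post_pos && base_pos && !is.na(fold) && fold >= fold_threshold) {
    "amplified_preexisting"
  } else {
    "preexisting_only"
  }
  list(classification = classification,
       fold_change = fold,
       positive_at_baseline = base_pos,
       positive_post = post_pos,
       responded = classification %in% c("de_novo", "amplified_preexisting"),
       flag = flag)
}

#' Call responses for every target in an ELISpot table
#'
#' Consumes the long-format assay table written by [generate_assay_data()]
#' (columns `target_id`, `timepoint`, `assay`, `compartment`, `condition`,
#' `replicate`, `spots`) and produces one response call per target x assay
#' x compartment.
#'
#' @param elispot ELISpot tibble.
#' @param fold_threshold,floor,alpha,min_spot_delta See [call_response()].
#' @return Tibble of calls.
#' @export
call_responses_from_table <- function(elispot, fold_threshold = 2, floor = 1,
                                      alpha = 0.05, min_spot_delta = 5) {
  wells <- function(target, tp, assay, comp, cond) {
    x <- elispot[elispot$timepoint == tp & elispot$assay == assay &
                   elispot$compartment == comp & elispot$condition == cond, ]
    if (cond == "stimulated") x <- x[x$target_id == target, ]
    x$spots
  }
  grid <- unique(elispot[elispot$condition == "stimulated",
                         c("target_id", "assay", "compartment")])
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    mk <- function(tp) {
      stim <- wells(g$target_id, tp, g$assay, g$compartment, "stimulated")
      if (length(stim) == 0) return(NULL)
      list(stimulated = stim,
           control = wells(g$target_id, tp, g$assay, g$compartment, "control"),
           positive_control = wells(g$target_id, tp, g$assay, g$compartment,
                                    "positive_control"))
    }
    post <- mk("post_induction")
    if (is.null(post)) return(NULL)
    cl <- call_response(mk("baseline"), post, fold_threshold = fold_threshold,
                        floor = floor, alpha = alpha,
                        min_spot_delta = min_spot_delta)
    tibble::tibble(target_id = g$target_id, assay = g$assay,
                   compartment = g$compartment,
                   classification = cl$classification,
                   fold_change = cl$fold_change,
                   positive_at_baseline = cl$positive_at_baseline,
                   positive_post = cl$positive_post,
                   responded = cl$responded, flag = cl$flag)
  })
  dplyr::bind_rows(rows)
}

#' Summarize a patient's response calls
#'
#' A patient is a responder when at least one target is de novo or
#' amplified. Per-target phenotype comes from the CD4/CD8 compartment
#' calls of the post-IVS assay (`CD4_only`, `CD8_only`, `CD4_and_CD8`).
#'
#' @param calls Tibble from [call_responses_from_table()].
#' @return List with `responder`, `n_targets_positive`, `phenotypes` tibble.
#' @export
summarize_patient <- function(calls) {
  if (nrow(calls) == 0) {
    return(list(responder = FALSE, n_targets_positive = 0L,
                phenotypes = tibble::tibble(target_id = character(0),
                                            phenotype = character(0))))
  }
  responded_targets <- unique(calls$target_id[calls$responded])
  ivs <- calls[calls$assay == "post_IVS", ]
  phen <- dplyr::summarise(
    dplyr::group_by(ivs, .data$target_id),
    cd4 = any(.data$compartment == "CD4" & .data$responded),
    cd8 = any(.data$compartment == "CD8" & .data$responded))
  phen$phenotype <- dplyr::case_when(
    phen$cd4 & phen$cd8 ~ "CD4_and_CD8",
    phen$cd4 ~ "CD4_only",
    phen$cd8 ~ "CD8_only",
    TRUE ~ "n/a")
  list(responder = length(responded_targets) > 0,
       n_targets_positive = length(responded_targets),
       phenotypes = phen[, c("target_id", "phenotype")])
}

#' Select peptide-HLA multimer candidates
#'
#' From all scored mutation-containing 8-11-mer / class I allele pairs,
#' keep pairs with percentile rank below `max_rank` (default 5), sort
#' ascending and take the top `top_n` (default 3). Ties break on peptide
#' then allele, so selection is deterministic.
#'
#' @param scores Scored candidate tibble (`peptide`, `allele`,
#'   `percentile_rank`).
#' @param max_rank Admission cutoff (default 5).
#' @param top_n Maximum pairs returned (default 3).
#' @return Up to `top_n` rows of `scores`, best rank first.
#' @export
select_multimer_candidates <- function(scores, max_rank = 5, top_n = 3L) {
  adm <- scores[scores$percentile_rank < max_rank, , drop = FALSE]
  adm <- adm[order(adm$percentile_rank, adm$peptide, adm$allele), , drop = FALSE]
  head(adm, top_n)
}
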