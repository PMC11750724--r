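# Pluggable HLA-binding percentile-rank scoring. The bundled mock predictor
# maps (peptide, allele) deterministically to a rank in [0, 100) via a keyed
# string hash, with a pinning hook so tests can fix chosen pairs. Real
# predictor adapters can implement the same interface; nothing in the
# package requires one.

#' Enumerate mutation-containing epitope candidates from an MPS
#'
#' All k-mers of the requested lengths whose span intersects the mutated
#' span, crossed with the supplied alleles.
#'
#' @param mps One-row MPS tibble.
#' @param alleles Character vector of HLA allele names.
#' @param lengths Peptide lengths; 8-11 for class I, 15 for the class II
#'   (HLA-DRB) windows.
#' @return Tibble with `peptide`, `allele`, `length`, `start` (1-based in
#'   the MPS), `source_variant`, `contains_mutation`.
#' @export
enumerate_candidates <- function(mps, alleles, lengths = 8:11) {
  w <- enum_windows(mps$sequence, mps$span_start, mps$span_end, lengths)
  n <- length(w$peptide)
  na <- length(alleles)
  tibble::tibble(
    peptide = rep(w$peptide, each = na),
    allele = rep(alleles, times = n),
    length = rep(w$length, each = na),
    start = rep(w$start, each = na),
    source_variant = if (n * na > 0) mps$variant_id else character(0),
    contains_mutation = rep(TRUE, n * na)
  )
}

# Mutation-overlapping k-mer windows of an MPS, as plain vectors.
enum_windows <- function(sequence, span_start, span_end, lengths) {
  L <- nchar(sequence)
  peptide <- character(0); length_v <- integer(0); start_v <- integer(0)
  for (k in lengths) {
    if (is.na(L) || L < k) next
    starts <- seq.int(max(1L, span_start - k + 1L), min(L - k + 1L, span_end))
    if (length(starts) == 0) next
    peptide <- c(peptide, substring(sequence, starts, starts + k - 1L))
    length_v <- c(length_v, rep.int(as.integer(k), length(starts)))
    start_v <- c(start_v, as.integer(starts))
  }
  list(peptide = peptide, length = length_v, start = start_v)
}

#' Deterministic mock binding predictor
#'
#' Maps every (peptide, allele) pair to a fixed percentile rank in
#' \[0, 100) through a keyed polynomial hash: identical inputs always give
#' identical ranks, with no external tool involved. `pins` lets tests fix
#' the rank of chosen pairs, named `"PEPTIDE|ALLELE"`.
#'
#' @param pins Named numeric vector of pinned ranks.
#' @param key Integer hash key; changing it yields an independent score
#'   landscape.
#' @return A `neovax_predictor` object.
#' @export
mock_predictor <- function(pins = numeric(0), key = 0) {
  stopifnot(is.numeric(pins))
  structure(list(predictor_id = paste0("mock-hash-v1/", key),
                 pins = pins, key = key),
            class = "neovax_predictor")
}

.ALLELE_RE <- "^HLA-[A-Z]+[0-9]*\\*[0-9]+:[0-9]+$"

#' Score epitope candidates with a predictor
#'
#' @param candidates Tibble from [enumerate_candidates()].
#' @param predictor A predictor object; default [mock_predictor()].
#' @return `candidates` with `percentile_rank` in \[0, 100\] (lower =
#'   stronger predicted binding) and `predictor_id` columns appended.
#' @export
predict_binding <- function(candidates, predictor = mock_predictor()) {
  stopifnot(inherits(predictor, "neovax_predictor"))
  if (nrow(candidates) > 0) {
    bad <- !grepl(.ALLELE_RE, candidates$allele)
    if (any(bad)) {
      abort(paste0("unrecognized allele name(s): ",
                   paste(unique(candidates$allele[bad]), collapse = ", ")),
            class = "neovax_validation_error")
    }
  }
  keys <- paste0(candidates$peptide, "|", candidates$allele)
  rank <- str_hash(keys, key = predictor$key) / .hash_mod * 100
  pinned <- match(keys, names(predictor$pins))
  rank[!is.na(pinned)] <- unname(predictor$pins[pinned[!is.na(pinned)]])
  dplyr::mutate(candidates, percentile_rank = rank,
                predictor_id = predictor$predictor_id)
}

#' Reduce scores to the best rank per MPS
#'
#' The best consensus score for a variant is the minimum percentile rank
#' over all of its scored candidates. An MPS with no candidates gets the
#' worst rank (100) and a `no_candidates` flag.
#'
#' @param mps One-row MPS tibble.
#' @param scores Scored candidates covering the MPS (class I or class II).
#' @param class Which slot to fill: `"I"` (`best_class1_rank`) or `"II"`
#'   (`best_class2_rank`).
#' @return The MPS with the best rank filled in.
#' @export
best_score_for_mps <- function(mps, scores, class = c("I", "II")) {
  class <- match.arg(class)
  own <- scores[scores$source_variant == mps$variant_id, , drop = FALSE]
  if (nrow(own) == 0) {
    best <- 100
    mps$flag <- trimws(paste(mps$flag, "no_candidates"))
  } else {
    best <- min(own$percentile_rank)
  }
  if (class == "I") mps$best_class1_rank <- best else mps$best_class2_rank <- best
  mps
}

#' Score all candidates of a patient and annotate best ranks
#'
#' Enumerates class I candidates (8-11-mers against the class I genotype)
#' and class II candidates (15-mers against the DRB genotype) for every
#' kept MPS, scores them in one pass, and fills `best_class1_rank` /
#' `best_class2_rank` with the per-variant minima.
#'
#' @param kept Candidate MPS tibble (from [extract_candidates()]).
#' @param hla_class1,hla_drb Patient allele names.
#' @param predictor Binding predictor.
#' @param class1_lengths Class I peptide lengths (default 8-11).
#' @param class2_length Class II window length (default 15).
#' @return List with annotated `candidates` and the raw `class1_scores` /
#'   `class2_scores` tables.
#' @export
score_candidates <- function(kept, hla_class1, hla_drb,
                             predictor = mock_predictor(),
                             class1_lengths = 8:11, class2_length = 15L) {
  enum_all <- function(alleles, lengths) {
    if (nrow(kept) == 0 || length(alleles) == 0) {
      return(tibble::tibble(peptide = character(0), allele = character(0),
                            length = integer(0), start = integer(0),
                            source_variant = character(0),
                            contains_mutation = logical(0)))
    }
    ws <- lapply(seq_len(nrow(kept)), function(i) {
      enum_windows(kept$sequence[i], kept$span_start[i], kept$span_end[i],
                   lengths)
    })
    n_each <- vapply(ws, function(w) length(w$peptide), integer(1))
    na <- length(alleles)
    n_tot <- sum(n_each)
    tibble::tibble(
      peptide = rep(unlist(lapply(ws, `[[`, "peptide"), use.names = FALSE),
                    each = na),
      allele = rep(alleles, times = n_tot),
      length = rep(unlist(lapply(ws, `[[`, "length"), use.names = FALSE),
                   each = na),
      start = rep(unlist(lapply(ws, `[[`, "start"), use.names = FALSE),
                  each = na),
      source_variant = rep(rep(kept$variant_id, n_each), each = na),
      contains_mutation = rep(TRUE, n_tot * na)
    )
  }
  c1 <- predict_binding(enum_all(hla_class1, class1_lengths), predictor)
  c2 <- predict_binding(enum_all(hla_drb, class2_length), predictor)
  if (nrow(kept) > 0) {
    best1 <- dplyr::summarise(dplyr::group_by(c1, .data$source_variant),
                              best = min(.data$percentile_rank))
    best2 <- dplyr::summarise(dplyr::group_by(c2, .data$source_variant),
                              best = min(.data$percentile_rank))
    kept$best_class1_rank <- best1$best[match(kept$variant_id, best1$source_variant)]
    kept$best_class2_rank <- best2$best[match(kept$variant_id, best2$source_variant)]
    no1 <- is.na(kept$best_class1_rank)
    kept$best_class1_rank[no1] <- 100
    kept$best_class2_rank[is.na(kept$best_class2_rank)] <- 100
    kept$flag[no1] <- trimws(paste(kept$flag[no1], "no_candidates"))
  }
  list(candidates = kept, class1_scores = c1, class2_scores = c2)
}

#' Write a score cache TSV
#'
#' @param scores Scored candidate tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_cache <- function(scores, path) {
  readr::write_tsv(
    scores[, c("peptide", "allele", "percentile_rank", "predictor_id")], path)
  invisible(path)
}
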