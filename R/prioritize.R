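# Tiered prioritization of annotated MPS candidates down to at most 46,
# following the printed tier order: RNA-expressed variants first (indels by
# class I rank, then SNVs at >=10 RPKM by rank, then SNVs at >=1 RPKM by
# rank, then remaining SNVs by expression), topped up with RNA-VAF-zero
# candidates when the list is short.

#' Default tier caps
#'
#' @return Named vector `c(indel = 5, hi = 20, lo = 20, total = 46)`.
#' @export
default_caps <- function() c(indel = 5L, hi = 20L, lo = 20L, total = 46L)

# Deterministic candidate ordering: primary key, then rank asc, RPKM desc,
# variant id lexicographic.
order_by_rank <- function(x) {
  x[order(x$best_class1_rank, -x$rpkm, x$variant_id), , drop = FALSE]
}
order_by_expr <- function(x) {
  x[order(-x$rpkm, x$best_class1_rank, x$variant_id), , drop = FALSE]
}

#' Prioritize MPS candidates into the tiered list
#'
#' Tiers, in order, each candidate consumed at most once:
#' \describe{
#'   \item{INDEL}{RNA-expressed (`vaf_rna > 0`) indel MPS by ascending class
#'     I rank, up to `caps["indel"]`.}
#'   \item{SNV_HI_EXPR}{RNA-expressed SNVs with RPKM >= 10 by class I rank,
#'     up to `caps["hi"]`.}
#'   \item{SNV_LO_EXPR}{RNA-expressed SNVs with RPKM >= 1 by class I rank,
#'     up to `caps["lo"]`. A >= 10 RPKM SNV that missed the HI tier on rank
#'     competes here (the expression thresholds are nested).}
#'   \item{EXPR_FILL}{Remaining RNA-expressed SNVs by descending RPKM until
#'     `caps["total"]`.}
#'   \item{VAF0_BACKFILL}{If still short, candidates with RNA VAF of zero,
#'     by class I rank then RPKM.}
#' }
#'
#' @param candidates Annotated MPS tibble (`best_class1_rank`, `rpkm`,
#'   `vaf_rna` populated).
#' @param caps Tier caps, see [default_caps()].
#' @return The input rows (at most `caps["total"]`) with `tier` and a
#'   contiguous 1-based `rank` column, in selection order.
#' @export
prioritize <- function(candidates, caps = default_caps()) {
  stopifnot(all(c("indel", "hi", "lo", "total") %in% names(caps)))
  empty <- dplyr::mutate(candidates[0, ], tier = character(0),
                         rank = integer(0))
  if (nrow(candidates) == 0) return(empty)
  stopifnot(!anyNA(candidates$best_class1_rank),
            !anyNA(candidates$rpkm), !anyNA(candidates$vaf_rna))

  taken <- character(0)
  picks <- list()
  grab <- function(pool, n, tier) {
    pool <- pool[!pool$variant_id %in% taken, , drop = FALSE]
    sel <- head(pool, max(0L, n))
    if (nrow(sel) > 0) {
      sel$tier <- tier
      taken <<- c(taken, sel$variant_id)
      picks[[length(picks) + 1L]] <<- sel
    }
    nrow(sel)
  }

  expressed <- candidates[candidates$vaf_rna > 0, , drop = FALSE]
  snv <- expressed[expressed$source_kind == "SNV", , drop = FALSE]
  total <- 0L
  total <- total + grab(order_by_rank(
    expressed[expressed$source_kind == "indel", , drop = FALSE]),
    caps[["indel"]], "INDEL")
  total <- total + grab(order_by_rank(snv[snv$rpkm >= 10, , drop = FALSE]),
                        caps[["hi"]], "SNV_HI_EXPR")
  total <- total + grab(order_by_rank(snv[snv$rpkm >= 1, , drop = FALSE]),
                        caps[["lo"]], "SNV_LO_EXPR")
  total <- total + grab(order_by_expr(snv), caps[["total"]] - total,
                        "EXPR_FILL")
  if (total < caps[["total"]]) {
    vaf0 <- candidates[candidates$vaf_rna == 0, , drop = FALSE]
    total <- total + grab(order_by_rank(vaf0), caps[["total"]] - total,
                          "VAF0_BACKFILL")
  }
  if (length(picks) == 0) return(empty)
  out <- dplyr::bind_rows(picks)
  out$rank <- seq_len(nrow(out))
  out
}

#' Write a prioritized list to TSV
#'
#' Round-trips losslessly with [read_prioritized_tsv()].
#'
#' @param prioritized Tibble from [prioritize()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prioritized_tsv <- function(prioritized, path) {
  readr::write_tsv(prioritized, path)
  invisible(path)
}

#' @rdname write_prioritized_tsv
#' @export
read_prioritized_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, na = character())
  for (col in intersect(c("span_start", "span_end", "protein_position",
                          "rank"), names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  for (col in intersect(c("incorporated_germline", "flag"), names(out))) {
    out[[col]] <- as.character(out[[col]])
  }
  out
}
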