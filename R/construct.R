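# Target selection and concatamer construct assembly. At most 20 targets
# are chosen from the prioritized list by a composite score over class I /
# class II binding, expression and DNA VAF, split across up to two mRNA
# constructs of at most 10 targets each, and fused between a secretory
# signal peptide (SEC) and the MHC class I trafficking domain (MITD) with
# 30-nt glycine/serine linkers between consecutive targets.

#' Fixed construct elements
#'
#' SEC leader (26 aa), MITD tail (55 aa), the 30-nt Gly/Ser linker and its
#' 10-residue peptide, and the 3' UTR element stored verbatim as opaque
#' metadata.
#' @name construct-elements
NULL

#' @rdname construct-elements
#' @export
SEC_PEPTIDE <- "MRVMAPRTLILLLSGALALTETWAGS"

#' @rdname construct-elements
#' @export
MITD_PEPTIDE <- "IVGIVAGLAVLAVVVIGAVVATVMCRRKSSGGKGGSYSQAASSDSAQGSDVSLTA"

#' @rdname construct-elements
#' @export
LINKER_NT <- "GGCGGCAGCGGCGGCAGCGGCGGCAGCGGC"  # encodes GGSGGSGGSG

#' @rdname construct-elements
#' @export
LINKER_PEPTIDE <- "GGSGGSGGSG"

# Vector element recorded as given, uninterpreted.
.UTR3_ELEMENT <- "LVLHARNASCPFPVLGTPSLPRPRVPGMLPPPPAPLTTSASSRHL"

#' Selection configuration
#'
#' @param max_targets Maximum targets to select (default 20).
#' @param weights Non-negative weights of the composite score over
#'   normalized class I rank, class II rank, log expression and DNA VAF.
#' @param min_neoantigens_eligibility Minimum identified neoantigens for a
#'   patient to be eligible (default 5).
#' @return A `neovax_selection_config` list.
#' @export
selection_config <- function(max_targets = 20L,
                             weights = c(class1 = 0.4, class2 = 0.2,
                                         expr = 0.25, vaf = 0.15),
                             min_neoantigens_eligibility = 5L) {
  stopifnot(max_targets >= 1)
  stopifnot(all(c("class1", "class2", "expr", "vaf") %in% names(weights)))
  if (any(weights < 0) || all(weights == 0)) {
    abort("weights must be >= 0 and not all zero", class = "neovax_config_error")
  }
  structure(list(max_targets = as.integer(max_targets), weights = weights,
                 min_neoantigens_eligibility = as.integer(min_neoantigens_eligibility)),
            class = "neovax_selection_config")
}

#' Patient eligibility by identified neoantigen count
#'
#' @param candidate_count Number of identified neoantigen candidates.
#' @param min_neoantigens Eligibility threshold (default 5).
#' @return `TRUE` iff `candidate_count >= min_neoantigens`.
#' @export
check_eligibility <- function(candidate_count, min_neoantigens = 5L) {
  stopifnot(candidate_count >= 0)
  candidate_count >= min_neoantigens
}

#' Select up to 20 targets from the prioritized list
#'
#' Composite score per entry: weighted sum of `(100 - class I rank)/100`,
#' `(100 - class II rank)/100`, `log10(1 + RPKM)` scaled to the input
#' maximum, and DNA VAF. Ties break on prioritization rank, so selection is
#' deterministic.
#'
#' @param prioritized Tibble from [prioritize()].
#' @param config A [selection_config()].
#' @return At most `max_targets` rows with `selection_score` and
#'   `selection_rank`, in descending score order.
#' @export
select_targets <- function(prioritized, config = selection_config()) {
  if (nrow(prioritized) == 0) {
    return(dplyr::mutate(prioritized, selection_score = numeric(0),
                         selection_rank = integer(0)))
  }
  w <- config$weights
  expr_max <- max(log10(1 + prioritized$rpkm), 1e-12)
  score <- w[["class1"]] * (100 - prioritized$best_class1_rank) / 100 +
    w[["class2"]] * (100 - prioritized$best_class2_rank) / 100 +
    w[["expr"]] * log10(1 + prioritized$rpkm) / expr_max +
    w[["vaf"]] * prioritized$vaf_dna
  out <- prioritized
  out$selection_score <- score
  out <- out[order(-out$selection_score, out$rank), , drop = FALSE]
  out <- head(out, config$max_targets)
  out$selection_rank <- seq_len(nrow(out))
  out
}

#' Partition selected targets across up to two constructs
#'
#' Up to 10 targets fit a single construct; larger selections alternate
#' across two constructs in selection order, giving groups of size
#' `ceiling(n/2)` and `floor(n/2)`.
#'
#' @param selected Tibble from [select_targets()] (1-20 rows).
#' @return Named list of 1 or 2 tibbles (`RNA1`, `RNA2`).
#' @export
partition_targets <- function(selected) {
  n <- nrow(selected)
  if (n < 1 || n > 20) {
    abort("partition_targets requires 1-20 targets", class = "neovax_input_error")
  }
  if (n <= 10) return(list(RNA1 = selected))
  odd <- seq_len(n) %% 2L == 1L
  list(RNA1 = selected[odd, , drop = FALSE],
       RNA2 = selected[!odd, , drop = FALSE])
}

#' Assemble a concatamer construct from one target group
#'
#' Protein layout: `SEC + target1 + L + target2 + ... + targetN + MITD`
#' where `L` is the 10-residue Gly/Ser linker; linkers sit between
#' consecutive targets only (SEC and MITD are direct-fused). The
#' nucleotide sequence is a deterministic reverse translation with a fixed
#' codon per amino acid; the linker region is exactly the configured 30-nt
#' sequence, so the standard-table translation of the nucleotide sequence
#' reproduces the protein.
#'
#' @param group Tibble of targets (uses `sequence` and `variant_id`).
#' @param construct_id `"RNA1"` or `"RNA2"`.
#' @param linker_nt 30-nt glycine/serine linker.
#' @return A `neovax_construct` list with protein and nucleotide sequences.
#' @export
assemble_construct <- function(group, construct_id = "RNA1",
                               linker_nt = LINKER_NT) {
  if (nrow(group) == 0) {
    abort("cannot assemble an empty construct", class = "neovax_input_error")
  }
  if (nrow(group) > 10) {
    abort("a construct carries at most 10 targets", class = "neovax_input_error")
  }
  stopifnot(nchar(linker_nt) == 30L)
  linker_pep <- sub("\\*$", "", translate_nt(linker_nt))
  targets <- group$sequence
  protein <- paste0(SEC_PEPTIDE,
                    paste(targets, collapse = linker_pep),
                    MITD_PEPTIDE)
  nt_targets <- vapply(targets, reverse_translate, character(1),
                       USE.NAMES = FALSE)
  nucleotide <- paste0(reverse_translate(SEC_PEPTIDE),
                       paste(nt_targets, collapse = linker_nt),
                       reverse_translate(MITD_PEPTIDE))
  structure(list(
    construct_id = construct_id,
    target_ids = group$variant_id,
    tiers = if ("tier" %in% names(group)) group$tier
            else rep(NA_character_, nrow(group)),
    n_targets = nrow(group),
    sec_peptide = SEC_PEPTIDE,
    mitd_peptide = MITD_PEPTIDE,
    linker_nt = linker_nt,
    protein_sequence = protein,
    nucleotide_sequence = nucleotide,
    metadata = c(utr3_element = .UTR3_ELEMENT)
  ), class = "neovax_construct")
}

#' Write constructs to FASTA (protein and nucleotide records)
#'
#' @param constructs List of `neovax_construct` objects.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_construct_fasta <- function(constructs, path) {
  recs <- character(0)
  for (cs in constructs) {
    hdr <- paste0(cs$construct_id, " targets=",
                  paste(cs$target_ids, collapse = ","))
    recs <- c(recs,
              setNames(cs$protein_sequence, paste0(hdr, " type=protein")),
              setNames(cs$nucleotide_sequence, paste0(hdr, " type=nucleotide")))
  }
  writeLines(paste0(">", names(recs), "\n", unname(recs)), path)
  invisible(path)
}

#' @export
print.neovax_construct <- function(x, ...) {
  cat("<neovax_construct> ", x$construct_id, ": ", x$n_targets, " targets, ",
      nchar(x$protein_sequence), " aa / ", nchar(x$nucleotide_sequence),
      " nt\n", sep = "")
  invisible(x)
}
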