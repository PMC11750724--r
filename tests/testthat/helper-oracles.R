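# Independent oracles: straight-line implementations kept deliberately
# different in style (base R, character vectors, explicit loops) from the
# package code paths they check.

# Slice-and-substitute oracle for substitution windows.
oracle_snv_window <- function(protein, pos, alt_aa, flank = 13) {
  chars <- strsplit(protein, "")[[1]]
  chars[pos] <- alt_aa
  lo <- max(1, pos - flank)
  hi <- min(length(chars), pos + flank)
  list(sequence = paste(chars[lo:hi], collapse = ""),
       span = c(pos - lo + 1, pos - lo + 1))
}

# Standard-table translation through Biostrings (the package's own
# translator is a plain codon-table lookup).
oracle_translate <- function(nt) {
  nt <- substr(nt, 1, 3 * (nchar(nt) %/% 3))
  as.character(Biostrings::translate(Biostrings::DNAString(nt)))
}

# Frameshift oracle: edit the CDS, translate with Biostrings, walk to the
# first changed residue and cut at the first downstream stop.
oracle_frameshift_mps <- function(cds, pos, ref_nt, alt_nt, flank = 13) {
  mutated <- paste0(substr(cds, 1, pos - 1), alt_nt,
                    substr(cds, pos + nchar(ref_nt), nchar(cds)))
  wt <- sub("\\*.*$", "", oracle_translate(cds))
  mut <- oracle_translate(mutated)
  stop_i <- regexpr("*", mut, fixed = TRUE)
  if (stop_i > 0) mut <- substr(mut, 1, stop_i - 1)
  wt_c <- strsplit(wt, "")[[1]]
  mut_c <- strsplit(mut, "")[[1]]
  d <- 1
  while (d <= min(length(wt_c), length(mut_c)) && wt_c[d] == mut_c[d]) d <- d + 1
  if (d > length(mut_c)) return(NULL)  # no novel residue before the stop
  lo <- max(1, d - flank)
  list(sequence = paste(mut_c[lo:length(mut_c)], collapse = ""),
       first_changed = d, prefix_len = d - lo)
}

# Literal rule-by-rule prioritization oracle: plain data frames, order(),
# explicit tier loops.
oracle_prioritize <- function(cand, caps = c(indel = 5, hi = 20, lo = 20,
                                             total = 46)) {
  df <- as.data.frame(cand)
  by_rank <- function(x) x[order(x$best_class1_rank, -x$rpkm, x$variant_id), ]
  by_expr <- function(x) x[order(-x$rpkm, x$best_class1_rank, x$variant_id), ]
  picked <- data.frame()
  add <- function(pool, n, tier) {
    pool <- pool[!(pool$variant_id %in% picked$variant_id), ]
    n <- max(0, min(n, nrow(pool)))
    if (n > 0) {
      sel <- pool[seq_len(n), ]
      sel$tier <- tier
      picked <<- rbind(picked, sel)
    }
  }
  expressed <- df[df$vaf_rna > 0, ]
  add(by_rank(expressed[expressed$source_kind == "indel", ]),
      caps[["indel"]], "INDEL")
  snv <- expressed[expressed$source_kind == "SNV", ]
  add(by_rank(snv[snv$rpkm >= 10, ]), caps[["hi"]], "SNV_HI_EXPR")
  add(by_rank(snv[snv$rpkm >= 1, ]), caps[["lo"]], "SNV_LO_EXPR")
  add(by_expr(snv), caps[["total"]] - nrow(picked), "EXPR_FILL")
  if (nrow(picked) < caps[["total"]]) {
    add(by_rank(df[df$vaf_rna == 0, ]), caps[["total"]] - nrow(picked),
        "VAF0_BACKFILL")
  }
  picked
}

# Random annotated candidate tables for prioritization property tests;
# regimes force ties, zero VAFs, and expression atoms at the tier edges.
random_candidates <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      variant_id = sprintf("V%04d", sample(9999, n)),
      source_kind = sample(c("SNV", "indel"), n, replace = TRUE,
                           prob = c(0.85, 0.15)),
      sequence = vapply(seq_len(n), function(i) {
        paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"),
                     27, replace = TRUE), collapse = "")
      }, character(1)),
      span_start = 14L, span_end = 14L,
      rpkm = sample(c(0, 0.5, 1, 5, 10, 50, 200), n, replace = TRUE),
      vaf_rna = sample(c(0, 0.1, 0.4), n, replace = TRUE,
                       prob = c(0.3, 0.4, 0.3)),
      vaf_dna = round(runif(n), 3),
      best_class1_rank = sample(c(0.5, 2, 2, 7, 15, 40, 80), n, replace = TRUE),
      best_class2_rank = round(runif(n, 0, 100), 2),
      tier = NA_character_
    )
  })
}
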