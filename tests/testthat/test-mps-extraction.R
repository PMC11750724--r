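test_that("substitution windows follow the 13+13 rule with end truncation", {
  prot <- rand_protein(300, seed = 1)
  mid <- make_variant(protein_position = 100L,
                      ref_aa = substr(prot, 100, 100), alt_aa = "W")
  mps <- extract_mps_snv(mid, prot)
  expect_identical(nchar(mps$sequence), 27L)
  expect_identical(c(mps$span_start, mps$span_end), c(14L, 14L))
  expect_identical(substr(mps$sequence, 14, 14), "W")

  nterm <- make_variant(protein_position = 1L, ref_aa = substr(prot, 1, 1),
                        alt_aa = "W")
  mps1 <- extract_mps_snv(nterm, prot)
  expect_identical(nchar(mps1$sequence), 14L)
  expect_identical(c(mps1$span_start, mps1$span_end), c(1L, 1L))

  near_c <- make_variant(protein_position = 295L,
                         ref_aa = substr(prot, 295, 295), alt_aa = "W")
  mps2 <- extract_mps_snv(near_c, prot)
  orc <- oracle_snv_window(prot, 295, "W")
  expect_identical(nchar(mps2$sequence), 19L)
  expect_identical(mps2$sequence, orc$sequence)
  expect_identical(c(mps2$span_start, mps2$span_end), as.integer(orc$span))
})

test_that("substitution windows equal the slice oracle at every position", {
  for (seed in 1:3) {
    n <- c(25, 80, 200)[seed]
    prot <- rand_protein(n, seed = seed)
    for (pos in seq_len(n)) {
      ref <- substr(prot, pos, pos)
      alt <- if (ref == "W") "Y" else "W"
      v <- make_variant(protein_position = as.integer(pos), ref_aa = ref,
                        alt_aa = alt)
      mps <- extract_mps_snv(v, prot)
      orc <- oracle_snv_window(prot, pos, alt)
      expect_identical(mps$sequence, orc$sequence)
      expect_identical(c(mps$span_start, mps$span_end), as.integer(orc$span))
    }
  }
})

test_that("window property: undoing the substitution gives a protein substring", {
  prot <- rand_protein(120, seed = 4)
  for (pos in c(1, 2, 13, 14, 60, 107, 119, 120)) {
    ref <- substr(prot, pos, pos)
    alt <- if (ref == "H") "K" else "H"
    mps <- extract_mps_snv(make_variant(protein_position = as.integer(pos),
                                        ref_aa = ref, alt_aa = alt), prot)
    undone <- mps$sequence
    substr(undone, mps$span_start, mps$span_start) <- ref
    expect_true(grepl(undone, prot, fixed = TRUE))
  }
})

test_that("reference mismatches are rejected", {
  prot <- rand_protein(50, seed = 2)
  wrong_ref <- if (substr(prot, 20, 20) == "A") "C" else "A"
  expect_error(
    extract_mps_snv(make_variant(protein_position = 20L, ref_aa = wrong_ref,
                                 alt_aa = "W"), prot),
    class = "neovax_reference_mismatch")
})

test_that("frameshift MPS equals translation of the edited CDS to the next stop", {
  prot <- rand_protein(80, seed = 6)
  cds <- paste0(aa2nt(prot), "TAA")
  # 1-nt deletion at codon 30 (anchor at nt 88 deletes nt 89)
  v <- make_variant(id = "FS1", kind = "deletion", cds_pos = 88L,
                    ref_nt = substr(cds, 88, 89),
                    alt_nt = substr(cds, 88, 88), consequence = "frameshift")
  mps <- suppressWarnings(extract_mps_frameshift(v, cds))
  orc <- oracle_frameshift_mps(cds, 88, substr(cds, 88, 89),
                               substr(cds, 88, 88))
  expect_identical(mps$sequence, orc$sequence)
  expect_identical(mps$span_start, as.integer(orc$prefix_len + 1))
  expect_identical(mps$protein_position, as.integer(orc$first_changed))
  expect_false(grepl("*", mps$sequence, fixed = TRUE))
})

test_that("frameshift whose first novel codon is a stop is flagged null neo-ORF", {
  # K at position 21 has codon AAA (nt 61-63); a 1-nt T insertion after
  # nt 60 makes the first shifted codon read TAA: the neo-ORF is empty.
  prot <- paste0(rand_protein(20, seed = 8), "KLIE")
  cds <- paste0(aa2nt(prot), "TAA")
  stopifnot(substr(cds, 61, 63) == "AAA")
  v <- make_variant(id = "FS0", kind = "insertion", cds_pos = 60L,
                    ref_nt = substr(cds, 60, 60),
                    alt_nt = paste0(substr(cds, 60, 60), "T"),
                    consequence = "frameshift")
  mps <- extract_mps_frameshift(v, cds)
  expect_identical(mps$flag, "null_neo_ORF")
  expect_identical(mps$sequence, "")
  expect_identical(filter_candidates(mps)$dropped$reason, "null neo-ORF")
  expect_null(oracle_frameshift_mps(cds, 60, substr(cds, 60, 60),
                                    paste0(substr(cds, 60, 60), "T")))
})

test_that("random frameshifts agree with the translation oracle", {
  prot <- rand_protein(150, seed = 10)
  cds <- paste0(aa2nt(prot), "TAA")
  set.seed(99)
  for (i in 1:25) {
    pos <- sample(6:(nchar(cds) - 60), 1)
    if (i %% 2 == 0) {
      ref <- substr(cds, pos, pos + sample(1:2, 1))
      alt <- substr(cds, pos, pos)
      kind <- "deletion"
    } else {
      ref <- substr(cds, pos, pos)
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), sample(1:2, 1),
                                      replace = TRUE), collapse = ""))
      kind <- "insertion"
    }
    v <- make_variant(id = sprintf("FS%d", i), kind = kind,
                      cds_pos = as.integer(pos), ref_nt = ref, alt_nt = alt,
                      consequence = "frameshift")
    mps <- suppressWarnings(extract_mps_frameshift(v, cds))
    orc <- oracle_frameshift_mps(cds, pos, ref, alt)
    if (is.null(orc)) {
      expect_identical(mps$flag, "null_neo_ORF")
    } else {
      expect_identical(mps$sequence, orc$sequence)
    }
  }
})

test_that("in-frame single-residue insertion gets a 13+1+13 window", {
  prot <- rand_protein(100, seed = 12)
  cds <- paste0(aa2nt(prot), "TAA")
  # Insert codon for W after codon 50 (nt 150).
  v <- make_variant(id = "IF1", kind = "insertion", cds_pos = 150L,
                    ref_nt = substr(cds, 150, 150),
                    alt_nt = paste0(substr(cds, 150, 150), "TGG"),
                    consequence = "inframe_indel")
  mps <- extract_mps_frameshift(v, cds)
  expect_identical(nchar(mps$sequence), 27L)
  expect_identical(c(mps$span_start, mps$span_end), c(14L, 14L))
  expect_identical(substr(mps$sequence, 14, 14), "W")
  # window flanks are wild-type protein around the insertion point
  expect_identical(substr(mps$sequence, 1, 13), substr(prot, 38, 50))
  expect_identical(substr(mps$sequence, 15, 27), substr(prot, 51, 63))
})

test_that("read-through frameshifts are truncated at the CDS end and flagged", {
  prot <- rand_protein(30, seed = 14)
  cds <- paste0(aa2nt(prot), "TAA")
  # Find a frameshift with no downstream stop: delete 1 nt near the end.
  pos <- nchar(cds) - 7L
  v <- make_variant(id = "RT1", kind = "deletion", cds_pos = pos,
                    ref_nt = substr(cds, pos, pos + 1),
                    alt_nt = substr(cds, pos, pos),
                    consequence = "frameshift")
  mps <- withCallingHandlers(
    extract_mps_frameshift(v, cds),
    warning = function(w) invokeRestart("muffleWarning"))
  expect_true(mps$flag %in% c("read_through", "null_neo_ORF", ""))
})

test_that("in-phase germline variants are substituted into the window", {
  prot <- rand_protein(60, seed = 16)
  pos <- 30L
  ref <- substr(prot, pos, pos)
  alt <- if (ref == "D") "E" else "D"
  mps <- extract_mps_snv(make_variant(protein_position = pos, ref_aa = ref,
                                      alt_aa = alt), prot)
  g_pos <- 25L
  g_ref <- substr(prot, g_pos, g_pos)
  g_alt <- if (g_ref == "Q") "N" else "Q"
  germ <- tibble::tibble(
    id = "G1", transcript_id = "TX001", protein_position = g_pos,
    ref_aa = g_ref, alt_aa = g_alt, is_protein_changing = TRUE,
    somatic_id = "V1", cis_reads = 10L, trans_reads = 0L)

  out <- phase_and_incorporate(mps, germ)
  w <- g_pos - (pos - 13L) + 1L
  expect_identical(substr(out$sequence, w, w), g_alt)
  expect_identical(out$incorporated_germline, "G1")

  out_of_phase <- dplyr::mutate(germ, cis_reads = 0L, trans_reads = 12L)
  out2 <- phase_and_incorporate(mps, out_of_phase)
  expect_identical(out2$sequence, mps$sequence)
  expect_identical(out2$incorporated_germline, "")
})

test_that("multiple in-phase germline edits equal sequential application", {
  prot <- rand_protein(60, seed = 18)
  pos <- 30L
  ref <- substr(prot, pos, pos)
  mps <- extract_mps_snv(make_variant(protein_position = pos, ref_aa = ref,
                                      alt_aa = if (ref == "A") "G" else "A"),
                         prot)
  g <- tibble::tibble(
    id = c("G1", "G2"), transcript_id = "TX001",
    protein_position = c(36L, 22L),
    ref_aa = c(substr(prot, 36, 36), substr(prot, 22, 22)),
    alt_aa = c("W", "W"), is_protein_changing = TRUE,
    somatic_id = "V1", cis_reads = c(8L, 20L), trans_reads = c(1L, 0L))
  out <- phase_and_incorporate(mps, g)
  # independent apply-edits oracle on the window characters
  chars <- strsplit(mps$sequence, "")[[1]]
  for (gp in sort(g$protein_position)) {
    chars[gp - (pos - 13L) + 1L] <- "W"
  }
  expect_identical(out$sequence, paste(chars, collapse = ""))
  expect_setequal(strsplit(out$incorporated_germline, ",")[[1]], c("G1", "G2"))
})

test_that("germline colliding with the somatic residue is skipped, somatic wins", {
  prot <- rand_protein(60, seed = 20)
  pos <- 30L
  ref <- substr(prot, pos, pos)
  alt <- if (ref == "F") "L" else "F"
  mps <- extract_mps_snv(make_variant(protein_position = pos, ref_aa = ref,
                                      alt_aa = alt), prot)
  g <- tibble::tibble(id = "G1", transcript_id = "TX001",
                      protein_position = pos, ref_aa = ref, alt_aa = "Y",
                      is_protein_changing = TRUE, somatic_id = "V1",
                      cis_reads = 15L, trans_reads = 0L)
  expect_warning(out <- phase_and_incorporate(mps, g), "collides")
  expect_identical(substr(out$sequence, 14, 14), alt)
  expect_identical(out$incorporated_germline, "")
})

test_that("phasing is monotone in cis read support", {
  prot <- rand_protein(60, seed = 22)
  pos <- 30L
  ref <- substr(prot, pos, pos)
  mps <- extract_mps_snv(make_variant(protein_position = pos, ref_aa = ref,
                                      alt_aa = if (ref == "C") "S" else "C"),
                         prot)
  g0 <- tibble::tibble(id = "G1", transcript_id = "TX001",
                       protein_position = 26L,
                       ref_aa = substr(prot, 26, 26), alt_aa = "W",
                       is_protein_changing = TRUE, somatic_id = "V1",
                       cis_reads = 2L, trans_reads = 0L)
  incorporated_at <- function(cis) {
    g <- dplyr::mutate(g0, cis_reads = as.integer(cis))
    nchar(phase_and_incorporate(mps, g)$incorporated_germline) > 0
  }
  states <- vapply(c(0, 1, 2, 5, 20, 100), incorporated_at, logical(1))
  expect_identical(states, c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
})

test_that("filtering drops with reasons and conserves the partition", {
  cands <- dplyr::bind_rows(
    make_mps("A", variant_id = "K1", rpkm = 10),
    make_mps("A", variant_id = "K2", rpkm = 1),
    make_mps("A", variant_id = "D1", rpkm = 0),
    dplyr::mutate(make_mps("A", variant_id = "D2"), consequence = "synonymous"),
    dplyr::mutate(make_mps("A", variant_id = "D3"), consequence = "nonsense"),
    dplyr::mutate(make_mps("A", variant_id = "D4"), consequence = "stop_loss"),
    dplyr::mutate(make_mps("", variant_id = "D5", source_kind = "indel"),
                  consequence = "frameshift", flag = "null_neo_ORF"),
    make_mps("A", variant_id = "K3"),
    make_mps("A", variant_id = "K4"),
    dplyr::mutate(make_mps("A", variant_id = "D6"), consequence = "start_loss"))
  fl <- filter_candidates(cands)
  expect_identical(nrow(fl$kept) + nrow(fl$dropped), 10L)
  expect_setequal(fl$kept$variant_id, c("K1", "K2", "K3", "K4"))
  reasons <- setNames(fl$dropped$reason, fl$dropped$variant_id)
  expect_identical(reasons[["D1"]], "non-expressed")
  expect_identical(reasons[["D2"]], "synonymous")
  expect_identical(reasons[["D3"]], "nonsense")
  expect_identical(reasons[["D4"]], "stop-loss")
  expect_identical(reasons[["D5"]], "null neo-ORF")
  expect_identical(reasons[["D6"]], "start-loss")
  expect_length(intersect(fl$kept$variant_id, fl$dropped$variant_id), 0)
})
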