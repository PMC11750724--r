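make_sample <- function(junctions, counts, v = NULL, j = NULL) {
  tibble::tibble(
    junction_aa = junctions,
    v_call = if (is.null(v)) NA_character_ else v,
    j_call = if (is.null(j)) NA_character_ else j,
    duplicate_count = counts)
}

make_specific <- function(junctions, spec = "NEO1", ids = NULL) {
  tibble::tibble(
    tcr_id = ids %||% sprintf("TCR%02d", seq_along(junctions)),
    junction_aa = junctions,
    specificity = rep_len(spec, length(junctions)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("the Jurkat reporter call applies the twofold cutoff", {
  hit <- jurkat_specificity_call(2000, 800)
  expect_identical(hit$fold, 2.5)
  expect_true(hit$validated)

  near <- jurkat_specificity_call(1590, 800)
  expect_identical(near$fold, 1.9875)
  expect_false(near$validated)

  flat <- jurkat_specificity_call(800, 800)
  expect_identical(flat$fold, 1.0)
  expect_false(flat$validated)

  boundary <- jurkat_specificity_call(1600, 800)
  expect_true(boundary$validated)

  expect_error(jurkat_specificity_call(1000, 0),
               class = "neovax_assay_error")
})

test_that("tracking computes exact-match frequencies with zeros for misses", {
  sample <- make_sample(c("CASSX1F", "CASSX2F", "CASSX3F"),
                        c(50, 450, 500))
  sp <- make_specific(c("CASSX1F", "CASSABSENTF"))
  out <- track_clonotypes(sp, sample)
  expect_identical(out$frequency, c(0.05, 0))
  expect_identical(out$duplicate_count, c(50, 0))
})

test_that("V/J gene calls restrict matches only when both sides carry them", {
  sample <- make_sample(c("CASSX1F", "CASSX1F"), c(10, 30),
                        v = c("TRBV5", "TRBV9"), j = c("TRBJ1-1", "TRBJ1-1"))
  no_genes <- make_specific("CASSX1F")
  expect_identical(track_clonotypes(no_genes, sample)$duplicate_count, 40)

  with_genes <- dplyr::mutate(make_specific("CASSX1F"),
                              v_call = "TRBV5", j_call = "TRBJ1-1")
  expect_identical(track_clonotypes(with_genes, sample)$duplicate_count, 10)
})

test_that("tracking a large sample equals the set-intersection oracle", {
  withr::with_seed(90, {
    junctions <- unique(replicate(11000, paste0(
      "CASS", paste(sample(LETTERS[1:20], 7, TRUE), collapse = ""), "F")))
    n <- 10000
    sample <- make_sample(junctions[seq_len(n)],
                          sample(1:1000, n, replace = TRUE))
    present <- sample(junctions[seq_len(n)], 18)
    absent <- junctions[(n + 1):(n + 12)]
    sp <- make_specific(c(present, absent))
  })
  out <- track_clonotypes(sp, sample)
  # nested-loop / set-arithmetic oracle
  expect_setequal(sp$junction_aa[out$frequency > 0],
                  intersect(sp$junction_aa, sample$junction_aa))
  total <- sum(sample$duplicate_count)
  for (k in seq_len(nrow(sp))) {
    expect_identical(out$frequency[k],
                     sum(sample$duplicate_count[
                       sample$junction_aa == sp$junction_aa[k]]) / total)
  }
})

test_that("cumulative frequency is additive across specificities", {
  sample <- make_sample(c("CASSA1F", "CASSA2F", "CASSBGF", "CASSZZF"),
                        c(100, 100, 300, 9500))
  sp <- dplyr::bind_rows(
    make_specific(c("CASSA1F", "CASSA2F"), spec = "NEO1",
                  ids = c("T1", "T2")),
    make_specific("CASSBGF", spec = "NEO2", ids = "T3"),
    make_specific("CASSNOPEF", spec = "NEO3", ids = "T4"))
  cf <- cumulative_frequency(sp, sample)
  expect_equal(cf$cumulative, 0.05)
  per <- setNames(cf$per_specificity$frequency, cf$per_specificity$specificity)
  expect_equal(per[["NEO1"]], 0.02)
  expect_equal(per[["NEO2"]], 0.03)
  expect_identical(per[["NEO3"]], 0)
  expect_identical(cf$n_tcrs, 3L)
  expect_identical(cf$n_neoantigens, 2L)
  expect_equal(cf$cumulative, sum(cf$per_specificity$frequency))

  disjoint <- cumulative_frequency(make_specific("CASSQQF"), sample)
  expect_identical(disjoint$cumulative, 0)
})

test_that("tracking is idempotent and order-independent", {
  sample <- make_sample(sprintf("CASS%dF", 1:50), rep(20, 50))
  sp <- make_specific(sprintf("CASS%dF", c(3, 7, 99)))
  a <- track_clonotypes(sp, sample)
  b <- track_clonotypes(sp, sample[sample(nrow(sample)), ])
  expect_identical(a$frequency, b$frequency)
  expect_identical(track_clonotypes(sp, sample)$frequency, a$frequency)
})

test_that("baseline classification separates de novo from preexisting", {
  base <- make_sample(c("CASSPREF", "CASSOTHF"), c(3, 997))
  sp <- make_specific(c("CASSNEWF", "CASSPREF"), ids = c("T1", "T2"))
  out <- classify_baseline_status(sp, base)
  expect_identical(out$status, c("de_novo", "preexisting"))
  expect_identical(out$baseline_count, c(0, 3))

  unknown <- classify_baseline_status(sp, NULL)
  expect_true(all(unknown$status == "unknown"))

  # threshold: at 3 reads the preexisting clone falls under detection
  lax <- classify_baseline_status(sp, base, detection_threshold = 3)
  expect_identical(lax$status, c("de_novo", "de_novo"))
})

test_that("a planted de novo fraction is recovered exactly at zero noise", {
  # plant 99 of 140 specific TCRs as baseline-undetectable
  withr::with_seed(91, {
    sp <- make_specific(sprintf("CASSP%03dF", 1:140))
    de_novo_idx <- sample(140, 99)
  })
  base_junctions <- c(sp$junction_aa[-de_novo_idx],
                      sprintf("CASSBG%03dF", 1:500))
  base <- make_sample(base_junctions, rep(10, length(base_junctions)))
  out <- classify_baseline_status(sp, base)
  expect_identical(sum(out$status == "de_novo"), 99L)
  expect_identical(sum(out$status == "preexisting"), 41L)
})

test_that("biopsy overlap is symmetric and matches set arithmetic", {
  a <- make_sample(sprintf("CASS%dF", 1:30), rep(10, 30))
  sp <- make_specific(sprintf("CASS%dF", c(1:10, 100:104)))
  same <- biopsy_overlap(a, a, sp)
  expect_identical(same$jaccard, 1.0)

  b <- make_sample(sprintf("CASS%dF", 31:60), rep(10, 30))
  none <- biopsy_overlap(a, b, sp)
  expect_identical(none$jaccard, 0)

  withr::with_seed(92, {
    keep <- sort(sample(30, 12))
  })
  c_s <- a[keep, ]
  ov <- biopsy_overlap(a, c_s, sp)
  in_a <- intersect(sp$junction_aa, a$junction_aa)
  in_c <- intersect(sp$junction_aa, c_s$junction_aa)
  expect_identical(ov$jaccard,
                   length(intersect(in_a, in_c)) / length(union(in_a, in_c)))
  rev <- biopsy_overlap(c_s, a, sp)
  expect_identical(ov$jaccard, rev$jaccard)
  expect_setequal(ov$shared, rev$shared)
})

test_that("cumulative frequency never exceeds one on real samples", {
  dp <- designed_patient()
  ad <- generate_assay_data(dp$patient, dp$report$selected$variant_id,
                            seed = 5, noise = 1)
  for (sid in unique(ad$repertoire$sample_id)) {
    s <- ad$repertoire[ad$repertoire$sample_id == sid, ]
    cf <- cumulative_frequency(ad$specific_tcrs, s)
    expect_lte(cf$cumulative, 1)
    expect_equal(cf$cumulative, sum(cf$per_specificity$frequency))
  }
})
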