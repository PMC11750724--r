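# Synthetic downstream assay data for a designed patient: ELISpot spot
# counts per target per timepoint, bulk CDR3-beta repertoires for blood and
# tumor with planted specific clonotypes, and a Jurkat reporter table.

#' Assay generation parameters
#'
#' @param background_spots Mean background/control spot count per well.
#' @param response_spots Mean stimulated spot count of an immunogenic
#'   target after treatment.
#' @param preexisting_spots Mean baseline stimulated count of a preexisting
#'   response.
#' @param positive_control_spots Mean anti-CD3 positive-control count.
#' @param n_replicates Replicate wells per condition.
#' @param repertoire_depth Reads per repertoire sample.
#' @param n_background_clonotypes Background clonotypes per compartment.
#' @param specific_blood_freq Planted cumulative frequency of specific
#'   clonotypes in post-induction blood CD8 (default 0.073).
#' @param tumor_specific_freq Planted cumulative frequency of trafficked
#'   specific clonotypes among tumor CD8 clonotypes (default 0.01).
#' @param baseline_preexisting_freq Baseline frequency of each preexisting
#'   specific clonotype.
#' @param trafficking_frac Fraction of blood specific clonotypes also
#'   planted in the tumor (default 0.84).
#' @param tcrs_per_target_max Maximum specific TCRs planted per
#'   immunogenic target.
#' @param decoy_tcr_frac Extra non-specific TCR candidates added to the
#'   Jurkat screen, as a fraction of true specific TCRs.
#' @param baseline_day,post_day,tumor_day Sample timepoints (days from
#'   treatment start; negative = screening).
#' @return A named list of parameters.
#' @export
assay_params <- function(background_spots = 4,
                         response_spots = 60,
                         preexisting_spots = 20,
                         positive_control_spots = 500,
                         n_replicates = 3L,
                         repertoire_depth = 50000L,
                         n_background_clonotypes = 2000L,
                         specific_blood_freq = 0.073,
                         tumor_specific_freq = 0.01,
                         baseline_preexisting_freq = 0.002,
                         trafficking_frac = 0.84,
                         tcrs_per_target_max = 4L,
                         decoy_tcr_frac = 0.3,
                         baseline_day = -7L, post_day = 42L,
                         tumor_day = 42L) {
  as.list(environment())
}

random_junction <- function(n) {
  len <- sample(6:14, n, replace = TRUE)
  vapply(len, function(k) {
    paste0("CASS", paste(sample(.AA20, k, replace = TRUE), collapse = ""), "F")
  }, character(1))
}

#' Generate synthetic assay datasets for a designed patient
#'
#' Produces the downstream monitoring inputs consistent with the patient's
#' truth labels: immunogenic targets receive post-treatment spot counts
#' well above the twofold-call threshold (preexisting ones also elevated
#' at baseline), non-immunogenic targets are indistinguishable from
#' control; blood and tumor repertoires contain planted specific CDR3-beta
#' clonotypes (absent at baseline when the truth is de novo), and a Jurkat
#' reporter table validates the planted TCRs. With `noise = 0` all counts
#' are deterministic expectations, so downstream calling recovers the
#' planted truth exactly.
#'
#' @param patient A `neovax_patient`.
#' @param selected_targets Character vector of selected variant ids (must
#'   be a subset of the patient's somatic variant ids).
#' @param seed Integer seed for this patient's assay substream.
#' @param noise 1 = Poisson/multinomial sampling, 0 = deterministic
#'   expectations.
#' @param params [assay_params()].
#' @return List with `elispot`, `repertoire`, `jurkat` tibbles and the
#'   `specific_tcrs` truth table.
#' @export
generate_assay_data <- function(patient, selected_targets, seed = 1,
                                noise = 1, params = assay_params()) {
  unknown <- setdiff(selected_targets, patient$somatic_variants$id)
  if (length(unknown) > 0) {
    abort(paste0("targets not in patient: ", paste(unknown, collapse = ", ")),
          class = "neovax_input_error")
  }
  truth <- patient$truth
  info <- tibble::tibble(target_id = selected_targets)
  info$immunogenic <- info$target_id %in% truth$variant_id[truth$immunogenic]
  m <- match(info$target_id, truth$variant_id)
  info$phenotype <- ifelse(is.na(m), "n/a", truth$phenotype[m])
  info$preexisting <- !is.na(m) & truth$preexisting[m]

  withr::with_seed(derive_seed(seed, paste0("assay/", patient$patient_id)), {
    elispot <- simulate_elispot(patient$patient_id, info, noise, params)
    rep_out <- simulate_repertoires(patient$patient_id, info, noise, params)
    jurkat <- simulate_jurkat(rep_out$specific_tcrs, noise, params)
    list(elispot = elispot, repertoire = rep_out$repertoire,
         jurkat = jurkat, specific_tcrs = rep_out$specific_tcrs)
  })
}

simulate_elispot <- function(patient_id, info, noise, params) {
  grid <- expand.grid(gi = 1:3, timepoint = c("baseline", "post_induction"),
                      stringsAsFactors = FALSE)
  grid$assay <- c("ex_vivo", "post_IVS", "post_IVS")[grid$gi]
  grid$compartment <- c("bulk", "CD4", "CD8")[grid$gi]
  nt <- nrow(info)
  blocks <- lapply(seq_len(nrow(grid)), function(i) {
    comp <- grid$compartment[i]
    tp <- grid$timepoint[i]
    responds <- info$immunogenic & switch(comp,
      bulk = TRUE,
      CD4 = info$phenotype %in% c("CD4_only", "CD4_and_CD8"),
      CD8 = info$phenotype %in% c("CD8_only", "CD4_and_CD8"))
    lam_t <- ifelse(!responds, params$background_spots,
                    ifelse(tp == "baseline",
                           ifelse(info$preexisting, params$preexisting_spots,
                                  params$background_spots),
                           params$response_spots))
    list(timepoint = rep(tp, nt + 2L),
         assay = rep(grid$assay[i], nt + 2L),
         compartment = rep(comp, nt + 2L),
         target_id = c("", "", info$target_id),
         condition = c("control", "positive_control", rep("stimulated", nt)),
         lambda = c(params$background_spots, params$positive_control_spots,
                    lam_t))
  })
  cat_f <- function(f) unlist(lapply(blocks, `[[`, f), use.names = FALSE)
  nr <- params$n_replicates
  lambda <- rep(cat_f("lambda"), each = nr)
  tibble::tibble(
    patient = patient_id,
    timepoint = rep(cat_f("timepoint"), each = nr),
    assay = rep(cat_f("assay"), each = nr),
    compartment = rep(cat_f("compartment"), each = nr),
    target_id = rep(cat_f("target_id"), each = nr),
    condition = rep(cat_f("condition"), each = nr),
    replicate = rep(seq_len(nr), times = length(lambda) / nr),
    spots = if (noise == 0) round(lambda) else rpois(length(lambda), lambda)
  )
}

simulate_repertoires <- function(patient_id, info, noise, params) {
  n_bg <- params$n_background_clonotypes
  bg <- tibble::tibble(
    junction_aa = random_junction(n_bg),
    v_call = sprintf("TRBV%d", sample(1:30, n_bg, replace = TRUE)),
    j_call = sprintf("TRBJ%d-%d", sample(1:2, n_bg, replace = TRUE),
                     sample(1:7, n_bg, replace = TRUE)),
    weight = 1 / seq_len(n_bg)^1.1
  )
  imm <- info[info$immunogenic, , drop = FALSE]
  specific <- if (nrow(imm) > 0) {
    n_tcr <- sample(seq_len(params$tcrs_per_target_max), nrow(imm),
                    replace = TRUE,
                    prob = c(0.3, 0.4, 0.2, 0.1)[seq_len(params$tcrs_per_target_max)])
    sp <- tibble::tibble(
      specificity = rep(imm$target_id, n_tcr),
      preexisting = rep(imm$preexisting, n_tcr))
    sp$tcr_id <- sprintf("%s_TCR%03d", patient_id, seq_len(nrow(sp)))
    sp$junction_aa <- random_junction(nrow(sp))
    sp$v_call <- sprintf("TRBV%d", sample(1:30, nrow(sp), replace = TRUE))
    sp$j_call <- sprintf("TRBJ%d-%d", sample(1:2, nrow(sp), replace = TRUE),
                         sample(1:7, nrow(sp), replace = TRUE))
    w <- runif(nrow(sp), 0.2, 1)
    sp$blood_freq <- params$specific_blood_freq * w / sum(w)
    sp$in_tumor <- runif(nrow(sp)) < params$trafficking_frac
    if (any(sp$in_tumor)) {
      wt <- w * sp$in_tumor
      sp$tumor_freq <- params$tumor_specific_freq * wt / sum(wt)
    } else {
      sp$tumor_freq <- 0
    }
    sp
  } else {
    tibble::tibble(specificity = character(0), preexisting = logical(0),
                   tcr_id = character(0), junction_aa = character(0),
                   v_call = character(0), j_call = character(0),
                   blood_freq = numeric(0), in_tumor = logical(0),
                   tumor_freq = numeric(0))
  }

  compose <- function(spec_freq) {
    keep <- spec_freq > 0
    spec_total <- sum(spec_freq[keep])
    bg_freq <- bg$weight / sum(bg$weight) * (1 - spec_total)
    tibble::tibble(
      junction_aa = c(bg$junction_aa, specific$junction_aa[keep]),
      v_call = c(bg$v_call, specific$v_call[keep]),
      j_call = c(bg$j_call, specific$j_call[keep]),
      freq = c(bg_freq, spec_freq[keep]))
  }
  realize <- function(tbl, compartment, timepoint, sample_id) {
    depth <- params$repertoire_depth
    counts <- if (noise == 0) {
      round(tbl$freq * depth)
    } else {
      as.vector(rmultinom(1, depth, tbl$freq))
    }
    out <- tbl[counts > 0, c("junction_aa", "v_call", "j_call")]
    out$duplicate_count <- counts[counts > 0]
    out$patient <- patient_id
    out$compartment <- compartment
    out$timepoint <- timepoint
    out$sample_id <- sample_id
    out[, c("patient", "sample_id", "compartment", "timepoint",
            "junction_aa", "v_call", "j_call", "duplicate_count")]
  }

  base_freq <- ifelse(specific$preexisting,
                      params$baseline_preexisting_freq, 0)
  repertoire <- dplyr::bind_rows(
    realize(compose(base_freq), "blood_CD8", params$baseline_day,
            "blood_baseline"),
    realize(compose(specific$blood_freq), "blood_CD8", params$post_day,
            "blood_post"),
    realize(compose(specific$tumor_freq), "tumor", params$tumor_day,
            "tumor_biopsy_1"))
  list(repertoire = repertoire,
       specific_tcrs = specific[, c("tcr_id", "junction_aa", "v_call",
                                    "j_call", "specificity", "preexisting",
                                    "blood_freq", "in_tumor", "tumor_freq")])
}

simulate_jurkat <- function(specific_tcrs, noise, params) {
  effectors_only <- 800
  n_sp <- nrow(specific_tcrs)
  true_fold <- if (noise == 0) rep(4, n_sp) else runif(n_sp, 2.5, 8)
  rows <- tibble::tibble(
    tcr_id = specific_tcrs$tcr_id,
    junction_aa = specific_tcrs$junction_aa,
    specificity = specific_tcrs$specificity,
    luminescence = effectors_only * true_fold,
    effectors_only = effectors_only,
    truly_specific = TRUE
  )
  n_decoy <- ceiling(n_sp * params$decoy_tcr_frac)
  if (n_decoy > 0 && n_sp > 0) {
    decoy_fold <- if (noise == 0) rep(1.2, n_decoy) else runif(n_decoy, 0.7, 1.7)
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      tcr_id = sprintf("%s_D%02d", specific_tcrs$tcr_id[1], seq_len(n_decoy)),
      junction_aa = random_junction(n_decoy),
      specificity = sample(specific_tcrs$specificity, n_decoy, replace = TRUE),
      luminescence = effectors_only * decoy_fold,
      effectors_only = effectors_only,
      truly_specific = FALSE))
  }
  rows
}

#' Write assay tables for a patient
#'
#' @param assays List from [generate_assay_data()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_assay_bundle <- function(assays, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(assays$elispot, file.path(dir, "elispot.tsv"))
  readr::write_tsv(assays$repertoire, file.path(dir, "repertoire.tsv"))
  readr::write_tsv(assays$jurkat, file.path(dir, "jurkat.tsv"))
  readr::write_tsv(assays$specific_tcrs, file.path(dir, "specific_tcrs.tsv"))
  invisible(dir)
}
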