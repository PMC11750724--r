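# End-to-end orchestration: design (variants -> candidates -> prioritized
# -> selected -> constructs, with a full audit trail) and monitoring
# (ELISpot response calls, multimer candidates, TCR tracking), both
# reproducible from a config + seed and emitting machine-readable reports.

#' Pipeline configuration
#'
#' All tunable module parameters in one list; every stage reads from here
#' so a run is reproducible from `(inputs, config, seed)`.
#'
#' @param min_phase_reads,phase_fraction Germline phasing thresholds.
#' @param expressed_min Non-expressed filter floor (RPKM).
#' @param caps Prioritization tier caps ([default_caps()]).
#' @param selection [selection_config()].
#' @param class1_lengths,class2_length Epitope lengths for binding.
#' @param predictor_key Key of the bundled deterministic predictor.
#' @param alpha,min_spot_delta ELISpot positivity parameters.
#' @param fold_threshold,fold_floor Response fold-change parameters.
#' @param multimer_max_rank,multimer_top_n Multimer selection parameters.
#' @param detection_threshold Baseline detection threshold (reads) for de
#'   novo clonotype classification.
#' @param seed Pipeline seed.
#' @return A `neovax_pipeline_config` list.
#' @export
pipeline_config <- function(min_phase_reads = 2L, phase_fraction = 0.8,
                            expressed_min = 0.001,
                            caps = default_caps(),
                            selection = selection_config(),
                            class1_lengths = 8:11, class2_length = 15L,
                            predictor_key = 0,
                            alpha = 0.05, min_spot_delta = 5,
                            fold_threshold = 2, fold_floor = 1,
                            multimer_max_rank = 5, multimer_top_n = 3L,
                            detection_threshold = 0, seed = 1L) {
  structure(as.list(environment()), class = "neovax_pipeline_config")
}

config_hash <- function(config) {
  flat <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                           digits = NA, force = TRUE)
  as.character(str_hash(as.character(flat)))
}

#' Design a patient's vaccine from variants to constructs
#'
#' Runs extraction + phasing + filtering, binding annotation with the
#' configured predictor, tiered prioritization, the 5-neoantigen
#' eligibility gate, composite selection of at most 20 targets, and
#' construct assembly. The returned report records every candidate's fate.
#'
#' @param patient A `neovax_patient` (from [generate_cohort()] or
#'   [read_patient_bundle()]).
#' @param config A [pipeline_config()].
#' @return A design report list (`eligible`, `candidates`, `dropped`,
#'   `prioritized`, `selected`, `constructs`, `audit`, `provenance`).
#' @export
design_patient <- function(patient, config = pipeline_config()) {
  fl <- extract_candidates(patient,
                           min_phase_reads = config$min_phase_reads,
                           phase_fraction = config$phase_fraction,
                           expressed_min = config$expressed_min)
  predictor <- mock_predictor(key = config$predictor_key)
  scored <- score_candidates(fl$kept, patient$hla_class1, patient$hla_drb,
                             predictor = predictor,
                             class1_lengths = config$class1_lengths,
                             class2_length = config$class2_length)
  candidates <- scored$candidates
  eligible <- check_eligibility(nrow(candidates),
                                config$selection$min_neoantigens_eligibility)
  if (eligible) {
    prioritized <- prioritize(candidates, caps = config$caps)
    selected <- select_targets(prioritized, config$selection)
    groups <- if (nrow(selected) > 0) partition_targets(selected) else list()
    constructs <- purrr::imap(groups, function(g, id) {
      assemble_construct(g, construct_id = id)
    })
  } else {
    prioritized <- prioritize(candidates[0, ], caps = config$caps)
    selected <- dplyr::mutate(prioritized, selection_score = numeric(0),
                              selection_rank = integer(0))
    constructs <- list()
  }

  fate <- setNames(rep("candidate_not_prioritized", nrow(candidates)),
                   candidates$variant_id)
  fate[prioritized$variant_id] <- paste0("prioritized:", prioritized$tier)
  for (cs in constructs) {
    fate[cs$target_ids] <- paste0("selected:", cs$construct_id)
  }
  audit <- dplyr::bind_rows(
    tibble::tibble(variant_id = names(fate), fate = unname(fate)),
    tibble::tibble(variant_id = fl$dropped$variant_id,
                   fate = paste0("dropped:", fl$dropped$reason)))
  audit <- audit[order(audit$variant_id), ]

  list(
    patient_id = patient$patient_id,
    hla_class1 = patient$hla_class1,
    hla_drb = patient$hla_drb,
    n_candidates = nrow(candidates),
    eligible = eligible,
    candidates = candidates,
    dropped = fl$dropped,
    prioritized = prioritized,
    selected = selected,
    constructs = constructs,
    audit = audit,
    provenance = list(
      package_version = as.character(utils::packageVersion("neovax")),
      predictor_id = predictor$predictor_id,
      seed = config$seed,
      config_hash = config_hash(config))
  )
}

#' Run the design stage on a patient bundle directory
#'
#' File-facing wrapper around [design_patient()]: reads the bundle, writes
#' `design_report.json`, `prioritized.tsv` and (when eligible)
#' `constructs.fasta` into `out_dir`.
#'
#' @param bundle_dir Patient bundle directory ([write_patient_bundle()]
#'   layout).
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return The design report, invisibly.
#' @export
run_design <- function(bundle_dir, out_dir, config = pipeline_config()) {
  patient <- read_patient_bundle(bundle_dir)
  report <- design_patient(patient, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_prioritized_tsv(report$prioritized, file.path(out_dir, "prioritized.tsv"))
  if (length(report$constructs) > 0) {
    write_construct_fasta(report$constructs, file.path(out_dir, "constructs.fasta"))
  }
  json <- report
  json$constructs <- lapply(report$constructs, unclass)
  jsonlite::write_json(json, file.path(out_dir, "design_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Monitor the immune response for a designed patient
#'
#' Takes the design report plus assay tables and produces per-target
#' response calls, the patient summary, multimer candidates (from the
#' selected targets' mutation-containing 8-11-mers against the class I
#' genotype), and TCR tracking: Jurkat-validated specific TCRs tracked in
#' post-induction blood and tumor, classified de novo/preexisting against
#' baseline blood.
#'
#' @param design Design report from [design_patient()] (or the path of a
#'   `design_report.json`).
#' @param elispot,repertoire,jurkat Assay tibbles from
#'   [generate_assay_data()] (or TSV paths).
#' @param config A [pipeline_config()].
#' @return A monitoring report list.
#' @export
run_monitoring <- function(design, elispot, repertoire, jurkat,
                           config = pipeline_config()) {
  if (is.character(design)) {
    design <- jsonlite::read_json(design, simplifyVector = TRUE)
    design$selected <- tibble::as_tibble(design$selected)
  }
  read_maybe <- function(x) {
    if (is.character(x)) readr::read_tsv(x, show_col_types = FALSE) else x
  }
  elispot <- read_maybe(elispot)
  repertoire <- read_maybe(repertoire)
  jurkat <- read_maybe(jurkat)

  known <- design$selected$variant_id
  stim_targets <- unique(elispot$target_id[elispot$condition == "stimulated"])
  unknown_rows <- setdiff(stim_targets, known)
  elispot_known <- elispot[elispot$condition != "stimulated" |
                             elispot$target_id %in% known, ]

  calls <- call_responses_from_table(
    elispot_known, fold_threshold = config$fold_threshold,
    floor = config$fold_floor, alpha = config$alpha,
    min_spot_delta = config$min_spot_delta)
  summary <- summarize_patient(calls)

  multimer <- if (nrow(design$selected) > 0) {
    predictor <- mock_predictor(key = config$predictor_key)
    sc <- dplyr::bind_rows(lapply(seq_len(nrow(design$selected)), function(i) {
      enumerate_candidates(design$selected[i, ], design$hla_class1,
                           config$class1_lengths)
    }))
    select_multimer_candidates(predict_binding(sc, predictor),
                               max_rank = config$multimer_max_rank,
                               top_n = config$multimer_top_n)
  } else NULL

  jk <- jurkat_specificity_call(jurkat$luminescence, jurkat$effectors_only,
                                fold_threshold = config$fold_threshold)
  specific <- jurkat[jk$validated, c("tcr_id", "junction_aa", "specificity")]
  specific$fold_change <- jk$fold[jk$validated]

  one_sample <- function(compartment, which = c("post", "baseline")) {
    which <- match.arg(which)
    x <- repertoire[repertoire$compartment == compartment, ]
    if (nrow(x) == 0) return(NULL)
    tp <- if (which == "baseline") min(x$timepoint) else max(x$timepoint)
    x[x$timepoint == tp, ]
  }
  blood_post <- one_sample("blood_CD8", "post")
  blood_base <- one_sample("blood_CD8", "baseline")
  if (!is.null(blood_base) && !is.null(blood_post) &&
      identical(blood_base$timepoint[1], blood_post$timepoint[1])) {
    blood_base <- NULL
  }
  tumor <- one_sample("tumor", "post")

  tracking <- list(
    blood = if (!is.null(blood_post)) cumulative_frequency(specific, blood_post),
    tumor = if (!is.null(tumor)) cumulative_frequency(specific, tumor),
    baseline_status = classify_baseline_status(
      specific, blood_base, detection_threshold = config$detection_threshold)
  )

  list(
    patient_id = design$patient_id,
    calls = calls,
    responder = summary$responder,
    n_targets_positive = summary$n_targets_positive,
    phenotypes = summary$phenotypes,
    multimer_candidates = multimer,
    specific_tcrs = specific,
    tracking = tracking,
    unknown_assay_targets = unknown_rows,
    provenance = list(config_hash = config_hash(config))
  )
}

#' Cohort roll-up of monitoring reports
#'
#' @param reports List of monitoring reports.
#' @return Tibble with one row per patient (responder flag, positives,
#'   cumulative blood/tumor frequencies, de novo TCR fraction).
#' @export
summarize_cohort <- function(reports) {
  dplyr::bind_rows(lapply(reports, function(r) {
    st <- r$tracking$baseline_status
    tibble::tibble(
      patient_id = r$patient_id,
      responder = r$responder,
      n_targets_positive = r$n_targets_positive,
      n_specific_tcrs = nrow(r$specific_tcrs),
      blood_cumulative_freq = if (!is.null(r$tracking$blood))
        r$tracking$blood$cumulative else NA_real_,
      tumor_cumulative_freq = if (!is.null(r$tracking$tumor))
        r$tracking$tumor$cumulative else NA_real_,
      frac_de_novo = if (nrow(st) > 0 && !all(st$status == "unknown"))
        mean(st$status == "de_novo") else NA_real_
    )
  }))
}
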