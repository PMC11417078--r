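#' Run the full monitoring pipeline on one cohort
#'
#' Chains candidate detection, buffycoat panel construction, the quantile
#' artifact filter and — when a clinical table is supplied — per-patient
#' response classification and the Fisher association test.
#'
#' @param counts Site counts for all libraries (single tibble with
#'   `library_id`).
#' @param manifest Raw manifest tibble (see [read_manifest()]).
#' @param clinical Optional clinical tibble (`patient_id`, `dworak_trg`).
#' @param caller A [caller_params()].
#' @param filter A [filter_params()].
#' @param stable_rel_tol Stable band for [classify_variant_change()].
#' @return A list: `candidates`, `panel`, `filtered` (see
#'   [filter_cohort()]), and with clinical data also `calls`,
#'   `contingency`, `p_value`.
#' @export
monitor_cohort <- function(counts, manifest, clinical = NULL,
                           caller = caller_params(),
                           filter = filter_params(),
                           stable_rel_tol = 0.10) {
  patients <- unique(manifest$patient_id)
  candidates <- detect_candidates(counts, manifest, caller)
  bc_libs <- manifest$library_id[manifest$compartment == "buffycoat"]
  bc_counts <- counts[counts$library_id %in% bc_libs, , drop = FALSE]
  if (nrow(candidates) > 0) {
    panel <- build_panel(bc_counts, candidates, filter)
  } else {
    panel <- NULL
  }
  filtered <- filter_cohort(candidates, panel, filter, patients = patients)
  out <- list(candidates = candidates, panel = panel, filtered = filtered)
  if (!is.null(clinical)) {
    out$calls <- classify_cohort(filtered$variants, patients,
                                 stable_rel_tol)
    out$contingency <- build_contingency(out$calls, clinical)
    out$p_value <- fisher_exact_2x2(out$contingency)
  }
  out
}

#' Compare pipeline output against simulation truth
#'
#' Joins the validated-variant verdicts back onto the generator's truth
#' labels and summarises recovery per variant origin. A tumor variant
#' counts as *eligible* when its expected VAF (larger timepoint) exceeds
#' twice the observed buffycoat percentile VAF at its position plus three
#' binomial standard errors at pooled duplicate depth — the regime in
#' which the filter is expected to keep it.
#'
#' @param truth A [generate_cohort()] result.
#' @param counts The matching [generate_site_counts()] output.
#' @param result A [monitor_cohort()] result for those counts.
#' @param filter The [filter_params()] used (for the threshold).
#' @return A list: `by_origin` (tibble of n / n_validated per origin),
#'   `tumor_eligible_n`, `tumor_eligible_recovered`, `chip_rejected_frac`,
#'   `germline_rejected_frac`.
#' @export
recovery_stats <- function(truth, counts, result,
                           filter = filter_params()) {
  tv <- truth$variants
  bc_libs <- truth$manifest$library_id[
    truth$manifest$compartment == "buffycoat"]
  bc_counts <- counts[counts$library_id %in% bc_libs, , drop = FALSE]
  truth_panel <- build_panel(bc_counts, tv, filter)
  passed <- result$filtered$variants
  if (nrow(passed) > 0 && "passed" %in% names(passed)) {
    passed <- passed[passed$passed, c("patient_id", "chrom", "pos")]
    passed$validated <- TRUE
  } else {
    passed <- tibble::tibble(patient_id = character(), chrom = character(),
                             pos = integer(), validated = logical())
  }
  tv <- dplyr::left_join(tv, passed, by = c("patient_id", "chrom", "pos"))
  tv$validated[is.na(tv$validated)] <- FALSE
  tv <- dplyr::left_join(tv, truth_panel$table[, c("chrom", "pos", "q")],
                         by = c("chrom", "pos"))
  by_origin <- dplyr::summarise(
    dplyr::group_by(tv, .data$origin),
    n = dplyr::n(),
    n_validated = sum(.data$validated),
    .groups = "drop")

  tum <- tv[tv$origin == "tumor", , drop = FALSE]
  v <- pmax(tum$vaf_t0, tum$vaf_t1)
  pooled_depth <- 2 * truth$config$depth_mean
  eligible <- v > filter$multiplier * tum$q +
    3 * sqrt(v * (1 - v) / pooled_depth)
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  list(
    by_origin = by_origin,
    tumor_eligible_n = sum(eligible),
    tumor_eligible_recovered = frac(sum(tum$validated[eligible]),
                                    sum(eligible)),
    chip_rejected_frac = frac(
      sum(!tv$validated[tv$origin == "chip"]),
      sum(tv$origin == "chip")),
    germline_rejected_frac = frac(
      sum(!tv$validated[tv$origin == "germline"]),
      sum(tv$origin == "germline"))
  )
}
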