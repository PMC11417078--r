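#' Artifact filter parameters
#'
#' A candidate somatic variant is deemed true only if its VAF is strictly
#' greater than `multiplier` times the `percentile`-percentile VAF observed
#' at the same genomic position across all patients' buffycoat libraries.
#' The defaults — the 95th percentile doubled — target recurrent
#' position-specific technical artifacts and clonal-hematopoiesis hotspots.
#'
#' @param percentile Percentile in (0, 100).
#' @param multiplier Positive factor applied to the percentile VAF.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(percentile = 95, multiplier = 2) {
  stopifnot(percentile > 0, percentile < 100, multiplier > 0)
  structure(list(percentile = percentile, multiplier = multiplier),
            class = "filter_params")
}

# percentile by sorted linear interpolation between order statistics at
# rank p/100 * (n-1) (0-based); the convention pinned by the filter's
# contract and cross-checked against an independent implementation in tests
percentile_interp <- function(x, p) {
  n <- length(x)
  if (n == 0) stop("empty VAF list", call. = FALSE)
  s <- sort(x)
  h <- p / 100 * (n - 1)
  lo <- floor(h)
  if (lo >= n - 1) return(s[n])
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

#' Build the cohort buffycoat background panel
#'
#' For each queried position, collects the VAF in every patient's buffycoat
#' library (libraries with zero depth at the position are recorded as
#' missing and excluded) and computes the percentile VAF that anchors the
#' artifact filter.
#'
#' @param bc_counts Site counts of all buffycoat libraries (one tibble with
#'   `library_id`).
#' @param positions A data frame of positions to evaluate (`chrom`, `pos`,
#'   and optionally `ref`/`alt`; background is per genomic position).
#' @param params A [filter_params()].
#' @return A list of class `buffycoat_panel`: `table` (per position: `q`,
#'   `n_obs`, `n_missing`, list-column `vafs`), `n_libraries`, `percentile`.
#' @export
build_panel <- function(bc_counts, positions, params = filter_params()) {
  libs <- unique(bc_counts$library_id)
  if (length(libs) < 2) {
    stop("need at least 2 buffycoat libraries to build a background panel",
         call. = FALSE)
  }
  pos <- dplyr::distinct(tibble::as_tibble(positions)[, c("chrom", "pos")])
  bc <- dplyr::semi_join(bc_counts, pos, by = c("chrom", "pos"))
  bc$depth <- bc$ref_reads + bc$alt_reads
  bc <- bc[bc$depth > 0, , drop = FALSE]
  bc$vaf <- bc$alt_reads / bc$depth
  agg <- dplyr::summarise(
    dplyr::group_by(bc, .data$chrom, .data$pos),
    vafs = list(.data$vaf),
    n_obs = dplyr::n(),
    .groups = "drop")
  tab <- dplyr::left_join(pos, agg, by = c("chrom", "pos"))
  absent <- is.na(tab$n_obs)
  if (any(absent)) {
    stop("position(s) absent from every buffycoat library: ",
         paste(paste0(tab$chrom[absent], ":", tab$pos[absent]),
               collapse = ", "), call. = FALSE)
  }
  tab$n_missing <- length(libs) - tab$n_obs
  tab$q <- vapply(tab$vafs, percentile_interp, 0, p = params$percentile)
  structure(list(table = tab, n_libraries = length(libs),
                 percentile = params$percentile),
            class = "buffycoat_panel")
}

#' Validate candidate variants against the buffycoat panel
#'
#' The evaluated VAF is the larger of the two pooled timepoint VAFs — a
#' variant real at either timepoint is real. `passed` is true iff the
#' evaluated VAF is *strictly* greater than `multiplier * q`; the
#' percentile VAF and threshold are recorded for audit, along with
#' per-timepoint verdicts.
#'
#' @param candidates Candidate tibble from [detect_candidates()] (any
#'   subset of rows).
#' @param panel A [build_panel()] result covering the candidates'
#'   positions.
#' @param params A [filter_params()].
#' @return The candidates with added columns `q95`, `threshold`,
#'   `evaluated_vaf`, `passed`, `passed_t0`, `passed_t1`.
#' @export
validate_variant <- function(candidates, panel, params = filter_params()) {
  stopifnot(inherits(panel, "buffycoat_panel"))
  out <- dplyr::left_join(
    tibble::as_tibble(candidates),
    panel$table[, c("chrom", "pos", "q")], by = c("chrom", "pos"))
  if (any(is.na(out$q))) {
    bad <- out[is.na(out$q), , drop = FALSE]
    stop("candidate position(s) missing from panel: ",
         paste(unique(paste0(bad$chrom, ":", bad$pos)), collapse = ", "),
         call. = FALSE)
  }
  names(out)[names(out) == "q"] <- "q95"
  out$threshold <- params$multiplier * out$q95
  out$evaluated_vaf <- pmax(out$vaf_t0, out$vaf_t1)
  out$passed <- out$evaluated_vaf > out$threshold
  out$passed_t0 <- out$vaf_t0 > out$threshold
  out$passed_t1 <- out$vaf_t1 > out$threshold
  out
}

#' Filter a cohort's candidates and summarise detection
#'
#' Annotates every candidate with its filter verdict and reports
#' per-patient candidate and validated counts plus the cohort detection
#' rate (fraction of patients with at least one validated variant).
#'
#' @param candidates Candidate tibble from [detect_candidates()].
#' @param panel A [build_panel()] result.
#' @param params A [filter_params()].
#' @param patients Optional vector (or tibble with `patient_id`) of all
#'   cohort patients, so the detection-rate denominator includes patients
#'   without any candidate.
#' @return A list: `variants` (all candidates with verdicts), `per_patient`
#'   (n_candidates, n_validated), `detection_rate`, `mean_candidates`,
#'   `mean_validated`.
#' @export
filter_cohort <- function(candidates, panel, params = filter_params(),
                          patients = NULL) {
  if (!is.null(patients) && is.data.frame(patients)) {
    patients <- patients$patient_id
  }
  ids <- unique(c(candidates$patient_id, patients))
  if (nrow(candidates) == 0) {
    variants <- candidates
    per_patient <- tibble::tibble(patient_id = ids, n_candidates = 0L,
                                  n_validated = 0L)
  } else {
    variants <- validate_variant(candidates, panel, params)
    per_patient <- dplyr::summarise(
      dplyr::group_by(variants, .data$patient_id),
      n_candidates = dplyr::n(),
      n_validated = sum(.data$passed),
      .groups = "drop")
    missing <- setdiff(ids, per_patient$patient_id)
    if (length(missing) > 0) {
      per_patient <- dplyr::bind_rows(
        per_patient,
        tibble::tibble(patient_id = missing, n_candidates = 0L,
                       n_validated = 0L))
    }
    per_patient <- per_patient[order(per_patient$patient_id), ]
  }
  n_pat <- length(ids)
  list(
    variants = variants,
    per_patient = per_patient,
    detection_rate = if (n_pat > 0) mean(per_patient$n_validated >= 1) else 0,
    mean_candidates = if (n_pat > 0) mean(per_patient$n_candidates) else 0,
    mean_validated = if (n_pat > 0) mean(per_patient$n_validated) else 0
  )
}
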