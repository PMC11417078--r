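severity_rank <- function(consequence) {
  match(consequence, CONSEQUENCE_LEVELS)
}

#' Oncoplot matrix and per-gene frequencies
#'
#' Builds the genes-by-patients mutation landscape from validated variants.
#' Multiple mutations of one gene in one patient collapse to the most
#' severe consequence class (the per-cell variant count is retained
#' separately). Gene frequency is the percentage of *mutated* patients
#' (those with at least one validated variant) carrying the gene — the
#' denominator that makes 3 of 12 carriers a 25% gene.
#'
#' @param validated Validated-variant tibble; rows with `passed == FALSE`
#'   are dropped if a `passed` column is present.
#' @param clinical Optional clinical tibble (`patient_id`, `dworak_trg` or
#'   `responder`) used to order patients responders-first.
#' @return A list of class `oncoplot_matrix`: `matrix` (character,
#'   genes x patients, `NA` where unmutated), `gene_frequency` (tibble
#'   `gene`, `n_patients`, `frequency` in percent, 1 decimal), `cells`
#'   (per gene-patient consequence and variant count), `n_mutated`.
#' @export
oncoplot_matrix <- function(validated, clinical = NULL) {
  if ("passed" %in% names(validated)) {
    validated <- validated[validated$passed, , drop = FALSE]
  }
  if (nrow(validated) == 0) {
    return(structure(list(
      matrix = matrix(character(), 0, 0),
      gene_frequency = tibble::tibble(gene = character(),
                                      n_patients = integer(),
                                      frequency = double()),
      cells = tibble::tibble(gene = character(), patient_id = character(),
                             consequence = character(),
                             n_variants = integer()),
      n_mutated = 0L), class = "oncoplot_matrix"))
  }
  cells <- dplyr::summarise(
    dplyr::group_by(validated, .data$gene, .data$patient_id),
    consequence = CONSEQUENCE_LEVELS[min(severity_rank(.data$consequence))],
    n_variants = dplyr::n(),
    .groups = "drop")
  n_mutated <- dplyr::n_distinct(cells$patient_id)
  freq <- dplyr::summarise(
    dplyr::group_by(cells, .data$gene),
    n_patients = dplyr::n(),
    frequency = round_half_up(100 * dplyr::n() / n_mutated, 1),
    .groups = "drop")
  freq <- freq[order(-freq$frequency, freq$gene), ]

  pats <- unique(cells$patient_id)
  if (!is.null(clinical)) {
    if (!"responder" %in% names(clinical)) {
      clinical$responder <- responder_from_trg(clinical$dworak_trg)
    }
    ord <- clinical[order(-clinical$responder, clinical$patient_id), ]
    pats <- c(intersect(ord$patient_id, pats),
              setdiff(pats, ord$patient_id))
  } else {
    pats <- sort(pats)
  }
  m <- matrix(NA_character_, nrow(freq), length(pats),
              dimnames = list(freq$gene, pats))
  m[cbind(match(cells$gene, freq$gene),
          match(cells$patient_id, pats))] <- cells$consequence
  structure(list(matrix = m, gene_frequency = freq, cells = cells,
                 n_mutated = n_mutated), class = "oncoplot_matrix")
}

#' Per-variant VAF series for stacked-bar plotting
#'
#' One row per validated variant with both pooled timepoint VAFs — a
#' variant undetectable at t1 keeps its 0.0, since disappearing bars are
#' part of the picture. Patients are partitioned responders-first when a
#' clinical table is supplied.
#'
#' @inheritParams oncoplot_matrix
#' @return A tibble: `patient_id`, `responder` (if clinical given), `gene`,
#'   `chrom`, `pos`, `consequence`, `vaf_t0`, `vaf_t1`.
#' @export
stacked_bar_data <- function(validated, clinical = NULL) {
  if ("passed" %in% names(validated)) {
    validated <- validated[validated$passed, , drop = FALSE]
  }
  cols <- intersect(c("patient_id", "gene", "chrom", "pos", "ref", "alt",
                      "consequence", "vaf_t0", "vaf_t1"), names(validated))
  out <- tibble::as_tibble(validated)[, cols]
  if (!is.null(clinical)) {
    if (!"responder" %in% names(clinical)) {
      clinical$responder <- responder_from_trg(clinical$dworak_trg)
    }
    out <- dplyr::left_join(out,
                            clinical[, c("patient_id", "responder")],
                            by = "patient_id")
    out <- out[order(-out$responder, out$patient_id, out$gene), ]
  }
  out
}

#' Cohort-level summary report
#'
#' Collects the headline numbers of a monitoring run: detection rate,
#' total and distinct validated mutations, consequence-class tallies,
#' per-patient candidate/validated means, per-timepoint VAF summaries of
#' validated variants, and (when quantification results are supplied)
#' cfDNA mass and genome-copy summaries.
#'
#' @param filtered A [filter_cohort()] result.
#' @param patients All cohort patient ids (vector or tibble with
#'   `patient_id`).
#' @param quant Optional [quantify_samples()] result.
#' @return A list of class `cohort_report`.
#' @export
cohort_report <- function(filtered, patients, quant = NULL) {
  if (is.data.frame(patients)) patients <- patients$patient_id
  v <- filtered$variants
  if (nrow(v) > 0 && "passed" %in% names(v)) {
    v <- v[v$passed, , drop = FALSE]
  }
  n_pat <- length(patients)
  cons <- table(factor(v$consequence, levels = CONSEQUENCE_LEVELS))
  vaf_summary <- if (nrow(v) > 0) {
    tibble::tibble(
      timepoint = c("t0", "t1"),
      min_vaf = c(min(v$vaf_t0), min(v$vaf_t1)),
      median_vaf = c(stats::median(v$vaf_t0), stats::median(v$vaf_t1)),
      max_vaf = c(max(v$vaf_t0), max(v$vaf_t1)))
  } else {
    tibble::tibble(timepoint = character(), min_vaf = double(),
                   median_vaf = double(), max_vaf = double())
  }
  rep <- list(
    n_patients = n_pat,
    n_patients_detected = sum(filtered$per_patient$n_validated >= 1),
    detection_rate = filtered$detection_rate,
    detection_rate_percent = round_half_up(100 * filtered$detection_rate, 0),
    n_validated_total = nrow(v),
    n_distinct_variants = if (nrow(v) > 0) {
      nrow(dplyr::distinct(v[, c("chrom", "pos", "ref", "alt")]))
    } else 0L,
    consequence_counts = cons,
    mean_candidates_per_patient = filtered$mean_candidates,
    mean_validated_per_patient = filtered$mean_validated,
    per_patient = filtered$per_patient,
    vaf_summary = vaf_summary
  )
  if (!is.null(quant)) {
    rep$mass_summary <- summarize_masses(quant)
    if (!"diploid_copies" %in% names(quant)) {
      quant <- quantify_samples(quant)
    }
    rep$copies_summary <- dplyr::summarise(
      dplyr::group_by(tibble::as_tibble(quant), .data$timepoint),
      min_diploid_copies = min(.data$diploid_copies),
      max_diploid_copies = max(.data$diploid_copies),
      .groups = "drop")
  }
  structure(rep, class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("ctDNA monitoring cohort report\n")
  cat(sprintf("  patients: %d; with >=1 validated mutation: %d (%g%%)\n",
              x$n_patients, x$n_patients_detected,
              x$detection_rate_percent))
  cat(sprintf("  validated mutations: %d (%d distinct)\n",
              x$n_validated_total, x$n_distinct_variants))
  cat(sprintf("  mean per patient: %.1f candidates, %.1f validated\n",
              x$mean_candidates_per_patient, x$mean_validated_per_patient))
  cat("  consequence classes: ",
      paste(names(x$consequence_counts), as.integer(x$consequence_counts),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
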