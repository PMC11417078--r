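#' Dworak responder status from tumor regression grade
#'
#' Responders are TRG 3 (few residual tumor cells) or 4 (complete
#' regression); lower grades are non-responders.
#'
#' @param trg Integer vector of Dworak tumor regression grades in 0..4.
#' @return Logical vector.
#' @export
responder_from_trg <- function(trg) {
  if (any(is.na(trg)) || any(!trg %in% 0:4)) {
    stop("Dworak TRG must be an integer in 0..4", call. = FALSE)
  }
  trg >= 3
}

parse_stage <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  num <- suppressWarnings(as.integer(sub("^[a-zA-Z]*", "", as.character(x))))
  if (any(is.na(num))) {
    stop("unparsable staging category: ",
         paste(unique(x[is.na(num)]), collapse = ", "), call. = FALSE)
  }
  num
}

#' Clinical downstaging
#'
#' Downstaging requires a decrease in *both* the tumor (T) and nodal (N)
#' stage between pre-therapy clinical and post-therapy pathological
#' staging. Accepts bare integers or category codes such as `"cT3"`,
#' `"ypN0"`.
#'
#' @param cT,cN Pre-therapy clinical T and N categories.
#' @param ypT,ypN Post-therapy pathological T and N categories.
#' @return Logical vector.
#' @export
downstaging <- function(cT, cN, ypT, ypN) {
  parse_stage(ypT) < parse_stage(cT) & parse_stage(ypN) < parse_stage(cN)
}

#' Direction of a single variant's VAF change
#'
#' `stable` when both VAFs are zero or their difference is within
#' `stable_rel_tol` of the larger one ("nearly constant"); otherwise `down`
#' when the VAF fell and `up` when it rose.
#'
#' @param vaf_t0,vaf_t1 Pooled VAFs (fractions) at the two timepoints.
#' @param stable_rel_tol Relative tolerance of the stable band.
#' @return Character vector over `down`, `up`, `stable`.
#' @export
classify_variant_change <- function(vaf_t0, vaf_t1, stable_rel_tol = 0.10) {
  stopifnot(all(vaf_t0 >= 0 & vaf_t0 <= 1), all(vaf_t1 >= 0 & vaf_t1 <= 1))
  hi <- pmax(vaf_t0, vaf_t1)
  stable <- hi == 0 | abs(vaf_t1 - vaf_t0) <= stable_rel_tol * hi
  ifelse(stable, "stable", ifelse(vaf_t1 < vaf_t0, "down", "up"))
}

#' Classify one patient's ctDNA dynamic
#'
#' `ctdna_negative` with no validated variants; `decrease` when at least
#' one variant fell and none rose; `increase` when at least one rose and
#' none fell; `mixed` when both occurred. Patients whose variants are all
#' within the stable band are grouped with `increase` and flagged
#' `stable_only`: persistent ctDNA after therapy is the non-clearing
#' signal, the opposite of a decrease.
#'
#' @param variants Validated (passed) variants of one patient, with
#'   `vaf_t0` and `vaf_t1`; zero rows allowed.
#' @param stable_rel_tol Passed to [classify_variant_change()].
#' @return A one-row tibble: `class`, `stable_only`, `n_down`, `n_up`,
#'   `n_stable`.
#' @export
classify_patient <- function(variants, stable_rel_tol = 0.10) {
  if (is.null(variants) || nrow(variants) == 0) {
    return(tibble::tibble(class = "ctdna_negative", stable_only = FALSE,
                          n_down = 0L, n_up = 0L, n_stable = 0L))
  }
  dir <- classify_variant_change(variants$vaf_t0, variants$vaf_t1,
                                 stable_rel_tol)
  n_down <- sum(dir == "down")
  n_up <- sum(dir == "up")
  n_stable <- sum(dir == "stable")
  cls <- if (n_down > 0 && n_up > 0) {
    "mixed"
  } else if (n_down > 0) {
    "decrease"
  } else if (n_up > 0) {
    "increase"
  } else {
    "increase"  # all-stable: ctDNA persists, grouped with non-clearing
  }
  tibble::tibble(class = cls, stable_only = n_down == 0 && n_up == 0,
                 n_down = n_down, n_up = n_up, n_stable = n_stable)
}

#' Classify every patient in a cohort
#'
#' @param validated Validated-variant tibble (only rows with
#'   `passed == TRUE` are used if a `passed` column is present).
#' @param patients Character vector of all patient ids, or a tibble with
#'   `patient_id` — patients without validated variants become
#'   `ctdna_negative`.
#' @param stable_rel_tol Passed to [classify_variant_change()].
#' @return A tibble with one row per patient: `patient_id`, `class`,
#'   `stable_only`, direction counts.
#' @export
classify_cohort <- function(validated, patients, stable_rel_tol = 0.10) {
  if (is.data.frame(patients)) patients <- patients$patient_id
  if ("passed" %in% names(validated)) {
    validated <- validated[validated$passed, , drop = FALSE]
  }
  calls <- lapply(patients, function(p) {
    v <- validated[validated$patient_id == p, , drop = FALSE]
    cbind(tibble::tibble(patient_id = p),
          classify_patient(v, stable_rel_tol))
  })
  tibble::as_tibble(dplyr::bind_rows(calls))
}

#' Cross-tabulate ctDNA status against clinical response
#'
#' Rows are ctDNA status (negative / positive), columns Dworak responder
#' status.
#'
#' @param calls Response calls from [classify_cohort()].
#' @param clinical A clinical tibble with `patient_id` and `dworak_trg`
#'   (or a logical `responder` column).
#' @return A 2x2 integer matrix with named dimensions.
#' @export
build_contingency <- function(calls, clinical) {
  if (nrow(calls) == 0) stop("empty cohort", call. = FALSE)
  if (!"responder" %in% names(clinical)) {
    clinical$responder <- responder_from_trg(clinical$dworak_trg)
  }
  x <- dplyr::left_join(calls[, c("patient_id", "class")],
                        clinical[, c("patient_id", "responder")],
                        by = "patient_id")
  if (any(is.na(x$responder))) {
    stop("missing responder label for patient(s) ",
         paste(x$patient_id[is.na(x$responder)], collapse = ", "),
         call. = FALSE)
  }
  neg <- x$class == "ctdna_negative"
  m <- matrix(c(sum(neg & x$responder), sum(neg & !x$responder),
                sum(!neg & x$responder), sum(!neg & !x$responder)),
              nrow = 2, byrow = TRUE,
              dimnames = list(ctdna = c("ctdna_negative", "ctdna_positive"),
                              response = c("responder", "non_responder")))
  m
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Enumerates all tables with the observed margins and sums the
#' hypergeometric probabilities of those no more probable than the observed
#' table (probability-mass two-sided rule). Ties are compared with the
#' conventional 1e-7 relative tolerance.
#'
#' @param tab A 2x2 matrix of non-negative integer counts with positive
#'   row and column margins.
#' @return The two-tailed p-value.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(3, 2, 6, 6), 2, byrow = TRUE))  # 1
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) ||
      any(tab != round(tab))) {
    stop("need a 2x2 table of non-negative integers", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate margins: every row and column sum must be positive",
         call. = FALSE)
  }
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  lo <- max(0, r1 - (n - c1))
  hi <- min(r1, c1)
  dens <- stats::dhyper(lo:hi, c1, n - c1, r1)
  dobs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  min(1, sum(dens[dens <= dobs * (1 + 1e-7)]))
}
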