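#' Bundled 17-patient rectal cancer cohort tables
#'
#' Plain-text transcriptions of the published per-patient tables of a
#' 17-patient locally advanced rectal cancer cohort under neoadjuvant
#' radio(chemo)therapy, bundled so that the quantification and association
#' stages run on real printed inputs.
#'
#' `hroc_masses()` returns the measured plasma cfDNA mass per patient and
#' timepoint (t0 = before neoadjuvant therapy, t1 = right after the final
#' radiation fraction), in long form (`patient_id`, `timepoint`,
#' `cfdna_ng`). One value is printed inconsistently in the source (5.3 vs
#' 5.25 ng for the smallest t1 sample); the table stores 5.25 ng, the
#' value consistent with that sample's published genome-copy number.
#'
#' `hroc_clinical()` returns protocol, Dworak tumor regression grade and
#' downstaging per patient. The per-patient rows are authoritative where
#' the source's aggregate counts disagree with them.
#'
#' `hroc_manifest()` returns the path of a sequencing-library manifest
#' built from the mass table (duplicate plasma libraries per timepoint plus
#' one buffycoat library per patient), for use with [read_manifest()].
#'
#' @return `hroc_masses()` and `hroc_clinical()` return tibbles;
#'   `hroc_manifest()` returns a file path.
#' @name hroc_cohort
NULL

#' @rdname hroc_cohort
#' @export
hroc_masses <- function() {
  path <- system.file("extdata", "cfdna_masses_hroc.tsv",
                      package = "ctdnamon", mustWork = TRUE)
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  long <- tidyr::pivot_longer(wide, c("cfdna_t0_ng", "cfdna_t1_ng"),
                              names_to = "timepoint",
                              values_to = "cfdna_ng")
  long$timepoint <- sub("^cfdna_(t[01])_ng$", "\\1", long$timepoint)
  long
}

#' @rdname hroc_cohort
#' @export
hroc_clinical <- function() {
  read_clinical(system.file("extdata", "clinical_hroc.tsv",
                            package = "ctdnamon", mustWork = TRUE))
}

#' @rdname hroc_cohort
#' @export
hroc_manifest <- function() {
  system.file("extdata", "manifest_hroc.tsv", package = "ctdnamon",
              mustWork = TRUE)
}
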