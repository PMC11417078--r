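#' Genome weight constants
#'
#' Container for the physical constant converting cfDNA mass into genome
#' copies. The default, 6.51 pg per diploid genome, is the average weight of
#' a female human diploid genome.
#'
#' @param diploid_genome_pg Picograms of DNA per diploid genome. Must be
#'   positive.
#' @return A list of class `genome_constants`.
#' @export
#' @examples
#' genome_constants()
genome_constants <- function(diploid_genome_pg = 6.51) {
  if (!is.numeric(diploid_genome_pg) || length(diploid_genome_pg) != 1 ||
      is.na(diploid_genome_pg) || diploid_genome_pg <= 0) {
    stop("`diploid_genome_pg` must be a single positive number", call. = FALSE)
  }
  structure(list(diploid_genome_pg = diploid_genome_pg),
            class = "genome_constants")
}

# round-half-up at `digits` decimals; round() is banker's rounding, which
# would send 0.125 to 0.12 instead of the 0.13 the reporting convention needs
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Variant allele frequency from read counts
#'
#' VAF = alt / (alt + ref). Reads supporting other alleles are not part of
#' the model; the two counts define the denominator.
#'
#' @param alt_reads,ref_reads Non-negative integer vectors of equal length.
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
#' @examples
#' compute_vaf(10, 9990)  # 0.001
compute_vaf <- function(alt_reads, ref_reads) {
  if (any(alt_reads < 0) || any(ref_reads < 0)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  depth <- alt_reads + ref_reads
  if (any(depth == 0)) {
    stop("VAF undefined at zero total depth; exclude the site", call. = FALSE)
  }
  alt_reads / depth
}

#' Diploid genome copies in a plasma sample
#'
#' Converts cfDNA mass to the expected number of whole diploid genome
#' copies, truncating (floor) to an integer: a partial genome is not a
#' detectable copy. A relative epsilon guards exact divisions against
#' binary floating-point representation (e.g. 3.255 ng / 6.51 pg is exactly
#' 500 copies).
#'
#' @param mass_ng cfDNA mass in nanograms (vectorised, all > 0).
#' @param constants A [genome_constants()] object.
#' @return Integer vector of diploid copy numbers.
#' @export
#' @examples
#' diploid_copies(6.4)   # 983
#' diploid_copies(176)   # 27035
#' diploid_copies(5.25)  # 806
diploid_copies <- function(mass_ng, constants = genome_constants()) {
  stopifnot(inherits(constants, "genome_constants"))
  if (any(!is.finite(mass_ng)) || any(mass_ng <= 0)) {
    stop("`mass_ng` must be positive", call. = FALSE)
  }
  x <- mass_ng * 1000 / constants$diploid_genome_pg
  as.integer(floor(x * (1 + 1e-12) + 1e-9))
}

#' Biological limit of detection for a plasma sample
#'
#' The smallest observable tumor fraction is one haploid tumor genome among
#' all haploid genome equivalents assayed: `min_vaf_percent = 100 /
#' haploid_copies`, reported half-up to two decimals. Haploid copies are
#' twice the diploid copies.
#'
#' @inheritParams diploid_copies
#' @return A tibble with columns `mass_ng`, `diploid_copies`,
#'   `haploid_copies`, `min_vaf_percent`.
#' @export
#' @examples
#' detection_limit(6.4)   # 1966 haploid copies, min VAF 0.05%
#' detection_limit(5.25)  # 1612 haploid copies, min VAF 0.06%
detection_limit <- function(mass_ng, constants = genome_constants()) {
  d <- diploid_copies(mass_ng, constants)
  h <- 2L * d
  tibble::tibble(
    mass_ng = mass_ng,
    diploid_copies = d,
    haploid_copies = h,
    min_vaf_percent = round_half_up(100 / h, 2)
  )
}

#' Summarise cfDNA masses per timepoint
#'
#' Minimum, maximum and median mass per timepoint. The median over an odd
#' number of samples is the middle order statistic. Both the raw values and
#' nearest-ng (half-up) roundings are reported, matching how such summaries
#' are quoted.
#'
#' @param samples A data frame with columns `patient_id`, `timepoint`,
#'   `cfdna_ng` — one row per plasma sample.
#' @return A tibble with one row per timepoint: `n`, `min_ng`, `max_ng`,
#'   `median_ng`, `median_ng_nearest`.
#' @export
summarize_masses <- function(samples) {
  stopifnot(all(c("timepoint", "cfdna_ng") %in% names(samples)))
  samples <- samples[!is.na(samples$cfdna_ng), , drop = FALSE]
  if (nrow(samples) == 0) stop("no plasma masses to summarise", call. = FALSE)
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(samples), .data$timepoint),
    n = dplyr::n(),
    min_ng = min(.data$cfdna_ng),
    max_ng = max(.data$cfdna_ng),
    median_ng = stats::median(.data$cfdna_ng),
    median_ng_nearest = round_half_up(stats::median(.data$cfdna_ng), 0),
    .groups = "drop"
  )
}

#' Quantify genome equivalents for every plasma sample
#'
#' One row per plasma sample with its diploid/haploid genome copies and
#' biological detection limit.
#'
#' @param samples A data frame with columns `patient_id`, `timepoint`,
#'   `cfdna_ng`.
#' @param constants A [genome_constants()] object.
#' @return The input joined with [detection_limit()] columns.
#' @export
quantify_samples <- function(samples, constants = genome_constants()) {
  stopifnot(all(c("patient_id", "timepoint", "cfdna_ng") %in% names(samples)))
  dl <- detection_limit(samples$cfdna_ng, constants)
  dplyr::bind_cols(
    tibble::as_tibble(samples)[, c("patient_id", "timepoint", "cfdna_ng")],
    dl[, c("diploid_copies", "haploid_copies", "min_vaf_percent")]
  )
}
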