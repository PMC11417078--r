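#' Somatic caller parameters
#'
#' Thresholds for the count-based duplicate-concordance caller. Defaults:
#' at least 3 alt reads in *each* duplicate library at 100x minimum depth
#' (at 10,000x pooled ultradeep coverage this keeps binomial detection
#' probability above 95% down to the biological detection limit of the
#' smallest plasma samples, VAF ~5e-4), and a germline call in the matched
#' buffycoat when its VAF reaches 0.25 with at least 10 alt reads —
#' capturing heterozygous (~0.5) and homozygous sites while leaving low-VAF
#' clonal hematopoiesis to the cohort quantile filter.
#'
#' @param min_alt_reads Minimum alt reads required in each duplicate.
#' @param min_depth Minimum depth per library (and for the buffycoat to be
#'   evaluable).
#' @param germline_vaf_threshold Buffycoat VAF at or above which a site is
#'   germline.
#' @param germline_min_alt Minimum buffycoat alt reads for a germline call.
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(min_alt_reads = 3L, min_depth = 100L,
                          germline_vaf_threshold = 0.25,
                          germline_min_alt = 10L) {
  stopifnot(min_alt_reads >= 0, min_depth >= 0, germline_min_alt >= 0,
            germline_vaf_threshold > 0, germline_vaf_threshold < 1)
  structure(list(min_alt_reads = as.integer(min_alt_reads),
                 min_depth = as.integer(min_depth),
                 germline_vaf_threshold = germline_vaf_threshold,
                 germline_min_alt = as.integer(germline_min_alt)),
            class = "caller_params")
}

#' Pool duplicate libraries of one sample
#'
#' Component-wise sum of ref and alt reads at matching positions and
#' alleles. The pooled VAF is the depth-weighted mean of the duplicates'
#' VAFs, so it always lies between them.
#'
#' @param a,b Site-count tibbles for the two duplicates, same sites in the
#'   same order.
#' @return A site-counts tibble with summed `ref_reads` / `alt_reads`.
#' @export
pool_duplicates <- function(a, b) {
  key <- c("chrom", "pos", "ref", "alt")
  if (nrow(a) != nrow(b) ||
      !isTRUE(all.equal(as.data.frame(a[key]), as.data.frame(b[key]),
                        check.attributes = FALSE))) {
    stop("duplicate libraries disagree on positions or alleles",
         call. = FALSE)
  }
  out <- a
  out$ref_reads <- a$ref_reads + b$ref_reads
  out$alt_reads <- a$alt_reads + b$alt_reads
  out
}

#' Flag germline sites in a buffycoat library
#'
#' A site is germline when its buffycoat VAF reaches
#' `germline_vaf_threshold` with at least `germline_min_alt` alt reads.
#' Sites below `min_depth` are unevaluable (`NA`) and must be excluded
#' downstream.
#'
#' @param buffycoat A site-counts tibble for one buffycoat library.
#' @param params A [caller_params()].
#' @return Logical vector, `NA` where depth is insufficient.
#' @export
flag_germline <- function(buffycoat, params = caller_params()) {
  depth <- buffycoat$ref_reads + buffycoat$alt_reads
  vaf <- ifelse(depth > 0, buffycoat$alt_reads / depth, 0)
  out <- vaf >= params$germline_vaf_threshold &
    buffycoat$alt_reads >= params$germline_min_alt
  out[depth < params$min_depth] <- NA
  out
}

#' Detect candidate somatic variants for a cohort
#'
#' A site becomes a candidate for a patient when, at one or both
#' timepoints, *both* duplicate cfDNA libraries carry at least
#' `min_alt_reads` alt reads at `min_depth` coverage, and the site is not
#' germline in the patient's buffycoat. Candidates carry pooled
#' (duplicate-summed) VAFs at both timepoints — a pooled VAF of 0 at the
#' other timepoint is retained, since disappearing variants are part of the
#' therapy-response signal. Sites whose buffycoat is below `min_depth` are
#' unevaluable and dropped with a message; patients without a buffycoat
#' library are skipped with a warning.
#'
#' @param counts Site counts for all libraries (one tibble, `library_id`
#'   column), e.g. from [generate_site_counts()] or [read_counts_dir()].
#' @param manifest The raw manifest tibble (see [read_manifest()]).
#' @param params A [caller_params()].
#' @return A tibble of candidate variants: identity columns, per-timepoint
#'   pooled counts and VAFs (`alt_t0`, `depth_t0`, `vaf_t0`, ...),
#'   `support_t0`/`support_t1` flags, and buffycoat counts/VAF.
#' @export
detect_candidates <- function(counts, manifest, params = caller_params()) {
  stopifnot(all(MANIFEST_COLS %in% names(manifest)))
  bc_map <- manifest[manifest$compartment == "buffycoat",
                     c("patient_id", "library_id")]
  plasma_map <- manifest[manifest$compartment == "plasma",
                         c("patient_id", "timepoint", "replicate",
                           "library_id")]
  no_bc <- setdiff(plasma_map$patient_id, bc_map$patient_id)
  if (length(no_bc) > 0) {
    warning("no buffycoat library for patient(s) ",
            paste(no_bc, collapse = ", "), "; skipped", call. = FALSE)
    plasma_map <- plasma_map[!plasma_map$patient_id %in% no_bc, ]
  }

  pl <- dplyr::inner_join(counts, plasma_map, by = "library_id")
  pl$depth <- pl$ref_reads + pl$alt_reads
  wide <- tidyr::pivot_wider(
    pl[, c("patient_id", "timepoint", "replicate", "chrom", "pos", "ref",
           "alt", "gene", "consequence", "alt_reads", "depth")],
    names_from = c("timepoint", "replicate"),
    values_from = c("alt_reads", "depth"), values_fill = 0L)
  need <- c("alt_reads_t0_1", "alt_reads_t0_2", "alt_reads_t1_1",
            "alt_reads_t1_2", "depth_t0_1", "depth_t0_2", "depth_t1_1",
            "depth_t1_2")
  for (col in setdiff(need, names(wide))) wide[[col]] <- 0L

  sup <- function(a1, a2, d1, d2) {
    a1 >= params$min_alt_reads & a2 >= params$min_alt_reads &
      d1 >= params$min_depth & d2 >= params$min_depth
  }
  wide$support_t0 <- sup(wide$alt_reads_t0_1, wide$alt_reads_t0_2,
                         wide$depth_t0_1, wide$depth_t0_2)
  wide$support_t1 <- sup(wide$alt_reads_t1_1, wide$alt_reads_t1_2,
                         wide$depth_t1_1, wide$depth_t1_2)
  cand <- wide[wide$support_t0 | wide$support_t1, , drop = FALSE]

  cand$alt_t0 <- cand$alt_reads_t0_1 + cand$alt_reads_t0_2
  cand$depth_t0 <- cand$depth_t0_1 + cand$depth_t0_2
  cand$alt_t1 <- cand$alt_reads_t1_1 + cand$alt_reads_t1_2
  cand$depth_t1 <- cand$depth_t1_1 + cand$depth_t1_2
  cand$vaf_t0 <- ifelse(cand$depth_t0 > 0, cand$alt_t0 / cand$depth_t0, 0)
  cand$vaf_t1 <- ifelse(cand$depth_t1 > 0, cand$alt_t1 / cand$depth_t1, 0)

  bc <- dplyr::inner_join(counts, bc_map, by = "library_id")
  bc$bc_depth <- bc$ref_reads + bc$alt_reads
  bc$bc_vaf <- ifelse(bc$bc_depth > 0, bc$alt_reads / bc$bc_depth, 0)
  bc_flag <- flag_germline(
    tibble::tibble(ref_reads = bc$ref_reads, alt_reads = bc$alt_reads),
    params)
  bc$germline <- bc_flag
  bc$bc_alt <- bc$alt_reads
  bc <- bc[, c("patient_id", "chrom", "pos", "ref", "alt", "bc_alt",
               "bc_depth", "bc_vaf", "germline")]

  cand <- dplyr::left_join(cand, bc,
                           by = c("patient_id", "chrom", "pos", "ref",
                                  "alt"))
  unev <- is.na(cand$germline)
  if (any(unev)) {
    message(sum(unev), " candidate site(s) dropped: buffycoat depth below ",
            params$min_depth)
    cand <- cand[!unev, , drop = FALSE]
  }
  cand <- cand[!cand$germline, , drop = FALSE]
  out <- cand[, c("patient_id", "chrom", "pos", "ref", "alt", "gene",
                  "consequence", "support_t0", "support_t1", "alt_t0",
                  "depth_t0", "vaf_t0", "alt_t1", "depth_t1", "vaf_t1",
                  "bc_alt", "bc_depth", "bc_vaf")]
  out[order(out$patient_id, chrom_order_key(out$chrom), out$pos), ]
}
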