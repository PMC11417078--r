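#' @importFrom rlang .data
NULL

#' Consequence classes, most severe first
#'
#' Canonical tokens for the mutation consequence classes the panel reports.
#' The order encodes the severity ranking used when several mutations in one
#' gene collapse to a single oncoplot cell.
#'
#' @export
CONSEQUENCE_LEVELS <- c(
  "stop_gained", "frameshift", "essential_splice", "inframe_indel", "missense"
)

MANIFEST_COLS <- c("patient_id", "timepoint", "library_id", "replicate",
                   "compartment", "cfdna_ng")
COUNTS_COLS <- c("chrom", "pos", "ref", "alt", "ref_reads", "alt_reads",
                 "gene", "consequence")

read_tsv_checked <- function(path, required, what, col_types = NULL) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = col_types)
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Read a sample manifest
#'
#' The manifest lists every sequencing library: duplicate plasma cfDNA
#' libraries at timepoints t0 and t1 plus exactly one buffycoat (leukocyte)
#' library per patient. Plasma rows carry the cfDNA mass of the draw.
#'
#' @param path Path to a TSV with columns `patient_id`, `timepoint` (t0/t1),
#'   `library_id`, `replicate` (1/2, NA for buffycoat), `compartment`
#'   (plasma/buffycoat), `cfdna_ng` (NA for buffycoat).
#' @return A list with `plasma_samples` (one row per patient x timepoint:
#'   `patient_id`, `timepoint`, `cfdna_ng`, `library_1`, `library_2`),
#'   `buffycoat` (one row per patient: `patient_id`, `library_id`), and the
#'   raw `manifest` tibble.
#' @export
read_manifest <- function(path) {
  m <- read_tsv_checked(path, MANIFEST_COLS, "manifest")
  if (nrow(m) == 0) {
    return(list(
      plasma_samples = tibble::tibble(
        patient_id = character(), timepoint = character(),
        cfdna_ng = double(), library_1 = character(), library_2 = character()
      ),
      buffycoat = tibble::tibble(patient_id = character(),
                                 library_id = character()),
      manifest = m
    ))
  }
  m$timepoint <- as.character(m$timepoint)
  m$replicate <- suppressWarnings(as.integer(m$replicate))
  if (anyDuplicated(m$library_id)) {
    dup <- unique(m$library_id[duplicated(m$library_id)])
    stop("duplicate library id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!m$compartment %in% c("plasma", "buffycoat"))
  if (length(bad) > 0) {
    stop("unknown compartment at row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  plasma <- m[m$compartment == "plasma", , drop = FALSE]
  bad <- which(!plasma$timepoint %in% c("t0", "t1"))
  if (length(bad) > 0) {
    stop("plasma timepoint must be t0 or t1 (patient ",
         paste(unique(plasma$patient_id[bad]), collapse = ", "), ")",
         call. = FALSE)
  }
  bc <- m[m$compartment == "buffycoat", , drop = FALSE]
  patients <- unique(m$patient_id)
  n_bc <- table(factor(bc$patient_id, levels = patients))
  if (any(n_bc != 1)) {
    off <- names(n_bc)[n_bc != 1]
    stop("each patient needs exactly one buffycoat library; offending: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  plan <- dplyr::summarise(
    dplyr::group_by(plasma, .data$patient_id, .data$timepoint),
    n_rep = dplyr::n(),
    cfdna_ng = .data$cfdna_ng[1],
    library_1 = .data$library_id[order(.data$replicate)][1],
    library_2 = .data$library_id[order(.data$replicate)][2],
    .groups = "drop"
  )
  full <- tidyr::expand_grid(patient_id = patients, timepoint = c("t0", "t1"))
  chk <- dplyr::left_join(full, plan, by = c("patient_id", "timepoint"))
  bad <- chk[is.na(chk$n_rep) | chk$n_rep != 2, , drop = FALSE]
  if (nrow(bad) > 0) {
    stop("every patient needs 2 duplicate plasma libraries at each ",
         "timepoint; offending: ",
         paste(unique(paste0(bad$patient_id, ":", bad$timepoint)),
               collapse = ", "), call. = FALSE)
  }
  list(
    plasma_samples = plan[, c("patient_id", "timepoint", "cfdna_ng",
                              "library_1", "library_2")],
    buffycoat = tibble::tibble(patient_id = bc$patient_id,
                               library_id = bc$library_id),
    manifest = m
  )
}

#' Read a per-library site count table
#'
#' @param path TSV with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `ref_reads`, `alt_reads`, `gene`, `consequence`, and optionally
#'   `library_id`.
#' @param library_id Library id to attach if the file lacks the column
#'   (defaults to the file name without extension).
#' @return A tibble of validated site counts, input order preserved.
#' @export
read_site_counts <- function(path, library_id = NULL) {
  # ref/alt must never be guessed: a lone "T" is a base, not a logical
  x <- read_tsv_checked(
    path, COUNTS_COLS, "site counts",
    col_types = readr::cols(
      chrom = readr::col_character(), ref = readr::col_character(),
      alt = readr::col_character(), gene = readr::col_character(),
      consequence = readr::col_character(),
      .default = readr::col_guess()))
  if (!"library_id" %in% names(x)) {
    if (is.null(library_id)) {
      library_id <- sub("\\.[^.]+$", "", basename(path))
    }
    x$library_id <- library_id
  }
  validate_site_counts(x, where = path)
  x[, c("library_id", COUNTS_COLS)]
}

validate_site_counts <- function(x, where = "site counts") {
  bad <- which(x$pos < 1)
  if (length(bad) > 0) {
    stop(where, ": pos < 1 at row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(x$ref_reads < 0 | x$alt_reads < 0)
  if (length(bad) > 0) {
    stop(where, ": negative read counts at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- which(x$ref == x$alt)
  if (length(bad) > 0) {
    stop(where, ": ref == alt at row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' Write a site count table
#'
#' @param counts A site counts tibble (see [read_site_counts()]).
#' @param path Output TSV path.
#' @export
write_site_counts <- function(counts, path) {
  validate_site_counts(counts)
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read all per-library count files from a directory
#'
#' @param dir Directory of `<library_id>.tsv` files.
#' @return A single tibble with a `library_id` column.
#' @export
read_counts_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(files) == 0) stop("no .tsv count files in ", dir, call. = FALSE)
  dplyr::bind_rows(lapply(files, read_site_counts))
}

#' Read a clinical cohort table
#'
#' @param path TSV with columns `patient_id`, `protocol` (SCRT/RAPIDO/fRCT),
#'   `dworak_trg` (0-4), `downstaging` (logical or yes/no).
#' @return A validated tibble with `downstaging` as logical.
#' @export
read_clinical <- function(path) {
  x <- read_tsv_checked(path, c("patient_id", "protocol", "dworak_trg",
                                "downstaging"), "clinical table")
  if (anyDuplicated(x$patient_id)) {
    stop("duplicate patient id(s) in clinical table", call. = FALSE)
  }
  bad <- which(!x$dworak_trg %in% 0:4)
  if (length(bad) > 0) {
    stop("dworak_trg outside 0-4 at row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.logical(x$downstaging)) {
    x$downstaging <- tolower(as.character(x$downstaging)) %in%
      c("yes", "true", "1", "y")
  }
  bad <- which(!x$protocol %in% c("SCRT", "RAPIDO", "fRCT"))
  if (length(bad) > 0) {
    stop("unknown protocol at row(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x
}

# chr1 < chr2 < ... < chr22 < chrX < chrY < chrM, anything else after
chrom_order_key <- function(chrom) {
  core <- sub("^chr", "", chrom)
  num <- suppressWarnings(as.integer(core))
  num[core == "X"] <- 23L
  num[core == "Y"] <- 24L
  num[core %in% c("M", "MT")] <- 25L
  num[is.na(num)] <- 26L
  num
}

#' Write validated variants to a minimal VCF
#'
#' Emits a standards-conformant VCF 4.2 with INFO keys `GENE`, `CSQ`,
#' `VAF_T0`, `VAF_T1`, `Q95` and FILTER `PASS` (variant VAF exceeded the
#' buffycoat background threshold) or `quantile_fail`. Records are sorted by
#' chromosome, then position.
#'
#' @param variants A validated-variant tibble (see [filter_cohort()]) with
#'   columns `chrom`, `pos`, `ref`, `alt`, `gene`, `consequence`, `vaf_t0`,
#'   `vaf_t1`, `q95`, `passed`.
#' @param path Output VCF path.
#' @export
write_validated_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ctdnamon",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    paste0("##INFO=<ID=VAF_T0,Number=1,Type=Float,Description=",
           "\"Pooled duplicate VAF before therapy\">"),
    paste0("##INFO=<ID=VAF_T1,Number=1,Type=Float,Description=",
           "\"Pooled duplicate VAF after final radiation\">"),
    paste0("##INFO=<ID=Q95,Number=1,Type=Float,Description=",
           "\"Cohort buffycoat percentile VAF at this position\">"),
    paste0("##FILTER=<ID=quantile_fail,Description=\"VAF not greater than ",
           "multiplier x percentile buffycoat VAF\">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  if (nrow(variants) > 0) {
    ord <- order(chrom_order_key(variants$chrom), variants$pos)
    v <- variants[ord, , drop = FALSE]
    info <- sprintf("GENE=%s;CSQ=%s;VAF_T0=%.6g;VAF_T1=%.6g;Q95=%.6g",
                    v$gene, v$consequence, v$vaf_t0, v$vaf_t1, v$q95)
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                    v$chrom, as.integer(v$pos), v$ref, v$alt,
                    ifelse(v$passed, "PASS", "quantile_fail"), info)
  } else {
    body <- character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}
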