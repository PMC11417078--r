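#' Targeted panel design
#'
#' Parameters of the hybridization-capture panel being emulated: a
#' pan-cancer design of 127 genes covering 800 kb. Simulation works on a
#' desk-scale site universe (`positions_per_gene` assayable sites per gene)
#' rather than every base of the target region; the panel object records the
#' real design's parameters.
#'
#' @param n_genes Number of genes on the panel.
#' @param target_size_bp Total target length in bases.
#' @param positions_per_gene Simulated assayable sites per gene.
#' @return A list of class `panel_design`.
#' @export
panel_design <- function(n_genes = 127, target_size_bp = 800000,
                         positions_per_gene = 3) {
  stopifnot(n_genes >= 1, target_size_bp >= n_genes, positions_per_gene >= 1)
  structure(list(n_genes = n_genes, target_size_bp = target_size_bp,
                 positions_per_gene = positions_per_gene),
            class = "panel_design")
}

#' Simulation configuration
#'
#' Defaults reproduce the statistical structure of a 17-patient locally
#' advanced rectal cancer cohort under neoadjuvant radio(chemo)therapy:
#' protocol mix 5 SCRT / 6 RAPIDO / 6 fRCT, 9/17 Dworak responders, 12/17
#' patients with detectable ctDNA, pre-therapy tumor VAFs log-uniform on
#' 0.1-8.4%, responders' tumor VAFs shrinking 5-fold at t1, ultradeep
#' 10,000x coverage, and a right-skewed per-site background error
#' distribution (recurrent position-specific artifacts are what the
#' downstream quantile filter targets).
#'
#' Clonal hematopoiesis (CHIP) is modelled as cohort-level recurrent hotspot
#' positions: every patient's buffycoat carries a VAF drawn from
#' `chip_vaf_range` at each hotspot, and the matching plasma carries the
#' same expected VAF. This is the contamination class the buffycoat
#' comparison and cohort quantile filter exist to remove.
#'
#' @param n_patients Cohort size.
#' @param protocol_mix Named proportions over SCRT, RAPIDO, fRCT (sum 1);
#'   patients are allocated deterministically by largest remainder, so a
#'   17-patient cohort under the default mix has exactly 5/6/6.
#' @param responder_fraction Probability a patient is a Dworak responder
#'   (TRG 3-4).
#' @param ctdna_positive_fraction Probability a patient carries detectable
#'   tumor variants.
#' @param vaf_range_t0 Pre-therapy tumor VAF range (fractions); draws are
#'   log-uniform.
#' @param response_effect Multiplicative change of tumor VAF at t1 for
#'   responders (0.2 = 5-fold decrease).
#' @param nonresponder_effect_range Per-variant t1 multiplier range for
#'   non-responders (uniform draw), producing increase and mixed dynamics.
#' @param n_tumor_variants_range Range of tumor variant counts per
#'   ctDNA-positive patient (uniform integer draw).
#' @param n_chip_variants_per_patient Number of CHIP hotspot positions.
#' @param chip_vaf_range CHIP VAF range (fractions, uniform draw per
#'   patient per hotspot).
#' @param germline_het_count Heterozygous germline variants per patient.
#' @param depth_mean Mean per-library sequencing depth (Poisson draw).
#' @param error_rate_mean,error_rate_shape,error_rate_max Per-site
#'   background error rates are Gamma(shape, mean) draws capped at max,
#'   constant across all libraries at the same site.
#' @param panel A [panel_design()].
#' @param seed Integer seed; fixes every downstream draw.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 17,
                       protocol_mix = c(SCRT = 5, RAPIDO = 6, fRCT = 6) / 17,
                       responder_fraction = 9 / 17,
                       ctdna_positive_fraction = 12 / 17,
                       vaf_range_t0 = c(0.001, 0.084),
                       response_effect = 0.2,
                       nonresponder_effect_range = c(0.5, 2),
                       n_tumor_variants_range = c(1, 4),
                       n_chip_variants_per_patient = 2,
                       chip_vaf_range = c(0.005, 0.05),
                       germline_het_count = 10,
                       depth_mean = 10000,
                       error_rate_mean = 5e-4,
                       error_rate_shape = 1,
                       error_rate_max = 5e-3,
                       panel = panel_design(),
                       seed = 1L) {
  cfg <- list(
    n_patients = n_patients, protocol_mix = protocol_mix,
    responder_fraction = responder_fraction,
    ctdna_positive_fraction = ctdna_positive_fraction,
    vaf_range_t0 = vaf_range_t0, response_effect = response_effect,
    nonresponder_effect_range = nonresponder_effect_range,
    n_tumor_variants_range = n_tumor_variants_range,
    n_chip_variants_per_patient = n_chip_variants_per_patient,
    chip_vaf_range = chip_vaf_range,
    germline_het_count = germline_het_count,
    depth_mean = depth_mean, error_rate_mean = error_rate_mean,
    error_rate_shape = error_rate_shape, error_rate_max = error_rate_max,
    panel = panel, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_patients < 1) stop("empty cohort: n_patients must be >= 1",
                               call. = FALSE)
  if (abs(sum(cfg$protocol_mix) - 1) > 1e-8 || any(cfg$protocol_mix < 0)) {
    stop("protocol_mix must be non-negative proportions summing to 1",
         call. = FALSE)
  }
  if (!all(names(cfg$protocol_mix) %in% c("SCRT", "RAPIDO", "fRCT"))) {
    stop("protocol_mix names must be SCRT, RAPIDO, fRCT", call. = FALSE)
  }
  probs <- c(cfg$responder_fraction, cfg$ctdna_positive_fraction)
  if (any(probs < 0 | probs > 1)) stop("fractions must lie in [0,1]",
                                       call. = FALSE)
  for (r in list(cfg$vaf_range_t0, cfg$chip_vaf_range)) {
    if (any(r < 0 | r > 1) || r[1] > r[2]) {
      stop("VAF ranges must be ordered intervals within [0,1]",
           call. = FALSE)
    }
  }
  if (cfg$depth_mean < 1) stop("depth_mean must be >= 1", call. = FALSE)
  invisible(cfg)
}

# exact largest-remainder apportionment of n patients over the mix
allocate_protocols <- function(n, mix) {
  raw <- n * mix
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  rep(names(mix), times = base)
}

# a handful of real CRC / pan-cancer panel symbols for readable output,
# padded to the panel size with generic symbols
panel_gene_symbols <- function(n) {
  known <- c("APC", "TP53", "KRAS", "FBXW7", "EP300", "TET2", "VHL",
             "PIK3CA", "SMAD4", "BRAF", "DNMT3A", "ATM", "NRAS", "PTEN",
             "CTNNB1", "EGFR", "ERBB2", "MSH2", "MLH1", "POLE")
  if (n <= length(known)) return(known[seq_len(n)])
  c(known, sprintf("GENE%03d", seq_len(n - length(known))))
}

build_panel_sites <- function(panel) {
  n_sites <- panel$n_genes * panel$positions_per_gene
  genes <- panel_gene_symbols(panel$n_genes)
  chrom <- paste0("chr", ((seq_len(panel$n_genes) - 1) %% 22) + 1)
  bases <- c("A", "C", "G", "T")
  sites <- tibble::tibble(
    site_id = seq_len(n_sites),
    gene = rep(genes, each = panel$positions_per_gene),
    chrom = rep(chrom, each = panel$positions_per_gene),
    gene_idx = rep(seq_len(panel$n_genes), each = panel$positions_per_gene),
    offset = rep(seq_len(panel$positions_per_gene), times = panel$n_genes)
  )
  # deterministic spacing: genes occupy disjoint loci on their chromosome
  sites$pos <- 1000000L + sites$gene_idx * 10000L + sites$offset * 100L
  sites$ref <- sample(bases, n_sites, replace = TRUE)
  sites$alt <- vapply(sites$ref,
                      function(r) sample(setdiff(bases, r), 1), "")
  sites$consequence <- sample(
    c("missense", "frameshift", "inframe_indel", "stop_gained",
      "essential_splice"),
    n_sites, replace = TRUE, prob = c(22, 13, 5, 2, 1))
  sites$gene_idx <- NULL
  sites$offset <- NULL
  sites
}

loguniform <- function(n, lo, hi) {
  if (lo <= 0) lo <- 1e-6
  exp(stats::runif(n, log(lo), log(hi)))
}

#' Generate a truth-labelled synthetic cohort
#'
#' Draws patient labels (protocol, Dworak TRG, staging, downstaging), the
#' panel site universe with per-site background error rates, and the true
#' variant set: tumor variants (plasma only, timepoint-specific VAFs), CHIP
#' hotspot variants (equal expected VAF in plasma and buffycoat, cohort-wide
#' recurrent), and heterozygous germline variants (VAF 0.5 in every
#' compartment). Also plans the sequencing libraries — two duplicate plasma
#' libraries per timepoint and one buffycoat library per patient — and draws
#' plasma cfDNA masses.
#'
#' @param config A [sim_config()].
#' @return A list of class `cohort_truth` with elements `patients`, `sites`,
#'   `variants`, `manifest`, `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  ids <- sprintf("SIM%03d", seq_len(n))

  protocol <- sample(allocate_protocols(n, config$protocol_mix))
  responder <- stats::runif(n) < config$responder_fraction
  trg <- ifelse(responder, sample(3:4, n, replace = TRUE), 1L)
  ctdna_positive <- stats::runif(n) < config$ctdna_positive_fraction

  # clinical staging: downstaging (decrease in BOTH T and N) holds for all
  # responders and about half the non-responders
  downstaging <- responder | stats::runif(n) < 0.5
  cT <- sample(3:4, n, replace = TRUE)
  cN <- sample(1:2, n, replace = TRUE)
  ypT <- ifelse(downstaging, cT - sample(1:2, n, replace = TRUE), cT)
  ypN <- ifelse(downstaging, cN - 1L, cN)
  ypT <- pmax(ypT, 0L)

  patients <- tibble::tibble(
    patient_id = ids, protocol = protocol, dworak_trg = as.integer(trg),
    responder = responder, downstaging = downstaging,
    cT = as.integer(cT), cN = as.integer(cN),
    ypT = as.integer(ypT), ypN = as.integer(ypN),
    ctdna_positive = ctdna_positive
  )

  sites <- build_panel_sites(config$panel)
  sites$error_rate <- if (config$error_rate_mean > 0) {
    pmin(
      stats::rgamma(nrow(sites), shape = config$error_rate_shape,
                    rate = config$error_rate_shape / config$error_rate_mean),
      config$error_rate_max)
  } else {
    rep(0, nrow(sites))
  }

  n_hot <- config$n_chip_variants_per_patient
  hotspot_ids <- if (n_hot > 0) sample(sites$site_id, n_hot) else integer()

  variant_list <- vector("list", n)
  for (i in seq_len(n)) {
    free <- setdiff(sites$site_id, hotspot_ids)
    rows <- list()
    if (ctdna_positive[i]) {
      k <- sample(seq(config$n_tumor_variants_range[1],
                      config$n_tumor_variants_range[2]), 1)
      tum_sites <- sample(free, k)
      free <- setdiff(free, tum_sites)
      v0 <- loguniform(k, config$vaf_range_t0[1], config$vaf_range_t0[2])
      mult <- if (responder[i]) {
        rep(config$response_effect, k)
      } else {
        stats::runif(k, config$nonresponder_effect_range[1],
                     config$nonresponder_effect_range[2])
      }
      rows$tumor <- tibble::tibble(site_id = tum_sites, origin = "tumor",
                                   vaf_t0 = v0, vaf_t1 = pmin(v0 * mult, 1))
    }
    if (n_hot > 0) {
      cv <- stats::runif(n_hot, config$chip_vaf_range[1],
                         config$chip_vaf_range[2])
      rows$chip <- tibble::tibble(site_id = hotspot_ids, origin = "chip",
                                  vaf_t0 = cv, vaf_t1 = cv)
    }
    if (config$germline_het_count > 0) {
      g_sites <- sample(free, config$germline_het_count)
      rows$germline <- tibble::tibble(site_id = g_sites, origin = "germline",
                                      vaf_t0 = 0.5, vaf_t1 = 0.5)
    }
    v <- dplyr::bind_rows(rows)
    if (nrow(v) > 0) v$patient_id <- ids[i]
    variant_list[[i]] <- v
  }
  variants <- dplyr::bind_rows(variant_list)
  if (nrow(variants) == 0) {
    variants <- tibble::tibble(
      patient_id = character(), site_id = integer(), chrom = character(),
      pos = integer(), ref = character(), alt = character(),
      gene = character(), consequence = character(), origin = character(),
      vaf_t0 = double(), vaf_t1 = double())
  }
  if (nrow(variants) > 0) {
    variants <- dplyr::left_join(
      variants,
      sites[, c("site_id", "chrom", "pos", "ref", "alt", "gene",
                "consequence")],
      by = "site_id")
    variants <- variants[, c("patient_id", "site_id", "chrom", "pos", "ref",
                             "alt", "gene", "consequence", "origin",
                             "vaf_t0", "vaf_t1")]
  }

  # plasma masses: log-normal around a ~30 ng median, clamped to the
  # realistic 5-400 ng span of 10 ml draws
  mass <- function(k) pmin(pmax(stats::rlnorm(k, log(30), 0.75), 5), 400)
  plasma <- tidyr::expand_grid(patient_id = ids, timepoint = c("t0", "t1"),
                               replicate = 1:2)
  masses <- tidyr::expand_grid(patient_id = ids, timepoint = c("t0", "t1"))
  masses$cfdna_ng <- round(mass(nrow(masses)), 1)
  plasma <- dplyr::left_join(plasma, masses, by = c("patient_id", "timepoint"))
  plasma$library_id <- sprintf("%s-%s-%d", plasma$patient_id,
                               plasma$timepoint, plasma$replicate)
  plasma$compartment <- "plasma"
  bc <- tibble::tibble(patient_id = ids, timepoint = "t0",
                       replicate = NA_integer_, cfdna_ng = NA_real_,
                       library_id = paste0(ids, "-bc"),
                       compartment = "buffycoat")
  manifest <- dplyr::bind_rows(plasma, bc)[, MANIFEST_COLS]
  manifest <- manifest[order(manifest$patient_id, manifest$compartment ==
                               "buffycoat", manifest$timepoint,
                             manifest$replicate), ]

  structure(list(patients = patients, sites = sites, variants = variants,
                 manifest = manifest, config = config),
            class = "cohort_truth")
}

# expected VAF per (library, site): germline 0.5 everywhere, CHIP equal in
# plasma and buffycoat, tumor in plasma only at its timepoint's VAF
expected_vaf_table <- function(truth) {
  libs <- truth$manifest
  v <- truth$variants
  if (nrow(v) == 0) {
    return(tibble::tibble(library_id = character(), site_id = integer(),
                          evaf = double()))
  }
  long <- tidyr::pivot_longer(v, c("vaf_t0", "vaf_t1"),
                              names_to = "timepoint", values_to = "vaf")
  long$timepoint <- sub("vaf_", "", long$timepoint)
  pl <- dplyr::inner_join(
    libs[libs$compartment == "plasma", c("library_id", "patient_id",
                                         "timepoint")],
    long, by = c("patient_id", "timepoint"), relationship = "many-to-many")
  bc_v <- v[v$origin != "tumor", , drop = FALSE]  # buffycoat: no tumor DNA
  bc <- dplyr::inner_join(
    libs[libs$compartment == "buffycoat", c("library_id", "patient_id")],
    bc_v, by = "patient_id", relationship = "many-to-many")
  bc$vaf <- bc$vaf_t0
  out <- dplyr::bind_rows(pl[, c("library_id", "site_id", "vaf")],
                          bc[, c("library_id", "site_id", "vaf")])
  dplyr::summarise(dplyr::group_by(out, .data$library_id, .data$site_id),
                   evaf = sum(.data$vaf), .groups = "drop")
}

#' Simulate site counts for every library of a cohort
#'
#' For each library and each panel site, depth is Poisson around
#' `depth_mean` and alt reads are binomial with success probability equal
#' to the compartment's expected VAF plus the site's background error rate.
#' Duplicate libraries of the same sample are independent draws from the
#' same expectation. Deterministic given the config seed (an internal
#' offset decouples the count stream from the cohort-label stream).
#'
#' @param truth A [generate_cohort()] result.
#' @param config The same [sim_config()].
#' @return A site-counts tibble covering all libraries (columns
#'   `library_id`, `chrom`, `pos`, `ref`, `alt`, `ref_reads`, `alt_reads`,
#'   `gene`, `consequence`).
#' @export
generate_site_counts <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "cohort_truth"))
  set.seed((config$seed + 1000003L) %% .Machine$integer.max)
  grid <- tidyr::expand_grid(library_id = truth$manifest$library_id,
                             site_id = truth$sites$site_id)
  grid <- dplyr::left_join(grid, expected_vaf_table(truth),
                           by = c("library_id", "site_id"))
  grid$evaf[is.na(grid$evaf)] <- 0
  grid <- dplyr::left_join(grid, truth$sites, by = "site_id")
  p <- pmin(grid$evaf + grid$error_rate, 1)
  depth <- stats::rpois(nrow(grid), config$depth_mean)
  alt <- stats::rbinom(nrow(grid), depth, p)
  grid$alt_reads <- alt
  grid$ref_reads <- depth - alt
  grid[, c("library_id", COUNTS_COLS)]
}

#' Write a simulated cohort to disk as pipeline input files
#'
#' Emits `manifest.tsv`, `clinical.tsv`, `cohort_truth.tsv` (truth labels
#' for recovery tests) and one `counts/<library_id>.tsv` per library, in the
#' formats the readers in this package consume.
#'
#' @param truth A [generate_cohort()] result.
#' @param counts A [generate_site_counts()] result.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_fixture <- function(truth, counts, dir) {
  dir.create(file.path(dir, "counts"), recursive = TRUE, showWarnings = FALSE)
  files <- character()
  f <- file.path(dir, "manifest.tsv")
  readr::write_tsv(truth$manifest, f, progress = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "clinical.tsv")
  readr::write_tsv(truth$patients[, c("patient_id", "protocol", "dworak_trg",
                                      "downstaging")], f, progress = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "cohort_truth.tsv")
  readr::write_tsv(truth$variants, f, progress = FALSE)
  files <- c(files, f)
  for (lib in unique(counts$library_id)) {
    f <- file.path(dir, "counts", paste0(lib, ".tsv"))
    readr::write_tsv(counts[counts$library_id == lib, ], f, progress = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
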