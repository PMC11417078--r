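# simulate one cohort end to end; `...` overrides sim_config() defaults
run_sim <- function(seed, ...) {
  cfg <- sim_config(seed = seed, ...)
  truth <- generate_cohort(cfg)
  counts <- generate_site_counts(truth)
  list(cfg = cfg, truth = truth, counts = counts)
}

# compact panel for tests that only need structure, not 381 sites
small_panel <- function() panel_design(n_genes = 8, positions_per_gene = 2)

# hand-built site-count row(s)
sc_row <- function(library_id, chrom = "chr1", pos = 1000L, ref = "C",
                   alt = "T", ref_reads = 9990L, alt_reads = 10L,
                   gene = "APC", consequence = "missense") {
  tibble::tibble(library_id = library_id, chrom = chrom, pos = pos,
                 ref = ref, alt = alt, ref_reads = ref_reads,
                 alt_reads = alt_reads, gene = gene,
                 consequence = consequence)
}

# minimal manifest for one patient with duplicate plasma libraries at both
# timepoints plus a buffycoat
mini_manifest <- function(patient = "P1") {
  tibble::tibble(
    patient_id = patient,
    timepoint = c("t0", "t0", "t1", "t1", "t0"),
    library_id = paste0(patient, c("-t0-1", "-t0-2", "-t1-1", "-t1-2",
                                   "-bc")),
    replicate = c(1L, 2L, 1L, 2L, NA),
    compartment = c(rep("plasma", 4), "buffycoat"),
    cfdna_ng = c(30, 30, 40, 40, NA))
}

# independent sort-and-interpolate percentile: rank = p/100 * (n-1)
# between adjacent order statistics (the convention the filter pins)
quantile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- p / 100 * (n - 1)
  lo <- floor(h)
  if (lo >= n - 1) return(s[n])
  s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
}

# brute-force two-sided Fisher p by direct choose() enumeration
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 - (n - c1)); hi <- min(r1, c1)
  prob <- function(a) {
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
  }
  p_all <- vapply(lo:hi, prob, 0)
  p_obs <- prob(tab[1, 1])
  min(1, sum(p_all[p_all <= p_obs * (1 + 1e-7)]))
}
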