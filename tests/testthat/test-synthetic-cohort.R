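test_that("a fixed seed reproduces the cohort and every count byte", {
  a <- run_sim(3, panel = small_panel())
  b <- run_sim(3, panel = small_panel())
  expect_identical(a$truth$patients, b$truth$patients)
  expect_identical(a$truth$variants, b$truth$variants)
  expect_identical(a$truth$manifest, b$truth$manifest)
  expect_identical(a$counts, b$counts)
  c2 <- run_sim(4, panel = small_panel())
  expect_false(identical(a$counts, c2$counts))
})

test_that("protocol allocation is exact under the default mix", {
  truth <- generate_cohort(sim_config(seed = 1))
  tab <- table(truth$patients$protocol)
  expect_equal(unname(tab[c("RAPIDO", "fRCT", "SCRT")]),
               c(6L, 6L, 5L), ignore_attr = TRUE)
  expect_equal(nrow(truth$patients), 17)
  # every patient: 4 plasma libraries + 1 buffycoat
  libs <- table(truth$manifest$patient_id)
  expect_true(all(libs == 5))
})

test_that("degenerate fractions and invalid configs behave", {
  truth <- generate_cohort(sim_config(seed = 2, ctdna_positive_fraction = 0,
                                      panel = small_panel()))
  expect_false(any(truth$variants$origin == "tumor"))
  expect_error(sim_config(n_patients = 0), "empty cohort")
  expect_error(sim_config(protocol_mix = c(SCRT = 0.7, RAPIDO = 0.7,
                                           fRCT = -0.4)), "protocol_mix")
  expect_error(sim_config(vaf_range_t0 = c(0.5, 0.1)), "ordered intervals")
})

test_that("zero expected VAF and zero error rate give zero alt reads", {
  sim <- run_sim(5, panel = small_panel(), ctdna_positive_fraction = 0,
                 n_chip_variants_per_patient = 0, germline_het_count = 0,
                 error_rate_mean = 0, n_patients = 4)
  expect_true(all(sim$counts$alt_reads == 0))
})

test_that("simulated VAFs are binomially unbiased at depth 10,000", {
  # 50 patients x 4 plasma libraries = 200 replicate libraries, each with
  # expected VAF 0.05 at the single CHIP hotspot and no background error
  sim <- run_sim(6, n_patients = 50, ctdna_positive_fraction = 0,
                 germline_het_count = 0, n_chip_variants_per_patient = 1,
                 chip_vaf_range = c(0.05, 0.05), error_rate_mean = 0,
                 panel = small_panel())
  hot <- sim$truth$variants$pos[1]
  pl_libs <- sim$truth$manifest$library_id[
    sim$truth$manifest$compartment == "plasma"]
  x <- sim$counts[sim$counts$pos == hot &
                    sim$counts$library_id %in% pl_libs, ]
  expect_equal(nrow(x), 200)
  vaf <- x$alt_reads / (x$alt_reads + x$ref_reads)
  se_mean <- sqrt(0.05 * 0.95 / (10000 * 200))
  expect_lt(abs(mean(vaf) - 0.05), 3 * se_mean)
  # independent Monte-Carlo oracle from a separately seeded binomial draw
  set.seed(999)
  oracle <- mean(stats::rbinom(200, 10000, 0.05) / 10000)
  expect_lt(abs(oracle - 0.05), 3 * se_mean)
  expect_lt(abs(mean(vaf) - oracle), 6 * se_mean)
})

test_that("germline heterozygous sites stay near VAF 0.5 in buffycoat", {
  # binomial tail oracle: at depth >= 1000 and p = 0.5 the observed VAF
  # lies in (0.4, 0.6) with probability > 0.999
  p_in <- stats::pbinom(599, 1000, 0.5) - stats::pbinom(400, 1000, 0.5)
  expect_gt(p_in, 0.999)
  sim <- run_sim(7, panel = small_panel(), germline_het_count = 4,
                 n_patients = 10)
  g <- sim$truth$variants[sim$truth$variants$origin == "germline", ]
  bc_libs <- sim$truth$manifest[sim$truth$manifest$compartment ==
                                  "buffycoat", c("patient_id", "library_id")]
  g <- dplyr::left_join(g, bc_libs, by = "patient_id")
  obs <- dplyr::inner_join(
    sim$counts, g[, c("library_id", "pos")], by = c("library_id", "pos"))
  vaf <- obs$alt_reads / (obs$alt_reads + obs$ref_reads)
  expect_equal(length(vaf), nrow(g))
  expect_true(all(vaf > 0.4 & vaf < 0.6))
})

test_that("pooling duplicate libraries estimates the true VAF unbiasedly", {
  true_vaf <- 0.02
  err <- vapply(1:100, function(s) {
    sim <- run_sim(1000 + s, n_patients = 2, ctdna_positive_fraction = 0,
                   germline_het_count = 0, n_chip_variants_per_patient = 1,
                   chip_vaf_range = c(true_vaf, true_vaf),
                   error_rate_mean = 0,
                   panel = panel_design(n_genes = 2, positions_per_gene = 1))
    hot <- sim$truth$variants$pos[1]
    m <- sim$truth$manifest
    lib1 <- m$library_id[m$timepoint == "t0" & m$replicate %in% 1 &
                           m$compartment == "plasma"][1]
    lib2 <- m$library_id[m$timepoint == "t0" & m$replicate %in% 2 &
                           m$compartment == "plasma"][1]
    a <- sim$counts[sim$counts$library_id == lib1 & sim$counts$pos == hot, ]
    b <- sim$counts[sim$counts$library_id == lib2 & sim$counts$pos == hot, ]
    pooled <- pool_duplicates(a, b)
    pooled$alt_reads / (pooled$alt_reads + pooled$ref_reads) - true_vaf
  }, 0)
  se <- sqrt(true_vaf * (1 - true_vaf) / (2 * 10000 * 100))
  expect_lt(abs(mean(err)), 3 * se)
})

test_that("tumor variants leave buffycoat alt counts at error level", {
  hits <- 0L
  total <- 0L
  for (s in 1:10) {
    sim <- run_sim(2000 + s, panel = small_panel(),
                   ctdna_positive_fraction = 1, germline_het_count = 0,
                   n_chip_variants_per_patient = 0)
    tv <- sim$truth$variants[sim$truth$variants$origin == "tumor", ]
    bc_libs <- sim$truth$manifest[
      sim$truth$manifest$compartment == "buffycoat",
      c("patient_id", "library_id")]
    tv <- dplyr::left_join(tv, bc_libs, by = "patient_id")
    obs <- dplyr::inner_join(sim$counts, tv[, c("library_id", "pos")],
                             by = c("library_id", "pos"))
    obs <- dplyr::left_join(obs,
                            sim$truth$sites[, c("pos", "error_rate")],
                            by = "pos")
    depth <- obs$ref_reads + obs$alt_reads
    bound <- stats::qbinom(0.999, depth, obs$error_rate)
    hits <- hits + sum(obs$alt_reads <= bound)
    total <- total + nrow(obs)
  }
  expect_gte(hits / total, 0.99)
})

test_that("fixture files round-trip through the readers", {
  sim <- run_sim(8, panel = small_panel(), n_patients = 4)
  d <- withr::local_tempdir()
  write_fixture(sim$truth, sim$counts, d)
  m <- read_manifest(file.path(d, "manifest.tsv"))
  expect_equal(nrow(m$plasma_samples), 8)
  expect_equal(nrow(m$buffycoat), 4)
  expect_equal(as.data.frame(m$manifest),
               as.data.frame(sim$truth$manifest))
  counts2 <- read_counts_dir(file.path(d, "counts"))
  orig <- sim$counts[order(sim$counts$library_id, sim$counts$pos), ]
  counts2 <- counts2[order(counts2$library_id, counts2$pos), ]
  expect_equal(as.data.frame(counts2), as.data.frame(orig),
               ignore_attr = TRUE)
  cl <- read_clinical(file.path(d, "clinical.tsv"))
  expect_equal(cl$patient_id, sim$truth$patients$patient_id)
  truth2 <- readr::read_tsv(file.path(d, "cohort_truth.tsv"),
                            show_col_types = FALSE)
  expect_equal(nrow(truth2), nrow(sim$truth$variants))
})

test_that("an all-background cohort writes valid, empty-variant fixtures", {
  sim <- run_sim(9, panel = small_panel(), n_patients = 2,
                 ctdna_positive_fraction = 0, germline_het_count = 0,
                 n_chip_variants_per_patient = 0)
  d <- withr::local_tempdir()
  write_fixture(sim$truth, sim$counts, d)
  truth2 <- readr::read_tsv(file.path(d, "cohort_truth.tsv"),
                            show_col_types = FALSE)
  expect_equal(nrow(truth2), 0)
  expect_equal(nrow(read_manifest(file.path(d, "manifest.tsv"))$buffycoat),
               2)
})
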