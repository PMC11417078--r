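# buffycoat counts for one position across libraries, from a VAF vector at
# fixed depth
bc_from_vafs <- function(vafs, depth = 10000L, pos = 1000L) {
  dplyr::bind_rows(lapply(seq_along(vafs), function(i) {
    alt <- as.integer(round(vafs[i] * depth))
    sc_row(sprintf("BC%02d", i), pos = pos, ref_reads = depth - alt,
           alt_reads = alt)
  }))
}

cand_row <- function(vaf_t0, vaf_t1 = 0, pos = 1000L, depth = 20000L,
                     patient = "P1") {
  tibble::tibble(
    patient_id = patient, chrom = "chr1", pos = pos, ref = "C", alt = "T",
    gene = "APC", consequence = "missense",
    support_t0 = TRUE, support_t1 = FALSE,
    alt_t0 = round(vaf_t0 * depth), depth_t0 = depth, vaf_t0 = vaf_t0,
    alt_t1 = round(vaf_t1 * depth), depth_t1 = depth, vaf_t1 = vaf_t1,
    bc_alt = 0L, bc_depth = 10000L, bc_vaf = 0)
}

test_that("the percentile VAF interpolates between order statistics", {
  pan <- build_panel(bc_from_vafs(rep(0, 17)), cand_row(0.01))
  expect_equal(pan$table$q, 0)
  # {0 x16, 0.01}: rank 0.95 * 16 = 15.2 -> 0.2 of the final step
  pan <- build_panel(bc_from_vafs(c(rep(0, 16), 0.01)), cand_row(0.01))
  expect_equal(pan$table$q, 0.002)
  # never exceeds the maximum
  set.seed(31)
  for (i in 1:20) {
    v <- stats::runif(sample(2:25, 1), 0, 0.05)
    pan <- build_panel(bc_from_vafs(v), cand_row(0.01))
    expect_lte(pan$table$q, max(v) + 1e-12)
  }
})

test_that("panel construction handles missing coverage and bad input", {
  bc <- dplyr::bind_rows(
    bc_from_vafs(c(0, 0, 0.001)),
    sc_row("BC04", pos = 1000L, ref_reads = 0L, alt_reads = 0L))
  pan <- build_panel(bc, cand_row(0.01))
  expect_equal(pan$table$n_obs, 3)
  expect_equal(pan$table$n_missing, 1)
  expect_equal(pan$n_libraries, 4)
  expect_error(build_panel(bc, cand_row(0.01, pos = 9999L)),
               "chr1:9999")
  expect_error(build_panel(bc_from_vafs(0.001), cand_row(0.01)),
               "at least 2")
})

test_that("validation is strict: VAF must exceed twice the percentile", {
  pan <- build_panel(bc_from_vafs(rep(0.004, 17)), cand_row(0.01))
  v <- validate_variant(cand_row(0.010), pan)
  expect_equal(v$q95, 0.004)
  expect_equal(v$threshold, 0.008)
  expect_true(v$passed)
  # exactly at the threshold: fails
  v <- validate_variant(cand_row(0.008), pan)
  expect_false(v$passed)
  # zero background: any positive VAF passes
  pan0 <- build_panel(bc_from_vafs(rep(0, 17)), cand_row(6e-4))
  v <- validate_variant(cand_row(6e-4), pan0)
  expect_equal(v$threshold, 0)
  expect_true(v$passed)
  # evaluated VAF is the larger timepoint
  v <- validate_variant(cand_row(0.001, vaf_t1 = 0.02), pan)
  expect_equal(v$evaluated_vaf, 0.02)
  expect_true(v$passed)
  expect_false(v$passed_t0)
  expect_true(v$passed_t1)
  expect_error(validate_variant(cand_row(0.01, pos = 77L), pan),
               "missing from panel")
})

test_that("verdicts agree exactly with an independent recomputation", {
  set.seed(41)
  n_inst <- 1000
  ok <- logical(n_inst)
  for (i in seq_len(n_inst)) {
    n_lib <- sample(3:20, 1)
    vafs <- ifelse(stats::runif(n_lib) < 0.5, 0,
                   stats::runif(n_lib, 0, 0.02))
    cand_vaf <- if (i %% 5 == 0) {
      # boundary construction: exactly multiplier x percentile
      2 * unname(stats::quantile(vafs, 0.95, type = 7))
    } else {
      stats::runif(1, 0, 0.05)
    }
    pan <- build_panel(bc_from_vafs(vafs, depth = 1000L),
                       cand_row(0.01))
    dep <- 1000L
    cv <- round(cand_vaf * dep) / dep  # representable as counts
    v <- validate_variant(cand_row(cv, depth = dep), pan)
    # oracle: base quantile type 7 on the same observed VAF list
    obs_vafs <- sort(unlist(pan$table$vafs))
    q_oracle <- unname(stats::quantile(obs_vafs, 0.95, type = 7))
    ok[i] <- isTRUE(v$passed == (cv > 2 * q_oracle)) &&
      isTRUE(all.equal(v$q95, q_oracle, tolerance = 1e-12))
  }
  expect_true(all(ok))
})

test_that("raising multiplier or percentile never rescues a failure", {
  set.seed(43)
  vafs <- stats::runif(17, 0, 0.01)
  cand <- cand_row(0.012)
  base <- validate_variant(
    cand, build_panel(bc_from_vafs(vafs), cand), filter_params())
  for (mult in c(2.5, 3, 5)) {
    v <- validate_variant(cand, build_panel(bc_from_vafs(vafs), cand),
                          filter_params(multiplier = mult))
    expect_true(!v$passed || base$passed)
  }
  for (pct in c(97, 99)) {
    fp <- filter_params(percentile = pct)
    v <- validate_variant(cand, build_panel(bc_from_vafs(vafs), cand, fp),
                          fp)
    expect_true(!v$passed || base$passed)
  }
})

test_that("the panel is exchangeable over patient identity", {
  sim <- run_sim(44, panel = small_panel())
  man <- sim$truth$manifest
  bc_libs <- man$library_id[man$compartment == "buffycoat"]
  bc <- sim$counts[sim$counts$library_id %in% bc_libs, ]
  cand <- detect_candidates(sim$counts, man)
  pan <- build_panel(bc, cand)
  # permute the library ids: per-position VAF lists are unordered sets
  perm <- setNames(sample(bc_libs), bc_libs)
  bc2 <- bc
  bc2$library_id <- perm[bc2$library_id]
  pan2 <- build_panel(bc2, cand)
  expect_equal(pan$table$q, pan2$table$q)
  v1 <- validate_variant(cand, pan)
  v2 <- validate_variant(cand, pan2)
  expect_identical(v1$passed, v2$passed)
})

test_that("filter results are independent of candidate order", {
  sim <- run_sim(45, panel = small_panel())
  man <- sim$truth$manifest
  bc <- sim$counts[sim$counts$library_id %in%
                     man$library_id[man$compartment == "buffycoat"], ]
  cand <- detect_candidates(sim$counts, man)
  pan <- build_panel(bc, cand)
  a <- filter_cohort(cand, pan)
  set.seed(1)
  b <- filter_cohort(cand[sample(nrow(cand)), ], pan)
  key <- function(x) {
    x <- x$variants
    x[order(x$patient_id, x$chrom, x$pos), c("patient_id", "pos", "passed")]
  }
  expect_equal(key(a), key(b), ignore_attr = TRUE)
  expect_equal(a$detection_rate, b$detection_rate)
})

test_that("recurrent CHIP-level background is rejected cohort-wide", {
  # VAF 0.01 in the plasma and in every buffycoat: threshold 2 x 0.01
  pan <- build_panel(bc_from_vafs(rep(0.01, 17)), cand_row(0.01))
  v <- validate_variant(cand_row(0.01), pan)
  expect_false(v$passed)
  # zero candidates: detection rate 0
  f <- filter_cohort(cand_row(0.01)[0, ], pan, patients = c("P1", "P2"))
  expect_equal(f$detection_rate, 0)
  expect_equal(nrow(f$per_patient), 2)
})
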