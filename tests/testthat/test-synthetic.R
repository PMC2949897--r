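test_that("generators are deterministic under a fixed seed", {
  s1 <- simulate_pooled_intensities(n_snps = 30, seed = 77)
  s2 <- simulate_pooled_intensities(n_snps = 30, seed = 77)
  expect_identical(s1, s2)
  t1 <- simulate_score_table(n_snps = 100, seed = 77)
  t2 <- simulate_score_table(n_snps = 100, seed = 77)
  expect_identical(t1, t2)
  expect_identical(simulate_pvalue_table(50, seed = 3),
                   simulate_pvalue_table(50, seed = 3))
  expect_false(identical(simulate_pvalue_table(50, seed = 3)$value,
                         simulate_pvalue_table(50, seed = 4)$value))
})

test_that("the noiseless limit recovers true pooled frequencies exactly", {
  sim <- simulate_pooled_intensities(
    n_snps = 60, noise_sd = 0,
    spiked = tibble::tibble(chrom = "1", center = 30, width = 5, delta = 0.2),
    seed = 8)
  ras <- compute_ras(sim$intensity)
  joined <- dplyr::left_join(ras, sim$truth, by = c("snp_id", "chrom", "pos"))
  expect_equal(joined$ras[joined$group == "case"],
               joined$q_case[joined$group == "case"])
  expect_equal(joined$ras[joined$group == "control"],
               joined$q_control[joined$group == "control"])
})

test_that("per-SNP mean RAS tracks true frequency closely at realistic noise", {
  sim <- simulate_pooled_intensities(n_snps = 400, n_case = 4, n_control = 4,
                                     noise_sd = 0.02, seed = 15)
  ras <- compute_ras(sim$intensity)
  means <- dplyr::summarise(dplyr::group_by(ras, .data$snp_id),
                            m = mean(.data$ras), .groups = "drop")
  joined <- dplyr::left_join(means, sim$truth, by = "snp_id")
  frac_close <- mean(abs(joined$m - joined$q_control) <= 0.03)
  expect_gte(frac_close, 0.99)
})

test_that("score tables respect the background and spike construction", {
  none <- simulate_score_table(n_snps = 300, seed = 4)
  expect_true(all(none$table$value <= 70))
  expect_false(any(none$truth$is_spiked))
  sp <- simulate_score_table(
    n_snps = 5000,
    spiked = tibble::tibble(chrom = "1", center = 2500, width = 10), seed = 4)
  expect_equal(sum(sp$truth$is_spiked), 10)
  spike_vals <- sp$table$value[match(sp$truth$snp_id[sp$truth$is_spiked],
                                     sp$table$snp_id)]
  expect_true(all(spike_vals >= 90 & spike_vals <= 100))
  expect_false(is.unsorted(sp$table$pos, strictly = TRUE))
  expect_equal(value_kind(sp$table), "score")
})

test_that("out-of-bounds spike windows are rejected", {
  expect_error(
    simulate_score_table(
      n_snps = 100,
      spiked = tibble::tibble(chrom = "1", center = 99, width = 10), seed = 1),
    "bounds")
  expect_error(
    simulate_pooled_intensities(
      n_snps = 50,
      spiked = tibble::tibble(chrom = "1", center = 1, width = 5, delta = 0.1),
      seed = 1),
    "bounds")
  expect_error(
    simulate_pooled_intensities(
      n_snps = 50,
      spiked = tibble::tibble(chrom = "1", center = 25, width = 3, delta = 0.7),
      seed = 1),
    "delta")
})

test_that("dialect fixtures round-trip through their presets", {
  pv <- simulate_pvalue_table(n_snps = 40, chromosomes = c("2", "X"), seed = 6)
  d <- withr::local_tempdir()
  files <- write_dialect_fixtures(pv, d)
  expect_named(files, c("genepool", "plink_assoc", "eigenstrat"))
  for (nm in names(files)) {
    back <- read_association_table(files[[nm]], nm)
    expect_equal(as.character(back$chrom), as.character(pv$chrom))
    expect_equal(back$pos, pv$pos)
    expect_equal(back$snp_id, pv$snp_id)
    # 12-significant-digit serialisation
    expect_equal(back$value, pv$value, tolerance = 1e-11)
  }
  # header present in the plink dialect only
  expect_match(readLines(files[["plink_assoc"]], n = 1), "^CHR ")
  expect_no_match(readLines(files[["genepool"]], n = 1), "[A-Z]{2}")
})

test_that("empty tables produce empty (or header-only) fixtures that parse back", {
  empty <- simulate_pvalue_table(n_snps = 1, seed = 1)[0, ]
  empty <- assoc_table(character(), numeric(), character(), numeric(), "pvalue")
  d <- withr::local_tempdir()
  files <- write_dialect_fixtures(empty, d)
  for (nm in names(files)) {
    expect_equal(nrow(read_association_table(files[[nm]], nm)), 0)
  }
})

test_that("score tables cannot be written into p-value dialects silently", {
  sc <- simulate_score_table(n_snps = 20, seed = 2)
  d <- withr::local_tempdir()
  expect_error(write_dialect_fixtures(sc$table, d), "admissible")
  # the score-kind genepool dialect alone is fine
  f <- write_dialect_fixtures(sc$table, d, dialects = "genepool")
  back <- read_association_table(f[["genepool"]], "genepool")
  expect_equal(back$value, sc$table$value, tolerance = 1e-11)
})
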