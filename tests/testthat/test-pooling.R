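cell <- function(a, b, snp = "rs1", array = "p1", group = "case",
                 chrom = "1", pos = 1) {
  tibble::tibble(snp_id = snp, chrom = parse_chrom(chrom), pos = pos,
                 array_id = array, group = group, a = a, b = b)
}

# One SNP with explicit per-array RAS values, realised as intensities.
ras_fixture <- function(case, control) {
  n <- length(case) + length(control)
  tibble::tibble(
    snp_id = "rs1", chrom = parse_chrom(rep("1", n)), pos = 1,
    array_id = sprintf("p%02d", seq_len(n)),
    group = rep(c("case", "control"), c(length(case), length(control))),
    a = 1000 * c(case, control), b = 1000 * (1 - c(case, control))
  )
}

test_that("RAS is the channel ratio a/(a+b) with boundary cases intact", {
  expect_equal(compute_ras(cell(50, 50))$ras, 0.5)
  expect_equal(compute_ras(cell(75, 25))$ras, 0.75)
  expect_equal(compute_ras(cell(0, 10))$ras, 0)
  expect_error(compute_ras(cell(0, 0)), "rs1.*p1")
  expect_error(compute_ras(cell(-1, 5)), "non-negative")
})

test_that("mean RAS difference is case minus control with sign preserved", {
  x <- compute_ras(ras_fixture(c(0.6, 0.6), c(0.5, 0.5)))
  expect_equal(mean_ras_difference(x)$ras_diff, 0.1)
  y <- compute_ras(ras_fixture(0.4, 0.5))
  expect_equal(mean_ras_difference(y)$ras_diff, -0.1)
  z <- compute_ras(ras_fixture(c(0.3, 0.7), c(0.3, 0.7)))
  expect_equal(mean_ras_difference(z)$ras_diff, 0)
})

test_that("swapping case/control labels negates ras_diff and t but keeps p", {
  set.seed(11)
  x <- compute_ras(ras_fixture(runif(3), runif(4)))
  swapped <- dplyr::mutate(x, group = ifelse(group == "case", "control", "case"))
  expect_equal(mean_ras_difference(swapped)$ras_diff,
               -mean_ras_difference(x)$ras_diff)
  t1 <- ras_t_test(x); t2 <- ras_t_test(swapped)
  expect_equal(t2$t_stat, -t1$t_stat)
  expect_equal(t2$p_value, t1$p_value)
})

test_that("identical groups give t = 0, p = 1", {
  x <- compute_ras(ras_fixture(c(0.6, 0.6), c(0.6, 0.6)))
  tt <- ras_t_test(x)
  expect_equal(tt$t_stat, 0)
  expect_equal(tt$p_value, 1)
})

test_that("the Welch statistic matches stats::t.test to 1e-10", {
  cases <- list(
    list(case = c(0.7, 0.8, 0.9), control = c(0.1, 0.2, 0.3)),
    list(case = c(0.5, 0.51), control = c(0.52, 0.48, 0.55)),
    list(case = runif(6), control = runif(4))
  )
  set.seed(42)
  for (cs in cases) {
    x <- compute_ras(ras_fixture(cs$case, cs$control))
    tt <- ras_t_test(x)
    ref <- t.test(x$ras[x$group == "case"], x$ras[x$group == "control"],
                  var.equal = FALSE)
    expect_equal(tt$t_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(tt$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(tt$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("group size preconditions are enforced", {
  x <- compute_ras(ras_fixture(0.5, 0.6))
  expect_error(ras_t_test(x), "at least 2")
  only_case <- dplyr::filter(x, group == "case")
  expect_error(mean_ras_difference(only_case), "at least 1")
})

test_that("rank_snps follows the stated order statistics and tie-break", {
  expect_equal(rank_snps(c(5, 9, 1)), c(2L, 1L, 3L))
  expect_equal(rank_snps(c(0.2, 0.1, 0.3), descending = FALSE), c(2L, 1L, 3L))
  expect_equal(rank_snps(c(7, 7, 7)), c(1L, 2L, 3L))  # ties by map order
  expect_error(rank_snps(c(1, NA)), "finite")
  expect_error(rank_snps(c(1, Inf)), "finite")
})

test_that("rank_snps agrees with the sort-based oracle and is a permutation", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(1:60, 1)
    scores <- sample(round(runif(n, 0, 5), 1))  # duplicates likely
    desc <- rep %% 2 == 0
    r <- rank_snps(scores, descending = desc)
    expect_identical(r, rank_oracle(scores, desc))
    expect_setequal(r, seq_len(n))
  }
})

test_that("pool_analyze assembles the full result in map order", {
  sim <- simulate_pooled_intensities(
    n_snps = 40, n_case = 3, n_control = 3,
    spiked = tibble::tibble(chrom = "1", center = 20, width = 1, delta = 0.3),
    noise_sd = 0.01, seed = 5)
  res <- pool_analyze(sim$intensity)
  expect_equal(nrow(res), 40)
  expect_setequal(res$rank, 1:40)
  expect_false(is.unsorted(res$pos))
  expect_true(all(res$ras_diff >= -1 & res$ras_diff <= 1))
  expect_equal(res$ras_diff, res$mean_ras_case - res$mean_ras_control)
  spiked_id <- sim$truth$snp_id[sim$truth$is_spiked]
  expect_equal(res$rank[res$snp_id == spiked_id], 1L)
})

test_that("pooling results written to disk are readable by the genepool preset", {
  sim <- simulate_pooled_intensities(n_snps = 15, seed = 9)
  res <- pool_analyze(sim$intensity)
  f <- tempfile()
  write_pooling_result(res, f)
  back <- read_association_table(f, "genepool")
  expect_equal(back$snp_id, res$snp_id)
  expect_equal(back$value, res$t_stat, tolerance = 1e-11)
})

test_that("intensity matrices round-trip through the wide TSV format", {
  sim <- simulate_pooled_intensities(n_snps = 8, n_case = 2, n_control = 3,
                                     seed = 2)
  ip <- tempfile(); sp <- tempfile()
  write_intensity_matrix(sim$intensity, ip, sp)
  back <- read_intensity_matrix(ip, sp)
  ord <- order(back$snp_id, back$array_id)
  ord0 <- order(sim$intensity$snp_id, sim$intensity$array_id)
  expect_equal(back$a[ord], sim$intensity$a[ord0], tolerance = 1e-12)
  expect_equal(back$b[ord], sim$intensity$b[ord0], tolerance = 1e-12)
  expect_equal(back$group[ord], sim$intensity$group[ord0])
})
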