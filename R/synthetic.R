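#' Simulate pooled two-channel SNP-array intensities
#'
#' Generates an intensity table with known ground truth for testing the
#' pooling pipeline end to end. Each SNP gets a true A-allele frequency `q`
#' drawn uniform(0.05, 0.95); SNPs inside a spiked window get
#' `q_case = q + delta` (clamped into (0.01, 0.99)) while controls keep
#' `q`. Per array, the A-channel mean is `intensity_total * q_group` and
#' the B-channel mean `intensity_total * (1 - q_group)`; each channel is
#' perturbed by multiplicative lognormal noise, `x * exp(N(0, noise_sd))`,
#' whose relative standard deviation is approximately `noise_sd`. With
#' `noise_sd = 0` every array's RAS equals the true pooled frequency
#' exactly. Fully deterministic given `seed`.
#'
#' @param n_snps SNPs per chromosome.
#' @param chromosomes chromosome labels to simulate.
#' @param n_case,n_control number of case / control arrays (`>= 2` for the
#'   t statistic downstream).
#' @param spiked tibble/data frame with columns `chrom`, `center` (SNP
#'   index within the chromosome), `width` (window length in SNPs) and
#'   `delta` (case-minus-control pooled frequency shift, in (-0.5, 0.5));
#'   `NULL` for no spike.
#' @param intensity_total mean total intensity per SNP.
#' @param noise_sd per-channel relative noise level, `>= 0`.
#' @param seed integer RNG seed.
#' @return list with elements `intensity` (long tibble as in
#'   [read_intensity_matrix()]) and `truth` (per-SNP tibble with `snp_id`,
#'   `chrom`, `pos`, `q_case`, `q_control`, `is_spiked`).
#' @export
simulate_pooled_intensities <- function(n_snps = 1000,
                                        chromosomes = "1",
                                        n_case = 4, n_control = 4,
                                        spiked = NULL,
                                        intensity_total = 2000,
                                        noise_sd = 0.02,
                                        seed = 1) {
  if (n_case < 2 || n_control < 2) {
    stop("need at least 2 arrays per class", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(spiked)) {
    stopifnot(all(c("chrom", "center", "width", "delta") %in% names(spiked)))
    if (any(abs(spiked$delta) >= 0.5)) {
      stop("delta must lie in (-0.5, 0.5)", call. = FALSE)
    }
  }
  set.seed(seed)
  truth <- purrr::map(chromosomes, function(ch) {
    pos <- cumsum(sample.int(2000, n_snps, replace = TRUE))
    q <- stats::runif(n_snps, 0.05, 0.95)
    spike <- rep(FALSE, n_snps)
    delta <- rep(0, n_snps)
    if (!is.null(spiked)) {
      for (i in which(as.character(spiked$chrom) == as.character(ch))) {
        lo <- spiked$center[i] - floor(spiked$width[i] / 2)
        hi <- lo + spiked$width[i] - 1
        if (lo < 1 || hi > n_snps) {
          stop("spiked window [", lo, ", ", hi, "] exceeds chromosome bounds",
               call. = FALSE)
        }
        spike[lo:hi] <- TRUE
        delta[lo:hi] <- spiked$delta[i]
      }
    }
    tibble::tibble(
      snp_id = sprintf("rs%s_%05d", ch, seq_len(n_snps)),
      chrom = parse_chrom(rep(ch, n_snps)),
      pos = pos,
      q_control = q,
      q_case = pmin(pmax(q + delta, 0.01), 0.99),
      is_spiked = spike
    )
  })
  truth <- dplyr::bind_rows(truth)
  arrays <- tibble::tibble(
    array_id = c(sprintf("case%02d", seq_len(n_case)),
                 sprintf("ctrl%02d", seq_len(n_control))),
    group = rep(c("case", "control"), c(n_case, n_control))
  )
  grid <- tidyr::crossing(dplyr::select(truth, "snp_id", "chrom", "pos",
                                        "q_case", "q_control"),
                          arrays)
  grid <- dplyr::arrange(grid, .data$chrom, .data$pos, .data$snp_id,
                         .data$array_id)
  q <- ifelse(grid$group == "case", grid$q_case, grid$q_control)
  n_cell <- nrow(grid)
  noise <- function() {
    if (noise_sd == 0) rep(1, n_cell) else exp(stats::rnorm(n_cell, 0, noise_sd))
  }
  intensity <- dplyr::mutate(
    dplyr::select(grid, "snp_id", "chrom", "pos", "array_id", "group"),
    a = intensity_total * q * noise(),
    b = intensity_total * (1 - q) * noise()
  )
  list(intensity = intensity, truth = truth)
}

#' Simulate a score table with a localized peak
#'
#' Emulates the background-plus-peak structure of a noisy genome-wide rank
#' or score plot: background SNPs draw scores uniform(0, 70), SNPs inside
#' spiked windows draw uniform(90, 100). Positions are strictly increasing
#' within each chromosome; values are score-kind on the 0–100 display
#' scale. Fully deterministic given `seed`.
#'
#' @inheritParams simulate_pooled_intensities
#' @param spiked tibble with columns `chrom`, `center`, `width` (`delta`
#'   is ignored for score tables); `NULL` for pure background.
#' @param background_max upper bound of the background score band.
#' @param spike_range score band for spiked SNPs.
#' @return list with `table` (an `assoc_tbl`, value_kind `"score"`) and
#'   `truth` (per-SNP tibble with `is_spiked`).
#' @export
simulate_score_table <- function(n_snps = 5000, chromosomes = "1",
                                 spiked = NULL, background_max = 70,
                                 spike_range = c(90, 100), seed = 1) {
  set.seed(seed)
  rows <- purrr::map(chromosomes, function(ch) {
    pos <- cumsum(sample.int(2000, n_snps, replace = TRUE))
    value <- stats::runif(n_snps, 0, background_max)
    spike <- rep(FALSE, n_snps)
    if (!is.null(spiked)) {
      for (i in which(as.character(spiked$chrom) == as.character(ch))) {
        lo <- spiked$center[i] - floor(spiked$width[i] / 2)
        hi <- lo + spiked$width[i] - 1
        if (lo < 1 || hi > n_snps) {
          stop("spiked window [", lo, ", ", hi, "] exceeds chromosome bounds",
               call. = FALSE)
        }
        spike[lo:hi] <- TRUE
      }
    }
    value[spike] <- stats::runif(sum(spike), spike_range[1], spike_range[2])
    tibble::tibble(
      snp_id = sprintf("rs%s_%05d", ch, seq_len(n_snps)),
      chrom = rep(ch, n_snps), pos = pos, value = value, is_spiked = spike
    )
  })
  rows <- dplyr::bind_rows(rows)
  table <- assoc_table(rows$chrom, rows$pos, rows$snp_id, rows$value, "score")
  truth <- dplyr::select(
    dplyr::mutate(rows, chrom = parse_chrom(.data$chrom)),
    "snp_id", "chrom", "pos", "is_spiked")
  list(table = table, truth = sort_map_order(truth))
}

#' Simulate a null p-value table
#'
#' Uniform(0, 1) p-values on a simulated map — the null input for Q-Q and
#' genomic-control calibration checks.
#'
#' @inheritParams simulate_score_table
#' @return an `assoc_tbl` with value_kind `"pvalue"`.
#' @export
simulate_pvalue_table <- function(n_snps = 1000, chromosomes = "1", seed = 1) {
  set.seed(seed)
  rows <- purrr::map(chromosomes, function(ch) {
    tibble::tibble(
      snp_id = sprintf("rs%s_%05d", ch, seq_len(n_snps)),
      chrom = rep(ch, n_snps),
      pos = cumsum(sample.int(2000, n_snps, replace = TRUE)),
      value = stats::runif(n_snps)
    )
  })
  rows <- dplyr::bind_rows(rows)
  assoc_table(rows$chrom, rows$pos, rows$snp_id, rows$value, "pvalue")
}

fmt_sig <- function(x) sprintf("%.12g", x)

#' Write an association table in the built-in dialects
#'
#' Emits one file per built-in preset (`genepool.txt`, `plink_assoc.txt`,
#' `eigenstrat.txt`) whose contents parse back via the corresponding preset
#' to the same (chrom, pos, id, value) records. Values are written with 12
#' significant digits. The table's values must be admissible under every
#' dialect's value kind (the plink_assoc and eigenstrat presets are
#' p-value-kind, so values must lie in (0, 1] to write all three); the
#' function errors rather than converting silently. The plink_assoc file
#' carries a header line, the other two do not, so header auto-detection is
#' exercised both ways.
#'
#' @param table an `assoc_tbl`.
#' @param out_dir output directory; created if missing.
#' @param dialects subset of `c("genepool", "plink_assoc", "eigenstrat")`.
#' @return (invisibly) named character vector of the files written.
#' @export
write_dialect_fixtures <- function(table, out_dir,
                                   dialects = c("genepool", "plink_assoc",
                                                "eigenstrat")) {
  dialects <- match.arg(dialects, several.ok = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  presets <- builtin_presets()
  v <- table$value
  out <- character()
  for (d in dialects) {
    pr <- presets[[d]]
    validate_values_or_explain(v, pr$value_kind, d)
    lines <- switch(
      d,
      genepool = sprintf("%s %s %d %s", table$snp_id,
                         as.character(table$chrom), as.integer(table$pos),
                         fmt_sig(v)),
      plink_assoc = c(
        "CHR SNP BP A1 F_A F_U A2 CHISQ P",
        sprintf("%s %s %d A 0.5 0.5 G %s %s", as.character(table$chrom),
                table$snp_id, as.integer(table$pos),
                fmt_sig(-2 * log(pmax(v, .Machine$double.xmin))), fmt_sig(v))
      ),
      eigenstrat = sprintf("%s\t%s\t%d\t%s", table$snp_id,
                           as.character(table$chrom), as.integer(table$pos),
                           fmt_sig(v))
    )
    path <- file.path(out_dir, paste0(d, ".txt"))
    con <- file(path, open = "wb")
    writeLines(lines, con)
    close(con)
    out[d] <- path
  }
  invisible(out)
}

validate_values_or_explain <- function(v, kind, dialect) {
  ok <- tryCatch({ validate_values(v, kind); TRUE }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("table values are not admissible for the '", dialect,
         "' dialect (", kind, "-kind): ", conditionMessage(ok), call. = FALSE)
  }
  invisible(TRUE)
}
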