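#' Pooled intensity tables
#'
#' DNA-pooling designs hybridise pooled case and control DNA on separate
#' arrays; the two allele-channel intensities A and B at each SNP then
#' reflect the pool's allele frequencies. The package carries pooled
#' intensities as a long tibble with one row per (SNP, array) cell:
#' columns `snp_id`, `chrom`, `pos`, `array_id`, `group` ("case"/"control"),
#' `a`, `b` (non-negative channel intensities).
#'
#' `read_intensity_matrix()` reads the wide on-disk form: a TSV with columns
#' `snp_id`, `chrom`, `pos`, then one `<array>_A`, `<array>_B` column pair
#' per array, plus a two-column sample sheet TSV (`array_id`, `group`).
#'
#' @param path intensity TSV path.
#' @param sample_sheet sample-sheet TSV path (`array_id<TAB>group` with
#'   header).
#' @return long intensity tibble as described above.
#' @export
read_intensity_matrix <- function(path, sample_sheet) {
  if (!file.exists(path)) stop("intensity file not found: ", path, call. = FALSE)
  if (!file.exists(sample_sheet)) {
    stop("sample sheet not found: ", sample_sheet, call. = FALSE)
  }
  sheet <- utils::read.delim(sample_sheet, header = TRUE,
                             colClasses = "character")
  names(sheet) <- tolower(names(sheet))
  stopifnot(all(c("array_id", "group") %in% names(sheet)))
  wide <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  long <- tidyr::pivot_longer(
    wide, cols = -c("snp_id", "chrom", "pos"),
    names_to = c("array_id", "channel"), names_pattern = "^(.*)_([AB])$",
    values_to = "intensity"
  )
  long <- tidyr::pivot_wider(long, names_from = "channel",
                             values_from = "intensity")
  names(long)[names(long) %in% c("A", "B")] <- c("a", "b")
  long <- dplyr::left_join(long, sheet, by = "array_id")
  if (any(is.na(long$group))) {
    stop("sample sheet is missing arrays: ",
         paste(unique(long$array_id[is.na(long$group)]), collapse = ", "),
         call. = FALSE)
  }
  long$chrom <- parse_chrom(long$chrom)
  dplyr::select(long, "snp_id", "chrom", "pos", "array_id", "group", "a", "b")
}

#' Write a pooled intensity table and sample sheet
#'
#' Inverse of [read_intensity_matrix()].
#'
#' @param intensities long intensity tibble.
#' @param path,sample_sheet output paths.
#' @return invisibly, `path`.
#' @export
write_intensity_matrix <- function(intensities, path, sample_sheet) {
  wide <- tidyr::pivot_wider(
    dplyr::select(intensities, "snp_id", "chrom", "pos", "array_id", "a", "b"),
    names_from = "array_id", values_from = c("a", "b"),
    names_glue = "{array_id}_{toupper(.value)}"
  )
  arrays <- unique(intensities$array_id)
  ord <- c("snp_id", "chrom", "pos",
           as.vector(rbind(paste0(arrays, "_A"), paste0(arrays, "_B"))))
  utils::write.table(wide[, ord], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sheet <- unique(dplyr::select(intensities, "array_id", "group"))
  utils::write.table(sheet, sample_sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Relative allele signal (RAS)
#'
#' RAS is the per-SNP, per-array ratio A/(A+B) of the two allele-channel
#' intensities; for a pooled array it estimates the A-allele frequency of
#' the pool.
#'
#' @param intensities long intensity tibble (see [read_intensity_matrix()]).
#' @return the input with a `ras` column appended (values in `[0, 1]`).
#' @examples
#' x <- tibble::tibble(snp_id = "rs1", chrom = "1", pos = 1,
#'                     array_id = "p1", group = "case", a = 75, b = 25)
#' compute_ras(x)$ras  # 0.75
#' @export
compute_ras <- function(intensities) {
  tot <- intensities$a + intensities$b
  if (any(!is.finite(tot)) || any(tot <= 0)) {
    i <- which(!is.finite(tot) | tot <= 0)[1]
    stop("zero or invalid total intensity at SNP ", intensities$snp_id[i],
         ", array ", intensities$array_id[i], call. = FALSE)
  }
  if (any(intensities$a < 0) || any(intensities$b < 0)) {
    stop("channel intensities must be non-negative", call. = FALSE)
  }
  dplyr::mutate(intensities, ras = .data$a / (.data$a + .data$b))
}

check_groups <- function(group, min_per_class = 1) {
  n_case <- sum(group == "case")
  n_ctrl <- sum(group == "control")
  if (!all(group %in% c("case", "control"))) {
    stop("group labels must be 'case' or 'control'", call. = FALSE)
  }
  if (n_case < min_per_class || n_ctrl < min_per_class) {
    stop("need at least ", min_per_class, " array(s) per class; got ",
         n_case, " case, ", n_ctrl, " control", call. = FALSE)
  }
  invisible(TRUE)
}

#' Signed mean-RAS difference per SNP
#'
#' The mean RAS over case arrays minus the mean over control arrays, sign
#' preserved: a positive difference means allele A is more frequent in
#' cases, so it is evident which allele predominates in which group.
#'
#' @param ras a long tibble with columns `snp_id`, `chrom`, `pos`, `group`,
#'   `ras` (e.g. the output of [compute_ras()]).
#' @return per-SNP tibble with `mean_ras_case`, `mean_ras_control` and
#'   `ras_diff` in `[-1, 1]`, in map order.
#' @export
mean_ras_difference <- function(ras) {
  check_groups(unique(ras[, c("array_id", "group")])$group, 1)
  out <- dplyr::summarise(
    dplyr::group_by(ras, .data$snp_id, .data$chrom, .data$pos),
    mean_ras_case = mean(.data$ras[.data$group == "case"]),
    mean_ras_control = mean(.data$ras[.data$group == "control"]),
    .groups = "drop"
  )
  out <- dplyr::mutate(out, ras_diff = .data$mean_ras_case - .data$mean_ras_control)
  sort_map_order(out)
}

#' Per-SNP Welch two-sample t test on RAS values
#'
#' Treats each array's RAS at a SNP as one observation and compares case
#' vs control arrays with the unequal-variance (Welch) two-sample t
#' statistic; the two-sided p-value comes from the t distribution with
#' Welch–Satterthwaite degrees of freedom. When both groups have zero
#' variance and equal means, t = 0 and p = 1; with unequal means the
#' statistic is infinite and the p-value is floored at
#' `.Machine$double.xmin` to stay within (0, 1].
#'
#' @inheritParams mean_ras_difference
#' @return per-SNP tibble with `t_stat`, `df` and `p_value`, in map order.
#' @export
ras_t_test <- function(ras) {
  check_groups(unique(ras[, c("array_id", "group")])$group, 2)
  welch <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    m1 <- mean(x); m2 <- mean(y)
    v1 <- stats::var(x); v2 <- stats::var(y)
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) {
      if (m1 == m2) return(c(t = 0, df = n1 + n2 - 2, p = 1))
      return(c(t = sign(m1 - m2) * Inf, df = n1 + n2 - 2,
               p = .Machine$double.xmin))
    }
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    c(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
  }
  out <- dplyr::summarise(
    dplyr::group_by(ras, .data$snp_id, .data$chrom, .data$pos),
    res = list(welch(.data$ras[.data$group == "case"],
                     .data$ras[.data$group == "control"])),
    .groups = "drop"
  )
  out <- dplyr::mutate(
    out,
    t_stat = purrr::map_dbl(.data$res, "t"),
    df = purrr::map_dbl(.data$res, "df"),
    p_value = pmax(purrr::map_dbl(.data$res, "p"), .Machine$double.xmin)
  )
  sort_map_order(dplyr::select(out, -"res"))
}

#' Rank SNPs by a score
#'
#' Rank 1 is the best SNP: the largest score when `descending = TRUE`, the
#' smallest (e.g. a p-value) when `descending = FALSE`. Ties are broken by
#' input order, which for map-sorted tables means the earlier
#' chromosome/position gets the better rank; the result is always a
#' permutation of 1..N.
#'
#' @param scores finite numeric vector, one per SNP in map order.
#' @param descending rank largest first? Default `TRUE`.
#' @return integer ranks, same length as `scores`.
#' @examples
#' rank_snps(c(5, 9, 1))              # 2 1 3
#' rank_snps(c(.2, .1, .3), FALSE)    # 2 1 3
#' @export
rank_snps <- function(scores, descending = TRUE) {
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  key <- if (descending) -scores else scores
  ord <- order(key, seq_along(scores))
  ranks <- integer(length(scores))
  ranks[ord] <- seq_along(scores)
  ranks
}

#' Full pooling analysis
#'
#' Runs the whole pooled-RAS pipeline for one intensity table: RAS values,
#' per-SNP case/control mean RAS and signed difference, Welch t statistic
#' with two-sided p-value, and the genome-wide rank (rank 1 = smallest
#' p-value, ties broken by map order).
#'
#' @inheritParams compute_ras
#' @return per-SNP tibble in map order with columns `snp_id`, `chrom`,
#'   `pos`, `mean_ras_case`, `mean_ras_control`, `ras_diff`, `t_stat`,
#'   `p_value`, `rank`.
#' @export
pool_analyze <- function(intensities) {
  ras <- compute_ras(intensities)
  diffs <- mean_ras_difference(ras)
  tt <- ras_t_test(ras)
  out <- dplyr::left_join(diffs, dplyr::select(tt, -"df"),
                          by = c("snp_id", "chrom", "pos"))
  out$rank <- rank_snps(out$p_value, descending = FALSE)
  out
}

#' Write a pooling result as a GenePool-dialect association table
#'
#' Columns `snp_id chrom pos t_stat p_value rank ras_diff`,
#' whitespace-delimited, no header — readable with the built-in
#' `"genepool"` preset (which picks up the t statistic as the value).
#'
#' @param result output of [pool_analyze()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pooling_result <- function(result, path) {
  lines <- sprintf("%s\t%s\t%d\t%.12g\t%.12g\t%d\t%.12g",
                   result$snp_id, as.character(result$chrom),
                   as.integer(result$pos), result$t_stat, result$p_value,
                   as.integer(result$rank), result$ras_diff)
  con <- file(path, open = "wb")
  writeLines(lines, con)
  close(con)
  invisible(path)
}
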