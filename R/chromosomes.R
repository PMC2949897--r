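#' Canonical chromosome ordering
#'
#' Association tables are kept in map order: autosomes 1..22, then X, Y, MT,
#' positions ascending within each chromosome. `chrom_levels()` returns the
#' label set in that order; `parse_chrom()` normalises arbitrary input labels
#' ("chr1", "x", "chrMT", ...) onto it.
#'
#' @return `chrom_levels()`: character vector of the 25 canonical labels.
#' @export
chrom_levels <- function() c(as.character(1:22), "X", "Y", "MT")

#' @rdname chrom_levels
#' @param x character vector of chromosome labels; a leading "chr" prefix is
#'   stripped and case is ignored for X/Y/MT ("M" is accepted for MT).
#' @return `parse_chrom()`: factor with levels `chrom_levels()`.
#' @export
parse_chrom <- function(x) {
  lab <- toupper(sub("^chr", "", as.character(x), ignore.case = TRUE))
  lab[lab == "M"] <- "MT"
  bad <- !(lab %in% chrom_levels())
  if (any(bad)) {
    stop("unknown chromosome label(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  factor(lab, levels = chrom_levels())
}

# Sort a per-SNP tibble into map order and check (chrom, pos, snp_id) unique.
sort_map_order <- function(tbl) {
  tbl <- dplyr::arrange(tbl, .data$chrom, .data$pos, .data$snp_id)
  key <- paste(tbl$chrom, tbl$pos, tbl$snp_id)
  if (anyDuplicated(key)) {
    stop("duplicate (chrom, pos, snp_id) rows: ",
         paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "),
         call. = FALSE)
  }
  tbl
}
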