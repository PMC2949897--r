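#' Build an association table
#'
#' The association table is the universal currency of the package: one row
#' per SNP with `chrom`, `pos`, `snp_id` and a `value` whose meaning
#' (`"score"`, `"rank"` or `"pvalue"`) travels with the table as the
#' `value_kind` attribute. Rows are kept in map order (chromosomes 1..22,
#' X, Y, MT; positions ascending) and duplicate (chrom, pos, snp_id)
#' triples are rejected.
#'
#' @param chrom chromosome labels (coerced via [parse_chrom()]).
#' @param pos 1-based base-pair positions (positive integers).
#' @param snp_id SNP identifiers.
#' @param value per-SNP values, finite; p-values must lie in (0, 1],
#'   ranks must be >= 1.
#' @param value_kind `"score"`, `"rank"` or `"pvalue"`.
#' @return a tibble of class `assoc_tbl` with columns
#'   `chrom`, `pos`, `snp_id`, `value` and attribute `value_kind`.
#' @export
assoc_table <- function(chrom, pos, snp_id, value,
                        value_kind = c("score", "rank", "pvalue")) {
  value_kind <- match.arg(value_kind)
  tbl <- tibble::tibble(
    chrom = parse_chrom(chrom),
    pos = as.numeric(pos),
    snp_id = as.character(snp_id),
    value = as.numeric(value)
  )
  if (any(!is.finite(tbl$pos)) || any(tbl$pos < 1) || any(tbl$pos != round(tbl$pos))) {
    stop("positions must be positive integers (1-based)", call. = FALSE)
  }
  validate_values(tbl$value, value_kind)
  tbl <- sort_map_order(tbl)
  new_assoc_tbl(tbl, value_kind)
}

new_assoc_tbl <- function(tbl, value_kind) {
  structure(tbl,
            value_kind = value_kind,
            class = c("assoc_tbl", class(tibble::as_tibble(tbl))))
}

#' @rdname assoc_table
#' @param x an `assoc_tbl`.
#' @export
value_kind <- function(x) attr(x, "value_kind", exact = TRUE)

validate_values <- function(value, value_kind, line = NULL) {
  where <- function(i) {
    if (is.null(line)) paste0("row ", i) else paste0("line ", line[i])
  }
  bad <- !is.finite(value)
  if (any(bad)) {
    stop("non-finite value at ", where(which(bad)[1]), call. = FALSE)
  }
  if (value_kind == "pvalue" && any(value <= 0 | value > 1)) {
    i <- which(value <= 0 | value > 1)[1]
    stop("p-value outside (0, 1] at ", where(i), ": ", value[i], call. = FALSE)
  }
  if (value_kind == "rank" && any(value < 1)) {
    i <- which(value < 1)[1]
    stop("rank < 1 at ", where(i), ": ", value[i], call. = FALSE)
  }
  invisible(TRUE)
}

split_fields <- function(lines, delimiter_policy) {
  if (delimiter_policy == "tab") {
    strsplit(lines, "\t", fixed = TRUE)
  } else {
    strsplit(trimws(lines), "[ \t]+")
  }
}

#' Read an association table from delimited text
#'
#' Handles any tab- or whitespace-delimited text file, with or without a
#' header line; the column layout comes from a [column_preset()]. With
#' `header_mode = "auto"` the first line is treated as a header iff its
#' value field does not parse as a real number. Rows are re-sorted into map
#' order regardless of input order.
#'
#' @param path path to the text file.
#' @param preset a [column_preset()] or the name of a built-in preset.
#' @return an `assoc_tbl` (see [assoc_table()]).
#' @examples
#' f <- tempfile()
#' writeLines(c("chr pos id p", "1 100 rs1 0.5", "1 50 rs2 0.1"), f)
#' pr <- column_preset("demo", "auto", "any_whitespace", 1, 2, 3, 4, "pvalue", 8)
#' read_association_table(f, pr)
#' @export
read_association_table <- function(path, preset) {
  preset <- resolve_preset(preset)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(new_assoc_tbl(
      tibble::tibble(chrom = parse_chrom(character()), pos = numeric(),
                     snp_id = character(), value = numeric()),
      preset$value_kind))
  }
  fields <- split_fields(lines, preset$delimiter_policy)
  need <- max(preset$chrom_col, preset$pos_col, preset$id_col, preset$value_col)
  first_val <- if (length(fields[[1]]) >= preset$value_col) {
    fields[[1]][preset$value_col]
  } else {
    NA_character_
  }
  drop_header <- switch(
    preset$header_mode,
    yes = TRUE,
    no = FALSE,
    auto = is.na(suppressWarnings(as.numeric(first_val)))
  )
  if (drop_header) {
    fields <- fields[-1]
    line_no <- line_no[-1]
  }
  if (length(fields) == 0) {
    return(new_assoc_tbl(
      tibble::tibble(chrom = parse_chrom(character()), pos = numeric(),
                     snp_id = character(), value = numeric()),
      preset$value_kind))
  }
  nf <- lengths(fields)
  if (any(nf < need)) {
    i <- which(nf < need)[1]
    stop("line ", line_no[i], " has ", nf[i], " field(s); preset '",
         preset$name, "' needs at least ", need, call. = FALSE)
  }
  grab <- function(col) vapply(fields, `[[`, character(1), col)
  value <- suppressWarnings(as.numeric(grab(preset$value_col)))
  if (any(is.na(value))) {
    i <- which(is.na(value))[1]
    stop("non-numeric value field at line ", line_no[i], ": '",
         grab(preset$value_col)[i], "'", call. = FALSE)
  }
  pos <- suppressWarnings(as.numeric(grab(preset$pos_col)))
  if (any(is.na(pos))) {
    i <- which(is.na(pos))[1]
    stop("non-numeric position field at line ", line_no[i], call. = FALSE)
  }
  validate_values(value, preset$value_kind, line = line_no)
  tbl <- tibble::tibble(
    chrom = parse_chrom(grab(preset$chrom_col)),
    pos = pos,
    snp_id = grab(preset$id_col),
    value = value
  )
  new_assoc_tbl(sort_map_order(tbl), preset$value_kind)
}

#' Write per-chromosome numeric track files
#'
#' Writes one TSV per chromosome present in the track, named by chromosome
#' label (`1.txt` ... `X.txt`), each line `snp_id<TAB>pos<TAB>height` in
#' position order, heights formatted to 6 decimal places. These companion
#' files make the numeric line heights of the rendered bitmaps available to
#' downstream tools (spreadsheets, scripts).
#'
#' @param track a `height_track` (see [scale_to_height()]) or any tibble
#'   with columns `chrom`, `pos`, `snp_id`, `height` in `[0, 100]`.
#' @param out_dir output directory; created if missing.
#' @return (invisibly) character vector of the files written.
#' @export
write_chromosome_tracks <- function(track, out_dir) {
  stopifnot(all(c("chrom", "pos", "snp_id", "height") %in% names(track)))
  if (nrow(track) > 0 &&
      (any(track$height < 0) || any(track$height > 100))) {
    stop("heights must lie in [0, 100]", call. = FALSE)
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", out_dir, call. = FALSE)
  }
  written <- character()
  for (ch in levels(droplevels(track$chrom))) {
    sub <- dplyr::arrange(dplyr::filter(track, .data$chrom == ch), .data$pos)
    path <- file.path(out_dir, paste0(ch, ".txt"))
    lines <- sprintf("%s\t%d\t%.6f", sub$snp_id, as.integer(sub$pos), sub$height)
    con <- file(path, open = "wb")  # fixed LF endings for byte-stable output
    writeLines(lines, con)
    close(con)
    written <- c(written, path)
  }
  invisible(written)
}

#' Read a numeric track file written by [write_chromosome_tracks()]
#'
#' @param path path to one per-chromosome TSV.
#' @param chrom chromosome label to attach.
#' @return tibble with columns `chrom`, `pos`, `snp_id`, `height`.
#' @export
read_chromosome_track <- function(path, chrom) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(
    chrom = parse_chrom(rep(chrom, length(fields))),
    pos = vapply(fields, function(f) as.numeric(f[2]), numeric(1)),
    snp_id = vapply(fields, `[[`, character(1), 1),
    height = vapply(fields, function(f) as.numeric(f[3]), numeric(1))
  )
}
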