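#' Column presets for delimited association tables
#'
#' A column preset describes one delimited-text dialect: how a file produced
#' by some association-analysis program maps onto the universal per-SNP
#' record (chromosome, position, SNP id, value). Any tab- or
#' whitespace-delimited text file, with or without a header line, can be
#' described this way.
#'
#' @param name preset label.
#' @param header_mode `"auto"`, `"yes"` or `"no"`. In `"auto"` mode the first
#'   line is treated as a header iff its value column does not parse as a
#'   real number.
#' @param delimiter_policy `"tab"` (split on single tabs) or
#'   `"any_whitespace"` (collapse runs of spaces/tabs).
#' @param chrom_col,pos_col,id_col,value_col 1-based column indices; must be
#'   distinct.
#' @param value_kind what the value column holds: `"score"` (non-negative
#'   real), `"rank"` (1 = best) or `"pvalue"` (in (0, 1]).
#' @param max_expected maximum expected value, used for height scaling. For
#'   p-values it is the maximum expected -log10(p).
#'
#' @return a `column_preset` object (named list).
#' @examples
#' column_preset("mytool", "yes", "tab", 1, 2, 3, 4, "pvalue", 8)
#' @export
column_preset <- function(name, header_mode, delimiter_policy,
                          chrom_col, pos_col, id_col, value_col,
                          value_kind, max_expected) {
  header_mode <- match.arg(header_mode, c("auto", "yes", "no"))
  delimiter_policy <- match.arg(delimiter_policy, c("tab", "any_whitespace"))
  value_kind <- match.arg(value_kind, c("score", "rank", "pvalue"))
  idx <- c(chrom_col = chrom_col, pos_col = pos_col,
           id_col = id_col, value_col = value_col)
  if (any(idx != round(idx)) || any(idx < 1)) {
    stop("column indices must be positive integers", call. = FALSE)
  }
  if (anyDuplicated(idx)) stop("column indices must be distinct", call. = FALSE)
  if (!is.numeric(max_expected) || max_expected <= 0) {
    stop("max_expected must be > 0", call. = FALSE)
  }
  structure(
    list(name = name, header_mode = header_mode,
         delimiter_policy = delimiter_policy,
         chrom_col = as.integer(chrom_col), pos_col = as.integer(pos_col),
         id_col = as.integer(id_col), value_col = as.integer(value_col),
         value_kind = value_kind, max_expected = as.numeric(max_expected)),
    class = "column_preset"
  )
}

#' @export
print.column_preset <- function(x, ...) {
  cat(sprintf(
    "<column_preset '%s'> header=%s delim=%s chrom=%d pos=%d id=%d value=%d (%s, max %g)\n",
    x$name, x$header_mode, x$delimiter_policy, x$chrom_col, x$pos_col,
    x$id_col, x$value_col, x$value_kind, x$max_expected))
  invisible(x)
}

#' Built-in presets
#'
#' Ships dialects for the three table layouts the package itself writes:
#' \describe{
#'   \item{genepool}{pooling-analysis output: `snp_id chrom pos t_stat
#'     p_value rank ras_diff`, whitespace-delimited, no header; the value
#'     column is the t statistic (score kind).}
#'   \item{plink_assoc}{PLINK `--assoc`-style: header line
#'     `CHR SNP BP A1 F_A F_U A2 CHISQ P`, whitespace-delimited; the value
#'     is the p-value in column 9.}
#'   \item{eigenstrat}{an approximation of EIGENSTRAT-style per-SNP output
#'     rearranged to carry map coordinates: `snp_id chrom pos pvalue`,
#'     tab-delimited, no header.}
#' }
#' The plink_assoc and eigenstrat layouts approximate those programs'
#' dialects; they are exact for files written by [write_dialect_fixtures()].
#'
#' @return named list of [column_preset()] objects.
#' @export
builtin_presets <- function() {
  list(
    genepool = column_preset("genepool", "no", "any_whitespace",
                             chrom_col = 2, pos_col = 3, id_col = 1,
                             value_col = 4, value_kind = "score",
                             max_expected = 100),
    plink_assoc = column_preset("plink_assoc", "yes", "any_whitespace",
                                chrom_col = 1, pos_col = 3, id_col = 2,
                                value_col = 9, value_kind = "pvalue",
                                max_expected = 8),
    eigenstrat = column_preset("eigenstrat", "no", "tab",
                               chrom_col = 2, pos_col = 3, id_col = 1,
                               value_col = 4, value_kind = "pvalue",
                               max_expected = 8)
  )
}

#' Load column presets from an INI file
#'
#' Each `[section]` defines one preset; keys are the [column_preset()]
#' fields (`header_mode`, `delimiter_policy`, `chrom_col`, `pos_col`,
#' `id_col`, `value_col`, `value_kind`, `max_expected`). The built-in
#' presets remain available alongside the loaded ones; a loaded preset with
#' the same name as a built-in overrides it.
#'
#' @param path path to the INI file.
#' @param include_builtin prepend [builtin_presets()]? Default `TRUE`.
#' @return named list of `column_preset` objects.
#' @export
load_presets <- function(path, include_builtin = TRUE) {
  if (!file.exists(path)) stop("preset file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#") & !startsWith(lines, ";")]
  sections <- list()
  current <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      current <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (!is.null(sections[[current]])) {
        stop("duplicate preset section '", current, "' in ", path, call. = FALSE)
      }
      sections[[current]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(current)) {
        stop("key outside any [section] in ", path, ": ", ln, call. = FALSE)
      }
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!is.null(sections[[current]][[key]])) {
        stop("duplicate field '", key, "' in section '", current, "'",
             call. = FALSE)
      }
      sections[[current]][[key]] <- val
    } else {
      stop("unparseable preset line: ", ln, call. = FALSE)
    }
  }
  required <- c("header_mode", "delimiter_policy", "chrom_col", "pos_col",
                "id_col", "value_col", "value_kind", "max_expected")
  loaded <- purrr::imap(sections, function(kv, nm) {
    missing <- setdiff(required, names(kv))
    if (length(missing) > 0) {
      stop("preset section '", nm, "' is missing field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    column_preset(nm, kv$header_mode, kv$delimiter_policy,
                  as.numeric(kv$chrom_col), as.numeric(kv$pos_col),
                  as.numeric(kv$id_col), as.numeric(kv$value_col),
                  kv$value_kind, as.numeric(kv$max_expected))
  })
  if (include_builtin) {
    out <- builtin_presets()
    out[names(loaded)] <- loaded
    out
  } else {
    loaded
  }
}

# Resolve a preset given a name, a column_preset, or NULL -> error listing
# available names. Used by the CLI entry points.
resolve_preset <- function(preset, presets = builtin_presets()) {
  if (inherits(preset, "column_preset")) return(preset)
  if (is.character(preset) && length(preset) == 1) {
    if (!is.null(presets[[preset]])) return(presets[[preset]])
    stop("unknown preset '", preset, "'; available: ",
         paste(names(presets), collapse = ", "), call. = FALSE)
  }
  stop("preset must be a column_preset or a preset name", call. = FALSE)
}
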