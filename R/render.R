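#' Rendering configuration
#'
#' Controls the deterministic raster renderers ([render_chromosome_tracks()],
#' [render_manhattan()], [render_qq()]). Images carry no timestamps or
#' variable metadata, so identical inputs give byte-identical PNG files.
#'
#' @param width image width in pixels (`>= 64`), or `NULL` to use one pixel
#'   column per SNP (minimum 64).
#' @param height image height in pixels (`>= 64`).
#' @param x_mode `"index"` (equal spacing per SNP, the default) or
#'   `"basepair"` (columns proportional to genomic position).
#' @param colors two foreground colours, alternated between chromosomes in
#'   Manhattan plots; the first is used for single-chromosome track images.
#' @param background background colour.
#' @return a `render_config` list.
#' @export
render_config <- function(width = NULL, height = 200,
                          x_mode = c("index", "basepair"),
                          colors = c("#16366e", "#8a9cc9"),
                          background = "white") {
  x_mode <- match.arg(x_mode)
  if (!is.null(width) && (width < 64 || width != round(width))) {
    stop("width must be an integer >= 64 (or NULL for auto)", call. = FALSE)
  }
  if (height < 64 || height != round(height)) {
    stop("height must be an integer >= 64", call. = FALSE)
  }
  stopifnot(length(colors) == 2)
  list(width = width, height = as.integer(height), x_mode = x_mode,
       colors = colors, background = background)
}

rgb01 <- function(col) as.numeric(grDevices::col2rgb(col)) / 255

# Blank height x width x 3 canvas filled with the background colour.
blank_canvas <- function(height, width, background) {
  bg <- rgb01(background)
  array(rep(bg, each = height * width), dim = c(height, width, 3))
}

# Draw vertical lines growing up from the bottom row. xcol/hpx parallel
# vectors; several SNPs mapped to one column keep the tallest line.
draw_lines <- function(img, xcol, hpx, color) {
  H <- dim(img)[1]; W <- dim(img)[2]
  fg <- rgb01(color)
  colh <- numeric(W)
  tall <- tapply(hpx, xcol, max)
  colh[as.integer(names(tall))] <- as.numeric(tall)
  mask <- outer(seq_len(H), colh, function(r, h) r > H - h)
  for (k in 1:3) {
    plane <- img[, , k]
    plane[mask] <- fg[k]
    img[, , k] <- plane
  }
  img
}

map_columns <- function(track_chrom, width, x_mode) {
  n <- nrow(track_chrom)
  if (x_mode == "basepair" && n > 1) {
    p <- track_chrom$pos
    frac <- (p - min(p)) / max(max(p) - min(p), 1)
    pmin(width, pmax(1, 1 + round(frac * (width - 1))))
  } else if (n == 1) {
    1L
  } else {
    pmin(width, pmax(1, round(seq(1, width, length.out = n))))
  }
}

#' Render per-chromosome track bitmaps
#'
#' Writes one PNG per chromosome present in the track. Every SNP is drawn
#' as a vertical line whose pixel height is proportional to its height
#' value: 100 spans the full drawable height. A companion numeric track
#' file per chromosome is written via [write_chromosome_tracks()]. Empty
#' chromosomes are skipped with a message.
#'
#' @param track a `height_track` (heights in `[0, 100]`).
#' @param out_dir output directory; created if missing.
#' @param config a [render_config()].
#' @return (invisibly) tibble with columns `chrom`, `png`, `track_file`.
#' @export
render_chromosome_tracks <- function(track, out_dir, config = render_config()) {
  if (nrow(track) > 0 && (any(track$height < 0) || any(track$height > 100))) {
    stop("heights must lie in [0, 100]", call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  track_files <- write_chromosome_tracks(track, out_dir)
  out <- list()
  for (ch in levels(droplevels(track$chrom))) {
    sub <- dplyr::arrange(dplyr::filter(track, .data$chrom == ch), .data$pos)
    if (nrow(sub) == 0) {
      message("chromosome ", ch, " is empty; skipped")
      next
    }
    W <- config$width %||% max(64L, nrow(sub))
    H <- config$height
    img <- blank_canvas(H, W, config$background)
    xcol <- map_columns(sub, W, config$x_mode)
    hpx <- round(sub$height / 100 * H)
    img <- draw_lines(img, xcol, hpx, config$colors[1])
    path <- file.path(out_dir, paste0(ch, ".png"))
    png::writePNG(img, path)
    out[[ch]] <- tibble::tibble(chrom = ch, png = path,
                                track_file = file.path(out_dir,
                                                       paste0(ch, ".txt")))
  }
  invisible(dplyr::bind_rows(out))
}

# y display value per value_kind: p-values on the -log10 scale, ranks
# flipped so rank 1 plots highest, scores as-is.
manhattan_y <- function(table) {
  kind <- value_kind(table) %||% "score"
  switch(kind,
         pvalue = -log10(table$value),
         rank = max(table$value) - table$value + 1,
         score = table$value)
}

#' Render an unfiltered Manhattan plot
#'
#' One genome-wide image: chromosomes concatenated in map order with
#' alternating colours; the y axis is -log10(p) for p-value tables, the raw
#' score for score tables, and the flipped rank for rank tables. No height
#' filters are applied regardless of any configured chain — this is the
#' quick overview of the raw data set.
#'
#' @param table an `assoc_tbl`.
#' @param path output PNG path.
#' @param config a [render_config()].
#' @return invisibly, `path`.
#' @export
render_manhattan <- function(table, path, config = render_config()) {
  if (nrow(table) == 0) stop("empty association table", call. = FALSE)
  y <- manhattan_y(table)
  ymax <- max(y, 1e-12)
  W <- config$width %||% max(64L, nrow(table))
  H <- config$height
  img <- blank_canvas(H, W, config$background)
  n <- nrow(table)
  xcol <- if (n == 1) 1L else pmin(W, pmax(1, round(seq(1, W, length.out = n))))
  hpx <- round(pmax(y, 0) / ymax * H)
  chroms <- levels(droplevels(table$chrom))
  for (k in seq_along(chroms)) {
    sel <- table$chrom == chroms[k]
    img <- draw_lines(img, xcol[sel], hpx[sel],
                      config$colors[(k - 1) %% 2 + 1])
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Render a Q-Q plot
#'
#' Scatter of -log10(expected) vs -log10(observed) p-values with the y = x
#' reference diagonal; when the table carries a `gc_p` column the corrected
#' series is overlaid in the second configured colour.
#'
#' @param qq a `qq_tbl` from [make_qq_table()].
#' @param path output PNG path.
#' @param config a [render_config()]; `width = NULL` renders at
#'   `height` x `height`.
#' @return invisibly, `path`.
#' @export
render_qq <- function(qq, path, config = render_config()) {
  if (nrow(qq) == 0) stop("empty Q-Q table", call. = FALSE)
  W <- config$width %||% config$height
  H <- config$height
  img <- blank_canvas(H, W, config$background)
  x <- -log10(qq$expected_p)
  y <- -log10(qq$observed_p)
  series <- list(list(y = y, col = config$colors[1]))
  if ("gc_p" %in% names(qq)) {
    series <- c(series, list(list(y = -log10(qq$gc_p), col = config$colors[2])))
  }
  lim <- max(x, vapply(series, function(s) max(s$y), numeric(1)), 1e-12)
  px <- function(v, extent) pmin(extent, pmax(1, 1 + round(v / lim * (extent - 1))))
  set_px <- function(img, row, col, fg) {
    for (k in 1:3) img[cbind(row, col, k)] <- fg[k]
    img
  }
  t_diag <- seq(0, lim, length.out = max(W, H))  # y = x reference line
  img <- set_px(img, H + 1 - px(t_diag, H), px(t_diag, W), rgb01("grey60"))
  for (s in series) {
    img <- set_px(img, H + 1 - px(s$y, H), px(x, W), rgb01(s$col))
  }
  png::writePNG(img, path)
  invisible(path)
}

#' UCSC Genome Browser gateway URL for a SNP's region
#'
#' Builds a link showing a window (default 10 kb) centred on the SNP, so a
#' locus of interest can be inspected in its genomic context.
#'
#' @param chrom chromosome label.
#' @param pos 1-based base-pair position, `>= 1`.
#' @param window_bp window size in base pairs centred on `pos`; the lower
#'   bound is clamped at 1.
#' @param db genome build passed as the `db` parameter (default `"hg19"`).
#' @return the gateway URL string.
#' @examples
#' ucsc_url("1", 1e6)  # ...position=chr1:995000-1005000...
#' @export
ucsc_url <- function(chrom, pos, window_bp = 10000, db = "hg19") {
  ch <- as.character(parse_chrom(chrom))
  if (length(pos) != 1 || !is.finite(pos) || pos < 1) {
    stop("pos must be a single position >= 1", call. = FALSE)
  }
  half <- floor(window_bp / 2)
  start <- max(1, pos - half)
  end <- pos + half
  sprintf("http://genome.ucsc.edu/cgi-bin/hgGateway?db=%s&position=chr%s:%d-%d",
          db, ch, as.integer(start), as.integer(end))
}
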