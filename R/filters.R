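#' Height tracks
#'
#' The rendering functions take display values from 0 to 100, where 100 is a
#' fully saturated signal. `scale_to_height()` converts an association
#' table's values onto that scale:
#' \itemize{
#'   \item score: `height = 100 * min(v, max_expected) / max_expected`;
#'   \item pvalue: `v' = -log10(v)` first, then scaled as a score against
#'     `max_expected` (the maximum expected -log10 p);
#'   \item rank: `height = 100 * (N - rank + 1) / N`, so rank 1 saturates.
#' }
#' All outputs are clipped to `[0, 100]`.
#'
#' @param table an `assoc_tbl` (see [assoc_table()]).
#' @param max_expected maximum expected value; defaults to the preset value
#'   carried by tables the package reads, else must be supplied. Ignored
#'   for rank tables (the number of SNPs is used).
#' @return a tibble of class `height_track` with columns `chrom`, `pos`,
#'   `snp_id`, `height`.
#' @examples
#' tab <- assoc_table("1", c(100, 200), c("a", "b"), c(50, 80), "score")
#' scale_to_height(tab, max_expected = 100)$height  # 50 80
#' @export
scale_to_height <- function(table, max_expected = 100) {
  kind <- value_kind(table)
  if (is.null(kind)) kind <- "score"
  if (!is.numeric(max_expected) || max_expected <= 0) {
    stop("max_expected must be > 0", call. = FALSE)
  }
  v <- table$value
  height <- switch(
    kind,
    score = 100 * pmin(v, max_expected) / max_expected,
    pvalue = {
      if (any(v <= 0)) stop("p-values must be > 0", call. = FALSE)
      100 * pmin(-log10(v), max_expected) / max_expected
    },
    rank = {
      n <- length(v)
      100 * (n - v + 1) / n
    }
  )
  out <- tibble::tibble(
    chrom = table$chrom, pos = table$pos, snp_id = table$snp_id,
    height = pmin(pmax(height, 0), 100)
  )
  structure(out, class = c("height_track", class(tibble::tibble())))
}

replace_heights <- function(track, height) {
  track$height <- height
  track
}

#' Logarithmic enhancement filter
#'
#' Remaps each height r to `r_new = s * 2^(f * (r/s - 1))` with saturation
#' scale `s = 100`. The map is strictly increasing, fixes the saturated
#' value (`r = s` maps to `s`), and compresses the background towards — but
#' never onto — zero: `r = 0` maps to `s * 2^-f > 0`. Larger `f` means a
#' more stringent filter (stronger background suppression).
#'
#' @param track a `height_track`.
#' @param f stringency factor, `> 0`. The Figure-2 style default is 50.
#' @param s saturation scale; the renderer expects 100.
#' @return the track with transformed heights.
#' @export
log_filter <- function(track, f, s = 100) {
  if (!is.numeric(f) || length(f) != 1 || f <= 0) {
    stop("f must be a single positive number", call. = FALSE)
  }
  replace_heights(track, s * 2^(f * (track$height / s - 1)))
}

# Best-of-window mean for one chromosome's height vector.
window_best_chrom <- function(h, m, d) {
  L <- length(h)
  if (m == 1 || L == 0) return(h)
  out <- numeric(L)
  for (i in seq_len(L)) {
    w <- h[i:min(i + m - 1, L)]
    k <- min(m - d, length(w))
    out[i] <- mean(sort(w, decreasing = TRUE)[seq_len(k)])
  }
  out
}

#' Best-of-window sliding mean
#'
#' Assigns to every SNP the average of the best `m - d` of the window formed
#' by itself and the following `m - 1` SNPs. Windows never cross chromosome
#' boundaries; at a chromosome end the window is truncated and the
#' best-count shrinks to the window size. With `m = 1` the filter is the
#' identity; with `d = 0` and full windows it is the plain forward moving
#' average.
#'
#' @param track a `height_track`.
#' @param m window length, `>= 1`.
#' @param d drop count: the `d` worst SNPs of each window are ignored;
#'   `0 <= d < m`.
#' @return the track with smoothed heights.
#' @export
sliding_window_best <- function(track, m, d = 0) {
  if (m < 1 || m != round(m)) stop("m must be an integer >= 1", call. = FALSE)
  if (d < 0 || d >= m || d != round(d)) {
    stop("d must satisfy 0 <= d < m", call. = FALSE)
  }
  parts <- split(track$height, track$chrom, drop = FALSE)
  new_h <- unsplit(lapply(parts, window_best_chrom, m = m, d = d), track$chrom)
  replace_heights(track, new_h)
}

#' Cutoff-and-stretch filter
#'
#' Crops the lowest `p_cut` percent of the maximum height and stretches the
#' remainder so the maximum is normalised back to 100: with `M` the track
#' maximum and `t = (p_cut/100) * M`, heights at or below `t` become 0 and
#' heights above become `100 * (r - t) / (M - t)`. An all-zero track is
#' returned unchanged.
#'
#' @param track a `height_track`.
#' @param p_cut cutoff percent in `[0, 100)`.
#' @param per_chromosome apply the cutoff relative to each chromosome's own
#'   maximum instead of the whole-track maximum? Default `FALSE`
#'   (whole-track).
#' @return the track with cropped and stretched heights.
#' @export
cutoff_stretch <- function(track, p_cut, per_chromosome = FALSE) {
  if (!is.numeric(p_cut) || p_cut < 0 || p_cut >= 100) {
    stop("p_cut must lie in [0, 100)", call. = FALSE)
  }
  stretch <- function(h) {
    M <- max(h)
    if (M <= 0) return(h)
    t <- p_cut / 100 * M
    pmin(ifelse(h <= t, 0, 100 * (h - t) / (M - t)), 100)
  }
  if (nrow(track) == 0) return(track)
  if (per_chromosome) {
    parts <- split(track$height, track$chrom, drop = FALSE)
    parts <- lapply(parts, function(h) if (length(h)) stretch(h) else h)
    replace_heights(track, unsplit(parts, track$chrom))
  } else {
    replace_heights(track, stretch(track$height))
  }
}

#' Filter-chain steps
#'
#' Constructors for the elements of a filter chain, applied left to right by
#' [apply_filter_chain()]. A chain like
#' `list(step_log(50), step_window(5, 0), step_cutoff(20))` reproduces the
#' classic enhancement recipe: logarithmic transformation, best-of-window
#' sliding mean, then cutoff of the lowest 20%.
#'
#' @param f,m,d,p_cut,per_chromosome filter parameters; see [log_filter()],
#'   [sliding_window_best()], [cutoff_stretch()].
#' @return a `filter_step` object.
#' @export
step_log <- function(f) {
  structure(list(filter = "log", f = f), class = "filter_step")
}

#' @rdname step_log
#' @export
step_window <- function(m, d = 0) {
  structure(list(filter = "window", m = m, d = d), class = "filter_step")
}

#' @rdname step_log
#' @export
step_cutoff <- function(p_cut, per_chromosome = FALSE) {
  structure(list(filter = "cutoff", p_cut = p_cut,
                 per_chromosome = per_chromosome), class = "filter_step")
}

#' Apply a chain of height filters
#'
#' Applies the given filter steps strictly left to right. Filters only ever
#' change heights: track length and (chrom, pos, id) identity are preserved,
#' and outputs stay within `[0, 100]`.
#'
#' @param track a `height_track`.
#' @param chain list of [step_log()] / [step_window()] / [step_cutoff()]
#'   steps (an empty chain is the identity).
#' @return the filtered track.
#' @export
apply_filter_chain <- function(track, chain) {
  for (st in chain) {
    if (!is.list(st) || is.null(st$filter)) {
      stop("chain elements must be filter steps", call. = FALSE)
    }
    track <- switch(
      st$filter,
      log = log_filter(track, st$f),
      window = sliding_window_best(track, st$m, st$d %||% 0),
      cutoff = cutoff_stretch(track, st$p_cut,
                              st$per_chromosome %||% FALSE),
      stop("unknown filter '", st$filter, "'", call. = FALSE)
    )
  }
  track
}
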