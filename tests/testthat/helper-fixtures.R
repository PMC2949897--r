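# Shared helpers: quick track construction and brute-force oracles.

score_track <- function(heights, chrom = "1") {
  n <- length(heights)
  tab <- assoc_table(rep(chrom, n), seq_len(n) * 10, sprintf("s%03d", seq_len(n)),
                     heights, "score")
  scale_to_height(tab, max_expected = 100)
}

# Brute-force best-of-window oracle: materialize every window, sort it,
# average the top m - d (shrunk at chromosome ends).
window_oracle <- function(h, m, d) {
  vapply(seq_along(h), function(i) {
    w <- h[i:min(i + m - 1, length(h))]
    k <- min(m - d, length(w))
    mean(sort(w, decreasing = TRUE)[seq_len(k)])
  }, numeric(1))
}

# Sort-based ranking oracle.
rank_oracle <- function(scores, descending = TRUE) {
  key <- if (descending) -scores else scores
  match(seq_along(scores), order(key, seq_along(scores)))
}

write_tmp_lines <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}
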