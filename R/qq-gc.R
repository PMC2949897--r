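#' Expected uniform quantiles for a Q-Q plot
#'
#' Under the null, p-values are uniform on (0, 1); the expected value of the
#' i-th smallest of n is approximated by the midpoint convention
#' `(i - 0.5) / n` (default) or by `i / (n + 1)`.
#'
#' @param n number of p-values, `>= 1`.
#' @param method `"midpoint"` for `(i - 0.5)/n` or `"uniform_order"` for
#'   `i/(n + 1)`.
#' @return ascending numeric vector of length `n`, strictly inside (0, 1).
#' @examples
#' expected_quantiles(4)  # 0.125 0.375 0.625 0.875
#' @export
expected_quantiles <- function(n, method = c("midpoint", "uniform_order")) {
  method <- match.arg(method)
  if (length(n) != 1 || !is.finite(n) || n < 1 || n != round(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  i <- seq_len(n)
  switch(method, midpoint = (i - 0.5) / n, uniform_order = i / (n + 1))
}

#' Genomic-control correction for 2-df chi-square p-values
#'
#' For p-values arising from a chi-square test with 2 degrees of freedom the
#' conversions have closed forms: the observed statistic is
#' `chisq = -2 * ln(p)` and the survival function is `exp(-x/2)`. The
#' inflation factor is the ratio of the observed median statistic to the
#' theoretical null median `2 * ln 2`:
#' `lambda = median(chisq) / (2 ln 2)`. Every statistic is divided by
#' lambda and converted back to a corrected p-value
#' `gc_p = exp(-(chisq / lambda) / 2)`. By the standard genomic-control
#' convention lambda is clamped below at 1, so apparent deflation is never
#' "corrected" into inflation; set `clamp = FALSE` to disable.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param clamp clamp lambda below at 1? Default `TRUE`.
#' @return an object of class `gc_result`: a list with elements
#'   `lambda` (applied inflation factor), `lambda_unclamped`, `df` (always
#'   2), `chisq` (per-SNP observed statistics), `p` (input) and `gc_p`
#'   (corrected p-values). Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @examples
#' gc <- gc_correct(rep(0.5, 5))
#' gc$lambda          # 1: the input sits exactly at the null median
#' all(gc$gc_p == 0.5)
#' @export
gc_correct <- function(p_values, clamp = TRUE) {
  if (length(p_values) == 0) stop("no p-values supplied", call. = FALSE)
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  chisq <- -2 * log(p_values)
  lambda_raw <- stats::median(chisq) / (2 * log(2))
  lambda <- if (clamp) max(lambda_raw, 1) else lambda_raw
  gc_p <- exp(-(chisq / lambda) / 2)
  structure(
    list(lambda = lambda, lambda_unclamped = lambda_raw, df = 2L,
         chisq = chisq, p = p_values, gc_p = gc_p),
    class = "gc_result"
  )
}

#' @export
print.gc_result <- function(x, ...) {
  cat(sprintf("<gc_result> n = %d, lambda = %.4f (unclamped %.4f), df = 2\n",
              length(x$p), x$lambda, x$lambda_unclamped))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a genomic-control result
#'
#' @param x a `gc_result`.
#' @param ... unused.
#' @return `tidy()`: one row per SNP with `p`, `chisq`, `gc_p`;
#'   `glance()`: one row with `lambda`, `lambda_unclamped`, `df`,
#'   `n`, `median_chisq`.
#' @exportS3Method generics::tidy
tidy.gc_result <- function(x, ...) {
  tibble::tibble(p = x$p, chisq = x$chisq, gc_p = x$gc_p)
}

#' @rdname tidy.gc_result
#' @exportS3Method generics::glance
glance.gc_result <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, lambda_unclamped = x$lambda_unclamped,
                 df = x$df, n = length(x$p),
                 median_chisq = stats::median(x$chisq))
}

#' Build a Q-Q table of expected vs observed p-values
#'
#' Sorts the p-values ascending, attaches the expected uniform quantiles,
#' and optionally a genomic-control corrected column (2-df chi-square, see
#' [gc_correct()]). Sorted and unsorted input give identical tables.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @param apply_gc include the `gc_p` column? Default `FALSE`.
#' @param method quantile convention, see [expected_quantiles()].
#' @return tibble of class `qq_tbl` with columns `observed_p`,
#'   `expected_p` and (optionally) `gc_p`, ascending in `observed_p`; the
#'   applied lambda is attached as attribute `"lambda"` when `apply_gc`.
#' @examples
#' make_qq_table(c(0.9, 0.1))
#' @export
make_qq_table <- function(p_values, apply_gc = FALSE,
                          method = c("midpoint", "uniform_order")) {
  method <- match.arg(method)
  if (length(p_values) == 0) stop("no p-values supplied", call. = FALSE)
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  obs <- sort(p_values)
  out <- tibble::tibble(
    observed_p = obs,
    expected_p = expected_quantiles(length(obs), method)
  )
  lambda <- NULL
  if (apply_gc) {
    gc <- gc_correct(obs)
    out$gc_p <- gc$gc_p
    lambda <- gc$lambda
  }
  structure(out, lambda = lambda,
            class = c("qq_tbl", class(tibble::tibble())))
}

#' Write a Q-Q table as TSV
#'
#' Header `observed_p`, `expected_p` and, when present, `gc_p`; full double
#' precision.
#'
#' @param qq a `qq_tbl` from [make_qq_table()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_qq_table <- function(qq, path) {
  cols <- intersect(c("observed_p", "expected_p", "gc_p"), names(qq))
  body <- do.call(paste, c(lapply(qq[cols], function(x) sprintf("%.12g", x)),
                           sep = "\t"))
  con <- file(path, open = "wb")
  writeLines(c(paste(cols, collapse = "\t"), body), con)
  close(con)
  invisible(path)
}
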