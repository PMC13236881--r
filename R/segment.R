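#' Select the linear segment of an x-y series
#'
#' Scatchard plots and loading curves are linear only over part of their
#' range (curvature appears at saturation or from outliers). This
#' selector enumerates every contiguous run of at least `min_len` points,
#' scores each by the R-squared of its ordinary least-squares line, and
#' returns the longest run whose R-squared meets `r2_min`; ties are
#' broken by higher R-squared, then by lower starting index. When the
#' full series qualifies it is returned whole.
#'
#' Runs with zero spread in x cannot define a line and are skipped; runs
#' whose residuals are exactly zero (collinear points) score R-squared 1.
#'
#' @param x,y Numeric vectors of equal length (in input order).
#' @param min_len Minimum run length (default 4: with fewer points a
#'   two-parameter line is barely constrained and R-squared is
#'   uninformative).
#' @param r2_min R-squared threshold a run must meet (default 0.99,
#'   the order of fit quality a well-behaved 1:1 system attains).
#' @return A list of class `linear_segment`: integer `start`, `end`,
#'   `r_squared`, and `indices`.
#' @export
#' @examples
#' x <- 1:8; y <- 2 * x + 1
#' select_linear_segment(x, y)$indices
select_linear_segment <- function(x, y, min_len = 4L, r2_min = 0.99) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  min_len <- as.integer(min_len)
  if (min_len < 3L) {
    abort("`min_len` must be at least 3.", class = "arsbind_invalid_argument")
  }
  if (n < min_len) {
    abort(sprintf("Need at least %d points; got %d.", min_len, n),
          class = "arsbind_insufficient_data")
  }

  runs <- list()
  best_any <- NULL # best run regardless of threshold, for diagnostics
  for (len in seq(n, min_len)) {
    for (start in seq_len(n - len + 1L)) {
      idx <- start:(start + len - 1L)
      r2 <- segment_r_squared(x[idx], y[idx])
      if (is.na(r2)) next
      run <- list(start = start, end = start + len - 1L, len = len, r2 = r2)
      if (is.null(best_any) || r2 > best_any$r2) best_any <- run
      if (r2 >= r2_min) runs[[length(runs) + 1L]] <- run
    }
  }
  if (length(runs) == 0L) {
    diag <- if (is.null(best_any)) "no run had usable x-spread" else {
      sprintf("best run [%d, %d] reached R^2 = %.4f", best_any$start,
              best_any$end, best_any$r2)
    }
    abort(sprintf("No contiguous run of >= %d points reaches R^2 >= %.3f (%s).",
                  min_len, r2_min, diag),
          class = "arsbind_no_linear_segment")
  }
  lens <- vapply(runs, `[[`, numeric(1), "len")
  r2s <- vapply(runs, `[[`, numeric(1), "r2")
  starts <- vapply(runs, `[[`, numeric(1), "start")
  best <- runs[[order(-lens, -r2s, starts)[1]]]
  structure(
    list(start = best$start, end = best$end, r_squared = best$r2,
         indices = best$start:best$end),
    class = "linear_segment"
  )
}

# R^2 of the OLS line through (x, y); NA when x has no spread,
# 1 when the points are exactly collinear (zero residual).
segment_r_squared <- function(x, y) {
  sx <- sum((x - mean(x))^2)
  if (sx == 0) return(NA_real_)
  sy <- sum((y - mean(y))^2)
  if (sy == 0) return(1)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r2 <- (sxy^2) / (sx * sy)
  min(r2, 1)
}

#' @export
print.linear_segment <- function(x, ...) {
  cat(sprintf("<linear_segment: points %d..%d, R^2 = %.4f>\n",
              x$start, x$end, x$r_squared))
  invisible(x)
}
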