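#' Build a serial dilution series
#'
#' Constructs the descending geometric concentration ladder used on screening
#' plates. The screening default is a 10-point, threefold series, which spans
#' a `3^9 = 19683`-fold concentration range; single-point assays use
#' `n_points = 1`.
#'
#' @param top_concentration highest concentration, in molar (M). Must be > 0.
#' @param n_points number of points in the series (>= 1).
#' @param fold dilution factor between consecutive points (> 1). Ignored when
#'   `n_points == 1`.
#' @return an object of class `dilution_series` with fields
#'   `top_concentration`, `n_points`, `fold` and `concentrations`
#'   (descending molar values).
#' @examples
#' s <- build_dilution_series(35e-6, 10, 3)
#' max(s$concentrations) / min(s$concentrations) # 19683
#' @export
build_dilution_series <- function(top_concentration, n_points = 10, fold = 3) {
  if (!is.numeric(top_concentration) || length(top_concentration) != 1 ||
      !is.finite(top_concentration) || top_concentration <= 0) {
    stopf("`top_concentration` must be a single positive number (molar)")
  }
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 1) {
    stopf("`n_points` must be an integer >= 1")
  }
  if (n_points > 1 && (!is.finite(fold) || fold <= 1)) {
    stopf("`fold` must be > 1 for a multi-point series")
  }
  conc <- top_concentration / fold^(seq_len(n_points) - 1)
  structure(
    list(
      top_concentration = top_concentration,
      n_points = n_points,
      fold = if (n_points > 1) fold else NA_real_,
      concentrations = conc
    ),
    class = "dilution_series"
  )
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf(
    "Dilution series: %d point(s), top %.3g M%s\n",
    x$n_points, x$top_concentration,
    if (x$n_points > 1) {
      sprintf(", %g-fold steps (%g-fold range)", x$fold,
              x$fold^(x$n_points - 1))
    } else ""
  ))
  invisible(x)
}
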