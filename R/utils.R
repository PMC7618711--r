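#' @keywords internal
"_PACKAGE"

AVOGADRO <- 6.02214076e23

## Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Round to a number of significant figures (reporting convention)
#'
#' Headline numbers in this package are reported at one significant figure
#' (e.g. a depletion rate of 2.67e6 molecules/s is reported as 3e6), while
#' raw precision is always retained internally.
#'
#' @param x numeric vector.
#' @param digits significant figures (default 1).
#' @return `x` rounded to `digits` significant figures.
#' @export
report_signif <- function(x, digits = 1L) signif(x, digits = digits)

stop_if_not_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop(sprintf("`%s` must be finite numeric", name), call. = FALSE)
  if (positive && any(x <= 0))
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && any(x < 0))
    stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}
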