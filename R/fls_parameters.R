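#' FLS algorithm parameters
#'
#' Bundles the four scalar constants of the Verdoux familial loading score:
#' the lifetime prevalence of depression and/or anxiety among persons with a
#' positive family history (`a`), the prevalence among persons without
#' (`b`, conventionally half the general-population lifetime prevalence),
#' and the upper and lower age limits (`c_upper`, `d_lower`) of the window
#' in which most first onsets occur.
#'
#' @param a Lifetime prevalence given FH+; probability in (0, 1). Default 0.50.
#' @param b Lifetime prevalence given FH-; probability in (0, 1), must be
#'   strictly below `a`. Default 0.134.
#' @param c_upper Upper limit of the first-onset risk window, in years.
#'   Default 65.
#' @param d_lower Lower limit of the first-onset risk window, in years.
#'   Default 5.
#'
#' @return An object of class `fls_parameters` (a named list).
#' @examples
#' p <- fls_parameters()
#' p$a / p$b # likelihood ratio contributed by any affected relative
#' @export
fls_parameters <- function(a = 0.50, b = 0.134, c_upper = 65, d_lower = 5) {
  stopifnot(is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(c_upper), length(c_upper) == 1L, is.finite(c_upper),
            is.numeric(d_lower), length(d_lower) == 1L, is.finite(d_lower))
  if (!(a > 0 && a < 1) || !(b > 0 && b < 1))
    stop("prevalences 'a' and 'b' must lie strictly in (0, 1)", call. = FALSE)
  if (b > a)
    stop("'b' must not exceed 'a': with b > a the likelihood-ratio ",
         "directions invert", call. = FALSE)
  if (!(d_lower >= 0 && d_lower < c_upper))
    stop("risk window requires 0 <= d_lower < c_upper", call. = FALSE)
  structure(list(a = a, b = b, c_upper = c_upper, d_lower = d_lower),
            class = "fls_parameters")
}

#' @export
print.fls_parameters <- function(x, ...) {
  cat("FLS parameters:\n")
  cat(sprintf("  a (prevalence | FH+) : %.4g\n", x$a))
  cat(sprintf("  b (prevalence | FH-) : %.4g\n", x$b))
  cat(sprintf("  first-onset window   : [%g, %g] years\n", x$d_lower, x$c_upper))
  invisible(x)
}

#' Prevalence among family-history-negative persons
#'
#' The FLS fixes the FH- lifetime prevalence `b` as half the
#' general-population lifetime prevalence of depression and/or anxiety,
#' following the original algorithm. With the Dutch population estimate of
#' 26.8% this yields the default b = 0.134.
#'
#' @param population_prevalence General-population lifetime prevalence,
#'   a probability in (0, 1). Default 0.268.
#' @return The FH- prevalence, `population_prevalence / 2`.
#' @examples
#' fh_negative_prevalence(0.268) # 0.134
#' @export
fh_negative_prevalence <- function(population_prevalence = 0.268) {
  stopifnot(is.numeric(population_prevalence),
            length(population_prevalence) == 1L,
            population_prevalence > 0, population_prevalence < 1)
  population_prevalence / 2
}
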