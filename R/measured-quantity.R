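#' Measured quantity with uncertainty
#'
#' The universal carrier of uncertainty in this package: a value in its native
#' units, its standard deviation (SD, same units), and optionally the replicate
#' count `n` behind it. All propagation is done in SD; the standard error of
#' the mean is derived at report time with [sem()].
#'
#' @param value Numeric value in native units.
#' @param sd Non-negative standard deviation, same units. Default 0 (exact).
#' @param n Optional positive integer replicate count.
#' @return An object of class `mq`.
#' @examples
#' ti_treated <- mq(3417, 279, n = 19)
#' sem(ti_treated)
#' @export
mq <- function(value, sd = 0, n = NULL) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  stopifnot(is.numeric(sd), length(sd) == 1L, is.finite(sd))
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  if (!is.null(n)) {
    if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
      stop("n must be a positive integer", call. = FALSE)
    n <- as.integer(n)
  }
  structure(list(value = value, sd = sd, n = n), class = "mq")
}

#' @rdname mq
#' @param x Object to test or report on.
#' @export
is_mq <- function(x) inherits(x, "mq")

#' Standard error of the mean of a measured quantity
#'
#' @param x An [mq()] with a replicate count `n`.
#' @return `sd / sqrt(n)`.
#' @export
sem <- function(x) {
  stopifnot(is_mq(x))
  if (is.null(x$n)) stop("replicate count n is not recorded for this quantity",
                         call. = FALSE)
  x$sd / sqrt(x$n)
}

#' Coerce to a measured quantity
#'
#' Plain numbers become exact quantities (sd = 0); `mq` objects pass through.
#'
#' @param x Numeric scalar or `mq`.
#' @return An `mq`.
#' @export
as_mq <- function(x) {
  if (is_mq(x)) return(x)
  mq(x, 0)
}

#' @export
format.mq <- function(x, digits = 4, ...) {
  out <- paste0(signif(x$value, digits), " ± ", signif(x$sd, digits))
  if (!is.null(x$n)) out <- paste0(out, " (n = ", x$n, ")")
  out
}

#' @export
print.mq <- function(x, ...) {
  cat("<measured> ", format(x, ...), "\n", sep = "")
  invisible(x)
}
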