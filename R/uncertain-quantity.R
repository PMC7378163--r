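#' Uncertain quantity: a mean +/- SD scalar with a unit
#'
#' The atom of all uncertainty handling in the package: a non-negative mean,
#' a non-negative standard deviation, and a unit string carried as metadata
#' (e.g. `"Mg C ha-1"`). Linear rescaling (`*`, `/` by a positive scalar)
#' scales mean and SD together.
#'
#' @param mean Non-negative finite mean.
#' @param sd Non-negative finite standard deviation (default 0).
#' @param unit Non-empty unit string.
#' @return An object of class `uncertain_quantity` with fields `mean`, `sd`,
#'   `unit`.
#' @examples
#' uq(3.9, 0.9, "Mg C ha-1 yr-1")
#' @export
uq <- function(mean, sd = 0, unit = "1") {
  if (!is_scalar_number(mean) || mean < 0)
    stop_invalid_input("`mean` must be a single finite number >= 0")
  if (!is_scalar_number(sd) || sd < 0)
    stop_invalid_input("`sd` must be a single finite number >= 0")
  if (!is.character(unit) || length(unit) != 1L || !nzchar(unit))
    stop_invalid_input("`unit` must be a non-empty string")
  structure(list(mean = mean, sd = sd, unit = unit),
            class = "uncertain_quantity")
}

#' @export
print.uncertain_quantity <- function(x, digits = 3, ...) {
  cat(format(signif(x$mean, digits)), "+/-", format(signif(x$sd, digits)),
      x$unit, "\n")
  invisible(x)
}

#' Coefficient of variation of an uncertain quantity
#'
#' @param x An [uq()] object.
#' @return `sd / mean`, or 0 when the mean is 0 and the sd is 0.
#' @export
uq_cv <- function(x) {
  stopifnot(inherits(x, "uncertain_quantity"))
  if (x$mean == 0) {
    if (x$sd == 0) return(0)
    stop_invalid_input("CV undefined: zero mean with non-zero SD")
  }
  x$sd / x$mean
}

scale_uq <- function(x, factor, unit = x$unit) {
  uq(x$mean * factor, x$sd * factor, unit)
}

#' Unit conversions between field and continental scales
#'
#' `1 Mha = 1e6 ha`; `1 Tg = 1e6 Mg`. Kept explicit so every scale change
#' in the accounting chain is visible and round-trips exactly.
#'
#' @param x Numeric vector.
#' @return Numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
ha_to_mha <- function(x) x / 1e6

#' @rdname units
#' @export
mha_to_ha <- function(x) x * 1e6

#' @rdname units
#' @export
mg_to_tg <- function(x) x / 1e6

#' @rdname units
#' @export
tg_to_mg <- function(x) x * 1e6
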