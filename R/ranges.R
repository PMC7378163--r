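#' Min--max ranges for areas, stocks and fluxes
#'
#' The published accounting carries habitat-extent uncertainty as an
#' explicit minimum--maximum interval rather than a distribution: the area
#' range comes from reef area times mean percent cover +/- SD, and stock and
#' flux ranges are that interval scaled by a per-area point estimate. These
#' constructors enforce `0 <= lo <= hi` and tag the unit.
#'
#' @param lo,hi Interval endpoints, `0 <= lo <= hi`, finite.
#' @return An object of class `carbon_range` (and a type-specific subclass)
#'   with fields `lo`, `hi`, `unit`.
#' @examples
#' area_range(3.2, 7.1)
#' stock_range(10.3, 22.7)
#' @name ranges
NULL

new_range <- function(lo, hi, unit, subclass) {
  if (!is_scalar_number(lo) || !is_scalar_number(hi))
    stop_invalid_input("range endpoints must be single finite numbers")
  if (lo < 0 || hi < lo)
    stop_invalid_input(sprintf("invalid range [%g, %g]: need 0 <= lo <= hi", lo, hi))
  structure(list(lo = lo, hi = hi, unit = unit),
            class = c(subclass, "carbon_range"))
}

#' @rdname ranges
#' @export
area_range <- function(lo, hi) new_range(lo, hi, "Mha", "area_range")

#' @rdname ranges
#' @export
stock_range <- function(lo, hi) new_range(lo, hi, "Tg C", "stock_range")

#' @rdname ranges
#' @export
flux_range <- function(lo, hi) new_range(lo, hi, "Tg C yr-1", "flux_range")

#' @export
print.carbon_range <- function(x, digits = 3, ...) {
  cat(format(signif(x$lo, digits)), "-", format(signif(x$hi, digits)),
      x$unit, "\n")
  invisible(x)
}

#' Midpoint of a range
#'
#' @param x A `carbon_range`.
#' @return `(lo + hi) / 2`.
#' @export
range_midpoint <- function(x) {
  stopifnot(inherits(x, "carbon_range"))
  (x$lo + x$hi) / 2
}

as_range_pair <- function(x, what) {
  if (inherits(x, "carbon_range")) return(c(x$lo, x$hi))
  if (is.numeric(x) && length(x) == 2L && all(is.finite(x)) &&
      x[1] >= 0 && x[2] >= x[1]) return(as.numeric(x))
  stop_invalid_input(sprintf("`%s` must be a carbon_range or an ordered numeric pair", what))
}
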