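#' Australian blue-carbon budget fixture
#'
#' Literature values for the multi-ecosystem budget: per-area aboveground
#' carbon density and sequestration rate (mean +/- SD), habitat area ranges,
#' and the resulting stock and flux ranges for tidal marshes, mangrove
#' forests, seagrass beds and kelp forests, plus the published continental
#' total row. Values for the three sediment-accreting ecosystems are
#' external literature values shipped verbatim, never recomputed; the kelp
#' row is the one this package recomputes. The published totals carry more
#' precision than the printed per-row ranges, so the total row is kept as a
#' literature value alongside the row sums computed by [assemble_budget()].
#'
#' @return List with `rows` (data frame, one row per ecosystem) and
#'   `published_total` (data frame, the published total row).
#' @export
australian_blue_carbon <- function() {
  path <- system.file("extdata", "ecosystems.csv", package = "kelpcarbon",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  num <- setdiff(names(tab), c("ecosystem", "source"))
  tab[num] <- lapply(tab[num], as.numeric)
  is_total <- tab$ecosystem == "Total"
  list(rows = tab[!is_total, , drop = FALSE],
       published_total = tab[is_total, , drop = FALSE])
}

budget_range_cols <- c("stock_area_lo_mha", "stock_area_hi_mha",
                       "stock_lo_tg", "stock_hi_tg",
                       "flux_area_lo_mha", "flux_area_hi_mha",
                       "flux_lo_tg", "flux_hi_tg")

#' Assemble a multi-ecosystem budget table with a total row
#'
#' Sums the area, stock and flux range endpoints component-wise across
#' ecosystems and appends the computed total row. Note that published
#' continental totals may differ slightly from these row sums when the
#' printed per-row ranges are rounded versions of higher-precision values;
#' compare against `published_total` from [australian_blue_carbon()].
#'
#' @param rows Data frame with column `ecosystem` (unique names) and the
#'   range columns `stock_area_lo_mha`, `stock_area_hi_mha`, `stock_lo_tg`,
#'   `stock_hi_tg`, `flux_area_lo_mha`, `flux_area_hi_mha`, `flux_lo_tg`,
#'   `flux_hi_tg` (per-area `density_mean`/`density_sd`/`rate_mean`/
#'   `rate_sd` columns are carried through unsummed when present).
#' @return The input with a `"Total"` row appended.
#' @export
assemble_budget <- function(rows) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop_invalid_input("`rows` must be a non-empty data frame")
  if (!"ecosystem" %in% names(rows))
    stop_invalid_input("`rows` needs an 'ecosystem' column")
  if (anyDuplicated(rows$ecosystem))
    stop_invalid_input("duplicate ecosystem names")
  missing <- setdiff(budget_range_cols, names(rows))
  if (length(missing) > 0L)
    stop_invalid_input(sprintf("`rows` lacks columns: %s",
                               paste(missing, collapse = ", ")))
  total <- rows[1, , drop = FALSE]
  total[1, ] <- NA
  total$ecosystem <- "Total"
  for (cc in budget_range_cols) total[[cc]] <- sum(rows[[cc]])
  if ("source" %in% names(rows)) total$source <- "row sums"
  out <- rbind(rows, total)
  rownames(out) <- NULL
  out
}

#' Replace the kelp row of the budget with freshly computed ranges
#'
#' Recomputes the kelp stock and flux ranges from a per-area density and
#' sequestration rate and the stored area ranges, leaving the literature
#' rows untouched.
#'
#' @param rows Budget rows as from [australian_blue_carbon()]`$rows`.
#' @param density,rate [uq()] per-area density (Mg C ha^-1) and
#'   sequestration rate (Mg C ha^-1 yr^-1) for kelp.
#' @param kelp Name of the kelp row (default `"Kelp forests"`).
#' @return `rows` with the kelp row's stock/flux ranges and per-area values
#'   replaced.
#' @export
update_kelp_row <- function(rows, density, rate, kelp = "Kelp forests") {
  i <- match(kelp, rows$ecosystem)
  if (is.na(i)) stop_invalid_input(sprintf("no row named '%s'", kelp))
  stock <- scale_stock(area_range(rows$stock_area_lo_mha[i],
                                  rows$stock_area_hi_mha[i]), density)
  flux <- scale_flux(area_range(rows$flux_area_lo_mha[i],
                                rows$flux_area_hi_mha[i]), rate)
  rows$density_mean[i] <- density$mean
  rows$density_sd[i] <- density$sd
  rows$rate_mean[i] <- rate$mean
  rows$rate_sd[i] <- rate$sd
  rows$stock_lo_tg[i] <- stock$lo
  rows$stock_hi_tg[i] <- stock$hi
  rows$flux_lo_tg[i] <- flux$lo
  rows$flux_hi_tg[i] <- flux$hi
  if ("source" %in% names(rows)) rows$source[i] <- "computed"
  rows
}

#' Share of a component range in a total range
#'
#' Two conventions are in use for expressing one range as a share of
#' another: the midpoint convention, `100 * mid(component) / mid(total)`,
#' giving a single percentage; and the range convention, which ratios
#' matching endpoints, `(100 * hi_c / hi_t, 100 * lo_c / lo_t)` ordered
#' ascending, giving a percentage range. (A component that is a larger
#' slice of the low total than of the high total makes the endpoint ratios
#' cross; ordering ascending keeps the result an interval.)
#'
#' @param component,total Ranges (any `carbon_range` or ordered numeric
#'   pair); `total` must have `lo > 0`.
#' @param convention `"midpoint"` or `"range"`.
#' @return A percent (midpoint) or ascending percent pair (range).
#' @examples
#' share_of_total(c(1.3, 2.8), c(4.9, 8.5), "midpoint") # ~30.6
#' share_of_total(c(10.3, 22.7), c(77, 206), "range")   # ~(11.0, 13.4)
#' @export
share_of_total <- function(component, total,
                           convention = c("midpoint", "range")) {
  convention <- match.arg(convention)
  comp <- as_range_pair(component, "component")
  tot <- as_range_pair(total, "total")
  if (tot[1] <= 0)
    stop_undefined_baseline("total range must have lo > 0 for a share")
  if (convention == "midpoint") {
    100 * mean(comp) / mean(tot)
  } else {
    sort(c(100 * comp[2] / tot[2], 100 * comp[1] / tot[1]))
  }
}
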