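#' Read and validate a CSV table against a schema
#'
#' Comma-separated, UTF-8, header row mandatory, "." decimal separator.
#' Required columns must be present; numeric columns are parsed and any
#' unparseable or (where forbidden) negative cell is reported with its row
#' number. Extra columns are carried through untouched.
#'
#' @param path Path to a CSV file.
#' @param schema Named character vector mapping column name to one of
#'   `"character"`, `"numeric"`, `"numeric?"` (optional column), or
#'   `"integer"`.
#' @return A validated data frame.
#' @export
read_table <- function(path, schema) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop_schema(sprintf("file not found: %s", path))
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                    check.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop_schema(sprintf("cannot parse %s: %s", path,
                                            conditionMessage(e))))
  if (nrow(raw) == 0L) stop_schema(sprintf("%s is empty", path))
  optional <- endsWith(schema, "?")
  types <- sub("\\?$", "", schema)
  required <- names(schema)[!optional]
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L)
    stop_schema(sprintf("%s lacks required columns: %s", path,
                        paste(missing, collapse = ", ")))
  for (col in intersect(names(schema), names(raw))) {
    ty <- types[[col]]
    if (ty == "character") next
    cell <- trimws(raw[[col]])
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & nzchar(cell) & is.na(val))
    if (length(bad) > 0L)
      stop_schema(sprintf("%s column '%s': non-numeric value%s in row%s %s",
                          path, col, if (length(bad) > 1) "s" else "",
                          if (length(bad) > 1) "s" else "",
                          paste(utils::head(bad, 5), collapse = ", ")))
    raw[[col]] <- if (ty == "integer") as.integer(val) else val
  }
  raw
}

plants_schema <- c(site_id = "character", biomass_dry_kg = "numeric",
                   growth_rate_kg_yr = "numeric?")
plots_schema <- c(plot_id = "character", region = "character",
                  density_per_m2 = "numeric", cover_frac = "numeric?")
cover_schema <- c(region = "character", year = "integer",
                  cover_pct = "numeric")
events_schema <- c(region = "character", period = "character",
                   driver = "character", coastline_km = "numeric?",
                   cover_loss_pct = "numeric?", area_loss_ha = "numeric?")
scenarios_schema <- c(label = "character",
                      distribution_loss_frac = "numeric",
                      horizon_year = "integer")

#' Typed readers for the pipeline's CSV schemas
#'
#' `read_plants()` expects `site_id, biomass_dry_kg[, growth_rate_kg_yr]`;
#' `read_plots()` expects `plot_id, region, density_per_m2[, cover_frac]`;
#' `read_cover_series()` expects `region, year, cover_pct` and returns a
#' list of per-region data frames ordered by year; `read_loss_events()`
#' expects `region, period, driver, coastline_km, cover_loss_pct,
#' area_loss_ha` and returns a list of [loss_event()]s;
#' `read_scenarios()` expects `label, distribution_loss_frac, horizon_year`
#' and returns a list of [scenario_projection()]s.
#'
#' @param path Path to the CSV file.
#' @return See details above.
#' @name readers
NULL

#' @rdname readers
#' @export
read_plants <- function(path) {
  tab <- read_table(path, plants_schema)
  check_plants(tab)
  tab
}

#' @rdname readers
#' @export
read_plots <- function(path) {
  tab <- read_table(path, plots_schema)
  check_plots(tab)
  tab
}

#' @rdname readers
#' @export
read_cover_series <- function(path) {
  tab <- read_table(path, cover_schema)
  out <- lapply(split(tab, tab$region), function(d) {
    d <- d[order(d$year), c("year", "cover_pct")]
    names(d) <- c("year", "cover")
    rownames(d) <- NULL
    d
  })
  out
}

#' @rdname readers
#' @export
read_loss_events <- function(path) {
  tab <- read_table(path, events_schema)
  na_or <- function(x) if (is.null(x)) rep(NA_real_, nrow(tab)) else x
  cl <- na_or(tab$coastline_km); cv <- na_or(tab$cover_loss_pct)
  ar <- na_or(tab$area_loss_ha)
  lapply(seq_len(nrow(tab)), function(i)
    loss_event(tab$region[i], tab$period[i], tab$driver[i],
               cl[i], cv[i], ar[i]))
}

#' @rdname readers
#' @export
read_scenarios <- function(path) {
  tab <- read_table(path, scenarios_schema)
  lapply(seq_len(nrow(tab)), function(i)
    scenario_projection(tab$label[i], tab$distribution_loss_frac[i],
                        tab$horizon_year[i]))
}

#' Bundled historical loss events and scenario projections
#'
#' Convenience loaders for the shipped records of documented Australian
#' kelp-loss events (region, period, driver, affected coastline, percent
#' cover loss, reported area loss, and the published per-event carbon
#' losses for cross-checking) and the 2100 range-contraction scenarios.
#'
#' @return `kelp_loss_events()`: list of [loss_event()]s;
#'   `kelp_loss_table()`: the raw data frame including published carbon
#'   columns; `kelp_scenarios()`: list of [scenario_projection()]s.
#' @name bundled
NULL

#' @rdname bundled
#' @export
kelp_loss_events <- function() {
  read_loss_events(system.file("extdata", "loss_events.csv",
                               package = "kelpcarbon", mustWork = TRUE))
}

#' @rdname bundled
#' @export
kelp_loss_table <- function() {
  read_table(system.file("extdata", "loss_events.csv",
                         package = "kelpcarbon", mustWork = TRUE),
             c(events_schema, published_stock_loss_mgc = "numeric",
               published_seq_loss_mgc_yr = "numeric"))
}

#' @rdname bundled
#' @export
kelp_scenarios <- function() {
  read_scenarios(system.file("extdata", "scenarios.csv",
                             package = "kelpcarbon", mustWork = TRUE))
}

#' Read a run configuration (YAML or JSON)
#'
#' Unknown keys are rejected; missing keys fall back to [kelp_params()].
#'
#' @param path Path to a `.yml`/`.yaml` or `.json` file.
#' @return A full parameter list as from [kelp_params()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("config not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
    yml = , yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop_schema(sprintf("unsupported config format: .%s", ext)))
  defaults <- kelp_params()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L)
    stop_invalid_config(sprintf("unknown config keys: %s",
                                paste(unknown, collapse = ", ")))
  out <- utils::modifyList(defaults, user)
  derive_deep_fraction(out$total_npp_frac, out$shelf_burial_frac)  # validates
  if (out$area_lo_mha < 0 || out$area_hi_mha < out$area_lo_mha)
    stop_invalid_config("need 0 <= area_lo_mha <= area_hi_mha")
  out
}

fmt_sig <- function(x, sig = 3) formatC(signif(x, sig), format = "fg", flag = "#")

#' Render budget, loss and projection results as text and CSV
#'
#' Produces an aligned text report (values at 3 significant figures, units
#' in headers) and, when `dir` is given, machine-readable CSV twins holding
#' full precision. Empty loss or projection sections are omitted with a
#' notice line.
#'
#' @param budget Budget table from [assemble_budget()].
#' @param losses Optional list of `loss_impact`s.
#' @param projections Optional list of results from [project_scenario()].
#' @param dir Optional output directory for CSV twins.
#' @param sigfigs Significant figures for the text tables.
#' @return Character vector of report lines (invisibly printed);
#'   attribute `files` lists any CSVs written.
#' @export
render_report <- function(budget, losses = NULL, projections = NULL,
                          dir = NULL, sigfigs = 3) {
  lines <- c("Blue carbon budget (stocks in Tg C, fluxes in Tg C yr-1, areas in Mha)",
             sprintf("%-18s %14s %14s %14s", "Ecosystem",
                     "Area (Mha)", "Stock (Tg C)", "Flux (Tg C/yr)"))
  for (i in seq_len(nrow(budget))) {
    lines <- c(lines, sprintf("%-18s %14s %14s %14s",
      budget$ecosystem[i],
      paste0(fmt_sig(budget$stock_area_lo_mha[i], sigfigs), "-",
             fmt_sig(budget$stock_area_hi_mha[i], sigfigs)),
      paste0(fmt_sig(budget$stock_lo_tg[i], sigfigs), "-",
             fmt_sig(budget$stock_hi_tg[i], sigfigs)),
      paste0(fmt_sig(budget$flux_lo_tg[i], sigfigs), "-",
             fmt_sig(budget$flux_hi_tg[i], sigfigs))))
  }
  files <- character(0)

  if (is.null(losses) || length(losses) == 0L) {
    lines <- c(lines, "", "No loss events supplied; losses section omitted.")
  } else {
    lines <- c(lines, "", "Historical losses",
               sprintf("%-18s %12s %14s %16s %16s", "Region", "Area (ha)",
                       "Stock (Mg C)", "Seq (Mg C/yr)", "Reminer (Mg C)"))
    for (im in losses)
      lines <- c(lines, sprintf("%-18s %12s %14s %16s %16s", im$region,
        fmt_sig(im$area_loss_ha, sigfigs), fmt_sig(im$stock_loss_mgc, sigfigs),
        fmt_sig(im$seq_loss_mgc_yr, sigfigs),
        fmt_sig(im$remineralised_mgc, sigfigs)))
  }

  if (!is.null(projections) && length(projections) > 0L) {
    lines <- c(lines, "", "Projected losses",
               sprintf("%-10s %16s %20s", "Scenario", "Stock loss (Tg C)",
                       "Flux loss (Tg C/yr)"))
    for (p in projections)
      lines <- c(lines, sprintf("%-10s %16s %20s", p$label,
        fmt_sig(p$stock_loss_tg, sigfigs), fmt_sig(p$flux_loss_tg_yr, sigfigs)))
  }

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    bpath <- file.path(dir, "budget.csv")
    utils::write.csv(budget, bpath, row.names = FALSE)
    files <- bpath
    if (!is.null(losses) && length(losses) > 0L) {
      lpath <- file.path(dir, "losses.csv")
      utils::write.csv(do.call(rbind, lapply(losses, function(x)
        data.frame(region = x$region, area_loss_ha = x$area_loss_ha,
                   stock_loss_mgc = x$stock_loss_mgc,
                   seq_loss_mgc_yr = x$seq_loss_mgc_yr,
                   remineralised_mgc = x$remineralised_mgc))),
        lpath, row.names = FALSE)
      files <- c(files, lpath)
    }
    if (!is.null(projections) && length(projections) > 0L) {
      ppath <- file.path(dir, "projections.csv")
      utils::write.csv(do.call(rbind, lapply(projections, function(p)
        data.frame(label = p$label, stock_loss_tg = p$stock_loss_tg,
                   flux_loss_tg_yr = p$flux_loss_tg_yr,
                   convention = p$convention))),
        ppath, row.names = FALSE)
      files <- c(files, ppath)
    }
    writeLines(lines, file.path(dir, "report.txt"))
    files <- c(files, file.path(dir, "report.txt"))
  }
  structure(lines, files = files)
}
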