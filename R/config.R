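# Run configuration, the Florida case fixture, and file I/O.

#' Run configuration
#'
#' The validated bundle everything else is built from: crops, economy, the
#' per-unit plot template, initial funds, and the strategy vocabulary (which
#' crops the monocropped units plant and which set the diversified units
#' plant).
#'
#' @param crops named list of [crop_params()].
#' @param economy an [economy_params()].
#' @param plot_acres numeric vector of plot sizes per unit (acres).
#' @param yields_per_acre named numeric vector of kg/acre by crop, applied to
#'   every plot.
#' @param initial_funds starting funds per unit, USD.
#' @param mono_crops crops planted by monocropped units (one unit class per
#'   crop).
#' @param diversified_crops the crop set planted by diversified units.
#' @param mode planting mode passed through to [region_state()].
#' @return an object of class `run_config`.
#' @export
run_config <- function(crops, economy, plot_acres, yields_per_acre,
                       initial_funds, mono_crops, diversified_crops,
                       mode = "strategy_constrained") {
  if (!length(crops) || !all(vapply(crops, inherits, TRUE, "crop_params")))
    csk_stop("crops must be a list of crop_params", "cropshock_invalid")
  names(crops) <- vapply(crops, `[[`, "", "name")
  stopifnot(inherits(economy, "economy_params"))
  if (!is.numeric(plot_acres) || !length(plot_acres) || any(plot_acres <= 0))
    csk_stop("plot_acres must be positive", "cropshock_invalid")
  cn <- names(crops)
  if (!all(names(yields_per_acre) %in% cn))
    csk_stop("yields_per_acre names unknown crop(s)", "cropshock_invalid")
  if (any(yields_per_acre < 0))
    csk_stop("yields must be non-negative", "cropshock_invalid")
  if (!all(mono_crops %in% cn) || !all(diversified_crops %in% cn))
    csk_stop("strategy crops must be defined in `crops`", "cropshock_invalid")
  if (length(diversified_crops) < 2L || anyDuplicated(diversified_crops))
    csk_stop("diversified_crops must name >= 2 distinct crops",
             "cropshock_invalid")
  if (!is_number(initial_funds))
    csk_stop("initial_funds must be a finite number", "cropshock_invalid")
  mode <- match.arg(mode, c("strategy_constrained", "free"))
  structure(list(crops = crops, economy = economy,
                 plot_acres = as.numeric(plot_acres),
                 yields_per_acre = yields_per_acre,
                 initial_funds = initial_funds,
                 mono_crops = mono_crops,
                 diversified_crops = diversified_crops,
                 mode = mode),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %d crops (%s); %d plots/unit of %s acres; initial funds %s USD\n",
              length(x$crops), paste(names(x$crops), collapse = ", "),
              length(x$plot_acres), paste(x$plot_acres, collapse = "+"),
              format(x$initial_funds, big.mark = ",")))
  cat(sprintf("  mono strategies: %s | diversified: %s | mode %s\n",
              paste(x$mono_crops, collapse = ", "),
              paste(x$diversified_crops, collapse = "+"), x$mode))
  invisible(x)
}

#' Florida strawberry/tomato case configuration
#'
#' The case parameterization: farm budgets and elasticities for Florida
#' strawberry and fresh-market tomato production, units with two 100-acre
#' plots, and initial funds of 1,871,571 USD. Strawberries are the
#' high-value, high-labor crop (95 laborers per 100 acres); tomatoes need
#' less than a third of that labor.
#'
#' The price-law calibration anchors (mean price in USD/kg and mean yield in
#' kg/acre per crop) are documented placeholder values on the scale of public
#' USDA statistics for Florida in the 2000s, not a published series:
#' strawberry 2.65 USD/kg at 10,000 kg/acre, tomato 1.00 USD/kg at
#' 14,500 kg/acre. Override them by editing the returned object or by
#' supplying an annual price/yield CSV through [load_price_yield_csv()].
#' The economy-wide per-laborer wage defaults to the mean of the two
#' per-crop derivations (about 8,251 USD per laborer-season, see
#' [derive_labor_cost()]); the two crop budgets imply per-laborer costs that
#' differ by roughly 1%.
#'
#' @param labor_cost_per_laborer optional override of the economy-wide wage.
#' @return a [run_config()].
#' @export
#' @examples
#' cfg <- florida_fixture()
#' cfg$crops$strawberry$elasticity   # -0.66
florida_fixture <- function(labor_cost_per_laborer = NULL) {
  strawberry <- crop_params(
    name = "strawberry",
    elasticity = -0.66,
    production_cost_per_acre = 12305,
    labor_cost_per_acre = 7788,
    labor_requirement_per_acre = 95 / 100,
    mean_price = 2.65,                 # placeholder calibration anchor
    mean_yield_per_acre = 10000)       # placeholder calibration anchor
  tomato <- crop_params(
    name = "tomato",
    elasticity = -0.58,
    production_cost_per_acre = 10078,
    labor_cost_per_acre = 2408,
    labor_requirement_per_acre = 29 / 100,
    mean_price = 1.00,                 # placeholder calibration anchor
    mean_yield_per_acre = 14500)       # placeholder calibration anchor
  CL <- labor_cost_per_laborer %||% mean(c(
    derive_labor_cost(strawberry$labor_cost_per_acre,
                      strawberry$labor_requirement_per_acre),
    derive_labor_cost(tomato$labor_cost_per_acre,
                      tomato$labor_requirement_per_acre)))
  run_config(
    crops = list(strawberry = strawberry, tomato = tomato),
    economy = economy_params(labor_cost_per_laborer = CL),
    plot_acres = c(100, 100),
    yields_per_acre = c(strawberry = strawberry$mean_yield_per_acre,
                        tomato = tomato$mean_yield_per_acre),
    initial_funds = 1871571,
    mono_crops = c("strawberry", "tomato"),
    diversified_crops = c("strawberry", "tomato"))
}

#' Mean price and yield from an annual price/yield CSV
#'
#' Reads a two-column-per-crop annual series (columns `year`, `price`,
#' `yield`) and returns the arithmetic means, the calibration inputs of
#' [derive_price_constant()]. Row order is irrelevant.
#'
#' @param path CSV file path.
#' @return a list with `mean_price`, `mean_yield` and `n_years`.
#' @export
load_price_yield_csv <- function(path) {
  if (!file.exists(path))
    csk_stop(sprintf("file not found: %s", path), "cropshock_parse")
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   csk_stop(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
                            "cropshock_parse"))
  need <- c("year", "price", "yield")
  missing <- setdiff(need, names(df))
  if (length(missing))
    csk_stop(sprintf("%s: missing column(s) %s", path,
                     paste(missing, collapse = ", ")), "cropshock_parse")
  if (!nrow(df))
    csk_stop(sprintf("%s: no data rows", path), "cropshock_parse")
  for (col in c("price", "yield")) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals))
    if (length(bad))
      csk_stop(sprintf("%s: non-numeric %s in row %d", path, col, bad[1]),
               "cropshock_parse")
    df[[col]] <- vals
  }
  list(mean_price = mean(df$price), mean_yield = mean(df$yield),
       n_years = nrow(df))
}

#' Write / read a run configuration as YAML
#'
#' The on-disk form is plain YAML with a schema tag; unknown keys are
#' rejected on load and the reloaded object is identical to the original.
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns the [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  crops <- lapply(config$crops, function(cr)
    cr[c("name", "elasticity", "production_cost_per_acre",
         "labor_cost_per_acre", "labor_requirement_per_acre",
         "mean_price", "mean_yield_per_acre")])
  doc <- list(
    schema = "cropshock/run_config/v1",
    crops = crops,
    economy = unclass(config$economy),
    plot_acres = config$plot_acres,
    yields_per_acre = as.list(config$yields_per_acre),
    initial_funds = config$initial_funds,
    mono_crops = as.list(config$mono_crops),
    diversified_crops = as.list(config$diversified_crops),
    mode = config$mode)
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- c("schema", "crops", "economy", "plot_acres", "yields_per_acre",
             "initial_funds", "mono_crops", "diversified_crops", "mode")
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    csk_stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
             "cropshock_parse")
  if (!identical(doc$schema, "cropshock/run_config/v1"))
    csk_stop("missing or unsupported config schema tag", "cropshock_parse")
  crops <- lapply(doc$crops, function(cr) {
    extra <- setdiff(names(cr), c("name", "elasticity", "production_cost_per_acre",
                                  "labor_cost_per_acre", "labor_requirement_per_acre",
                                  "mean_price", "mean_yield_per_acre"))
    if (length(extra))
      csk_stop(sprintf("crop '%s': unknown key(s) %s", cr$name %||% "?",
                       paste(extra, collapse = ", ")), "cropshock_parse")
    do.call(crop_params, cr)
  })
  run_config(
    crops = crops,
    economy = economy_params(doc$economy$labor_cost_per_laborer,
                             doc$economy$price_floor_frac),
    plot_acres = as.numeric(doc$plot_acres),
    yields_per_acre = unlist(doc$yields_per_acre),
    initial_funds = doc$initial_funds,
    mono_crops = unlist(doc$mono_crops),
    diversified_crops = unlist(doc$diversified_crops),
    mode = doc$mode)
}

#' Write a simulation trajectory as tidy CSV
#'
#' One row per (season, unit) with the profit components, funds, and the
#' harvested mass of every crop.
#'
#' @param sim a [run_simulation()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(sim, path) {
  stopifnot(inherits(sim, "shock_sim"))
  utils::write.csv(sim$seasons, path, row.names = FALSE)
  invisible(path)
}

#' Write sweep results as tidy CSV
#'
#' @param sweep a [run_sweep()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "shock_sweep"))
  utils::write.csv(sweep$table, path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON run summary
#'
#' Records the configuration fingerprint, the shock schedule, and mean end
#' funds by strategy, for provenance alongside the trajectory CSV.
#'
#' @param sim a [run_simulation()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_summary <- function(sim, path) {
  stopifnot(inherits(sim, "shock_sim"))
  fin <- final_funds_by_strategy(sim)
  jsonlite::write_json(list(
    fingerprint = sim$fingerprint,
    tau = sim$tau,
    shock = unclass(sim$schedule),
    mean_end_funds = as.list(fin)), path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}
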