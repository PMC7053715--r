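#' Plot specification
#'
#' An indivisible parcel of land. A plot carries at most one crop per season
#' and must be planted in its entirety; yields are plot- and crop-specific.
#'
#' @param plot_id label.
#' @param size_acres acreage, positive.
#' @param yield_by_crop named numeric vector, kg/acre by crop name. Crops
#'   absent from the map yield zero on this plot.
#' @return an object of class `plot_spec`.
#' @export
plot_spec <- function(plot_id, size_acres, yield_by_crop) {
  if (!is_number(size_acres) || size_acres <= 0)
    csk_stop("size_acres must be strictly positive", "cropshock_invalid")
  if (!is.numeric(yield_by_crop) || is.null(names(yield_by_crop)) ||
      any(!nzchar(names(yield_by_crop))))
    csk_stop("yield_by_crop must be a named numeric vector", "cropshock_invalid")
  if (any(yield_by_crop < 0) || any(!is.finite(yield_by_crop)))
    csk_stop("yields must be finite and non-negative", "cropshock_invalid")
  structure(list(plot_id = as.character(plot_id), size_acres = size_acres,
                 yield_by_crop = yield_by_crop),
            class = "plot_spec")
}

#' Farming unit
#'
#' The simulated agent: a farm with fixed plots, funds, and a cropping
#' strategy that stays constant over a simulation. A strategy naming one crop
#' is "monocropped"; a strategy naming two or more distinct crops is
#' "diversified" and requires each strategy crop to occupy at least one plot.
#'
#' @param unit_id label.
#' @param strategy character vector of crop names: length one for a
#'   monocropped unit, two or more (distinct) for a diversified unit.
#' @param funds initial funds, USD.
#' @param plots list of [plot_spec()] objects.
#' @return an object of class `farming_unit`.
#' @export
farming_unit <- function(unit_id, strategy, funds, plots) {
  if (!is.character(strategy) || length(strategy) < 1L ||
      anyDuplicated(strategy))
    csk_stop("strategy must name one or more distinct crops", "cropshock_invalid")
  if (!is_number(funds))
    csk_stop("funds must be a finite number", "cropshock_invalid")
  if (!length(plots) || !all(vapply(plots, inherits, TRUE, "plot_spec")))
    csk_stop("plots must be a non-empty list of plot_spec", "cropshock_invalid")
  type <- if (length(strategy) == 1L) "monocropped" else "diversified"
  # structural fingerprint used for within-season decision caching: two units
  # with the same strategy and identical plots make identical decisions
  key <- paste(c(strategy,
                 unlist(lapply(plots, function(p)
                   c(format(p$size_acres, digits = 17),
                     names(p$yield_by_crop),
                     format(p$yield_by_crop, digits = 17))))),
               collapse = "|")
  structure(list(unit_id = as.character(unit_id),
                 strategy = strategy,
                 strategy_type = type,
                 strategy_label = if (type == "monocropped") strategy else "diversified",
                 funds = funds,
                 plots = plots,
                 planting_plan = NULL,
                 labor_share = NA_real_,
                 decision_key = key),
            class = "farming_unit")
}

#' @export
print.farming_unit <- function(x, ...) {
  cat(sprintf("<farming_unit> %s: %s (%s), %d plot(s), funds %s USD\n",
              x$unit_id, x$strategy_type, paste(x$strategy, collapse = "+"),
              length(x$plots), format(round(x$funds), big.mark = ",")))
  invisible(x)
}

#' Market state
#'
#' @param price_by_crop named numeric, USD/kg; all positive.
#' @param last_total_harvest_by_crop named numeric, kg; defaults to zero.
#' @return an object of class `market_state`.
#' @export
market_state <- function(price_by_crop,
                         last_total_harvest_by_crop = setNames(
                           rep(0, length(price_by_crop)), names(price_by_crop))) {
  if (!is.numeric(price_by_crop) || is.null(names(price_by_crop)) ||
      any(price_by_crop <= 0) || any(!is.finite(price_by_crop)))
    csk_stop("prices must be a named vector of positive numbers",
             "cropshock_invalid")
  if (any(last_total_harvest_by_crop < 0))
    csk_stop("harvests must be non-negative", "cropshock_invalid")
  structure(list(price_by_crop = price_by_crop,
                 last_total_harvest_by_crop = last_total_harvest_by_crop),
            class = "market_state")
}

# Structural baseline planting used only for calibration: monocropped units
# put all acres on their crop; diversified units rotate their strategy crops
# across plots in order. This is also what the planting optimizer chooses at
# calibration prices for symmetric plots, so the calibrated prices are a
# fixed point of the full-labor season.
baseline_acres_by_crop <- function(units, crop_names) {
  acres <- setNames(numeric(length(crop_names)), crop_names)
  for (u in units) {
    k <- length(u$strategy)
    for (j in seq_along(u$plots)) {
      cn <- u$strategy[((j - 1L) %% k) + 1L]
      acres[cn] <- acres[cn] + u$plots[[j]]$size_acres
    }
  }
  acres
}

#' Assemble (and calibrate) a regional state
#'
#' Builds the container the season loop runs on: the farming units, the crop
#' economics, the market, and the regional labor pool. Unless every crop
#' already carries a price constant, the price law of each crop is calibrated
#' against this region's expected harvest at its baseline composition
#' (mean yield per acre times the acres structurally planted to the crop), so
#' that a full-labor season reproduces the supplied mean prices.
#'
#' Baseline regional labor is sized so that the most labor-intensive crop
#' could be fully harvested on every acre of the region; each unit receives an
#' equal share of whatever labor is available in a season.
#'
#' @param units list of [farming_unit()].
#' @param crops list of [crop_params()]; names are taken from the crops.
#' @param economy an [economy_params()].
#' @param mode planting mode, `"strategy_constrained"` (default: units plant
#'   every plot according to their fixed strategy) or `"free"` (profit-driven
#'   allocation, fallow allowed).
#' @param market optional [market_state()]; defaults to the calibration mean
#'   prices.
#' @return an object of class `region_state`.
#' @export
region_state <- function(units, crops, economy, mode = "strategy_constrained",
                         market = NULL) {
  if (!length(units) || !all(vapply(units, inherits, TRUE, "farming_unit")))
    csk_stop("units must be a non-empty list of farming_unit", "cropshock_invalid")
  if (!length(crops) || !all(vapply(crops, inherits, TRUE, "crop_params")))
    csk_stop("crops must be a non-empty list of crop_params", "cropshock_invalid")
  stopifnot(inherits(economy, "economy_params"))
  mode <- match.arg(mode, c("strategy_constrained", "free"))
  names(crops) <- vapply(crops, `[[`, "", "name")
  cn <- names(crops)
  for (u in units) {
    missing <- setdiff(u$strategy, cn)
    if (length(missing))
      csk_stop(sprintf("unit '%s' strategy names unknown crop(s): %s",
                       u$unit_id, paste(missing, collapse = ", ")),
               "cropshock_invalid")
  }

  acres <- baseline_acres_by_crop(units, cn)
  total_acres <- sum(vapply(units, function(u)
    sum(vapply(u$plots, `[[`, 0, "size_acres")), 0))

  needs_cal <- !all(vapply(crops, function(cr) is.finite(cr$price_constant), TRUE))
  if (needs_cal) {
    for (nm in cn) {
      cr <- crops[[nm]]
      if (!is_number(cr$mean_price) || !is_number(cr$mean_yield_per_acre))
        csk_stop(sprintf("crop '%s' has no price_constant and no calibration means",
                         nm), "cropshock_invalid_calibration")
      cal_harvest <- cr$mean_yield_per_acre * acres[[nm]]
      if (cal_harvest <= 0)
        csk_stop(sprintf("crop '%s': calibration harvest is zero (no acres or yield)",
                         nm), "cropshock_invalid_calibration")
      cr$price_constant <- derive_price_constant(cr$mean_price, cal_harvest,
                                                 cr$elasticity)
      cr$price_floor <- economy$price_floor_frac * cal_harvest
      crops[[nm]] <- cr
    }
  }

  if (is.null(market)) {
    prices <- vapply(crops, function(cr) {
      if (is_number(cr$mean_price)) cr$mean_price
      else update_market_price(cr, cr$price_floor / economy$price_floor_frac)
    }, 0)
    market <- market_state(setNames(prices, cn))
  }

  baseline <- max(vapply(crops, `[[`, 0, "labor_requirement_per_acre")) * total_acres

  structure(list(units = units,
                 crops = crops,
                 economy = economy,
                 market = market,
                 season = 0L,
                 baseline_labor_total = baseline,
                 total_acres = total_acres,
                 baseline_acres_by_crop = acres,
                 labor_split = "equal",
                 mode = mode),
            class = "region_state")
}

#' @export
print.region_state <- function(x, ...) {
  tab <- table(vapply(x$units, `[[`, "", "strategy_label"))
  cat(sprintf("<region_state> %d farming units (%s), %d crops, season %d\n",
              length(x$units),
              paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
              length(x$crops), x$season))
  cat(sprintf("  baseline labor %.4g laborers over %.4g acres; mode %s\n",
              x$baseline_labor_total, x$total_acres, x$mode))
  cat("  prices (USD/kg):",
      paste(sprintf("%s %.4g", names(x$market$price_by_crop),
                    x$market$price_by_crop), collapse = ", "), "\n")
  invisible(x)
}

#' Validate a regional state against all structural invariants
#'
#' Checks every type invariant: negative elasticities, positive price
#' constants and floors, reciprocal harvest efficiency, non-negative costs and
#' yields, positive plot sizes and prices, distinct diversified strategies
#' with enough plots, finite funds, positive baseline labor.
#'
#' @param region a [region_state()].
#' @return `TRUE` invisibly; otherwise an error naming the violated field.
#' @export
validate_region <- function(region) {
  stopifnot(inherits(region, "region_state"))
  for (cr in region$crops) {
    if (cr$elasticity >= 0)
      csk_stop(sprintf("crop '%s': elasticity must be negative", cr$name),
               "cropshock_invalid")
    if (!is.finite(cr$price_constant) || cr$price_constant <= 0)
      csk_stop(sprintf("crop '%s': price_constant must be positive", cr$name),
               "cropshock_invalid")
    if (abs(cr$harvest_efficiency * cr$labor_requirement_per_acre - 1) > 1e-12)
      csk_stop(sprintf("crop '%s': harvest_efficiency must be 1/labor_requirement",
                       cr$name), "cropshock_invalid")
    if (cr$production_cost_per_acre < 0 || cr$labor_cost_per_acre < 0)
      csk_stop(sprintf("crop '%s': costs must be non-negative", cr$name),
               "cropshock_invalid")
  }
  if (any(region$market$price_by_crop <= 0))
    csk_stop("market prices must be positive", "cropshock_invalid")
  for (u in region$units) {
    if (!is.finite(u$funds))
      csk_stop(sprintf("unit '%s': funds must be finite", u$unit_id),
               "cropshock_invalid")
    if (u$strategy_type == "diversified" && length(u$strategy) < 2L)
      csk_stop(sprintf("unit '%s': diversified strategy needs >= 2 crops",
                       u$unit_id), "cropshock_invalid")
    if (length(u$plots) < length(u$strategy))
      csk_stop(sprintf("unit '%s': fewer plots than strategy crops", u$unit_id),
               "cropshock_infeasible_strategy")
    for (p in u$plots) {
      if (p$size_acres <= 0)
        csk_stop(sprintf("unit '%s', plot '%s': size must be positive",
                         u$unit_id, p$plot_id), "cropshock_invalid")
      if (any(p$yield_by_crop < 0))
        csk_stop(sprintf("unit '%s', plot '%s': yields must be non-negative",
                         u$unit_id, p$plot_id), "cropshock_invalid")
    }
  }
  if (region$baseline_labor_total <= 0)
    csk_stop("baseline_labor_total must be positive", "cropshock_invalid")
  invisible(TRUE)
}
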