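#' Crop parameter set
#'
#' Bundles the per-crop economics used throughout the simulator: the demand
#' elasticity and calibration constant of the market price law, non-labor
#' production cost, harvest labor cost and labor requirement, and the derived
#' harvest efficiency (acres one laborer can harvest in a season).
#'
#' The market price of a crop at the end of a season is
#' \deqn{V_t = a \, Y_t^{\epsilon}}
#' where \eqn{Y_t} is the total mass (kg) of the crop harvested by all farming
#' units in the region that season, \eqn{\epsilon < 0} is the demand
#' elasticity, and \eqn{a} is a constant calibrated from mean historical price
#' and harvest so that the price at the calibration harvest equals the
#' calibration price (see [derive_price_constant()]).
#'
#' @param name crop label (e.g. `"strawberry"`).
#' @param elasticity demand elasticity \eqn{\epsilon}; must be negative.
#' @param production_cost_per_acre non-labor production cost, USD/acre
#'   (transplants, fertilizer, equipment, ...). Incurred for every planted
#'   acre whether or not it is harvested.
#' @param labor_cost_per_acre harvest labor cost, USD/acre, as reported in
#'   farm budgets; used to derive a per-laborer wage via
#'   [derive_labor_cost()].
#' @param labor_requirement_per_acre laborers needed to harvest one acre in a
#'   season. Its reciprocal is the harvest efficiency \eqn{h} (acres/laborer).
#' @param mean_price,mean_yield_per_acre optional calibration anchors: mean
#'   historical market price (USD/kg) and mean yield (kg/acre). The price
#'   constant itself is derived against a concrete region composition when a
#'   region is built, because the price law acts on the regional total
#'   harvest.
#' @param price_constant,price_floor usually left `NA` and filled in by
#'   region calibration; supply them directly only for standalone use of
#'   [update_market_price()].
#'
#' @return an object of class `crop_params`.
#' @seealso [derive_price_constant()], [update_market_price()],
#'   [florida_fixture()]
#' @export
#' @examples
#' crop_params("tomato", elasticity = -0.58,
#'   production_cost_per_acre = 10078, labor_cost_per_acre = 2408,
#'   labor_requirement_per_acre = 0.29)
crop_params <- function(name, elasticity, production_cost_per_acre,
                        labor_cost_per_acre, labor_requirement_per_acre,
                        mean_price = NA_real_, mean_yield_per_acre = NA_real_,
                        price_constant = NA_real_, price_floor = NA_real_) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    csk_stop("crop `name` must be a non-empty string", "cropshock_invalid")
  if (!is_number(elasticity) || elasticity >= 0)
    csk_stop(sprintf("elasticity of crop '%s' must be negative (got %s)",
                     name, format(elasticity)), "cropshock_invalid")
  if (!is_number(production_cost_per_acre) || production_cost_per_acre < 0)
    csk_stop("production_cost_per_acre must be a non-negative number",
             "cropshock_invalid")
  if (!is_number(labor_cost_per_acre) || labor_cost_per_acre < 0)
    csk_stop("labor_cost_per_acre must be a non-negative number",
             "cropshock_invalid")
  if (!is_number(labor_requirement_per_acre) || labor_requirement_per_acre <= 0)
    csk_stop("labor_requirement_per_acre must be strictly positive",
             "cropshock_invalid")
  if (!is.na(price_constant) && price_constant <= 0)
    csk_stop("price_constant must be strictly positive", "cropshock_invalid")
  structure(list(
    name = name,
    elasticity = elasticity,
    price_constant = price_constant,
    production_cost_per_acre = production_cost_per_acre,
    labor_cost_per_acre = labor_cost_per_acre,
    labor_requirement_per_acre = labor_requirement_per_acre,
    harvest_efficiency = 1 / labor_requirement_per_acre,
    price_floor = price_floor,
    mean_price = mean_price,
    mean_yield_per_acre = mean_yield_per_acre
  ), class = "crop_params")
}

#' @export
print.crop_params <- function(x, ...) {
  cat(sprintf("<crop_params> %s\n", x$name))
  cat(sprintf("  elasticity %.3g | production %s USD/acre | harvest labor %s USD/acre\n",
              x$elasticity, format(x$production_cost_per_acre, big.mark = ","),
              format(x$labor_cost_per_acre, big.mark = ",")))
  cat(sprintf("  labor requirement %.3g laborers/acre (efficiency %.4g acres/laborer)\n",
              x$labor_requirement_per_acre, x$harvest_efficiency))
  if (is.finite(x$price_constant))
    cat(sprintf("  price law: V = %.6g * Y^%.3g (floor %.5g kg)\n",
                x$price_constant, x$elasticity, x$price_floor))
  invisible(x)
}

#' Economy-wide parameters
#'
#' @param labor_cost_per_laborer wage per laborer per season, USD. The harvest
#'   objective charges this single economy-wide \eqn{C_L} against every
#'   allocated laborer.
#' @param price_floor_frac fraction of each crop's calibration harvest used as
#'   the lower clamp on the aggregate harvest entering the price law. The
#'   power law diverges as the harvest goes to zero (negative elasticity), so
#'   a season with no harvest is priced as if the harvest were this small
#'   positive floor.
#'
#' @return an object of class `economy_params`.
#' @export
economy_params <- function(labor_cost_per_laborer, price_floor_frac = 0.01) {
  if (!is_number(labor_cost_per_laborer) || labor_cost_per_laborer < 0)
    csk_stop("labor_cost_per_laborer must be a non-negative number",
             "cropshock_invalid")
  if (!is_number(price_floor_frac) || price_floor_frac <= 0)
    csk_stop("price_floor_frac must be strictly positive", "cropshock_invalid")
  structure(list(labor_cost_per_laborer = labor_cost_per_laborer,
                 price_floor_frac = price_floor_frac),
            class = "economy_params")
}

#' Calibrate the market price constant
#'
#' Inverts the price law at a calibration point: given a mean historical price
#' \eqn{\bar V} and mean total harvest \eqn{\bar Y}, returns
#' \eqn{a = \bar V / \bar Y^{\epsilon}} so that the price evaluated at the
#' calibration harvest reproduces the calibration price exactly.
#'
#' @param mean_price mean market price, USD/kg; must be positive.
#' @param mean_yield mean total harvest at calibration, kg; must be positive.
#' @param elasticity demand elasticity (dimensionless, typically negative).
#' @return the price constant `a` (a positive scalar).
#' @export
#' @examples
#' a <- derive_price_constant(2, 4, -0.5)  # a = 4; check: 4 * 4^-0.5 == 2
derive_price_constant <- function(mean_price, mean_yield, elasticity) {
  if (!is_number(mean_price) || mean_price <= 0)
    csk_stop("calibration mean_price must be strictly positive",
             "cropshock_invalid_calibration")
  if (!is_number(mean_yield) || mean_yield <= 0)
    csk_stop("calibration mean_yield must be strictly positive",
             "cropshock_invalid_calibration")
  if (!is_number(elasticity))
    csk_stop("elasticity must be a finite number", "cropshock_invalid")
  mean_price / mean_yield^elasticity
}

#' End-of-season market price from the regional harvest
#'
#' Evaluates \eqn{V_t = a \max(Y_t, Y_{floor})^{\epsilon}} for one crop. The
#' floor keeps the price finite when little or nothing is harvested; above the
#' floor the price is strictly decreasing in the harvest because the
#' elasticity is negative.
#'
#' @param crop a [crop_params()] with `price_constant` and `price_floor` set
#'   (region calibration fills these in).
#' @param total_harvest aggregate regional harvest of this crop, kg; may be
#'   zero. Vectorized.
#' @return price(s), USD/kg.
#' @export
update_market_price <- function(crop, total_harvest) {
  stopifnot(inherits(crop, "crop_params"))
  if (!is.finite(crop$price_constant) || !is.finite(crop$price_floor))
    csk_stop(sprintf("crop '%s' is not calibrated (price_constant/price_floor missing)",
                     crop$name), "cropshock_invalid_calibration")
  if (any(!is.finite(total_harvest)) || any(total_harvest < 0))
    csk_stop("total_harvest must be finite and non-negative", "cropshock_invalid")
  crop$price_constant * pmax(total_harvest, crop$price_floor)^crop$elasticity
}

#' Per-laborer wage from a per-acre labor cost
#'
#' Farm budgets report harvest labor cost per acre; the harvest optimization
#' charges labor per laborer. The two are reconciled by dividing the per-acre
#' cost by the per-acre labor requirement.
#'
#' @param labor_cost_per_acre USD/acre.
#' @param labor_requirement_per_acre laborers/acre; must be positive.
#' @return USD per laborer per season.
#' @export
#' @examples
#' derive_labor_cost(7788, 0.95)  # ~8198 USD/laborer (strawberry budget)
#' derive_labor_cost(2408, 0.29)  # ~8303 USD/laborer (tomato budget)
derive_labor_cost <- function(labor_cost_per_acre, labor_requirement_per_acre) {
  if (!is_number(labor_cost_per_acre) || labor_cost_per_acre < 0)
    csk_stop("labor_cost_per_acre must be a non-negative number",
             "cropshock_invalid")
  if (!is_number(labor_requirement_per_acre) || labor_requirement_per_acre <= 0)
    csk_stop("labor_requirement_per_acre must be strictly positive",
             "cropshock_division_guard")
  labor_cost_per_acre / labor_requirement_per_acre
}

#' Labor needed to harvest a plot in full
#'
#' @param plot a [plot_spec()] (or a plain acreage).
#' @param crop a [crop_params()].
#' @return laborers required for a complete harvest of the plot:
#'   acres divided by the crop's harvest efficiency.
#' @export
#' @examples
#' tomato <- crop_params("tomato", -0.58, 10078, 2408, 0.29)
#' harvest_capacity(100, tomato)  # 29 laborers per 100 acres
harvest_capacity <- function(plot, crop) {
  stopifnot(inherits(crop, "crop_params"))
  acres <- if (inherits(plot, "plot_spec")) plot$size_acres else plot
  if (!is.numeric(acres) || any(acres <= 0))
    csk_stop("plot size must be strictly positive", "cropshock_invalid")
  acres * crop$labor_requirement_per_acre
}
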