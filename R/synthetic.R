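# Seeded generator of randomized-but-valid regions, used for property tests.

#' Specification for the synthetic region generator
#'
#' Parameter ranges from which [generate_synthetic_region()] samples. All
#' defaults stay inside the structural invariants (negative elasticities,
#' positive costs and labor requirements), on the order of magnitude of
#' labor-intensive specialty crops.
#'
#' @param seed integer RNG seed; the generator is fully reproducible.
#' @param n_crops_range,n_plots_range,n_units_range integer ranges (inclusive).
#' @param elasticity_range strictly negative range for the demand elasticity.
#' @param price_range mean calibration price, USD/kg.
#' @param yield_range mean yield, kg/acre.
#' @param production_cost_range,labor_cost_range USD/acre ranges.
#' @param labor_requirement_range laborers/acre range, strictly positive.
#' @param acres_range plot size range, acres.
#' @param initial_funds starting funds per unit, USD.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed,
                           n_crops_range = c(2L, 3L),
                           n_plots_range = c(2L, 3L),
                           n_units_range = c(4L, 10L),
                           elasticity_range = c(-1, -0.2),
                           price_range = c(0.5, 5),
                           yield_range = c(5000, 20000),
                           production_cost_range = c(2000, 15000),
                           labor_cost_range = c(1000, 9000),
                           labor_requirement_range = c(0.2, 1.2),
                           acres_range = c(50, 150),
                           initial_funds = 1e6) {
  if (!is_number(seed) || seed != round(seed))
    csk_stop("seed must be an integer", "cropshock_invalid")
  if (any(elasticity_range >= 0))
    csk_stop("elasticity_range must be strictly negative", "cropshock_invalid")
  if (any(labor_requirement_range <= 0))
    csk_stop("labor_requirement_range must be strictly positive",
             "cropshock_invalid")
  rngs <- list(n_crops_range = n_crops_range, n_plots_range = n_plots_range,
               n_units_range = n_units_range,
               elasticity_range = elasticity_range, price_range = price_range,
               yield_range = yield_range,
               production_cost_range = production_cost_range,
               labor_cost_range = labor_cost_range,
               labor_requirement_range = labor_requirement_range,
               acres_range = acres_range)
  for (nm in names(rngs)) {
    r <- rngs[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2])
      csk_stop(sprintf("%s must be a valid (lo, hi) range", nm),
               "cropshock_invalid")
  }
  structure(c(list(seed = as.integer(seed), initial_funds = initial_funds),
              rngs), class = "synthetic_spec")
}

#' Generate a randomized, valid region
#'
#' Draws a region whose crops, plots and units all satisfy the structural
#' invariants: a property-test input generator spanning the parameter space
#' rather than a realistic scenario. Monocropped and diversified units are
#' mixed at random (always at least one of each when possible); plots within
#' a unit share sampled per-crop yields; crops are calibrated against the
#' sampled composition so the region is immediately runnable. The same seed
#' always yields an identical region.
#'
#' @param spec a [synthetic_spec()].
#' @return a calibrated, validated [region_state()].
#' @export
#' @examples
#' region <- generate_synthetic_region(synthetic_spec(seed = 42))
#' validate_region(region)
generate_synthetic_region <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)

  ri <- function(r) if (r[1] == r[2]) as.integer(r[1]) else sample(r[1]:r[2], 1L)
  ru <- function(r, n = 1L) stats::runif(n, r[1], r[2])

  m <- ri(spec$n_crops_range)
  crops <- vector("list", m)
  for (i in seq_len(m)) {
    crops[[i]] <- crop_params(
      name = sprintf("crop%02d", i),
      elasticity = ru(spec$elasticity_range),
      production_cost_per_acre = ru(spec$production_cost_range),
      labor_cost_per_acre = ru(spec$labor_cost_range),
      labor_requirement_per_acre = ru(spec$labor_requirement_range),
      mean_price = ru(spec$price_range),
      mean_yield_per_acre = ru(spec$yield_range))
  }
  names(crops) <- vapply(crops, `[[`, "", "name")
  cn <- names(crops)

  n_units <- ri(spec$n_units_range)
  units <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    n_plots <- ri(spec$n_plots_range)
    # the first unit diversifies over every crop so each crop has non-zero
    # baseline acreage (the price law needs a positive calibration harvest);
    # the rest alternate between monocropped and diversified at random
    if (u == 1L && m > 1L) {
      n_plots <- max(n_plots, m)
      strat <- cn
    } else if (u %% 2L == 0L || m < 2L) {
      strat <- cn[ri(c(1L, m))]
    } else {
      k <- min(m, n_plots, ri(c(2L, m)))
      strat <- if (k < 2L) cn[ri(c(1L, m))] else sort(sample(cn, k))
    }
    yields <- setNames(ru(spec$yield_range, m), cn)
    plots <- lapply(seq_len(n_plots), function(j)
      plot_spec(sprintf("u%02dp%d", u, j), ru(spec$acres_range), yields))
    units[[u]] <- farming_unit(sprintf("unit%02d", u), strat,
                               spec$initial_funds, plots)
  }
  CL <- mean(vapply(crops, function(cr)
    derive_labor_cost(cr$labor_cost_per_acre, cr$labor_requirement_per_acre), 0))
  region <- region_state(units, crops, economy_params(CL))
  validate_region(region)
  region
}
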