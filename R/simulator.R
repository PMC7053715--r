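#' Labor shock schedule
#'
#' A shock is a period of `duration` consecutive seasons during which only the
#' fraction `intensity` of the region's baseline labor is available. Lower
#' intensity means a more extreme shock (`intensity = 1` leaves labor
#' untouched; `intensity = 0.1` leaves 10% of the usual labor). Shocks start
#' in the first season by default.
#'
#' @param intensity fraction of baseline labor available during the shock,
#'   in \[0, 1\].
#' @param duration shock length in seasons, >= 1.
#' @param start_season first shocked season, >= 1.
#' @return an object of class `shock_schedule`.
#' @export
shock_schedule <- function(intensity, duration, start_season = 1L) {
  if (!is_number(intensity) || intensity < 0 || intensity > 1)
    csk_stop("intensity must lie in [0, 1]", "cropshock_invalid")
  if (!is_number(duration) || duration < 1 || duration != round(duration))
    csk_stop("duration must be an integer >= 1", "cropshock_invalid")
  if (!is_number(start_season) || start_season < 1 || start_season != round(start_season))
    csk_stop("start_season must be an integer >= 1", "cropshock_invalid")
  structure(list(intensity = intensity, duration = as.integer(duration),
                 start_season = as.integer(start_season)),
            class = "shock_schedule")
}

#' @export
print.shock_schedule <- function(x, ...) {
  cat(sprintf("<shock_schedule> i = %.2g for %d season(s) starting season %d\n",
              x$intensity, x$duration, x$start_season))
  invisible(x)
}

#' Baseline regional labor
#'
#' The regional labor pool is sized from the most labor-intensive crop: its
#' per-acre labor requirement times the total acreage of the region, so that
#' in the absence of a shock every unit could fully harvest even the most
#' demanding crop.
#'
#' @param region a [region_state()].
#' @return laborers available to the region in an unshocked season.
#' @export
baseline_labor <- function(region) {
  stopifnot(inherits(region, "region_state"))
  max(vapply(region$crops, `[[`, 0, "labor_requirement_per_acre")) *
    region$total_acres
}

#' Regional labor available in a given season
#'
#' @param season season index (1-based).
#' @param schedule a [shock_schedule()].
#' @param baseline baseline regional labor (laborers).
#' @return `intensity * baseline` while the shock is active, else `baseline`.
#'   Each farming unit receives an equal per-unit share of this amount.
#' @export
available_labor <- function(season, schedule, baseline) {
  stopifnot(inherits(schedule, "shock_schedule"))
  if (!is_number(season) || season < 1)
    csk_stop("season must be >= 1", "cropshock_invalid")
  shocked <- season >= schedule$start_season &&
    season < schedule$start_season + schedule$duration
  if (shocked) schedule$intensity * baseline else baseline
}

#' Advance the region by one season
#'
#' Runs one full season in the order: (1) every unit plants via
#' [plan_planting()] using the current market prices as expected prices;
#' (2) every unit harvests via [plan_harvest()] at its equal share of the
#' available labor, decisions valued at the same expected prices; (3) the
#' regional harvest is aggregated per crop; (4) end-of-season prices are
#' recomputed from the aggregate harvest via [update_market_price()];
#' (5) realized revenue is booked at the new prices and each unit's funds are
#' updated with its realized profit. Decisions therefore use lagged (expected)
#' prices while accounting uses the season's realized prices.
#'
#' Units with identical strategy and plots face identical decision problems
#' (decisions do not depend on funds), so their optimizations are solved once
#' and shared; accounting remains per unit.
#'
#' @param region a [region_state()].
#' @param labor_available regional labor this season (laborers).
#' @return a list with the updated `region` and the season `outcome`: a
#'   per-unit data frame (revenue, labor cost, production cost, profit,
#'   funds, harvested mass per crop), the realized `prices`, and the regional
#'   `harvest` by crop.
#' @export
step_season <- function(region, labor_available) {
  stopifnot(inherits(region, "region_state"))
  if (!is_number(labor_available) || labor_available < 0)
    csk_stop("labor_available must be non-negative", "cropshock_invalid")
  units <- region$units
  N <- length(units)
  share <- labor_available / N
  crops <- region$crops
  cn <- names(crops)
  economy <- region$economy
  prices <- region$market$price_by_crop

  cache <- new.env(parent = emptyenv(), size = 8L)
  plans <- vector("list", N)
  for (k in seq_len(N)) {
    u <- units[[k]]
    key <- u$decision_key
    hit <- cache[[key]]
    if (is.null(hit)) {
      plan <- plan_planting(u, crops, prices, economy, mode = region$mode)
      u$planting_plan <- plan
      harv <- plan_harvest(u, prices, share, crops, economy)
      hit <- list(plan = plan, harv = harv)
      cache[[key]] <- hit
    }
    plans[[k]] <- hit
  }

  total <- setNames(numeric(length(cn)), cn)
  for (k in seq_len(N)) total <- total + plans[[k]]$harv$harvested_mass

  new_prices <- setNames(numeric(length(cn)), cn)
  for (i in seq_along(crops))
    new_prices[i] <- update_market_price(crops[[i]], total[[i]])

  revenue <- labor_cost <- production_cost <- profit <- funds <- numeric(N)
  mass <- matrix(0, N, length(cn), dimnames = list(NULL, cn))
  CL <- economy$labor_cost_per_laborer
  for (k in seq_len(N)) {
    h <- plans[[k]]$harv
    revenue[k] <- sum(h$harvested_mass * new_prices)
    labor_cost[k] <- CL * h$labor_used
    production_cost[k] <- plans[[k]]$plan$production_cost
    profit[k] <- revenue[k] - labor_cost[k] - production_cost[k]
    units[[k]]$planting_plan <- plans[[k]]$plan
    units[[k]]$labor_share <- share
    funds[k] <- units[[k]]$funds + profit[k]
    units[[k]]$funds <- funds[k]
    mass[k, ] <- h$harvested_mass
  }

  season <- region$season + 1L
  region$units <- units
  region$season <- season
  region$market <- market_state(new_prices, total)

  outcome <- list(
    season = season,
    units = data.frame(
      season = season,
      unit_id = vapply(units, `[[`, "", "unit_id"),
      strategy = vapply(units, `[[`, "", "strategy_label"),
      revenue = revenue, labor_cost = labor_cost,
      production_cost = production_cost, profit = profit, funds = funds,
      stringsAsFactors = FALSE),
    mass = mass,
    prices = new_prices,
    harvest = total,
    labor_available = labor_available,
    labor_share = share)
  list(region = region, outcome = outcome)
}

#' Run a full simulation
#'
#' Iterates [step_season()] for `tau` seasons under a labor shock schedule.
#' In replication mode `tau` defaults to the shock duration plus one season,
#' so every run ends with one post-shock season. The model is deterministic:
#' identical inputs give bit-identical trajectories.
#'
#' @param region a [region_state()] (season 0, calibrated).
#' @param schedule a [shock_schedule()].
#' @param tau number of seasons; default `schedule$duration + 1`.
#' @param exit_floor optional funds floor (USD): units whose funds fall below
#'   it at the end of a season exit production and are removed from the
#'   region for the remaining seasons. Off (`NULL`) by default — under the
#'   Florida parameterization no unit ever exits — and provided as a hook
#'   for harsher economies.
#' @return an object of class `shock_sim`: tidy per-(season, unit) accounting
#'   in `$seasons` (with harvested mass per crop in `mass_<crop>` columns),
#'   per-season prices and regional harvests in `$prices`, the final region,
#'   and a config fingerprint.
#' @export
#' @examples
#' region <- compose_region(florida_fixture(), n_units = 6, n_diversified = 2)
#' sim <- run_simulation(region, shock_schedule(intensity = 0.5, duration = 2))
#' summary(sim)
run_simulation <- function(region, schedule, tau = NULL, exit_floor = NULL) {
  stopifnot(inherits(region, "region_state"), inherits(schedule, "shock_schedule"))
  if (is.null(tau)) tau <- schedule$duration + 1L
  if (!is_number(tau) || tau < 1 || tau != round(tau))
    csk_stop("tau must be an integer >= 1", "cropshock_invalid")
  tau <- as.integer(tau)
  baseline <- region$baseline_labor_total
  initial_funds <- setNames(vapply(region$units, `[[`, 0, "funds"),
                            vapply(region$units, `[[`, "", "unit_id"))
  fingerprint <- csk_fingerprint(list(
    crops = region$crops, economy = region$economy,
    units = lapply(region$units, function(u) u[c("strategy", "funds", "plots")]),
    mode = region$mode, schedule = unclass(schedule), tau = tau))

  season_rows <- vector("list", tau)
  price_rows <- vector("list", tau)
  exits <- data.frame(season = integer(), unit_id = character(),
                      funds = numeric(), stringsAsFactors = FALSE)
  for (t in seq_len(tau)) {
    lab <- available_labor(t, schedule, baseline)
    st <- step_season(region, lab)
    region <- st$region
    out <- st$outcome
    df <- out$units
    for (nm in colnames(out$mass)) df[[paste0("mass_", nm)]] <- out$mass[, nm]
    season_rows[[t]] <- df
    price_rows[[t]] <- data.frame(season = t, crop = names(out$prices),
                                  price = unname(out$prices),
                                  regional_harvest = unname(out$harvest),
                                  labor_available = lab,
                                  stringsAsFactors = FALSE)
    if (!is.null(exit_floor)) {
      funds <- vapply(region$units, `[[`, 0, "funds")
      gone <- funds < exit_floor
      if (any(gone)) {
        exits <- rbind(exits, data.frame(
          season = t,
          unit_id = vapply(region$units[gone], `[[`, "", "unit_id"),
          funds = funds[gone], stringsAsFactors = FALSE))
        if (all(gone))
          csk_stop("every farming unit exited production", "cropshock_collapse")
        region$units <- region$units[!gone]
      }
    }
  }
  structure(list(
    seasons = do.call(rbind, season_rows),
    prices = do.call(rbind, price_rows),
    initial_funds = initial_funds,
    schedule = schedule,
    tau = tau,
    region = region,
    exits = exits,
    fingerprint = fingerprint), class = "shock_sim")
}

#' @export
print.shock_sim <- function(x, ...) {
  cat(sprintf("<shock_sim> %d season(s), %d units; shock i = %.2g for %d season(s)\n",
              x$tau, length(x$region$units), x$schedule$intensity,
              x$schedule$duration))
  fin <- final_funds_by_strategy(x)
  cat("  mean end funds by strategy (USD):\n")
  for (nm in names(fin))
    cat(sprintf("    %-12s %s\n", nm, format(round(fin[[nm]]), big.mark = ",")))
  invisible(x)
}

#' @export
summary.shock_sim <- function(object, ...) {
  last <- object$seasons[object$seasons$season == object$tau, ]
  agg <- stats::aggregate(funds ~ strategy, data = last, FUN = mean)
  structure(list(tau = object$tau, schedule = object$schedule,
                 mean_end_funds = setNames(agg$funds, agg$strategy),
                 prices = object$prices),
            class = "summary.shock_sim")
}

#' @export
print.summary.shock_sim <- function(x, ...) {
  cat(sprintf("Simulation of %d season(s) under shock i = %.2g, d = %d\n",
              x$tau, x$schedule$intensity, x$schedule$duration))
  cat("Mean end-of-run funds by strategy (USD):\n")
  print(round(x$mean_end_funds))
  cat("End-of-season prices (USD/kg):\n")
  print(utils::tail(x$prices[, c("season", "crop", "price")], 2 * length(unique(x$prices$crop))),
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.shock_sim <- function(x, ...) x$seasons

#' @export
plot.shock_sim <- function(x, ...) {
  agg <- stats::aggregate(funds ~ season + strategy, data = x$seasons, FUN = mean)
  strategies <- sort(unique(agg$strategy))
  cols <- grDevices::hcl.colors(max(3L, length(strategies)), "Dark 3")
  graphics::plot(range(agg$season), range(agg$funds) / 1e6, type = "n",
                 xlab = "season", ylab = "mean funds (million USD)", ...)
  for (s in seq_along(strategies)) {
    sub <- agg[agg$strategy == strategies[s], ]
    graphics::lines(sub$season, sub$funds / 1e6, col = cols[s], lwd = 2)
    graphics::points(sub$season, sub$funds / 1e6, col = cols[s], pch = 16)
  }
  graphics::legend("topleft", legend = strategies, col = cols[seq_along(strategies)],
                   lwd = 2, bty = "n")
  invisible(x)
}

final_funds_by_strategy <- function(sim) {
  last <- sim$seasons[sim$seasons$season == sim$tau, ]
  agg <- stats::aggregate(funds ~ strategy, data = last, FUN = mean)
  setNames(agg$funds, agg$strategy)
}
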