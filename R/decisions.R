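# Planting (crop -> plot integer program) and harvesting (labor -> plot
# allocation) optimizers, plus profit accounting.
#
# Both optimizers are exact. Planting: the objective is additive over plots,
# so the unconstrained ("free") problem decomposes into independent per-plot
# argmaxes; the diversified coverage constraint (each strategy crop on at
# least one plot) is handled by dynamic programming over plots with a bitmask
# of crops already covered. Harvesting: a single-resource LP with box
# constraints, solved exactly by filling plots in descending order of
# marginal profit per laborer.

# expected full-harvest value of planting crop i on plot j:
#   V_i * Y_ij * S_j  -  C_L * r_i * S_j  -  c_i * S_j
# (revenue at full harvest minus labor at full harvest minus production cost)
planting_value_matrix <- function(unit, crops, prices, economy) {
  m <- length(crops); n <- length(unit$plots)
  cn <- names(crops)
  v <- matrix(0, m, n, dimnames = list(cn, vapply(unit$plots, `[[`, "", "plot_id")))
  CL <- economy$labor_cost_per_laborer
  for (j in seq_len(n)) {
    p <- unit$plots[[j]]
    S <- p$size_acres
    for (i in seq_len(m)) {
      cr <- crops[[i]]
      Y <- p$yield_by_crop[[cr$name]] %||% 0
      if (is.na(Y)) Y <- 0
      v[i, j] <- prices[[cr$name]] * Y * S -
        CL * cr$labor_requirement_per_acre * S -
        cr$production_cost_per_acre * S
    }
  }
  v
}

new_planting_plan <- function(crop_for_plot, crops, unit, objective, mode) {
  m <- length(crops); n <- length(crop_for_plot)
  x <- matrix(0L, m, n, dimnames = list(names(crops),
                                        vapply(unit$plots, `[[`, "", "plot_id")))
  prod_cost <- 0
  for (j in seq_len(n)) {
    i <- crop_for_plot[j]
    if (i > 0L) {
      x[i, j] <- 1L
      prod_cost <- prod_cost +
        crops[[i]]$production_cost_per_acre * unit$plots[[j]]$size_acres
    }
  }
  structure(list(crop_for_plot = crop_for_plot, x = x,
                 objective = objective, production_cost = prod_cost,
                 mode = mode),
            class = "planting_plan")
}

#' @export
print.planting_plan <- function(x, ...) {
  cn <- rownames(x$x)
  lab <- ifelse(x$crop_for_plot > 0L, cn[pmax(x$crop_for_plot, 1L)], "(fallow)")
  cat(sprintf("<planting_plan> [%s] expected profit %s USD (%s mode)\n",
              paste(sprintf("%s: %s", colnames(x$x), lab), collapse = ", "),
              format(round(x$objective), big.mark = ","), x$mode))
  invisible(x)
}

# exact coverage-constrained assignment by DP over plots; strat_idx are crop
# indices (ascending), every plot must be planted with a strategy crop and
# every strategy crop must appear at least once
solve_coverage_dp <- function(v, strat_idx, n) {
  m <- length(strat_idx)
  nmask <- bitwShiftL(1L, m)
  full <- nmask - 1L
  val <- rep(-Inf, nmask); val[1L] <- 0
  choice <- matrix(NA_integer_, nmask, n)  # crop slot chosen to reach mask at plot j
  parent <- matrix(NA_integer_, nmask, n)
  for (j in seq_len(n)) {
    newval <- rep(-Inf, nmask)
    for (mask in 0:(nmask - 1L)) {
      base <- val[mask + 1L]
      if (!is.finite(base)) next
      for (k in seq_len(m)) {
        nm <- bitwOr(mask, bitwShiftL(1L, k - 1L))
        cand <- base + v[strat_idx[k], j]
        if (cand > newval[nm + 1L]) {   # strict > keeps lexicographic first
          newval[nm + 1L] <- cand
          choice[nm + 1L, j] <- k
          parent[nm + 1L, j] <- mask
        }
      }
    }
    val <- newval
  }
  if (!is.finite(val[full + 1L]))
    csk_stop("no feasible assignment covers every strategy crop",
             "cropshock_infeasible_strategy")
  assign <- integer(n)
  mask <- full
  for (j in rev(seq_len(n))) {
    k <- choice[mask + 1L, j]
    assign[j] <- strat_idx[k]
    mask <- parent[mask + 1L, j]
  }
  list(assign = assign, objective = val[full + 1L])
}

#' Plant crops on plots by exact constrained integer programming
#'
#' Chooses the binary crop-to-plot assignment \eqn{x_{ij}} that maximizes the
#' unit's expected seasonal profit under the assumption that planted plots
#' will be harvested in full (planting precedes the labor draw, so the
#' planner cannot anticipate a shock). Each plot carries at most one crop.
#'
#' In `strategy_constrained` mode (the case-study setting) the unit's fixed
#' strategy binds: a monocropped unit plants its crop on every plot; a
#' diversified unit plants every plot with one of its strategy crops such that
#' each strategy crop occupies at least one plot. In `free` mode any crop (or
#' fallow) may go on any plot. Equal-objective optima are resolved
#' deterministically in favor of lower crop index on lower plot index.
#'
#' @param unit a [farming_unit()].
#' @param crops named list of calibrated [crop_params()].
#' @param expected_prices named price vector (USD/kg) used as the expected
#'   market prices, typically the previous season's realized prices.
#' @param economy an [economy_params()].
#' @param mode `"strategy_constrained"` or `"free"`.
#' @return a `planting_plan` with the assignment, its binary matrix `x`, and
#'   the expected (full-harvest) profit as `objective`.
#' @export
plan_planting <- function(unit, crops, expected_prices, economy,
                          mode = c("strategy_constrained", "free")) {
  mode <- match.arg(mode)
  stopifnot(inherits(unit, "farming_unit"))
  if (any(expected_prices <= 0) || any(!is.finite(expected_prices)))
    csk_stop("expected prices must be positive and finite", "cropshock_invalid")
  n <- length(unit$plots)
  if (n < 1L) csk_stop("unit has no plots", "cropshock_invalid")
  v <- planting_value_matrix(unit, crops, expected_prices, economy)

  if (mode == "free") {
    assign <- integer(n)
    obj <- 0
    for (j in seq_len(n)) {
      i <- which.max(v[, j])           # first maximum -> lowest crop index
      if (v[i, j] >= 0) {              # ties with fallow resolved to planting
        assign[j] <- i
        obj <- obj + v[i, j]
      }
    }
    return(new_planting_plan(assign, crops, unit, obj, mode))
  }

  strat_idx <- sort(match(unit$strategy, names(crops)))
  if (anyNA(strat_idx))
    csk_stop("strategy names a crop not present in `crops`", "cropshock_invalid")
  if (length(strat_idx) == 1L) {
    assign <- rep(strat_idx, n)        # every plot planted in its entirety
    return(new_planting_plan(assign, crops, unit, sum(v[strat_idx, ]), mode))
  }
  if (n < length(strat_idx))
    csk_stop(sprintf("unit '%s': %d strategy crops but only %d plots",
                     unit$unit_id, length(strat_idx), n),
             "cropshock_infeasible_strategy")
  sol <- solve_coverage_dp(v, strat_idx, n)
  new_planting_plan(sol$assign, crops, unit, sol$objective, mode)
}

#' Allocate harvest labor across planted plots
#'
#' Solves the harvest-time linear program: maximize
#' \eqn{\sum_{ij} (V_i Y_{ij} h_i - C_L) L_{ij}} over labor allocations
#' \eqn{L_{ij} \ge 0} subject to the unit's labor budget and per-plot
#' capacities \eqn{L_{ij} \le S_j / h_i}. Labor is divisible, so partial
#' harvests are possible. Plots whose marginal profit per laborer is not
#' positive receive no labor: a unit only harvests what the expected market
#' price dictates to be profitable. With one shared budget and box
#' constraints the greedy fill by descending marginal profit per laborer is
#' the exact LP optimum; ties break on (crop index, plot index).
#'
#' @param unit a [farming_unit()] whose `planting_plan` is set.
#' @param decision_prices expected prices (USD/kg) the unit believes it will
#'   receive; realized revenue may later be booked at different prices.
#' @param labor_budget laborers available to this unit this season.
#' @param crops named list of [crop_params()].
#' @param economy an [economy_params()].
#' @return a `harvest_plan`: labor by plot and as the matrix `L`, harvested
#'   mass by crop (kg), labor used, and the expected-value objective.
#' @export
plan_harvest <- function(unit, decision_prices, labor_budget, crops, economy) {
  stopifnot(inherits(unit, "farming_unit"))
  if (!is_number(labor_budget) || labor_budget < 0)
    csk_stop("labor_budget must be a non-negative number", "cropshock_invalid")
  plan <- unit$planting_plan
  if (is.null(plan))
    csk_stop(sprintf("unit '%s' has no planting plan", unit$unit_id),
             "cropshock_invalid")
  n <- length(unit$plots)
  cn <- names(crops)
  CL <- economy$labor_cost_per_laborer

  labor <- numeric(n)
  planted <- which(plan$crop_for_plot > 0L)
  margin <- cap <- numeric(length(planted))
  for (k in seq_along(planted)) {
    j <- planted[k]
    i <- plan$crop_for_plot[j]
    cr <- crops[[i]]
    p <- unit$plots[[j]]
    Y <- p$yield_by_crop[[cr$name]] %||% 0
    if (is.na(Y)) Y <- 0
    margin[k] <- decision_prices[[cr$name]] * Y * cr$harvest_efficiency - CL
    cap[k] <- p$size_acres * cr$labor_requirement_per_acre
  }
  ord <- order(-margin, plan$crop_for_plot[planted], planted)
  left <- labor_budget
  for (k in ord) {
    if (left <= 0 || margin[k] <= 0) next
    take <- min(cap[k], left)
    labor[planted[k]] <- take
    left <- left - take
  }

  L <- matrix(0, length(cn), n, dimnames = list(cn, vapply(unit$plots, `[[`, "", "plot_id")))
  mass <- setNames(numeric(length(cn)), cn)
  for (k in seq_along(planted)) {
    j <- planted[k]
    i <- plan$crop_for_plot[j]
    L[i, j] <- labor[j]
    cr <- crops[[i]]
    p <- unit$plots[[j]]
    Y <- p$yield_by_crop[[cr$name]] %||% 0
    if (is.na(Y)) Y <- 0
    # a fully staffed plot is harvested in exactly its acreage
    acres <- if (labor[j] >= cap[k]) p$size_acres
             else labor[j] * cr$harvest_efficiency
    mass[i] <- mass[i] + Y * acres
  }
  structure(list(labor_by_plot = labor, L = L, harvested_mass = mass,
                 labor_used = sum(labor),
                 objective = sum(margin * labor[planted])),
            class = "harvest_plan")
}

#' @export
print.harvest_plan <- function(x, ...) {
  cat(sprintf("<harvest_plan> %.4g laborers used; harvest (kg): %s\n",
              x$labor_used,
              paste(sprintf("%s %.4g", names(x$harvested_mass), x$harvested_mass),
                    collapse = ", ")))
  invisible(x)
}

#' Seasonal profit of a planting plan under a labor allocation
#'
#' Evaluates the seasonal profit
#' \eqn{\Psi = \sum_{ij} (V_i Y_{ij} h_i L_{ij} - C_L L_{ij} - a_{ij}) x_{ij}}
#' where the production cost \eqn{a_{ij}} (the per-acre cost times the plot
#' size) is incurred for every planted plot regardless of how much of it is
#' harvested. Labor on an unplanted plot violates the plan invariants and is
#' an error.
#'
#' @param plan a `planting_plan`.
#' @param labor a `harvest_plan`, a numeric vector of laborers by plot, or
#'   the string `"full"` for the full-harvest assumption
#'   \eqn{L_{ij} = S_j / h_i}.
#' @param prices named price vector, USD/kg.
#' @param unit,crops,economy as elsewhere.
#' @return a `profit_breakdown` with `revenue`, `labor_cost`,
#'   `production_cost` and `profit` (all USD).
#' @export
expected_profit <- function(plan, labor, prices, unit, crops, economy) {
  stopifnot(inherits(plan, "planting_plan"))
  n <- length(plan$crop_for_plot)
  if (inherits(labor, "harvest_plan")) {
    lab <- labor$labor_by_plot
  } else if (identical(labor, "full")) {
    lab <- numeric(n)
    for (j in seq_len(n)) {
      i <- plan$crop_for_plot[j]
      if (i > 0L)
        lab[j] <- unit$plots[[j]]$size_acres * crops[[i]]$labor_requirement_per_acre
    }
  } else if (is.numeric(labor) && length(labor) == n) {
    lab <- labor
  } else {
    csk_stop("labor must be a harvest_plan, a numeric vector per plot, or \"full\"",
             "cropshock_invalid")
  }
  if (any(lab < 0))
    csk_stop("labor must be non-negative", "cropshock_invalid")
  if (any(lab > 1e-12 & plan$crop_for_plot == 0L))
    csk_stop("labor allocated to an unplanted plot", "cropshock_invariant")

  CL <- economy$labor_cost_per_laborer
  revenue <- 0; production <- 0
  for (j in seq_len(n)) {
    i <- plan$crop_for_plot[j]
    if (i == 0L) next
    cr <- crops[[i]]
    p <- unit$plots[[j]]
    Y <- p$yield_by_crop[[cr$name]] %||% 0
    if (is.na(Y)) Y <- 0
    revenue <- revenue + prices[[cr$name]] * Y * cr$harvest_efficiency * lab[j]
    production <- production + cr$production_cost_per_acre * p$size_acres
  }
  labor_cost <- CL * sum(lab)
  structure(list(revenue = revenue, labor_cost = labor_cost,
                 production_cost = production,
                 profit = revenue - labor_cost - production),
            class = "profit_breakdown")
}

#' @export
print.profit_breakdown <- function(x, ...) {
  cat(sprintf("<profit_breakdown> revenue %s - labor %s - production %s = profit %s USD\n",
              format(round(x$revenue), big.mark = ","),
              format(round(x$labor_cost), big.mark = ","),
              format(round(x$production_cost), big.mark = ","),
              format(round(x$profit), big.mark = ",")))
  invisible(x)
}
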