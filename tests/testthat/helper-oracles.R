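# Independent oracles and instance generators used to certify the bespoke
# optimizers. The oracles share no code with the solvers they check:
# planting is certified against exhaustive enumeration of all feasible
# assignments, harvesting against a dense LP solve (boot::simplex).

# best achievable expected (full-harvest) profit over every feasible
# crop-to-plot assignment, by brute force
oracle_best_planting <- function(unit, crops, prices, economy,
                                 mode = c("free", "strategy_constrained")) {
  mode <- match.arg(mode)
  m <- length(crops)
  n <- length(unit$plots)
  choices <- if (mode == "free") 0:m else match(unit$strategy, names(crops))
  grid <- as.matrix(do.call(expand.grid, rep(list(choices), n)))
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    assign <- as.integer(grid[r, ])
    if (mode == "strategy_constrained" &&
        !all(match(unit$strategy, names(crops)) %in% assign)) next
    plan <- cropshock:::new_planting_plan(assign, crops, unit, NA_real_, mode)
    val <- expected_profit(plan, "full", prices, unit, crops, economy)$profit
    if (val > best) best <- val
  }
  best
}

# LP optimum of the harvest allocation: maximize sum(margin * L) subject to
# sum(L) <= budget, 0 <= L <= cap
oracle_best_harvest <- function(margins, caps, budget) {
  k <- length(margins)
  if (k == 0L || budget <= 0) return(0)
  sol <- boot::simplex(a = margins,
                       A1 = rbind(rep(1, k), diag(k)),
                       b1 = c(budget, caps),
                       maxi = TRUE)
  unname(sol$value)
}

# margins and capacities of a unit's planted plots, recomputed independently
# of plan_harvest's internals
harvest_margins <- function(unit, crops, prices, economy) {
  plan <- unit$planting_plan
  planted <- which(plan$crop_for_plot > 0L)
  margins <- caps <- numeric(length(planted))
  for (k in seq_along(planted)) {
    j <- planted[k]
    cr <- crops[[plan$crop_for_plot[j]]]
    p <- unit$plots[[j]]
    Y <- p$yield_by_crop[[cr$name]]
    if (is.null(Y) || is.na(Y)) Y <- 0
    margins[k] <- prices[[cr$name]] * Y / cr$labor_requirement_per_acre -
      economy$labor_cost_per_laborer
    caps[k] <- p$size_acres * cr$labor_requirement_per_acre
  }
  list(margins = margins, caps = caps)
}

# a random small decision instance (<= 3 crops, <= 3 plots) with occasional
# zero yields and a random existing planting plan for harvest tests
random_instance <- function(seed) {
  set.seed(seed)
  m <- sample(1:3, 1)
  n <- sample(1:3, 1)
  crops <- lapply(seq_len(m), function(i)
    crop_params(sprintf("c%d", i),
                elasticity = stats::runif(1, -1, -0.2),
                production_cost_per_acre = stats::runif(1, 0, 15000),
                labor_cost_per_acre = stats::runif(1, 0, 9000),
                labor_requirement_per_acre = stats::runif(1, 0.1, 1.5)))
  names(crops) <- vapply(crops, `[[`, "", "name")
  prices <- stats::setNames(stats::runif(m, 0.2, 5), names(crops))
  plots <- lapply(seq_len(n), function(j) {
    y <- stats::runif(m, 0, 25000)
    y[stats::runif(m) < 0.15] <- 0          # occasional worthless plantings
    plot_spec(sprintf("p%d", j), stats::runif(1, 20, 200),
              stats::setNames(y, names(crops)))
  })
  strategy <- if (m >= 2 && n >= 2 && stats::runif(1) < 0.5)
    sort(sample(names(crops), min(sample(2:m, 1), n)))
  else sample(names(crops), 1)
  unit <- farming_unit("u1", strategy, 1e6, plots)
  economy <- economy_params(stats::runif(1, 1000, 12000))
  budget <- stats::runif(1, 0, 1.5 * sum(vapply(seq_len(n), function(j)
    plots[[j]]$size_acres * crops[[sample(m, 1)]]$labor_requirement_per_acre, 0)))
  list(unit = unit, crops = crops, prices = prices, economy = economy,
       budget = budget, m = m, n = n)
}

florida_region <- function(n_units = 30, n_diversified = 2) {
  compose_region(florida_fixture(), n_units, n_diversified)
}
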