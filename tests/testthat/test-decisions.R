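# The two bespoke optimizers and the profit accounting they share.

mk_simple <- function() {
  crops <- list(
    strawberry = crop_params("strawberry", -0.66, 12305, 7788, 0.95),
    tomato = crop_params("tomato", -0.58, 10078, 2408, 0.29))
  plots <- list(plot_spec("p1", 100, c(strawberry = 10000, tomato = 14500)),
                plot_spec("p2", 100, c(strawberry = 10000, tomato = 14500)))
  list(crops = crops, plots = plots,
       prices = c(strawberry = 2.65, tomato = 1.0),
       economy = economy_params(8250))
}

test_that("profit evaluation matches hand-computed cases", {
  s <- mk_simple()
  unit <- farming_unit("u", "tomato", 0, s$plots[1])
  plan <- plan_planting(unit, s$crops, s$prices, s$economy)
  # no harvest: the full production cost of the planted plot is still incurred
  zero <- expected_profit(plan, c(0), s$prices, unit, s$crops, s$economy)
  expect_equal(zero$profit, -1007800)
  expect_equal(zero$revenue, 0)

  # pure revenue: V * Y * h * L with 29 laborers on 100 acres at 0.29/acre
  crops <- list(c1 = crop_params("c1", -0.5, 0, 0, 0.29))
  unit2 <- farming_unit("u2", "c1", 0, list(plot_spec("p", 100, c(c1 = 10000))))
  plan2 <- plan_planting(unit2, crops, c(c1 = 2), economy_params(0))
  pb <- expected_profit(plan2, c(29), c(c1 = 2), unit2, crops, economy_params(0))
  expect_equal(pb$revenue, 2e6)
  expect_equal(pb$profit, 2e6)

  # empty plan earns and costs nothing
  empty <- cropshock:::new_planting_plan(c(0L), crops, unit2, 0, "free")
  expect_equal(expected_profit(empty, c(0), c(c1 = 2), unit2, crops,
                               economy_params(0))$profit, 0)
  # labor on an unplanted plot violates the plan invariants
  expect_error(expected_profit(empty, c(5), c(c1 = 2), unit2, crops,
                               economy_params(0)),
               class = "cropshock_invariant")
})

test_that("planting allocation matches expectation in degenerate and tie cases", {
  s <- mk_simple()
  # single profitable crop, free mode: plant it everywhere
  unit <- farming_unit("u", "tomato", 0, s$plots)
  p1 <- plan_planting(unit, s$crops["tomato"], s$prices["tomato"], s$economy,
                      mode = "free")
  expect_equal(p1$crop_for_plot, c(1L, 1L))

  # dominant crop wins both identical plots in free mode; certified by brute force
  unit2 <- farming_unit("u2", "strawberry", 0, s$plots)
  p2 <- plan_planting(unit2, s$crops, s$prices, s$economy, mode = "free")
  expect_equal(rownames(p2$x)[p2$crop_for_plot], c("strawberry", "strawberry"))
  expect_equal(p2$objective,
               oracle_best_planting(unit2, s$crops, s$prices, s$economy, "free"))

  # diversified on two identical plots: both assignments tie; the lower crop
  # index lands on the lower plot index
  div <- farming_unit("d", c("strawberry", "tomato"), 0, s$plots)
  p3 <- plan_planting(div, s$crops, s$prices, s$economy)
  expect_equal(p3$crop_for_plot, c(1L, 2L))
  swapped <- cropshock:::new_planting_plan(c(2L, 1L), s$crops, div, NA, "strategy_constrained")
  expect_equal(expected_profit(swapped, "full", s$prices, div, s$crops,
                               s$economy)$profit, p3$objective)

  # more strategy crops than plots is infeasible
  one_plot <- farming_unit("d2", c("strawberry", "tomato"), 0, s$plots[1])
  expect_error(plan_planting(one_plot, s$crops, s$prices, s$economy),
               class = "cropshock_infeasible_strategy")
})

test_that("harvest allocation follows marginal profit per laborer", {
  s <- mk_simple()
  unit <- farming_unit("u", "tomato", 0, s$plots)
  unit$planting_plan <- plan_planting(unit, s$crops, s$prices, s$economy)

  h0 <- plan_harvest(unit, s$prices, 0, s$crops, s$economy)
  expect_equal(h0$labor_used, 0)
  expect_equal(sum(h0$harvested_mass), 0)

  # tomato monocrop, 2 x 100 acres: 58 laborers suffice for a full harvest
  h1 <- plan_harvest(unit, s$prices, 200, s$crops, s$economy)
  expect_equal(h1$labor_used, 58)
  expect_equal(unname(h1$harvested_mass["tomato"]), 14500 * 200)

  # diversified split: raise the strawberry price so its marginal profit per
  # laborer dominates; budget = strawberry capacity + 10 spills 10 laborers
  # into the tomato plot (hand-solvable two-variable LP)
  div <- farming_unit("d", c("strawberry", "tomato"), 0, s$plots)
  prices <- c(strawberry = 6, tomato = 1)
  div$planting_plan <- plan_planting(div, s$crops, prices, s$economy)
  stopifnot(div$planting_plan$crop_for_plot[1] == 1L)
  h2 <- plan_harvest(div, prices, 95 + 10, s$crops, s$economy)
  expect_equal(h2$labor_by_plot, c(95, 10))
  mg <- harvest_margins(div, s$crops, prices, s$economy)
  expect_equal(h2$objective, oracle_best_harvest(mg$margins, mg$caps, 105),
               tolerance = 1e-10)

  expect_error(plan_harvest(div, prices, -1, s$crops, s$economy),
               class = "cropshock_invalid")
})

test_that("unprofitable plots receive no labor even with slack budget", {
  s <- mk_simple()
  unit <- farming_unit("u", "strawberry", 0, s$plots)
  # price so low that V*Y*h < C_L for strawberry
  low <- c(strawberry = 0.5, tomato = 1.0)
  unit$planting_plan <- plan_planting(unit, s$crops, low, s$economy)
  stopifnot(0.5 * 10000 / 0.95 < 8250)
  h <- plan_harvest(unit, low, 1000, s$crops, s$economy)
  expect_equal(h$labor_used, 0)
  expect_equal(sum(h$harvested_mass), 0)
})

test_that("harvest objective is monotone in the budget and saturates at capacity", {
  set.seed(21)
  for (rep in 1:20) {
    inst <- random_instance(2100 + rep)
    unit <- inst$unit
    unit$planting_plan <- plan_planting(unit, inst$crops, inst$prices,
                                        inst$economy, mode = "free")
    budgets <- sort(runif(5, 0, inst$budget + 50))
    objs <- vapply(budgets, function(b)
      plan_harvest(unit, inst$prices, b, inst$crops, inst$economy)$objective, 0)
    expect_true(all(diff(objs) >= -1e-9))
  }

  # all margins positive and budget beyond total capacity: exact full harvest
  s <- mk_simple()
  div <- farming_unit("d", c("strawberry", "tomato"), 0, s$plots)
  div$planting_plan <- plan_planting(div, s$crops, s$prices, s$economy)
  h <- plan_harvest(div, s$prices, 1e4, s$crops, s$economy)
  expect_identical(unname(h$harvested_mass["strawberry"]), 10000 * 100)
  expect_identical(unname(h$harvested_mass["tomato"]), 14500 * 100)
})

test_that("both optimizers agree with their oracles on random small instances", {
  for (rep in 1:80) {
    inst <- random_instance(4000 + rep)
    for (mode in c("free", "strategy_constrained")) {
      plan <- plan_planting(inst$unit, inst$crops, inst$prices, inst$economy,
                            mode = mode)
      best <- oracle_best_planting(inst$unit, inst$crops, inst$prices,
                                   inst$economy, mode)
      expect_equal(plan$objective, best,
                   tolerance = 1e-6 * max(1, abs(best)),
                   label = sprintf("planting objective (seed %d, %s)",
                                   4000 + rep, mode))
      unit <- inst$unit
      unit$planting_plan <- plan
      h <- plan_harvest(unit, inst$prices, inst$budget, inst$crops, inst$economy)
      mg <- harvest_margins(unit, inst$crops, inst$prices, inst$economy)
      lp <- oracle_best_harvest(mg$margins, mg$caps, inst$budget)
      expect_equal(h$objective, lp, tolerance = 1e-6 * max(1, abs(lp)),
                   label = sprintf("harvest objective (seed %d, %s)",
                                   4000 + rep, mode))
    }
  }
})
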