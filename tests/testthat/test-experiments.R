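# Sweep layer: composition, grids, robustness metrics, advantage analysis.

test_that("region composition splits monocropped units evenly", {
  cfg <- florida_fixture()
  counts <- function(region) table(vapply(region$units, `[[`, "", "strategy_label"))
  c2 <- counts(compose_region(cfg, 30, 2))
  expect_equal(unname(c2[c("diversified", "strawberry", "tomato")]),
               c(2L, 14L, 14L), ignore_attr = TRUE)
  c4 <- counts(compose_region(cfg, 30, 4))
  expect_equal(unname(c4[c("diversified", "strawberry", "tomato")]),
               c(4L, 13L, 13L), ignore_attr = TRUE)
  c28 <- counts(compose_region(cfg, 30, 28))
  expect_equal(unname(c28[c("diversified", "strawberry", "tomato")]),
               c(28L, 1L, 1L), ignore_attr = TRUE)
  expect_error(compose_region(cfg, 30, 3), class = "cropshock_composition")
  expect_error(compose_region(cfg, 30, 31), class = "cropshock_composition")
})

test_that("the sweep covers the full grid and is deterministic", {
  cfg <- florida_fixture()
  sc <- sweep_config(cfg, diversified_counts = c(2L, 10L),
                     intensity_grid = c(0.2, 0.6, 1.0), duration_grid = 1:2)
  sw <- run_sweep(sc)
  expect_equal(nrow(sw$table), 2 * 3 * 2)
  expect_true(all(c("funds_strawberry", "funds_tomato", "funds_diversified",
                    "div_gt_strawberry", "div_gt_both") %in% names(sw$table)))
  sw2 <- run_sweep(sc)
  expect_identical(sw$table, sw2$table)

  single <- run_sweep(sweep_config(cfg, diversified_counts = 2L,
                                   intensity_grid = 0.5, duration_grid = 3L))
  expect_equal(nrow(single$table), 1L)

  expect_error(sweep_config(cfg, diversified_counts = c(2L, 3L)),
               class = "cropshock_composition")
})

test_that("robustness summary equals independently recomputed strategy means", {
  cfg <- florida_fixture()
  sc <- sweep_config(cfg, diversified_counts = 28L, intensity_grid = 1.0,
                     duration_grid = 2L)
  sw <- run_sweep(sc)
  rs <- robustness_summary(sw)
  # with one strawberry and one tomato unit the group mean is that unit's funds;
  # recompute both from a fresh trajectory
  sim <- run_simulation(compose_region(cfg, 30, 28), shock_schedule(1, 2))
  fin <- sim$seasons[sim$seasons$season == sim$tau, ]
  expect_equal(rs[["strawberry"]], fin$funds[fin$strategy == "strawberry"])
  expect_equal(rs[["tomato"]], fin$funds[fin$strategy == "tomato"])
  expect_equal(rs[["diversified"]], mean(fin$funds[fin$strategy == "diversified"]))
  # identical units within a group: zero within-group variance
  expect_equal(stats::sd(fin$funds[fin$strategy == "diversified"]), 0)
  expect_error(robustness_summary(sw, intensity = 0.123),
               class = "cropshock_invalid")
})

test_that("advantage percentages and thresholds agree with a hand recomputation", {
  cfg <- florida_fixture()
  sc <- sweep_config(cfg, diversified_counts = c(2L, 6L),
                     intensity_grid = c(0.4, 0.6, 0.8), duration_grid = 1:4)
  sw <- run_sweep(sc)
  adv <- advantage_analysis(sw)
  tb <- sw$table
  for (r in seq_len(nrow(adv$cells))) {
    cell <- adv$cells[r, ]
    rows <- tb[tb$n_diversified == cell$n_diversified &
                 abs(tb$intensity - cell$intensity) < 1e-9, ]
    expect_equal(cell$pct_gt_strawberry,
                 100 * mean(rows$funds_diversified > rows$funds_strawberry))
    expect_equal(cell$pct_gt_both,
                 100 * mean(rows$funds_diversified > rows$funds_strawberry &
                              rows$funds_diversified > rows$funds_tomato))
  }
  # a cell with a full-duration advantage reports exactly 100%
  full_cells <- adv$cells[adv$cells$pct_gt_both == 100, ]
  expect_gt(nrow(full_cells), 0)
  # thresholds are the first intensity with a 100% cell, per composition
  for (nd in unique(adv$thresholds$n_diversified)) {
    g <- adv$cells[adv$cells$n_diversified == nd, ]
    g <- g[order(g$intensity), ]
    expected <- suppressWarnings(min(g$intensity[g$pct_gt_both == 100]))
    got <- adv$thresholds$first_i_gt_both[adv$thresholds$n_diversified == nd]
    if (is.finite(expected)) expect_equal(got, expected) else expect_true(is.na(got))
  }
})

test_that("mean funds by strategy can be sliced along every grid axis", {
  cfg <- florida_fixture()
  sc <- sweep_config(cfg, diversified_counts = c(2L, 6L),
                     intensity_grid = c(0.5, 1.0), duration_grid = 1:2)
  sw <- run_sweep(sc)
  whole <- robustness_summary(sw)
  part <- robustness_summary(sw, n_diversified = 2L, intensity = 0.5, duration = 1L)
  expect_named(part, c("strawberry", "tomato", "diversified", "region"))
  row <- sw$table[sw$table$n_diversified == 2 & sw$table$intensity == 0.5 &
                    sw$table$duration == 1, ]
  expect_equal(part[["diversified"]], row$funds_diversified)
  expect_true(all(is.finite(whole)))
})
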