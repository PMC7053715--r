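# Sweep experiment layer: region composition over strategy mixes, the
# (intensity, duration, n_diversified) grid, robustness metrics, advantage
# fractions and crossover intensities.

#' Compose a region from a template and a strategy mix
#'
#' Builds a region of `n_units` farming units that are identical except for
#' their cropping strategy: `n_diversified` diversified units and the
#' remainder split evenly between the template's two monocrops (the even
#' split balances the monocropped units' effects on the two market prices).
#' Crops are calibrated against the composed region (see [region_state()]).
#'
#' @param template a run configuration such as [florida_fixture()].
#' @param n_units total farming units (default 30).
#' @param n_diversified number of diversified units; the remainder must split
#'   evenly between the two monocrops.
#' @return a calibrated [region_state()].
#' @export
#' @examples
#' region <- compose_region(florida_fixture(), 30, 2)  # 2 div + 14 + 14
compose_region <- function(template, n_units = 30L, n_diversified) {
  stopifnot(inherits(template, "run_config"))
  if (!is_number(n_units) || n_units < 1)
    csk_stop("n_units must be >= 1", "cropshock_invalid")
  if (!is_number(n_diversified) || n_diversified < 0 || n_diversified >= n_units)
    csk_stop("n_diversified must lie in [0, n_units)", "cropshock_composition")
  mono <- template$mono_crops
  n_mono <- n_units - n_diversified
  if (length(mono) && n_mono %% length(mono) != 0)
    csk_stop(sprintf(
      "%d monocropped units cannot be split evenly across %d crops",
      n_mono, length(mono)), "cropshock_composition")
  per_mono <- n_mono / length(mono)

  mk_plots <- function() {
    lapply(seq_along(template$plot_acres), function(j)
      plot_spec(paste0("p", j), template$plot_acres[j], template$yields_per_acre))
  }
  units <- vector("list", n_units)
  k <- 0L
  for (d in seq_len(n_diversified)) {
    k <- k + 1L
    units[[k]] <- farming_unit(sprintf("div%02d", d), template$diversified_crops,
                               template$initial_funds, mk_plots())
  }
  for (ci in seq_along(mono)) {
    for (d in seq_len(per_mono)) {
      k <- k + 1L
      units[[k]] <- farming_unit(sprintf("%s%02d", mono[ci], d), mono[ci],
                                 template$initial_funds, mk_plots())
    }
  }
  region_state(units, template$crops, template$economy, mode = template$mode)
}

#' Sweep configuration
#'
#' The replication experiment design: for every regional strategy composition
#' and every (intensity, duration) pair, one deterministic simulation of
#' `duration + 1` seasons is run.
#'
#' @param template a run configuration ([florida_fixture()] or similar).
#' @param n_units total units per region (default 30).
#' @param diversified_counts numbers of diversified units to sweep (default
#'   2, 4, ..., 28).
#' @param intensity_grid shock intensities (default 0.1, 0.2, ..., 1.0; a
#'   zero-labor intensity can be added with `include_zero_intensity`).
#' @param duration_grid shock durations in seasons (default 1..10).
#' @param include_zero_intensity add `i = 0` to the intensity grid.
#' @return an object of class `sweep_config`.
#' @export
sweep_config <- function(template, n_units = 30L,
                         diversified_counts = seq(2L, 28L, by = 2L),
                         intensity_grid = seq(0.1, 1.0, by = 0.1),
                         duration_grid = 1:10,
                         include_zero_intensity = FALSE) {
  stopifnot(inherits(template, "run_config"))
  if (include_zero_intensity) intensity_grid <- c(0, intensity_grid)
  intensity_grid <- sort(unique(round(intensity_grid, 10)))
  if (any(intensity_grid < 0 | intensity_grid > 1))
    csk_stop("intensities must lie in [0, 1]", "cropshock_invalid")
  if (any(duration_grid < 1 | duration_grid != round(duration_grid)))
    csk_stop("durations must be integers >= 1", "cropshock_invalid")
  n_mono_crops <- length(template$mono_crops)
  for (nd in diversified_counts)
    if (nd >= n_units || (n_units - nd) %% n_mono_crops != 0)
      csk_stop(sprintf("diversified count %d incompatible with %d units", nd,
                       n_units), "cropshock_composition")
  structure(list(template = template, n_units = as.integer(n_units),
                 diversified_counts = as.integer(diversified_counts),
                 intensity_grid = intensity_grid,
                 duration_grid = as.integer(duration_grid)),
            class = "sweep_config")
}

#' Run the full shock sweep
#'
#' Runs one simulation per (n_diversified, intensity, duration) grid point
#' with `tau = duration + 1` and records the mean end-of-run funds per
#' strategy plus the diversification advantage flags. Deterministic: a rerun
#' yields a byte-identical table.
#'
#' @param config a [sweep_config()].
#' @param verbose print one progress line per composition.
#' @return an object of class `shock_sweep` whose `$table` has one row per
#'   grid point: `n_diversified`, `intensity`, `duration`, one
#'   `funds_<strategy>` column per strategy, regional mean funds, and logical
#'   advantage columns `div_gt_<crop>` / `div_gt_both`.
#' @export
run_sweep <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  mono <- config$template$mono_crops
  labels <- c(mono, "diversified")
  grid <- expand.grid(duration = config$duration_grid,
                      intensity = config$intensity_grid,
                      n_diversified = config$diversified_counts)
  grid <- grid[, c("n_diversified", "intensity", "duration")]
  rows <- vector("list", nrow(grid))
  for (nd in config$diversified_counts) {
    if (verbose)
      message(sprintf("composition: %d diversified of %d units", nd, config$n_units))
    region0 <- compose_region(config$template, config$n_units, nd)
    idx <- which(grid$n_diversified == nd)
    for (r in idx) {
      sched <- shock_schedule(grid$intensity[r], grid$duration[r])
      sim <- run_simulation(region0, sched)
      fin <- final_funds_by_strategy(sim)
      row <- as.list(grid[r, ])
      for (lb in labels) row[[paste0("funds_", lb)]] <- unname(fin[[lb]])
      row$funds_region <- mean(sim$seasons$funds[sim$seasons$season == sim$tau])
      for (mc in mono)
        row[[paste0("div_gt_", mc)]] <- fin[["diversified"]] > fin[[mc]]
      row$div_gt_both <- all(fin[["diversified"]] > fin[mono])
      rows[[r]] <- row
    }
  }
  table <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  rownames(table) <- NULL
  structure(list(table = table, config = config, strategy_labels = labels),
            class = "shock_sweep")
}

#' @export
print.shock_sweep <- function(x, ...) {
  cat(sprintf("<shock_sweep> %d runs: %d composition(s) x %d intensities x %d durations\n",
              nrow(x$table), length(x$config$diversified_counts),
              length(x$config$intensity_grid), length(x$config$duration_grid)))
  adv <- advantage_analysis(x)
  cat(sprintf("  diversified > strawberry-type mono above i = %.2g; > both monos above i = %.2g\n",
              adv$crossovers[["div_over_mono_high_labor"]],
              adv$crossovers[["div_over_both"]]))
  invisible(x)
}

#' @export
summary.shock_sweep <- function(object, ...) {
  adv <- advantage_analysis(object)
  structure(list(n_runs = nrow(object$table), adv = adv), class = "summary.shock_sweep")
}

#' @export
print.summary.shock_sweep <- function(x, ...) {
  cat(sprintf("Shock sweep over %d runs\n", x$n_runs))
  cat("Crossover intensities (advantage holds strictly above):\n")
  print(round(x$adv$crossovers, 3))
  cat("\nAdvantage fractions by composition and intensity (% of durations):\n")
  print(x$adv$cells, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Mean end-of-run funds by strategy over a slice of the sweep
#'
#' The robustness metric: strategies whose units retain greater average funds
#' after the shocks are the more robust ones. Arguments left `NULL` select
#' the full grid on that axis.
#'
#' @param sweep a `shock_sweep`.
#' @param n_diversified,intensity,duration optional grid values to filter on.
#' @return named vector of mean funds (USD) per strategy over the selected
#'   grid points, plus `region` for the all-unit mean.
#' @export
robustness_summary <- function(sweep, n_diversified = NULL, intensity = NULL,
                               duration = NULL) {
  stopifnot(inherits(sweep, "shock_sweep"))
  tb <- sweep$table
  keep <- rep(TRUE, nrow(tb))
  if (!is.null(n_diversified)) keep <- keep & tb$n_diversified %in% n_diversified
  if (!is.null(intensity))
    keep <- keep & vapply(tb$intensity, function(i) any(abs(i - intensity) < 1e-9), TRUE)
  if (!is.null(duration)) keep <- keep & tb$duration %in% duration
  tb <- tb[keep, ]
  if (!nrow(tb))
    csk_stop("slice selects no grid points", "cropshock_invalid")
  out <- vapply(sweep$strategy_labels,
                function(lb) mean(tb[[paste0("funds_", lb)]]), 0)
  c(out, region = mean(tb$funds_region))
}

#' Diversification advantage fractions and crossover intensities
#'
#' For every (n_diversified, intensity) cell, the percentage of shock
#' durations for which the diversified units' mean end funds exceed (a) each
#' monocrop's and (b) both monocrops'. Thresholds per composition give the
#' smallest grid intensity at which an advantage holds for every duration;
#' the aggregate crossovers report the largest grid intensity at which the
#' advantage does not yet hold everywhere (so the advantage holds strictly
#' above the crossover), computed from mean funds per intensity across the
#' whole sweep.
#'
#' The two monocrops are also labeled by labor intensity:
#' `mono_high_labor` is the crop with the larger per-acre labor requirement
#' (strawberry in the Florida case), `mono_low_labor` the other (tomato).
#'
#' @param sweep a `shock_sweep`.
#' @return a list: `cells` (per-cell advantage percentages), `thresholds`
#'   (per-composition first all-duration advantage intensity),
#'   `intensity_profile` (mean funds per strategy by intensity) and
#'   `crossovers` (named aggregate crossover intensities).
#' @export
advantage_analysis <- function(sweep) {
  stopifnot(inherits(sweep, "shock_sweep"))
  tb <- sweep$table
  mono <- setdiff(sweep$strategy_labels, "diversified")
  crops <- sweep$config$template$crops
  req <- vapply(mono, function(mc) crops[[mc]]$labor_requirement_per_acre, 0)
  hi <- mono[which.max(req)]; lo <- mono[which.min(req)]
  igrid <- sweep$config$intensity_grid
  step <- if (length(igrid) > 1) min(diff(igrid)) else igrid

  cells <- do.call(rbind, lapply(split(tb, list(tb$n_diversified, tb$intensity),
                                       drop = TRUE), function(g) {
    out <- data.frame(n_diversified = g$n_diversified[1], intensity = g$intensity[1])
    for (mc in mono)
      out[[paste0("pct_gt_", mc)]] <- 100 * mean(g[[paste0("div_gt_", mc)]])
    out$pct_gt_both <- 100 * mean(g$div_gt_both)
    out
  }))
  cells <- cells[order(cells$n_diversified, cells$intensity), ]
  rownames(cells) <- NULL

  first_full <- function(pct, is) {
    ok <- is[pct >= 100 - 1e-9]
    if (length(ok)) min(ok) else NA_real_
  }
  thresholds <- do.call(rbind, lapply(split(cells, cells$n_diversified),
                                      function(g) {
    g <- g[order(g$intensity), ]
    out <- data.frame(n_diversified = g$n_diversified[1])
    for (mc in mono)
      out[[paste0("first_i_gt_", mc)]] <- first_full(g[[paste0("pct_gt_", mc)]],
                                                     g$intensity)
    out$first_i_gt_both <- first_full(g$pct_gt_both, g$intensity)
    out
  }))
  rownames(thresholds) <- NULL

  # Fig-2 style aggregate: mean funds per strategy as a function of intensity,
  # averaged over durations and compositions
  prof <- stats::aggregate(tb[paste0("funds_", sweep$strategy_labels)],
                           by = list(intensity = tb$intensity), FUN = mean)
  div <- prof$funds_diversified
  # the largest intensity of the initial run of grid points where the
  # diversified mean does not lead: the advantage "begins above" this value
  crossover <- function(other) {
    lead <- div > other
    if (lead[1]) return(igrid[1] - step)            # leads from the bottom
    if (!any(lead)) return(NA_real_)                # never leads
    igrid[which(lead)[1] - 1L]
  }
  crossovers <- c(
    div_over_mono_high_labor = crossover(prof[[paste0("funds_", hi)]]),
    div_over_mono_low_labor = crossover(prof[[paste0("funds_", lo)]]),
    div_over_both = crossover(pmax(prof[[paste0("funds_", hi)]],
                                   prof[[paste0("funds_", lo)]])))
  names(crossovers) <- c("div_over_mono_high_labor", "div_over_mono_low_labor",
                         "div_over_both")
  list(cells = cells, thresholds = thresholds, intensity_profile = prof,
       crossovers = crossovers, mono_high_labor = hi, mono_low_labor = lo,
       grid_step = step)
}

#' @export
plot.shock_sweep <- function(x, which = c("profile", "advantage"), ...) {
  which <- match.arg(which)
  adv <- advantage_analysis(x)
  if (which == "profile") {
    prof <- adv$intensity_profile
    labs <- x$strategy_labels
    cols <- grDevices::hcl.colors(max(3L, length(labs)), "Dark 3")
    graphics::matplot(prof$intensity,
                      as.matrix(prof[paste0("funds_", labs)]) / 1e6,
                      type = "b", pch = 16, lty = 1, lwd = 2, col = cols,
                      xlab = "shock intensity i (fraction of baseline labor)",
                      ylab = "mean end funds (million USD)", ...)
    graphics::legend("topleft", legend = labs, col = cols, lwd = 2, bty = "n")
  } else {
    cells <- adv$cells
    graphics::symbols(cells$intensity, cells$n_diversified,
                      circles = sqrt(pmax(cells$pct_gt_both, 1)) / 40,
                      inches = FALSE, fg = "grey30",
                      bg = grDevices::gray(1 - cells$pct_gt_both / 120),
                      xlab = "shock intensity i",
                      ylab = "diversified units in region", ...)
  }
  invisible(x)
}
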