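#' Sweep the enrichment-threshold grid and assemble the metrics table
#'
#' For each screening threshold `t` in `grid`: estimate the subgroup survival
#' curve among patients with biomarker at or above the `t` quantile, convert
#' it into control- and treatment-arm event rates (at the trial duration for a
#' fixed design; Simpson's-rule average over the follow-up range for an
#' accrual design), derive the trial sample size from the required number of
#' events, and compute the number of patients screened and (optionally) total
#' cost and the cost reduction relative to the unenriched (`t = 0`) row.
#'
#' Standard errors: for a fixed-duration design with the KM estimator they
#' come from Greenwood's formula propagated by the delta method; for accrual
#' designs and for the NNE estimator they come from the nonparametric
#' bootstrap (`B` replicates per threshold; `B = 0` skips them, leaving `NA`).
#'
#' Time-dependent cost uses the expected time in trial before the endpoint:
#' the restricted mean observation time to the trial horizon, computed per arm
#' (control from the subgroup curve, treatment from the curve raised to the
#' power HR) and averaged with equal arm weights; for an accrual design this
#' per-arm average is evaluated at horizons `f`, `f + a/2`, `f + a` and
#' combined with Simpson weights, mirroring the event-rate treatment.
#'
#' @param dataset a [biomarker_survival_data()] object (floor: 20 subjects).
#' @param design a [fixed_design()] or [accrual_design()].
#' @param testing a [testing_spec()].
#' @param costs a [cost_spec()], or `NULL` to skip the cost columns.
#' @param grid increasing thresholds in \[0, 0.95\]; must include 0.
#' @param estimator `"km"` or `"nne"`; accrual designs support `"km"` only.
#' @param span NNE neighborhood width (default `0.25 * n^(-0.2)`).
#' @param B bootstrap replicates for bootstrap-based SEs (default 200;
#'   0 = skip).
#' @param seed integer seed for the bootstrap streams.
#' @param min_n minimum sample size accepted (default 20).
#' @return An `enrichment_table` object: element `table` is a data.frame with
#'   one row per threshold holding exact and display-rounded metrics; element
#'   `curves` keeps the subgroup curves for plotting; `metadata` records the
#'   estimator, span, `B`, seed and input provenance.
#' @examples
#' d <- simulate_dataset(simulation_spec(n = 400, anchor_p = 0.7, anchor_T = 48,
#'                                       biomarker_hr = 2, seed = 1))
#' tab <- analyze(d, fixed_design(36), testing_spec(treatment_hr = 0.8),
#'                grid = c(0, 0.25, 0.5), B = 0)
#' tab$table$sample_size
#' @export
analyze <- function(dataset, design, testing, costs = NULL,
                    grid = seq(0, 0.90, by = 0.05),
                    estimator = c("km", "nne"), span = NULL,
                    B = 200L, seed = 1L, min_n = 20L) {
  stopifnot(inherits(dataset, "biomarker_survival_data"),
            inherits(design, "trial_design"),
            inherits(testing, "testing_spec"))
  estimator <- match.arg(estimator)
  if (dataset$n < min_n)
    stop(sprintf("dataset has %d subjects; analysis floor is %d",
                 dataset$n, min_n), call. = FALSE)
  grid <- sort(unique(grid))
  if (any(grid < 0 | grid > 0.95))
    stop("thresholds must lie in [0, 0.95]", call. = FALSE)
  if (grid[1] != 0)
    stop("grid must include the unenriched threshold 0", call. = FALSE)
  if (design$kind == "accrual" && estimator == "nne")
    stop("accrual designs use Kaplan-Meier estimation only", call. = FALSE)
  if (is.null(span)) span <- 0.25 * dataset$n^(-0.2)
  n0 <- events_required(testing)
  hr <- testing$treatment_hr
  horizon <- if (design$kind == "fixed") design$duration
             else design$followup + design$accrual

  rows <- vector("list", length(grid))
  curves <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    t <- grid[i]
    curve <- tryCatch(
      subgroup_curve(dataset, t, method = estimator, span = span),
      error = function(e)
        stop(sprintf("threshold %.2f: %s", t, conditionMessage(e)),
             call. = FALSE))
    curves[[i]] <- curve

    if (design$kind == "fixed") {
      s <- survival_at(curve, design$duration)
      rates <- event_rates_fixed(s$surv, s$se, hr)
    } else {
      rates <- event_rates_accrual(curve, design$accrual, design$followup, hr)
    }

    # bootstrap-based SEs where the delta method is unavailable
    need_boot <- design$kind == "accrual" || estimator == "nne"
    if (need_boot && B > 0) {
      reps <- bootstrap_replicates(dataset, design, testing, t, B,
                                   seed = seed + i, estimator = estimator,
                                   span = span)
      rates$sd_p <- sd(reps$p_sum)
      rates$sd_p_control <- sd(reps$p_control)
    }

    size <- sample_size(n0, rates)

    cost <- rc <- etime <- NA_real_
    if (!is.null(costs)) {
      if (!is.null(costs$cost_per_time)) {
        etime <- expected_time_in_trial(curve, design, hr)
        cost <- total_cost(size$total_n, t, costs,
                           expected_time_in_trial = etime)
      } else {
        cost <- total_cost(size$total_n, t, costs)
      }
    }

    rows[[i]] <- data.frame(
      threshold = t,
      biomarker_cutoff = biomarker_cutoff(dataset, t),
      n_eligible = curve$n,
      event_rate_pct_exact = 100 * rates$p_control,
      event_rate_se = 100 * rates$sd_p_control,
      treatment_event_rate_pct_exact = 100 * rates$p_treatment,
      sample_size_exact = size$total_n,
      sample_size_se = size$sd_n,
      total_screened_exact = total_screened(size$total_n, t),
      expected_time_in_trial = etime,
      total_cost = cost,
      cost_reduction_pct = NA_real_)
  }
  df <- do.call(rbind, rows)
  if (!is.null(costs))
    df$cost_reduction_pct <- cost_reduction(df$total_cost, df$total_cost[1])
  # display-rounded companions (tables print whole percents / whole patients)
  df$event_rate_pct <- round_half_up(df$event_rate_pct_exact)
  df$sample_size <- round_half_up(df$sample_size_exact)
  df$total_screened <- round_half_up(df$total_screened_exact)

  structure(list(
    table = df, design = design, testing = testing, costs = costs,
    curves = curves,
    metadata = list(estimator = toupper(estimator), span = span, B = B,
                    seed = seed, n = dataset$n, grid = grid,
                    flipped = dataset$flipped)),
    class = "enrichment_table")
}

# E[time in trial before the endpoint]: per-arm restricted mean observation
# time averaged with equal arm weights; Simpson-combined over the accrual
# range for accrual designs (mirrors the event-rate treatment).
expected_time_in_trial <- function(curve, design, hr) {
  both_arms <- function(h) {
    (rmst_step(curve$times, curve$surv, h) +
       rmst_step(curve$times, curve$surv^hr, h)) / 2
  }
  if (design$kind == "fixed") return(both_arms(design$duration))
  hs <- design$followup + c(0, 0.5, 1) * design$accrual
  if (max(hs) > curve$tmax)
    stop(sprintf("follow-up horizon %g beyond observed follow-up (%g)",
                 max(hs), curve$tmax), call. = FALSE)
  sum(c(1, 4, 1) / 6 * vapply(hs, both_arms, numeric(1)))
}

#' @export
print.enrichment_table <- function(x, ...) {
  d <- x$design
  cat(sprintf("Enrichment analysis (%s estimator), n = %d, %s\n",
              x$metadata$estimator, x$metadata$n,
              if (d$kind == "fixed")
                sprintf("fixed duration %g", d$duration)
              else sprintf("accrual %g + follow-up %g", d$accrual, d$followup)))
  cat(sprintf("alpha = %g, power = %g, treatment HR = %g (N0 = %.1f events)\n",
              x$testing$alpha, x$testing$power, x$testing$treatment_hr,
              events_required(x$testing)))
  cols <- c("threshold", "event_rate_pct", "sample_size", "total_screened")
  if (!is.null(x$costs)) cols <- c(cols, "cost_reduction_pct")
  out <- x$table[, cols]
  if ("cost_reduction_pct" %in% names(out))
    out$cost_reduction_pct <- round(out$cost_reduction_pct)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Write analysis outputs to a directory
#'
#' Always writes `<prefix>.csv` (via [write_enrichment_table()]) and
#' `<prefix>_run.json` (a log of every parameter of the run). With
#' `make_figures = TRUE` also writes `<prefix>.png`: subgroup survival curves
#' for thresholds 0 / 0.25 / 0.50 / 0.75 (those present in the grid) with
#' vertical lines at the trial horizon(s), plus event-rate, sample-size,
#' total-screened and cost panels against the threshold with +/- 1 SE bands
#' where available.
#'
#' @param table an `enrichment_table` from [analyze()].
#' @param out_dir output directory (created if missing).
#' @param make_figures also write the summary figure.
#' @param prefix basename for the output files (default "results").
#' @return Invisibly, the paths written.
#' @export
render_outputs <- function(table, out_dir, make_figures = FALSE,
                           prefix = "results") {
  stopifnot(inherits(table, "enrichment_table"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  csv <- file.path(out_dir, paste0(prefix, ".csv"))
  write_enrichment_table(table, csv)
  runlog <- file.path(out_dir, paste0(prefix, "_run.json"))
  jsonlite::write_json(
    list(design = unclass(table$design),
         testing = unclass(table$testing),
         costs = if (is.null(table$costs)) NULL else unclass(table$costs),
         metadata = table$metadata),
    runlog, auto_unbox = TRUE, digits = NA, null = "null")
  paths <- c(csv, runlog)
  if (make_figures) {
    fig <- file.path(out_dir, paste0(prefix, ".png"))
    grDevices::png(fig, width = 1500, height = 1000, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_enrichment(table)
    paths <- c(paths, fig)
  }
  invisible(paths)
}

# Five-panel summary figure on the current device.
plot_enrichment <- function(x) {
  op <- par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(par(op), add = TRUE)
  d <- x$design
  vlines <- if (d$kind == "fixed") d$duration
            else c(d$followup, d$followup + d$accrual)
  show <- c(0, 0.25, 0.5, 0.75)
  idx <- which(x$metadata$grid %in% show)
  cols <- seq_along(idx)
  plot(NULL, xlim = c(0, max(vlines) * 1.05), ylim = c(0, 1),
       xlab = "Time", ylab = "Survival", main = "Subgroup survival")
  for (j in seq_along(idx)) {
    cv <- x$curves[[idx[j]]]
    lines(stats::stepfun(cv$times, c(1, cv$surv)), col = cols[j],
          do.points = FALSE)
  }
  abline(v = vlines, lty = 3, col = "grey40")
  legend("bottomleft", bty = "n", col = cols, lty = 1,
         legend = sprintf("%.0f%%", 100 * x$metadata$grid[idx]))

  df <- x$table
  panel <- function(y, se, ylab, main) {
    ylim <- range(c(y - ifelse(is.na(se), 0, se), y + ifelse(is.na(se), 0, se)),
                  na.rm = TRUE)
    plot(100 * df$threshold, y, type = "l", xlab = "Enrichment level (%)",
         ylab = ylab, main = main, ylim = ylim)
    if (any(!is.na(se)))
      polygon(c(100 * df$threshold, rev(100 * df$threshold)),
              c(y - se, rev(y + se)), border = NA,
              col = adjustcolor("steelblue", 0.3))
  }
  panel(df$event_rate_pct_exact, df$event_rate_se,
        "Event rate (%)", "Control-arm event rate")
  panel(df$sample_size_exact, df$sample_size_se,
        "Patients", "Trial sample size")
  panel(df$total_screened_exact, NA, "Patients", "Total screened")
  if (!is.null(x$costs)) {
    panel(df$total_cost, NA, "Cost", "Total trial cost")
  } else {
    graphics::plot.new()
  }
  invisible(x)
}
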