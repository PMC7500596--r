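# Curves are right-continuous step functions starting at (0, 1), defined on
# the observed event times, carried as plain vectors plus the maximum observed
# time (tmax) so strict evaluation can refuse extrapolation.
new_survival_curve <- function(times, surv, se, n_risk, n_event, method,
                               threshold, tmax, n) {
  structure(list(times = times, surv = surv, se = se, n_risk = n_risk,
                 n_event = n_event, method = method, threshold = threshold,
                 tmax = tmax, n = n),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("%s survival curve: %d subjects, %d event times, follow-up to %g",
              x$method, x$n, length(x$times), x$tmax),
      if (x$threshold > 0) sprintf(" (enrichment threshold %.2f)", x$threshold),
      "\n", sep = "")
  invisible(x)
}

#' Kaplan-Meier curve for the whole sample
#'
#' Product-limit estimate with Greenwood pointwise standard errors, computed
#' by [survival::survfit()].
#'
#' @param dataset a [biomarker_survival_data()] object.
#' @return A `survival_curve` object: event-time grid, survival estimates,
#'   Greenwood standard errors, numbers at risk.
#' @examples
#' d <- biomarker_survival_data(1:4, c(5, 8, 12, 20), c(1, 1, 0, 1))
#' kaplan_meier(d)$surv  # 0.75, 0.50, 0.00
#' @export
kaplan_meier <- function(dataset) {
  stopifnot(inherits(dataset, "biomarker_survival_data"))
  km_curve(dataset$data$time, dataset$data$event, threshold = 0)
}

# survfit-backed product-limit restricted to event times
km_curve <- function(time, event, threshold) {
  if (!length(time)) stop("empty dataset", call. = FALSE)
  if (all(time == 0))
    stop("degenerate data: all observation times are zero", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "none")
  keep <- fit$n.event > 0
  se <- fit$surv[keep] * fit$std.err[keep]   # Greenwood: std.err is on log scale
  se[fit$surv[keep] == 0] <- 0               # curve has hit zero: no variance
  new_survival_curve(
    times = fit$time[keep], surv = fit$surv[keep], se = se,
    n_risk = fit$n.risk[keep], n_event = fit$n.event[keep],
    method = "KM", threshold = threshold, tmax = max(time), n = length(time))
}

# Lean product-limit evaluation of S(at) used in bootstrap hot loops; agrees
# with survfit to machine precision (tested) but skips the variance pass.
km_surv_at <- function(time, event, at) {
  o <- order(time, method = "radix")
  time <- time[o]; event <- event[o]
  et <- time[event == 1]
  if (!length(et)) return(rep(1, length(at)))
  ut <- unique(et)
  d <- tabulate(match(et, ut))
  nrisk <- length(time) - findInterval(ut, time, left.open = TRUE)
  s <- cumprod(1 - d / nrisk)
  c(1, s)[findInterval(at, ut) + 1]
}

#' Biomarker cutoff for an enrichment threshold
#'
#' Nearest-rank (inverse empirical CDF) quantile: the smallest observed value
#' whose empirical CDF reaches `threshold`. Eligibility for the enriched trial
#' is `biomarker >= cutoff`, so ties at the cutoff are included.
#'
#' @param dataset a [biomarker_survival_data()] object.
#' @param threshold enrichment level in \[0, 1): the proportion of the
#'   population screened out.
#' @return The cutoff value on the working (oriented) biomarker scale.
#' @export
biomarker_cutoff <- function(dataset, threshold) {
  stopifnot(threshold >= 0, threshold < 1)
  quantile(dataset$data$biomarker, threshold, type = 1, names = FALSE)
}

#' Survival curve in a biomarker-enriched subgroup
#'
#' Estimates survival among patients with biomarker at or above the
#' `threshold` quantile, either by Kaplan-Meier applied to the subset
#' (`method = "km"`) or by a nearest-neighbor bivariate estimator
#' (`method = "nne"`) that smooths survival over biomarker-percentile
#' neighborhoods and tolerates censoring that depends on the marker.
#'
#' The NNE variant uses a boxcar kernel of total width `span` on the
#' percentile scale: each eligible subject contributes the product-limit
#' estimate computed in its symmetric percentile neighborhood (truncated at
#' the data boundary), and the subgroup curve is the average of these
#' conditional curves, i.e. an estimate of P(T > t | X >= cutoff). Standard
#' errors are not available in closed form for the NNE path (`se` is `NA`);
#' use the bootstrap.
#'
#' @inheritParams biomarker_cutoff
#' @param method `"km"` or `"nne"`.
#' @param span NNE neighborhood width on the percentile scale; default
#'   `0.25 * n^(-0.2)`.
#' @param min_subgroup minimum number of eligible subjects (default 10).
#' @return A `survival_curve` object.
#' @export
subgroup_curve <- function(dataset, threshold, method = c("km", "nne"),
                           span = NULL, min_subgroup = 10L) {
  stopifnot(inherits(dataset, "biomarker_survival_data"))
  method <- match.arg(method)
  cutoff <- biomarker_cutoff(dataset, threshold)
  eligible <- dataset$data$biomarker >= cutoff
  if (!any(eligible)) stop("threshold too high: empty subgroup", call. = FALSE)
  if (sum(eligible) < min_subgroup)
    stop(sprintf("threshold %.2f leaves only %d subjects (< %d)",
                 threshold, sum(eligible), min_subgroup), call. = FALSE)
  if (method == "km") {
    return(km_curve(dataset$data$time[eligible], dataset$data$event[eligible],
                    threshold = threshold))
  }
  nne_curve(dataset, threshold, cutoff,
            span = if (is.null(span)) 0.25 * dataset$n^(-0.2) else span)
}

nne_curve <- function(dataset, threshold, cutoff, span) {
  tm <- dataset$data$time
  ev <- dataset$data$event
  grid <- sort(unique(tm[ev == 1]))
  if (!length(grid)) grid <- max(tm)
  res <- nne_surv_at(dataset$data$biomarker, tm, ev, grid, cutoff, span)
  new_survival_curve(
    times = grid, surv = res$surv, se = rep(NA_real_, length(grid)),
    n_risk = rep(NA_real_, length(grid)), n_event = rep(NA_real_, length(grid)),
    method = "NNE", threshold = threshold, tmax = max(tm), n = res$n_eligible)
}

# Nearest-neighbor (boxcar kernel in biomarker percentile) estimate of
# P(T > at | X >= cutoff): average over eligible subjects of the
# product-limit estimate in their symmetric percentile window (half-width
# span/2, truncated at the boundary).
nne_surv_at <- function(x, tm, ev, at, cutoff, span) {
  stopifnot(span > 0)
  n <- length(x)
  o <- order(x)
  xs <- x[o]; ts <- tm[o]; es <- ev[o]
  h <- max(1L, floor(span * n / 2))
  eligible <- which(xs >= cutoff)
  acc <- numeric(length(at))
  for (j in eligible) {
    win <- max(1L, j - h):min(n, j + h)
    acc <- acc + km_surv_at(ts[win], es[win], at)
  }
  list(surv = acc / length(eligible), n_eligible = length(eligible))
}

#' Evaluate a survival curve at given times
#'
#' Right-continuous step-function evaluation. Beyond the last observed time,
#' strict mode errors; lenient mode carries the last value forward with a
#' warning.
#'
#' @param curve a `survival_curve`.
#' @param t non-negative time(s).
#' @param strict refuse extrapolation beyond the observed follow-up.
#' @return A list with vectors `surv` and `se` (same length as `t`);
#'   `surv(0) = 1` with `se = 0`.
#' @export
survival_at <- function(curve, t, strict = TRUE) {
  stopifnot(inherits(curve, "survival_curve"), all(t >= 0))
  if (any(t > curve$tmax)) {
    if (strict)
      stop(sprintf("time %g beyond observed follow-up (%g)",
                   max(t), curve$tmax), call. = FALSE)
    warning(sprintf("time beyond follow-up (%g); carrying last value forward",
                    curve$tmax), call. = FALSE)
  }
  idx <- findInterval(t, curve$times)
  list(surv = c(1, curve$surv)[idx + 1], se = c(0, curve$se)[idx + 1])
}

#' Restricted mean observation time
#'
#' Area under the survival step curve from 0 to `horizon`: the expected time
#' a patient is under observation before the endpoint (or the horizon),
#' the basis of time-dependent per-patient trial cost.
#'
#' @inheritParams survival_at
#' @param horizon upper limit of integration (>= 0).
#' @return A single time value.
#' @export
restricted_mean_observation <- function(curve, horizon, strict = TRUE) {
  stopifnot(inherits(curve, "survival_curve"), horizon >= 0)
  if (horizon == 0) return(0)
  if (horizon > curve$tmax && strict)
    stop(sprintf("horizon %g beyond observed follow-up (%g)",
                 horizon, curve$tmax), call. = FALSE)
  rmst_step(curve$times, curve$surv, horizon)
}

# area under right-continuous step function with S(0)=1 and steps at `times`
rmst_step <- function(times, surv, horizon) {
  keep <- times < horizon
  knots <- c(0, times[keep], horizon)
  vals <- c(1, surv[keep])
  sum(vals * diff(knots))
}
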