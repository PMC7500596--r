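#' Statistical testing specification
#'
#' @param alpha two-sided type I error rate in (0, 1).
#' @param power target power 1 - beta in (0, 1).
#' @param treatment_hr treatment hazard ratio the trial is powered to detect
#'   (must differ from 1).
#' @return A `testing_spec` object.
#' @export
testing_spec <- function(alpha = 0.05, power = 0.90, treatment_hr = 0.8) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1, treatment_hr > 0)
  if (treatment_hr == 1)
    stop("treatment_hr = 1: no effect to detect, design infeasible",
         call. = FALSE)
  structure(list(alpha = alpha, power = power, treatment_hr = treatment_hr),
            class = "testing_spec")
}

#' Trial design descriptors
#'
#' `fixed_design(duration)` describes a trial in which every participant is
#' observed for the same period. `accrual_design(accrual, followup)` describes
#' uniform enrollment over an accrual period `a` followed by a follow-up
#' period `f`, so observation spans `[f, f + a]`.
#'
#' @param duration,accrual,followup positive times (same unit as the data).
#' @return A `trial_design` object with `kind` "fixed" or "accrual".
#' @export
fixed_design <- function(duration) {
  stopifnot(duration > 0)
  structure(list(kind = "fixed", duration = duration), class = "trial_design")
}

#' @rdname fixed_design
#' @export
accrual_design <- function(accrual, followup) {
  stopifnot(accrual > 0, followup > 0)
  structure(list(kind = "accrual", accrual = accrual, followup = followup),
            class = "trial_design")
}

#' Cost specification
#'
#' Exactly one trial-cost mode is active: a constant cost per enrolled patient
#' (`trial_cost`), or a rate per unit of time the patient spends in the trial
#' before the primary endpoint (`cost_per_time`). `screening_cost` is paid for
#' every patient screened.
#'
#' @param screening_cost cost per screened patient (>= 0).
#' @param trial_cost constant cost per enrolled patient, or `NULL`.
#' @param cost_per_time cost per unit time in trial, or `NULL`.
#' @return A `cost_spec` object.
#' @export
cost_spec <- function(screening_cost, trial_cost = NULL, cost_per_time = NULL) {
  stopifnot(screening_cost >= 0)
  if (is.null(trial_cost) == is.null(cost_per_time))
    stop("specify exactly one of trial_cost or cost_per_time", call. = FALSE)
  if (!is.null(trial_cost)) stopifnot(trial_cost >= 0)
  if (!is.null(cost_per_time)) stopifnot(cost_per_time >= 0)
  structure(list(screening_cost = screening_cost, trial_cost = trial_cost,
                 cost_per_time = cost_per_time),
            class = "cost_spec")
}

#' Number of events required by the log-rank test
#'
#' `N0 = 4 (z[1-alpha/2] + z[1-beta])^2 / log(HR)^2`, the classic
#' required-events formula for a two-arm 1:1 trial. Kept unrounded; rounding
#' happens at the sample-size stage.
#'
#' @param spec a [testing_spec()].
#' @return Required number of events (positive real).
#' @examples
#' events_required(testing_spec(0.05, 0.90, 0.8))  # ~844.1
#' @export
events_required <- function(spec) {
  stopifnot(inherits(spec, "testing_spec"))
  z <- qnorm(1 - spec$alpha / 2) + qnorm(spec$power)
  4 * z^2 / log(spec$treatment_hr)^2
}

#' Arm-specific event rates for a fixed-duration trial
#'
#' Control-arm event rate `pC = 1 - S`, treatment-arm rate `pT = 1 - S^HR`
#' under proportional hazards, where `S` is estimated survival at the trial
#' length. The standard deviation of `p = pC + pT` comes from the delta
#' method: `SD(p) = (1 + HR * S^(HR-1)) * SD(S)`.
#'
#' @param s_hat estimated survival probability at the end of the trial,
#'   in (0, 1].
#' @param sd_s standard error of `s_hat` (may be `NA`).
#' @param treatment_hr treatment hazard ratio.
#' @return An `event_rate_estimate`: list with `p_control`, `p_treatment`,
#'   `p_sum`, `sd_p`, and `sd_p_control`.
#' @export
event_rates_fixed <- function(s_hat, sd_s = NA_real_, treatment_hr) {
  stopifnot(s_hat >= 0, s_hat <= 1, treatment_hr > 0)
  if (s_hat == 0 && treatment_hr < 1)
    warning("estimated survival is 0: delta-method SD unreliable", call. = FALSE)
  pc <- 1 - s_hat
  pt <- 1 - s_hat^treatment_hr
  sd_p <- (1 + treatment_hr * s_hat^(treatment_hr - 1)) * sd_s
  structure(list(p_control = pc, p_treatment = pt, p_sum = pc + pt,
                 sd_p = sd_p, sd_p_control = sd_s),
            class = "event_rate_estimate")
}

#' Arm-specific event rates for an accrual + follow-up design
#'
#' With uniform enrollment over the accrual period, the follow-up time is
#' uniform on `[f, f + a]`; the average event probability is approximated by
#' Simpson's rule over that interval:
#' `pC = 1 - (S(f) + 4 S(f + a/2) + S(f + a)) / 6`, and analogously for the
#' treatment arm with each survival probability raised to the power HR.
#' Uncertainty for this design is estimated by the bootstrap
#' ([bootstrap_se()]), not the delta method, so `sd_p` is `NA` here.
#'
#' @param curve a `survival_curve` extending to `f + a` (strict mode).
#' @param accrual,followup accrual period `a` and follow-up period `f`.
#' @param treatment_hr treatment hazard ratio.
#' @param strict refuse evaluation beyond observed follow-up.
#' @return An `event_rate_estimate` (see [event_rates_fixed()]).
#' @export
event_rates_accrual <- function(curve, accrual, followup, treatment_hr,
                                strict = TRUE) {
  stopifnot(accrual >= 0, followup > 0, treatment_hr > 0)
  at <- followup + c(0, 0.5, 1) * accrual
  s3 <- survival_at(curve, at, strict = strict)$surv
  w <- c(1, 4, 1) / 6
  pc <- 1 - sum(w * s3)
  pt <- 1 - sum(w * s3^treatment_hr)
  structure(list(p_control = pc, p_treatment = pt, p_sum = pc + pt,
                 sd_p = NA_real_, sd_p_control = NA_real_),
            class = "event_rate_estimate")
}

#' Trial sample size from required events and event rates
#'
#' With equal arms, `N/2 * (pC + pT) = N0`, so the total sample size is
#' `N = 2 N0 / (pC + pT)`. `N0` is treated as fixed; sampling variability
#' enters through `p = pC + pT`: `SD(N) = (2 N0 / p^2) * SD(p)`.
#'
#' @param n0 required events ([events_required()]), unrounded.
#' @param rates an `event_rate_estimate`.
#' @return A list with `total_n` (exact), `total_n_display` (rounded half away
#'   from zero), `required_events`, and `sd_n`.
#' @export
sample_size <- function(n0, rates) {
  stopifnot(inherits(rates, "event_rate_estimate"), n0 > 0)
  p <- rates$p_sum
  if (p <= 0)
    stop("zero event rate: required sample size is infinite", call. = FALSE)
  n <- 2 * n0 / p
  list(total_n = n, total_n_display = round_half_up(n),
       required_events = n0, sd_n = (2 * n0 / p^2) * rates$sd_p)
}

#' Total number of patients screened
#'
#' At enrichment threshold `t`, a fraction `1 - t` of screened patients is
#' eligible, so enrolling `N` requires screening `N / (1 - t)` on average.
#'
#' @param total_n trial sample size (exact value).
#' @param threshold enrichment threshold in \[0, 1).
#' @return Expected number screened (exact; display rounding is applied at
#'   the table-writing stage).
#' @export
total_screened <- function(total_n, threshold) {
  stopifnot(total_n >= 0)
  if (threshold < 0 || threshold >= 1)
    stop("threshold must be in [0, 1)", call. = FALSE)
  total_n / (1 - threshold)
}

#' Total trial cost
#'
#' Constant mode: `C1 * N + C2 * N / (1 - t)` with `C1` the per-patient trial
#' cost and `C2` the screening cost. Time mode: the per-patient cost is
#' `cost_per_time * E[time in trial before the endpoint]`, with the expected
#' time supplied from [restricted_mean_observation()] (see [analyze()] for
#' how it is averaged over arms and accrual).
#'
#' @param total_n trial sample size (exact).
#' @param threshold enrichment threshold in \[0, 1).
#' @param costs a [cost_spec()].
#' @param expected_time_in_trial required in time mode; ignored otherwise.
#' @return Total cost (currency units of the cost spec).
#' @export
total_cost <- function(total_n, threshold, costs, expected_time_in_trial = NULL) {
  stopifnot(inherits(costs, "cost_spec"))
  screened <- total_screened(total_n, threshold)
  if (!is.null(costs$trial_cost))
    return(costs$trial_cost * total_n + costs$screening_cost * screened)
  if (is.null(expected_time_in_trial))
    stop("time-dependent cost mode needs expected_time_in_trial", call. = FALSE)
  costs$cost_per_time * expected_time_in_trial * total_n +
    costs$screening_cost * screened
}

#' Percent reduction in total cost relative to an unenriched trial
#'
#' `100 * (1 - cost_enriched / cost_unenriched)`; negative values mean the
#' enriched trial is *more* expensive.
#'
#' @param cost_enriched,cost_unenriched total costs; `cost_unenriched > 0`.
#' @return Percent reduction.
#' @export
cost_reduction <- function(cost_enriched, cost_unenriched) {
  stopifnot(cost_unenriched > 0)
  100 * (1 - cost_enriched / cost_unenriched)
}

#' Bootstrap standard error of enrichment statistics
#'
#' Nonparametric bootstrap: subjects are resampled with replacement; the
#' enrichment cutoff, subgroup and survival curve are re-derived in every
#' replicate; the SE is the standard deviation of the statistic across
#' replicates. `statistic = "event_rate"` is the summed rate
#' `p = pC + pT`; `statistic = "sample_size"` is the total N.
#'
#' Replicates whose eligible subgroup is empty are skipped with a log message;
#' more than 10\% skipped is an error.
#'
#' @param dataset a [biomarker_survival_data()] object.
#' @param design a [fixed_design()] or [accrual_design()].
#' @param spec a [testing_spec()].
#' @param threshold enrichment threshold in \[0, 1).
#' @param statistic `"event_rate"` or `"sample_size"`.
#' @param B number of replicates (>= 50).
#' @param seed integer seed; same seed gives the same SE.
#' @param estimator subgroup survival estimator, `"km"` (default) or `"nne"`.
#' @param span NNE neighborhood width (see [subgroup_curve()]).
#' @return The bootstrap standard error (single number).
#' @export
bootstrap_se <- function(dataset, design, spec, threshold,
                         statistic = c("event_rate", "sample_size"),
                         B = 200L, seed = 1L, estimator = "km", span = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(B >= 50)
  reps <- bootstrap_replicates(dataset, design, spec, threshold, B, seed,
                               estimator = estimator, span = span)
  sd(if (statistic == "event_rate") reps$p_sum else reps$total_n)
}

# One pass of B resamples returning p_control, p_sum and total_n per
# replicate, re-deriving the cutoff and subgroup curve each time. The lean
# product-limit evaluator keeps the KM path fast.
bootstrap_replicates <- function(dataset, design, spec, threshold, B, seed,
                                 estimator = "km", span = NULL) {
  stopifnot(inherits(design, "trial_design"), inherits(spec, "testing_spec"))
  estimator <- match.arg(estimator, c("km", "nne"))
  n0 <- events_required(spec)
  hr <- spec$treatment_hr
  at <- if (design$kind == "fixed") design$duration
        else design$followup + c(0, 0.5, 1) * design$accrual
  w <- if (design$kind == "fixed") 1 else c(1, 4, 1) / 6
  x <- dataset$data$biomarker
  tm <- dataset$data$time
  ev <- dataset$data$event
  n <- dataset$n
  if (is.null(span)) span <- 0.25 * n^(-0.2)
  set.seed(seed)
  pc <- psum <- nn <- rep(NA_real_, B)
  skipped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    xb <- x[idx]
    cut <- quantile(xb, threshold, type = 1, names = FALSE)
    keep <- xb >= cut
    if (!any(keep)) { skipped <- skipped + 1L; next }
    s <- if (estimator == "km") km_surv_at(tm[idx][keep], ev[idx][keep], at)
         else nne_surv_at(xb, tm[idx], ev[idx], at, cut, span)$surv
    p_c <- 1 - sum(w * s)
    p_t <- 1 - sum(w * s^hr)
    pc[b] <- p_c
    psum[b] <- p_c + p_t
    nn[b] <- if (p_c + p_t > 0) 2 * n0 / (p_c + p_t) else NA_real_
  }
  if (skipped > 0) {
    message(sprintf("bootstrap: skipped %d/%d replicates with empty subgroup",
                    skipped, B))
    if (skipped > 0.1 * B)
      stop("more than 10% of bootstrap replicates had an empty subgroup",
           call. = FALSE)
  }
  ok <- !is.na(psum)
  list(p_control = pc[ok], p_sum = psum[ok], total_n = nn[ok])
}
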