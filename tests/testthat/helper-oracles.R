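# Independent oracles and small fixture builders shared across test files.

# Brute-force product-limit estimator with Greenwood variance, written
# term-by-term with explicit loops; deliberately independent of the package's
# survfit-backed path and of its lean evaluator.
brute_force_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  gw <- 0   # running Greenwood sum d / (r (r - d))
  surv <- se <- numeric(length(ut))
  for (j in seq_along(ut)) {
    r <- 0; d <- 0
    for (i in seq_along(time)) {
      if (time[i] >= ut[j]) r <- r + 1
      if (time[i] == ut[j] && event[i] == 1) d <- d + 1
    }
    s <- s * (1 - d / r)
    if (r > d) gw <- gw + d / (r * (r - d)) else gw <- Inf
    surv[j] <- s
    se[j] <- if (is.finite(gw)) s * sqrt(gw) else 0  # S=0: SE defined as 0
  }
  list(times = ut, surv = surv, se = se)
}

# dataset wrapper for hand-specified small examples
tiny_data <- function(time, event, biomarker = seq_along(time)) {
  biomarker_survival_data(biomarker, time, event)
}

# study-condition simulation used across tests (simulated cohort of the
# strongly prognostic marker example)
sim_example2 <- function(seed, n = 5000) {
  simulate_dataset(simulation_spec(
    n = n, shape_k = 1, anchor_p = 0.82, anchor_T = 48,
    biomarker_hr = 2.8, biomarker_dist = "normal", seed = seed))
}
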