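# n distinct substream seeds derived from one master seed, so patient i's
# trajectory is reproducible independently of simulation order
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Simulate a cohort of independent patients
#'
#' Each patient consumes a deterministic substream derived from `seed`, so
#' the cohort is reproducible and order-independent.
#'
#' @param n Number of patients.
#' @param strategy `"EMPIRICAL"` or `"TEST_BASED"`.
#' @param params A `tdm_params` parameter set (one per simulation run).
#' @param horizon Follow-up in weeks.
#' @param seed Integer master seed for the cohort.
#' @return List of `n` `tdm_trajectory` objects.
#' @export
simulate_cohort <- function(n, strategy, params, horizon, seed) {
  pseeds <- derive_seeds(seed, n)
  lapply(seq_len(n), function(i) {
    set.seed(pseeds[i])
    simulate_patient(strategy, params, horizon)
  })
}

count_tests <- function(traj, horizon, tests_counted_as) {
  k <- sum(traj$tests$week < horizon)
  if (identical(tests_counted_as, "assays")) 2L * k else k
}

summarize_trajectories <- function(trajectories, costs, horizon,
                                   include_tests = TRUE,
                                   tests_counted_as = "events",
                                   strategy = NULL) {
  totals <- vapply(trajectories, function(tr)
    trajectory_cost(tr, costs, include_tests = include_tests,
                    horizon = horizon)$total_cents, numeric(1))
  exit_weeks <- vapply(trajectories, `[[`, integer(1), "exit_week")
  failed <- vapply(trajectories, `[[`, logical(1), "surgery_eligible") &
    exit_weeks < horizon
  structure(list(
    strategy = strategy %||% trajectories[[1]]$strategy,
    n = length(trajectories),
    horizon_weeks = horizon,
    total_cost = sum(totals) / 100,
    mean_cost = mean(totals) / 100,
    sd_cost = stats::sd(totals) / 100,
    n_tests = sum(vapply(trajectories, count_tests, integer(1),
                         horizon = horizon, tests_counted_as = tests_counted_as)),
    n_surgery_eligible = sum(failed),
    mean_weeks_to_failure = if (any(failed)) mean(exit_weeks[failed]) else NA_real_
  ), class = "tdm_cohort_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one cohort and summarize it
#'
#' Simulates `n` independent patients under one strategy and aggregates the
#' base-mode costs (drug plus test; no surgery).
#'
#' @inheritParams simulate_cohort
#' @param costs A `tdm_costs` table.
#' @param include_tests Bill EUR 100 per test event (default `TRUE`; the
#'   empirical arm performs no tests either way).
#' @param tests_counted_as `"events"` (default) or `"assays"` (trough and
#'   antibody assays counted separately, two per test event) — affects the
#'   reported test count only, never the billed amount.
#' @param keep_trajectories Attach the simulated trajectories to the result.
#' @return Object of class `tdm_cohort_summary`: totals, per-patient mean
#'   and SD (euros), test count, surgery-eligible count and mean weeks to
#'   failure among failures.
#' @examples
#' cfg <- build_default_config()
#' set.seed(7)
#' p <- draw_parameter_set(cfg)
#' run_cohort(200, "EMPIRICAL", 260, p, build_cost_table(cfg), seed = 7)
#' @export
run_cohort <- function(n, strategy, horizon, params, costs, seed,
                       include_tests = TRUE, tests_counted_as = "events",
                       keep_trajectories = FALSE) {
  stopifnot(n >= 1)
  trajs <- simulate_cohort(n, strategy, params, horizon, seed)
  s <- summarize_trajectories(trajs, costs, horizon, include_tests,
                              tests_counted_as, strategy = strategy)
  if (keep_trajectories) s$trajectories <- trajs
  s
}

#' @export
print.tdm_cohort_summary <- function(x, ...) {
  cat(sprintf("%s cohort: %d patients, %d weeks\n", x$strategy, x$n, x$horizon_weeks))
  cat(sprintf("  total EUR %.0f | mean EUR %.0f/patient | SD EUR %.0f\n",
              x$total_cost, x$mean_cost, x$sd_cost))
  cat(sprintf("  tests: %d | surgery-eligible: %d | mean weeks to failure: %s\n",
              x$n_tests, x$n_surgery_eligible,
              if (is.na(x$mean_weeks_to_failure)) "-" else
                sprintf("%.0f", x$mean_weeks_to_failure)))
  invisible(x)
}

#' Compare the two strategies on a paired parameter draw
#'
#' Draws one concrete parameter set from the configuration, simulates both
#' arms to the longest requested horizon with independent patient streams,
#' and reports per-horizon totals, means, savings and the saving as a
#' percentage of the empirical-arm total. Trajectories are truncated (not
#' re-simulated) at the shorter horizons, so each patient's 1-year costs
#' are a prefix of their 5-year costs.
#'
#' With `include_surgery = TRUE`, the surgery extension (EUR 12,000 per
#' surgery-eligible exit plus post-operative IFX for a random quarter of
#' them until the end of follow-up) is added to both arms at the longest
#' horizon.
#'
#' @param config A `tdm_config`.
#' @param n Patients per arm.
#' @param horizons Horizons in weeks (subset of 52/156/260 in the standard
#'   analysis).
#' @param seed Integer master seed (parameter draw, both arms and the
#'   surgery draws all derive from it).
#' @param include_surgery Add the surgery/post-operative extension at the
#'   longest horizon.
#' @return Object of class `tdm_savings`: the per-arm summaries by horizon,
#'   a `savings` data.frame, the drawn parameter set, and (if requested) a
#'   `surgery` component with surgery-inclusive totals.
#' @export
compare_strategies <- function(config, n = 10000, horizons = c(52L, 156L, 260L),
                               seed = 1, include_surgery = FALSE) {
  stopifnot(n >= 1, length(horizons) >= 1)
  horizons <- sort(as.integer(horizons))
  hmax <- max(horizons)
  costs <- build_cost_table(config)

  seeds <- derive_seeds(seed, 5L)
  set.seed(seeds[1])
  params <- draw_parameter_set(config)
  trajs_e <- simulate_cohort(n, "EMPIRICAL", params, hmax, seeds[2])
  trajs_t <- simulate_cohort(n, "TEST_BASED", params, hmax, seeds[3])

  emp <- list(); tst <- list()
  rows <- vector("list", length(horizons))
  for (i in seq_along(horizons)) {
    h <- horizons[i]
    e <- summarize_trajectories(trajs_e, costs, h,
                                tests_counted_as = config$tests_counted_as,
                                strategy = "EMPIRICAL")
    t <- summarize_trajectories(trajs_t, costs, h,
                                tests_counted_as = config$tests_counted_as,
                                strategy = "TEST_BASED")
    emp[[as.character(h)]] <- e
    tst[[as.character(h)]] <- t
    rows[[i]] <- data.frame(
      horizon_weeks = h,
      empirical_total = e$total_cost, test_total = t$total_cost,
      saving_total = e$total_cost - t$total_cost,
      saving_mean = e$mean_cost - t$mean_cost,
      saving_pct = 100 * (e$total_cost - t$total_cost) / e$total_cost)
  }

  out <- structure(list(
    n = n, horizons_weeks = horizons, params = params,
    empirical = emp, test_based = tst,
    savings = do.call(rbind, rows)
  ), class = "tdm_savings")

  if (include_surgery) {
    set.seed(seeds[4])
    delta_e <- vapply(trajs_e, function(tr)
      surgery_extension(tr, costs)$total_cents, numeric(1))
    set.seed(seeds[5])
    delta_t <- vapply(trajs_t, function(tr)
      surgery_extension(tr, costs)$total_cents, numeric(1))
    e_full <- emp[[as.character(hmax)]]; t_full <- tst[[as.character(hmax)]]
    out$surgery <- list(
      horizon_weeks = hmax,
      empirical_total = e_full$total_cost + sum(delta_e) / 100,
      test_total = t_full$total_cost + sum(delta_t) / 100,
      saving_total = (e_full$total_cost + sum(delta_e) / 100) -
        (t_full$total_cost + sum(delta_t) / 100),
      n_surgery = c(empirical = e_full$n_surgery_eligible,
                    test_based = t_full$n_surgery_eligible))
  }
  out
}

#' @export
print.tdm_savings <- function(x, ...) {
  cat(sprintf("Strategy comparison, %d patients per arm\n", x$n))
  df <- x$savings
  df[-1] <- round(df[-1])
  print(df, row.names = FALSE)
  if (!is.null(x$surgery)) {
    cat(sprintf(
      "with surgery at %d weeks: saving EUR %.0f (surgeries %d vs %d)\n",
      x$surgery$horizon_weeks, x$surgery$saving_total,
      x$surgery$n_surgery["empirical"], x$surgery$n_surgery["test_based"]))
  }
  invisible(x)
}

#' Sensitivity analysis over uniform parameter draws
#'
#' Repeats the paired two-arm experiment with a fresh uniform parameter
#' draw per simulation (the published design: 30 simulations of 10,000
#' patients over 5 years) and tabulates per-simulation mean costs, the
#' saving and the number of tests.
#'
#' @param config A `tdm_config`.
#' @param n_sims Number of simulations (>= 2).
#' @param n_patients Patients per arm per simulation.
#' @param horizon Follow-up in weeks.
#' @param seed Integer master seed.
#' @return data.frame with one row per simulation: `sim`,
#'   `mean_cost_without_test`, `mean_cost_with_test`, `cost_saving` (euros
#'   per patient) and `n_tests`.
#' @export
sensitivity_analysis <- function(config, n_sims = 30, n_patients = 10000,
                                 horizon = 260, seed = 1) {
  stopifnot(n_sims >= 2)
  costs <- build_cost_table(config)
  sim_seeds <- derive_seeds(seed, 3L * n_sims)
  rows <- vector("list", n_sims)
  for (j in seq_len(n_sims)) {
    set.seed(sim_seeds[3 * j - 2])
    params <- draw_parameter_set(config)
    e <- run_cohort(n_patients, "EMPIRICAL", horizon, params, costs,
                    seed = sim_seeds[3 * j - 1],
                    tests_counted_as = config$tests_counted_as)
    t <- run_cohort(n_patients, "TEST_BASED", horizon, params, costs,
                    seed = sim_seeds[3 * j],
                    tests_counted_as = config$tests_counted_as)
    rows[[j]] <- data.frame(
      sim = j,
      mean_cost_without_test = e$mean_cost,
      mean_cost_with_test = t$mean_cost,
      cost_saving = e$mean_cost - t$mean_cost,
      n_tests = t$n_tests)
  }
  do.call(rbind, rows)
}

#' Bootstrap of simulation-level means
#'
#' Resamples a vector of simulation-level values (e.g. the 30 per-simulation
#' mean cost savings) with replacement and reports the sample mean, the
#' bootstrap standard deviation and the percentile 95% confidence interval.
#'
#' @param values Non-empty numeric vector (euros).
#' @param n_boot Number of bootstrap replicates (published analysis: 3,000).
#' @param seed Optional integer seed for the resampling.
#' @return Object of class `tdm_bootstrap`: `point_mean`, `sd`, `ci95`
#'   (named `low`/`high`), `n_boot`, `n_values`.
#' @examples
#' bootstrap_summary(c(12619, 13284, 13188), n_boot = 500, seed = 1)
#' @export
bootstrap_summary <- function(values, n_boot = 3000, seed = NULL) {
  stopifnot(length(values) >= 1, is.numeric(values))
  if (!is.null(seed)) set.seed(seed)
  if (length(values) == 1) {
    return(structure(list(point_mean = values, sd = 0,
                          ci95 = c(low = values, high = values),
                          n_boot = n_boot, n_values = 1L),
                     class = "tdm_bootstrap"))
  }
  reps <- vapply(seq_len(n_boot), function(b)
    mean(sample(values, replace = TRUE)), numeric(1))
  ci <- unname(stats::quantile(reps, c(0.025, 0.975), names = FALSE))
  structure(list(point_mean = mean(values), sd = stats::sd(reps),
                 ci95 = c(low = ci[1], high = ci[2]),
                 n_boot = n_boot, n_values = length(values)),
            class = "tdm_bootstrap")
}

#' @export
print.tdm_bootstrap <- function(x, ...) {
  cat(sprintf(
    "Bootstrap of %d values (%d replicates): mean EUR %.2f, SD %.2f, 95%% CI [%.2f, %.2f]\n",
    x$n_values, x$n_boot, x$point_mean, x$sd, x$ci95["low"], x$ci95["high"]))
  invisible(x)
}
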