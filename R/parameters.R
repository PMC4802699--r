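#' Regimen identifiers
#'
#' The eight treatment regimens of the model, in empirical escalation order.
#' `POSTOP_IFX_Q8` is only used by the surgery extension.
#'
#' @format Character vector of regimen ids.
#' @export
REGIMEN_IDS <- c(
  "IFX5_Q8", "IFX10_Q8", "IFX10_Q6", "IFX10_Q6_IS",
  "ADA_INDUCTION", "ADA_Q2", "ADA_Q1", "POSTOP_IFX_Q8"
)

# cycle length in weeks for each regimen (the consultation grid)
REGIMEN_CYCLE_WEEKS <- c(
  IFX5_Q8 = 8L, IFX10_Q8 = 8L, IFX10_Q6 = 6L, IFX10_Q6_IS = 6L,
  ADA_INDUCTION = 4L, ADA_Q2 = 2L, ADA_Q1 = 1L, POSTOP_IFX_Q8 = 8L
)

#' Probability range
#'
#' A closed interval `[min, max]` of probabilities, the form in which the
#' model's per-consultation event probabilities are published.
#'
#' @param min,max Probabilities with `0 <= min <= max <= 1`.
#' @return A named numeric vector of class `prob_range`.
#' @examples
#' prob_range(0.019, 0.023)
#' @export
prob_range <- function(min, max) {
  stopifnot(is.numeric(min), is.numeric(max), length(min) == 1, length(max) == 1)
  structure(c(min = min, max = max), class = "prob_range")
}

range_ok <- function(r) {
  is.numeric(r) && length(r) == 2 &&
    !anyNA(r) && r[1] >= 0 && r[1] <= r[2] && r[2] <= 1
}

regimen_spec <- function(id, cycle_weeks, cost_cents, lor_range, ae_range,
                         response_range = NULL) {
  list(id = id, cycle_weeks = as.integer(cycle_weeks),
       cost_cents = as.numeric(cost_cents),
       lor_range = lor_range, ae_range = ae_range,
       response_range = response_range)
}

test_outcome_spec <- function(label, probability, decision, routed_regimen,
                              efficacy_horizon_weeks, efficacy_retention) {
  list(label = label, probability = probability, decision = decision,
       routed_regimen = routed_regimen,
       efficacy_horizon_weeks = efficacy_horizon_weeks,
       efficacy_retention = efficacy_retention)
}

#' Default model configuration
#'
#' Builds the complete model configuration from the published inputs:
#' per-consultation loss-of-response (LOR) and serious-adverse-event (AE)
#' probability ranges for every regimen, complementary response-after-
#' optimization ranges, per-cycle reimbursement tariffs, the three-outcome
#' specification of each drug-monitoring test (probability, routing decision
#' and treatment-retention efficacy), and the unit costs (test EUR 100,
#' IFX vial EUR 492.81, infusion EUR 361.75, surgery EUR 12,000, 25%
#' post-operative IFX).
#'
#' All monetary amounts are stored as integer euro-cents so cohort totals
#' are exactly additive.
#'
#' @return A validated configuration object of class `tdm_config`.
#' @examples
#' cfg <- build_default_config()
#' cfg$regimens$IFX5_Q8$lor_range
#' @export
build_default_config <- function() {
  regimens <- list(
    IFX5_Q8 = regimen_spec("IFX5_Q8", 8, 184018,
      prob_range(0.019, 0.023), prob_range(0.026, 0.032)),
    IFX10_Q8 = regimen_spec("IFX10_Q8", 8, 331861,
      prob_range(0.098, 0.104), prob_range(0.026, 0.032),
      prob_range(0.896, 0.902)),
    IFX10_Q6 = regimen_spec("IFX10_Q6", 6, 331861,
      prob_range(0.075, 0.079), prob_range(0.021, 0.023),
      prob_range(0.921, 0.925)),
    IFX10_Q6_IS = regimen_spec("IFX10_Q6_IS", 6, 334842,
      prob_range(0.075, 0.079), prob_range(0.019, 0.024),
      prob_range(0.921, 0.925)),
    ADA_INDUCTION = regimen_spec("ADA_INDUCTION", 4, 188420,
      prob_range(0, 0), prob_range(0, 0)),
    ADA_Q2 = regimen_spec("ADA_Q2", 2, 30672,
      prob_range(0.007697, 0.008689), prob_range(0.006729, 0.007603),
      prob_range(0.9913, 0.9923)),
    # the published table carries no weekly-ADA AE row; following the table's
    # own per-consultation rescaling (its ADA LOR rows halve from q2w to q1w),
    # the maintenance AE range is halved for the weekly interval
    ADA_Q1 = regimen_spec("ADA_Q1", 1, 30672,
      prob_range(0.003832, 0.004354), prob_range(0.0033645, 0.0038015),
      prob_range(0.9956, 0.9961)),
    POSTOP_IFX_Q8 = regimen_spec("POSTOP_IFX_Q8", 8, 184018,
      prob_range(0, 0), prob_range(0, 0))
  )

  ifx_test <- list(
    HIGH_TROUGH = test_outcome_spec(
      "HIGH_TROUGH", 0.50, "switch_class", NA_character_,
      integer(0), numeric(0)),
    LOW_TROUGH_NO_AB = test_outcome_spec(
      "LOW_TROUGH_NO_AB", 0.29, "optimize_same_drug", "IFX10_Q8",
      52L, 0.80),
    LOW_TROUGH_WITH_AB = test_outcome_spec(
      "LOW_TROUGH_WITH_AB", 0.21, "switch_other_anti_tnf", "ADA_Q2",
      52L, 0.75)
  )
  ada_test <- list(
    HIGH_TROUGH = test_outcome_spec(
      "HIGH_TROUGH", 0.43, "switch_class", NA_character_,
      integer(0), numeric(0)),
    LOW_TROUGH_NO_AB = test_outcome_spec(
      "LOW_TROUGH_NO_AB", 0.24, "optimize_same_drug", "ADA_Q1",
      c(26L, 52L), c(0.67, 0.57)),
    LOW_TROUGH_WITH_AB = test_outcome_spec(
      "LOW_TROUGH_WITH_AB", 0.33, "switch_other_anti_tnf", "IFX5_Q8",
      c(26L, 52L), c(0.80, 0.57))
  )

  costs <- list(
    test_cents = 10000,
    surgery_cents = 1200000,
    postop_fraction = 0.25,
    ifx_vial_cents = 49281,
    infusion_cents = 36175,
    ada_40mg_cents = 41705  # informational; billing uses the per-cycle tariff
  )

  cfg <- structure(list(
    regimens = regimens,
    ifx_test = ifx_test,
    ada_test = ada_test,
    costs = costs,
    horizons_weeks = c(52L, 156L, 260L),
    cohort_sizes = c(3000L, 10000L),
    tests_counted_as = "events"  # or "assays": trough + antibody counted separately
  ), class = "tdm_config")

  v <- validate_config(cfg)
  if (length(v) > 0) stop("default configuration invalid: ", paste(v, collapse = "; "))
  cfg
}

#' Validate a model configuration
#'
#' Checks every structural invariant of the configuration and returns the
#' violations found (an empty character vector for a valid configuration).
#' Nothing is thrown: callers decide whether violations are fatal.
#'
#' Checked rules: probability ranges lie in `[0, 1]` with `min <= max`;
#' cycle lengths are among the model's time units; costs are non-negative;
#' the three outcome probabilities of each test sum to 1; test efficacies
#' are retention probabilities in `(0, 1]`, non-increasing over strictly
#' increasing horizons; the LOR range and the response-after-optimization
#' range of each optimized regimen are complementary (sum to 1 within
#' 0.005, the rounding of the published tables).
#'
#' @param config A `tdm_config` object.
#' @return Character vector of human-readable violations; `character(0)` if valid.
#' @export
validate_config <- function(config) {
  bad <- character(0)
  say <- function(...) bad <<- c(bad, sprintf(...))

  if (!is.list(config$regimens) || length(config$regimens) == 0) {
    return("config has no regimens")
  }
  for (rg in config$regimens) {
    id <- rg$id
    if (!rg$cycle_weeks %in% c(1L, 2L, 4L, 6L, 8L))
      say("%s: cycle_weeks %s not in {1,2,4,6,8}", id, rg$cycle_weeks)
    if (!is.numeric(rg$cost_cents) || rg$cost_cents < 0)
      say("%s: cost_per_cycle negative", id)
    if (!range_ok(rg$lor_range)) say("%s: lor_range min > max or outside [0,1]", id)
    if (!range_ok(rg$ae_range)) say("%s: ae_range min > max or outside [0,1]", id)
    if (!is.null(rg$response_range)) {
      if (!range_ok(rg$response_range)) {
        say("%s: response_range min > max or outside [0,1]", id)
      } else if (range_ok(rg$lor_range)) {
        # complementarity of published LOR and response-after-optimization ranges
        if (abs(rg$lor_range[["min"]] + rg$response_range[["max"]] - 1) > 0.005 ||
            abs(rg$lor_range[["max"]] + rg$response_range[["min"]] - 1) > 0.005)
          say("%s: lor_range and response_range not complementary (sum != 1 +/- 0.005)", id)
      }
    }
  }

  for (side in c("ifx_test", "ada_test")) {
    test <- config[[side]]
    if (length(test) != 3) { say("%s: expected 3 outcomes", side); next }
    p <- vapply(test, function(o) o$probability, numeric(1))
    if (any(p < 0 | p > 1)) say("%s: outcome probability outside [0,1]", side)
    if (abs(sum(p) - 1) > 1e-9) say("%s: test probabilities sum != 1", side)
    for (o in test) {
      eh <- o$efficacy_horizon_weeks; er <- o$efficacy_retention
      if (length(eh) != length(er))
        say("%s/%s: efficacy horizons and retentions differ in length", side, o$label)
      if (length(er) > 0) {
        if (any(er <= 0 | er > 1)) say("%s/%s: retention outside (0,1]", side, o$label)
        if (length(eh) > 1 && any(diff(eh) <= 0))
          say("%s/%s: efficacy horizons not strictly increasing", side, o$label)
        if (length(er) > 1 && any(diff(er) > 0))
          say("%s/%s: retention increases across horizons", side, o$label)
      }
      if (o$decision != "switch_class" &&
          (is.na(o$routed_regimen) || !o$routed_regimen %in% names(config$regimens)))
        say("%s/%s: routed regimen unknown", side, o$label)
    }
  }

  cc <- config$costs
  for (f in c("test_cents", "surgery_cents", "ifx_vial_cents", "infusion_cents"))
    if (!is.numeric(cc[[f]]) || cc[[f]] < 0) say("costs$%s: negative or missing", f)
  if (!is.numeric(cc$postop_fraction) || cc$postop_fraction < 0 || cc$postop_fraction > 1)
    say("costs$postop_fraction: outside [0,1]")
  if (!identical(config$tests_counted_as, "events") &&
      !identical(config$tests_counted_as, "assays"))
    say("tests_counted_as: must be 'events' or 'assays'")
  bad
}

#' Convert a retention probability at a horizon into a per-cycle event probability
#'
#' The published test-arm efficacies are treatment-retention probabilities at
#' a stated horizon (e.g. 80% still responding at 1 year). The simulation
#' needs the complementary constant per-cycle event probability `p` such that
#' surviving `n_cycles` consecutive cycles reproduces the retention:
#' `(1 - p)^n_cycles = retention`, i.e. `p = 1 - retention^(1/n_cycles)`.
#'
#' @param retention Retention (survival-without-event) probability in `(0, 1]`.
#' @param n_cycles Number of treatment cycles in the horizon (positive,
#'   possibly fractional, e.g. 6.5 eight-week cycles per year).
#' @return Per-cycle event probability in `[0, 1)`.
#' @examples
#' retention_to_cycle_loss(0.80, 6.5)   # q8w regimen, 80% retention at 1 year
#' @export
retention_to_cycle_loss <- function(retention, n_cycles) {
  stopifnot(length(retention) == 1, length(n_cycles) == 1)
  if (!is.finite(retention) || retention <= 0 || retention > 1)
    stop("retention must lie in (0, 1] (zero retention implies infinite hazard)")
  if (!is.finite(n_cycles) || n_cycles <= 0) stop("n_cycles must be positive")
  1 - retention^(1 / n_cycles)
}

#' Piecewise per-cycle event probabilities from two-horizon efficacies
#'
#' Some published efficacies give retention at 6 months and at 1 year (e.g.
#' 67% and 57%). The event hazard is then piecewise constant: one per-cycle
#' probability for the first period and one for the second, chosen so the
#' survival through both periods equals the 1-year retention exactly.
#'
#' @param eff_first Retention at the end of the first period, in `(0, 1]`.
#' @param eff_second Retention at the end of the second period;
#'   `eff_second <= eff_first` (retention cannot increase).
#' @param cycles_per_period Number of cycles in each (equal-length) period.
#' @return Numeric vector `c(first, second)` of per-cycle event probabilities.
#' @examples
#' piecewise_cycle_loss(0.67, 0.57, 26)   # weekly ADA, 26 cycles per half-year
#' @export
piecewise_cycle_loss <- function(eff_first, eff_second, cycles_per_period) {
  if (!is.finite(eff_second) || eff_second <= 0)
    stop("eff_second must be positive")
  if (eff_second > eff_first)
    stop("eff_second > eff_first: retention cannot increase over time")
  c(retention_to_cycle_loss(eff_first, cycles_per_period),
    retention_to_cycle_loss(eff_second / eff_first, cycles_per_period))
}

# per-cycle event probabilities for a routed (test-resolved) course:
# constant hazard for one-point efficacies, piecewise for two-point ones.
routed_hazard <- function(outcome, cycle_weeks) {
  er <- outcome$efficacy_retention
  eh <- outcome$efficacy_horizon_weeks
  if (length(er) == 0) return(NULL)
  if (length(er) == 1) {
    h <- retention_to_cycle_loss(er, eh / cycle_weeks)
    list(kind = "constant", p = h)
  } else {
    period <- eh[2] - eh[1]  # equal-length periods by construction
    h <- piecewise_cycle_loss(er[1], er[2], period / cycle_weeks)
    list(kind = "piecewise", p = h, break_week = eh[1])
  }
}

#' Draw a concrete parameter set for one simulation run
#'
#' Every per-consultation LOR and AE probability is drawn uniformly and
#' independently from its published `[min, max]` range (the sensitivity
#' design: one fresh parameter set per simulation, shared by all patients
#' of that simulation). Test-outcome probabilities are published as point
#' values and carried over as-is; per-cycle hazards for the test-routed
#' branches are derived from the efficacy retentions at this point.
#'
#' Uses R's global random number stream: call `set.seed()` beforehand for
#' reproducible draws.
#'
#' @param config A valid `tdm_config`.
#' @return Object of class `tdm_params`: named vectors `lor` and `ae`
#'   (one concrete probability per regimen), `cycle_weeks`, `cost_cents`,
#'   test outcome probability vectors, and derived routing hazards.
#' @export
draw_parameter_set <- function(config) {
  v <- validate_config(config)
  if (length(v) > 0) stop("invalid config: ", paste(v, collapse = "; "))
  ids <- names(config$regimens)
  draw1 <- function(r) runif(1, r[["min"]], r[["max"]])
  lor <- vapply(config$regimens, function(rg) draw1(rg$lor_range), numeric(1))
  ae <- vapply(config$regimens, function(rg) draw1(rg$ae_range), numeric(1))
  names(lor) <- names(ae) <- ids

  hz <- function(side) {
    out <- list()
    for (o in config[[side]]) {
      if (o$decision == "switch_class") { out[[o$label]] <- NULL; next }
      cw <- config$regimens[[o$routed_regimen]]$cycle_weeks
      out[[o$label]] <- routed_hazard(o, cw)
      out[[o$label]]$routed_regimen <- o$routed_regimen
    }
    out
  }

  structure(list(
    lor = lor,
    ae = ae,
    cycle_weeks = vapply(config$regimens, `[[`, integer(1), "cycle_weeks"),
    cost_cents = vapply(config$regimens, `[[`, numeric(1), "cost_cents"),
    ifx_test_probs = vapply(config$ifx_test, `[[`, numeric(1), "probability"),
    ada_test_probs = vapply(config$ada_test, `[[`, numeric(1), "probability"),
    ifx_test_routes = hz("ifx_test"),
    ada_test_routes = hz("ada_test"),
    test_cents = config$costs$test_cents
  ), class = "tdm_params")
}

#' @export
print.tdm_config <- function(x, ...) {
  cat("Anti-TNF cost model configuration\n")
  cat(sprintf("  %d regimens; horizons %s weeks; cohort sizes %s\n",
              length(x$regimens),
              paste(x$horizons_weeks, collapse = "/"),
              paste(x$cohort_sizes, collapse = "/")))
  for (rg in x$regimens) {
    cat(sprintf("  %-14s q%dw  EUR %9.2f/cycle  LOR [%.6g, %.6g]  AE [%.6g, %.6g]\n",
                rg$id, rg$cycle_weeks, rg$cost_cents / 100,
                rg$lor_range[["min"]], rg$lor_range[["max"]],
                rg$ae_range[["min"]], rg$ae_range[["max"]]))
  }
  cat(sprintf("  test EUR %.2f | surgery EUR %.2f | post-op fraction %.2f\n",
              x$costs$test_cents / 100, x$costs$surgery_cents / 100,
              x$costs$postop_fraction))
  invisible(x)
}

#' @export
print.tdm_params <- function(x, ...) {
  cat("Concrete parameter set (one simulation run)\n")
  df <- data.frame(regimen = names(x$lor),
                   lor = round(unname(x$lor), 6),
                   ae = round(unname(x$ae), 6))
  print(df, row.names = FALSE)
  invisible(x)
}
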