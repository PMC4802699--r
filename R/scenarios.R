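# Degenerate parameter scenarios with closed-form expected costs. The
# expected-cost arithmetic below never calls the simulation engine: it
# enumerates consultation weeks directly from the tariff table, so
# agreement between the two is evidence, not tautology.

set_regimen_probs <- function(config, regimen, lor, ae) {
  config$regimens[[regimen]]$lor_range <- prob_range(lor, lor)
  config$regimens[[regimen]]$ae_range <- prob_range(ae, ae)
  # a forced probability breaks the published complementarity; drop the
  # response range rather than fabricate one
  config$regimens[[regimen]]$response_range <- NULL
  config
}

zero_all_probs <- function(config) {
  for (id in names(config$regimens)) config <- set_regimen_probs(config, id, 0, 0)
  config
}

new_scenario <- function(name, config, expected_cost, description) {
  v <- validate_config(config)
  if (length(v) > 0) stop("scenario config invalid: ", paste(v, collapse = "; "))
  structure(list(name = name, config = config, expected_cost = expected_cost,
                 description = description), class = "tdm_scenario")
}

#' @export
print.tdm_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': %s\n", x$name, x$description))
  invisible(x)
}

#' Scenario: no events ever occur
#'
#' All LOR and AE probabilities are zero, so every patient stays on IFX
#' 5 mg/kg q8w until the horizon in both arms. The expected per-patient
#' cost has the closed form `ceiling(H / 8) * 1840.18` euros (consultations
#' at weeks 0, 8, ... strictly before `H`).
#'
#' @return A `tdm_scenario` with fields `config` (a valid degenerate
#'   `tdm_config`) and `expected_cost`, a function of the horizon in weeks
#'   returning euros.
#' @examples
#' no_event_scenario()$expected_cost(52)   # 12881.26
#' @export
no_event_scenario <- function() {
  cfg <- zero_all_probs(build_default_config())
  cyc <- cfg$regimens$IFX5_Q8$cost_cents
  new_scenario(
    "no_event", cfg,
    expected_cost = function(horizon_weeks)
      ceiling(horizon_weeks / 8) * cyc / 100,
    description = "all event probabilities zero; patients stay on IFX5_Q8 q8w")
}

# is (from -> to) an edge of the empirical transition graph, and via which event?
edge_event <- function(from, to) {
  lor_to <- tryCatch(empirical_successor(from, "LOR"), error = function(e) NA)
  if (identical(lor_to, to)) return("LOR")
  ae_to <- tryCatch(empirical_successor(from, "AE"), error = function(e) NA)
  if (identical(ae_to, to)) return("AE")
  NA_character_
}

#' Scenario: a forced path through the empirical escalation chain
#'
#' Sets the event probabilities so the patient deterministically walks the
#' given chain: each non-terminal regimen gets probability 1 on the event
#' leading to its successor (LOR where the successor is the LOR successor,
#' AE where only the AE edge reaches it), and the final regimen gets
#' probability 0 on everything (the patient stays on it to the horizon).
#' A terminal `"FAILURE"` element instead forces an exit from the last
#' regimen.
#'
#' Under the billing convention of the engine, a triggering consultation
#' delivers (and bills) the successor's first dose, so each forced regimen
#' contributes exactly one cycle tariff (the induction block its flat
#' amount) and the final regimen bills every consultation up to the horizon.
#' `expected_cost` enumerates this arithmetic directly from the tariffs.
#'
#' @param path Character vector of regimen ids forming a chain starting at
#'   `"IFX5_Q8"`; `ADA_INDUCTION` is followed by `ADA_Q2` automatically if
#'   the next element is `ADA_Q2`; an optional final `"FAILURE"` forces the
#'   exit.
#' @return A `tdm_scenario` (see [no_event_scenario()]).
#' @examples
#' sc <- forced_path_scenario(c("IFX5_Q8", "IFX10_Q8"))
#' sc$expected_cost(260)
#' @export
forced_path_scenario <- function(path = c("IFX5_Q8", "IFX10_Q8", "IFX10_Q6",
                                          "IFX10_Q6_IS", "ADA_INDUCTION",
                                          "ADA_Q2", "ADA_Q1", "FAILURE")) {
  if (path[1] != "IFX5_Q8") stop("path must start at IFX5_Q8")
  cfg <- zero_all_probs(build_default_config())
  regs <- path[path != "FAILURE"]
  ends_in_failure <- path[length(path)] == "FAILURE"

  for (i in seq_along(regs)) {
    from <- regs[i]
    if (from == "ADA_INDUCTION") {
      if (i < length(regs) && regs[i + 1] != "ADA_Q2")
        stop("ADA_INDUCTION must be followed by ADA_Q2")
      next
    }
    to <- if (i < length(regs)) regs[i + 1]
          else if (ends_in_failure) "FAILURE" else NA
    if (is.na(to)) next  # terminal regimen: probabilities stay zero
    ev <- if (identical(to, "FAILURE")) {
      if (!identical(empirical_successor(from, "LOR"), "FAILURE") &&
          !identical(empirical_successor(from, "AE"), "FAILURE"))
        stop("'", from, "' cannot fail directly")
      if (identical(empirical_successor(from, "LOR"), "FAILURE")) "LOR" else "AE"
    } else edge_event(from, to)
    if (is.na(ev))
      stop("'", from, "' -> '", to, "' is not an edge of the escalation chain")
    cfg <- if (ev == "LOR") set_regimen_probs(cfg, from, 1, 0)
           else set_regimen_probs(cfg, from, 0, 1)
  }

  cyc_cents <- vapply(cfg$regimens, `[[`, numeric(1), "cost_cents")
  cyc_weeks <- vapply(cfg$regimens, `[[`, integer(1), "cycle_weeks")

  expected_cost <- function(horizon_weeks) {
    H <- horizon_weeks
    t <- 0; cents <- 0
    for (i in seq_along(regs)) {
      reg <- regs[i]
      if (t >= H) break
      if (reg == "ADA_INDUCTION") {
        cents <- cents + cyc_cents[[reg]]   # flat, billed once
        t <- t + 4
        next
      }
      L <- cyc_weeks[[reg]]
      terminal <- (i == length(regs)) && !ends_in_failure
      if (terminal) {
        # stays on this regimen: consultations at t, t+L, ... < H
        cents <- cents + ceiling((H - t) / L) * cyc_cents[[reg]]
        t <- H
      } else {
        # first dose at t; the event at t+L (if before H) hands over to the
        # successor, whose dose that consultation bills
        cents <- cents + cyc_cents[[reg]]
        if (t + L >= H) { t <- H; break }
        t <- t + L
      }
    }
    cents / 100
  }

  new_scenario(paste0("forced_", paste(path, collapse = ">")), cfg, expected_cost,
               paste("deterministic walk:", paste(path, collapse = " -> ")))
}

#' Exact expected cost of a single regimen under a geometric event time
#'
#' Independent verification oracle for one cyclic regimen: consultations at
#' weeks `0, L, 2L, ...` strictly before the horizon; the first is always
#' delivered; consultation `j` (j >= 2) is delivered only if none of the
#' `j - 1` preceding event draws fired, each with probability `p_event`
#' (the triggering consultation itself delivers the successor's dose and
#' bills nothing here). The expectation is the finite sum
#' `c * (1 + sum_{j=2}^{K} (1 - p)^(j-1))` with `K = ceiling(H / L)`.
#'
#' @param p_event Per-consultation event probability in `[0, 1]`.
#' @param cycle_cost_cents Per-cycle tariff in euro-cents.
#' @param cycle_len Cycle length in weeks.
#' @param horizon Horizon in weeks.
#' @return Expected cost in euros.
#' @examples
#' geometric_oracle(0, 184018, 8, 260)   # 33 certain consultations
#' geometric_oracle(1, 184018, 8, 260)   # exactly one cycle before transition
#' @export
geometric_oracle <- function(p_event, cycle_cost_cents, cycle_len, horizon) {
  stopifnot(p_event >= 0, p_event <= 1)
  K <- ceiling(horizon / cycle_len)
  if (K < 1) return(0)
  surv <- (1 - p_event)^(seq_len(K) - 1)   # P(consultation j delivered), j = 1..K
  sum(surv) * cycle_cost_cents / 100
}

#' Look up a named scenario preset
#'
#' @param name `"no_event"`, `"forced_full_chain"` (the complete empirical
#'   escalation chain ending in failure), or `"default"` (the published
#'   configuration, no closed form).
#' @return A `tdm_scenario`.
#' @export
scenario_preset <- function(name) {
  switch(name,
    no_event = no_event_scenario(),
    forced_full_chain = forced_path_scenario(),
    default = new_scenario("default", build_default_config(),
                           expected_cost = function(h) NA_real_,
                           description = "published model inputs"),
    stop("unknown scenario '", name, "'"))
}
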