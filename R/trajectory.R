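#' Successor regimen under empirical dose escalation
#'
#' Encodes the escalation chain of the empirical arm. A loss of response
#' (LOR) intensifies treatment one step along
#' `IFX5_Q8 -> IFX10_Q8 -> IFX10_Q6 -> IFX10_Q6_IS -> ADA_INDUCTION ->
#' (ADA_Q2) -> ADA_Q1 -> FAILURE`; a serious adverse event (AE) on any IFX
#' regimen switches the patient to ADA induction, and an AE on ADA exhausts
#' the anti-TNF class (`FAILURE`).
#'
#' @param current A regimen id (see [REGIMEN_IDS]); must be a regimen on
#'   which events can occur (not the induction block or post-operative IFX).
#' @param event `"LOR"` or `"AE"`.
#' @return The successor regimen id, or `"FAILURE"` when no anti-TNF option
#'   remains.
#' @examples
#' empirical_successor("IFX5_Q8", "LOR")
#' empirical_successor("ADA_Q1", "LOR")
#' @export
empirical_successor <- function(current, event) {
  event <- match.arg(event, c("LOR", "AE"))
  lor_chain <- c(IFX5_Q8 = "IFX10_Q8", IFX10_Q8 = "IFX10_Q6",
                 IFX10_Q6 = "IFX10_Q6_IS", IFX10_Q6_IS = "ADA_INDUCTION",
                 ADA_Q2 = "ADA_Q1", ADA_Q1 = "FAILURE")
  ifx <- c("IFX5_Q8", "IFX10_Q8", "IFX10_Q6", "IFX10_Q6_IS")
  ada <- c("ADA_Q2", "ADA_Q1")
  if (!current %in% c(ifx, ada))
    stop("no successor defined for regimen '", current, "'")
  if (event == "LOR") unname(lor_chain[current])
  else if (current %in% ifx) "ADA_INDUCTION" else "FAILURE"
}

#' Sample the event at one consultation
#'
#' At each scheduled administration after the first of a course, the model
#' draws a serious adverse event first (probability `ae_p`) and, only if
#' none occurred, a loss of response (probability `lor_p`); the two never
#' co-occur. Consequently `P(AE) = ae_p`, `P(LOR) = (1 - ae_p) * lor_p` and
#' `P(CONTINUE) = (1 - ae_p) * (1 - lor_p)`.
#'
#' @param lor_p,ae_p Per-consultation probabilities in `[0, 1]`.
#' @param n Number of independent draws.
#' @return Character vector of `"AE"`, `"LOR"`, `"CONTINUE"`.
#' @export
consultation_step <- function(lor_p, ae_p, n = 1) {
  stopifnot(lor_p >= 0, lor_p <= 1, ae_p >= 0, ae_p <= 1)
  u <- runif(n)
  out <- rep("CONTINUE", n)
  out[u < ae_p + (1 - ae_p) * lor_p] <- "LOR"
  out[u < ae_p] <- "AE"
  out
}

# sample one of the three test outcomes from a named probability vector
sample_test_outcome <- function(probs) {
  u <- runif(1)
  cum <- cumsum(probs)
  names(probs)[which(u < cum)[1]]
}

#' Resolve the drug-monitoring test at the first loss of response on IFX
#'
#' Samples one of the three published outcomes of the IFX trough/antibody
#' test and returns the routing it implies: a high trough level exits the
#' anti-TNF class; a low trough without antibodies routes to IFX dose
#' optimization (with the hazard derived from the published 80% 1-year
#' retention); a low trough with antibodies routes to ADA (75% 1-year
#' retention). The simulation engine invokes this at most once per patient.
#'
#' @param params A `tdm_params` parameter set.
#' @return List with `outcome` (label), `decision`, and for routed outcomes
#'   the `routed_regimen` and its `hazard` description.
#' @export
resolve_ifx_test <- function(params) {
  outcome <- sample_test_outcome(params$ifx_test_probs)
  route <- params$ifx_test_routes[[outcome]]
  list(outcome = outcome,
       decision = if (is.null(route)) "switch_class" else "route",
       routed_regimen = route$routed_regimen,
       hazard = route)
}

#' Resolve the drug-monitoring test at the first loss of response on ADA
#'
#' As [resolve_ifx_test()], for the ADA trough/antibody test: a high trough
#' exits the class; a low trough without antibodies routes to weekly ADA
#' (piecewise hazard from the 67%/57% retentions at 6 months/1 year); a low
#' trough with antibodies routes back to standard-dose IFX (80%/57%).
#' Events on the routed regimen end the anti-TNF sequence (no third test).
#'
#' @inheritParams resolve_ifx_test
#' @return As [resolve_ifx_test()].
#' @export
resolve_ada_test <- function(params) {
  outcome <- sample_test_outcome(params$ada_test_probs)
  route <- params$ada_test_routes[[outcome]]
  list(outcome = outcome,
       decision = if (is.null(route)) "switch_class" else "route",
       routed_regimen = route$routed_regimen,
       hazard = route)
}

# course "modes" drive both the event probabilities and the routing:
#   empirical  - Table-driven LOR/AE, empirical_successor routing
#   pre_ifx    - test arm, IFX before the first test: LOR -> IFX test, AE -> ADA
#   pre_ada    - test arm, ADA maintenance before the ADA test:
#                LOR -> ADA test, AE -> failure
#   ifx_opt    - test-routed IFX optimization: LOR -> ADA induction (no 2nd IFX test)
#   ada_sw     - test-routed switch to ADA: LOR -> ADA test
#   post2_opt  - after the ADA test, optimized weekly ADA: any event -> failure
#   post2_sw   - after the ADA test, back on IFX: any event -> failure

course_probs <- function(mode, regimen, params) {
  if (mode %in% c("empirical", "pre_ifx", "pre_ada")) {
    list(kind = "constant", lor = unname(params$lor[regimen]),
         ae = unname(params$ae[regimen]))
  } else {
    hz <- switch(mode,
      ifx_opt = params$ifx_test_routes$LOW_TROUGH_NO_AB,
      ada_sw = params$ifx_test_routes$LOW_TROUGH_WITH_AB,
      post2_opt = params$ada_test_routes$LOW_TROUGH_NO_AB,
      post2_sw = params$ada_test_routes$LOW_TROUGH_WITH_AB)
    # efficacy-derived hazards absorb all discontinuation; no separate AE channel
    if (hz$kind == "constant")
      list(kind = "constant", lor = hz$p, ae = 0)
    else
      list(kind = "piecewise", lor = hz$p, break_week = hz$break_week, ae = 0)
  }
}

#' Simulate one patient trajectory
#'
#' Runs a single Crohn's disease patient through the chosen strategy on the
#' weekly consultation grid. The patient starts at week 0 on IFX 5 mg/kg
#' q8w as a responder. Consultations occur at the start of each course and
#' every cycle thereafter while before `min(exit, horizon)`; the first
#' consultation of a course delivers the dose without an event draw (a
#' treatment cannot fail before being received), later consultations draw
#' AE-then-LOR. A triggering consultation delivers the first dose of the
#' successor regimen at that same week, so the trigger is recorded (and
#' billed) under the successor course. The ADA induction block (160/80 mg)
#' is a single 4-week course billed once, with no event draws.
#'
#' In the empirical arm events route along [empirical_successor()]. In the
#' test-based arm the first LOR on IFX triggers the IFX trough/antibody
#' test, the first LOR on ADA maintenance triggers the ADA test, AEs on IFX
#' route to ADA induction, and AEs on ADA or any event after the second
#' test's routing end the anti-TNF sequence. Exits with both anti-TNFs
#' failed are flagged surgery-eligible; exits from the anti-TNF class after
#' a high-trough test result are not.
#'
#' Uses R's global random number stream.
#'
#' @param strategy `"EMPIRICAL"` or `"TEST_BASED"`.
#' @param params A `tdm_params` parameter set from [draw_parameter_set()].
#' @param horizon Follow-up horizon in weeks (standard analyses use 52, 156
#'   or 260).
#' @return Object of class `tdm_trajectory`: course table (regimen, start
#'   and end week, billed consultations, end reason), test events, exit
#'   reason/week and the surgery-eligibility flag.
#' @examples
#' cfg <- build_default_config()
#' set.seed(1)
#' p <- draw_parameter_set(cfg)
#' simulate_patient("TEST_BASED", p, horizon = 260)
#' @export
simulate_patient <- function(strategy, params, horizon) {
  strategy <- match.arg(strategy, c("EMPIRICAL", "TEST_BASED"))
  if (!inherits(params, "tdm_params")) stop("params must be a tdm_params object")
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon < 1 ||
      horizon != floor(horizon))
    stop("horizon must be a positive integer number of weeks")
  horizon <- as.integer(horizon)

  cycle_weeks <- params$cycle_weeks

  # course accumulators (preallocated; at most ~8 courses are reachable)
  cap <- 16L
  c_reg <- character(cap); c_start <- integer(cap); c_end <- integer(cap)
  c_ncons <- integer(cap); c_reason <- character(cap)
  nc <- 0L
  push_course <- function(reg, s, e, n, why) {
    nc <<- nc + 1L
    c_reg[nc] <<- reg; c_start[nc] <<- s; c_end[nc] <<- e
    c_ncons[nc] <<- n; c_reason[nc] <<- why
  }

  t_week <- integer(2); t_drug <- character(2); t_out <- character(2); nt <- 0L

  regimen <- "IFX5_Q8"
  mode <- if (strategy == "EMPIRICAL") "empirical" else "pre_ifx"
  induction_next_mode <- NA_character_
  week <- 0L
  exit_reason <- NA_character_; exit_week <- NA_integer_

  repeat {
    if (regimen == "ADA_INDUCTION") {
      end <- week + 4L
      if (end >= horizon) {
        push_course("ADA_INDUCTION", week, horizon, 1L, "HORIZON")
        exit_reason <- "HORIZON"; exit_week <- horizon
        break
      }
      push_course("ADA_INDUCTION", week, end, 1L, "COMPLETED")
      week <- end
      regimen <- "ADA_Q2"
      mode <- if (strategy == "EMPIRICAL") "empirical" else induction_next_mode
      next
    }

    pr <- course_probs(mode, regimen, params)
    L <- cycle_weeks[[regimen]]
    start <- week
    consults <- 1L          # first dose, no draw
    consult <- start
    event <- NULL
    repeat {
      nxt <- consult + L
      if (nxt >= horizon) break
      lor_p <- if (pr$kind == "constant") pr$lor
               else if (nxt - start <= pr$break_week) pr$lor[1] else pr$lor[2]
      u <- runif(1)
      if (u < pr$ae) { event <- "AE"; week <- nxt; break }
      if (u < pr$ae + (1 - pr$ae) * lor_p) { event <- "LOR"; week <- nxt; break }
      consults <- consults + 1L
      consult <- nxt
    }

    if (is.null(event)) {
      push_course(regimen, start, horizon, consults, "HORIZON")
      exit_reason <- "HORIZON"; exit_week <- horizon
      break
    }

    # resolve routing; the trigger consultation at `week` belongs to the successor
    if (mode == "empirical") {
      nxt_reg <- empirical_successor(regimen, event)
      push_course(regimen, start, week, consults, event)
      if (nxt_reg == "FAILURE") { exit_reason <- "FAILURE"; exit_week <- week; break }
      regimen <- nxt_reg
    } else if (mode == "pre_ifx") {
      if (event == "AE") {
        push_course(regimen, start, week, consults, event)
        regimen <- "ADA_INDUCTION"; induction_next_mode <- "pre_ada"
      } else {
        res <- resolve_ifx_test(params)
        nt <- nt + 1L; t_week[nt] <- week; t_drug[nt] <- "IFX"; t_out[nt] <- res$outcome
        push_course(regimen, start, week, consults, "TEST_ROUTE")
        if (res$decision == "switch_class") {
          exit_reason <- "SWITCH_CLASS"; exit_week <- week; break
        }
        if (res$routed_regimen == "ADA_Q2") {
          regimen <- "ADA_INDUCTION"; induction_next_mode <- "ada_sw"
        } else {
          regimen <- res$routed_regimen; mode <- "ifx_opt"
        }
      }
    } else if (mode == "ifx_opt") {
      # LOR after test-guided IFX optimization: only one IFX test is ever done,
      # so the patient moves to ADA without re-testing
      push_course(regimen, start, week, consults, event)
      regimen <- "ADA_INDUCTION"; induction_next_mode <- "pre_ada"
    } else if (mode %in% c("pre_ada", "ada_sw")) {
      if (event == "AE") {
        push_course(regimen, start, week, consults, event)
        exit_reason <- "FAILURE"; exit_week <- week; break
      }
      res <- resolve_ada_test(params)
      nt <- nt + 1L; t_week[nt] <- week; t_drug[nt] <- "ADA"; t_out[nt] <- res$outcome
      push_course(regimen, start, week, consults, "TEST_ROUTE")
      if (res$decision == "switch_class") {
        exit_reason <- "SWITCH_CLASS"; exit_week <- week; break
      }
      mode <- if (res$routed_regimen == "ADA_Q1") "post2_opt" else "post2_sw"
      regimen <- res$routed_regimen
    } else {  # post2_opt / post2_sw: both anti-TNFs now exhausted on any event
      push_course(regimen, start, week, consults, event)
      exit_reason <- "FAILURE"; exit_week <- week; break
    }
  }

  structure(list(
    strategy = strategy,
    horizon = horizon,
    courses = list(regimen = c_reg[seq_len(nc)],
                   start_week = c_start[seq_len(nc)],
                   end_week = c_end[seq_len(nc)],
                   n_consultations = c_ncons[seq_len(nc)],
                   end_reason = c_reason[seq_len(nc)]),
    tests = list(week = t_week[seq_len(nt)],
                 drug = t_drug[seq_len(nt)],
                 outcome = t_out[seq_len(nt)]),
    exit_reason = exit_reason,
    exit_week = exit_week,
    surgery_eligible = identical(exit_reason, "FAILURE")
  ), class = "tdm_trajectory")
}

#' @export
print.tdm_trajectory <- function(x, ...) {
  cat(sprintf("Patient trajectory [%s, %d weeks]: exit %s at week %d%s\n",
              x$strategy, x$horizon, x$exit_reason, x$exit_week,
              if (x$surgery_eligible) " (surgery-eligible)" else ""))
  print(as.data.frame(x), row.names = FALSE)
  if (length(x$tests$week) > 0)
    cat(sprintf("  test at week %d on %s: %s\n",
                x$tests$week, x$tests$drug, x$tests$outcome), sep = "")
  invisible(x)
}

#' @export
as.data.frame.tdm_trajectory <- function(x, ...) {
  as.data.frame(x$courses, stringsAsFactors = FALSE)
}

#' Course-level table for a set of trajectories
#'
#' Stacks the per-course records of a list of trajectories into one
#' data.frame (one row per treatment course), the stable export format.
#'
#' @param trajectories List of `tdm_trajectory` objects.
#' @param patient_ids Optional ids; defaults to `seq_along(trajectories)`.
#' @return data.frame with columns `patient_id`, `strategy`, `regimen`,
#'   `start_week`, `end_week`, `n_consultations`, `end_reason`.
#' @export
courses_table <- function(trajectories, patient_ids = seq_along(trajectories)) {
  out <- mapply(function(tr, id) {
    k <- length(tr$courses$regimen)
    data.frame(patient_id = rep(id, k), strategy = rep(tr$strategy, k),
               as.data.frame(tr$courses, stringsAsFactors = FALSE),
               stringsAsFactors = FALSE)
  }, trajectories, patient_ids, SIMPLIFY = FALSE)
  do.call(rbind, out)
}

#' Patient-level table for a set of trajectories
#'
#' @inheritParams courses_table
#' @return data.frame with one row per patient: `patient_id`, `strategy`,
#'   `exit_reason`, `exit_week`, `n_tests`, `surgery_eligible`.
#' @export
patients_table <- function(trajectories, patient_ids = seq_along(trajectories)) {
  data.frame(
    patient_id = patient_ids,
    strategy = vapply(trajectories, `[[`, character(1), "strategy"),
    exit_reason = vapply(trajectories, `[[`, character(1), "exit_reason"),
    exit_week = vapply(trajectories, `[[`, integer(1), "exit_week"),
    n_tests = vapply(trajectories, function(tr) length(tr$tests$week), integer(1)),
    surgery_eligible = vapply(trajectories, `[[`, logical(1), "surgery_eligible"),
    stringsAsFactors = FALSE
  )
}
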