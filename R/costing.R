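#' Cost table of the model
#'
#' Extracts the billing inputs from a configuration: per-cycle tariff and
#' cycle length of each regimen, the EUR 100 test, the EUR 12,000 surgical
#' procedure and the post-operative IFX fraction. All amounts are integer
#' euro-cents.
#'
#' @param config A `tdm_config`.
#' @return Object of class `tdm_costs`.
#' @export
build_cost_table <- function(config = build_default_config()) {
  structure(list(
    cycle_cents = vapply(config$regimens, `[[`, numeric(1), "cost_cents"),
    cycle_weeks = vapply(config$regimens, `[[`, integer(1), "cycle_weeks"),
    test_cents = config$costs$test_cents,
    surgery_cents = config$costs$surgery_cents,
    postop_fraction = config$costs$postop_fraction,
    ifx_vial_cents = config$costs$ifx_vial_cents,
    infusion_cents = config$costs$infusion_cents
  ), class = "tdm_costs")
}

cost_breakdown <- function(drug = 0, test = 0, surgery = 0, postop = 0) {
  structure(list(drug_cents = drug, test_cents = test,
                 surgery_cents = surgery, postop_drug_cents = postop,
                 total_cents = drug + test + surgery + postop),
            class = "tdm_cost_breakdown")
}

#' @export
print.tdm_cost_breakdown <- function(x, ...) {
  cat(sprintf(
    "Cost breakdown (EUR): drug %.2f | tests %.2f | surgery %.2f | post-op drug %.2f | total %.2f\n",
    x$drug_cents / 100, x$test_cents / 100, x$surgery_cents / 100,
    x$postop_drug_cents / 100, x$total_cents / 100))
  invisible(x)
}

#' Drug cost of one treatment course
#'
#' Cyclic regimens bill their per-cycle tariff once per delivered
#' consultation; the ADA induction block (160/80 mg) is billed once as a
#' flat amount regardless of its duration.
#'
#' @param course List (or one-row data.frame) with at least `regimen` and
#'   `n_consultations`.
#' @param costs A `tdm_costs` table.
#' @return Cost in euro-cents.
#' @examples
#' course_cost(list(regimen = "IFX5_Q8", n_consultations = 7), build_cost_table())
#' @export
course_cost <- function(course, costs) {
  reg <- as.character(course$regimen)
  if (!reg %in% names(costs$cycle_cents)) stop("unknown regimen '", reg, "'")
  if (reg == "ADA_INDUCTION") return(unname(costs$cycle_cents[reg]))
  course$n_consultations * unname(costs$cycle_cents[reg])
}

# number of consultations of a course visible before week `h`
consults_before <- function(start, end, n_recorded, L, h) {
  if (h >= end) return(n_recorded)
  m <- h - start
  if (m <= 0) return(0L)
  as.integer(ceiling(m / L))
}

#' Cost of a whole trajectory
#'
#' Sums the drug cost of every course and, when `include_tests`, EUR 100
#' per drug-monitoring test event. Surgery components are zero in base
#' mode (see [surgery_extension()]). An optional `horizon` truncates the
#' trajectory: only consultations, induction blocks and tests occurring
#' strictly before that week are billed, so costs at 1/3/5 years can be
#' read off one 5-year simulation.
#'
#' @param traj A `tdm_trajectory`.
#' @param costs A `tdm_costs` table.
#' @param include_tests Bill EUR 100 per test event (default `TRUE`).
#' @param horizon Optional truncation week; defaults to the trajectory's
#'   own horizon.
#' @return A `tdm_cost_breakdown` (euro-cents; `total_cents` is the sum of
#'   the components).
#' @export
trajectory_cost <- function(traj, costs, include_tests = TRUE, horizon = NULL) {
  if (is.null(horizon)) horizon <- traj$horizon
  cs <- traj$courses
  drug <- 0
  for (i in seq_along(cs$regimen)) {
    if (cs$start_week[i] >= horizon) break
    reg <- cs$regimen[i]
    if (reg == "ADA_INDUCTION") {
      drug <- drug + unname(costs$cycle_cents[reg])
    } else {
      n <- consults_before(cs$start_week[i], cs$end_week[i],
                           cs$n_consultations[i],
                           unname(costs$cycle_weeks[reg]), horizon)
      drug <- drug + n * unname(costs$cycle_cents[reg])
    }
  }
  test <- if (include_tests) sum(traj$tests$week < horizon) * costs$test_cents else 0
  cost_breakdown(drug = drug, test = test)
}

#' Surgery and post-operative anti-TNF extension
#'
#' For a patient who exits with both anti-TNFs failed (surgery-eligible), a
#' surgical procedure (EUR 12,000) is billed at the exit week and, with the
#' post-operative probability (25%), standard-dose IFX q8w is given from
#' the exit week to the end of follow-up to prevent recurrence. Patients
#' leaving the anti-TNF class after a high-trough test result, or still on
#' treatment at the horizon, accrue nothing here.
#'
#' Uses R's global random number stream for the post-operative draw, which
#' is independent of the base-mode costs.
#'
#' @param traj A `tdm_trajectory` (simulated to the full follow-up,
#'   typically 260 weeks).
#' @param costs A `tdm_costs` table.
#' @return A `tdm_cost_breakdown` delta (surgery and post-operative drug
#'   components only).
#' @export
surgery_extension <- function(traj, costs) {
  if (!isTRUE(traj$surgery_eligible)) return(cost_breakdown())
  postop <- 0
  if (runif(1) < costs$postop_fraction) {
    L <- unname(costs$cycle_weeks["POSTOP_IFX_Q8"])
    n <- length(seq.int(traj$exit_week, traj$horizon - 1L, by = L))
    postop <- n * unname(costs$cycle_cents["POSTOP_IFX_Q8"])
  }
  cost_breakdown(surgery = costs$surgery_cents, postop = postop)
}

#' Patient-level cost table
#'
#' One row per patient with the cost components in euros (two decimals),
#' the stable cost export format.
#'
#' @param trajectories List of `tdm_trajectory` objects.
#' @param costs A `tdm_costs` table.
#' @param include_tests Bill EUR 100 per test event.
#' @param horizon Optional truncation week.
#' @param patient_ids Optional ids.
#' @return data.frame with `patient_id`, `arm`, `drug_cost`, `test_cost`,
#'   `surgery_cost`, `postop_drug_cost`, `total` (euros).
#' @export
costs_table <- function(trajectories, costs, include_tests = TRUE,
                        horizon = NULL, patient_ids = seq_along(trajectories)) {
  rows <- lapply(trajectories, trajectory_cost, costs = costs,
                 include_tests = include_tests, horizon = horizon)
  data.frame(
    patient_id = patient_ids,
    arm = vapply(trajectories, `[[`, character(1), "strategy"),
    drug_cost = round(vapply(rows, `[[`, numeric(1), "drug_cents") / 100, 2),
    test_cost = round(vapply(rows, `[[`, numeric(1), "test_cents") / 100, 2),
    surgery_cost = round(vapply(rows, `[[`, numeric(1), "surgery_cents") / 100, 2),
    postop_drug_cost = round(vapply(rows, `[[`, numeric(1), "postop_drug_cents") / 100, 2),
    total = round(vapply(rows, `[[`, numeric(1), "total_cents") / 100, 2),
    stringsAsFactors = FALSE
  )
}
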