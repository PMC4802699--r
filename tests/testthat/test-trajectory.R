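test_that("empirical escalation chain is ordered and always terminates", {
  expect_identical(empirical_successor("IFX5_Q8", "LOR"), "IFX10_Q8")
  expect_identical(empirical_successor("IFX10_Q8", "LOR"), "IFX10_Q6")
  expect_identical(empirical_successor("IFX10_Q6", "LOR"), "IFX10_Q6_IS")
  expect_identical(empirical_successor("IFX10_Q6_IS", "LOR"), "ADA_INDUCTION")
  expect_identical(empirical_successor("ADA_Q2", "LOR"), "ADA_Q1")
  expect_identical(empirical_successor("ADA_Q1", "LOR"), "FAILURE")

  # serious AE: any IFX regimen switches class member; ADA exhausts the class
  for (r in c("IFX5_Q8", "IFX10_Q8", "IFX10_Q6", "IFX10_Q6_IS"))
    expect_identical(empirical_successor(r, "AE"), "ADA_INDUCTION")
  expect_identical(empirical_successor("ADA_Q2", "AE"), "FAILURE")
  expect_identical(empirical_successor("ADA_Q1", "AE"), "FAILURE")

  expect_error(empirical_successor("ADA_INDUCTION", "LOR"), "no successor")
  expect_error(empirical_successor("POSTOP_IFX_Q8", "AE"), "no successor")

  # transition-graph enumeration: every LOR/AE path reaches an exit
  for (ev in c("LOR", "AE")) {
    for (start in c("IFX5_Q8", "IFX10_Q8", "IFX10_Q6", "IFX10_Q6_IS",
                    "ADA_Q2", "ADA_Q1")) {
      cur <- start
      for (step in 1:8) {
        if (cur == "ADA_INDUCTION") cur <- "ADA_Q2"  # induction completes
        else cur <- empirical_successor(cur, ev)
        if (cur == "FAILURE") break
      }
      expect_identical(cur, "FAILURE")
    }
  }
})

test_that("consultation events follow the sequential AE-then-LOR scheme", {
  expect_true(all(consultation_step(0, 0, 50) == "CONTINUE"))
  expect_true(all(consultation_step(1, 0, 50) == "LOR"))
  expect_true(all(consultation_step(0, 1, 50) == "AE"))
  expect_true(all(consultation_step(1, 1, 50) == "AE"))  # AE pre-empts LOR

  set.seed(14)
  x <- consultation_step(0.021, 0.029, 2e5)
  f <- table(factor(x, levels = c("AE", "LOR", "CONTINUE"))) / 2e5
  expect_equal(unname(f[["AE"]]), 0.029, tolerance = 0.002 / 0.029)
  expect_equal(unname(f[["LOR"]]), (1 - 0.029) * 0.021, tolerance = 0.002 / 0.02)
  expect_equal(unname(f[["CONTINUE"]]), (1 - 0.029) * (1 - 0.021),
               tolerance = 0.002)
})

test_that("an event-free patient stays on IFX5_Q8 for the whole horizon", {
  p <- deg_params()
  for (strat in c("EMPIRICAL", "TEST_BASED")) {
    tr <- simulate_patient(strat, p, 260)
    expect_identical(tr$courses$regimen, "IFX5_Q8")
    expect_identical(tr$courses$n_consultations, 33L)  # weeks 0, 8, ..., 256
    expect_identical(tr$courses$end_reason, "HORIZON")
    expect_identical(tr$exit_reason, "HORIZON")
    expect_identical(tr$exit_week, 260L)
    expect_false(tr$surgery_eligible)
    expect_length(tr$tests$week, 0)
  }
  expect_identical(simulate_patient("EMPIRICAL", p, 52)$courses$n_consultations, 7L)
})

test_that("a certain LOR walks the full empirical chain and fails at week 35", {
  p <- deg_params(lor = c(IFX5_Q8 = 1, IFX10_Q8 = 1, IFX10_Q6 = 1,
                          IFX10_Q6_IS = 1, ADA_Q2 = 1, ADA_Q1 = 1))
  tr <- simulate_patient("EMPIRICAL", p, 260)
  expect_identical(tr$courses$regimen,
                   c("IFX5_Q8", "IFX10_Q8", "IFX10_Q6", "IFX10_Q6_IS",
                     "ADA_INDUCTION", "ADA_Q2", "ADA_Q1"))
  # trigger consultations deliver the successor's dose: one billed
  # administration per course, induction billed once
  expect_true(all(tr$courses$n_consultations == 1L))
  # hand-enumerated consultation weeks: 0, 8, 16, 22, 28 (induction), 32, 34, 35
  expect_identical(tr$courses$start_week, c(0L, 8L, 16L, 22L, 28L, 32L, 34L))
  expect_identical(tr$exit_reason, "FAILURE")
  expect_identical(tr$exit_week, 35L)
  expect_true(tr$surgery_eligible)
  # courses tile [0, exit_week)
  expect_identical(tr$courses$start_week[-1],
                   tr$courses$end_week[-length(tr$courses$end_week)])
})

test_that("a serious AE on IFX switches straight to ADA induction", {
  p <- deg_params(ae = c(IFX5_Q8 = 1))
  tr <- simulate_patient("EMPIRICAL", p, 260)
  expect_identical(tr$courses$regimen[1:3], c("IFX5_Q8", "ADA_INDUCTION", "ADA_Q2"))
  expect_identical(tr$courses$end_reason[1], "AE")
  expect_identical(tr$courses$start_week[2], 8L)
  # event-free thereafter: ADA_Q2 runs to the horizon
  expect_identical(tr$exit_reason, "HORIZON")

  # same AE in the test arm also routes to ADA, without any test
  tr2 <- simulate_patient("TEST_BASED", p, 260)
  expect_identical(tr2$courses$regimen[1:3], c("IFX5_Q8", "ADA_INDUCTION", "ADA_Q2"))
  expect_length(tr2$tests$week, 0)
})

test_that("the IFX test fires once at the first IFX LOR and routes per outcome", {
  base <- deg_config(lor = c(IFX5_Q8 = 1))

  cfg <- force_test_outcome(base, "ifx_test", "HIGH_TROUGH")
  tr <- simulate_patient("TEST_BASED", draw_parameter_set(cfg), 260)
  expect_identical(tr$tests$week, 8L)
  expect_identical(tr$tests$drug, "IFX")
  expect_identical(tr$tests$outcome, "HIGH_TROUGH")
  expect_identical(tr$exit_reason, "SWITCH_CLASS")
  expect_identical(tr$exit_week, 8L)
  expect_false(tr$surgery_eligible)          # leaves the class, no surgery
  expect_identical(tr$courses$end_reason[1], "TEST_ROUTE")

  cfg <- force_test_outcome(base, "ifx_test", "LOW_TROUGH_NO_AB")
  tr <- simulate_patient("TEST_BASED", draw_parameter_set(cfg), 260)
  expect_identical(tr$courses$regimen[1:2], c("IFX5_Q8", "IFX10_Q8"))
  expect_length(tr$tests$week, 1)  # one IFX test only, whatever follows

  cfg <- force_test_outcome(base, "ifx_test", "LOW_TROUGH_WITH_AB")
  tr <- simulate_patient("TEST_BASED", draw_parameter_set(cfg), 260)
  expect_identical(tr$courses$regimen[1:3], c("IFX5_Q8", "ADA_INDUCTION", "ADA_Q2"))
})

test_that("the ADA test fires at the first ADA LOR; post-test events end the sequence", {
  # route: AE on IFX -> ADA; forced ADA LOR at the first ADA_Q2 draw (week 14)
  base <- deg_config(lor = c(ADA_Q2 = 1), ae = c(IFX5_Q8 = 1))

  cfg <- force_test_outcome(base, "ada_test", "HIGH_TROUGH")
  tr <- simulate_patient("TEST_BASED", draw_parameter_set(cfg), 260)
  expect_identical(tr$tests$drug, "ADA")
  expect_identical(tr$tests$week, 14L)  # AE at 8, induction 8-12, dose 12, LOR at 14
  expect_identical(tr$exit_reason, "SWITCH_CLASS")

  cfg <- force_test_outcome(base, "ada_test", "LOW_TROUGH_NO_AB")
  cfg <- fast_failure_efficacy(cfg, "ada_test", "LOW_TROUGH_NO_AB")
  tr <- simulate_patient("TEST_BASED", draw_parameter_set(cfg), 260)
  k <- length(tr$courses$regimen)
  expect_identical(tr$courses$regimen[k], "ADA_Q1")
  expect_identical(tr$exit_reason, "FAILURE")   # no third test ever
  expect_length(tr$tests$week, 1)
  expect_true(tr$surgery_eligible)

  cfg <- force_test_outcome(base, "ada_test", "LOW_TROUGH_WITH_AB")
  cfg <- fast_failure_efficacy(cfg, "ada_test", "LOW_TROUGH_WITH_AB")
  tr <- simulate_patient("TEST_BASED", draw_parameter_set(cfg), 260)
  k <- length(tr$courses$regimen)
  expect_identical(tr$courses$regimen[k], "IFX5_Q8")  # switch back to IFX
  expect_identical(tr$exit_reason, "FAILURE")
  expect_length(tr$tests$week, 1)
})

test_that("both tests can occur, in order IFX then ADA, never more", {
  # IFX LOR -> test -> (forced) IFX optimization; its certain-failure hazard
  # sends the patient to ADA, whose LOR triggers the second test
  cfg <- deg_config(lor = c(IFX5_Q8 = 1, ADA_Q2 = 1))
  cfg <- force_test_outcome(cfg, "ifx_test", "LOW_TROUGH_NO_AB")
  cfg <- fast_failure_efficacy(cfg, "ifx_test", "LOW_TROUGH_NO_AB")
  cfg <- force_test_outcome(cfg, "ada_test", "HIGH_TROUGH")
  set.seed(4)
  tr <- simulate_patient("TEST_BASED", draw_parameter_set(cfg), 260)
  expect_identical(tr$tests$drug, c("IFX", "ADA"))
  expect_identical(tr$exit_reason, "SWITCH_CLASS")
})

test_that("test outcome frequencies match the published probabilities", {
  cfg <- build_default_config()
  set.seed(8)
  p <- draw_parameter_set(cfg)

  draws <- character(1e5)
  for (i in seq_len(1e5)) draws[i] <- resolve_ifx_test(p)$outcome
  f <- table(draws) / 1e5
  expect_equal(unname(f[["HIGH_TROUGH"]]), 0.50, tolerance = 0.005 / 0.5)
  expect_equal(unname(f[["LOW_TROUGH_NO_AB"]]), 0.29, tolerance = 0.005 / 0.29)
  expect_equal(unname(f[["LOW_TROUGH_WITH_AB"]]), 0.21, tolerance = 0.005 / 0.21)

  for (i in seq_len(1e5)) draws[i] <- resolve_ada_test(p)$outcome
  f <- table(draws) / 1e5
  expect_equal(unname(f[["HIGH_TROUGH"]]), 0.43, tolerance = 0.005 / 0.43)
  expect_equal(unname(f[["LOW_TROUGH_NO_AB"]]), 0.24, tolerance = 0.005 / 0.24)
  expect_equal(unname(f[["LOW_TROUGH_WITH_AB"]]), 0.33, tolerance = 0.005 / 0.33)
})

test_that("trajectory invariants hold across random parameter draws", {
  cfg <- build_default_config()
  set.seed(21)
  params <- draw_parameter_set(cfg)
  cw <- params$cycle_weeks

  set.seed(22)
  seeds <- sample.int(1e6, 200)
  for (s in seeds) {
    set.seed(s)
    strat <- if (s %% 2 == 0) "EMPIRICAL" else "TEST_BASED"
    tr <- simulate_patient(strat, params, 260)
    cs <- tr$courses
    k <- length(cs$regimen)
    # contiguous tiling of [0, exit_week)
    expect_identical(cs$start_week[1], 0L)
    if (k > 1) expect_identical(cs$start_week[-1], cs$end_week[-k])
    expect_identical(cs$end_week[k], tr$exit_week)
    expect_lte(tr$exit_week, 260L)
    # consultation counts match the schedule arithmetic
    for (i in seq_len(k)) {
      if (cs$regimen[i] == "ADA_INDUCTION") {
        expect_identical(cs$n_consultations[i], 1L)
      } else {
        expect_identical(cs$n_consultations[i],
          as.integer(ceiling((cs$end_week[i] - cs$start_week[i]) /
                             cw[[cs$regimen[i]]])))
      }
    }
    expect_lte(length(tr$tests$week), 2L)
    expect_identical(tr$surgery_eligible, tr$exit_reason == "FAILURE")
    if (strat == "EMPIRICAL") expect_length(tr$tests$week, 0)
  }
})

test_that("truncated trajectories are prefixes of the full-horizon ones", {
  cfg <- build_default_config()
  set.seed(31)
  params <- draw_parameter_set(cfg)
  costs <- build_cost_table(cfg)
  set.seed(32)
  seeds <- sample.int(1e6, 50)
  for (s in seeds) {
    set.seed(s); t_long <- simulate_patient("EMPIRICAL", params, 260)
    set.seed(s); t_short <- simulate_patient("EMPIRICAL", params, 52)
    # identical course structure up to the truncation week
    n_short <- length(t_short$courses$regimen)
    expect_identical(t_short$courses$regimen,
                     t_long$courses$regimen[seq_len(n_short)])
    expect_identical(t_short$courses$start_week,
                     t_long$courses$start_week[seq_len(n_short)])
    # truncated billing on the long trajectory equals the short simulation
    expect_identical(trajectory_cost(t_long, costs, horizon = 52)$total_cents,
                     trajectory_cost(t_short, costs)$total_cents)
    # cost is non-decreasing in the horizon
    c_prev <- 0
    for (h in c(52, 104, 156, 208, 260)) {
      c_h <- trajectory_cost(t_long, costs, horizon = h)$total_cents
      expect_gte(c_h, c_prev)
      c_prev <- c_h
    }
  }
})

test_that("consultations to the first event are geometric: engine matches the oracle", {
  # single active regimen: LOR probability 0.1 on IFX5_Q8, nothing else;
  # compare the IFX5_Q8 course cost against the closed-form finite sum
  p <- deg_params(lor = c(IFX5_Q8 = 0.1))
  n <- 1e4
  costs_v <- numeric(n)
  set.seed(77)
  for (i in seq_len(n)) {
    tr <- simulate_patient("EMPIRICAL", p, 260)
    idx <- tr$courses$regimen == "IFX5_Q8"
    costs_v[i] <- sum(tr$courses$n_consultations[idx]) * 1840.18
  }
  oracle <- geometric_oracle(0.1, 184018, 8, 260)
  se <- sd(costs_v) / sqrt(n)
  expect_lt(abs(mean(costs_v) - oracle), 3 * se)
})

test_that("course and patient tables stack trajectories for export", {
  p <- deg_params(ae = c(IFX5_Q8 = 1))
  trajs <- simulate_cohort(3, "EMPIRICAL", p, 104, seed = 5)
  ct <- courses_table(trajs)
  expect_identical(unique(ct$patient_id), 1:3)
  expect_true(all(c("regimen", "start_week", "end_week", "n_consultations",
                    "end_reason") %in% names(ct)))
  pt <- patients_table(trajs)
  expect_identical(nrow(pt), 3L)
  expect_true(all(pt$exit_reason == "HORIZON"))
  expect_true(all(pt$n_tests == 0))
})
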