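# Degenerate configurations used across test files. All start from the
# no-event scenario (every probability zero) and force the stated
# probabilities, so parameter draws are deterministic.

deg_config <- function(lor = c(), ae = c()) {
  cfg <- no_event_scenario()$config
  for (r in names(lor)) cfg$regimens[[r]]$lor_range <- prob_range(lor[[r]], lor[[r]])
  for (r in names(ae)) cfg$regimens[[r]]$ae_range <- prob_range(ae[[r]], ae[[r]])
  cfg
}

deg_params <- function(lor = c(), ae = c()) {
  draw_parameter_set(deg_config(lor, ae))
}

# force a single test outcome (probability 1) on one of the tests
force_test_outcome <- function(cfg, side, label) {
  for (o in names(cfg[[side]]))
    cfg[[side]][[o]]$probability <- as.numeric(o == label)
  cfg
}

# near-zero retention so an event fires within a few consultations of a
# test-routed course
fast_failure_efficacy <- function(cfg, side, label) {
  k <- length(cfg[[side]][[label]]$efficacy_retention)
  cfg[[side]][[label]]$efficacy_retention <-
    if (k == 2) c(1e-10, 1e-12) else 1e-10
  cfg
}

cents <- function(euros) round(euros * 100)
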