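# a hypercube that comfortably satisfies the 5% screening criterion
# (transcription capped at 0.5 keeps protein well below saturation)
.passing_space <- function() {
  parameter_space(sigma = c(0.012, 0.5), d = c(0, 1.5), lam = c(0, 0.8),
                  tau = c(0.125, 1), delta = c(0, 1.5), gamma = c(0.4, 0.9))
}

.fast_cfg <- function(...) {
  exploration_config(n_test_samples = 64L, ...)
}

test_that("the calibrated hypercube ships with the published constants", {
  sp <- default_parameter_space()
  expect_identical(unname(sp["sigma", ]), c(0.012, 2.0))
  expect_identical(unname(sp["d", ]), c(0.0, 1.5))
  expect_identical(unname(sp["lam", ]), c(0.0, 0.8))
  expect_identical(unname(sp["tau", ]), c(0.125, 1.0))
  expect_identical(unname(sp["delta", ]), c(0.0, 1.5))
  expect_identical(unname(sp["gamma", ]), c(0.4, 0.9))
  seed <- seed_parameter_space()
  expect_identical(unname(seed["tau", ]), c(0.012, 1))
  expect_identical(unname(seed["gamma", ]), c(0.2248, 1))
})

test_that("invalid hypercubes are rejected", {
  expect_error(parameter_space(sigma = c(1, 0.5)), "lower bound")
  expect_error(parameter_space(sigma = c(-0.1, 1)), ">= 0")
  expect_error(parameter_space(sigma = 1), "c\\(lower, upper\\)")
})

test_that("trajectories classify as saturated, undetectable or valid", {
  cfg <- exploration_config()
  n <- 4
  # strong synthesis, no mRNA decay: protein blows past the ceiling
  hot <- simulate_expression(initial_condition("ubiquitous", 1, n),
                             model_parameters(sigma = 2, tau = 1, gamma = 0.4),
                             t_end = 10, n_nuclei = n)
  expect_identical(as.character(classify_simulation(hot, cfg)), "saturated")
  # all rates zero from a zero state: protein never appears
  dead <- simulate_expression(initial_condition("ubiquitous", 0, n),
                              model_parameters(), t_end = 10, n_nuclei = n)
  expect_identical(as.character(classify_simulation(dead, cfg)), "undetectable")
  # balanced kinetics settle near 1: inside the plausible band
  ok <- simulate_expression(initial_condition("ubiquitous", 1, n),
                            model_parameters(sigma = 0.5, lam = 0.5,
                                             tau = 0.5, gamma = 0.5),
                            t_end = 10, n_nuclei = n)
  expect_identical(as.character(classify_simulation(ok, cfg)), "valid")
  # labels are exhaustive and mutually exclusive
  for (sim in list(hot, dead, ok)) {
    cls <- classify_simulation(sim, cfg)
    expect_identical(levels(cls), c("saturated", "undetectable", "valid"))
    expect_identical(sum(cls == levels(cls)), 1L)
  }
  expect_error(classify_simulation(
    simulate_expression(initial_condition("ubiquitous", 1, n),
                        model_parameters(), t_end = 2, n_nuclei = n), cfg),
    "cover")
})

test_that("a transcription-free boundary forces widespread undetectability", {
  # sigma pinned at its seed lower bound 0: no transcription, so the three
  # protein-free initial conditions can only make protein from deposited
  # mRNA; brute-force screening marks well over half of all runs as failing
  rate <- boundary_failure_rate(seed_parameter_space(), "sigma", "lower",
                                .fast_cfg())
  expect_gte(rate, 0.5)
  expect_lte(rate, 1)
})

test_that("an all-valid space has zero boundary failure rate", {
  sp <- .passing_space()
  rate <- boundary_failure_rate(sp, "lam", "upper", .fast_cfg())
  expect_gte(rate, 0)
  expect_lte(rate, 0.05)
})

test_that("a space satisfying the joint criterion is a fixed point of the screen", {
  sp <- .passing_space()
  cfg <- .fast_cfg()
  expect_lte(joint_failure_rate(sp, cfg), 0.05)
  out <- explore_parameter_space(sp, cfg)
  expect_identical(unclass(out)[, ], unclass(sp)[, ])
  expect_true(attr(out, "converged"))
  expect_identical(attr(out, "sweeps"), 0L)
})

test_that("failing bounds move inward by whole adjustment steps", {
  # deliberately saturating hypercube: huge transcription and translation
  sp <- parameter_space(sigma = c(1.5, 3), d = c(0, 1.5), lam = c(0, 0.4),
                        tau = c(0.5, 1), delta = c(0, 1.5),
                        gamma = c(0.4, 0.9))
  cfg <- .fast_cfg(max_sweeps = 2L)
  out <- suppressWarnings(explore_parameter_space(sp, cfg))
  moves <- (unclass(out) - unclass(sp)) / cfg$adjust_step
  expect_true(all(abs(moves - round(moves)) < 1e-9))
  # lower bounds moved up (or stayed), upper bounds moved down (or stayed)
  expect_true(all(out[, "lower"] >= sp[, "lower"]))
  expect_true(all(out[, "upper"] <= sp[, "upper"]))
  expect_true(all(out[, "lower"] >= 0))
  expect_true(all(out[, "lower"] <= out[, "upper"]))
})

test_that("non-convergence is flagged, not silently returned", {
  sp <- parameter_space(sigma = c(2, 2.2), tau = c(0.9, 1),
                        lam = c(0, 0.1), gamma = c(0.4, 0.5),
                        d = c(0, 0.1), delta = c(0, 0.1))
  cfg <- .fast_cfg(max_sweeps = 1L)
  expect_warning(out <- explore_parameter_space(sp, cfg), "did not converge")
  expect_false(attr(out, "converged"))
  expect_gt(attr(out, "joint_failure_rate"), 0.05)
})

test_that("exploration configuration enforces its invariants", {
  expect_error(exploration_config(adjust_min = 0.2, adjust_max = 0.1))
  expect_error(exploration_config(failure_fraction = 0))
  expect_error(exploration_config(adjust_step = 0.5))
})
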