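#' Configuration for the parameter-space screen
#'
#' Settings for the iterative procedure that trims parameter ranges until
#' almost all simulated trajectories stay in a biologically plausible band:
#' protein is classified *saturated* at or above `saturation_threshold`
#' (default 7 concentration units) and *undetectable* at or below
#' `undetectable_threshold` (default 0.01). A bound fails its test when more
#' than `failure_fraction` (default 5%) of simulations -- `n_test_samples`
#' parameter sets, each run under all five canonical initial conditions --
#' are saturated or undetectable.
#'
#' @param saturation_threshold protein concentration at or above which a
#'   trajectory counts as saturated.
#' @param undetectable_threshold protein concentration at or below which
#'   protein counts as undetectable.
#' @param failure_fraction tolerated fraction of failing simulations.
#' @param adjust_min,adjust_max admissible bounds for a single range
#'   adjustment step.
#' @param adjust_step the fixed adjustment actually applied (must lie within
#'   `[adjust_min, adjust_max]`); a failing lower bound moves up, a failing
#'   upper bound moves down, so every move shrinks the range.
#' @param n_test_samples Sobol-sampled parameter sets per boundary test.
#' @param t_end simulation horizon for the screen, minutes.
#' @param dt integration step, minutes.
#' @param record_every interval between states inspected for saturation.
#' @param saturation_scope `"any_time"` (default) judges saturation over all
#'   recorded times; `"final"` only at `t_end`.
#' @param undetectable_scope `"final"` (default) judges undetectability at
#'   `t_end` only; `"any_time"` requires it at every recorded time.
#' @param max_sweeps cap on full passes over the six parameters before the
#'   procedure reports non-convergence.
#' @param deposit_level mRNA amount for the maternal-deposit initial
#'   conditions.
#' @return A list of class `exploration_config`.
#' @export
exploration_config <- function(saturation_threshold = 7,
                               undetectable_threshold = 0.01,
                               failure_fraction = 0.05,
                               adjust_min = 0.001, adjust_max = 0.1,
                               adjust_step = 0.05,
                               n_test_samples = 500L,
                               t_end = 10, dt = 0.01, record_every = 0.1,
                               saturation_scope = c("any_time", "final"),
                               undetectable_scope = c("final", "any_time"),
                               max_sweeps = 200L,
                               deposit_level = 1) {
  stopifnot(0 < adjust_min, adjust_min <= adjust_max,
            adjust_min <= adjust_step, adjust_step <= adjust_max,
            0 < failure_fraction, failure_fraction < 1,
            n_test_samples >= 1, t_end > 0, dt > 0,
            saturation_threshold > undetectable_threshold,
            deposit_level >= 0)
  structure(list(saturation_threshold = saturation_threshold,
                 undetectable_threshold = undetectable_threshold,
                 failure_fraction = failure_fraction,
                 adjust_min = adjust_min, adjust_max = adjust_max,
                 adjust_step = adjust_step,
                 n_test_samples = as.integer(n_test_samples),
                 t_end = t_end, dt = dt, record_every = record_every,
                 saturation_scope = match.arg(saturation_scope),
                 undetectable_scope = match.arg(undetectable_scope),
                 max_sweeps = as.integer(max_sweeps),
                 deposit_level = deposit_level),
            class = "exploration_config")
}

# the five canonical initial conditions of the screen
.screen_ics <- function(n_nuclei, deposit_level) {
  list(ubiquitous_0 = initial_condition("ubiquitous", 0, n_nuclei),
       ubiquitous_05 = initial_condition("ubiquitous", 0.5, n_nuclei),
       ubiquitous_1 = initial_condition("ubiquitous", 1, n_nuclei),
       anterior = initial_condition("anterior", deposit_level, n_nuclei),
       posterior = initial_condition("posterior", deposit_level, n_nuclei))
}

# classify a batch of trajectories from per-sample protein summaries
.classify_batch <- function(max_prot_any, max_prot_final, min_is_undetectable,
                            cfg) {
  sat_stat <- if (cfg$saturation_scope == "any_time") max_prot_any else max_prot_final
  saturated <- sat_stat >= cfg$saturation_threshold
  undetectable <- !saturated & min_is_undetectable
  out <- rep("valid", length(saturated))
  out[undetectable] <- "undetectable"
  out[saturated] <- "saturated"
  factor(out, levels = c("saturated", "undetectable", "valid"))
}

# run one batch of parameter sets under one IC and classify each trajectory
.screen_batch <- function(params_mat, ic, n_nuclei, cfg) {
  n_steps <- round(cfg$t_end / cfg$dt)
  stride <- round(cfg$record_every / cfg$dt)
  rec <- seq.int(0L, n_steps, by = stride)
  if (rec[length(rec)] != n_steps) rec <- c(rec, n_steps)
  arr <- rk4_batch_cpp(params_mat, as.numeric(ic), as.integer(n_nuclei),
                       cfg$dt, as.integer(rec), as.integer(n_steps))
  dim(arr) <- c(nrow(params_mat), 2L * n_nuclei, length(rec))
  prot <- arr[, n_nuclei + seq_len(n_nuclei), , drop = FALSE]
  max_any <- apply(prot, 1L, max)
  final <- prot[, , length(rec), drop = FALSE]
  max_final <- apply(final, 1L, max)
  und <- if (cfg$undetectable_scope == "final") {
    apply(final, 1L, max) <= cfg$undetectable_threshold
  } else {
    apply(prot, 1L, max) <= cfg$undetectable_threshold
  }
  .classify_batch(max_any, max_final, und, cfg)
}

#' Classify a simulated trajectory as saturated, undetectable or valid
#'
#' A trajectory is *saturated* when any protein concentration in any nucleus
#' reaches the saturation threshold (by default judged over every recorded
#' time), *undetectable* when every protein concentration stays at or below
#' the undetectability threshold (by default judged at the final time), and
#' *valid* otherwise. The two scopes are configurable in
#' [exploration_config()].
#'
#' @param sim an `expression_sim` covering `[0, cfg$t_end]`.
#' @param cfg an [exploration_config()].
#' @return A length-1 factor with levels `saturated`, `undetectable`,
#'   `valid`.
#' @export
classify_simulation <- function(sim, cfg = exploration_config()) {
  stopifnot(inherits(sim, "expression_sim"))
  if (max(sim$times) < cfg$t_end - 1e-9) {
    stop("simulation must cover [0, t_end] of the configuration",
         call. = FALSE)
  }
  n <- sim$n_nuclei
  keep <- sim$times <= cfg$t_end + 1e-9
  prot <- sim$states[keep, n + seq_len(n), drop = FALSE]
  final <- prot[nrow(prot), ]
  und <- if (cfg$undetectable_scope == "final") {
    max(final) <= cfg$undetectable_threshold
  } else {
    max(prot) <= cfg$undetectable_threshold
  }
  .classify_batch(max(prot), max(final), und, cfg)
}

# failure fraction of a space, optionally with one parameter pinned
.failure_rate <- function(space, cfg, n_nuclei = 52L, pin = NULL) {
  design <- sobol_design(cfg$n_test_samples, space)
  params <- design$scaled
  if (!is.null(pin)) params[, pin$param] <- pin$value
  ics <- .screen_ics(n_nuclei, cfg$deposit_level)
  n_fail <- 0L
  n_tot <- 0L
  for (ic in ics) {
    cls <- .screen_batch(params, ic, n_nuclei, cfg)
    n_fail <- n_fail + sum(cls != "valid")
    n_tot <- n_tot + length(cls)
  }
  n_fail / n_tot
}

#' Failure rate with one parameter held at a range boundary
#'
#' Pins one parameter at the lower or upper bound of its range, Sobol-samples
#' all remaining parameters within their current ranges, runs every sampled
#' parameter set under the five canonical initial conditions (ubiquitous at
#' levels 0, 1/2 and 1; anterior and posterior maternal deposits), and
#' returns the fraction of simulations classified saturated or undetectable.
#'
#' @param space a [parameter_space()].
#' @param param one of `"sigma"`, `"d"`, `"lam"`, `"tau"`, `"delta"`,
#'   `"gamma"`.
#' @param side `"lower"` or `"upper"`.
#' @param cfg an [exploration_config()].
#' @param n_nuclei number of nuclei simulated.
#' @return A proportion in `[0, 1]`.
#' @export
boundary_failure_rate <- function(space, param, side = c("lower", "upper"),
                                  cfg = exploration_config(),
                                  n_nuclei = 52L) {
  stopifnot(inherits(space, "parameter_space"))
  side <- match.arg(side)
  if (!param %in% rownames(space)) {
    stop("'param' must be one of: ", paste(rownames(space), collapse = ", "),
         call. = FALSE)
  }
  .failure_rate(space, cfg, n_nuclei,
                pin = list(param = param, value = space[param, side]))
}

#' Joint failure rate of a parameter space
#'
#' All six parameters vary within their ranges; the returned proportion is
#' the fraction of the `n_test_samples` x 5 simulations (five canonical
#' initial conditions) that are saturated or undetectable.
#'
#' @inheritParams boundary_failure_rate
#' @return A proportion in `[0, 1]`.
#' @export
joint_failure_rate <- function(space, cfg = exploration_config(),
                               n_nuclei = 52L) {
  stopifnot(inherits(space, "parameter_space"))
  .failure_rate(space, cfg, n_nuclei)
}

#' Iteratively trim parameter ranges to a realistic regime
#'
#' Implements the parameter-space screen: starting from `space`, the joint
#' test is run first; if its failure rate is within tolerance the space is
#' returned unchanged after that single verification pass. Otherwise each
#' parameter's lower and upper bound is tested in turn with
#' [boundary_failure_rate()], and every failing bound is moved inward by
#' `cfg$adjust_step` (lower bounds up, upper bounds down; lower bounds are
#' never allowed below 0 and bounds never cross). Sweeps repeat until the
#' joint criterion is met or `cfg$max_sweeps` is reached, in which case the
#' result is flagged as non-converged.
#'
#' @param space starting [parameter_space()], e.g.
#'   [seed_parameter_space()].
#' @param cfg an [exploration_config()].
#' @param n_nuclei number of nuclei simulated.
#' @param verbose print per-sweep progress.
#' @return The final [parameter_space()], with attributes `converged`
#'   (logical), `sweeps` (number of adjustment sweeps performed) and
#'   `joint_failure_rate` (rate at the last joint test).
#' @export
explore_parameter_space <- function(space = seed_parameter_space(),
                                    cfg = exploration_config(),
                                    n_nuclei = 52L, verbose = FALSE) {
  stopifnot(inherits(space, "parameter_space"))
  sweeps <- 0L
  converged <- FALSE
  rate <- NA_real_
  repeat {
    rate <- joint_failure_rate(space, cfg, n_nuclei)
    if (verbose) {
      message(sprintf("sweep %d: joint failure rate %.4f", sweeps, rate))
    }
    if (rate <= cfg$failure_fraction) {
      converged <- TRUE
      break
    }
    if (sweeps >= cfg$max_sweeps) break
    sweeps <- sweeps + 1L
    for (param in rownames(space)) {
      for (side in c("lower", "upper")) {
        r <- boundary_failure_rate(space, param, side, cfg, n_nuclei)
        if (r > cfg$failure_fraction) {
          lo <- space[param, "lower"]
          hi <- space[param, "upper"]
          if (side == "lower") {
            space[param, "lower"] <- min(lo + cfg$adjust_step, hi)
          } else {
            space[param, "upper"] <- max(hi - cfg$adjust_step, lo)
          }
        }
      }
    }
  }
  attr(space, "converged") <- converged
  attr(space, "sweeps") <- sweeps
  attr(space, "joint_failure_rate") <- rate
  if (!converged) {
    warning("parameter-space exploration did not converge within ",
            cfg$max_sweeps, " sweeps (joint failure rate ",
            signif(rate, 3), ")", call. = FALSE)
  }
  space
}
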