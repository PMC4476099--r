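#' Kinetic parameters of the gene expression model
#'
#' Bundles the six rate constants of the reaction-diffusion model. All rates
#' are per minute; `sigma` is a zeroth-order synthesis rate in concentration
#' units per minute, the others are first-order rate constants.
#'
#' @param sigma transcription rate (constant mRNA synthesis per nucleus).
#' @param d mRNA diffusion rate between neighbouring nuclei.
#' @param lam mRNA decay rate.
#' @param tau translation rate (protein synthesis per unit mRNA).
#' @param delta protein diffusion rate between neighbouring nuclei.
#' @param gamma protein decay rate.
#'
#' @return An object of class `model_parameters`: a named numeric vector in
#'   the fixed order `sigma, d, lam, tau, delta, gamma`.
#' @examples
#' model_parameters(sigma = 1, d = 0.5, lam = 0.3, tau = 0.5, delta = 0.5,
#'                  gamma = 0.6)
#' @export
model_parameters <- function(sigma = 0, d = 0, lam = 0, tau = 0, delta = 0,
                             gamma = 0) {
  p <- c(sigma = sigma, d = d, lam = lam, tau = tau, delta = delta,
         gamma = gamma)
  if (!is.numeric(p) || length(p) != 6L) {
    stop("all six parameters must be single numeric values", call. = FALSE)
  }
  if (any(!is.finite(p))) stop("parameters must be finite", call. = FALSE)
  if (any(p < 0)) stop("parameters must be non-negative", call. = FALSE)
  structure(p, class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Model parameters (min^-1):\n")
  print(unclass(x), ...)
  invisible(x)
}

.param_names <- c("sigma", "d", "lam", "tau", "delta", "gamma")

.ic_kinds <- c("ubiquitous", "anterior", "posterior")

#' Build an initial condition over the nuclear chain
#'
#' Constructs the state vector (mRNA then protein concentration, one entry per
#' nucleus) for the initial-condition classes used in the analysis:
#' `"ubiquitous"` sets every mRNA and protein entry to `level` (spatially
#' uniform expression, e.g. a housekeeping gene); `"anterior"` / `"posterior"`
#' model a maternally deposited transcript, placing `level` units of mRNA in
#' the single terminal nucleus at the respective end of the chain, with zero
#' mRNA elsewhere and zero protein everywhere.
#'
#' @param kind one of `"ubiquitous"`, `"anterior"`, `"posterior"`.
#' @param level non-negative concentration; for ubiquitous the uniform mRNA
#'   and protein level, for the maternal deposits the mRNA amount placed in
#'   the end nucleus.
#' @param n_nuclei number of nuclei in the chain (default 52).
#' @return A numeric vector of length `2 * n_nuclei`: entries `1..n` are mRNA
#'   per nucleus (anterior to posterior), entries `n+1..2n` are protein.
#' @examples
#' initial_condition("anterior", level = 1, n_nuclei = 3)
#' @export
initial_condition <- function(kind = c("ubiquitous", "anterior", "posterior"),
                              level = 1, n_nuclei = 52L) {
  if (!is.character(kind) || !kind[1L] %in% .ic_kinds) {
    stop("unknown initial condition kind; must be one of: ",
         paste(.ic_kinds, collapse = ", "), call. = FALSE)
  }
  kind <- match.arg(kind)
  stopifnot(is.numeric(level), length(level) == 1L, is.finite(level),
            level >= 0, n_nuclei >= 1)
  n <- as.integer(n_nuclei)
  state <- numeric(2L * n)
  if (kind == "ubiquitous") {
    state[] <- level
  } else if (kind == "anterior") {
    state[1L] <- level
  } else {
    state[n] <- level
  }
  attr(state, "kind") <- kind
  attr(state, "level") <- level
  attr(state, "n_nuclei") <- n
  state
}

#' Instantaneous rate of change of the model state
#'
#' Evaluates the right-hand side of the reaction-diffusion system: each
#' nucleus gains mRNA at the constant transcription rate, exchanges mRNA and
#' protein with its neighbours by discrete diffusion (zero-flux boundaries:
#' the terminal nuclei have a single neighbour), loses each species by
#' first-order decay, and synthesizes protein proportionally to its local
#' mRNA concentration.
#'
#' This reference implementation is plain R; the integrator in
#' [simulate_expression()] uses a compiled equivalent.
#'
#' @param state numeric vector of length `2 * n_nuclei` (mRNA then protein).
#' @param params a [model_parameters()] object (or named vector with the same
#'   six names).
#' @param n_nuclei number of nuclei.
#' @return Numeric vector of length `2 * n_nuclei` with the time derivative
#'   of every component.
#' @export
expression_derivative <- function(state, params, n_nuclei) {
  n <- as.integer(n_nuclei)
  if (length(state) != 2L * n) {
    stop("'state' must have length 2 * n_nuclei = ", 2L * n, call. = FALSE)
  }
  p <- unclass(params)[.param_names]
  if (any(is.na(p))) stop("'params' must supply all six rates", call. = FALSE)
  m <- state[seq_len(n)]
  pr <- state[n + seq_len(n)]
  lap <- function(y) {
    if (n == 1L) return(0)
    c(y[2L] - y[1L],
      if (n > 2L) y[3:n] + y[1:(n - 2L)] - 2 * y[2:(n - 1L)],
      y[n - 1L] - y[n])
  }
  dm <- p[["sigma"]] + p[["d"]] * lap(m) - p[["lam"]] * m
  dp <- p[["tau"]] * m + p[["delta"]] * lap(pr) - p[["gamma"]] * pr
  c(dm, dp)
}

#' Integrate the gene expression model
#'
#' Runs the classic fixed-step fourth-order Runge-Kutta scheme over
#' `[0, t_end]` and records the full state on an evenly spaced output grid.
#' The recording interval defaults to 0.1 min so that whole-minute analysis
#' times always land exactly on recorded points.
#'
#' @param ic initial state vector, e.g. from [initial_condition()].
#' @param params a [model_parameters()] object.
#' @param t_end simulation end time in minutes.
#' @param dt integration step in minutes (default 0.01).
#' @param record_every interval between recorded states, in minutes; must be
#'   a multiple of `dt`.
#' @param n_nuclei number of nuclei; defaults to `length(ic) / 2`.
#' @return An object of class `expression_sim`: a list with `times` (recorded
#'   time points, starting at 0), `states` (matrix, one row per recorded time,
#'   `2 * n_nuclei` columns: `mRNA_1..mRNA_n, protein_1..protein_n`),
#'   `params`, `n_nuclei` and `dt`.
#' @examples
#' sim <- simulate_expression(initial_condition("ubiquitous", 1, 4),
#'                            model_parameters(sigma = 1, lam = 0.5,
#'                                             tau = 0.5, gamma = 0.5),
#'                            t_end = 2)
#' @export
simulate_expression <- function(ic, params, t_end = 20, dt = 0.01,
                                record_every = 0.1,
                                n_nuclei = length(ic) / 2) {
  stopifnot(t_end > 0, dt > 0, record_every > 0)
  n <- as.integer(n_nuclei)
  if (length(ic) != 2L * n) {
    stop("'ic' must have length 2 * n_nuclei", call. = FALSE)
  }
  n_steps <- round(t_end / dt)
  if (abs(n_steps * dt - t_end) > 1e-8) {
    stop("'t_end' must be an integer number of steps of size 'dt'",
         call. = FALSE)
  }
  rec_stride <- round(record_every / dt)
  if (abs(rec_stride * dt - record_every) > 1e-8 || rec_stride < 1) {
    stop("'record_every' must be a positive multiple of 'dt'", call. = FALSE)
  }
  rec_steps <- seq.int(0L, n_steps, by = rec_stride)
  if (rec_steps[length(rec_steps)] != n_steps) {
    rec_steps <- c(rec_steps, n_steps)
  }
  p <- unclass(params)[.param_names]
  arr <- rk4_batch_cpp(matrix(p, nrow = 1L), as.numeric(ic), n, dt,
                       as.integer(rec_steps), as.integer(n_steps))
  states <- matrix(arr, nrow = length(rec_steps), ncol = 2L * n, byrow = TRUE)
  colnames(states) <- c(paste0("mRNA_", seq_len(n)),
                        paste0("protein_", seq_len(n)))
  structure(list(times = rec_steps * dt, states = states,
                 params = p, n_nuclei = n, dt = dt),
            class = "expression_sim")
}

#' @export
print.expression_sim <- function(x, ...) {
  cat(sprintf("Gene expression simulation: %d nuclei, t in [0, %g] min (%d recorded states)\n",
              x$n_nuclei, max(x$times), length(x$times)))
  cat("Parameters:", paste(sprintf("%s = %g", names(x$params), x$params),
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.expression_sim <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

.spatial_kinds <- c("anterior_nucleus", "middle_nucleus", "posterior_nucleus",
                    "spatial_mean")

#' Scalar model objective: protein output at a location and time
#'
#' @param spatial where protein is read out: one of `"anterior_nucleus"`
#'   (nucleus 1), `"middle_nucleus"` (nucleus `ceiling(n/2)`, i.e. 26 of 52),
#'   `"posterior_nucleus"` (nucleus `n`), or `"spatial_mean"` (mean protein
#'   over all nuclei).
#' @param time analysis time in minutes; must be a recorded simulation time.
#' @return An object of class `objective_spec`.
#' @export
objective_spec <- function(spatial = c("anterior_nucleus", "middle_nucleus",
                                       "posterior_nucleus", "spatial_mean"),
                           time = 4) {
  spatial <- match.arg(spatial)
  stopifnot(is.numeric(time), length(time) == 1L, time >= 0)
  structure(list(spatial = spatial, time = time), class = "objective_spec")
}

.spatial_index <- function(spatial, n) {
  switch(spatial,
         anterior_nucleus = 1L,
         middle_nucleus = as.integer(ceiling(n / 2)),
         posterior_nucleus = as.integer(n),
         spatial_mean = NA_integer_)
}

#' Extract a protein objective from a simulation
#'
#' Reads the protein concentration at the nucleus designated by the
#' objective (or the spatial mean over all nuclei) at the requested time.
#' The time must coincide with a recorded point; no interpolation is done.
#'
#' @param sim an `expression_sim` from [simulate_expression()].
#' @param objective an [objective_spec()].
#' @return A single protein concentration.
#' @export
extract_objective <- function(sim, objective) {
  stopifnot(inherits(sim, "expression_sim"), inherits(objective, "objective_spec"))
  k <- which(abs(sim$times - objective$time) < 1e-9)
  if (length(k) != 1L) {
    stop(sprintf("time %g is not on the recorded output grid (no interpolation)",
                 objective$time), call. = FALSE)
  }
  n <- sim$n_nuclei
  prot <- sim$states[k, n + seq_len(n)]
  if (objective$spatial == "spatial_mean") return(mean(prot))
  prot[[.spatial_index(objective$spatial, n)]]
}
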