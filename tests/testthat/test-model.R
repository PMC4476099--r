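test_that("initial conditions realize the three deposit patterns", {
  expect_equal(initial_condition("ubiquitous", 1, 52),
               rep(1, 104), ignore_attr = TRUE)
  expect_equal(initial_condition("ubiquitous", 0, 52),
               rep(0, 104), ignore_attr = TRUE)
  expect_equal(initial_condition("anterior", 1, 3),
               c(1, 0, 0, 0, 0, 0), ignore_attr = TRUE)
  expect_equal(initial_condition("posterior", 2.5, 4),
               c(0, 0, 0, 2.5, rep(0, 4)), ignore_attr = TRUE)
  expect_error(initial_condition("everywhere", 1, 3), "ubiquitous")
  expect_error(initial_condition("ubiquitous", -1, 3))
})

test_that("derivative implements the reaction-diffusion right-hand side", {
  n <- 3
  zero <- model_parameters()
  state <- c(1, 2, 3, 4, 5, 6)
  expect_equal(expression_derivative(state, zero, n), rep(0, 6))

  # uniform state: diffusion cancels by symmetry
  diff_only <- model_parameters(d = 0.7, delta = 0.3)
  expect_equal(expression_derivative(rep(2, 6), diff_only, n), rep(0, 6))

  # hand-evaluated boundary/interior case: mRNA (1,0,0), d = 0.5
  p <- model_parameters(d = 0.5)
  expect_equal(expression_derivative(c(1, 0, 0, 0, 0, 0), p, n),
               c(-0.5, 0.5, 0, 0, 0, 0))

  # translation couples protein production to local mRNA
  p2 <- model_parameters(tau = 2, gamma = 1)
  expect_equal(expression_derivative(c(3, 0, 0, 0, 1, 0), p2, n),
               c(0, 0, 0, 6, -1, 0))

  expect_error(expression_derivative(c(1, 2), p, n), "length")
})

test_that("RK4 matches the single-compartment closed form at 4th order", {
  p <- model_parameters(sigma = 1, lam = 0.5)
  ic <- c(0, 0)  # one nucleus, no mRNA or protein
  sim <- simulate_expression(ic, p, t_end = 2, dt = 0.01, n_nuclei = 1)
  m_hat <- unname(sim$states[nrow(sim$states), "mRNA_1"])
  expect_equal(m_hat, 2 * (1 - exp(-1)), tolerance = 1e-6)
  expect_lt(abs(m_hat - closed_form_mrna(2, 1, 0.5)), 1e-6)

  err <- vapply(c(0.02, 0.01), function(dt) {
    s <- simulate_expression(ic, p, t_end = 2, dt = dt, record_every = dt,
                             n_nuclei = 1)
    abs(s$states[nrow(s$states), "mRNA_1"] - closed_form_mrna(2, 1, 0.5))
  }, numeric(1))
  ratio <- err[1] / err[2]
  expect_gt(ratio, 8)   # ~2^4 for a 4th-order scheme
  expect_lt(ratio, 32)
})

test_that("zero dynamics preserve the initial state exactly", {
  ic <- initial_condition("ubiquitous", 1, 5)
  sim <- simulate_expression(ic, model_parameters(), t_end = 1, dt = 0.01,
                             n_nuclei = 5)
  expect_true(all(sim$states == 1))
  expect_identical(sim$states[1, ], sim$states[nrow(sim$states), ])
})

test_that("zero-flux diffusion conserves total mRNA and protein", {
  n <- 8
  set.seed(11)
  ic <- c(runif(n, 0, 2), runif(n, 0, 2))
  p <- model_parameters(d = 1.2, delta = 0.8)
  sim <- simulate_expression(ic, p, t_end = 5, dt = 0.01, n_nuclei = n)
  m_tot <- rowSums(sim$states[, seq_len(n)])
  p_tot <- rowSums(sim$states[, n + seq_len(n)])
  expect_lt(max(abs(m_tot - m_tot[1])) / m_tot[1], 1e-8)
  expect_lt(max(abs(p_tot - p_tot[1])) / p_tot[1], 1e-8)
})

test_that("uniform initial conditions reduce to one compartment, independent of diffusion", {
  n <- 6
  ic <- initial_condition("ubiquitous", 0.5, n)
  base <- model_parameters(sigma = 1, lam = 0.4, tau = 0.6, gamma = 0.5)
  diffp <- model_parameters(sigma = 1, d = 1.5, lam = 0.4, tau = 0.6,
                            delta = 1.5, gamma = 0.5)
  s0 <- simulate_expression(ic, base, t_end = 10, n_nuclei = n)
  s1 <- simulate_expression(ic, diffp, t_end = 10, n_nuclei = n)
  expect_lt(max(abs(s0$states - s1$states)), 1e-10)
  # every nucleus traces the same trajectory
  spread <- apply(s1$states[, seq_len(n)], 1, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-10)
  # and it matches the single-compartment run
  s_single <- simulate_expression(c(0.5, 0.5), base, t_end = 10, n_nuclei = 1)
  expect_lt(max(abs(s1$states[, c(1, n + 1)] - s_single$states)), 1e-10)
})

test_that("long-time levels approach sigma/lam and tau*sigma/(lam*gamma)", {
  p <- model_parameters(sigma = 0.8, lam = 0.4, tau = 0.5, gamma = 0.6)
  sim <- simulate_expression(initial_condition("ubiquitous", 1, 2), p,
                             t_end = 200, n_nuclei = 2)
  final <- sim$states[nrow(sim$states), ]
  expect_equal(unname(final[1]), 0.8 / 0.4, tolerance = 1e-3)
  expect_equal(unname(final[3]), 0.5 * 0.8 / (0.4 * 0.6), tolerance = 1e-3)
})

test_that("concentrations stay non-negative for non-negative inputs", {
  set.seed(7)
  for (i in 1:5) {
    p <- model_parameters(sigma = runif(1, 0, 2), d = runif(1, 0, 1.5),
                          lam = runif(1, 0, 0.8), tau = runif(1, 0.1, 1),
                          delta = runif(1, 0, 1.5), gamma = runif(1, 0.4, 0.9))
    ic <- initial_condition(sample(c("ubiquitous", "anterior", "posterior"), 1),
                            runif(1, 0, 1), 10)
    sim <- simulate_expression(ic, p, t_end = 10, n_nuclei = 10)
    expect_gt(min(sim$states), -1e-9)
  }
})

test_that("compiled trajectories agree with the reference derivative", {
  n <- 5
  p <- model_parameters(sigma = 1.2, d = 0.9, lam = 0.3, tau = 0.7,
                        delta = 0.4, gamma = 0.6)
  ic <- initial_condition("anterior", 1, n)
  sim <- simulate_expression(ic, p, t_end = 0.02, dt = 0.01,
                             record_every = 0.01, n_nuclei = n)
  manual <- rk4_step_r(as.numeric(ic), p, n, 0.01)
  manual <- rk4_step_r(manual, p, n, 0.01)
  expect_equal(unname(sim$states[3, ]), manual, tolerance = 1e-12)
})

test_that("objectives read the designated nucleus or the spatial mean", {
  n <- 52
  p <- model_parameters(sigma = 1, d = 0.5, lam = 0.2, tau = 0.5,
                        delta = 0.2, gamma = 0.5)
  sim <- simulate_expression(initial_condition("anterior", 1, n), p,
                             t_end = 2, n_nuclei = n)
  k <- which(sim$times == 2)
  prot <- sim$states[k, n + seq_len(n)]
  expect_identical(extract_objective(sim, objective_spec("middle_nucleus", 2)),
                   unname(prot[26]))
  expect_identical(extract_objective(sim, objective_spec("anterior_nucleus", 2)),
                   unname(prot[1]))
  expect_identical(extract_objective(sim, objective_spec("posterior_nucleus", 2)),
                   unname(prot[52]))
  expect_equal(extract_objective(sim, objective_spec("spatial_mean", 2)),
               mean(prot))
  # protein starts at zero under a maternal deposit
  expect_identical(extract_objective(sim, objective_spec("anterior_nucleus", 0)), 0)
  # uniform protein: the mean is that constant
  s2 <- simulate_expression(initial_condition("ubiquitous", 0.75, 4),
                            model_parameters(), t_end = 1, n_nuclei = 4)
  expect_identical(extract_objective(s2, objective_spec("spatial_mean", 1)), 0.75)
  expect_error(extract_objective(sim, objective_spec("spatial_mean", 0.05)),
               "not on the recorded")
})
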