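# Closed-form single-compartment solutions used as integration oracles.
# mRNA: M' = sigma - lam * M  =>  M(t) = sigma/lam + (M0 - sigma/lam) e^(-lam t)
closed_form_mrna <- function(t, sigma, lam, m0 = 0) {
  if (lam == 0) return(m0 + sigma * t)
  sigma / lam + (m0 - sigma / lam) * exp(-lam * t)
}

# Brute-force ANOVA decomposition of f on a midpoint tensor grid in [0,1]^3.
# Returns first-order indices S_i and pairwise indices S_ij computed from
# grid means, independent of any polynomial expansion.
grid_anova_3d <- function(f, n_grid = 50) {
  u <- (seq_len(n_grid) - 0.5) / n_grid
  g <- expand.grid(u1 = u, u2 = u, u3 = u)
  y <- f(g$u1, g$u2, g$u3)
  f0 <- mean(y)
  D <- mean((y - f0)^2)
  marg <- function(fac) tapply(y, fac, mean) - f0
  m1 <- lapply(list(g$u1, g$u2, g$u3), marg)
  S1 <- vapply(m1, function(m) mean(m^2) / D, numeric(1))
  pair_idx <- list(c(1, 2), c(1, 3), c(2, 3))
  vars <- list(g$u1, g$u2, g$u3)
  S2 <- matrix(0, 3, 3)
  for (p in pair_idx) {
    i <- p[1]; j <- p[2]
    fac <- interaction(vars[[i]], vars[[j]])
    mij <- tapply(y, fac, mean) - f0
    # subtract univariate parts on the pair grid
    mi <- m1[[i]][as.character(tapply(vars[[i]], fac, function(z) z[1]))]
    mj <- m1[[j]][as.character(tapply(vars[[j]], fac, function(z) z[1]))]
    comp <- mij - mi - mj
    S2[i, j] <- S2[j, i] <- mean(comp^2) / D
  }
  list(S1 = S1, S2 = S2, f0 = f0, D = D)
}

# Centered L2 discrepancy (Hickernell) of a design in [0,1]^d, vectorized.
centered_l2_discrepancy <- function(X) {
  n <- nrow(X)
  d <- ncol(X)
  xc <- abs(X - 0.5)
  term1 <- (13 / 12)^d
  prod2 <- apply(1 + 0.5 * xc - 0.5 * xc^2, 1, prod)
  term2 <- 2 / n * sum(prod2)
  acc <- matrix(1, n, n)
  for (k in seq_len(d)) {
    xi <- matrix(X[, k], n, n)
    acc <- acc * (1 + 0.5 * abs(xi - 0.5) + 0.5 * t(abs(xi - 0.5)) -
                    0.5 * abs(xi - t(xi)))
  }
  term3 <- sum(acc) / n^2
  sqrt(term1 - term2 + term3)
}

# One classic RK4 step in plain R from the reference derivative, used to
# cross-check the compiled integrator.
rk4_step_r <- function(state, params, n_nuclei, dt) {
  k1 <- expression_derivative(state, params, n_nuclei)
  k2 <- expression_derivative(state + dt / 2 * k1, params, n_nuclei)
  k3 <- expression_derivative(state + dt / 2 * k2, params, n_nuclei)
  k4 <- expression_derivative(state + dt * k3, params, n_nuclei)
  state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}
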