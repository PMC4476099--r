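#' Orthonormal shifted Legendre polynomials on \[0, 1\]
#'
#' Basis functions used for the HDMR component-function expansions. Degrees
#' 1 to 3 are closed-form; higher degrees are built by the Legendre
#' three-term recurrence and normalized to unit L2 norm on `[0, 1]`.
#'
#' @param u numeric vector in `[0, 1]`.
#' @param degree polynomial degree, a positive integer.
#' @return Numeric vector `phi_degree(u)` with
#'   `int_0^1 phi_p phi_q du = delta_pq`.
#' @export
shifted_legendre <- function(u, degree) {
  stopifnot(degree >= 1, degree == round(degree))
  x <- 2 * u - 1  # map to [-1, 1]
  if (degree == 1) return(sqrt(3) * x)
  if (degree == 2) return(sqrt(5) / 2 * (3 * x^2 - 1))
  if (degree == 3) return(sqrt(7) / 2 * (5 * x^3 - 3 * x))
  p_prev <- rep(1, length(x))
  p <- x
  for (k in 2:degree) {
    p_next <- ((2 * k - 1) * x * p - (k - 1) * p_prev) / k
    p_prev <- p
    p <- p_next
  }
  sqrt(2 * degree + 1) * p
}

#' HDMR variance decomposition of model outputs over a sampling design
#'
#' Decomposes the output `f(u)` of a model sampled on the unit hypercube into
#' a mean, univariate and bivariate component functions,
#' `f = f0 + sum_i f_i(u_i) + sum_{i<j} f_ij(u_i, u_j) + ...`,
#' with each component expanded in orthonormal shifted Legendre polynomials.
#' Expansion coefficients are estimated by (quasi) Monte Carlo projection:
#' `alpha_r^i = mean((f - f0) * phi_r(u_i))` for first-order terms and, after
#' subtracting the fitted first-order parts to prevent leakage,
#' `beta_pq^ij = mean(resid * phi_p(u_i) * phi_q(u_j))` for pairs. Sensitivity
#' indices are the component variances normalized by the total output
#' variance: `S_i = sum_r (alpha_r^i)^2 / D` and
#' `S_ij = sum_pq (beta_pq^ij)^2 / D`.
#'
#' When the outputs carry (numerically) zero variance -- e.g. a model read
#' out at time zero, where every parameter set returns the initial condition
#' -- all indices are defined as zero.
#'
#' @param design a `sobol_design` (its `unit` matrix is used) or a plain
#'   numeric matrix of unit-hypercube coordinates.
#' @param outputs numeric vector of model outputs, one per design row.
#' @param degree maximum polynomial degree of the expansions (default 3).
#' @param include_second_order estimate pairwise terms (default `TRUE`).
#' @param backend `"projection"` (Monte Carlo projection, default) or
#'   `"least_squares"` (per-dimension ridge-free least squares fit of the
#'   first-order basis; pairwise terms still by projection on the residual).
#' @return An object of class `hdmr_result`: a list with `f0` (mean output),
#'   `variance` (total variance, denominator of all indices), `first_order`
#'   (named vector of `S_i`), `second_order` (symmetric matrix of `S_ij`,
#'   zero diagonal), `totals` (`S_i + sum_j S_ij` per parameter),
#'   `coefficients` (list with `alpha`, degree x p, and `beta`, a list keyed
#'   `"i:j"`), `n_samples` and `degree`.
#' @examples
#' u <- sobol_sequence(2048, 2)
#' h <- hdmr_decompose(u, u[, 1] * u[, 2])
#' h$first_order  # ~ 3/7 each
#' @export
hdmr_decompose <- function(design, outputs, degree = 3L,
                           include_second_order = TRUE,
                           backend = c("projection", "least_squares")) {
  backend <- match.arg(backend)
  U <- if (inherits(design, "sobol_design")) design$unit else as.matrix(design)
  if (nrow(U) != length(outputs)) {
    stop("'outputs' must have one value per design row", call. = FALSE)
  }
  if (any(!is.finite(outputs))) {
    stop("non-finite model outputs at rows: ",
         paste(utils::head(which(!is.finite(outputs)), 5L), collapse = ", "),
         call. = FALSE)
  }
  degree <- as.integer(degree)
  if (degree < 1L || degree >= nrow(U)) {
    stop("'degree' must be >= 1 and smaller than the design size",
         call. = FALSE)
  }
  N <- nrow(U)
  p <- ncol(U)
  pnames <- colnames(U)
  if (is.null(pnames)) pnames <- paste0("x", seq_len(p))

  f0 <- mean(outputs)
  yc <- outputs - f0
  D <- mean(yc^2)

  empty <- function() {
    s1 <- stats::setNames(numeric(p), pnames)
    s2 <- matrix(0, p, p, dimnames = list(pnames, pnames))
    structure(list(f0 = f0, variance = D, first_order = s1, second_order = s2,
                   totals = s1, coefficients = list(alpha = NULL, beta = NULL),
                   n_samples = N, degree = degree),
              class = "hdmr_result")
  }
  if (D <= 1e-12 * (1 + f0^2)) return(empty())

  # per-parameter basis matrices, N x degree
  B <- lapply(seq_len(p), function(j) {
    vapply(seq_len(degree), function(r) shifted_legendre(U[, j], r),
           numeric(N))
  })

  alpha <- matrix(0, degree, p, dimnames = list(NULL, pnames))
  for (j in seq_len(p)) {
    alpha[, j] <- if (backend == "projection") {
      crossprod(B[[j]], yc) / N
    } else {
      stats::lsfit(B[[j]], yc, intercept = FALSE)$coefficients
    }
  }
  first_order <- stats::setNames(pmax(colSums(alpha^2), 0) / D, pnames)

  second_order <- matrix(0, p, p, dimnames = list(pnames, pnames))
  beta <- NULL
  if (include_second_order) {
    fit1 <- matrix(0, N, p)
    for (j in seq_len(p)) fit1[, j] <- B[[j]] %*% alpha[, j]
    resid <- yc - rowSums(fit1)
    beta <- list()
    for (i in seq_len(p - 1L)) {
      for (j in (i + 1L):p) {
        bij <- crossprod(B[[i]], resid * B[[j]]) / N  # degree x degree
        beta[[paste(pnames[i], pnames[j], sep = ":")]] <- bij
        s <- sum(bij^2) / D
        second_order[i, j] <- s
        second_order[j, i] <- s
      }
    }
  }
  totals <- first_order + rowSums(second_order)
  structure(list(f0 = f0, variance = D, first_order = first_order,
                 second_order = second_order, totals = totals,
                 coefficients = list(alpha = alpha, beta = beta),
                 n_samples = N, degree = degree),
            class = "hdmr_result")
}

#' @export
print.hdmr_result <- function(x, digits = 3, ...) {
  cat(sprintf("HDMR decomposition (N = %d, degree %d)\n", x$n_samples,
              x$degree))
  cat(sprintf("  mean output f0 = %.4g, total variance D = %.4g\n",
              x$f0, x$variance))
  cat("  first-order indices:\n")
  print(round(x$first_order, digits))
  s2 <- sum(x$second_order[upper.tri(x$second_order)])
  cat(sprintf("  sum S_i = %.*f, sum S_ij = %.*f\n", digits,
              sum(x$first_order), digits, s2))
  invisible(x)
}

#' Share of model sensitivity captured at first and second order
#'
#' Summarizes how the output variance splits across orders of the HDMR
#' expansion: `first_order_share` is the sum of all first-order indices,
#' `first_plus_second_share` additionally includes all pairwise indices
#' (each unordered pair counted once), and `max_pairwise_share_of_total` is
#' the largest share, over parameters, of total (first-plus-second-order)
#' model sensitivity contributed by that parameter's pairwise terms,
#' `max_i sum_j S_ij / (sum_k S_k + sum_{k<l} S_kl)`, with `0/0` defined
#' as 0.
#'
#' @param result an [hdmr_decompose()] result with second-order terms.
#' @return A list with `first_order_share`, `first_plus_second_share` and
#'   `max_pairwise_share_of_total`.
#' @export
sensitivity_budget <- function(result) {
  stopifnot(inherits(result, "hdmr_result"))
  s1 <- sum(result$first_order)
  s2 <- sum(result$second_order[upper.tri(result$second_order)])
  total <- s1 + s2
  pairwise <- rowSums(result$second_order)
  max_share <- if (total > 0) max(pairwise) / total else 0
  list(first_order_share = s1,
       first_plus_second_share = total,
       max_pairwise_share_of_total = max_share)
}
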