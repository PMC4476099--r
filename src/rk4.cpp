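#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Rate of change of the full state for a batch of parameter sets.
// Y is N x 2n (rows = parameter sets, cols = state components: mRNA 1..n,
// protein n+1..2n). Zero-flux boundaries: end nuclei exchange with their
// single neighbour only.
static void deriv_batch(const arma::mat& Y, arma::mat& dY, const int n,
                        const arma::vec& sigma, const arma::vec& d,
                        const arma::vec& lam, const arma::vec& tau,
                        const arma::vec& del, const arma::vec& gam) {
  if (n == 1) {
    dY.col(0) = sigma - lam % Y.col(0);
    dY.col(1) = tau % Y.col(0) - gam % Y.col(1);
    return;
  }
  // mRNA block
  dY.col(0) = sigma + d % (Y.col(1) - Y.col(0)) - lam % Y.col(0);
  for (int j = 1; j < n - 1; ++j) {
    dY.col(j) = sigma + d % (Y.col(j + 1) + Y.col(j - 1) - 2.0 * Y.col(j))
                - lam % Y.col(j);
  }
  dY.col(n - 1) = sigma + d % (Y.col(n - 2) - Y.col(n - 1)) - lam % Y.col(n - 1);
  // protein block
  dY.col(n) = tau % Y.col(0) + del % (Y.col(n + 1) - Y.col(n)) - gam % Y.col(n);
  for (int j = 1; j < n - 1; ++j) {
    dY.col(n + j) = tau % Y.col(j)
                    + del % (Y.col(n + j + 1) + Y.col(n + j - 1) - 2.0 * Y.col(n + j))
                    - gam % Y.col(n + j);
  }
  dY.col(2 * n - 1) = tau % Y.col(n - 1)
                      + del % (Y.col(2 * n - 2) - Y.col(2 * n - 1))
                      - gam % Y.col(2 * n - 1);
}

// Fixed-step classic RK4 for a batch of parameter sets sharing one initial
// condition. params is N x 6 (sigma, d, lam, tau, delta, gamma); ic has
// length 2*n_nuclei. record_steps are step indices (0 = initial state) at
// which the full state is stored. Returns an array of dim (N, 2n, length(record_steps)).
// [[Rcpp::export]]
NumericVector rk4_batch_cpp(const NumericMatrix& params, const NumericVector& ic,
                            const int n_nuclei, const double dt,
                            const IntegerVector& record_steps, const int n_steps) {
  const int N = params.nrow();
  const int m = 2 * n_nuclei;
  const int T = record_steps.size();
  if (params.ncol() != 6) stop("'params' must have 6 columns");
  if (ic.size() != m) stop("initial condition must have length 2 * n_nuclei");

  const arma::mat P(const_cast<double*>(params.begin()), N, 6, false, true);
  const arma::vec sigma = P.col(0), d = P.col(1), lam = P.col(2);
  const arma::vec tau = P.col(3), del = P.col(4), gam = P.col(5);

  arma::mat Y(N, m);
  for (int j = 0; j < m; ++j) Y.col(j).fill(ic[j]);

  arma::mat k1(N, m), k2(N, m), k3(N, m), k4(N, m), Yt(N, m);

  NumericVector out(static_cast<R_xlen_t>(N) * m * T);
  out.attr("dim") = IntegerVector::create(N, m, T);

  int next_rec = 0;
  auto record = [&](int step) {
    while (next_rec < T && record_steps[next_rec] == step) {
      if (!Y.is_finite()) {
        arma::uvec bad = arma::find_nonfinite(Y.col(0));
        // locate first offending row across all columns
        int row = -1;
        for (int i = 0; i < N && row < 0; ++i)
          if (!Y.row(i).is_finite()) row = i;
        stop("non-finite state at step %d (t = %.4f) for parameter set %d",
             step, step * dt, row + 1);
      }
      double* dst = out.begin() + static_cast<R_xlen_t>(next_rec) * N * m;
      std::copy(Y.begin(), Y.end(), dst);
      ++next_rec;
    }
  };

  record(0);
  const double h2 = dt / 2.0, h6 = dt / 6.0;
  for (int s = 1; s <= n_steps && next_rec < T; ++s) {
    deriv_batch(Y, k1, n_nuclei, sigma, d, lam, tau, del, gam);
    Yt = Y + h2 * k1;
    deriv_batch(Yt, k2, n_nuclei, sigma, d, lam, tau, del, gam);
    Yt = Y + h2 * k2;
    deriv_batch(Yt, k3, n_nuclei, sigma, d, lam, tau, del, gam);
    Yt = Y + dt * k3;
    deriv_batch(Yt, k4, n_nuclei, sigma, d, lam, tau, del, gam);
    Y += h6 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    record(s);
  }
  return out;
}
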