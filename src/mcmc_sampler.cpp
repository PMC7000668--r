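#include <Rcpp.h>
using namespace Rcpp;

// Adaptive Metropolis-within-Gibbs for the Bernoulli-logit occurrence model
// with optional crossed random intercepts (site pair, species) and
// variance hyperparameters r with prior density proportional to r^-2 on
// (r_lower, Inf).  Blocks: each fixed effect (scalar random walk), each
// random intercept (scalar random walk over its own rows only), each
// variance (reflected random walk on log r).  Proposal scales adapt toward
// a target acceptance rate during the burn-in iterations only, so the
// retained draws come from a fixed-kernel chain.

static inline double log1pexp_c(double x) {
  return (x > 30.0) ? x : std::log1p(std::exp(x));
}

// change in Bernoulli-logit log likelihood when eta[rows] shifts by
// delta * w[rows] (w = covariate column, or implicit 1 for intercepts)
static double delta_loglik(const IntegerVector& y, const NumericVector& eta,
                           const std::vector<int>& rows,
                           const NumericMatrix& X, int col, double delta) {
  double d = 0.0;
  for (size_t k = 0; k < rows.size(); ++k) {
    int i = rows[k];
    double step = (col >= 0) ? delta * X(i, col) : delta;
    double e_new = eta[i] + step;
    d += y[i] * step - log1pexp_c(e_new) + log1pexp_c(eta[i]);
  }
  return d;
}

static void apply_shift(NumericVector& eta, const std::vector<int>& rows,
                        const NumericMatrix& X, int col, double delta) {
  for (size_t k = 0; k < rows.size(); ++k) {
    int i = rows[k];
    eta[i] += (col >= 0) ? delta * X(i, col) : delta;
  }
}

struct Adapter {
  double ls;        // log proposal scale
  long t;           // proposals seen during adaptation
  long acc, tries;  // post-burn-in acceptance bookkeeping
  Adapter(double scale) : ls(std::log(scale)), t(0), acc(0), tries(0) {}
  double scale() const { return std::exp(ls); }
  void adapt(bool accepted, double target) {
    ++t;
    double step = std::min(0.25, 5.0 / std::sqrt((double)t));
    ls += (accepted ? 1.0 - target : -target) * step;
    ls = std::min(std::max(ls, -15.0), 15.0);
  }
  void record(bool accepted) { ++tries; if (accepted) ++acc; }
};

// [[Rcpp::export]]
List mcmc_chain_cpp(IntegerVector y, NumericMatrix X,
                    IntegerVector pair_index, IntegerVector species_index,
                    int n_pair, int n_species,
                    NumericVector beta0, NumericVector u0, NumericVector v0,
                    double r_pair0, double r_species0,
                    NumericMatrix beta_prec, double r_lower,
                    int n_iter, int thin, int n_burn_iter, int n_retain,
                    double target_accept, NumericVector beta_scale0) {
  const int n = y.size(), p = X.ncol();
  const bool has_pair = n_pair > 0, has_species = n_species > 0;

  // row lists per random-effect level (indices are 1-based from R)
  std::vector< std::vector<int> > pair_rows(std::max(n_pair, 0));
  std::vector< std::vector<int> > species_rows(std::max(n_species, 0));
  std::vector<int> all_rows(n);
  for (int i = 0; i < n; ++i) {
    all_rows[i] = i;
    if (has_pair) pair_rows[pair_index[i] - 1].push_back(i);
    if (has_species) species_rows[species_index[i] - 1].push_back(i);
  }

  NumericVector beta = clone(beta0), u = clone(u0), v = clone(v0);
  // running prior gradient: Pb = beta_prec %*% beta (Gaussian prior may be
  // correlated when the design has been linearly reparametrized in R)
  std::vector<double> Pb(p, 0.0);
  for (int j = 0; j < p; ++j)
    for (int k = 0; k < p; ++k) Pb[j] += beta_prec(j, k) * beta[k];
  double log_r_pair = has_pair ? std::log(r_pair0) : 0.0;
  double log_r_species = has_species ? std::log(r_species0) : 0.0;
  const double log_r_floor = std::log(r_lower);

  NumericVector eta(n);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    if (has_pair) e += u[pair_index[i] - 1];
    if (has_species) e += v[species_index[i] - 1];
    eta[i] = e;
  }
  double ss_u = 0.0, ss_v = 0.0;
  for (int j = 0; j < n_pair; ++j) ss_u += u[j] * u[j];
  for (int k = 0; k < n_species; ++k) ss_v += v[k] * v[k];

  std::vector<Adapter> beta_ad, u_ad, v_ad;
  for (int j = 0; j < p; ++j) beta_ad.push_back(Adapter(beta_scale0[j]));
  for (int j = 0; j < n_pair; ++j) u_ad.push_back(Adapter(1.0));
  for (int k = 0; k < n_species; ++k) v_ad.push_back(Adapter(1.0));
  Adapter rp_ad(1.0), rs_ad(1.0);

  const int n_col = p + n_pair + n_species + (has_pair ? 1 : 0) +
                    (has_species ? 1 : 0);
  NumericMatrix draws(n_retain, n_col);
  int stored = 0;

  for (int it = 1; it <= n_iter; ++it) {
    const bool adapting = it <= n_burn_iter;

    // fixed effects: scalar random-walk MH, full-likelihood delta
    for (int j = 0; j < p; ++j) {
      double d = R::rnorm(0.0, beta_ad[j].scale());
      double logr = delta_loglik(y, eta, all_rows, X, j, d)
        - (d * Pb[j] + 0.5 * d * d * beta_prec(j, j));
      bool acc = std::log(R::runif(0.0, 1.0)) < logr;
      if (acc) {
        apply_shift(eta, all_rows, X, j, d);
        beta[j] += d;
        for (int k = 0; k < p; ++k) Pb[k] += beta_prec(k, j) * d;
      }
      if (adapting) beta_ad[j].adapt(acc, target_accept);
      else beta_ad[j].record(acc);
    }

    // pair random intercepts
    if (has_pair) {
      double r = std::exp(log_r_pair);
      for (int j = 0; j < n_pair; ++j) {
        double d = R::rnorm(0.0, u_ad[j].scale());
        double logr = delta_loglik(y, eta, pair_rows[j], X, -1, d)
          - ((u[j] + d) * (u[j] + d) - u[j] * u[j]) / (2.0 * r);
        bool acc = std::log(R::runif(0.0, 1.0)) < logr;
        if (acc) {
          apply_shift(eta, pair_rows[j], X, -1, d);
          ss_u += (u[j] + d) * (u[j] + d) - u[j] * u[j];
          u[j] += d;
        }
        if (adapting) u_ad[j].adapt(acc, target_accept);
        else u_ad[j].record(acc);
      }
      // variance: reflected random walk on log r; target in log space is
      // -(1 + J/2) log r - SS/(2r)  (r^-2 prior + Normal + Jacobian)
      {
        double z = log_r_pair + R::rnorm(0.0, rp_ad.scale());
        while (z < log_r_floor) z = 2.0 * log_r_floor - z;
        double f_new = -(1.0 + n_pair / 2.0) * z - ss_u / (2.0 * std::exp(z));
        double f_old = -(1.0 + n_pair / 2.0) * log_r_pair -
          ss_u / (2.0 * std::exp(log_r_pair));
        bool acc = std::log(R::runif(0.0, 1.0)) < f_new - f_old;
        if (acc) log_r_pair = z;
        if (adapting) rp_ad.adapt(acc, target_accept);
        else rp_ad.record(acc);
      }
    }

    // species random intercepts
    if (has_species) {
      double r = std::exp(log_r_species);
      for (int k = 0; k < n_species; ++k) {
        double d = R::rnorm(0.0, v_ad[k].scale());
        double logr = delta_loglik(y, eta, species_rows[k], X, -1, d)
          - ((v[k] + d) * (v[k] + d) - v[k] * v[k]) / (2.0 * r);
        bool acc = std::log(R::runif(0.0, 1.0)) < logr;
        if (acc) {
          apply_shift(eta, species_rows[k], X, -1, d);
          ss_v += (v[k] + d) * (v[k] + d) - v[k] * v[k];
          v[k] += d;
        }
        if (adapting) v_ad[k].adapt(acc, target_accept);
        else v_ad[k].record(acc);
      }
      {
        double z = log_r_species + R::rnorm(0.0, rs_ad.scale());
        while (z < log_r_floor) z = 2.0 * log_r_floor - z;
        double f_new = -(1.0 + n_species / 2.0) * z -
          ss_v / (2.0 * std::exp(z));
        double f_old = -(1.0 + n_species / 2.0) * log_r_species -
          ss_v / (2.0 * std::exp(log_r_species));
        bool acc = std::log(R::runif(0.0, 1.0)) < f_new - f_old;
        if (acc) log_r_species = z;
        if (adapting) rs_ad.adapt(acc, target_accept);
        else rs_ad.record(acc);
      }
    }

    if (it > n_burn_iter && (it - n_burn_iter) % thin == 0 &&
        stored < n_retain) {
      int c = 0;
      for (int j = 0; j < p; ++j) draws(stored, c++) = beta[j];
      for (int j = 0; j < n_pair; ++j) draws(stored, c++) = u[j];
      for (int k = 0; k < n_species; ++k) draws(stored, c++) = v[k];
      if (has_pair) draws(stored, c++) = std::exp(log_r_pair);
      if (has_species) draws(stored, c++) = std::exp(log_r_species);
      ++stored;
    }
  }

  auto rate = [](const std::vector<Adapter>& v) {
    long a = 0, t = 0;
    for (const Adapter& x : v) { a += x.acc; t += x.tries; }
    return t > 0 ? (double)a / t : NA_REAL;
  };
  NumericVector accept = NumericVector::create(
    _["beta"] = rate(beta_ad),
    _["u"] = has_pair ? rate(u_ad) : NA_REAL,
    _["v"] = has_species ? rate(v_ad) : NA_REAL,
    _["r_pair"] = (has_pair && rp_ad.tries > 0)
      ? (double)rp_ad.acc / rp_ad.tries : NA_REAL,
    _["r_species"] = (has_species && rs_ad.tries > 0)
      ? (double)rs_ad.acc / rs_ad.tries : NA_REAL);

  return List::create(_["draws"] = draws, _["n_stored"] = stored,
                      _["accept"] = accept);
}
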