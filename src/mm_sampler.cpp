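// Data-augmented MCMC for the many-to-many mixed stock model.
//
// Latent structure: each mixed-stock individual i carries a source label
// z_i; given (phi, f) the z are conditionally independent categoricals,
// given z the baseline frequencies f are conjugate Dirichlet, and the
// rookery-centric dispersal rows phi are updated one at a time by
// Metropolis-within-Gibbs with a Dirichlet proposal centred on the current
// row (the size-weighted theta transform couples rows through the
// denominator, which breaks conjugacy for phi).  Proposal concentration is
// adapted during burn-in only, so the post-burn-in kernel is fixed.
//
// All randomness goes through R's RNG, so set.seed() in the caller gives
// bit-for-bit reproducible chains.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double rgamma_pos(double shape) {
  double g = R::rgamma(shape, 1.0);
  // guard against underflow at tiny shapes; statistically invisible floor
  return (g < 1e-300) ? 1e-300 : g;
}

static void dirichlet_draw(const std::vector<double> &shape,
                           std::vector<double> &out) {
  const int n = (int)shape.size();
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    out[i] = rgamma_pos(shape[i]);
    s += out[i];
  }
  for (int i = 0; i < n; ++i) out[i] /= s;
}

// sequential conditional binomial multinomial draw (same scheme as R's
// rmultinom); probs need not be normalized
static void multinom_draw(int n, const std::vector<double> &w, double wsum,
                          std::vector<int> &out) {
  const int k = (int)w.size();
  int remaining = n;
  double rem_p = wsum;
  for (int i = 0; i < k; ++i) out[i] = 0;
  for (int i = 0; i < k - 1; ++i) {
    if (remaining <= 0) break;
    if (rem_p <= 0.0) break;
    double p = w[i] / rem_p;
    if (p > 1.0) p = 1.0;
    if (p < 0.0) p = 0.0;
    int draw = (int)R::rbinom((double)remaining, p);
    out[i] = draw;
    remaining -= draw;
    rem_p -= w[i];
  }
  if (remaining > 0) out[k - 1] += remaining;
}

static inline double safe_log(double x) {
  return std::log(x < 1e-300 ? 1e-300 : x);
}

// [[Rcpp::export(name = ".mm_chain_cpp")]]
List mm_chain_cpp(const IntegerMatrix X,     // R x H baseline counts
                  const IntegerMatrix Y,     // M x H mixed counts
                  const NumericVector N,     // R rookery sizes
                  const NumericMatrix alpha, // R x (M+1) prior
                  const double beta,         // per-haplotype prior mass
                  const int iterations, const int burn_in,
                  const NumericMatrix phi0,  // R x (M+1) init
                  const NumericMatrix f0,    // R x H init
                  const double kappa0, const bool update_f,
                  const bool store_f) {
  const int R = X.nrow(), H = X.ncol(), M = Y.nrow();
  const int D = M + 1;
  const int n_keep = iterations - burn_in;

  std::vector<double> phi(R * D), f(R * H);
  for (int r = 0; r < R; ++r)
    for (int d = 0; d < D; ++d) phi[r + R * d] = phi0(r, d);
  for (int r = 0; r < R; ++r)
    for (int h = 0; h < H; ++h) f[r + R * h] = f0(r, h);

  std::vector<double> theta(M * R);     // theta[m + M*r]
  std::vector<double> denom(M);
  std::vector<int> czm(M * R);          // latent-source counts per stock
  std::vector<int> arh(R * H);          // latent counts per rookery x hap
  std::vector<int> Cm(M);               // stock sample sizes
  for (int m = 0; m < M; ++m) {
    int s = 0;
    for (int h = 0; h < H; ++h) s += Y(m, h);
    Cm[m] = s;
  }

  std::vector<double> kappa(R, kappa0);
  std::vector<int> acc_win(R, 0), acc_tot(R, 0), rw_try(R, 0);
  std::vector<double> w(R), prop(D), shape(D), fshape(H), frow(H);
  std::vector<int> zdraw(R);

  NumericMatrix phi_out(n_keep, R * D);
  NumericMatrix f_out(store_f ? n_keep : 1, store_f ? R * H : 1);

  for (int iter = 0; iter < iterations; ++iter) {
    // ---- theta from current phi ----
    for (int m = 0; m < M; ++m) {
      double dsum = 0.0;
      for (int r = 0; r < R; ++r) dsum += N[r] * phi[r + R * m];
      denom[m] = dsum;
      for (int r = 0; r < R; ++r)
        theta[m + M * r] = (dsum > 0.0) ? N[r] * phi[r + R * m] / dsum
                                        : N[r];
    }

    // ---- z step: latent source assignments, cell by cell ----
    std::fill(czm.begin(), czm.end(), 0);
    std::fill(arh.begin(), arh.end(), 0);
    for (int m = 0; m < M; ++m) {
      for (int h = 0; h < H; ++h) {
        int y = Y(m, h);
        if (y == 0) continue;
        double wsum = 0.0;
        for (int r = 0; r < R; ++r) {
          w[r] = theta[m + M * r] * f[r + R * h];
          wsum += w[r];
        }
        if (wsum <= 0.0) {            // degenerate; fall back to theta
          wsum = 0.0;
          for (int r = 0; r < R; ++r) { w[r] = theta[m + M * r]; wsum += w[r]; }
          if (wsum <= 0.0) { for (int r = 0; r < R; ++r) w[r] = 1.0; wsum = R; }
        }
        multinom_draw(y, w, wsum, zdraw);
        for (int r = 0; r < R; ++r) {
          czm[m + M * r] += zdraw[r];
          arh[r + R * h] += zdraw[r];
        }
      }
    }

    // ---- f step: conjugate Dirichlet per rookery ----
    for (int r = 0; r < R; ++r) {
      for (int h = 0; h < H; ++h)
        fshape[h] = beta + X(r, h) + (update_f ? arh[r + R * h] : 0);
      dirichlet_draw(fshape, frow);
      for (int h = 0; h < H; ++h) f[r + R * h] = frow[h];
    }

    // ---- phi step: Metropolis-within-Gibbs per rookery row ----
    for (int m = 0; m < M; ++m) {
      double dsum = 0.0;
      for (int r = 0; r < R; ++r) dsum += N[r] * phi[r + R * m];
      denom[m] = dsum;
    }
    for (int r = 0; r < R; ++r) {
      // Two MH kernels, mixed at random, both with stationary conditional
      // p(phi_r | z):
      //  (a) independence proposal from Dirichlet(alpha_r + assigned
      //      counts), under which the prior and phi^c terms cancel
      //      analytically, leaving only the size-weighted denominator
      //      ratio -- robust near the simplex boundary;
      //  (b) adaptive Dirichlet random walk centred on the current row --
      //      efficient local moves for strongly informed (dominant)
      //      rookeries where the denominator term matters.
      bool indep = (unif_rand() < 0.5);
      double delta = 0.0;
      if (indep) {
        for (int d = 0; d < D; ++d)
          shape[d] = alpha(r, d) + ((d < M) ? czm[d + M * r] : 0);
        dirichlet_draw(shape, prop);
        for (int m = 0; m < M; ++m) {
          if (Cm[m] == 0) continue;
          double dnew = denom[m] + N[r] * (prop[m] - phi[r + R * m]);
          delta -= Cm[m] * (safe_log(dnew) - safe_log(denom[m]));
        }
      } else {
        // proposal offset = prior mass: for components near the simplex
        // boundary the Hastings term then cancels the prior term exactly,
        // so tiny-mass components refresh from their prior shape instead
        // of freezing
        for (int d = 0; d < D; ++d)
          shape[d] = kappa[r] * phi[r + R * d] + alpha(r, d);
        dirichlet_draw(shape, prop);
        for (int d = 0; d < D; ++d) {
          double lc = safe_log(phi[r + R * d]), lpv = safe_log(prop[d]);
          // prior
          delta += (alpha(r, d) - 1.0) * (lpv - lc);
          // Hastings (normalizing lgamma(sum) terms cancel: same kappa)
          double sp = kappa[r] * prop[d] + alpha(r, d);
          double sc = kappa[r] * phi[r + R * d] + alpha(r, d);
          delta += -R::lgammafn(sp) + (sp - 1.0) * lc;
          delta -= -R::lgammafn(sc) + (sc - 1.0) * lpv;
        }
        // likelihood of latent counts through theta
        for (int m = 0; m < M; ++m) {
          if (Cm[m] == 0) continue;
          double lc = safe_log(phi[r + R * m]), lpv = safe_log(prop[m]);
          delta += czm[m + M * r] * (lpv - lc);
          double dnew = denom[m] + N[r] * (prop[m] - phi[r + R * m]);
          delta -= Cm[m] * (safe_log(dnew) - safe_log(denom[m]));
        }
      }
      if (!indep) rw_try[r] += 1;
      if (std::log(unif_rand()) < delta) {
        for (int m = 0; m < M; ++m)
          denom[m] += N[r] * (prop[m] - phi[r + R * m]);
        for (int d = 0; d < D; ++d) phi[r + R * d] = prop[d];
        if (!indep) acc_win[r] += 1;
        acc_tot[r] += 1;
      }
    }

    // ---- random-walk proposal adaptation, burn-in only ----
    if (iter < burn_in && (iter + 1) % 100 == 0) {
      for (int r = 0; r < R; ++r) {
        if (rw_try[r] >= 10) {
          double rate = acc_win[r] / (double)rw_try[r];
          if (rate < 0.20) kappa[r] *= 1.5;
          else if (rate > 0.50) kappa[r] /= 1.5;
          if (kappa[r] < 5.0) kappa[r] = 5.0;
          if (kappa[r] > 1e7) kappa[r] = 1e7;
        }
        acc_win[r] = 0;
        rw_try[r] = 0;
      }
    }

    // ---- store ----
    if (iter >= burn_in) {
      int row = iter - burn_in;
      for (int j = 0; j < R * D; ++j) phi_out(row, j) = phi[j];
      if (store_f)
        for (int j = 0; j < R * H; ++j) f_out(row, j) = f[j];
    }
  }

  NumericVector acc(R);
  for (int r = 0; r < R; ++r) acc[r] = acc_tot[r] / (double)iterations;
  List out = List::create(_["phi"] = phi_out,
                          _["accept"] = acc,
                          _["kappa"] = NumericVector(kappa.begin(), kappa.end()));
  if (store_f) out["f"] = f_out;
  return out;
}

// Classic many-to-one Dirichlet-multinomial mixture sampler: fully
// conjugate Gibbs on (z, theta, f) for a single mixed stock.
// [[Rcpp::export(name = ".m1_chain_cpp")]]
List m1_chain_cpp(const IntegerMatrix X,    // R x H baseline counts
                  const IntegerVector y,    // H mixed counts, one stock
                  const NumericVector prior,// R Dirichlet prior on theta
                  const double beta,
                  const int iterations, const int burn_in,
                  const NumericVector theta0,
                  const NumericMatrix f0,
                  const bool update_f) {
  const int R = X.nrow(), H = X.ncol();
  const int n_keep = iterations - burn_in;

  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> f(R * H);
  for (int r = 0; r < R; ++r)
    for (int h = 0; h < H; ++h) f[r + R * h] = f0(r, h);

  std::vector<int> nz(R), arh(R * H), zdraw(R);
  std::vector<double> w(R), tshape(R), fshape(H), frow(H);
  NumericMatrix theta_out(n_keep, R);

  for (int iter = 0; iter < iterations; ++iter) {
    std::fill(nz.begin(), nz.end(), 0);
    std::fill(arh.begin(), arh.end(), 0);
    for (int h = 0; h < H; ++h) {
      if (y[h] == 0) continue;
      double wsum = 0.0;
      for (int r = 0; r < R; ++r) {
        w[r] = theta[r] * f[r + R * h];
        wsum += w[r];
      }
      if (wsum <= 0.0) {
        for (int r = 0; r < R; ++r) w[r] = theta[r];
        wsum = 1.0;
      }
      multinom_draw(y[h], w, wsum, zdraw);
      for (int r = 0; r < R; ++r) {
        nz[r] += zdraw[r];
        arh[r + R * h] += zdraw[r];
      }
    }
    for (int r = 0; r < R; ++r) tshape[r] = prior[r] + nz[r];
    dirichlet_draw(tshape, theta);
    for (int r = 0; r < R; ++r) {
      for (int h = 0; h < H; ++h)
        fshape[h] = beta + X(r, h) + (update_f ? arh[r + R * h] : 0);
      dirichlet_draw(fshape, frow);
      for (int h = 0; h < H; ++h) f[r + R * h] = frow[h];
    }
    if (iter >= burn_in) {
      int row = iter - burn_in;
      for (int r = 0; r < R; ++r) theta_out(row, r) = theta[r];
    }
  }
  return List::create(_["theta"] = theta_out);
}
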