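// Componentwise adaptive random-walk Metropolis (Metropolis-within-Gibbs)
// for the two-level binomial-logit model. Every scalar - fixed effects,
// variance components (on the sigma^2 scale, reflected at the uniform-prior
// bounds) and latent effects - gets its own random-walk proposal whose step
// size is tuned toward ~0.44 acceptance during burn-in only, then frozen so
// detailed balance holds for the kept draws.
//
// The linear predictor and per-record log-likelihood terms are cached and
// updated incrementally: a proposal only re-evaluates the records it touches
// (all records for a fixed effect, one date/population group for gamma or
// omega, a single record for eps). The binomial-coefficient constant cancels
// in every Metropolis ratio and is omitted here.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline double log1p_exp(double x) {
  if (x > 0.0) return x + log1p(std::exp(-x));
  return log1p(std::exp(x));
}

// binomial log-likelihood term without the constant: y*eta - n*log(1+e^eta)
static inline double ll_term(double y, double n, double eta) {
  return y * eta - n * log1p_exp(eta);
}

// In addition to the one-scalar updates, the sampler makes "compensated"
// moves that shift a fixed effect and counter-shift a latent block so the
// linear predictor (hence the likelihood) is unchanged: for a design column
// that is constant within population (or date) groups, beta_m += delta and
// omega_j -= delta * x_j (gamma_k likewise); with the observation-level
// overdispersion term present, any column can be compensated through eps.
// Only the normal priors enter those Metropolis ratios, which breaks the
// strong posterior coupling between intercept-like effects and their
// random-effect blocks that otherwise cripples componentwise mixing.

// [[Rcpp::export]]
List mwg_sampler(IntegerVector y, IntegerVector n, NumericMatrix X,
                 IntegerVector date_id, IntegerVector pop_id,
                 int K, int J, bool use_eps,
                 double coef_var, double var_upper,
                 int n_iter, int n_burn, int thin,
                 NumericVector init, NumericVector init_step,
                 int adapt_interval,
                 IntegerVector pop_cols, NumericMatrix Vpop,
                 IntegerVector date_cols, NumericMatrix Vdate,
                 bool eps_comp) {
  const int N = y.size();
  const int P_fix = X.ncol();
  const int idx_s2 = P_fix;              // sigma2_gamma, sigma2_eps, sigma2_omega
  const int G0 = P_fix + 3;
  const int NE = use_eps ? N : 0;
  const int E0 = G0 + K;
  const int O0 = E0 + NE;
  const int P_total = O0 + J;
  const int n_pc = pop_cols.size();
  const int n_dc = date_cols.size();
  const int n_ec = eps_comp ? P_fix : 0;
  const int P_steps = P_total + n_pc + n_dc + n_ec;

  if (init.size() != P_total) stop("init has wrong length");
  if (init_step.size() != P_steps) stop("init_step has wrong length");
  if (n_burn >= n_iter || thin < 1) stop("invalid chain configuration");

  std::vector<std::vector<int> > date_rows(K), pop_rows(J);
  for (int i = 0; i < N; ++i) {
    if (K > 0) date_rows[date_id[i] - 1].push_back(i);
    if (J > 0) pop_rows[pop_id[i] - 1].push_back(i);
  }

  std::vector<double> theta(init.begin(), init.end());
  std::vector<double> eta(N), ll(N);
  for (int i = 0; i < N; ++i) {
    double e = 0.0;
    for (int m = 0; m < P_fix; ++m) e += X(i, m) * theta[m];
    if (K > 0) e += theta[G0 + date_id[i] - 1];
    if (use_eps) e += theta[E0 + i];
    if (J > 0) e += theta[O0 + pop_id[i] - 1];
    eta[i] = e;
    ll[i] = ll_term(y[i], n[i], e);
  }

  std::vector<double> log_step(P_steps), scratch_eta(N), scratch_ll(N);
  for (int p = 0; p < P_steps; ++p) log_step[p] = std::log(init_step[p]);
  std::vector<int> acc_window(P_steps, 0), att_window(P_steps, 0);
  std::vector<long> acc_total(P_steps, 0), att_total(P_steps, 0);

  const int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix draws(n_keep, P_total);
  int keep_row = 0, batch = 0;

  // normal log-density kernel difference for a latent u -> u' given variance v
  // (constant cancels): -(u'^2 - u^2) / (2 v)

  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- fixed effects ---
    for (int m = 0; m < P_fix; ++m) {
      double step = std::exp(log_step[m]);
      double delta = norm_rand() * step;
      double b = theta[m], b_new = b + delta;
      double d_ll = 0.0;
      for (int i = 0; i < N; ++i) {
        double e_new = eta[i] + delta * X(i, m);
        scratch_eta[i] = e_new;
        scratch_ll[i] = ll_term(y[i], n[i], e_new);
        d_ll += scratch_ll[i] - ll[i];
      }
      double d_prior = -(b_new * b_new - b * b) / (2.0 * coef_var);
      ++att_window[m]; ++att_total[m];
      if (std::log(unif_rand()) < d_ll + d_prior) {
        theta[m] = b_new;
        for (int i = 0; i < N; ++i) { eta[i] = scratch_eta[i]; ll[i] = scratch_ll[i]; }
        ++acc_window[m]; ++acc_total[m];
      }
    }

    // --- variance components (reflected random walk on (0, var_upper)) ---
    int s2_active[3] = { K > 0, use_eps ? 1 : 0, J > 0 };
    int block_start[3] = { G0, E0, O0 };
    int block_len[3] = { K, NE, J };
    for (int c = 0; c < 3; ++c) {
      if (!s2_active[c]) continue;
      int p = idx_s2 + c;
      double step = std::exp(log_step[p]);
      double v = theta[p];
      double v_new = v + norm_rand() * step;
      for (int guard = 0; guard < 1000 && (v_new <= 0.0 || v_new >= var_upper); ++guard) {
        if (v_new <= 0.0) v_new = -v_new;
        if (v_new >= var_upper) v_new = 2.0 * var_upper - v_new;
      }
      ++att_window[p]; ++att_total[p];
      if (v_new > 0.0 && v_new < var_upper) {
        double ss = 0.0;
        int m_lat = block_len[c];
        for (int q = 0; q < m_lat; ++q) {
          double u = theta[block_start[c] + q];
          ss += u * u;
        }
        double d_post = -0.5 * m_lat * (std::log(v_new) - std::log(v)) -
                        0.5 * ss * (1.0 / v_new - 1.0 / v);
        if (std::log(unif_rand()) < d_post) {
          theta[p] = v_new;
          ++acc_window[p]; ++acc_total[p];
        }
      }
    }

    // --- date-within-year effects gamma ---
    if (K > 0) {
      double v_g = theta[idx_s2];
      for (int k = 0; k < K; ++k) {
        int p = G0 + k;
        double delta = norm_rand() * std::exp(log_step[p]);
        double g = theta[p], g_new = g + delta;
        double d_ll = 0.0;
        const std::vector<int>& rows = date_rows[k];
        for (size_t r = 0; r < rows.size(); ++r) {
          int i = rows[r];
          d_ll += ll_term(y[i], n[i], eta[i] + delta) - ll[i];
        }
        double d_prior = -(g_new * g_new - g * g) / (2.0 * v_g);
        ++att_window[p]; ++att_total[p];
        if (std::log(unif_rand()) < d_ll + d_prior) {
          theta[p] = g_new;
          for (size_t r = 0; r < rows.size(); ++r) {
            int i = rows[r];
            eta[i] += delta;
            ll[i] = ll_term(y[i], n[i], eta[i]);
          }
          ++acc_window[p]; ++acc_total[p];
        }
      }
    }

    // --- observation-level overdispersion eps ---
    if (use_eps) {
      double v_e = theta[idx_s2 + 1];
      for (int i = 0; i < N; ++i) {
        int p = E0 + i;
        double delta = norm_rand() * std::exp(log_step[p]);
        double u = theta[p], u_new = u + delta;
        double e_new = eta[i] + delta;
        double ll_new = ll_term(y[i], n[i], e_new);
        double d_prior = -(u_new * u_new - u * u) / (2.0 * v_e);
        ++att_window[p]; ++att_total[p];
        if (std::log(unif_rand()) < (ll_new - ll[i]) + d_prior) {
          theta[p] = u_new;
          eta[i] = e_new;
          ll[i] = ll_new;
          ++acc_window[p]; ++acc_total[p];
        }
      }
    }

    // --- population-replicate effects omega ---
    if (J > 0) {
      double v_o = theta[idx_s2 + 2];
      for (int j = 0; j < J; ++j) {
        int p = O0 + j;
        double delta = norm_rand() * std::exp(log_step[p]);
        double w = theta[p], w_new = w + delta;
        double d_ll = 0.0;
        const std::vector<int>& rows = pop_rows[j];
        for (size_t r = 0; r < rows.size(); ++r) {
          int i = rows[r];
          d_ll += ll_term(y[i], n[i], eta[i] + delta) - ll[i];
        }
        double d_prior = -(w_new * w_new - w * w) / (2.0 * v_o);
        ++att_window[p]; ++att_total[p];
        if (std::log(unif_rand()) < d_ll + d_prior) {
          theta[p] = w_new;
          for (size_t r = 0; r < rows.size(); ++r) {
            int i = rows[r];
            eta[i] += delta;
            ll[i] = ll_term(y[i], n[i], eta[i]);
          }
          ++acc_window[p]; ++acc_total[p];
        }
      }
    }

    // --- compensated (likelihood-invariant) moves ---
    // beta_m += delta, omega_j -= delta * v_j for pop-constant columns
    for (int c = 0; c < n_pc; ++c) {
      int p = P_total + c;
      int m = pop_cols[c];
      double delta = norm_rand() * std::exp(log_step[p]);
      double b = theta[m];
      double v_o = theta[idx_s2 + 2];
      double d_post = -((b + delta) * (b + delta) - b * b) / (2.0 * coef_var);
      for (int j = 0; j < J; ++j) {
        double w = theta[O0 + j];
        double w_new = w - delta * Vpop(j, c);
        d_post += -(w_new * w_new - w * w) / (2.0 * v_o);
      }
      ++att_window[p]; ++att_total[p];
      if (std::log(unif_rand()) < d_post) {
        theta[m] = b + delta;
        for (int j = 0; j < J; ++j) theta[O0 + j] -= delta * Vpop(j, c);
        ++acc_window[p]; ++acc_total[p];
      }
    }
    // beta_m += delta, gamma_k -= delta * v_k for date-constant columns
    for (int c = 0; c < n_dc; ++c) {
      int p = P_total + n_pc + c;
      int m = date_cols[c];
      double delta = norm_rand() * std::exp(log_step[p]);
      double b = theta[m];
      double v_g = theta[idx_s2];
      double d_post = -((b + delta) * (b + delta) - b * b) / (2.0 * coef_var);
      for (int k = 0; k < K; ++k) {
        double g = theta[G0 + k];
        double g_new = g - delta * Vdate(k, c);
        d_post += -(g_new * g_new - g * g) / (2.0 * v_g);
      }
      ++att_window[p]; ++att_total[p];
      if (std::log(unif_rand()) < d_post) {
        theta[m] = b + delta;
        for (int k = 0; k < K; ++k) theta[G0 + k] -= delta * Vdate(k, c);
        ++acc_window[p]; ++acc_total[p];
      }
    }
    // beta_m += delta, eps_i -= delta * X(i, m): valid for every column
    if (eps_comp) {
      double v_e = theta[idx_s2 + 1];
      for (int m = 0; m < P_fix; ++m) {
        int p = P_total + n_pc + n_dc + m;
        double delta = norm_rand() * std::exp(log_step[p]);
        double b = theta[m];
        double d_post = -((b + delta) * (b + delta) - b * b) / (2.0 * coef_var);
        for (int i = 0; i < N; ++i) {
          double u = theta[E0 + i];
          double u_new = u - delta * X(i, m);
          d_post += -(u_new * u_new - u * u) / (2.0 * v_e);
        }
        ++att_window[p]; ++att_total[p];
        if (std::log(unif_rand()) < d_post) {
          theta[m] = b + delta;
          for (int i = 0; i < N; ++i) theta[E0 + i] -= delta * X(i, m);
          ++acc_window[p]; ++acc_total[p];
        }
      }
    }

    // --- step-size adaptation, burn-in only ---
    if (iter <= n_burn && iter % adapt_interval == 0) {
      ++batch;
      double d = std::min(0.1, 1.0 / std::sqrt((double)batch));
      for (int p = 0; p < P_steps; ++p) {
        if (att_window[p] == 0) continue;
        double rate = (double)acc_window[p] / att_window[p];
        log_step[p] += (rate > 0.44) ? d : -d;
        acc_window[p] = 0;
        att_window[p] = 0;
      }
    }

    if (iter > n_burn && (iter - n_burn) % thin == 0 && keep_row < n_keep) {
      for (int p = 0; p < P_total; ++p) draws(keep_row, p) = theta[p];
      ++keep_row;
    }
  }

  NumericVector final_step(P_steps), accept_rate(P_steps);
  for (int p = 0; p < P_steps; ++p) {
    final_step[p] = std::exp(log_step[p]);
    accept_rate[p] = att_total[p] > 0 ? (double)acc_total[p] / att_total[p] : NA_REAL;
  }
  return List::create(
    _["draws"] = draws,
    _["step_sizes"] = final_step,
    _["accept_rate"] = accept_rate,
    _["n_kept"] = keep_row
  );
}
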