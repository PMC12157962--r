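#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Simulated panel probabilities for a mixed logit with diagonal normal
// mixing, plus the gradient components needed by maximum simulated
// likelihood and by finite-mixture (latent-class) assembly.
//
// For respondent i and draw r the taste vector is
//   beta_ir[p] = beta[p] + sigma[k] * eta[k,r,i]   for p = rand_idx[k];
// the panel probability P_ir is the product over the respondent's tasks of
// the within-task softmax probability of the chosen alternative, and
//   S[i]  = mean_r P_ir
//   G[i,] = mean_r P_ir * d log P_ir / d(beta, sigma).
// The mixed-logit score is G[i,]/S[i]; a mixture reweights S and G by
// class-membership probabilities before normalising.
//
// The gradient uses the residual form d log P_ir / d beta =
// sum_rows (y_j - p_jr) x_j: per draw only the scalar row weights
// P_ir * (y_j - p_jr) (and their eta-weighted versions for sigma) are
// accumulated; the fold against X happens once per respondent.
//
// Xt:    P x n_rows encoded matrix, transposed; rows ordered
//        (respondent, task, alternative)
// Xrt:   q x n_rows random-coefficient columns, transposed
// task_start:      n_task+1 0-based row offsets per task
// chosen_row:      0-based chosen row per task
// resp_task_start: n_resp+1 0-based task offsets per respondent
// eta:   q x R x n_resp draw array (column-major)
// [[Rcpp::export]]
List msl_components_cpp(NumericMatrix Xt, NumericMatrix Xrt,
                        IntegerVector task_start, IntegerVector chosen_row,
                        IntegerVector resp_task_start,
                        NumericVector beta, NumericVector sigma,
                        IntegerVector rand_idx, NumericVector eta,
                        int R, bool want_grad) {
  const int P = Xt.nrow();
  const int q = rand_idx.size();
  const int n_rows = Xt.ncol();
  const int n_resp = resp_task_start.size() - 1;
  const int n_task = task_start.size() - 1;
  const double *x = REAL(Xt);
  const double *xr = REAL(Xrt);
  const double *et = REAL(eta);

  // base utilities X beta (fixed across draws)
  std::vector<double> base(n_rows);
  for (int j = 0; j < n_rows; ++j) {
    const double *xj = x + (size_t)P * j;
    double u = 0.0;
    for (int p = 0; p < P; ++p) u += xj[p] * beta[p];
    base[j] = u;
  }

  NumericVector S(n_resp);
  NumericMatrix G = want_grad ? NumericMatrix(n_resp, P + q)
                              : NumericMatrix(0, 0);

  std::vector<double> sk(q), u(64), pr(64);
  std::vector<double> c0, ck, wrow;

  for (int i = 0; i < n_resp; ++i) {
    const int t0 = resp_task_start[i], t1 = resp_task_start[i + 1];
    const int a0 = task_start[t0], b0 = task_start[t1];
    const int ni = b0 - a0;                       // rows of this respondent
    if (want_grad) {
      c0.assign(ni, 0.0);
      ck.assign((size_t)ni * q, 0.0);
      wrow.resize(ni);
    }
    double Si = 0.0;
    for (int r = 0; r < R; ++r) {
      const double *eta_ir = et + (size_t)q * (r + (size_t)R * i);
      for (int k = 0; k < q; ++k) sk[k] = sigma[k] * eta_ir[k];

      double Pir = 1.0;
      for (int t = t0; t < t1; ++t) {
        const int a = task_start[t], b = task_start[t + 1];
        const int nt = b - a;
        if ((int)u.size() < nt) { u.resize(nt); pr.resize(nt); }
        for (int j = 0; j < nt; ++j) {
          const double *xrj = xr + (size_t)q * (a + j);
          double uu = base[a + j];
          for (int k = 0; k < q; ++k) uu += sk[k] * xrj[k];
          u[j] = uu;
        }
        const int ch = chosen_row[t] - a;
        if (nt == 2) {
          const double e = std::exp(u[1 - ch] - u[ch]);
          const double pch = 1.0 / (1.0 + e);
          Pir *= pch;
          if (want_grad) { pr[ch] = pch; pr[1 - ch] = 1.0 - pch; }
        } else {
          double umax = u[0];
          for (int j = 1; j < nt; ++j) if (u[j] > umax) umax = u[j];
          double denom = 0.0;
          for (int j = 0; j < nt; ++j) { pr[j] = std::exp(u[j] - umax); denom += pr[j]; }
          for (int j = 0; j < nt; ++j) pr[j] /= denom;
          Pir *= pr[ch];
        }
        if (want_grad) {
          for (int j = 0; j < nt; ++j) {
            wrow[a + j - a0] = ((j == ch) ? 1.0 : 0.0) - pr[j];
          }
        }
      }
      Si += Pir;
      if (want_grad) {
        for (int j = 0; j < ni; ++j) {
          const double w = Pir * wrow[j];
          c0[j] += w;
          double *ckj = &ck[(size_t)j * q];
          for (int k = 0; k < q; ++k) ckj[k] += w * eta_ir[k];
        }
      }
    }
    S[i] = Si / R;
    if (want_grad) {
      for (int j = 0; j < ni; ++j) {
        const double *xj = x + (size_t)P * (a0 + j);
        const double w = c0[j] / R;
        for (int p = 0; p < P; ++p) G(i, p) += w * xj[p];
        const double *xrj = xr + (size_t)q * (a0 + j);
        const double *ckj = &ck[(size_t)j * q];
        for (int k = 0; k < q; ++k) G(i, P + k) += (ckj[k] / R) * xrj[k];
      }
    }
  }
  (void)n_task;
  if (want_grad) return List::create(_["S"] = S, _["G"] = G);
  return List::create(_["S"] = S);
}
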