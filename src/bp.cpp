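// Sum-product belief propagation over a pedigree-shaped factor graph.
//
// Variables: one binary carrier state per individual. Factors: one per
// nuclear family (father, mother, shared children); in male-bias mode the
// mother is irrelevant and families are keyed by father alone, making the
// factor graph a forest (BP exact on every pedigree). Each family factor
// bundles, per child, the sex-evidence term P(S_child | C_father) and the
// inheritance term P(C_child | C_father, C_mother, S_child).
//
// Messages are normalised 2-vectors. A sweep is one leaves-to-roots pass
// (messages to parents) followed by one roots-to-leaves pass (messages to
// children); on tree factor graphs the second sweep confirms convergence.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline void normalize2(double* v) {
  double s = v[0] + v[1];
  if (s > 0.0) {
    v[0] /= s;
    v[1] /= s;
  } else {
    v[0] = v[1] = 0.5;
  }
}

// [[Rcpp::export]]
List bp_run_cpp(int n, IntegerVector sex,
                IntegerVector fam_father, IntegerVector fam_mother,
                IntegerVector fam_cptr, IntegerVector fam_cidx,
                IntegerVector fam_order,
                IntegerVector child_fam, IntegerVector child_slot,
                IntegerVector pf_ptr, IntegerVector pf_fam,
                IntegerVector pf_role,
                IntegerVector is_root,
                int ymode, double pen, double alpha, double mu,
                double tol, int max_sweeps, double damp) {
  const int F = fam_father.size();
  const int C = fam_cidx.size();

  // Unary founder priors. In male-bias mode only males can carry.
  std::vector<double> un0(n), un1(n);
  for (int i = 0; i < n; i++) {
    if (is_root[i]) {
      double a = alpha;
      if (ymode && sex[i] != 1) a = 0.0;
      un0[i] = 1.0 - a;
      un1[i] = a;
    } else {
      un0[i] = 1.0;
      un1[i] = 1.0;
    }
  }

  // Per child slot: E[a] = P(S_child | C_father=a), T1[a][b] = P(C_child=1 |
  // C_father=a, C_mother=b). A missing parent enters as a fixed non-carrier.
  std::vector<double> E(2 * (size_t)C), T1(4 * (size_t)C);
  for (int f = 0; f < F; f++) {
    int fa = fam_father[f];
    for (int s = fam_cptr[f]; s < fam_cptr[f + 1]; s++) {
      int c = fam_cidx[s];
      int sx = sex[c];  // 1 male, 2 female, 0 unknown
      double e0 = 1.0, e1 = 1.0;
      if (fa >= 0 && sx != 0) {
        int favored = ymode ? 1 : 2;
        e0 = 0.5;
        e1 = (sx == favored) ? pen : (1.0 - pen);
      }
      E[2 * (size_t)s] = e0;
      E[2 * (size_t)s + 1] = e1;
      for (int a = 0; a < 2; a++) {
        for (int b = 0; b < 2; b++) {
          double t1;
          if (ymode) {
            t1 = (sx == 1) ? (a == 1 ? 1.0 - mu : mu) : 0.0;
          } else {
            double tf = (a == 1 && fa >= 0 && sx == 2) ? (1.0 - mu) : 0.0;
            double tm = (b == 1) ? 0.5 * (1.0 - mu) : 0.0;
            t1 = 1.0 - (1.0 - tf) * (1.0 - tm) * (1.0 - mu);
          }
          T1[4 * (size_t)s + 2 * a + b] = t1;
        }
      }
    }
  }

  std::vector<double> mF(2 * (size_t)F, 0.5), mM(2 * (size_t)F, 0.5),
      mC(2 * (size_t)C, 0.5);
  std::vector<double> post(n, 0.0), post_old(n, -1.0);

  // Product of incoming messages at variable i, excluding the message from
  // family exf in role exrole (0 father, 1 mother, 2 child; exf = -1: none).
  auto var_in = [&](int i, int exf, int exrole, double* out) {
    out[0] = un0[i];
    out[1] = un1[i];
    int cf = child_fam[i];
    if (cf >= 0 && !(cf == exf && exrole == 2)) {
      int s = child_slot[i];
      out[0] *= mC[2 * (size_t)s];
      out[1] *= mC[2 * (size_t)s + 1];
    }
    for (int k = pf_ptr[i]; k < pf_ptr[i + 1]; k++) {
      int g = pf_fam[k];
      int r = pf_role[k];
      if (g == exf && r == exrole) continue;
      if (r == 0) {
        out[0] *= mF[2 * (size_t)g];
        out[1] *= mF[2 * (size_t)g + 1];
      } else {
        out[0] *= mM[2 * (size_t)g];
        out[1] *= mM[2 * (size_t)g + 1];
      }
    }
    normalize2(out);
  };

  auto store = [&](double* slot, const double* fresh) {
    double v0 = damp * fresh[0] + (1.0 - damp) * slot[0];
    double v1 = damp * fresh[1] + (1.0 - damp) * slot[1];
    slot[0] = v0;
    slot[1] = v1;
    normalize2(slot);
  };

  std::vector<double> W;
  auto process = [&](int f, bool toparents) {
    int fa = fam_father[f], mo = fam_mother[f];
    double vf[2], vm[2];
    if (fa >= 0) var_in(fa, f, 0, vf); else { vf[0] = 1.0; vf[1] = 0.0; }
    if (mo >= 0) var_in(mo, f, 1, vm); else { vm[0] = 1.0; vm[1] = 0.0; }
    int s0 = fam_cptr[f], s1 = fam_cptr[f + 1], k = s1 - s0;
    W.assign((size_t)4 * k, 0.0);
    // Per (a, b): product of non-zero child terms plus a zero count, so the
    // leave-one-out products needed for child messages stay well defined.
    double Pnz[4] = {1.0, 1.0, 1.0, 1.0};
    int nz[4] = {0, 0, 0, 0};
    double vc[2];
    for (int j = 0; j < k; j++) {
      int s = s0 + j;
      int c = fam_cidx[s];
      var_in(c, f, 2, vc);
      for (int a = 0; a < 2; a++) {
        for (int b = 0; b < 2; b++) {
          double t1 = T1[4 * (size_t)s + 2 * a + b];
          double w = (vc[1] * t1 + vc[0] * (1.0 - t1)) * E[2 * (size_t)s + a];
          W[4 * (size_t)j + 2 * a + b] = w;
          if (w == 0.0) nz[2 * a + b]++; else Pnz[2 * a + b] *= w;
        }
      }
      double m = std::max(std::max(std::fabs(Pnz[0]), std::fabs(Pnz[1])),
                          std::max(std::fabs(Pnz[2]), std::fabs(Pnz[3])));
      if (m > 0.0 && m < 1e-280) {  // rescale all four together: ratios only
        for (int q = 0; q < 4; q++) Pnz[q] /= m;
      }
    }
    if (toparents) {
      double Wp[4];
      for (int q = 0; q < 4; q++) Wp[q] = nz[q] ? 0.0 : Pnz[q];
      if (fa >= 0) {
        double out[2];
        out[0] = vm[0] * Wp[0] + vm[1] * Wp[1];
        out[1] = vm[0] * Wp[2] + vm[1] * Wp[3];
        normalize2(out);
        store(&mF[2 * (size_t)f], out);
      }
      if (mo >= 0) {
        double out[2];
        out[0] = vf[0] * Wp[0] + vf[1] * Wp[2];
        out[1] = vf[0] * Wp[1] + vf[1] * Wp[3];
        normalize2(out);
        store(&mM[2 * (size_t)f], out);
      }
    } else {
      for (int j = 0; j < k; j++) {
        int s = s0 + j;
        double out[2] = {0.0, 0.0};
        for (int a = 0; a < 2; a++) {
          for (int b = 0; b < 2; b++) {
            int q = 2 * a + b;
            double wj = W[4 * (size_t)j + q];
            double loo;
            if (nz[q] == 0) {
              loo = Pnz[q] / wj;
            } else if (nz[q] == 1 && wj == 0.0) {
              loo = Pnz[q];
            } else {
              loo = 0.0;
            }
            double base = vf[a] * vm[b] * loo * E[2 * (size_t)s + a];
            double t1 = T1[4 * (size_t)s + q];
            out[0] += base * (1.0 - t1);
            out[1] += base * t1;
          }
        }
        normalize2(out);
        store(&mC[2 * (size_t)s], out);
      }
    }
  };

  bool converged = false;
  int sweeps = 0;
  for (int it = 1; it <= max_sweeps; it++) {
    sweeps = it;
    for (int q = F - 1; q >= 0; q--) process(fam_order[q], true);
    for (int q = 0; q < F; q++) process(fam_order[q], false);
    double delta = 0.0;
    double b2[2];
    for (int i = 0; i < n; i++) {
      var_in(i, -1, -1, b2);
      double p = b2[1];
      double d = (post_old[i] < 0.0) ? 1.0 : std::fabs(p - post_old[i]);
      if (d > delta) delta = d;
      post[i] = p;
    }
    post_old = post;
    if (delta < tol) {
      converged = true;
      break;
    }
  }

  return List::create(_["posterior"] = NumericVector(post.begin(), post.end()),
                      _["n_sweeps"] = sweeps,
                      _["converged"] = converged);
}
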