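// Energy and analytic gradient of the bead-chain toy potential used for
// basin-hopping benchmarks: harmonic bonds and angles, cosine-series
// torsional terms, and a soft inverse-power repulsion between nonbonded
// beads.  Compiled because basin-hopping performs O(10^5) local
// minimizations during a benchmark, each with hundreds of evaluations.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

// Dihedral angle (radians, IUPAC sign) over atoms a,b,c,d and, when grad
// is non-null, its derivatives with respect to the four atom positions.
static double dihedral(const double* ra, const double* rb, const double* rc,
                       const double* rd, double grad[4][3]) {
  double b1[3], b2[3], b3[3];
  for (int i = 0; i < 3; ++i) {
    b1[i] = rb[i] - ra[i];
    b2[i] = rc[i] - rb[i];
    b3[i] = rd[i] - rc[i];
  }
  double n1[3], n2[3];
  cross3(b1, b2, n1);
  cross3(b2, b3, n2);
  double nb2 = norm3(b2);
  double x = dot3(n1, n2);
  double cr[3];
  cross3(n1, n2, cr);
  double y = dot3(cr, b2) / nb2;
  double phi = std::atan2(y, x);
  if (grad != nullptr) {
    double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
    double F[3], G[3];
    for (int i = 0; i < 3; ++i) {
      F[i] = -nb2 / n1sq * n1[i];          // dphi/d ra
      G[i] = nb2 / n2sq * n2[i];           // dphi/d rd
    }
    double t = dot3(b1, b2) / (nb2 * nb2);
    double s = dot3(b3, b2) / (nb2 * nb2);
    for (int i = 0; i < 3; ++i) {
      grad[0][i] = F[i];
      grad[1][i] = -(1.0 + t) * F[i] + s * G[i];
      grad[2][i] = t * F[i] - (1.0 + s) * G[i];
      grad[3][i] = G[i];
    }
  }
  return phi;
}

// Plain-C++ mirror of the parameter list, unpacked once per call chain
// so the inner loops never touch R data structures.
struct ChainParams {
  int natoms;
  std::vector<int> bond_i, bond_j;
  double bond_r0, bond_k;
  std::vector<int> ang_i, ang_j, ang_k;
  std::vector<double> theta0;
  double angle_k;
  std::vector<int> t_a, t_b, t_c, t_d, t_m;
  std::vector<double> t_k, t_delta;
  std::vector<int> nb_i, nb_j;
  double rep_eps, rep_sigma;
};

static ChainParams unpack(const List& params) {
  ChainParams p;
  p.natoms = as<int>(params["natoms"]);
  IntegerMatrix bonds = params["bonds"];
  for (int b = 0; b < bonds.nrow(); ++b) {
    p.bond_i.push_back(bonds(b, 0) - 1);
    p.bond_j.push_back(bonds(b, 1) - 1);
  }
  p.bond_r0 = as<double>(params["bond_r0"]);
  p.bond_k = as<double>(params["bond_k"]);
  IntegerMatrix angles = params["angles"];
  NumericVector th0 = params["angle_theta0"];
  for (int a = 0; a < angles.nrow(); ++a) {
    p.ang_i.push_back(angles(a, 0) - 1);
    p.ang_j.push_back(angles(a, 1) - 1);
    p.ang_k.push_back(angles(a, 2) - 1);
    p.theta0.push_back(th0[a]);
  }
  p.angle_k = as<double>(params["angle_k"]);
  IntegerMatrix tors = params["torsions"];
  IntegerVector tm = params["torsion_m"];
  NumericVector tk = params["torsion_k"], td = params["torsion_delta"];
  for (int t = 0; t < tors.nrow(); ++t) {
    p.t_a.push_back(tors(t, 0) - 1);
    p.t_b.push_back(tors(t, 1) - 1);
    p.t_c.push_back(tors(t, 2) - 1);
    p.t_d.push_back(tors(t, 3) - 1);
    p.t_m.push_back(tm[t]);
    p.t_k.push_back(tk[t]);
    p.t_delta.push_back(td[t]);
  }
  IntegerMatrix nb = params["nonbonded"];
  for (int q = 0; q < nb.nrow(); ++q) {
    p.nb_i.push_back(nb(q, 0) - 1);
    p.nb_j.push_back(nb(q, 1) - 1);
  }
  p.rep_eps = as<double>(params["rep_eps"]);
  p.rep_sigma = as<double>(params["rep_sigma"]);
  return p;
}

static double eval(const double* r, int ncoord, const ChainParams& P,
                   double* g) {
  if (ncoord != 3 * P.natoms) stop("coordinate length mismatch");
  double energy = 0.0;
  if (g) std::fill(g, g + ncoord, 0.0);

  for (size_t b = 0; b < P.bond_i.size(); ++b) {
    const int i = P.bond_i[b], j = P.bond_j[b];
    double d[3];
    for (int c = 0; c < 3; ++c) d[c] = r[3 * i + c] - r[3 * j + c];
    double len = norm3(d);
    double dev = len - P.bond_r0;
    energy += P.bond_k * dev * dev;
    if (g) {
      double f = 2.0 * P.bond_k * dev / len;
      for (int c = 0; c < 3; ++c) {
        g[3 * i + c] += f * d[c];
        g[3 * j + c] -= f * d[c];
      }
    }
  }

  for (size_t a = 0; a < P.ang_i.size(); ++a) {
    const int i = P.ang_i[a], j = P.ang_j[a], k = P.ang_k[a];
    double u[3], v[3];
    for (int c = 0; c < 3; ++c) {
      u[c] = r[3 * i + c] - r[3 * j + c];
      v[c] = r[3 * k + c] - r[3 * j + c];
    }
    double nu = norm3(u), nv = norm3(v);
    double ct = dot3(u, v) / (nu * nv);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
    double th = std::acos(ct);
    double dev = th - P.theta0[a];
    energy += P.angle_k * dev * dev;
    if (g) {
      double st = std::sqrt(1.0 - ct * ct);
      if (st < 1e-8) st = 1e-8;
      double coef = -2.0 * P.angle_k * dev / st;
      for (int c = 0; c < 3; ++c) {
        double dci = (v[c] / (nu * nv)) - ct * u[c] / (nu * nu);
        double dck = (u[c] / (nu * nv)) - ct * v[c] / (nv * nv);
        g[3 * i + c] += coef * dci;
        g[3 * k + c] += coef * dck;
        g[3 * j + c] -= coef * (dci + dck);
      }
    }
  }

  for (size_t t = 0; t < P.t_a.size(); ++t) {
    const int ia = P.t_a[t], ib = P.t_b[t], ic = P.t_c[t], id = P.t_d[t];
    double dg[4][3];
    double phi = dihedral(r + 3 * ia, r + 3 * ib, r + 3 * ic, r + 3 * id,
                          g ? dg : nullptr);
    const double m = P.t_m[t];
    energy += P.t_k[t] * (1.0 + std::cos(m * phi - P.t_delta[t]));
    if (g) {
      double dE = -P.t_k[t] * m * std::sin(m * phi - P.t_delta[t]);
      const int idx[4] = {ia, ib, ic, id};
      for (int a = 0; a < 4; ++a)
        for (int c = 0; c < 3; ++c)
          g[3 * idx[a] + c] += dE * dg[a][c];
    }
  }

  for (size_t q = 0; q < P.nb_i.size(); ++q) {
    const int i = P.nb_i[q], j = P.nb_j[q];
    double d[3];
    for (int c = 0; c < 3; ++c) d[c] = r[3 * i + c] - r[3 * j + c];
    double r2 = dot3(d, d);
    double s2 = P.rep_sigma * P.rep_sigma / r2;
    double s6 = s2 * s2 * s2;
    energy += P.rep_eps * s6;
    if (g) {
      double f = -6.0 * P.rep_eps * s6 / r2;
      for (int c = 0; c < 3; ++c) {
        g[3 * i + c] += f * d[c];
        g[3 * j + c] -= f * d[c];
      }
    }
  }

  return energy;
}

// [[Rcpp::export]]
double toychain_energy(NumericVector x, List params) {
  ChainParams P = unpack(params);
  return eval(x.begin(), x.size(), P, nullptr);
}

// [[Rcpp::export]]
NumericVector toychain_gradient(NumericVector x, List params) {
  ChainParams P = unpack(params);
  NumericVector g(x.size());
  eval(x.begin(), x.size(), P, g.begin());
  return g;
}

// Limited-memory BFGS with Armijo backtracking, specialized to the
// bead-chain potential so that benchmark runs avoid R callback overhead
// on every energy evaluation.  Convergence criterion: RMS gradient.
// [[Rcpp::export]]
List toychain_minimize(NumericVector x0, List params, double rms_tol,
                       int max_iter) {
  const int n = x0.size();
  const int mhist = 8;
  ChainParams P = unpack(params);
  std::vector<double> x(x0.begin(), x0.end()), g(n), gnew(n), xnew(n);
  std::vector<std::vector<double>> S, Y;
  std::vector<double> rho;
  int evals = 0;

  double f = eval(x.data(), n, P, g.data()); ++evals;
  double rms = 0.0;
  bool converged = false;

  for (int iter = 0; iter < max_iter; ++iter) {
    rms = 0.0;
    for (int i = 0; i < n; ++i) rms += g[i] * g[i];
    rms = std::sqrt(rms / n);
    if (rms <= rms_tol) { converged = true; break; }

    // two-loop recursion
    std::vector<double> q(g.begin(), g.end());
    const int k = S.size();
    std::vector<double> alpha(k);
    for (int i = k - 1; i >= 0; --i) {
      double a = 0.0;
      for (int j = 0; j < n; ++j) a += S[i][j] * q[j];
      a *= rho[i];
      alpha[i] = a;
      for (int j = 0; j < n; ++j) q[j] -= a * Y[i][j];
    }
    double h0 = 1.0;
    if (k > 0) {
      double sy = 0.0, yy = 0.0;
      for (int j = 0; j < n; ++j) {
        sy += S[k - 1][j] * Y[k - 1][j];
        yy += Y[k - 1][j] * Y[k - 1][j];
      }
      if (yy > 0) h0 = sy / yy;
    }
    for (int j = 0; j < n; ++j) q[j] *= h0;
    for (int i = 0; i < k; ++i) {
      double b = 0.0;
      for (int j = 0; j < n; ++j) b += Y[i][j] * q[j];
      b *= rho[i];
      for (int j = 0; j < n; ++j) q[j] += S[i][j] * (alpha[i] - b);
    }
    // descent direction d = -q; ensure it is a descent direction
    double gd = 0.0;
    for (int j = 0; j < n; ++j) gd += -q[j] * g[j];
    if (gd >= 0) {  // reset to steepest descent
      S.clear(); Y.clear(); rho.clear();
      for (int j = 0; j < n; ++j) q[j] = g[j];
      gd = 0.0;
      for (int j = 0; j < n; ++j) gd += -q[j] * g[j];
    }

    // Armijo backtracking
    double step = 1.0;
    const double c1 = 1e-4;
    double fnew = f;
    bool ok = false;
    for (int ls = 0; ls < 50; ++ls) {
      for (int j = 0; j < n; ++j) xnew[j] = x[j] - step * q[j];
      fnew = eval(xnew.data(), n, P, gnew.data()); ++evals;
      if (fnew <= f + c1 * step * gd) { ok = true; break; }
      step *= 0.5;
    }
    if (!ok) {
      if (!S.empty()) {  // retry from a fresh quasi-Newton state
        S.clear(); Y.clear(); rho.clear();
        continue;
      }
      break;  // steepest descent cannot decrease: machine precision
    }

    std::vector<double> s(n), y(n);
    double sy = 0.0, ss = 0.0, yy = 0.0;
    for (int j = 0; j < n; ++j) {
      s[j] = xnew[j] - x[j];
      y[j] = gnew[j] - g[j];
      sy += s[j] * y[j];
      ss += s[j] * s[j];
      yy += y[j] * y[j];
    }
    if (sy > 1e-10 * std::sqrt(ss * yy) && sy > 0.0) {
      S.push_back(s); Y.push_back(y); rho.push_back(1.0 / sy);
      if ((int)S.size() > mhist) {
        S.erase(S.begin()); Y.erase(Y.begin()); rho.erase(rho.begin());
      }
    }
    x = xnew; g = gnew; f = fnew;
  }
  rms = 0.0;
  for (int i = 0; i < n; ++i) rms += g[i] * g[i];
  rms = std::sqrt(rms / n);
  return List::create(_["par"] = NumericVector(x.begin(), x.end()),
                      _["value"] = f, _["rms"] = rms,
                      _["converged"] = converged || rms <= rms_tol,
                      _["evaluations"] = evals);
}
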