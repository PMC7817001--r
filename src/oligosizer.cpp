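#include <Rcpp.h>
#include <cmath>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// union-find helpers
// ---------------------------------------------------------------------------

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int i, int j) {
  int ri = uf_find(parent, i), rj = uf_find(parent, j);
  if (ri != rj) parent[std::max(ri, rj)] = std::min(ri, rj);
}

// relabel components as 1,2,... in order of first occurrence (lowest index)
static std::vector<int> uf_labels(std::vector<int>& parent) {
  int m = (int)parent.size();
  std::vector<int> lab(m);
  std::unordered_map<int, int> seen;
  int next = 1;
  for (int i = 0; i < m; ++i) {
    int r = uf_find(parent, i);
    auto it = seen.find(r);
    if (it == seen.end()) { seen[r] = next; lab[i] = next; ++next; }
    else lab[i] = it->second;
  }
  return lab;
}

// connected components of the graph with an edge whenever the pairwise
// distance is <= thr (strict = false) or < thr (strict = true); equivalent to
// cutting a single-linkage dendrogram at height thr.
static std::vector<int> threshold_components(const double* x, const double* y,
                                             int m, double thr, bool strict) {
  std::vector<int> parent(m);
  for (int i = 0; i < m; ++i) parent[i] = i;
  double t2 = thr * thr;
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      bool link = strict ? (d2 < t2) : (d2 <= t2);
      if (link) uf_union(parent, i, j);
    }
  }
  return uf_labels(parent);
}

// [[Rcpp::export(name = ".cluster_threshold_cpp")]]
IntegerVector cluster_threshold_cpp(NumericVector x, NumericVector y,
                                    double thr, bool strict) {
  int m = x.size();
  std::vector<int> lab = threshold_components(REAL(x), REAL(y), m, thr, strict);
  return IntegerVector(lab.begin(), lab.end());
}

// Spatial single-linkage connectivity at distance `gap` via a grid hash:
// points are binned into gap-sized cells, and only pairs in the same or
// adjacent cells are tested (distance < gap, strict). Exact and O(m) for
// bounded local density.
// [[Rcpp::export(name = ".cluster_spatial_cpp")]]
IntegerVector cluster_spatial_cpp(NumericVector x, NumericVector y, double gap) {
  int m = x.size();
  if (m == 0) return IntegerVector(0);
  std::vector<int> parent(m);
  for (int i = 0; i < m; ++i) parent[i] = i;
  std::unordered_map<long long, std::vector<int> > cells;
  cells.reserve((size_t)m * 2);
  std::vector<long long> cx(m), cy(m);
  for (int i = 0; i < m; ++i) {
    cx[i] = (long long)std::floor(x[i] / gap);
    cy[i] = (long long)std::floor(y[i] / gap);
    long long key = cx[i] * 2147483647LL + cy[i];
    cells[key].push_back(i);
  }
  double g2 = gap * gap;
  for (int i = 0; i < m; ++i) {
    for (long long dx = -1; dx <= 1; ++dx) {
      for (long long dy = -1; dy <= 1; ++dy) {
        long long key = (cx[i] + dx) * 2147483647LL + (cy[i] + dy);
        auto it = cells.find(key);
        if (it == cells.end()) continue;
        for (int j : it->second) {
          if (j <= i) continue;
          double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (ddx * ddx + ddy * ddy < g2) uf_union(parent, i, j);
        }
      }
    }
  }
  std::vector<int> lab = uf_labels(parent);
  return IntegerVector(lab.begin(), lab.end());
}

// ---------------------------------------------------------------------------
// Levenberg-Marquardt geometric circle fit
// objective S(a,b,R) = sum_i (sqrt((x_i-a)^2 + (y_i-b)^2) - R)^2
// ---------------------------------------------------------------------------

struct FitResult {
  double a, b, R, S, lambda;
  int iters;
  bool converged;
};

// A circle whose radius is an order of magnitude beyond the data's own
// half-spread subtends only a few degrees of arc: the points are collinear
// at the data scale and the "fit" is an unrealistic solution. A regular
// polygon has R equal to half its diameter, so the factor 10 flags only
// configurations no regular oligomer could produce.
static bool collinear_at_scale(const double* x, const double* y, int n,
                               double R) {
  double dmax2 = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 > dmax2) dmax2 = d2;
    }
  return R > 10.0 * 0.5 * std::sqrt(dmax2);
}

static double circle_obj(const double* x, const double* y, int n,
                         double a, double b, double R) {
  double S = 0.0;
  for (int i = 0; i < n; ++i) {
    double dx = x[i] - a, dy = y[i] - b;
    double f = std::sqrt(dx * dx + dy * dy) - R;
    S += f * f;
  }
  return S;
}

static FitResult lm_fit(const double* x, const double* y, int n,
                        double a0, double b0, double R0,
                        double lambda0, double up, double down,
                        double tol, int maxit) {
  double a = a0, b = b0, R = R0, lambda = lambda0;
  double S = circle_obj(x, y, n, a, b, R);
  bool converged = false;
  int it = 0;
  for (it = 0; it < maxit && !converged; ++it) {
    // normal equations from Jacobian rows D_i = ((a-x_i)/rho, (b-y_i)/rho, -1)
    double JtJ[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    double Jtf[3] = {0, 0, 0};
    for (int i = 0; i < n; ++i) {
      double dx = a - x[i], dy = b - y[i];
      double rho = std::sqrt(dx * dx + dy * dy);
      double f = rho - R;
      double Da = 0.0, Db = 0.0;
      if (rho > 1e-300) { Da = dx / rho; Db = dy / rho; }
      double D[3] = {Da, Db, -1.0};
      for (int p = 0; p < 3; ++p) {
        for (int q = p; q < 3; ++q) JtJ[p][q] += D[p] * D[q];
        Jtf[p] += D[p] * f;
      }
    }
    JtJ[1][0] = JtJ[0][1]; JtJ[2][0] = JtJ[0][2]; JtJ[2][1] = JtJ[1][2];
    bool give_up = false;
    while (true) {
      // solve (JtJ + lambda I) d = -Jtf by gaussian elimination w/ pivoting
      double A[3][4];
      for (int p = 0; p < 3; ++p) {
        for (int q = 0; q < 3; ++q) A[p][q] = JtJ[p][q] + (p == q ? lambda : 0.0);
        A[p][3] = -Jtf[p];
      }
      bool ok = true;
      for (int c = 0; c < 3 && ok; ++c) {
        int piv = c;
        for (int r = c + 1; r < 3; ++r)
          if (std::fabs(A[r][c]) > std::fabs(A[piv][c])) piv = r;
        if (std::fabs(A[piv][c]) < 1e-300) { ok = false; break; }
        if (piv != c)
          for (int q = 0; q < 4; ++q) std::swap(A[c][q], A[piv][q]);
        for (int r = c + 1; r < 3; ++r) {
          double fac = A[r][c] / A[c][c];
          for (int q = c; q < 4; ++q) A[r][q] -= fac * A[c][q];
        }
      }
      double d[3] = {0, 0, 0};
      if (ok) {
        for (int c = 2; c >= 0; --c) {
          double s = A[c][3];
          for (int q = c + 1; q < 3; ++q) s -= A[c][q] * d[q];
          d[c] = s / A[c][c];
        }
      }
      double dn = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
      if (!ok || !std::isfinite(dn)) {
        lambda *= up;
        if (lambda > 1e15) { give_up = true; break; }
        continue;
      }
      double at = a + d[0], bt = b + d[1], Rt = R + d[2];
      if (Rt < 0) Rt = -Rt;  // reflect: R constrained to [0, Inf)
      double St = circle_obj(x, y, n, at, bt, Rt);
      if (St < S) {
        a = at; b = bt; R = Rt; S = St;
        lambda *= down;
        if (dn < tol) converged = true;
        break;
      }
      if (dn < tol) { converged = true; break; }  // no improving step left
      lambda *= up;
      if (lambda > 1e15) { give_up = true; break; }
    }
    if (give_up) break;
  }
  FitResult out;
  out.a = a; out.b = b; out.R = R; out.S = S;
  out.lambda = lambda; out.iters = it; out.converged = converged;
  if (converged && collinear_at_scale(x, y, n, R)) out.converged = false;
  return out;
}

// [[Rcpp::export(name = ".fit_circle_cpp")]]
List fit_circle_cpp(NumericVector x, NumericVector y,
                    double a0, double b0, double R0,
                    double lambda0, double lambda_up, double lambda_down,
                    double tol_step, int max_iter) {
  FitResult r = lm_fit(REAL(x), REAL(y), x.size(), a0, b0, R0,
                       lambda0, lambda_up, lambda_down, tol_step, max_iter);
  return List::create(_["a"] = r.a, _["b"] = r.b, _["r_hat"] = r.R,
                      _["S"] = r.S, _["iterations"] = r.iters,
                      _["converged"] = r.converged,
                      _["lambda_final"] = r.lambda);
}

// Batch LM fit: the i-th block of `n` consecutive points is one oligomer's
// set of group means. The initial guess per block is the mean of the points
// and half the RMS distance from it.
// [[Rcpp::export(name = ".fit_circles_batch_cpp")]]
List fit_circles_batch_cpp(NumericVector x, NumericVector y, int n,
                           double lambda0, double lambda_up,
                           double lambda_down, double tol_step, int max_iter) {
  int total = x.size();
  int nf = total / n;
  NumericVector a(nf), b(nf), R(nf), S(nf);
  IntegerVector iters(nf);
  LogicalVector conv(nf);
  for (int k = 0; k < nf; ++k) {
    const double* xi = REAL(x) + (size_t)k * n;
    const double* yi = REAL(y) + (size_t)k * n;
    double a0 = 0, b0 = 0;
    for (int i = 0; i < n; ++i) { a0 += xi[i]; b0 += yi[i]; }
    a0 /= n; b0 /= n;
    double ms = 0;
    for (int i = 0; i < n; ++i) {
      double dx = xi[i] - a0, dy = yi[i] - b0;
      ms += dx * dx + dy * dy;
    }
    double R0 = 0.5 * std::sqrt(ms / n);
    if (R0 < 1e-12) {  // zero spread: degenerate configuration
      a[k] = a0; b[k] = b0; R[k] = 0; S[k] = 0; iters[k] = 0; conv[k] = false;
      continue;
    }
    FitResult r = lm_fit(xi, yi, n, a0, b0, R0, lambda0, lambda_up,
                         lambda_down, tol_step, max_iter);
    a[k] = r.a; b[k] = r.b; R[k] = r.R; S[k] = r.S;
    iters[k] = r.iters; conv[k] = r.converged;
  }
  return List::create(_["a"] = a, _["b"] = b, _["r_hat"] = R, _["S"] = S,
                      _["iterations"] = iters, _["converged"] = conv);
}

// ---------------------------------------------------------------------------
// Batch blink assignment per oligomer
// ---------------------------------------------------------------------------

// Rows must be sorted by oligomer id (contiguous blocks). For every oligomer:
// threshold clustering (<= delta_p merges) in the (Nx, Ny) plane, eligibility
// (exactly n_expect groups), correctness against molecule ids if available,
// and per-group statistics (mean position, z_hat = sum(s_j^2)/m^2) for the
// eligible oligomers, groups ordered by lowest member row.
// [[Rcpp::export(name = ".assign_batch_cpp")]]
List assign_batch_cpp(IntegerVector oligo, NumericVector Nx, NumericVector Ny,
                      NumericVector x, NumericVector y, NumericVector sj,
                      IntegerVector mol, bool has_truth,
                      double delta_p, int n_expect) {
  int nrow = oligo.size();
  std::vector<int> starts;
  for (int i = 0; i < nrow; ++i)
    if (i == 0 || oligo[i] != oligo[i - 1]) starts.push_back(i);
  starts.push_back(nrow);
  int nolig = (int)starts.size() - 1;

  IntegerVector out_id(nolig), n_found(nolig);
  LogicalVector eligible(nolig), all_correct(nolig);
  std::vector<double> gx, gy, gz;
  std::vector<int> gm, elig_idx;

  for (int k = 0; k < nolig; ++k) {
    int s = starts[k], e = starts[k + 1], m = e - s;
    out_id[k] = oligo[s];
    std::vector<int> lab = threshold_components(REAL(Nx) + s, REAL(Ny) + s,
                                                m, delta_p, false);
    int ng = 0;
    for (int i = 0; i < m; ++i) if (lab[i] > ng) ng = lab[i];
    n_found[k] = ng;
    bool elig = (ng == n_expect);
    eligible[k] = elig;
    bool correct = true;
    if (has_truth) {
      // pure groups: one molecule id per group, and distinct across groups
      std::vector<int> gmol(ng, NA_INTEGER);
      for (int i = 0; i < m && correct; ++i) {
        int g = lab[i] - 1;
        if (gmol[g] == NA_INTEGER) gmol[g] = mol[s + i];
        else if (gmol[g] != mol[s + i]) correct = false;
      }
      if (correct) {
        for (int p = 0; p < ng && correct; ++p)
          for (int q = p + 1; q < ng; ++q)
            if (gmol[p] == gmol[q]) { correct = false; break; }
      }
    }
    all_correct[k] = has_truth ? correct : NA_LOGICAL;
    if (!elig) continue;
    elig_idx.push_back(k + 1);
    std::vector<double> sx(ng, 0), sy(ng, 0), ss2(ng, 0);
    std::vector<int> cnt(ng, 0);
    for (int i = 0; i < m; ++i) {
      int g = lab[i] - 1;
      sx[g] += x[s + i];
      sy[g] += y[s + i];
      ss2[g] += sj[s + i] * sj[s + i];
      cnt[g] += 1;
    }
    for (int g = 0; g < ng; ++g) {
      gx.push_back(sx[g] / cnt[g]);
      gy.push_back(sy[g] / cnt[g]);
      gz.push_back(ss2[g] / ((double)cnt[g] * cnt[g]));
      gm.push_back(cnt[g]);
    }
  }
  return List::create(
      _["oligomer_id"] = out_id, _["n_found"] = n_found,
      _["eligible"] = eligible, _["all_correct"] = all_correct,
      _["eligible_index"] = IntegerVector(elig_idx.begin(), elig_idx.end()),
      _["xbar"] = NumericVector(gx.begin(), gx.end()),
      _["ybar"] = NumericVector(gy.begin(), gy.end()),
      _["zhat"] = NumericVector(gz.begin(), gz.end()),
      _["m"] = IntegerVector(gm.begin(), gm.end()));
}
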