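#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
#include <cstdint>
#include <unordered_map>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// k-nearest-neighbour machinery.
//
// Point sets are passed column-major with one point per column (d x n), so a
// point's coordinates are contiguous. Queries use a sorted scan on the first
// coordinate with pruning: for small d (parameter spaces here are 1-4
// dimensional) this is close to O(n log n) and needs no tree structure.
// ---------------------------------------------------------------------------

namespace {

// k-d tree over points stored column-major (one point per column); implicit
// median-split layout over an index array, leaf buckets scanned linearly
struct KdTree {
  int d, n;
  std::vector<int> idx;            // original point index per tree slot
  std::vector<double> rpts;        // coordinates in tree-slot order (contiguous leaf scans)
  std::vector<signed char> axis_;  // split axis, stored at each node's mid position
  static const int LEAF = 12;

  KdTree(const double *pts_, int d_, int n_) : d(d_), n(n_), idx(n_),
                                               axis_(n_, 0) {
    for (int j = 0; j < n; ++j) idx[j] = j;
    build(pts_, 0, n, 0);
    rpts.resize((size_t)n * d);
    for (int s = 0; s < n; ++s)
      std::copy(pts_ + (size_t)d * idx[s], pts_ + (size_t)d * (idx[s] + 1),
                rpts.begin() + (size_t)d * s);
  }

  inline double coord(int slot, int a) const { return rpts[(size_t)d * slot + a]; }

  void build(const double *pts, int lo, int hi, int depth) {
    if (hi - lo <= LEAF) return;
    int mid = (lo + hi) / 2;
    int a = depth % d;
    axis_[mid] = (signed char)a;
    const int dd = d;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [pts, dd, a](int x, int y) {
                       return pts[(size_t)dd * x + a] < pts[(size_t)dd * y + a];
                     });
    build(pts, lo, mid, depth + 1);
    build(pts, mid + 1, hi, depth + 1);
  }

  inline void consider(int slot, const double *q, int k, int skip,
                       std::vector<double> &heap) const {
    if (idx[slot] == skip) return;
    const double *p = rpts.data() + (size_t)d * slot;
    double acc = 0.0;
    for (int l = 0; l < d; ++l) {
      double dl = q[l] - p[l];
      acc += dl * dl;
    }
    if ((int)heap.size() < k) {
      heap.push_back(acc);
      std::push_heap(heap.begin(), heap.end());
    } else if (acc < heap.front()) {
      std::pop_heap(heap.begin(), heap.end());
      heap.back() = acc;
      std::push_heap(heap.begin(), heap.end());
    }
  }

  // descend with incremental squared distance to the current cell (rd) and
  // per-axis offsets, so subtrees far from the query are pruned even when
  // the reference points are tightly clustered
  void search(int lo, int hi, const double *q, int k, int skip,
              std::vector<double> &heap, double rd, double *off) const {
    if ((int)heap.size() == k && rd >= heap.front()) return;
    if (hi - lo <= LEAF) {
      for (int i = lo; i < hi; ++i) consider(i, q, k, skip, heap);
      return;
    }
    int mid = (lo + hi) / 2;
    int a = axis_[mid];
    consider(mid, q, k, skip, heap);
    double delta = q[a] - coord(mid, a);
    int nlo, nhi, flo, fhi;
    if (delta <= 0) { nlo = lo; nhi = mid; flo = mid + 1; fhi = hi; }
    else { nlo = mid + 1; nhi = hi; flo = lo; fhi = mid; }
    search(nlo, nhi, q, k, skip, heap, rd, off);
    double old = off[a];
    double rd_far = rd - old * old + delta * delta;
    if ((int)heap.size() < k || rd_far < heap.front()) {
      off[a] = delta < 0 ? -delta : delta;
      search(flo, fhi, q, k, skip, heap, rd_far, off);
      off[a] = old;
    }
  }

  // scratch buffers reusable across queries
  double kth_dist(const double *q, int k, int skip, std::vector<double> &heap,
                  std::vector<double> &off) const {
    heap.clear();
    std::fill(off.begin(), off.end(), 0.0);
    search(0, n, q, k, skip, heap, 0.0, off.data());
    return std::sqrt(heap.front());
  }
};

// nu_k(i): distance from each column of X (d x nx) to its k-th nearest
// neighbour among columns of Y (d x ny); exclude_self assumes X and Y are the
// same matrix and skips the matching column index.
void knn_dists(const double *X, int nx, const double *Y, int ny, int d, int k,
               bool exclude_self, double *out) {
  KdTree tree(Y, d, ny);
  std::vector<double> heap, off(d);
  heap.reserve(k + 1);
  for (int i = 0; i < nx; ++i)
    out[i] = tree.kth_dist(X + (size_t)d * i, k, exclude_self ? i : -1, heap, off);
}

// Eq-2 style sum given precomputed rho and freshly computed nu.
// Returns raw D_alpha estimate (unclipped); NA if all nu are zero.
double alpha_div_from_dists(const std::vector<double> &rho,
                            const std::vector<double> &nu, int ny,
                            double alpha, double Bcoef) {
  int n = (int)rho.size();
  // duplicate-point guard: replace zero nu with smallest positive nu
  double minpos = R_PosInf;
  for (double v : nu) if (v > 0.0 && v < minpos) minpos = v;
  if (!R_FINITE(minpos)) return NA_REAL;
  double expo = 1.0 - alpha, acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double nui = (nu[i] > 0.0) ? nu[i] : minpos;
    double ratio = ((double)(n - 1) * rho[i]) / ((double)ny * nui);
    acc += std::pow(ratio, expo);
  }
  return acc / n * Bcoef;
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_knn_kth_dist(NumericMatrix ref_t, NumericMatrix query_t,
                               int k, bool exclude_self) {
  int d = ref_t.nrow(), nref = ref_t.ncol(), nq = query_t.ncol();
  NumericVector out(nq);
  knn_dists(&query_t[0], nq, &ref_t[0], nref, d, k, exclude_self, &out[0]);
  return out;
}

// Raw k-NN alpha-divergence estimate D_hat_alpha(X || Y), unclipped.
// X_t, Y_t: d x n matrices, one point per column.
// [[Rcpp::export]]
double cpp_knn_alpha_divergence(NumericMatrix X_t, NumericMatrix Y_t, int k,
                                double alpha, double Bcoef) {
  int d = X_t.nrow(), nx = X_t.ncol(), ny = Y_t.ncol();
  std::vector<double> rho(nx), nu(nx);
  knn_dists(&X_t[0], nx, &X_t[0], nx, d, k, true, rho.data());
  knn_dists(&X_t[0], nx, &Y_t[0], ny, d, k, false, nu.data());
  return alpha_div_from_dists(rho, nu, ny, alpha, Bcoef);
}

// rho_k within a fixed point set (self-excluded); precomputed once per
// generation so repeated objective evaluations only recompute nu.
// [[Rcpp::export]]
NumericVector cpp_knn_self_dist(NumericMatrix X_t, int k) {
  int d = X_t.nrow(), nx = X_t.ncol();
  NumericVector out(nx);
  knn_dists(&X_t[0], nx, &X_t[0], nx, d, k, true, &out[0]);
  return out;
}

// ---------------------------------------------------------------------------
// Weighted Euclidean ABC distance and closest-N selection
// ---------------------------------------------------------------------------

// summaries: M x kappa (R layout); observed, w: length kappa.
// [[Rcpp::export]]
NumericVector cpp_weighted_dist(NumericMatrix summaries, NumericVector observed,
                                NumericVector w) {
  int M = summaries.nrow(), kap = summaries.ncol();
  NumericVector d2(M);
  for (int j = 0; j < kap; ++j) {
    double wj = w[j], oj = observed[j];
    if (wj == 0.0) continue;
    const double *col = &summaries[0] + (size_t)M * j;
    for (int i = 0; i < M; ++i) {
      double dl = col[i] - oj;
      d2[i] += wj * dl * dl;
    }
  }
  for (int i = 0; i < M; ++i) d2[i] = std::sqrt(d2[i]);
  return d2;
}

// Indices (1-based) of the nkeep smallest weighted distances, stable in
// (distance, simulation index); also returns the full distance vector.
// [[Rcpp::export]]
List cpp_select_closest(NumericMatrix summaries, NumericVector observed,
                        NumericVector w, int nkeep) {
  NumericVector d = cpp_weighted_dist(summaries, observed, w);
  int M = d.size();
  std::vector<int> idx(M);
  for (int i = 0; i < M; ++i) idx[i] = i;
  const double *dp = &d[0];
  auto cmp = [dp](int a, int b) {
    if (dp[a] != dp[b]) return dp[a] < dp[b];
    return a < b;
  };
  std::partial_sort(idx.begin(), idx.begin() + nkeep, idx.end(), cmp);
  IntegerVector kept(nkeep);
  for (int i = 0; i < nkeep; ++i) kept[i] = idx[i] + 1;
  return List::create(_["idx"] = kept, _["dist"] = d);
}

// Memoization cache for objective evaluations: the objective is piecewise
// constant in w (it depends on w only through the selected candidate set),
// so identical selections can skip the k-NN computation.
// [[Rcpp::export]]
SEXP cpp_new_objective_cache() {
  Rcpp::XPtr<std::unordered_map<uint64_t, double> > p(
      new std::unordered_map<uint64_t, double>(), true);
  return p;
}

// Single-precision residuals (s_ij - s(y)_j), kappa columns of length M:
// halves the memory traffic of the distance loop inside repeated optimizer
// evaluations. Final results are always re-evaluated in double precision.
// [[Rcpp::export]]
SEXP cpp_make_residual_pool(NumericMatrix summaries, NumericVector observed) {
  int M = summaries.nrow(), kap = summaries.ncol();
  Rcpp::XPtr<std::vector<float> > p(new std::vector<float>((size_t)M * kap), true);
  std::vector<float> &f = *p;
  for (int j = 0; j < kap; ++j) {
    double oj = observed[j];
    const double *col = &summaries[0] + (size_t)M * j;
    float *fc = f.data() + (size_t)M * j;
    for (int i = 0; i < M; ++i) fc[i] = (float)(col[i] - oj);
  }
  return p;
}

// One evaluation of the weight-search objective
//   L(w) = 1 - clip( D_hat_{1/2}( prior_ref || closest-N thetas under w ) )
// thetas_t: p x M, prior_t: p x N, rho: precomputed self k-NN distances of
// the prior reference sample. cache: optional cpp_new_objective_cache().
// [[Rcpp::export]]
double cpp_weight_objective(NumericMatrix summaries, NumericVector observed,
                            NumericVector w, NumericMatrix thetas_t,
                            NumericMatrix prior_t, NumericVector rho,
                            int nkeep, int k, double Bcoef,
                            SEXP cache = R_NilValue, SEXP fpool = R_NilValue) {
  int M = summaries.nrow(), kap = summaries.ncol();
  int p = thetas_t.nrow();
  int N = prior_t.ncol();
  // squared weighted distances (ranking only, no sqrt needed)
  std::vector<double> d2(M, 0.0);
  if (!Rf_isNull(fpool)) {
    std::vector<float> &f = *Rcpp::XPtr<std::vector<float> >(fpool);
    for (int j = 0; j < kap; ++j) {
      double wj = w[j];
      if (wj == 0.0) continue;
      const float *fc = f.data() + (size_t)M * j;
      for (int i = 0; i < M; ++i) {
        double dl = fc[i];
        d2[i] += wj * dl * dl;
      }
    }
  } else {
    for (int j = 0; j < kap; ++j) {
      double wj = w[j], oj = observed[j];
      if (wj == 0.0) continue;
      const double *col = &summaries[0] + (size_t)M * j;
      for (int i = 0; i < M; ++i) {
        double dl = col[i] - oj;
        d2[i] += wj * dl * dl;
      }
    }
  }
  // closest-nkeep selection via a value threshold (ties at the threshold are
  // filled in simulation-index order, matching the stable (distance, index)
  // tie rule)
  std::vector<double> buf(d2);
  std::nth_element(buf.begin(), buf.begin() + (nkeep - 1), buf.end());
  double tau = buf[nkeep - 1];
  std::vector<int> idx;
  idx.reserve(nkeep);
  for (int i = 0; i < M && (int)idx.size() < nkeep; ++i)
    if (d2[i] < tau) idx.push_back(i);
  for (int i = 0; i < M && (int)idx.size() < nkeep; ++i)
    if (d2[i] == tau) idx.push_back(i);
  std::unordered_map<uint64_t, double> *cmap = NULL;
  uint64_t key = 1469598103934665603ULL;  // FNV-1a over the selected index set
  if (!Rf_isNull(cache)) {
    cmap = (std::unordered_map<uint64_t, double> *)R_ExternalPtrAddr(cache);
    for (int i = 0; i < nkeep; ++i) {
      key ^= (uint64_t)idx[i];
      key *= 1099511628211ULL;
    }
    std::unordered_map<uint64_t, double>::const_iterator it = cmap->find(key);
    if (it != cmap->end()) return it->second;
  }
  // gather selected parameter points
  std::vector<double> sel((size_t)p * nkeep);
  const double *tp = &thetas_t[0];
  for (int i = 0; i < nkeep; ++i)
    std::copy(tp + (size_t)p * idx[i], tp + (size_t)p * (idx[i] + 1),
              sel.begin() + (size_t)p * i);
  std::vector<double> rhov(rho.begin(), rho.end());
  std::vector<double> nu(N);
  knn_dists(&prior_t[0], N, sel.data(), nkeep, p, k, false, nu.data());
  double D = alpha_div_from_dists(rhov, nu, nkeep, 0.5, Bcoef);
  if (!R_FINITE(D)) return NA_REAL;
  if (D > 1.0) D = 1.0;
  double L = 1.0 - D;
  if (cmap) (*cmap)[key] = L;
  return L;
}

// ---------------------------------------------------------------------------
// SMC importance-weight denominators
// ---------------------------------------------------------------------------

// Mixture density sum_j v_j * prod_l Normal(theta_new_l ; theta_prev_jl, sd_l)
// theta_new: p x n, theta_prev: p x N (points in columns), v normalized.
// [[Rcpp::export]]
NumericVector cpp_kernel_mixture_density(NumericMatrix theta_new,
                                         NumericMatrix theta_prev,
                                         NumericVector v, NumericVector sd) {
  int p = theta_new.nrow(), n = theta_new.ncol(), N = theta_prev.ncol();
  std::vector<double> inv2(p);
  double normc = 1.0;
  for (int l = 0; l < p; ++l) {
    inv2[l] = 0.5 / (sd[l] * sd[l]);
    normc /= sd[l] * std::sqrt(2.0 * M_PI);
  }
  NumericVector out(n);
  const double *xn = &theta_new[0], *xp = &theta_prev[0], *vp = &v[0];
  for (int i = 0; i < n; ++i) {
    const double *qi = xn + (size_t)p * i;
    double acc = 0.0;
    for (int j = 0; j < N; ++j) {
      const double *pj = xp + (size_t)p * j;
      double e = 0.0;
      for (int l = 0; l < p; ++l) {
        double dl = qi[l] - pj[l];
        e += dl * dl * inv2[l];
      }
      acc += vp[j] * std::exp(-e);
    }
    out[i] = acc * normc;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Gillespie direct method for mass-action reaction networks
// ---------------------------------------------------------------------------

namespace {

// flattened network representation with a species -> dependent-reaction map
// so only affected propensities are recomputed after each firing
struct SparseNet {
  int s, r;
  std::vector<int> rx_start, rx_sp, rx_ord;    // reactant lists per reaction
  std::vector<int> ch_start, ch_sp, ch_delta;  // state changes per reaction
  std::vector<int> dep_start, dep_rx;          // species -> dependent reactions

  SparseNet(const IntegerMatrix &stoich, const IntegerMatrix &orders) {
    r = stoich.nrow();
    s = stoich.ncol();
    rx_start.assign(r + 1, 0);
    ch_start.assign(r + 1, 0);
    for (int j = 0; j < r; ++j) {
      rx_start[j] = (int)rx_sp.size();
      ch_start[j] = (int)ch_sp.size();
      for (int l = 0; l < s; ++l) {
        if (orders(j, l) > 0) { rx_sp.push_back(l); rx_ord.push_back(orders(j, l)); }
        if (stoich(j, l) != 0) { ch_sp.push_back(l); ch_delta.push_back(stoich(j, l)); }
      }
    }
    rx_start[r] = (int)rx_sp.size();
    ch_start[r] = (int)ch_sp.size();
    dep_start.assign(s + 1, 0);
    std::vector<std::vector<int> > dep(s);
    for (int j = 0; j < r; ++j)
      for (int m = rx_start[j]; m < rx_start[j + 1]; ++m)
        dep[rx_sp[m]].push_back(j);
    for (int l = 0; l < s; ++l) {
      dep_start[l] = (int)dep_rx.size();
      for (size_t m = 0; m < dep[l].size(); ++m) dep_rx.push_back(dep[l][m]);
    }
    dep_start[s] = (int)dep_rx.size();
  }

  inline double propensity(int j, const double *x, const double *rates) const {
    double a = rates[j];
    for (int m = rx_start[j]; m < rx_start[j + 1]; ++m) {
      double xs = x[rx_sp[m]];
      int o = rx_ord[m];
      // combinatorial counts: x for order 1, x(x-1)/2 for order 2, ...
      for (int l = 0; l < o; ++l) a *= (xs - l) / (l + 1);
    }
    return a > 0.0 ? a : 0.0;
  }
};

// simulate one trajectory, writing states at grid times into out
// (out has nt rows, s cols, R column-major with row stride nt)
void ssa_run(const SparseNet &net, const double *rates, std::vector<double> &x,
             const double *times, int nt, double *out, int out_stride,
             double max_steps) {
  int g = 0;
  const int r = net.r, s = net.s;
  double t = 0.0, steps = 0.0;
  std::vector<double> a(r);
  double A = 0.0;
  for (int j = 0; j < r; ++j) { a[j] = net.propensity(j, x.data(), rates); A += a[j]; }
  long refresh = 0;
  while (g < nt) {
    if (++refresh >= 4096) {  // periodically rebuild A against drift
      refresh = 0;
      A = 0.0;
      for (int j = 0; j < r; ++j) A += a[j];
    }
    if (!R_FINITE(A)) stop("non-finite propensity in Gillespie simulation");
    if (A <= 1e-13) {
      A = 0.0;  // exact rebuild before declaring the state frozen
      for (int j = 0; j < r; ++j) {
        a[j] = net.propensity(j, x.data(), rates);
        A += a[j];
      }
      if (A <= 0.0) break;
    }
    double tnew = t + exp_rand() / A;
    while (g < nt && times[g] <= tnew) {
      for (int l = 0; l < s; ++l) out[(size_t)out_stride * l + g] = x[l];
      ++g;
    }
    if (g >= nt) return;
    double u = unif_rand() * A, cum = 0.0;
    int jsel = r - 1;
    for (int j = 0; j < r; ++j) {
      cum += a[j];
      if (u <= cum) { jsel = j; break; }
    }
    if (a[jsel] <= 0.0) { refresh = 4096; continue; }  // drift artefact: resync
    for (int m = net.ch_start[jsel]; m < net.ch_start[jsel + 1]; ++m)
      x[net.ch_sp[m]] += net.ch_delta[m];
    // recompute only propensities that depend on the changed species
    for (int m = net.ch_start[jsel]; m < net.ch_start[jsel + 1]; ++m) {
      int sp = net.ch_sp[m];
      for (int q = net.dep_start[sp]; q < net.dep_start[sp + 1]; ++q) {
        int j = net.dep_rx[q];
        double anew = net.propensity(j, x.data(), rates);
        A += anew - a[j];
        a[j] = anew;
      }
    }
    t = tnew;
    if (++steps > max_steps) stop("Gillespie simulation exceeded max_steps");
  }
  for (; g < nt; ++g)
    for (int l = 0; l < s; ++l) out[(size_t)out_stride * l + g] = x[l];
}

}  // namespace

// Exact SSA trajectory sampled at grid times. Returns nt x s matrix
// (rows = observation times, cols = species).
// [[Rcpp::export]]
NumericMatrix cpp_gillespie(NumericVector x0, IntegerMatrix stoich,
                            IntegerMatrix orders, NumericVector rates,
                            NumericVector times, double max_steps) {
  SparseNet net(stoich, orders);
  int nt = times.size();
  NumericMatrix out(nt, net.s);
  std::vector<double> x(x0.begin(), x0.end());
  ssa_run(net, &rates[0], x, &times[0], nt, &out[0], nt, max_steps);
  return out;
}

// Batch of SSA simulations: rates is M x r (one parameter draw per row);
// returns M x (s * nt) summary matrix, each row the species-major
// concatenation [S_1(t_1..t_nt), S_2(t_1..t_nt), ...].
// [[Rcpp::export]]
NumericMatrix cpp_gillespie_batch(NumericVector x0, IntegerMatrix stoich,
                                  IntegerMatrix orders, NumericMatrix rates,
                                  NumericVector times, double max_steps) {
  SparseNet net(stoich, orders);
  int nt = times.size(), M = rates.nrow(), r = rates.ncol(), s = net.s;
  if (r != net.r) stop("rate matrix column count does not match reaction count");
  NumericMatrix out(M, s * nt);
  std::vector<double> traj((size_t)s * nt), rrow(r), x(s);
  for (int i = 0; i < M; ++i) {
    for (int j = 0; j < r; ++j) rrow[j] = rates(i, j);
    std::copy(x0.begin(), x0.end(), x.begin());
    ssa_run(net, rrow.data(), x, &times[0], nt, traj.data(), nt, max_steps);
    for (int c = 0; c < s * nt; ++c) out(i, c) = traj[c];
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Batch simulator for the uniform toy model: row i holds the order
// statistics of r i.i.d. Uniform[0, theta_i] draws.
// [[Rcpp::export]]
NumericMatrix cpp_uniform_toy_batch(NumericVector theta_nat, int r) {
  int M = theta_nat.size();
  NumericMatrix out(M, r);
  // fill a row-major staging buffer (contiguous per simulation), then
  // transpose into the column-major result once
  std::vector<double> stage((size_t)M * r);
  for (int i = 0; i < M; ++i) {
    double th = theta_nat[i];
    double *row = stage.data() + (size_t)r * i;
    for (int j = 0; j < r; ++j) row[j] = th * unif_rand();
    std::sort(row, row + r);
  }
  double *o = &out[0];
  const int B = 64;
  for (int ib = 0; ib < M; ib += B) {
    int ie = std::min(ib + B, M);
    for (int j = 0; j < r; ++j)
      for (int i = ib; i < ie; ++i)
        o[(size_t)M * j + i] = stage[(size_t)r * i + j];
  }
  return out;
}

// Nested acceptance rule: row i passes if its weighted distance to the
// observed summary is < eps_j under weights W[, j] for every stored
// generation j. Thresholds are checked newest-first (tightest in practice)
// with early exit.
// [[Rcpp::export]]
LogicalVector cpp_nested_accept(NumericMatrix summaries, NumericVector observed,
                                NumericMatrix W, NumericVector eps) {
  int M = summaries.nrow(), kap = summaries.ncol(), nh = eps.size();
  LogicalVector keep(M);
  const double *S = &summaries[0];
  for (int i = 0; i < M; ++i) {
    bool ok = true;
    for (int j = nh - 1; j >= 0 && ok; --j) {
      double e2 = eps[j] * eps[j], acc = 0.0;
      for (int c = 0; c < kap; ++c) {
        double dl = S[(size_t)M * c + i] - observed[c];
        acc += W(c, j) * dl * dl;
      }
      ok = acc < e2;
    }
    keep[i] = ok;
  }
  return keep;
}

// Resample-and-perturb proposals: draw an ancestor from the weighted previous
// population, add component-wise Gaussian noise, and repeat (per slot) until
// the proposal falls inside the prior box. Returns n x p matrix.
// [[Rcpp::export]]
NumericMatrix cpp_propose(NumericMatrix theta_prev, NumericVector v,
                          NumericVector sds, NumericVector lower,
                          NumericVector upper, int n) {
  int N = theta_prev.nrow(), p = theta_prev.ncol();
  std::vector<double> cum(N);
  double acc = 0.0;
  for (int j = 0; j < N; ++j) { acc += v[j]; cum[j] = acc; }
  double tot = acc;
  NumericMatrix out(n, p);
  std::vector<double> prop(p);
  for (int i = 0; i < n; ++i) {
    for (;;) {
      double u = unif_rand() * tot;
      int j = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
      if (j >= N) j = N - 1;
      bool inside = true;
      for (int l = 0; l < p; ++l) {
        prop[l] = theta_prev(j, l) + norm_rand() * sds[l];
        if (prop[l] < lower[l] || prop[l] > upper[l]) inside = false;
      }
      if (inside) break;
    }
    for (int l = 0; l < p; ++l) out(i, l) = prop[l];
  }
  return out;
}

// sort each row of a matrix ascending (order statistics of each simulated
// dataset for the uniform toy model)
// [[Rcpp::export]]
NumericMatrix cpp_row_sort(NumericMatrix m) {
  int n = m.nrow(), k = m.ncol();
  NumericMatrix out(n, k);
  std::vector<double> buf(k);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) buf[j] = m(i, j);
    std::sort(buf.begin(), buf.end());
    for (int j = 0; j < k; ++j) out(i, j) = buf[j];
  }
  return out;
}
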