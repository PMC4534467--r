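#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>

using namespace Rcpp;

// Geometry helpers -----------------------------------------------------------

static inline double dist2(const std::vector<double> &X,
                           const std::vector<double> &Y,
                           const std::vector<double> &Z,
                           int i, int j, bool has_z) {
  double dx = X[i] - X[j], dy = Y[i] - Y[j];
  double d2 = dx * dx + dy * dy;
  if (has_z) {
    double dz = Z[i] - Z[j];
    d2 += dz * dz;
  }
  return d2;
}

// Angle between directions focal->a and focal->b (works in 2d and 3d).
static inline double sep_angle(const std::vector<double> &X,
                               const std::vector<double> &Y,
                               const std::vector<double> &Z,
                               int focal, int a, int b, bool has_z) {
  double ax = X[a] - X[focal], ay = Y[a] - Y[focal];
  double bx = X[b] - X[focal], by = Y[b] - Y[focal];
  double dot = ax * bx + ay * by;
  double na = ax * ax + ay * ay, nb = bx * bx + by * by;
  if (has_z) {
    double az = Z[a] - Z[focal], bz = Z[b] - Z[focal];
    dot += az * bz;
    na += az * az;
    nb += bz * bz;
  }
  double c = dot / std::sqrt(na * nb);
  c = std::max(-1.0, std::min(1.0, c));
  return std::acos(c);
}

// Directed shadow-accepted neighbours of `focal`: candidates within `radius`
// sorted by distance (ties by index), accepted unless occluded (angular
// separation strictly below arctan(cell_radius / d_accepted)) by a previously
// accepted neighbour.
static std::vector<int> shadow_neighbors(const std::vector<double> &X,
                                         const std::vector<double> &Y,
                                         const std::vector<double> &Z,
                                         bool has_z, int focal,
                                         double radius, double cell_radius) {
  int n = (int)X.size();
  double r2 = radius * radius;
  std::vector<std::pair<double, int>> cand;
  cand.reserve(8);
  for (int j = 0; j < n; ++j) {
    if (j == focal) continue;
    double d2 = dist2(X, Y, Z, focal, j, has_z);
    if (d2 <= r2) {
      if (d2 <= 0.0)
        stop("coincident cell positions (distance 0) between distinct cells");
      cand.push_back(std::make_pair(d2, j));
    }
  }
  std::sort(cand.begin(), cand.end());
  std::vector<int> acc;
  acc.reserve(cand.size());
  for (size_t k = 0; k < cand.size(); ++k) {
    int c = cand[k].second;
    bool shadowed = false;
    for (size_t m = 0; m < acc.size(); ++m) {
      int p = acc[m];
      double dp = std::sqrt(dist2(X, Y, Z, focal, p, has_z));
      double theta = std::atan(cell_radius / dp);
      if (sep_angle(X, Y, Z, focal, c, p, has_z) < theta) {
        shadowed = true;
        break;
      }
    }
    if (!shadowed) acc.push_back(c);
  }
  return acc;
}

static void unpack_coords(const NumericMatrix &coords,
                          std::vector<double> &X, std::vector<double> &Y,
                          std::vector<double> &Z, bool &has_z) {
  int n = coords.nrow();
  has_z = coords.ncol() >= 3;
  X.assign(n, 0.0);
  Y.assign(n, 0.0);
  Z.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    X[i] = coords(i, 0);
    Y[i] = coords(i, 1);
    if (has_z) Z[i] = coords(i, 2);
  }
}

// Build the undirected edge list under the chosen symmetrisation.
static std::vector<std::pair<int, int>> build_edges(
    const std::vector<double> &X, const std::vector<double> &Y,
    const std::vector<double> &Z, bool has_z,
    double radius, double cell_radius, bool mutual) {
  int n = (int)X.size();
  std::vector<std::vector<char>> accept(n, std::vector<char>(n, 0));
  for (int i = 0; i < n; ++i) {
    std::vector<int> acc =
        shadow_neighbors(X, Y, Z, has_z, i, radius, cell_radius);
    for (size_t k = 0; k < acc.size(); ++k) accept[i][acc[k]] = 1;
  }
  std::vector<std::pair<int, int>> edges;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      bool keep = mutual ? (accept[i][j] && accept[j][i])
                         : (accept[i][j] || accept[j][i]);
      if (keep) edges.push_back(std::make_pair(i, j));
    }
  }
  return edges;
}

// [[Rcpp::export]]
IntegerVector cpp_directed_neighbors(NumericMatrix coords, int focal,
                                     double radius, double cell_radius) {
  std::vector<double> X, Y, Z;
  bool has_z;
  unpack_coords(coords, X, Y, Z, has_z);
  std::vector<int> acc =
      shadow_neighbors(X, Y, Z, has_z, focal - 1, radius, cell_radius);
  IntegerVector out(acc.size());
  for (size_t k = 0; k < acc.size(); ++k) out[k] = acc[k] + 1;
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_shadow_edges(NumericMatrix coords, double radius,
                               double cell_radius, bool mutual) {
  std::vector<double> X, Y, Z;
  bool has_z;
  unpack_coords(coords, X, Y, Z, has_z);
  std::vector<std::pair<int, int>> edges =
      build_edges(X, Y, Z, has_z, radius, cell_radius, mutual);
  IntegerMatrix out(edges.size(), 2);
  for (size_t k = 0; k < edges.size(); ++k) {
    out(k, 0) = edges[k].first + 1;
    out(k, 1) = edges[k].second + 1;
  }
  return out;
}

// Union-find components ------------------------------------------------------

struct DSU {
  std::vector<int> parent, size;
  DSU(int n) : parent(n), size(n, 1) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int a) {
    while (parent[a] != a) {
      parent[a] = parent[parent[a]];
      a = parent[a];
    }
    return a;
  }
  void unite(int a, int b) {
    a = find(a);
    b = find(b);
    if (a == b) return;
    if (size[a] < size[b]) std::swap(a, b);
    parent[b] = a;
    size[a] += size[b];
  }
};

struct Measures {
  int n, n_edges, n_components, n_singular;
  double mean_degree, cells_per_component, cells_per_nonsingular;
};

static Measures compute_measures(int n,
                                 const std::vector<std::pair<int, int>> &edges,
                                 std::vector<int> *degree_out = NULL,
                                 std::vector<int> *compsize_out = NULL) {
  Measures m;
  m.n = n;
  m.n_edges = (int)edges.size();
  std::vector<int> deg(n, 0);
  DSU dsu(n);
  for (size_t k = 0; k < edges.size(); ++k) {
    deg[edges[k].first]++;
    deg[edges[k].second]++;
    dsu.unite(edges[k].first, edges[k].second);
  }
  int ncomp = 0, nsing = 0;
  std::vector<int> csize(n, 0);
  for (int i = 0; i < n; ++i) {
    if (dsu.find(i) == i) {
      ncomp++;
      if (dsu.size[i] == 1) nsing++;
    }
  }
  m.n_components = ncomp;
  m.n_singular = nsing;
  m.mean_degree = n > 0 ? 2.0 * m.n_edges / n : NA_REAL;
  m.cells_per_component = ncomp > 0 ? (double)n / ncomp : NA_REAL;
  int nnons = ncomp - nsing;
  m.cells_per_nonsingular = nnons > 0 ? (double)(n - nsing) / nnons : NA_REAL;
  if (degree_out) *degree_out = deg;
  if (compsize_out) {
    compsize_out->assign(n, 0);
    for (int i = 0; i < n; ++i) (*compsize_out)[i] = dsu.size[dsu.find(i)];
  }
  return m;
}

// Relative-likelihood kernels ------------------------------------------------

// dir = +1 for RL+ (P), -1 for RL- (M).
static inline double rl(double x, int dir, double rlp) {
  return 0.5 + dir * 0.5 * std::tanh(x - rlp);
}

// Draw an index with probability proportional to w; uniform fallback when the
// weights underflow to zero.
static int sample_weighted(const std::vector<double> &w) {
  double total = 0.0;
  for (size_t i = 0; i < w.size(); ++i) total += w[i];
  if (total <= 0.0) return (int)(unif_rand() * w.size()) % (int)w.size();
  double u = unif_rand() * total, acc = 0.0;
  for (size_t i = 0; i < w.size(); ++i) {
    acc += w[i];
    if (u <= acc) return (int)i;
  }
  return (int)w.size() - 1;
}

// Free-angle sampling: complement of the union of occlusion intervals around
// the parent's graph neighbours. Returns true and sets `angle` on success.
static bool sample_free_angle(const std::vector<double> &X,
                              const std::vector<double> &Y,
                              int parent, const std::vector<int> &neighbors,
                              double cell_radius, double &angle) {
  const double TWO_PI = 2.0 * M_PI;
  std::vector<std::pair<double, double>> occ;  // intervals in [0, 2pi)
  for (size_t k = 0; k < neighbors.size(); ++k) {
    int nb = neighbors[k];
    double dx = X[nb] - X[parent], dy = Y[nb] - Y[parent];
    double d = std::sqrt(dx * dx + dy * dy);
    double a = std::atan2(dy, dx);
    if (a < 0) a += TWO_PI;
    double w = std::atan(cell_radius / d);
    double lo = a - w, hi = a + w;
    if (lo < 0) {  // wraps below 0
      occ.push_back(std::make_pair(lo + TWO_PI, TWO_PI));
      occ.push_back(std::make_pair(0.0, hi));
    } else if (hi > TWO_PI) {
      occ.push_back(std::make_pair(lo, TWO_PI));
      occ.push_back(std::make_pair(0.0, hi - TWO_PI));
    } else {
      occ.push_back(std::make_pair(lo, hi));
    }
  }
  if (occ.empty()) {
    angle = unif_rand() * TWO_PI;
    return true;
  }
  std::sort(occ.begin(), occ.end());
  // merge
  std::vector<std::pair<double, double>> merged;
  merged.push_back(occ[0]);
  for (size_t k = 1; k < occ.size(); ++k) {
    if (occ[k].first <= merged.back().second) {
      merged.back().second = std::max(merged.back().second, occ[k].second);
    } else {
      merged.push_back(occ[k]);
    }
  }
  // free gaps
  std::vector<std::pair<double, double>> freeiv;
  double cur = 0.0;
  for (size_t k = 0; k < merged.size(); ++k) {
    if (merged[k].first > cur)
      freeiv.push_back(std::make_pair(cur, merged[k].first));
    cur = std::max(cur, merged[k].second);
  }
  if (cur < TWO_PI) freeiv.push_back(std::make_pair(cur, TWO_PI));
  double total = 0.0;
  for (size_t k = 0; k < freeiv.size(); ++k)
    total += freeiv[k].second - freeiv[k].first;
  if (total <= 1e-12) return false;
  double u = unif_rand() * total;
  for (size_t k = 0; k < freeiv.size(); ++k) {
    double len = freeiv[k].second - freeiv[k].first;
    if (u <= len) {
      angle = freeiv[k].first + u;
      return true;
    }
    u -= len;
  }
  angle = freeiv.back().second;
  return true;
}

// Smallest step t >= 0 along the ray such that the moving vertex is at least
// d_min from every frozen vertex. Intervals where the constraint is violated
// are quadratic in t.
static double wave_t_lo(const std::vector<double> &X,
                        const std::vector<double> &Y,
                        const std::vector<char> &frozen,
                        int v1, double ux, double uy, double d_min) {
  std::vector<std::pair<double, double>> forb;
  for (size_t f = 0; f < frozen.size(); ++f) {
    if (!frozen[f]) continue;
    double wx = X[v1] - X[f], wy = Y[v1] - Y[f];
    double beta = ux * wx + uy * wy;
    double c0 = wx * wx + wy * wy - d_min * d_min;
    double disc = beta * beta - c0;
    if (disc > 0) {
      double s = std::sqrt(disc);
      double a = -beta - s, b = -beta + s;
      if (b > 0) forb.push_back(std::make_pair(std::max(0.0, a), b));
    }
  }
  if (forb.empty()) return 0.0;
  std::sort(forb.begin(), forb.end());
  double t = 0.0;
  for (size_t k = 0; k < forb.size(); ++k) {
    if (forb[k].first <= t + 1e-12 && forb[k].second > t) t = forb[k].second;
  }
  return t;
}

static double min_dist_to_frozen(const std::vector<double> &X,
                                 const std::vector<double> &Y,
                                 const std::vector<char> &frozen,
                                 double px, double py, int self) {
  double best = R_PosInf;
  for (size_t f = 0; f < frozen.size(); ++f) {
    if (!frozen[f] || (int)f == self) continue;
    double dx = px - X[f], dy = py - Y[f];
    double d = std::sqrt(dx * dx + dy * dy);
    if (d < best) best = d;
  }
  return best;
}

// Steric vertex addition: place v_new near `parent` at a free angle and a
// uniform distance in [lo, hi], then resolve crowding by the frozen/problem
// wave. Operates on X/Y in place (appends the new vertex). Returns the number
// of vertices moved, or -1 when the parent has no free angle.
static int add_vertex_wave(std::vector<double> &X, std::vector<double> &Y,
                           int parent, const std::vector<int> &nbrs,
                           double cell_radius, double d_min,
                           double lo, double hi, int max_wave) {
  double angle;
  if (!sample_free_angle(X, Y, parent, nbrs, cell_radius, angle)) return -1;
  double dist = lo + unif_rand() * (hi - lo);
  double nx = X[parent] + dist * std::cos(angle);
  double ny = Y[parent] + dist * std::sin(angle);
  X.push_back(nx);
  Y.push_back(ny);
  int n = (int)X.size();
  int vnew = n - 1;
  std::vector<char> frozen(n, 0);
  frozen[parent] = 1;
  frozen[vnew] = 1;
  std::vector<char> queued(n, 0);
  std::deque<int> problem;
  for (int i = 0; i < n; ++i) {
    if (frozen[i]) continue;
    double dx = X[i] - nx, dy = Y[i] - ny;
    if (std::sqrt(dx * dx + dy * dy) < d_min) {
      problem.push_back(i);
      queued[i] = 1;
    }
  }
  int moved = 0;
  while (!problem.empty()) {
    if (++moved > max_wave)
      stop("relocation wave exceeded its cycle guard (%d moves)", max_wave);
    int v1 = problem.front();
    problem.pop_front();
    double ux = X[v1] - X[parent], uy = Y[v1] - Y[parent];
    double un = std::sqrt(ux * ux + uy * uy);
    if (un <= 1e-12) {  // coincides with parent: push in a random direction
      double a = unif_rand() * 2.0 * M_PI;
      ux = std::cos(a);
      uy = std::sin(a);
    } else {
      ux /= un;
      uy /= un;
    }
    double t_lo = wave_t_lo(X, Y, frozen, v1, ux, uy, d_min);
    double t = t_lo;
    if (t_lo > 0.0 || min_dist_to_frozen(X, Y, frozen, X[v1], Y[v1], v1) <
                          d_min) {
      // sample within the admissible window [d_min, 10] of clearance
      double span = std::max(0.0, 10.0 - d_min);
      t = t_lo + unif_rand() * span;
      // keep out of any residual forbidden interval and inside contact range
      double px = X[v1] + t * ux, py = Y[v1] + t * uy;
      double md = min_dist_to_frozen(X, Y, frozen, px, py, v1);
      if (md < d_min || md > 10.0) t = t_lo;
    }
    if (t > 0.0) {
      X[v1] += t * ux;
      Y[v1] += t * uy;
    }
    frozen[v1] = 1;
    for (int i = 0; i < n; ++i) {
      if (frozen[i] || queued[i]) continue;
      double dx = X[i] - X[v1], dy = Y[i] - Y[v1];
      if (std::sqrt(dx * dx + dy * dy) < d_min) {
        problem.push_back(i);
        queued[i] = 1;
      }
    }
  }
  return moved;
}

// [[Rcpp::export]]
List cpp_add_vertex(NumericMatrix coords, int parent, double radius,
                    double cell_radius, bool mutual, double d_min,
                    double lo, double hi, int max_wave = 100000) {
  std::vector<double> X, Y, Z;
  bool has_z;
  unpack_coords(coords, X, Y, Z, has_z);
  if (has_z) stop("steric vertex addition is defined for 2d islets");
  d_min = std::min(d_min, lo);  // the newcomer-parent pair cannot exceed lo
  int p = parent - 1;
  std::vector<std::pair<int, int>> edges =
      build_edges(X, Y, Z, false, radius, cell_radius, mutual);
  std::vector<int> nbrs;
  for (size_t k = 0; k < edges.size(); ++k) {
    if (edges[k].first == p) nbrs.push_back(edges[k].second);
    if (edges[k].second == p) nbrs.push_back(edges[k].first);
  }
  int moved = add_vertex_wave(X, Y, p, nbrs, cell_radius, d_min, lo, hi,
                              max_wave);
  if (moved < 0)
    stop("parent vertex is fully enclosed: no free angle for placement");
  NumericMatrix out((int)X.size(), 2);
  for (size_t i = 0; i < X.size(); ++i) {
    out(i, 0) = X[i];
    out(i, 1) = Y[i];
  }
  return List::create(_["coords"] = out, _["n_moved"] = moved);
}

// [[Rcpp::export]]
double cpp_min_pairdist(NumericMatrix coords) {
  std::vector<double> X, Y, Z;
  bool has_z;
  unpack_coords(coords, X, Y, Z, has_z);
  int n = (int)X.size();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double d = std::sqrt(dist2(X, Y, Z, i, j, has_z));
      if (d < best) best = d;
    }
  return best;
}

// One islet, one replicate of the balanced rearrangement process: per
// iteration one RL-selected deletion then one RL-selected steric addition,
// with the contact graph and basis quantities recomputed after every move.
// dir codes: +1 = P (RL+), -1 = M (RL-); basis: 0 = degree, 1 = component.
// [[Rcpp::export]]
List cpp_simulate_islet(NumericMatrix coords, double radius,
                        double cell_radius, bool mutual,
                        int add_dir, double add_rlp,
                        int del_dir, double del_rlp,
                        int basis, int n_iter,
                        double place_lo, double place_hi, double d_min,
                        bool trajectory, int max_wave = 100000) {
  std::vector<double> X, Y, Z;
  bool has_z;
  unpack_coords(coords, X, Y, Z, has_z);
  if (has_z) stop("the rearrangement process is defined for 2d islets");
  d_min = std::min(d_min, place_lo);
  int n0 = (int)X.size();
  if (n0 < 2) stop("need at least 2 cells to rearrange");

  int keep = trajectory ? n_iter : 1;
  NumericMatrix traj(keep, 7);
  colnames(traj) = CharacterVector::create(
      "iteration", "n_vertices", "mean_degree", "n_components", "n_singular",
      "cells_per_component", "min_pairdist");

  std::vector<std::pair<int, int>> edges =
      build_edges(X, Y, Z, false, radius, cell_radius, mutual);
  std::vector<int> deg, csize;
  compute_measures((int)X.size(), edges, &deg, &csize);

  for (int it = 0; it < n_iter; ++it) {
    // deletion
    int n = (int)X.size();
    std::vector<double> w(n);
    for (int i = 0; i < n; ++i) {
      double x = basis == 0 ? (double)deg[i] : (double)csize[i];
      w[i] = rl(x, del_dir, del_rlp);
    }
    int victim = sample_weighted(w);
    X.erase(X.begin() + victim);
    Y.erase(Y.begin() + victim);
    edges = build_edges(X, Y, Z, false, radius, cell_radius, mutual);
    compute_measures((int)X.size(), edges, &deg, &csize);

    // addition
    n = (int)X.size();
    std::vector<double> wa(n);
    for (int i = 0; i < n; ++i) {
      double x = basis == 0 ? (double)deg[i] : (double)csize[i];
      wa[i] = rl(x, add_dir, add_rlp);
    }
    std::vector<char> tried(n, 0);
    int added = -1, guard = 0;
    while (added < 0) {
      if (++guard > 4 * n + 16)
        stop("no parent with a free placement angle could be found");
      int parent = sample_weighted(wa);
      if (tried[parent]) continue;
      tried[parent] = 1;
      std::vector<int> nbrs;
      for (size_t k = 0; k < edges.size(); ++k) {
        if (edges[k].first == parent) nbrs.push_back(edges[k].second);
        if (edges[k].second == parent) nbrs.push_back(edges[k].first);
      }
      added = add_vertex_wave(X, Y, parent, nbrs, cell_radius, d_min,
                              place_lo, place_hi, max_wave);
    }
    edges = build_edges(X, Y, Z, false, radius, cell_radius, mutual);
    Measures m = compute_measures((int)X.size(), edges, &deg, &csize);

    if ((int)X.size() != n0)
      stop("internal error: cell count not conserved");  // invariant

    if (trajectory || it == n_iter - 1) {
      int row = trajectory ? it : 0;
      double mind = R_PosInf;
      for (int i = 0; i < (int)X.size(); ++i)
        for (int j = i + 1; j < (int)X.size(); ++j) {
          double dx = X[i] - X[j], dy = Y[i] - Y[j];
          double d = std::sqrt(dx * dx + dy * dy);
          if (d < mind) mind = d;
        }
      traj(row, 0) = it + 1;
      traj(row, 1) = m.n;
      traj(row, 2) = m.mean_degree;
      traj(row, 3) = m.n_components;
      traj(row, 4) = m.n_singular;
      traj(row, 5) = m.cells_per_component;
      traj(row, 6) = mind;
    }
  }

  NumericMatrix fin((int)X.size(), 2);
  for (size_t i = 0; i < X.size(); ++i) {
    fin(i, 0) = X[i];
    fin(i, 1) = Y[i];
  }
  return List::create(_["measures"] = traj, _["coords"] = fin);
}
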