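// Density clustering primitives for incremental spatiotemporal segmentation.
//
// A spatial hash grid (cell size = eps) provides O(1) expected-time
// eps-neighbourhood queries.  dbscan_seeded_cpp runs a DBSCAN pass over a
// point set in which some points already carry fixed aggregate labels
// ("seeds"): fixed labels are never revoked, unlabeled density-reachable
// groups either join the aggregate(s) they touch or are born as new
// aggregates, and groups touching several aggregates are dissected
// point-by-point along nearest-seed pathways.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct HashGrid {
  double eps;
  std::unordered_map<int64_t, std::vector<int>> cells;
  const double *x, *y;
  int n;

  static int64_t key(int cx, int cy) {
    return (static_cast<int64_t>(cx) << 32) ^ (static_cast<uint32_t>(cy));
  }

  HashGrid(const double* x_, const double* y_, int n_, double eps_)
      : eps(eps_), x(x_), y(y_), n(n_) {
    cells.reserve(static_cast<size_t>(n) * 2 + 8);
    for (int i = 0; i < n; ++i) {
      cells[key(cell(x[i]), cell(y[i]))].push_back(i);
    }
  }

  int cell(double v) const { return static_cast<int>(std::floor(v / eps)); }

  // visit all points within eps of (px, py)
  template <class F>
  void each_neighbor(double px, double py, F f) const {
    const double e2 = eps * eps;
    int cx = cell(px), cy = cell(py);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        auto it = cells.find(key(cx + dx, cy + dy));
        if (it == cells.end()) continue;
        for (int j : it->second) {
          double ddx = x[j] - px, ddy = y[j] - py;
          if (ddx * ddx + ddy * ddy <= e2) f(j);
        }
      }
  }
};

}  // namespace

namespace {
struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n + 1) {
    for (int i = 0; i <= n; ++i) parent[i] = i;
  }
  int find(int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  }
  // canonical label is the smaller (older) id
  void merge(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (a < b) parent[b] = a; else parent[a] = b;
  }
};
}  // namespace

// `established` is indexed by label value (1-based: established[l-1]); young
// aggregates (not yet established) are satellite fragments of a growing
// structure and are merged into whatever they become density-connected
// with; dissection along nearest-seed pathways only happens between two or
// more established aggregates (distinct temporal pathways).
// `cen_x`, `cen_y`, `cen_r` give the centroid and equivalent radius of each
// pre-existing aggregate (indexed by label, 1-based).  When a component
// bridges two established aggregates they are dissected only if they look
// externally tangent: centroid separation >= sep_ratio * (r_a + r_b).
// Internal shards of one structure (centroids buried inside the union) fail
// this and merge instead.
// [[Rcpp::export]]
IntegerVector dbscan_seeded_cpp(NumericVector x, NumericVector y,
                                IntegerVector labels, double eps,
                                int min_pts, int first_new_id,
                                LogicalVector established,
                                NumericVector cen_x, NumericVector cen_y,
                                NumericVector cen_r, double sep_ratio) {
  const int n = x.size();
  if (labels.size() != n) stop("labels length mismatch");
  HashGrid g(x.begin(), y.begin(), n, eps);

  // degree (neighbour count including self) and core status over ALL points:
  // accumulated density from already-assigned points is what lets sparse new
  // events on an existing structure reach core status.
  std::vector<int> degree(n, 0);
  for (int i = 0; i < n; ++i) {
    int d = 0;
    g.each_neighbor(x[i], y[i], [&](int) { ++d; });
    degree[i] = d;
  }
  std::vector<char> core(n);
  for (int i = 0; i < n; ++i) core[i] = degree[i] >= min_pts;

  std::vector<int> lab(n);
  for (int i = 0; i < n; ++i) lab[i] = labels[i];

  int next_id = first_new_id;
  const int capacity = first_new_id + n + 1;
  UnionFind uf(capacity);
  std::vector<char> est(capacity + 1, 0);
  for (int l = 0; l < established.size() && l < capacity; ++l)
    est[l + 1] = established[l] ? 1 : 0;

  std::vector<int> comp;
  std::vector<char> in_comp(n, 0);

  for (int i = 0; i < n; ++i) {
    if (lab[i] != 0 || !core[i] || in_comp[i]) continue;
    comp.clear();
    std::vector<int> contacts;  // distinct canonical labels touched
    std::queue<int> q;
    q.push(i);
    in_comp[i] = 1;
    comp.push_back(i);
    while (!q.empty()) {
      int p = q.front(); q.pop();
      if (!core[p]) continue;  // border points are members but do not expand
      g.each_neighbor(x[p], y[p], [&](int r) {
        if (lab[r] == 0) {
          if (!in_comp[r]) {
            in_comp[r] = 1;
            comp.push_back(r);
            q.push(r);
          }
        } else {
          int c0 = uf.find(lab[r]);
          bool seen = false;
          for (int c : contacts) if (c == c0) { seen = true; break; }
          if (!seen) contacts.push_back(c0);
        }
      });
    }
    // established contacts that are not externally tangent are shards of a
    // single structure: merge them before deciding whether to dissect
    {
      std::vector<int> estc;
      for (int c : contacts) if (est[c]) estc.push_back(c);
      for (size_t a = 0; a + 1 < estc.size(); ++a)
        for (size_t b = a + 1; b < estc.size(); ++b) {
          int la = uf.find(estc[a]), lb = uf.find(estc[b]);
          if (la == lb) continue;
          bool have_a = la < cen_x.size() + 1 && la >= 1 && cen_r[la - 1] > 0;
          bool have_b = lb < cen_x.size() + 1 && lb >= 1 && cen_r[lb - 1] > 0;
          if (!have_a || !have_b) continue;
          double dx = cen_x[la - 1] - cen_x[lb - 1];
          double dy = cen_y[la - 1] - cen_y[lb - 1];
          double sep = std::sqrt(dx * dx + dy * dy);
          if (sep < sep_ratio * (cen_r[la - 1] + cen_r[lb - 1]))
            uf.merge(la, lb);
        }
      // re-canonicalize contact list
      std::vector<int> cc;
      for (int c : contacts) {
        int c0 = uf.find(c);
        bool seen = false;
        for (int d : cc) if (d == c0) { seen = true; break; }
        if (!seen) cc.push_back(c0);
      }
      contacts.swap(cc);
    }
    int n_est = 0;
    for (int c : contacts) if (est[c]) ++n_est;
    if (contacts.empty()) {
      int id = next_id++;
      for (int p : comp) lab[p] = id;
    } else if (n_est >= 2) {
      // dissect along nearest-seed pathways between established aggregates:
      // take the canonical label of the nearest labelled neighbour, then
      // propagate in waves through the component.
      std::vector<int> newlab(comp.size(), 0);
      std::unordered_map<int, int> pos;  // point -> index in comp
      pos.reserve(comp.size() * 2);
      for (size_t k = 0; k < comp.size(); ++k) pos[comp[k]] = static_cast<int>(k);
      for (size_t k = 0; k < comp.size(); ++k) {
        int p = comp[k];
        double best = R_PosInf; int bl = 0;
        g.each_neighbor(x[p], y[p], [&](int r) {
          if (lab[r] == 0) return;
          int l = uf.find(lab[r]);
          if (!est[l]) return;
          double ddx = x[r] - x[p], ddy = y[r] - y[p];
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 < best || (d2 == best && l < bl)) { best = d2; bl = l; }
        });
        newlab[k] = bl;
      }
      bool changed = true;
      while (changed) {
        changed = false;
        std::vector<int> upd(newlab);
        for (size_t k = 0; k < comp.size(); ++k) {
          if (newlab[k] != 0) continue;
          int p = comp[k];
          double best = R_PosInf; int bl = 0;
          g.each_neighbor(x[p], y[p], [&](int r) {
            auto it = pos.find(r);
            if (it == pos.end() || newlab[it->second] == 0) return;
            double ddx = x[r] - x[p], ddy = y[r] - y[p];
            double d2 = ddx * ddx + ddy * ddy;
            int l = newlab[it->second];
            if (d2 < best || (d2 == best && l < bl)) { best = d2; bl = l; }
          });
          if (bl != 0) { upd[k] = bl; changed = true; }
        }
        newlab.swap(upd);
      }
      int fallback = 0;
      for (int c : contacts) if (est[c] && (fallback == 0 || c < fallback))
        fallback = c;
      for (size_t k = 0; k < comp.size(); ++k)
        lab[comp[k]] = newlab[k] != 0 ? newlab[k] : fallback;
      // young aggregates caught between established ones join the nearest
      // established contact wholesale (rare)
      for (int c : contacts) {
        if (est[c]) continue;
        uf.merge(c, fallback);
      }
    } else {
      // at most one established contact: everything (component plus any
      // young contacted aggregates) merges; the canonical label is the
      // oldest (smallest) id involved.
      int target = contacts[0];
      for (int c : contacts) if (c < target) target = c;
      for (int c : contacts) uf.merge(c, target);
      target = uf.find(target);
      for (int p : comp) lab[p] = target;
    }
  }

  // resolve union-find on every labelled point
  for (int i = 0; i < n; ++i) if (lab[i] != 0) lab[i] = uf.find(lab[i]);

  // absorb remaining unlabeled border points adjacent to a labelled core
  // point (nearest such neighbour wins; snapshot semantics).
  std::vector<int> snap(lab);
  for (int i = 0; i < n; ++i) {
    if (snap[i] != 0) continue;
    double best = R_PosInf; int bl = 0;
    g.each_neighbor(x[i], y[i], [&](int r) {
      if (snap[r] == 0 || !core[r]) return;
      double ddx = x[r] - x[i], ddy = y[r] - y[i];
      double d2 = ddx * ddx + ddy * ddy;
      if (d2 < best || (d2 == best && snap[r] < bl)) { best = d2; bl = snap[r]; }
    });
    if (bl != 0) lab[i] = bl;
  }

  return IntegerVector(lab.begin(), lab.end());
}

// Nearest labelled point within `radius` for each query point.
// Returns a list with integer `label` (0 when none in range) and numeric
// `dist` (NA when none).
// [[Rcpp::export]]
List nearest_labeled_cpp(NumericVector px, NumericVector py,
                         IntegerVector plab, NumericVector qx,
                         NumericVector qy, double radius) {
  const int n = px.size(), m = qx.size();
  std::vector<double> lx, ly;
  std::vector<int> ll;
  lx.reserve(n); ly.reserve(n); ll.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (plab[i] != 0) { lx.push_back(px[i]); ly.push_back(py[i]); ll.push_back(plab[i]); }
  }
  IntegerVector outl(m);
  NumericVector outd(m);
  if (lx.empty()) {
    std::fill(outl.begin(), outl.end(), 0);
    std::fill(outd.begin(), outd.end(), NA_REAL);
    return List::create(_["label"] = outl, _["dist"] = outd);
  }
  HashGrid g(lx.data(), ly.data(), static_cast<int>(lx.size()), radius);
  for (int i = 0; i < m; ++i) {
    double best = R_PosInf; int bl = 0;
    g.each_neighbor(qx[i], qy[i], [&](int r) {
      double ddx = lx[r] - qx[i], ddy = ly[r] - qy[i];
      double d2 = ddx * ddx + ddy * ddy;
      if (d2 < best || (d2 == best && ll[r] < bl)) { best = d2; bl = ll[r]; }
    });
    outl[i] = bl;
    outd[i] = bl == 0 ? NA_REAL : std::sqrt(best);
  }
  return List::create(_["label"] = outl, _["dist"] = outd);
}

// Repeatedly attach unlabeled points to the nearest labelled point within
// eps (snapshot per pass).  Used as the final rim sweep: late-arriving
// events on the advancing growth front are individually sparse but sit
// within one eps of the established structure.
// [[Rcpp::export]]
IntegerVector sweep_labels_cpp(NumericVector x, NumericVector y,
                               IntegerVector labels, double eps, int passes) {
  const int n = x.size();
  std::vector<int> lab(labels.begin(), labels.end());
  HashGrid g(x.begin(), y.begin(), n, eps);
  for (int pass = 0; pass < passes; ++pass) {
    std::vector<int> snap(lab);
    bool changed = false;
    for (int i = 0; i < n; ++i) {
      if (snap[i] != 0) continue;
      double best = R_PosInf; int bl = 0;
      g.each_neighbor(x[i], y[i], [&](int r) {
        if (snap[r] == 0) return;
        double ddx = x[r] - x[i], ddy = y[r] - y[i];
        double d2 = ddx * ddx + ddy * ddy;
        if (d2 < best || (d2 == best && snap[r] < bl)) { best = d2; bl = snap[r]; }
      });
      if (bl != 0) { lab[i] = bl; changed = true; }
    }
    if (!changed) break;
  }
  return IntegerVector(lab.begin(), lab.end());
}
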