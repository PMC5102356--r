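#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Bottom-up multi-resolution region merging.
//
// Regions start as single pixels; the merge cost of two adjacent regions a, b is
//   f = (1 - shape_w) * dh_color + shape_w * dh_shape
//   dh_color = sum_c w_c * (n_m s_m - n_a s_a - n_b s_b)        (s = population sd)
//   dh_shape = cmpct_w * dh_cmp + (1 - cmpct_w) * dh_smooth
//   dh_cmp   = p_m sqrt(n_m) - p_a sqrt(n_a) - p_b sqrt(n_b)    (p = crack perimeter)
//   dh_smooth= n_m p_m / b_m - n_a p_a / b_a - n_b p_b / b_b    (b = bbox perimeter)
// Merging proceeds by local mutual-best-fitting in a seeded scan order and stops
// when no admissible merge has f < scale^2.  Merged regions take the smaller of
// the two region ids (ids are 0-based pixel linear indices), so the process is
// fully deterministic given the scan permutation.

namespace {

struct Engine {
  int nr, nc, N, nchan;
  double shape_w, cmpct_w, scale2;
  std::vector<double> w;                    // channel weights
  std::vector<int> parent, n, perim;
  std::vector<int> minr, maxr, minc, maxc;
  std::vector<std::vector<double>> sum, sumsq;  // [chan][region]
  std::vector<std::map<int, int>> adj;      // region -> (neighbor -> shared 4-edges)

  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }

  double sdev(double s, double ss, int nn) const {
    double m = s / nn;
    double v = ss / nn - m * m;
    return v > 0 ? std::sqrt(v) : 0.0;
  }

  double cost(int a, int b) {
    int na = n[a], nb = n[b], nm = na + nb;
    double col = 0.0;
    for (int c = 0; c < nchan; ++c) {
      double sa = sum[c][a], sb = sum[c][b];
      double ssa = sumsq[c][a], ssb = sumsq[c][b];
      col += w[c] * (nm * sdev(sa + sb, ssa + ssb, nm)
                     - na * sdev(sa, ssa, na)
                     - nb * sdev(sb, ssb, nb));
    }
    if (shape_w == 0.0) return col;
    std::map<int, int>::const_iterator it = adj[a].find(b);
    int shared = (it == adj[a].end()) ? 0 : it->second;
    double pa = perim[a], pb = perim[b], pm = pa + pb - 2.0 * shared;
    double cmp = pm * std::sqrt((double)nm) - pa * std::sqrt((double)na)
               - pb * std::sqrt((double)nb);
    double ba = 2.0 * ((maxr[a] - minr[a] + 1) + (maxc[a] - minc[a] + 1));
    double bb = 2.0 * ((maxr[b] - minr[b] + 1) + (maxc[b] - minc[b] + 1));
    int mr = std::min(minr[a], minr[b]), Mr = std::max(maxr[a], maxr[b]);
    int mc = std::min(minc[a], minc[b]), Mc = std::max(maxc[a], maxc[b]);
    double bm = 2.0 * ((Mr - mr + 1) + (Mc - mc + 1));
    double smo = nm * pm / bm - na * pa / ba - nb * pb / bb;
    double shape = cmpct_w * cmp + (1.0 - cmpct_w) * smo;
    return (1.0 - shape_w) * col + shape_w * shape;
  }

  // best neighbor: lowest cost, ties to the smaller neighbor id
  int best_neighbor(int r, double &fbest) {
    int b = -1;
    fbest = R_PosInf;
    for (std::map<int, int>::const_iterator it = adj[r].begin();
         it != adj[r].end(); ++it) {
      double f = cost(r, it->first);
      if (f < fbest || (f == fbest && (b < 0 || it->first < b))) {
        fbest = f;
        b = it->first;
      }
    }
    return b;
  }

  void merge(int a, int b) {
    int r = std::min(a, b), s = std::max(a, b);
    std::map<int, int>::iterator it = adj[r].find(s);
    int shared = (it == adj[r].end()) ? 0 : it->second;
    perim[r] = perim[r] + perim[s] - 2 * shared;
    n[r] += n[s];
    minr[r] = std::min(minr[r], minr[s]);
    maxr[r] = std::max(maxr[r], maxr[s]);
    minc[r] = std::min(minc[r], minc[s]);
    maxc[r] = std::max(maxc[r], maxc[s]);
    for (int c = 0; c < nchan; ++c) {
      sum[c][r] += sum[c][s];
      sumsq[c][r] += sumsq[c][s];
    }
    parent[s] = r;
    adj[r].erase(s);
    for (std::map<int, int>::iterator jt = adj[s].begin();
         jt != adj[s].end(); ++jt) {
      int t = jt->first;
      if (t == r) continue;
      adj[r][t] += jt->second;
      adj[t].erase(s);
      adj[t][r] += jt->second;
    }
    std::map<int, int>().swap(adj[s]);
  }
};

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_mrs(List channels, NumericVector weights, LogicalMatrix domain,
                      IntegerVector perm, double scale, double shape_w,
                      double cmpct_w, int connectivity) {
  Engine E;
  NumericMatrix ch0 = channels[0];
  E.nr = ch0.nrow();
  E.nc = ch0.ncol();
  E.N = E.nr * E.nc;
  E.nchan = channels.size();
  E.shape_w = shape_w;
  E.cmpct_w = cmpct_w;
  E.scale2 = scale * scale;
  E.w.assign(weights.begin(), weights.end());
  E.parent.resize(E.N);
  E.n.assign(E.N, 0);
  E.perim.assign(E.N, 0);
  E.minr.resize(E.N);
  E.maxr.resize(E.N);
  E.minc.resize(E.N);
  E.maxc.resize(E.N);
  E.sum.assign(E.nchan, std::vector<double>(E.N, 0.0));
  E.sumsq.assign(E.nchan, std::vector<double>(E.N, 0.0));
  E.adj.resize(E.N);

  std::vector<NumericMatrix> chs;
  for (int c = 0; c < E.nchan; ++c) chs.push_back(as<NumericMatrix>(channels[c]));

  for (int j = 0; j < E.nc; ++j) {
    for (int i = 0; i < E.nr; ++i) {
      if (!domain(i, j)) continue;
      int p = i + j * E.nr;
      E.parent[p] = p;
      E.n[p] = 1;
      E.perim[p] = 4;
      E.minr[p] = E.maxr[p] = i;
      E.minc[p] = E.maxc[p] = j;
      for (int c = 0; c < E.nchan; ++c) {
        double v = chs[c](i, j);
        E.sum[c][p] = v;
        E.sumsq[c][p] = v * v;
      }
    }
  }
  // adjacency (shared 4-edges; diagonal neighbors at 8-connectivity share none)
  for (int j = 0; j < E.nc; ++j) {
    for (int i = 0; i < E.nr; ++i) {
      if (!domain(i, j)) continue;
      int p = i + j * E.nr;
      if (i + 1 < E.nr && domain(i + 1, j)) {
        E.adj[p][p + 1] += 1;
        E.adj[p + 1][p] += 1;
      }
      if (j + 1 < E.nc && domain(i, j + 1)) {
        E.adj[p][p + E.nr] += 1;
        E.adj[p + E.nr][p] += 1;
      }
      if (connectivity == 8) {
        if (i + 1 < E.nr && j + 1 < E.nc && domain(i + 1, j + 1)) {
          E.adj[p][p + E.nr + 1];
          E.adj[p + E.nr + 1][p];
        }
        if (i + 1 < E.nr && j >= 1 && domain(i + 1, j - 1)) {
          E.adj[p][p - E.nr + 1];
          E.adj[p - E.nr + 1][p];
        }
      }
    }
  }

  // scan positions from the seeded permutation (1-based linear indices from R)
  std::vector<int> pos(E.N, -1);
  for (int k = 0; k < perm.size(); ++k) pos[perm[k] - 1] = k;

  std::vector<int> roots;
  roots.reserve(E.N);
  bool changed = true;
  while (changed) {
    changed = false;
    roots.clear();
    for (int p = 0; p < E.N; ++p)
      if (E.n[p] > 0 && E.parent[p] == p) roots.push_back(p);
    std::sort(roots.begin(), roots.end(),
              [&pos](int a, int b) { return pos[a] < pos[b]; });
    for (size_t k = 0; k < roots.size(); ++k) {
      int r = roots[k];
      if (E.parent[r] != r) continue;
      double fr;
      int b = E.best_neighbor(r, fr);
      if (b < 0 || !(fr < E.scale2)) continue;
      double fb;
      int b2 = E.best_neighbor(b, fb);
      if (b2 == r) {
        E.merge(r, b);
        changed = true;
      }
    }
    Rcpp::checkUserInterrupt();
  }

  IntegerMatrix lab(E.nr, E.nc);
  std::vector<int> newlab(E.N, 0);
  int next = 0;
  for (int i = 0; i < E.nr; ++i) {
    for (int j = 0; j < E.nc; ++j) {
      if (!domain(i, j)) { lab(i, j) = 0; continue; }
      int r = E.find(i + j * E.nr);
      if (newlab[r] == 0) newlab[r] = ++next;
      lab(i, j) = newlab[r];
    }
  }
  lab.attr("n_segments") = next;
  return lab;
}

// Connected-component labeling of a binary mask; labels assigned 1..n in
// row-major order of first encounter.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        const int di4[4] = {-1, 1, 0, 0}, dj4[4] = {0, 0, -1, 1};
        const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1},
                  dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
        int nn = (connectivity == 8) ? 8 : 4;
        const int *di = (connectivity == 8) ? di8 : di4;
        const int *dj = (connectivity == 8) ? dj8 : dj4;
        for (int k = 0; k < nn; ++k) {
          int qi = pi + di[k], qj = pj + dj[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  lab.attr("n_segments") = next;
  return lab;
}
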