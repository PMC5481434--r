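#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// ---- connected components (8-connectivity, two-pass union-find) ----

static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
  return i;
}

// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0); // label 0 = background
  int next = 1;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      // neighbours already visited in column-major order:
      // (r-1,c), (r-1,c-1), (r,c-1), (r+1,c-1)
      int nb[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      int lmin = 0;
      for (int k = 0; k < 4; ++k) {
        int rr = nb[k][0], cc = nb[k][1];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          int root = uf_find(parent, l);
          if (lmin == 0 || root < lmin) lmin = root;
        }
      }
      if (lmin == 0) {
        lab(r, c) = next;
        parent.push_back(next);
        ++next;
      } else {
        lab(r, c) = lmin;
        for (int k = 0; k < 4; ++k) {
          int rr = nb[k][0], cc = nb[k][1];
          if (rr < 0 || rr >= nr || cc < 0) continue;
          int l = lab(rr, cc);
          if (l > 0) parent[uf_find(parent, l)] = lmin;
        }
      }
    }
  }
  // relabel to consecutive ids
  std::vector<int> newid(next, 0);
  int out = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!lab(r, c)) continue;
      int root = uf_find(parent, lab(r, c));
      if (!newid[root]) newid[root] = ++out;
      lab(r, c) = newid[root];
    }
  lab.attr("n_components") = out;
  return lab;
}

// Remove 8-connected components smaller than min_size, then fill single-pixel
// holes: a false pixel inside `domain` whose in-bounds 8-neighbours are all
// true becomes true.
// [[Rcpp::export]]
LogicalMatrix clean_mask_cpp(LogicalMatrix mask, int min_size,
                             LogicalMatrix domain) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab = cc_label_cpp(mask);
  int ncomp = lab.attr("n_components");
  std::vector<int> size(ncomp + 1, 0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) size[lab(r, c)]++;
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = lab(r, c) > 0 && size[lab(r, c)] >= min_size;
  // fill 1-px holes
  LogicalMatrix res = clone(out);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (out(r, c) || !domain(r, c)) continue;
      bool all_on = true; int seen = 0;
      for (int dc = -1; dc <= 1 && all_on; ++dc)
        for (int dr = -1; dr <= 1; ++dr) {
          if (!dr && !dc) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          ++seen;
          if (!out(rr, cc)) { all_on = false; break; }
        }
      if (all_on && seen == 8) res(r, c) = true;
    }
  return res;
}

// ---- Marker State Space exhaustive threshold scan ----
//
// X: n x p marker matrix; y: 0 = control, 1 = case.
// grids: list of numeric candidate-threshold vectors, one per column of X.
// subsets: one subset of marker columns (1-based) per row, padded with 0.
// For every subset and every combination of one threshold per member the
// scan binarizes (value > threshold), labels each observed state by its
// majority class (ties and unobserved states -> control), and keeps the rule
// if training sensitivity and specificity both reach their minima.
// If a test set is supplied each qualifying rule is applied to it.
// collect = true materializes qualifying panels; otherwise only the count
// and the summed test accuracy are returned (used inside cross-validation).
// [[Rcpp::export]]
List mss_scan_cpp(NumericMatrix X, IntegerVector y, List grids,
                  IntegerMatrix subsets, double min_sens, double min_spec,
                  Nullable<NumericMatrix> Xtest_, Nullable<IntegerVector> ytest_,
                  bool collect) {
  int n = X.nrow();
  bool has_test = Xtest_.isNotNull();
  NumericMatrix Xtest;
  IntegerVector ytest;
  int ntest = 0;
  if (has_test) {
    Xtest = NumericMatrix(Xtest_);
    ytest = IntegerVector(ytest_);
    ntest = Xtest.nrow();
  }
  int n_case = 0;
  for (int i = 0; i < n; ++i) n_case += y[i];
  int n_ctrl = n - n_case;

  std::vector<int> out_subset, out_mask, out_tp, out_fn, out_fp, out_tn;
  std::vector<double> out_t1, out_t2, out_t3, out_testacc;
  long long n_panels = 0;
  double sum_testacc = 0.0;
  const double eps = 1e-12;

  for (int srow = 0; srow < subsets.nrow(); ++srow) {
    std::vector<int> mk;
    for (int j = 0; j < subsets.ncol(); ++j)
      if (subsets(srow, j) > 0) mk.push_back(subsets(srow, j) - 1);
    int m = mk.size();
    if (m == 0 || m > 3) stop("subsets must have 1-3 members");
    int n_states = 1 << m;

    std::vector<NumericVector> g(m);
    for (int j = 0; j < m; ++j) g[j] = grids[mk[j]];
    std::vector<int> idx(m, 0);
    // partial[j][i]: state bits of markers 0..j for patient i
    std::vector<std::vector<uint8_t> > partial(m, std::vector<uint8_t>(n));
    std::vector<std::vector<uint8_t> > tpartial;
    if (has_test) tpartial.assign(m, std::vector<uint8_t>(ntest));

    int redo_from = 0;
    bool done = false;
    std::vector<int> cnt_case(n_states), cnt_ctrl(n_states);
    while (!done) {
      for (int j = redo_from; j < m; ++j) {
        double t = g[j][idx[j]];
        const std::vector<uint8_t> *prev = j ? &partial[j - 1] : 0;
        for (int i = 0; i < n; ++i) {
          uint8_t b = X(i, mk[j]) > t ? (1 << j) : 0;
          partial[j][i] = (j ? (*prev)[i] : 0) | b;
        }
        if (has_test) {
          const std::vector<uint8_t> *tprev = j ? &tpartial[j - 1] : 0;
          for (int i = 0; i < ntest; ++i) {
            uint8_t b = Xtest(i, mk[j]) > t ? (1 << j) : 0;
            tpartial[j][i] = (j ? (*tprev)[i] : 0) | b;
          }
        }
      }
      std::fill(cnt_case.begin(), cnt_case.end(), 0);
      std::fill(cnt_ctrl.begin(), cnt_ctrl.end(), 0);
      const std::vector<uint8_t> &st = partial[m - 1];
      for (int i = 0; i < n; ++i) {
        if (y[i]) ++cnt_case[st[i]]; else ++cnt_ctrl[st[i]];
      }
      int tp = 0, tn = 0, case_mask = 0;
      for (int s = 0; s < n_states; ++s) {
        if (cnt_case[s] > cnt_ctrl[s]) { case_mask |= (1 << s); tp += cnt_case[s]; }
        else tn += cnt_ctrl[s];
      }
      double sens = n_case ? (double)tp / n_case : 0.0;
      double spec = n_ctrl ? (double)tn / n_ctrl : 0.0;
      if (sens + eps >= min_sens && spec + eps >= min_spec) {
        ++n_panels;
        double tacc = NA_REAL;
        if (has_test) {
          const std::vector<uint8_t> &ts = tpartial[m - 1];
          int correct = 0;
          for (int i = 0; i < ntest; ++i) {
            int pred = (case_mask >> ts[i]) & 1;
            if (pred == ytest[i]) ++correct;
          }
          tacc = ntest ? (double)correct / ntest : NA_REAL;
          sum_testacc += tacc;
        }
        if (collect) {
          out_subset.push_back(srow + 1);
          out_mask.push_back(case_mask);
          out_tp.push_back(tp);
          out_fn.push_back(n_case - tp);
          out_fp.push_back(n_ctrl - tn);
          out_tn.push_back(tn);
          out_t1.push_back(g[0][idx[0]]);
          out_t2.push_back(m > 1 ? g[1][idx[1]] : NA_REAL);
          out_t3.push_back(m > 2 ? g[2][idx[2]] : NA_REAL);
          if (has_test) out_testacc.push_back(tacc);
        }
      }
      // odometer increment (last digit fastest)
      int j = m - 1;
      while (j >= 0) {
        if (++idx[j] < g[j].size()) break;
        idx[j] = 0;
        --j;
      }
      if (j < 0) done = true; else redo_from = j;
    }
  }

  if (!collect)
    return List::create(_["n_panels"] = (double)n_panels,
                        _["mean_test_accuracy"] =
                          n_panels ? sum_testacc / n_panels : NA_REAL);
  List res = List::create(
    _["subset"] = wrap(out_subset), _["t1"] = wrap(out_t1),
    _["t2"] = wrap(out_t2), _["t3"] = wrap(out_t3),
    _["case_mask"] = wrap(out_mask), _["tp"] = wrap(out_tp),
    _["fn"] = wrap(out_fn), _["fp"] = wrap(out_fp), _["tn"] = wrap(out_tn),
    _["n_panels"] = (double)n_panels);
  if (has_test) res["test_accuracy"] = wrap(out_testacc);
  return res;
}
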