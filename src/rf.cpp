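// Random forest for regression and binary classification, with per-tree
// out-of-bag permutation importance (the classical importance baseline).
//
// CART-style trees: bootstrap resample per tree, `mtry` candidate features
// per node, best axis-aligned split by the sum-of-squares criterion (for
// 0/1 outcomes this ranks splits identically to Gini impurity), grown to
// `nodesize`.  Regression predicts the mean over trees; classification the
// fraction of tree votes for class 1.  All randomness comes from R's RNG
// so results are reproducible under set.seed().
//
// Tree growth uses presorted per-feature index slices that are partitioned
// in place at every split, so no sorting happens inside nodes: the cost per
// tree level is O(p * n) plus O(mtry * n) for the split search.

#include <Rcpp.h>
#include <algorithm>
#include <limits>
#include <numeric>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline int runif_int(int n) {
  int v = static_cast<int>(unif_rand() * n);
  return v < n ? v : n - 1;
}

struct ForestData {
  std::vector<int> svar, left, right;
  std::vector<double> sval, value;
  std::vector<int> offset, nnodes; // per tree
};

// Predict one row through one tree.  `override_var` (if >= 0) replaces that
// feature's value with `override_val` (used for OOB permutation).
static inline double tree_predict_row(const ForestData& fd, int tree,
                                      const double* X, int N, int row,
                                      int override_var = -1,
                                      double override_val = 0.0) {
  int node = fd.offset[tree];
  while (fd.svar[node] >= 0) {
    int v = fd.svar[node];
    double x = (v == override_var) ? override_val
                                   : X[static_cast<size_t>(v) * N + row];
    node = (x <= fd.sval[node]) ? fd.left[node] : fd.right[node];
  }
  return fd.value[node];
}

struct NodeJob { int node, start, end; };

// [[Rcpp::export]]
List cpp_rf_fit(NumericMatrix Xr, NumericVector yr, bool classify,
                int ntree, int mtry, int nodesize, bool importance) {
  const int N = Xr.nrow(), p = Xr.ncol();
  const double* X = REAL(Xr);
  const double* y = REAL(yr);
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;

  ForestData fd;
  NumericMatrix imp;
  if (importance) imp = NumericMatrix(ntree, p);

  // argsort of every feature column, shared by all trees
  std::vector<int> full_order(static_cast<size_t>(p) * N);
  for (int f = 0; f < p; ++f) {
    int* ord = full_order.data() + static_cast<size_t>(f) * N;
    std::iota(ord, ord + N, 0);
    const double* xf = X + static_cast<size_t>(f) * N;
    std::sort(ord, ord + N, [xf](int a, int b) { return xf[a] < xf[b]; });
  }

  // aggregated OOB predictions for the fit-quality estimate
  std::vector<double> oob_sum(N, 0.0);
  std::vector<int> oob_cnt(N, 0);

  // reusable per-tree buffers
  std::vector<int> SI(static_cast<size_t>(p) * N); // sorted index slices
  std::vector<int> tmpL(N), tmpR(N), inbag(N), feat(p), oob, perm;
  std::vector<char> goleft(N);
  std::vector<char> used(p);

  for (int t = 0; t < ntree; ++t) {
    // bootstrap resample (counts per original row)
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < N; ++i) inbag[runif_int(N)]++;
    oob.clear();
    for (int i = 0; i < N; ++i) if (inbag[i] == 0) oob.push_back(i);

    // per-feature sorted slices of the bootstrap sample (with repeats)
    for (int f = 0; f < p; ++f) {
      const int* ord = full_order.data() + static_cast<size_t>(f) * N;
      int* si = SI.data() + static_cast<size_t>(f) * N;
      int pos = 0;
      for (int k = 0; k < N; ++k) {
        const int i = ord[k];
        for (int c = 0; c < inbag[i]; ++c) si[pos++] = i;
      }
    }

    const int base = static_cast<int>(fd.svar.size());
    fd.offset.push_back(base);
    std::fill(used.begin(), used.end(), 0);
    for (int f = 0; f < p; ++f) feat[f] = f;

    fd.svar.push_back(-1); fd.sval.push_back(0.0);
    fd.left.push_back(-1); fd.right.push_back(-1); fd.value.push_back(0.0);
    std::vector<NodeJob> stack;
    stack.push_back({base, 0, N});

    while (!stack.empty()) {
      const NodeJob job = stack.back(); stack.pop_back();
      const int start = job.start, end = job.end, n = end - start;

      const int* si0 = SI.data() + start; // feature-0 slice holds the node
      double sum = 0.0, sumsq = 0.0;
      for (int k = 0; k < n; ++k) {
        const double v = y[si0[k]];
        sum += v; sumsq += v * v;
      }
      fd.value[job.node] = sum / n;
      if (n <= nodesize || sumsq - sum * sum / n < 1e-12) continue;

      int best_var = -1;
      double best_score = -std::numeric_limits<double>::infinity(),
             best_split = 0.0;
      for (int m = 0; m < mtry; ++m) {
        std::swap(feat[m], feat[m + runif_int(p - m)]);
        const int f = feat[m];
        const double* xf = X + static_cast<size_t>(f) * N;
        const int* si = SI.data() + static_cast<size_t>(f) * N + start;
        double cum = 0.0;
        for (int k = 0; k < n - 1; ++k) {
          cum += y[si[k]];
          const double xk = xf[si[k]], xk1 = xf[si[k + 1]];
          if (xk1 <= xk) continue;
          const double nl = k + 1, nr = n - k - 1;
          const double rest = sum - cum;
          const double score = cum * cum / nl + rest * rest / nr;
          if (score > best_score) {
            best_score = score;
            best_var = f;
            best_split = xk + 0.5 * (xk1 - xk);
          }
        }
      }
      if (best_var < 0) continue; // no improving split among candidates

      // partition every feature slice by the split, preserving sort order
      const double* xb = X + static_cast<size_t>(best_var) * N;
      const int* sib = SI.data() + static_cast<size_t>(best_var) * N + start;
      int nl = 0;
      for (int k = 0; k < n; ++k) {
        const int i = sib[k];
        const char g = xb[i] <= best_split;
        goleft[i] = g;
        nl += g;
      }
      if (nl == 0 || nl == n) continue; // numerical guard
      for (int f = 0; f < p; ++f) {
        int* si = SI.data() + static_cast<size_t>(f) * N + start;
        int cl = 0, cr = 0;
        for (int k = 0; k < n; ++k) {
          const int i = si[k];
          if (goleft[i]) tmpL[cl++] = i; else tmpR[cr++] = i;
        }
        std::copy(tmpL.begin(), tmpL.begin() + cl, si);
        std::copy(tmpR.begin(), tmpR.begin() + cr, si + cl);
      }

      const int li = static_cast<int>(fd.svar.size());
      fd.svar.push_back(-1); fd.sval.push_back(0.0);
      fd.left.push_back(-1); fd.right.push_back(-1); fd.value.push_back(0.0);
      const int ri = static_cast<int>(fd.svar.size());
      fd.svar.push_back(-1); fd.sval.push_back(0.0);
      fd.left.push_back(-1); fd.right.push_back(-1); fd.value.push_back(0.0);

      fd.svar[job.node] = best_var;
      fd.sval[job.node] = best_split;
      fd.left[job.node] = li;
      fd.right[job.node] = ri;
      used[best_var] = 1;
      stack.push_back({li, start, start + nl});
      stack.push_back({ri, start + nl, end});
    }
    fd.nnodes.push_back(static_cast<int>(fd.svar.size()) - base);

    // OOB bookkeeping and per-tree permutation importance
    const int no = static_cast<int>(oob.size());
    if (no > 0) {
      double err0 = 0.0;
      for (int k = 0; k < no; ++k) {
        const double pr = tree_predict_row(fd, t, X, N, oob[k]);
        const double pv = classify ? (pr >= 0.5 ? 1.0 : 0.0) : pr;
        oob_sum[oob[k]] += pv;
        oob_cnt[oob[k]] += 1;
        if (classify) {
          err0 += ((pr >= 0.5 ? 1.0 : 0.0) != y[oob[k]]) ? 1.0 : 0.0;
        } else {
          const double d = y[oob[k]] - pr;
          err0 += d * d;
        }
      }
      err0 /= no;
      if (importance) {
        perm.resize(no);
        for (int j = 0; j < p; ++j) {
          if (!used[j]) { imp(t, j) = 0.0; continue; }
          // permute feature j among the OOB samples
          for (int k = 0; k < no; ++k) perm[k] = k;
          for (int k = no - 1; k > 0; --k) {
            std::swap(perm[k], perm[runif_int(k + 1)]);
          }
          const double* xj = X + static_cast<size_t>(j) * N;
          double errj = 0.0;
          for (int k = 0; k < no; ++k) {
            const double xval = xj[oob[perm[k]]];
            const double pr = tree_predict_row(fd, t, X, N, oob[k], j, xval);
            if (classify) {
              errj += ((pr >= 0.5 ? 1.0 : 0.0) != y[oob[k]]) ? 1.0 : 0.0;
            } else {
              const double d = y[oob[k]] - pr;
              errj += d * d;
            }
          }
          errj /= no;
          imp(t, j) = errj - err0;
        }
      }
    } else if (importance) {
      for (int j = 0; j < p; ++j) imp(t, j) = NA_REAL;
    }
  }

  // overall OOB error of the aggregated forest
  double oob_err = NA_REAL;
  {
    double acc = 0.0; int cnt = 0;
    for (int i = 0; i < N; ++i) {
      if (oob_cnt[i] == 0) continue;
      const double pr = oob_sum[i] / oob_cnt[i];
      if (classify) {
        acc += ((pr >= 0.5 ? 1.0 : 0.0) != y[i]) ? 1.0 : 0.0;
      } else {
        const double d = y[i] - pr;
        acc += d * d;
      }
      ++cnt;
    }
    if (cnt > 0) oob_err = acc / cnt;
  }

  List forest = List::create(
    _["svar"] = wrap(fd.svar), _["sval"] = wrap(fd.sval),
    _["left"] = wrap(fd.left), _["right"] = wrap(fd.right),
    _["value"] = wrap(fd.value),
    _["offset"] = wrap(fd.offset), _["nnodes"] = wrap(fd.nnodes),
    _["ntree"] = ntree, _["p"] = p, _["classify"] = classify,
    _["oob_error"] = oob_err);
  if (importance) forest["tree_importance"] = imp;
  return forest;
}

// Cache-friendly packed representation for prediction: one 24-byte record
// per node (leaves carry the prediction in `sval` and svar = -1), trees
// visited outermost so a tree's nodes stay in cache while rows stream.
struct PackedNode { double sval; int svar, left; };

struct PackedForest {
  std::vector<PackedNode> nodes;
  std::vector<int> offset;
  int ntree;
  bool classify;
};

static PackedForest pack_forest(List forest) {
  PackedForest pf;
  std::vector<int> svar = as<std::vector<int>>(forest["svar"]);
  std::vector<double> sval = as<std::vector<double>>(forest["sval"]);
  std::vector<int> left = as<std::vector<int>>(forest["left"]);
  std::vector<double> value = as<std::vector<double>>(forest["value"]);
  pf.offset = as<std::vector<int>>(forest["offset"]);
  pf.ntree = as<int>(forest["ntree"]);
  pf.classify = as<bool>(forest["classify"]);
  const size_t nn = svar.size();
  pf.nodes.resize(nn);
  for (size_t k = 0; k < nn; ++k) {
    // children are allocated consecutively: right = left + 1
    pf.nodes[k] = {svar[k] >= 0 ? sval[k] : value[k], svar[k], left[k]};
  }
  return pf;
}

static NumericVector packed_predict(const PackedForest& pf,
                                    NumericMatrix newX) {
  const int n = newX.nrow();
  const double* X = REAL(newX);
  std::vector<double> acc(n, 0.0);
  for (int t = 0; t < pf.ntree; ++t) {
    const int base = pf.offset[t];
    for (int i = 0; i < n; ++i) {
      int node = base;
      const PackedNode* nd = &pf.nodes[node];
      while (nd->svar >= 0) {
        const double x = X[static_cast<size_t>(nd->svar) * n + i];
        node = (x <= nd->sval) ? nd->left : nd->left + 1;
        nd = &pf.nodes[node];
      }
      acc[i] += pf.classify ? (nd->sval >= 0.5 ? 1.0 : 0.0) : nd->sval;
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = acc[i] / pf.ntree;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_rf_predict(List forest, NumericMatrix newX) {
  PackedForest pf = pack_forest(forest);
  return packed_predict(pf, newX);
}

// External-pointer handle so repeated prediction (one call per feature and
// permutation) skips the list-to-packed conversion.
// [[Rcpp::export]]
SEXP cpp_rf_handle(List forest) {
  XPtr<PackedForest> ptr(new PackedForest(pack_forest(forest)), true);
  return ptr;
}

// [[Rcpp::export]]
NumericVector cpp_rf_predict_ptr(SEXP handle, NumericMatrix newX) {
  XPtr<PackedForest> ptr(handle);
  return packed_predict(*ptr, newX);
}
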