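// Bayesian additive regression trees: sum-of-trees model with the
// backfitting MCMC of Chipman, George & McCulloch (grow / prune / change
// proposals, conjugate normal leaf means, chi-square error variance).
// The outcome is internally shifted/scaled to [-0.5, 0.5]; leaf prior
// sd = 0.5 / (k * sqrt(ntree)); sigma^2 prior nu*lambda/chisq_nu with
// lambda calibrated so P(sigma < sd(y)) = q. Kept draws store the full
// forest so rules can be applied to new covariate tables later.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int var;      // -1 for leaf
  int cut;      // cutpoint index into grid of var
  int left, right, parent;
  double mu;    // leaf value
  int n;        // training obs in node
  double s;     // sum of partial residuals in node (refreshed per sweep)
};

struct Tree {
  std::vector<Node> nodes;
  std::vector<int> leaf_of;  // per training obs: node index
  Tree(int n) {
    nodes.push_back({-1, -1, -1, -1, -1, 0.0, n, 0.0});
    leaf_of.assign(n, 0);
  }
};

int depth(const std::vector<Node>& nd, int i) {
  int d = 0;
  while (nd[i].parent >= 0) { i = nd[i].parent; ++d; }
  return d;
}

void collect_leaves(const std::vector<Node>& nd, std::vector<int>& out) {
  out.clear();
  for (size_t i = 0; i < nd.size(); ++i)
    if (nd[i].var < 0 && nd[i].parent != -2) out.push_back((int)i);
}

// internal nodes whose two children are both leaves
void collect_singly(const std::vector<Node>& nd, std::vector<int>& out) {
  out.clear();
  for (size_t i = 0; i < nd.size(); ++i)
    if (nd[i].var >= 0 && nd[nd[i].left].var < 0 && nd[nd[i].right].var < 0)
      out.push_back((int)i);
}

double log_marg(double n, double s, double sig2, double smu2) {
  double denom = sig2 + n * smu2;
  return 0.5 * std::log(sig2 / denom) + smu2 * s * s / (2.0 * sig2 * denom);
}

double log_psplit(int d, double base, double power) {
  return std::log(base) - power * std::log1p((double)d);
}
double log_pnosplit(int d, double base, double power) {
  return std::log(1.0 - base * std::pow(1.0 + d, -power));
}

}  // namespace

// [[Rcpp::export]]
List bart_mcmc(NumericMatrix X, NumericVector y,
               int ntree, int nskip, int ndpost, int keepevery,
               double k, double power, double base_, double nu, double q,
               int numcut) {
  int n = X.nrow(), p = X.ncol();

  // cutpoint grids: uniform over the observed range of each variable
  std::vector<std::vector<double> > cuts(p);
  std::vector<int> usable;
  for (int j = 0; j < p; ++j) {
    double lo = R_PosInf, hi = R_NegInf;
    for (int i = 0; i < n; ++i) {
      double v = X(i, j);
      if (v < lo) lo = v;
      if (v > hi) hi = v;
    }
    if (hi > lo) {
      int nc = numcut;
      cuts[j].resize(nc);
      for (int c = 0; c < nc; ++c)
        cuts[j][c] = lo + (hi - lo) * (c + 1.0) / (nc + 1.0);
      usable.push_back(j);
    }
  }
  if (usable.empty()) stop("no splittable variable in the design");
  int pav = (int)usable.size();

  // scale y to [-0.5, 0.5]
  double ymin = min(y), ymax = max(y);
  if (ymax <= ymin) ymax = ymin + 1.0;
  double off = 0.5 * (ymin + ymax), scl = ymax - ymin;
  std::vector<double> ys(n);
  double ym = 0.0;
  for (int i = 0; i < n; ++i) { ys[i] = (y[i] - off) / scl; ym += ys[i]; }
  ym /= n;
  double yvar = 0.0;
  for (int i = 0; i < n; ++i) yvar += (ys[i] - ym) * (ys[i] - ym);
  yvar /= (n > 1 ? n - 1 : 1);

  double smu = 0.5 / (k * std::sqrt((double)ntree));
  double smu2 = smu * smu;
  double lambda = R::qchisq(1.0 - q, nu, 1, 0) * yvar / nu;
  double sig2 = yvar;

  std::vector<Tree> trees(ntree, Tree(n));
  std::vector<double> fhat(n, 0.0);

  int nsweep = nskip + ndpost * keepevery;
  int kept = 0;

  // forest storage for kept draws
  std::vector<int> f_var, f_left, f_right;
  std::vector<double> f_cut, f_mu;
  std::vector<int> f_off;  // node offset per (draw, tree), length kept*ntree+1
  f_off.push_back(0);

  NumericVector sigma_draws(ndpost);
  NumericVector train_mean(n);
  std::vector<int> leaves, singly;
  std::vector<double> res(n);

  for (int sweep = 0; sweep < nsweep; ++sweep) {
    for (int t = 0; t < ntree; ++t) {
      Tree& tr = trees[t];
      std::vector<Node>& nd = tr.nodes;
      // partial residuals for this tree
      for (int i = 0; i < n; ++i)
        res[i] = ys[i] - fhat[i] + nd[tr.leaf_of[i]].mu;
      // refresh leaf suff stats
      for (size_t j = 0; j < nd.size(); ++j) { nd[j].n = 0; nd[j].s = 0.0; }
      for (int i = 0; i < n; ++i) {
        Node& L = nd[tr.leaf_of[i]];
        L.n += 1; L.s += res[i];
      }

      double u = unif_rand();
      double pg = 0.25, pp = 0.25;  // grow, prune; rest = change
      collect_leaves(nd, leaves);
      collect_singly(nd, singly);
      int b = (int)leaves.size();

      if (u < pg) {
        // GROW
        int eta = leaves[(int)(unif_rand() * b)];
        int j = usable[(int)(unif_rand() * pav)];
        int nc = (int)cuts[j].size();
        int c = (int)(unif_rand() * nc);
        double cv = cuts[j][c];
        double nl = 0, sl = 0, nr = 0, sr = 0;
        for (int i = 0; i < n; ++i) {
          if (tr.leaf_of[i] != eta) continue;
          if (X(i, j) <= cv) { nl += 1; sl += res[i]; }
          else { nr += 1; sr += res[i]; }
        }
        if (nl > 0 && nr > 0) {
          int d = depth(nd, eta);
          // singly-internal count after grow: eta becomes one; its parent
          // (if it was singly internal) no longer is
          int w2_new = (int)singly.size() + 1;
          int par = nd[eta].parent;
          if (par >= 0 && nd[nd[par].left].var < 0 && nd[nd[par].right].var < 0)
            w2_new -= 1;
          double logA =
            log_psplit(d, base_, power) +
            2.0 * log_pnosplit(d + 1, base_, power) -
            log_pnosplit(d, base_, power) +
            log_marg(nl, sl, sig2, smu2) + log_marg(nr, sr, sig2, smu2) -
            log_marg(nd[eta].n, nd[eta].s, sig2, smu2) +
            std::log(pp) - std::log(pg) +
            std::log((double)b) - std::log((double)w2_new);
          if (std::log(unif_rand()) < logA) {
            int li = (int)nd.size();
            nd.push_back({-1, -1, -1, -1, eta, 0.0, (int)nl, sl});
            int ri = (int)nd.size();
            nd.push_back({-1, -1, -1, -1, eta, 0.0, (int)nr, sr});
            nd[eta].var = j; nd[eta].cut = c;
            nd[eta].left = li; nd[eta].right = ri;
            for (int i = 0; i < n; ++i)
              if (tr.leaf_of[i] == eta)
                tr.leaf_of[i] = (X(i, j) <= cv) ? li : ri;
          }
        }
      } else if (u < pg + pp) {
        // PRUNE
        if (!singly.empty()) {
          int w2 = (int)singly.size();
          int eta = singly[(int)(unif_rand() * w2)];
          int li = nd[eta].left, ri = nd[eta].right;
          int d = depth(nd, eta);
          int b_after = b - 1;
          double np = nd[li].n + nd[ri].n, sp = nd[li].s + nd[ri].s;
          double logA =
            -(log_psplit(d, base_, power) +
              2.0 * log_pnosplit(d + 1, base_, power) -
              log_pnosplit(d, base_, power)) -
            (log_marg(nd[li].n, nd[li].s, sig2, smu2) +
             log_marg(nd[ri].n, nd[ri].s, sig2, smu2) -
             log_marg(np, sp, sig2, smu2)) +
            std::log(pg) - std::log(pp) +
            std::log((double)w2) - std::log((double)b_after);
          if (std::log(unif_rand()) < logA) {
            nd[eta].var = -1;
            nd[eta].n = (int)np; nd[eta].s = sp;
            for (int i = 0; i < n; ++i)
              if (tr.leaf_of[i] == li || tr.leaf_of[i] == ri)
                tr.leaf_of[i] = eta;
            // mark children unused (kept in place; compacted on snapshot)
            nd[li].n = 0; nd[ri].n = 0;
            nd[li].parent = -2; nd[ri].parent = -2;
            nd[eta].left = nd[eta].right = -1;
          }
        }
      } else {
        // CHANGE rule of a singly-internal node
        if (!singly.empty()) {
          int eta = singly[(int)(unif_rand() * (int)singly.size())];
          int j = usable[(int)(unif_rand() * pav)];
          int nc = (int)cuts[j].size();
          int c = (int)(unif_rand() * nc);
          double cv = cuts[j][c];
          int li = nd[eta].left, ri = nd[eta].right;
          double nl = 0, sl = 0, nr = 0, sr = 0;
          for (int i = 0; i < n; ++i) {
            int lf = tr.leaf_of[i];
            if (lf != li && lf != ri) continue;
            if (X(i, j) <= cv) { nl += 1; sl += res[i]; }
            else { nr += 1; sr += res[i]; }
          }
          if (nl > 0 && nr > 0) {
            double logA =
              log_marg(nl, sl, sig2, smu2) + log_marg(nr, sr, sig2, smu2) -
              log_marg(nd[li].n, nd[li].s, sig2, smu2) -
              log_marg(nd[ri].n, nd[ri].s, sig2, smu2);
            if (std::log(unif_rand()) < logA) {
              nd[eta].var = j; nd[eta].cut = c;
              nd[li].n = (int)nl; nd[li].s = sl;
              nd[ri].n = (int)nr; nd[ri].s = sr;
              for (int i = 0; i < n; ++i) {
                int lf = tr.leaf_of[i];
                if (lf != li && lf != ri) continue;
                tr.leaf_of[i] = (X(i, j) <= cv) ? li : ri;
              }
            }
          }
        }
      }

      // draw leaf values and update the running fit
      for (size_t jj = 0; jj < nd.size(); ++jj) {
        if (nd[jj].var >= 0 || nd[jj].parent == -2) continue;
        double denom = sig2 + nd[jj].n * smu2;
        double mean = smu2 * nd[jj].s / denom;
        double sd = std::sqrt(sig2 * smu2 / denom);
        nd[jj].mu = mean + sd * norm_rand();
      }
      // fhat = (old fit minus this tree's old contribution) + new one;
      // ys - res is exactly the old fit without this tree
      for (int i = 0; i < n; ++i)
        fhat[i] = (ys[i] - res[i]) + nd[tr.leaf_of[i]].mu;
    }

    // sigma^2 update
    double sse = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = ys[i] - fhat[i];
      sse += e * e;
    }
    sig2 = (nu * lambda + sse) / R::rchisq(nu + n);

    // keep a snapshot
    if (sweep >= nskip && (sweep - nskip + 1) % keepevery == 0) {
      for (int t = 0; t < ntree; ++t) {
        const std::vector<Node>& nd = trees[t].nodes;
        // compact: map live node indices to contiguous ids
        std::vector<int> id(nd.size(), -1);
        int m = 0;
        for (size_t jj = 0; jj < nd.size(); ++jj)
          if (nd[jj].parent != -2) id[jj] = m++;
        for (size_t jj = 0; jj < nd.size(); ++jj) {
          if (nd[jj].parent == -2) continue;
          f_var.push_back(nd[jj].var);
          f_cut.push_back(nd[jj].var >= 0 ? cuts[nd[jj].var][nd[jj].cut]
                                          : 0.0);
          f_left.push_back(nd[jj].var >= 0 ? id[nd[jj].left] : -1);
          f_right.push_back(nd[jj].var >= 0 ? id[nd[jj].right] : -1);
          f_mu.push_back(nd[jj].mu * scl);  // back to outcome scale
        }
        f_off.push_back((int)f_var.size());
      }
      sigma_draws[kept] = std::sqrt(sig2) * scl;
      for (int i = 0; i < n; ++i)
        train_mean[i] += (fhat[i] * scl + off);
      kept += 1;
    }
  }
  for (int i = 0; i < n; ++i) train_mean[i] /= std::max(kept, 1);

  return List::create(
    _["var"] = f_var, _["cut"] = f_cut, _["left"] = f_left,
    _["right"] = f_right, _["mu"] = f_mu, _["offset"] = f_off,
    _["ntree"] = ntree, _["ndpost"] = kept, _["center"] = off,
    _["sigma"] = sigma_draws, _["yhat_train_mean"] = train_mean);
}

// Evaluate a stored forest on new data.
// Returns ndpost x n matrix of posterior draws if want_draws, else the
// posterior mean vector (1 x n matrix).
// [[Rcpp::export]]
NumericMatrix bart_eval(List forest, NumericMatrix X, bool want_draws) {
  IntegerVector var = forest["var"], left = forest["left"],
                right = forest["right"], offv = forest["offset"];
  NumericVector cut = forest["cut"], mu = forest["mu"];
  int ntree = forest["ntree"];
  int ndpost = forest["ndpost"];
  double center = forest["center"];
  int n = X.nrow(), p = X.ncol();
  const int *pv = var.begin(), *pl = left.begin(), *pr = right.begin(),
            *po = offv.begin();
  const double *pc = cut.begin(), *pm = mu.begin();
  // row-major copy so each observation's covariates are contiguous
  std::vector<double> xr((size_t)n * p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i) xr[(size_t)i * p + j] = X(i, j);
  NumericMatrix out(want_draws ? ndpost : 1, n);
  std::vector<double> acc(n);
  for (int d = 0; d < ndpost; ++d) {
    std::fill(acc.begin(), acc.end(), center);
    for (int t = 0; t < ntree; ++t) {
      int o = po[d * ntree + t];
      const int *v = pv + o, *l = pl + o, *r = pr + o;
      const double *c = pc + o, *m = pm + o;
      for (int i = 0; i < n; ++i) {
        const double* xi = &xr[(size_t)i * p];
        int node = 0;
        while (v[node] >= 0)
          node = (xi[v[node]] <= c[node]) ? l[node] : r[node];
        acc[i] += m[node];
      }
    }
    if (want_draws)
      for (int i = 0; i < n; ++i) out(d, i) = acc[i];
    else
      for (int i = 0; i < n; ++i) out(0, i) += acc[i] / ndpost;
  }
  return out;
}
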