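#include <Rcpp.h>
using namespace Rcpp;

// Plug-in mutual information (base 2) between two 0-based state vectors.
// Zero-count cells contribute 0 by convention.
static double mi_pair(const int* a, const int* b, int n, int ka, int kb) {
  std::vector<int> joint(ka * kb, 0), ma(ka, 0), mb(kb, 0);
  for (int t = 0; t < n; ++t) {
    joint[a[t] * kb + b[t]]++;
    ma[a[t]]++;
    mb[b[t]]++;
  }
  double mi = 0.0, dn = (double)n;
  for (int i = 0; i < ka; ++i) {
    if (ma[i] == 0) continue;
    for (int j = 0; j < kb; ++j) {
      int c = joint[i * kb + j];
      if (c == 0) continue;
      double pij = c / dn;
      mi += pij * std::log2(pij * dn * dn / ((double)ma[i] * (double)mb[j]));
    }
  }
  return mi < 0.0 ? 0.0 : mi;
}

// [[Rcpp::export]]
double cpp_mi(IntegerVector a, IntegerVector b, int ka, int kb) {
  if (a.size() != b.size()) stop("state vectors differ in length");
  return mi_pair(a.begin(), b.begin(), (int)a.size(), ka, kb);
}

// MI values and greedy scores are rounded to fixed decimal precision so
// that mathematically equal quantities compare equal regardless of
// floating-point summation order; ties then break deterministically
// toward the lower feature index (and identically in the R oracle).
static inline double round12(double x) {
  return std::nearbyint(x * 1e12) / 1e12;
}
static inline double round9(double x) {
  return std::nearbyint(x * 1e9) / 1e9;
}

// Greedy MIQ (mutual information quotient) selection.
// states: n x p matrix of 0-based states; nstates: per-column state count;
// y: 0-based response states with ky levels; K: number of features to rank.
// Step 1 maximises relevance V; later steps maximise MIQ = V / W with
// W = mean MI against the already-selected set.  W == 0 ranks as +Inf,
// ordered by V.  Ties break toward the lower column index.
// [[Rcpp::export]]
List cpp_mrmr_select(IntegerMatrix states, IntegerVector nstates,
                     IntegerVector y, int ky, int K) {
  int n = states.nrow(), p = states.ncol();
  if (y.size() != n) stop("y length does not match rows of states");
  if (K < 1) stop("K must be >= 1");
  if (K > p) K = p;

  std::vector<double> V(p);
  for (int j = 0; j < p; ++j)
    V[j] = round12(mi_pair(&states(0, j), y.begin(), n, nstates[j], ky));

  std::vector<bool> sel(p, false);
  std::vector<double> sumMI(p, 0.0);
  IntegerVector order(K);
  NumericVector Vout(K), Wout(K), MIQout(K);

  // step 1: pure relevance
  int best = 0;
  for (int j = 1; j < p; ++j) if (V[j] > V[best]) best = j;
  sel[best] = true;
  order[0] = best + 1;
  Vout[0] = V[best];
  Wout[0] = NA_REAL;
  MIQout[0] = NA_REAL;
  int last = best;

  for (int step = 1; step < K; ++step) {
    double ns = (double)step;
    int cand = -1;
    bool candInf = false;
    double candScore = 0.0, candV = 0.0;
    for (int j = 0; j < p; ++j) {
      if (sel[j]) continue;
      sumMI[j] += round12(mi_pair(&states(0, j), &states(0, last), n,
                                  nstates[j], nstates[last]));
      double w = round12(sumMI[j] / ns);
      bool inf = (w <= 0.0);
      double score = inf ? 0.0 : round9(V[j] / w);
      bool better;
      if (cand < 0) better = true;
      else if (inf != candInf) better = inf;                 // +Inf beats finite
      else if (inf) better = (V[j] > candV);                 // among +Inf: by V
      else better = (score > candScore);
      if (better) {
        cand = j; candInf = inf; candScore = score; candV = V[j];
      }
    }
    sel[cand] = true;
    order[step] = cand + 1;
    Vout[step] = V[cand];
    Wout[step] = round12(sumMI[cand] / ns);
    MIQout[step] = candInf ? R_PosInf : candScore;
    last = cand;
  }

  return List::create(_["order"] = order, _["V"] = Vout,
                      _["W"] = Wout, _["MIQ"] = MIQout);
}
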