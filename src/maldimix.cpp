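#include <Rcpp.h>
#include <deque>
#include <cmath>
using namespace Rcpp;

// Rolling minimum over a centered window of half-width h (window 2h+1 bins,
// truncated at the edges).  Monotonic deque, O(n).
// [[Rcpp::export(rng = false)]]
NumericVector roll_min_cpp(NumericVector x, int h) {
  int n = x.size();
  NumericVector out(n);
  std::deque<int> q;
  int j = 0;
  for (int i = 0; i < n; ++i) {
    int hi = std::min(n - 1, i + h);
    while (j <= hi) {
      while (!q.empty() && x[q.back()] >= x[j]) q.pop_back();
      q.push_back(j);
      ++j;
    }
    int lo = i - h;
    while (q.front() < lo) q.pop_front();
    out[i] = x[q.front()];
  }
  return out;
}

// Centered moving average of half-width h with truncated edge windows.
// [[Rcpp::export(rng = false)]]
NumericVector roll_mean_cpp(NumericVector x, int h) {
  int n = x.size();
  NumericVector out(n);
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i];
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - h), hi = std::min(n - 1, i + h);
    out[i] = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
  }
  return out;
}

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Eq-1 RMS (M = 1) of the network on (X, y), reported in the original
// response units given the stored min-max scaling of y to [0.1, 0.9].
static double net_rms(const NumericMatrix& X, const NumericVector& y,
                      const NumericMatrix& W1, const NumericVector& b1,
                      const NumericVector& w2, double b2,
                      double y_min, double y_rng) {
  int n = X.nrow(), p = X.ncol(), H = W1.ncol();
  double ss = 0.0;
  for (int r = 0; r < n; ++r) {
    double o = b2;
    for (int j = 0; j < H; ++j) {
      double a = b1[j];
      for (int i = 0; i < p; ++i) a += X(r, i) * W1(i, j);
      o += w2[j] * sigmoid(a);
    }
    o = sigmoid(o);
    double d = (o - y[r]) / 0.8 * y_rng;
    ss += d * d;
  }
  (void)y_min;
  return std::sqrt(ss / n);
}

// Online (per-pattern) back-propagation with momentum on a single-hidden-layer
// network with logistic-sigmoid activations throughout.  X and y must already
// be min-max scaled to [0.1, 0.9]; y_min / y_rng describe the inverse scaling
// of the response so the training trace can be recorded in original units.
// The per-epoch pattern shuffle draws from R's RNG (so set.seed() governs it).
// trace_every = 0 records only the final epoch.
// [[Rcpp::export]]
List ann_train_cpp(NumericMatrix X, NumericVector y,
                   NumericMatrix W1_in, NumericVector b1_in,
                   NumericVector w2_in, double b2_in,
                   int epochs, double lr, double momentum, int trace_every,
                   double y_min, double y_rng,
                   Nullable<NumericMatrix> Xv_ = R_NilValue,
                   Nullable<NumericVector> yv_ = R_NilValue) {
  int n = X.nrow(), p = X.ncol(), H = W1_in.ncol();
  NumericMatrix W1 = clone(W1_in);
  NumericVector b1 = clone(b1_in), w2 = clone(w2_in);
  double b2 = b2_in;

  bool has_v = Xv_.isNotNull();
  NumericMatrix Xv;
  NumericVector yv;
  if (has_v) { Xv = as<NumericMatrix>(Xv_); yv = as<NumericVector>(yv_); }

  std::vector<double> vW1(p * H, 0.0), vb1(H, 0.0), vw2(H, 0.0);
  double vb2 = 0.0;
  std::vector<int> ord(n);
  std::vector<double> hid(H), dh(H);

  // pattern-major copy of X for contiguous access, and flat weights
  std::vector<double> Xt((size_t)n * p);
  for (int r = 0; r < n; ++r)
    for (int i = 0; i < p; ++i) Xt[(size_t)r * p + i] = X(r, i);
  std::vector<double> W(p * H);                   // W[j*p + i]
  for (int j = 0; j < H; ++j)
    for (int i = 0; i < p; ++i) W[(size_t)j * p + i] = W1(i, j);

  std::vector<int> tr_epoch;
  std::vector<double> tr_train, tr_verif;
  int diverged = 0;

  for (int e = 1; e <= epochs; ++e) {
    for (int i = 0; i < n; ++i) ord[i] = i;
    for (int i = n - 1; i > 0; --i) {          // Fisher-Yates via R RNG
      int k = (int)std::floor(unif_rand() * (i + 1));
      if (k > i) k = i;
      std::swap(ord[i], ord[k]);
    }
    for (int s = 0; s < n; ++s) {
      int r = ord[s];
      const double* x = &Xt[(size_t)r * p];
      double o = b2;
      for (int j = 0; j < H; ++j) {
        const double* wj = &W[(size_t)j * p];
        double a = b1[j];
        for (int i = 0; i < p; ++i) a += x[i] * wj[i];
        hid[j] = sigmoid(a);
        o += w2[j] * hid[j];
      }
      o = sigmoid(o);
      double delta_o = (y[r] - o) * o * (1.0 - o);
      for (int j = 0; j < H; ++j) {
        dh[j] = delta_o * w2[j] * hid[j] * (1.0 - hid[j]);
        vw2[j] = momentum * vw2[j] + lr * delta_o * hid[j];
        w2[j] += vw2[j];
      }
      vb2 = momentum * vb2 + lr * delta_o;
      b2 += vb2;
      for (int j = 0; j < H; ++j) {
        double g = dh[j];
        double* wj = &W[(size_t)j * p];
        double* vj = &vW1[(size_t)j * p];
        for (int i = 0; i < p; ++i) {
          vj[i] = momentum * vj[i] + lr * g * x[i];
          wj[i] += vj[i];
        }
        vb1[j] = momentum * vb1[j] + lr * g;
        b1[j] += vb1[j];
      }
    }
    if (!std::isfinite(b2)) { diverged = e; break; }
    bool last = (e == epochs);
    if ((trace_every > 0 && e % trace_every == 0) || last) {
      for (int j = 0; j < H; ++j)
        for (int i = 0; i < p; ++i) W1(i, j) = W[(size_t)j * p + i];
      tr_epoch.push_back(e);
      tr_train.push_back(net_rms(X, y, W1, b1, w2, b2, y_min, y_rng));
      if (has_v)
        tr_verif.push_back(net_rms(Xv, yv, W1, b1, w2, b2, y_min, y_rng));
    }
  }
  for (int j = 0; j < H; ++j)
    for (int i = 0; i < p; ++i) W1(i, j) = W[(size_t)j * p + i];

  List trace = List::create(_["epoch"] = wrap(tr_epoch),
                            _["train_rms"] = wrap(tr_train),
                            _["verif_rms"] = has_v ? wrap(tr_verif) : R_NilValue);
  return List::create(_["W1"] = W1, _["b1"] = b1, _["w2"] = w2, _["b2"] = b2,
                      _["trace"] = trace, _["diverged"] = diverged);
}
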