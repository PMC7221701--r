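// Backpropagation core for the stepwise neural-network model builder.
//
// Multilayer perceptron with tanh activation in every non-input layer.
// Weight matrices are (n_in + 1) x n_out with the bias in the last row.
// Training is per-pattern (sequential) gradient descent with momentum
// (generalized delta rule); the pattern order of every epoch is supplied
// by the caller so reproducibility is governed by R's RNG.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

typedef std::vector<NumericMatrix> WeightSet;

static WeightSet as_weights(const List& weights) {
  WeightSet w;
  for (int l = 0; l < weights.size(); ++l) {
    NumericMatrix m = weights[l];
    w.push_back(clone(m));
  }
  return w;
}

static List as_list(const WeightSet& w) {
  List out(w.size());
  for (size_t l = 0; l < w.size(); ++l) out[l] = clone(w[l]);
  return out;
}

// forward pass; activations[l] holds the output of layer l (layer 0 = input)
static double forward_store(const WeightSet& w, const double* x, int nx,
                            std::vector<std::vector<double> >& act) {
  act.resize(w.size() + 1);
  act[0].assign(x, x + nx);
  for (size_t l = 0; l < w.size(); ++l) {
    const NumericMatrix& W = w[l];
    int nin = W.nrow() - 1, nout = W.ncol();
    act[l + 1].assign(nout, 0.0);
    for (int j = 0; j < nout; ++j) {
      double s = W(nin, j); // bias
      for (int i = 0; i < nin; ++i) s += W(i, j) * act[l][i];
      act[l + 1][j] = std::tanh(s);
    }
  }
  return act.back()[0];
}

// backprop of E = 0.5 (out - y)^2 for one pattern; grad has the same
// shapes as the weights
static void backprop(const WeightSet& w,
                     const std::vector<std::vector<double> >& act,
                     double y, std::vector<std::vector<double> >& delta) {
  int L = (int)w.size();
  delta.resize(L);
  // output layer
  {
    double out = act[L][0];
    delta[L - 1].assign(1, (out - y) * (1.0 - out * out));
  }
  for (int l = L - 2; l >= 0; --l) {
    const NumericMatrix& Wnext = w[l + 1];
    int nin = Wnext.nrow() - 1;
    delta[l].assign(nin, 0.0);
    for (int i = 0; i < nin; ++i) {
      double s = 0.0;
      for (int j = 0; j < Wnext.ncol(); ++j) s += Wnext(i, j) * delta[l + 1][j];
      double a = act[l + 1][i];
      delta[l][i] = s * (1.0 - a * a);
    }
  }
}

static double rms(const WeightSet& w, const NumericMatrix& X,
                  const NumericVector& y) {
  int n = X.nrow();
  if (n == 0) return NA_REAL;
  std::vector<std::vector<double> > act;
  std::vector<double> row(X.ncol());
  double ss = 0.0;
  for (int p = 0; p < n; ++p) {
    for (int j = 0; j < X.ncol(); ++j) row[j] = X(p, j);
    double out = forward_store(w, row.data(), X.ncol(), act);
    double e = out - y[p];
    ss += e * e;
  }
  return std::sqrt(ss / n);
}

// [[Rcpp::export]]
NumericVector cpp_ann_forward(List weights, NumericMatrix X) {
  WeightSet w = as_weights(weights);
  int n = X.nrow();
  NumericVector out(n);
  std::vector<std::vector<double> > act;
  std::vector<double> row(X.ncol());
  for (int p = 0; p < n; ++p) {
    for (int j = 0; j < X.ncol(); ++j) row[j] = X(p, j);
    out[p] = forward_store(w, row.data(), X.ncol(), act);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_ann_grad(List weights, NumericVector x, double y) {
  WeightSet w = as_weights(weights);
  std::vector<std::vector<double> > act, delta;
  forward_store(w, x.begin(), x.size(), act);
  backprop(w, act, y, delta);
  List grad(w.size());
  for (size_t l = 0; l < w.size(); ++l) {
    int nin = w[l].nrow() - 1, nout = w[l].ncol();
    NumericMatrix g(nin + 1, nout);
    for (int j = 0; j < nout; ++j) {
      for (int i = 0; i < nin; ++i) g(i, j) = act[l][i] * delta[l][j];
      g(nin, j) = delta[l][j];
    }
    grad[l] = g;
  }
  return grad;
}

// [[Rcpp::export]]
List cpp_ann_train(List weights, NumericMatrix Xtr, NumericVector ytr,
                   NumericMatrix Xval, NumericVector yval,
                   double eta, double alpha, int max_epochs, int patience,
                   double tol, IntegerMatrix orders) {
  WeightSet w = as_weights(weights);
  WeightSet vel, best;
  for (size_t l = 0; l < w.size(); ++l) {
    vel.push_back(NumericMatrix(w[l].nrow(), w[l].ncol()));
    best.push_back(clone(w[l]));
  }
  int ntr = Xtr.nrow(), nx = Xtr.ncol();
  bool has_val = Xval.nrow() > 0;
  double best_val = R_PosInf;
  int best_epoch = 0, since_best = 0, epochs_run = 0;
  NumericVector trace_val(max_epochs, NA_REAL), trace_tr(max_epochs, NA_REAL);
  std::vector<std::vector<double> > act, delta;
  std::vector<double> row(nx);

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    for (int q = 0; q < ntr; ++q) {
      int p = orders(epoch, q) - 1;
      for (int j = 0; j < nx; ++j) row[j] = Xtr(p, j);
      double out = forward_store(w, row.data(), nx, act);
      if (!std::isfinite(out)) stop("training diverged; try a smaller eta");
      backprop(w, act, ytr[p], delta);
      for (size_t l = 0; l < w.size(); ++l) {
        int nin = w[l].nrow() - 1, nout = w[l].ncol();
        for (int j = 0; j < nout; ++j) {
          for (int i = 0; i <= nin; ++i) {
            double a = (i < nin) ? act[l][i] : 1.0;
            double g = a * delta[l][j];
            double v = -eta * g + alpha * vel[l](i, j);
            vel[l](i, j) = v;
            w[l](i, j) += v;
          }
        }
      }
    }
    epochs_run = epoch + 1;
    double rt = rms(w, Xtr, ytr);
    trace_tr[epoch] = rt;
    if (!std::isfinite(rt)) stop("training diverged; try a smaller eta");
    if (has_val) {
      double rv = rms(w, Xval, yval);
      trace_val[epoch] = rv;
      if (rv < best_val - 1e-12) {
        best_val = rv;
        best_epoch = epoch + 1;
        since_best = 0;
        for (size_t l = 0; l < w.size(); ++l) best[l] = clone(w[l]);
      } else if (rv > best_val + tol) {
        if (++since_best >= patience) break;
      } else {
        since_best = 0;
      }
    } else {
      best_epoch = epoch + 1;
      for (size_t l = 0; l < w.size(); ++l) best[l] = clone(w[l]);
    }
  }
  return List::create(
    _["weights"] = as_list(best),
    _["epochs_run"] = epochs_run,
    _["best_epoch"] = best_epoch,
    _["rms_val"] = trace_val[Range(0, std::max(epochs_run - 1, 0))],
    _["rms_tr"] = trace_tr[Range(0, std::max(epochs_run - 1, 0))]);
}
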