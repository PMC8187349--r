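#include <Rcpp.h>
using namespace Rcpp;

// Damped synchronous signal propagation over a weighted signed edge list.
// States start at zero (clamped nodes at their clamp value) and iterate
//   s_j <- (1 - lambda) * s_j + lambda * tanh(sum_i w_ij s_i + b_j)
// until the largest state change is below tau or max_iter is reached.
// Clamped nodes are held fixed in every iteration, so states stay in [-1, 1].
static void propagate_core(int n,
                           const IntegerVector& from,
                           const IntegerVector& to,
                           const NumericVector& w,
                           const NumericVector& bias,
                           const IntegerVector& clamp_idx,
                           const NumericVector& clamp_val,
                           double lambda, double tau, int max_iter,
                           NumericVector& s, bool& converged, int& iters) {
  const int m = from.size();
  std::vector<bool> clamped(n, false);
  for (int k = 0; k < clamp_idx.size(); ++k) clamped[clamp_idx[k]] = true;

  std::fill(s.begin(), s.end(), 0.0);
  for (int k = 0; k < clamp_idx.size(); ++k) s[clamp_idx[k]] = clamp_val[k];

  NumericVector input(n);
  converged = false;
  iters = 0;
  for (int it = 1; it <= max_iter; ++it) {
    for (int j = 0; j < n; ++j) input[j] = bias[j];
    for (int e = 0; e < m; ++e) input[to[e]] += w[e] * s[from[e]];
    double max_delta = 0.0;
    for (int j = 0; j < n; ++j) {
      if (clamped[j]) continue;
      double next = (1.0 - lambda) * s[j] + lambda * std::tanh(input[j]);
      double d = std::fabs(next - s[j]);
      if (d > max_delta) max_delta = d;
      s[j] = next;
    }
    iters = it;
    if (max_delta < tau) { converged = true; break; }
  }
  if (max_iter == 0) { converged = true; iters = 0; }
}

// [[Rcpp::export]]
List propagate_cpp(int n, IntegerVector from, IntegerVector to,
                   NumericVector w, NumericVector bias,
                   IntegerVector clamp_idx, NumericVector clamp_val,
                   double lambda, double tau, int max_iter) {
  NumericVector s(n);
  bool converged;
  int iters;
  propagate_core(n, from, to, w, bias, clamp_idx, clamp_val,
                 lambda, tau, max_iter, s, converged, iters);
  return List::create(_["states"] = s,
                      _["converged"] = converged,
                      _["iterations"] = iters);
}

// Fraction of restrictions whose simulated sign matches the required sign.
// States within the eps dead-band count as unsatisfied: a silent node does
// not achieve any required direction.
static double accuracy_core(const NumericVector& s,
                            const IntegerVector& res_idx,
                            const IntegerVector& res_sign,
                            double eps) {
  const int r = res_idx.size();
  if (r == 0) return NA_REAL;
  int hits = 0;
  for (int k = 0; k < r; ++k) {
    double y = s[res_idx[k]];
    if (std::fabs(y) < eps) continue;
    if ((y > 0 && res_sign[k] > 0) || (y < 0 && res_sign[k] < 0)) ++hits;
  }
  return (double)hits / (double)r;
}

// [[Rcpp::export]]
double accuracy_cpp(NumericVector s, IntegerVector res_idx,
                    IntegerVector res_sign, double eps) {
  return accuracy_core(s, res_idx, res_sign, eps);
}

// Simulated annealing over edge-weight magnitudes. Edge signs are fixed by
// the network; a proposal rescales one magnitude by exp(U(-0.5, 0.5)),
// clipped to (0, 1]. Metropolis acceptance on objective = 1 - accuracy.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List anneal_cpp(int n, IntegerVector from, IntegerVector to,
                IntegerVector edge_sign, NumericVector w0, NumericVector bias,
                IntegerVector clamp_idx, NumericVector clamp_val,
                IntegerVector res_idx, IntegerVector res_sign,
                double eps, double lambda, double tau, int max_iter,
                double t0, double gamma, int steps_per_temp, double t_floor) {
  const int m = from.size();
  RNGScope scope;
  NumericVector w = clone(w0);
  NumericVector s(n);
  bool converged;
  int iters;

  propagate_core(n, from, to, w, bias, clamp_idx, clamp_val,
                 lambda, tau, max_iter, s, converged, iters);
  double acc = accuracy_core(s, res_idx, res_sign, eps);
  double obj = 1.0 - acc;

  NumericVector best_w = clone(w);
  double best_obj = obj;
  int n_temps = 0;
  for (double t = t0; t >= t_floor; t *= gamma) ++n_temps;
  NumericVector best_trace(n_temps);

  int ti = 0;
  for (double t = t0; t >= t_floor; t *= gamma, ++ti) {
    for (int step = 0; step < steps_per_temp; ++step) {
      int e = (int)std::floor(unif_rand() * m);
      if (e >= m) e = m - 1;
      double old_w = w[e];
      double mag = std::fabs(old_w) * std::exp(unif_rand() - 0.5);
      if (mag > 1.0) mag = 1.0;
      w[e] = (edge_sign[e] > 0 ? mag : -mag);

      propagate_core(n, from, to, w, bias, clamp_idx, clamp_val,
                     lambda, tau, max_iter, s, converged, iters);
      double new_obj = 1.0 - accuracy_core(s, res_idx, res_sign, eps);

      bool accept = new_obj <= obj ||
        unif_rand() < std::exp(-(new_obj - obj) / t);
      if (accept) {
        obj = new_obj;
        if (obj < best_obj) { best_obj = obj; best_w = clone(w); }
      } else {
        w[e] = old_w;
      }
      if (best_obj <= 0.0) break;
    }
    best_trace[ti] = best_obj;
    if (best_obj <= 0.0) {
      for (int k = ti + 1; k < n_temps; ++k) best_trace[k] = best_obj;
      break;
    }
  }

  propagate_core(n, from, to, best_w, bias, clamp_idx, clamp_val,
                 lambda, tau, max_iter, s, converged, iters);
  double best_acc = accuracy_core(s, res_idx, res_sign, eps);
  return List::create(_["weights"] = best_w,
                      _["accuracy"] = best_acc,
                      _["objective_trace"] = best_trace);
}
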