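#include <Rcpp.h>
using namespace Rcpp;

// Change in the mover's evaluation function when the symmetric tie (i, j)
// is toggled. Dyadic-weight effects (density, similarity, ego x alter) are
// folded into one weight matrix `wsum`; transitive triplets and degree
// popularity contribute through the current structure.
static double delta_eval(const IntegerMatrix &adj, const IntegerVector &deg,
                         int i, int j, const NumericMatrix &wsum,
                         double beta_tt, double beta_ip) {
  const int n = adj.nrow();
  const int sign = adj(i, j) ? -1 : 1;
  double d = sign * wsum(i, j);
  if (beta_tt != 0.0) {
    int common = 0;
    for (int k = 0; k < n; ++k) common += adj(i, k) * adj(j, k);
    d += sign * beta_tt * 2.0 * common;
  }
  if (beta_ip != 0.0) {
    // statistic on the resulting network: partner j enters/leaves the sum
    // with its post-toggle/pre-toggle degree respectively
    d += beta_ip * (adj(i, j) ? -double(deg[j]) : double(deg[j] + 1));
  }
  return d;
}

// [[Rcpp::export]]
double delta_eval_cpp(IntegerMatrix adj, int i, int j, NumericMatrix wsum,
                      double beta_tt, double beta_ip) {
  const int n = adj.nrow();
  IntegerVector deg(n);
  for (int a = 0; a < n; ++a) {
    int s = 0;
    for (int b = 0; b < n; ++b) s += adj(a, b);
    deg[a] = s;
  }
  return delta_eval(adj, deg, i - 1, j - 1, wsum, beta_tt, beta_ip);
}

// Simulate SAOM microsteps on a symmetric binary network.
//
// Actors receive change opportunities at rates `lambda` (zero for absent
// actors). At each opportunity the mover chooses among keeping the network
// or toggling the tie to one present partner, with multinomial-logit
// probabilities proportional to exp(f_i) of the resulting network.
//
// mode = 0: run until accumulated exponential waiting time reaches
//           `duration` (a step occurring after the boundary is not taken).
// mode = 1: run exactly `max_steps` microsteps (no clock).
//
// [[Rcpp::export]]
List simulate_microsteps_cpp(IntegerMatrix adj_in, NumericVector lambda,
                             NumericMatrix wsum, double beta_tt,
                             double beta_ip, double duration, int max_steps,
                             int mode) {
  IntegerMatrix adj = clone(adj_in);
  const int n = adj.nrow();
  IntegerVector deg(n);
  for (int a = 0; a < n; ++a) {
    int s = 0;
    for (int b = 0; b < n; ++b) s += adj(a, b);
    deg[a] = s;
  }
  std::vector<int> active;
  double tot_lambda = 0.0;
  for (int a = 0; a < n; ++a) {
    if (lambda[a] > 0) { active.push_back(a); tot_lambda += lambda[a]; }
  }
  if (active.size() < 2) stop("need at least two actors with positive rate");

  double t = 0.0;
  int steps = 0;
  bool hit_cap = false;
  std::vector<double> w(active.size() + 1);

  while (true) {
    if (mode == 1) {
      if (steps >= max_steps) break;
    } else {
      double dt = R::rexp(1.0 / tot_lambda);
      t += dt;
      if (t >= duration) break;
      if (steps >= max_steps) { hit_cap = true; break; }
    }
    // pick the mover proportional to lambda
    double u = unif_rand() * tot_lambda;
    int i = active.back();
    double acc = 0.0;
    for (size_t k = 0; k < active.size(); ++k) {
      acc += lambda[active[k]];
      if (u <= acc) { i = active[k]; break; }
    }
    // choice set: keep (delta f = 0) + toggle tie to each present partner
    double maxd = 0.0;
    int nopt = 0;
    std::vector<int> partner(active.size());
    for (size_t k = 0; k < active.size(); ++k) {
      int j = active[k];
      if (j == i) continue;
      double d = delta_eval(adj, deg, i, j, wsum, beta_tt, beta_ip);
      partner[nopt] = j;
      w[nopt] = d;
      if (d > maxd) maxd = d;
      ++nopt;
    }
    double tot_w = std::exp(0.0 - maxd);  // the "keep" option
    for (int k = 0; k < nopt; ++k) {
      w[k] = std::exp(w[k] - maxd);
      tot_w += w[k];
    }
    double u2 = unif_rand() * tot_w;
    int chosen = -1;  // -1 = keep
    double acc2 = 0.0;
    for (int k = 0; k < nopt; ++k) {
      acc2 += w[k];
      if (u2 <= acc2) { chosen = k; break; }
    }
    if (chosen >= 0) {
      int j = partner[chosen];
      if (adj(i, j)) {
        adj(i, j) = adj(j, i) = 0;
        --deg[i]; --deg[j];
      } else {
        adj(i, j) = adj(j, i) = 1;
        ++deg[i]; ++deg[j];
      }
    }
    ++steps;
  }

  return List::create(_["adjacency"] = adj, _["steps"] = steps,
                      _["time"] = t, _["hit_cap"] = hit_cap);
}
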