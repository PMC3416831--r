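#include <Rcpp.h>
using namespace Rcpp;

// combinatorial mass-action factor: number of distinct r-tuples from x copies
static inline double ma_factor(double x, int r) {
  switch (r) {
  case 0: return 1.0;
  case 1: return x;
  case 2: return x * (x - 1.0) / 2.0;
  default: return 0.0; // guarded at spec-build time
  }
}

// Exact direct-method realization of the jump process for reaction networks
// whose propensities compile to a small spec table. Reaction types:
//   0 mass action: h = c[rate] * prod_i choose(x_i, counts_i)
//   1 affine:      h = c[rate] * (a0 + sum_i a_i x_i)
//   2 saturating:  h = c[rate] * x[iy] * x[ix] / (x[ix] + c[ksat])
// Uses R's RNG, so set.seed() makes realizations reproducible.
// [[Rcpp::export(name = ".ssa_direct_cpp")]]
List ssa_direct_cpp(IntegerMatrix S, List rx, NumericVector c,
                    NumericVector x0, double t_max) {
  const int u = S.nrow(), v = S.ncol();
  std::vector<int> type(v), rate(v), ksat(v), ix(v), iy(v);
  std::vector<std::vector<int> > counts(v);
  std::vector<double> a0(v);
  std::vector<std::vector<double> > acoef(v);
  for (int j = 0; j < v; ++j) {
    List r = rx[j];
    type[j] = as<int>(r["type"]);
    rate[j] = as<int>(r["rate"]) - 1;
    if (type[j] == 0) {
      counts[j] = as<std::vector<int> >(r["counts"]);
    } else if (type[j] == 1) {
      a0[j] = as<double>(r["a0"]);
      acoef[j] = as<std::vector<double> >(r["a"]);
    } else {
      ksat[j] = as<int>(r["ksat"]) - 1;
      ix[j] = as<int>(r["ix"]) - 1;
      iy[j] = as<int>(r["iy"]) - 1;
    }
  }

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> times;
  std::vector<double> states;
  std::vector<int> rids;
  times.reserve(1024);
  states.reserve(1024 * u);
  times.push_back(0.0);
  for (int i = 0; i < u; ++i) states.push_back(x[i]);

  std::vector<double> h(v);
  double t = 0.0;
  bool absorbed = false;
  RNGScope scope;

  for (;;) {
    double H = 0.0;
    for (int j = 0; j < v; ++j) {
      double hj;
      switch (type[j]) {
      case 0: {
        hj = c[rate[j]];
        for (int i = 0; i < u; ++i)
          if (counts[j][i] > 0) hj *= ma_factor(x[i], counts[j][i]);
        break;
      }
      case 1: {
        double s = a0[j];
        for (int i = 0; i < u; ++i) s += acoef[j][i] * x[i];
        hj = c[rate[j]] * s;
        break;
      }
      default:
        hj = c[rate[j]] * x[iy[j]] * x[ix[j]] / (x[ix[j]] + c[ksat[j]]);
      }
      if (hj < 0.0) hj = 0.0;
      h[j] = hj;
      H += hj;
    }
    if (H <= 0.0) { absorbed = true; break; }
    t += exp_rand() / H;
    if (t > t_max) break;
    double uH = unif_rand() * H, acc = 0.0;
    int j = v - 1;
    for (int jj = 0; jj < v; ++jj) {
      acc += h[jj];
      if (uH <= acc) { j = jj; break; }
    }
    for (int i = 0; i < u; ++i) x[i] += S(i, j);
    times.push_back(t);
    for (int i = 0; i < u; ++i) states.push_back(x[i]);
    rids.push_back(j + 1);
  }

  const int n = (int) times.size();
  NumericMatrix st(u, n);
  for (int k = 0; k < n; ++k)
    for (int i = 0; i < u; ++i) st(i, k) = states[(size_t) k * u + i];
  return List::create(_["jump_times"] = NumericVector(times.begin(), times.end()),
                      _["states"] = st,
                      _["reaction_ids"] = IntegerVector(rids.begin(), rids.end()),
                      _["absorbed"] = absorbed);
}
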