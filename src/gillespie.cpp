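#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Continuous-time Markov jump process of a single excitation on a pigment
// network. Channel layout per state i: [0] intrinsic decay, [1..n] transfer
// to pigment j. Uses R's RNG so runs are reproducible via set.seed().

static void build_cumulative(const NumericMatrix& transfer,
                             const NumericVector& decay,
                             std::vector< std::vector<double> >& cum) {
  int n = decay.size();
  cum.assign(n, std::vector<double>(n + 1));
  for (int i = 0; i < n; ++i) {
    double s = decay[i];
    cum[i][0] = s;
    for (int j = 0; j < n; ++j) {
      s += transfer(i, j);
      cum[i][j + 1] = s;
    }
  }
}

// One trajectory; returns hop times/states (if recorded), decay time and
// terminal state (1-based).
static void run_one(const NumericMatrix& transfer,
                    const std::vector< std::vector<double> >& cum,
                    int start, bool record_hops,
                    std::vector<double>& hop_t, std::vector<int>& hop_s,
                    double& decay_time, int& terminal, int& n_hops) {
  int cur = start;
  double t = 0.0;
  n_hops = 0;
  for (;;) {
    const std::vector<double>& c = cum[cur];
    double lam = c.back();
    if (lam <= 0.0)
      stop("non-terminating state: pigment %d has zero total exit rate",
           cur + 1);
    t += R::rexp(1.0 / lam);  // R::rexp takes the scale 1/rate
    double u = unif_rand() * lam;
    if (u < c[0]) {  // decay event
      decay_time = t;
      terminal = cur + 1;
      return;
    }
    // first channel k with cum[k] > u; target pigment is k-1 (0-based)
    int k = int(std::upper_bound(c.begin(), c.end(), u) - c.begin());
    if (k > (int)transfer.ncol()) k = transfer.ncol();
    int j = k - 1;
    // guard against landing on a zero-rate channel through rounding
    while (j >= 0 && transfer(cur, j) <= 0.0) --j;
    if (j < 0) {  // numerically at the decay boundary
      decay_time = t;
      terminal = cur + 1;
      return;
    }
    cur = j;
    ++n_hops;
    if (record_hops) {
      hop_t.push_back(t);
      hop_s.push_back(cur + 1);
    }
  }
}

// [[Rcpp::export(name = ".gillespie_cpp")]]
List gillespie_cpp(NumericMatrix transfer, NumericVector decay, int start,
                   bool record_hops) {
  int n = decay.size();
  if (transfer.nrow() != n || transfer.ncol() != n)
    stop("transfer matrix and decay vector dimensions disagree");
  if (start < 1 || start > n) stop("start index out of range");
  std::vector< std::vector<double> > cum;
  build_cumulative(transfer, decay, cum);
  std::vector<double> hop_t;
  std::vector<int> hop_s;
  double dt; int term, nh;
  run_one(transfer, cum, start - 1, record_hops, hop_t, hop_s, dt, term, nh);
  return List::create(_["decay_time"] = dt, _["terminal"] = term,
                      _["n_hops"] = nh, _["hop_times"] = wrap(hop_t),
                      _["hop_states"] = wrap(hop_s));
}

// [[Rcpp::export(name = ".gillespie_ensemble_cpp")]]
List gillespie_ensemble_cpp(NumericMatrix transfer, NumericVector decay,
                            IntegerVector starts) {
  int n = decay.size();
  if (transfer.nrow() != n || transfer.ncol() != n)
    stop("transfer matrix and decay vector dimensions disagree");
  int m = starts.size();
  std::vector< std::vector<double> > cum;
  build_cumulative(transfer, decay, cum);
  NumericVector decay_time(m);
  IntegerVector terminal(m), n_hops(m);
  std::vector<double> hop_t;
  std::vector<int> hop_s;
  for (int r = 0; r < m; ++r) {
    if (starts[r] < 1 || starts[r] > n) stop("start index out of range");
    double dt; int term, nh;
    run_one(transfer, cum, starts[r] - 1, false, hop_t, hop_s, dt, term, nh);
    decay_time[r] = dt;
    terminal[r] = term;
    n_hops[r] = nh;
  }
  return List::create(_["decay_time"] = decay_time,
                      _["terminal"] = terminal, _["n_hops"] = n_hops);
}
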