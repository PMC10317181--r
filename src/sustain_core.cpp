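#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Score-probability tensors arrive as an N x R x L1 array (subject, region,
// level) of *log* probabilities, flattened column-major; level index 0 is the
// score-0 baseline. An event sequence is a permutation of the M = R x (L1 - 1)
// events, each event a (region, level) pair with level >= 1; validity (level s
// of a region never precedes level s - 1) is enforced by the callers and
// preserved by every move generated here.

static inline double lp(const NumericVector &logp, int N, int R,
                        int n, int r, int l) {
  return logp[n + N * (r + R * l)];
}

// Stage-conditional log-likelihood matrix: rows subjects, columns stages
// 0..M. Stage k implies, for each region, the highest level reached among the
// first k events (0 if none); the subject likelihood is the product over
// regions of the probability of that implied level.
static void stage_logliks(const NumericVector &logp, int N, int R,
                          const IntegerVector &ev_region,
                          const IntegerVector &ev_level,
                          const std::vector<int> &order,
                          std::vector<double> &out /* N x (M+1) */) {
  const int M = order.size();
  for (int n = 0; n < N; ++n) {
    double s0 = 0.0;
    for (int r = 0; r < R; ++r) s0 += lp(logp, N, R, n, r, 0);
    out[n] = s0;
  }
  for (int k = 0; k < M; ++k) {
    const int e = order[k];
    const int r = ev_region[e], l = ev_level[e];
    for (int n = 0; n < N; ++n) {
      out[n + N * (k + 1)] = out[n + N * k] +
        lp(logp, N, R, n, r, l) - lp(logp, N, R, n, r, l - 1);
    }
  }
}

// Dataset log-likelihood for one sequence: per subject, log sum over stages
// of prior_k * L(x | k), summed over subjects.
static double seq_objective(const NumericVector &logp, int N, int R,
                            const IntegerVector &ev_region,
                            const IntegerVector &ev_level,
                            const std::vector<int> &order,
                            const NumericVector &log_prior,
                            std::vector<double> &work) {
  const int M = order.size();
  stage_logliks(logp, N, R, ev_region, ev_level, order, work);
  double total = 0.0;
  for (int n = 0; n < N; ++n) {
    double mx = R_NegInf;
    for (int k = 0; k <= M; ++k) {
      double v = work[n + N * k] + log_prior[k];
      if (v > mx) mx = v;
    }
    double s = 0.0;
    for (int k = 0; k <= M; ++k)
      s += std::exp(work[n + N * k] + log_prior[k] - mx);
    total += mx + std::log(s);
  }
  return total;
}

// Constraint window for relocating event e: positions (in the order with e
// removed) strictly after level l-1 of the same region and at or before
// level l+1. Returns [lo, hi] of admissible insertion slots, 0-based.
static void move_window(const IntegerVector &ev_region,
                        const IntegerVector &ev_level,
                        const std::vector<int> &rest, int e,
                        int &lo, int &hi) {
  const int r = ev_region[e], l = ev_level[e];
  lo = 0;
  hi = rest.size();
  for (size_t j = 0; j < rest.size(); ++j) {
    const int e2 = rest[j];
    if (ev_region[e2] != r) continue;
    if (ev_level[e2] == l - 1) lo = j + 1;
    if (ev_level[e2] == l + 1 && (int)j < hi) hi = j;
  }
}

static std::vector<int> insert_at(const std::vector<int> &rest, int e, int j) {
  std::vector<int> out;
  out.reserve(rest.size() + 1);
  out.insert(out.end(), rest.begin(), rest.begin() + j);
  out.push_back(e);
  out.insert(out.end(), rest.begin() + j, rest.end());
  return out;
}

// [[Rcpp::export]]
NumericMatrix stage_logliks_cpp(NumericVector logp, IntegerVector dims,
                                IntegerVector ev_region, IntegerVector ev_level,
                                IntegerVector order) {
  const int N = dims[0], R = dims[1], M = order.size();
  std::vector<int> ord(order.begin(), order.end());
  std::vector<double> work((size_t)N * (M + 1));
  stage_logliks(logp, N, R, ev_region, ev_level, ord, work);
  NumericMatrix out(N, M + 1);
  std::copy(work.begin(), work.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
double seq_objective_cpp(NumericVector logp, IntegerVector dims,
                         IntegerVector ev_region, IntegerVector ev_level,
                         IntegerVector order, NumericVector log_prior) {
  const int N = dims[0], R = dims[1];
  std::vector<int> ord(order.begin(), order.end());
  std::vector<double> work((size_t)N * (order.size() + 1));
  return seq_objective(logp, N, R, ev_region, ev_level, ord, log_prior, work);
}

// [[Rcpp::export]]
NumericVector marginal_logliks_cpp(NumericVector logp, IntegerVector dims,
                                   IntegerVector ev_region,
                                   IntegerVector ev_level,
                                   IntegerVector order,
                                   NumericVector log_prior) {
  const int N = dims[0], R = dims[1], M = order.size();
  std::vector<int> ord(order.begin(), order.end());
  std::vector<double> work((size_t)N * (M + 1));
  stage_logliks(logp, N, R, ev_region, ev_level, ord, work);
  NumericVector out(N);
  for (int n = 0; n < N; ++n) {
    double mx = R_NegInf;
    for (int k = 0; k <= M; ++k) {
      double v = work[n + N * k] + log_prior[k];
      if (v > mx) mx = v;
    }
    double s = 0.0;
    for (int k = 0; k <= M; ++k)
      s += std::exp(work[n + N * k] + log_prior[k] - mx);
    out[n] = mx + std::log(s);
  }
  return out;
}

// Greedy coordinate ascent: repeatedly relocate each event (in canonical
// event-id order) to its best admissible position; earliest position wins
// ties; stops when a full sweep makes no strict improvement.
// [[Rcpp::export]]
List greedy_fit_cpp(NumericVector logp, IntegerVector dims,
                    IntegerVector ev_region, IntegerVector ev_level,
                    IntegerVector init_order, NumericVector log_prior,
                    int max_sweeps = 100) {
  const int N = dims[0], R = dims[1], M = init_order.size();
  std::vector<int> order(init_order.begin(), init_order.end());
  std::vector<double> work((size_t)N * (M + 1));
  double cur = seq_objective(logp, N, R, ev_region, ev_level, order,
                             log_prior, work);
  const double eps = 1e-9;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool moved = false;
    for (int e = 0; e < M; ++e) {
      std::vector<int> rest;
      rest.reserve(M - 1);
      for (int j = 0; j < M; ++j)
        if (order[j] != e) rest.push_back(order[j]);
      int lo, hi;
      move_window(ev_region, ev_level, rest, e, lo, hi);
      double best = cur;
      int best_j = -1;
      for (int j = lo; j <= hi; ++j) {
        std::vector<int> cand = insert_at(rest, e, j);
        double obj = seq_objective(logp, N, R, ev_region, ev_level, cand,
                                   log_prior, work);
        if (obj > best + eps) {  // earliest j among near-equal maxima
          best = obj;
          best_j = j;
        }
      }
      if (best_j >= 0) {
        order = insert_at(rest, e, best_j);
        cur = best;
        moved = true;
      }
    }
    if (!moved) break;
  }
  return List::create(_["order"] = IntegerVector(order.begin(), order.end()),
                      _["loglik"] = cur);
}

// Metropolis-Hastings over valid sequences. Proposal: a uniformly chosen
// event relocated to a uniformly chosen admissible slot (the slot count for
// a given event does not depend on its current position, so the proposal is
// symmetric). Acceptance min(1, L_new / L_old) on the dataset likelihood.
// Uses R's RNG so chains are reproducible under set.seed().
// [[Rcpp::export]]
List mcmc_cpp(NumericVector logp, IntegerVector dims,
              IntegerVector ev_region, IntegerVector ev_level,
              IntegerVector init_order, NumericVector log_prior,
              int n_iter, int burn, int thin) {
  const int N = dims[0], R = dims[1], M = init_order.size();
  std::vector<int> order(init_order.begin(), init_order.end());
  std::vector<double> work((size_t)N * (M + 1));
  double cur = seq_objective(logp, N, R, ev_region, ev_level, order,
                             log_prior, work);
  if (!R_finite(cur)) stop("zero-likelihood starting sequence");
  const int n_keep = (n_iter > burn) ? (n_iter - burn + thin - 1) / thin : 0;
  IntegerMatrix samples(n_keep, M);
  NumericVector logliks(n_keep);
  int kept = 0;
  long accepted = 0;
  for (int it = 0; it < n_iter; ++it) {
    const int e = (int)(unif_rand() * M) % M;
    std::vector<int> rest;
    rest.reserve(M - 1);
    for (int j = 0; j < M; ++j)
      if (order[j] != e) rest.push_back(order[j]);
    int lo, hi;
    move_window(ev_region, ev_level, rest, e, lo, hi);
    const int n_slots = hi - lo + 1;
    const int j = lo + ((int)(unif_rand() * n_slots) % n_slots);
    std::vector<int> cand = insert_at(rest, e, j);
    const double prop = seq_objective(logp, N, R, ev_region, ev_level, cand,
                                      log_prior, work);
    if (prop >= cur || unif_rand() < std::exp(prop - cur)) {
      order = cand;
      cur = prop;
      ++accepted;
    }
    if (it >= burn && (it - burn) % thin == 0) {
      for (int m = 0; m < M; ++m) samples(kept, m) = order[m];
      logliks[kept] = cur;
      ++kept;
    }
  }
  return List::create(_["samples"] = samples, _["logliks"] = logliks,
                      _["acceptance_rate"] = (double)accepted / n_iter,
                      _["final_order"] = IntegerVector(order.begin(),
                                                       order.end()),
                      _["final_loglik"] = cur);
}

// Batch marginal log-likelihoods for many sampled sequences: returns an
// N x S matrix, one column per sequence sample.
// [[Rcpp::export]]
NumericMatrix marginal_logliks_batch_cpp(NumericVector logp, IntegerVector dims,
                                         IntegerVector ev_region,
                                         IntegerVector ev_level,
                                         IntegerMatrix samples,
                                         NumericVector log_prior) {
  const int N = dims[0], R = dims[1], M = samples.ncol(), S = samples.nrow();
  NumericMatrix out(N, S);
  std::vector<double> work((size_t)N * (M + 1));
  std::vector<int> ord(M);
  for (int s = 0; s < S; ++s) {
    for (int m = 0; m < M; ++m) ord[m] = samples(s, m);
    stage_logliks(logp, N, R, ev_region, ev_level, ord, work);
    for (int n = 0; n < N; ++n) {
      double mx = R_NegInf;
      for (int k = 0; k <= M; ++k) {
        double v = work[n + N * k] + log_prior[k];
        if (v > mx) mx = v;
      }
      double acc = 0.0;
      for (int k = 0; k <= M; ++k)
        acc += std::exp(work[n + N * k] + log_prior[k] - mx);
      out(n, s) = mx + std::log(acc);
    }
  }
  return out;
}

// Stage posterior averaged over sampled sequences: N x (M + 1), rows sum
// to 1 (each sample's posterior is normalised before averaging).
// [[Rcpp::export]]
NumericMatrix avg_stage_posterior_cpp(NumericVector logp, IntegerVector dims,
                                      IntegerVector ev_region,
                                      IntegerVector ev_level,
                                      IntegerMatrix samples,
                                      NumericVector log_prior) {
  const int N = dims[0], R = dims[1], M = samples.ncol(), S = samples.nrow();
  NumericMatrix out(N, M + 1);
  std::vector<double> work((size_t)N * (M + 1));
  std::vector<int> ord(M);
  for (int s = 0; s < S; ++s) {
    for (int m = 0; m < M; ++m) ord[m] = samples(s, m);
    stage_logliks(logp, N, R, ev_region, ev_level, ord, work);
    for (int n = 0; n < N; ++n) {
      double mx = R_NegInf;
      for (int k = 0; k <= M; ++k) {
        double v = work[n + N * k] + log_prior[k];
        if (v > mx) mx = v;
      }
      double acc = 0.0;
      for (int k = 0; k <= M; ++k)
        acc += std::exp(work[n + N * k] + log_prior[k] - mx);
      for (int k = 0; k <= M; ++k)
        out(n, k) += std::exp(work[n + N * k] + log_prior[k] - mx) / acc / S;
    }
  }
  return out;
}
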