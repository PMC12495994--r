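#include <Rcpp.h>
#include <random>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Draw one node index from the cumulative noise distribution (binary search).
static inline int draw_noise(const std::vector<double>& cum,
                             std::mt19937_64& rng,
                             std::uniform_real_distribution<double>& unif) {
  double r = unif(rng) * cum.back();
  int k = (int)(std::lower_bound(cum.begin(), cum.end(), r) - cum.begin());
  if (k >= (int)cum.size()) k = (int)cum.size() - 1;
  return k;
}

// Skip-gram with negative sampling over random-walk corpora.
// Two parameter tables: syn0 (input/center vectors, returned as embedding)
// and syn1 (output/context vectors). K negatives per positive pair, noise
// distribution given as unnormalized weights (degree^{3/4}). Learning rate
// decays linearly over the processed pairs. Returns the embedding matrix and
// the mean per-epoch value of the sampled objective (log sigma(z_u.z_v) +
// sum_k log sigma(-z_k.z_v)), which should trend upward.
// [[Rcpp::export]]
List cpp_train_sgns(List walks, int n_nodes, int dim, int window,
                    int K, int epochs, double lr, NumericVector noise_weights,
                    int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 1442695040888963407ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  std::vector<double> cum(n_nodes);
  double acc = 0.0;
  for (int i = 0; i < n_nodes; ++i) { acc += noise_weights[i]; cum[i] = acc; }

  std::vector<double> syn0((size_t)n_nodes * dim), syn1((size_t)n_nodes * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) syn0[i] = (unif(rng) - 0.5) / dim;

  // count total center-context pairs for the learning-rate schedule
  R_xlen_t n_walks = walks.size();
  long long total_pairs = 0;
  for (R_xlen_t w = 0; w < n_walks; ++w) {
    IntegerVector wk = walks[w];
    int L = wk.size();
    for (int i = 0; i < L; ++i) {
      int lo = std::max(0, i - window), hi = std::min(L - 1, i + window);
      total_pairs += (hi - lo);
    }
  }
  total_pairs *= epochs;
  if (total_pairs == 0) stop("empty walk corpus");

  NumericVector epoch_obj(epochs);
  std::vector<double> grad(dim);
  long long seen = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    double obj = 0.0; long long n_obj = 0;
    for (R_xlen_t w = 0; w < n_walks; ++w) {
      IntegerVector wk = walks[w];
      int L = wk.size();
      for (int i = 0; i < L; ++i) {
        int center = wk[i];
        int lo = std::max(0, i - window), hi = std::min(L - 1, i + window);
        for (int j = lo; j <= hi; ++j) {
          if (j == i) continue;
          int context = wk[j];
          double alpha = lr * (1.0 - (double)seen / (double)(total_pairs + 1));
          if (alpha < lr * 1e-4) alpha = lr * 1e-4;
          ++seen;
          double* v_c = &syn0[(size_t)center * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          double pair_obj = 0.0;
          for (int k = 0; k <= K; ++k) {
            int target; double label;
            if (k == 0) { target = context; label = 1.0; }
            else        { target = draw_noise(cum, rng, unif); label = 0.0; }
            double* v_t = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int d = 0; d < dim; ++d) f += v_c[d] * v_t[d];
            double s = sigmoid(f);
            pair_obj += (k == 0) ? std::log(s + 1e-12) : std::log(1.0 - s + 1e-12);
            double g = (label - s) * alpha;
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * v_t[d];
              v_t[d]  += g * v_c[d];
            }
          }
          for (int d = 0; d < dim; ++d) v_c[d] += grad[d];
          obj += pair_obj; ++n_obj;
        }
      }
    }
    epoch_obj[ep] = n_obj ? obj / n_obj : NA_REAL;
  }

  NumericMatrix emb(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i)
    for (int d = 0; d < dim; ++d)
      emb(i, d) = syn0[(size_t)i * dim + d];
  return List::create(_["embedding"] = emb, _["epoch_objective"] = epoch_obj);
}

// Draw n samples from the training noise distribution; exposed so the noise
// sampler's empirical frequencies can be checked against degree^{3/4}.
// [[Rcpp::export]]
IntegerVector cpp_sample_noise(NumericVector noise_weights, int n, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 99u);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  int m = noise_weights.size();
  std::vector<double> cum(m);
  double acc = 0.0;
  for (int i = 0; i < m; ++i) { acc += noise_weights[i]; cum[i] = acc; }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = draw_noise(cum, rng, unif) + 1;
  return out;
}
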