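// Single-threaded word2vec (CBOW / skip-gram with negative sampling).
// Deterministic for a fixed seed: one worker, own LCG, fixed update order.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const int EXP_TABLE_SIZE = 1000;
const double MAX_EXP = 6.0;

struct Rng {
  unsigned long long state;
  explicit Rng(unsigned long long seed) : state(seed) {}
  unsigned long long next() {
    state = state * 25214903917ULL + 11ULL;
    return state;
  }
  // uniform in [0,1)
  double unif() { return ((next() >> 16) & 0xFFFFFFFFULL) / 4294967296.0; }
};

} // namespace

// [[Rcpp::export]]
NumericMatrix vm_w2v_train_cpp(List sentences, IntegerVector vocab_count,
                               int dim, int window, int negative, int epochs,
                               double alpha, bool cbow, double sample,
                               int seed) {
  const int V = vocab_count.size();
  if (V == 0) stop("empty vocabulary");
  Rng rng(static_cast<unsigned long long>(seed) + 1ULL);

  // precomputed sigmoid table, as in the reference implementation
  std::vector<double> expTable(EXP_TABLE_SIZE);
  for (int i = 0; i < EXP_TABLE_SIZE; i++) {
    double x = exp((i / (double)EXP_TABLE_SIZE * 2 - 1) * MAX_EXP);
    expTable[i] = x / (x + 1);
  }
  auto sigmoid = [&](double f) -> double {
    if (f > MAX_EXP) return 1.0;
    if (f < -MAX_EXP) return 0.0;
    return expTable[(int)((f + MAX_EXP) * (EXP_TABLE_SIZE / MAX_EXP / 2))];
  };

  // unigram table for negative sampling (power 0.75)
  const int table_size = 100000;
  std::vector<int> uni(table_size);
  double train_pow = 0.0;
  for (int v = 0; v < V; v++) train_pow += std::pow((double)vocab_count[v], 0.75);
  {
    int v = 0;
    double d1 = std::pow((double)vocab_count[0], 0.75) / train_pow;
    for (int i = 0; i < table_size; i++) {
      uni[i] = v;
      if ((double)(i + 1) / table_size > d1 && v < V - 1) {
        v++;
        d1 += std::pow((double)vocab_count[v], 0.75) / train_pow;
      }
    }
  }

  std::vector<double> syn0((size_t)V * dim), syn1((size_t)V * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); i++) syn0[i] = (rng.unif() - 0.5) / dim;

  long long total_words = 0;
  for (int s = 0; s < sentences.size(); s++)
    total_words += ((IntegerVector)sentences[s]).size();
  total_words *= epochs;
  if (total_words == 0) stop("empty corpus");
  long long words_done = 0;
  long long corpus_words = 0;
  for (int v = 0; v < V; v++) corpus_words += vocab_count[v];

  std::vector<double> neu1(dim), neu1e(dim);
  std::vector<int> sent;

  for (int ep = 0; ep < epochs; ep++) {
    for (int s = 0; s < sentences.size(); s++) {
      IntegerVector raw = sentences[s];
      sent.clear();
      for (int i = 0; i < raw.size(); i++) {
        int w = raw[i];
        words_done++;
        if (w < 0 || w >= V) continue;
        if (sample > 0) { // frequency subsampling
          double f = (double)vocab_count[w] / corpus_words;
          double keep = (std::sqrt(f / sample) + 1.0) * sample / f;
          if (keep < rng.unif()) continue;
        }
        sent.push_back(w);
      }
      int n = (int)sent.size();
      for (int pos = 0; pos < n; pos++) {
        double lr = alpha * (1.0 - (double)words_done / (total_words + 1));
        if (lr < alpha * 0.0001) lr = alpha * 0.0001;
        int b = (int)(rng.next() % (unsigned long long)window);
        int word = sent[pos];
        if (cbow) {
          std::fill(neu1.begin(), neu1.end(), 0.0);
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          int cw = 0;
          for (int a = b; a < window * 2 + 1 - b; a++) {
            if (a == window) continue;
            int c = pos - window + a;
            if (c < 0 || c >= n) continue;
            const double *v0 = &syn0[(size_t)sent[c] * dim];
            for (int k = 0; k < dim; k++) neu1[k] += v0[k];
            cw++;
          }
          if (cw == 0) continue;
          for (int k = 0; k < dim; k++) neu1[k] /= cw;
          for (int d = 0; d < negative + 1; d++) {
            int target; double label;
            if (d == 0) { target = word; label = 1.0; }
            else {
              target = uni[(rng.next() >> 16) % table_size];
              if (target == word) continue;
              label = 0.0;
            }
            double *v1 = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int k = 0; k < dim; k++) f += neu1[k] * v1[k];
            double g = (label - sigmoid(f)) * lr;
            for (int k = 0; k < dim; k++) { neu1e[k] += g * v1[k]; v1[k] += g * neu1[k]; }
          }
          for (int a = b; a < window * 2 + 1 - b; a++) {
            if (a == window) continue;
            int c = pos - window + a;
            if (c < 0 || c >= n) continue;
            double *v0 = &syn0[(size_t)sent[c] * dim];
            for (int k = 0; k < dim; k++) v0[k] += neu1e[k];
          }
        } else { // skip-gram
          for (int a = b; a < window * 2 + 1 - b; a++) {
            if (a == window) continue;
            int c = pos - window + a;
            if (c < 0 || c >= n) continue;
            double *v0 = &syn0[(size_t)sent[c] * dim];
            std::fill(neu1e.begin(), neu1e.end(), 0.0);
            for (int d = 0; d < negative + 1; d++) {
              int target; double label;
              if (d == 0) { target = word; label = 1.0; }
              else {
                target = uni[(rng.next() >> 16) % table_size];
                if (target == word) continue;
                label = 0.0;
              }
              double *v1 = &syn1[(size_t)target * dim];
              double f = 0.0;
              for (int k = 0; k < dim; k++) f += v0[k] * v1[k];
              double g = (label - sigmoid(f)) * lr;
              for (int k = 0; k < dim; k++) { neu1e[k] += g * v1[k]; v1[k] += g * v0[k]; }
            }
            for (int k = 0; k < dim; k++) v0[k] += neu1e[k];
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  NumericMatrix out(V, dim);
  for (int v = 0; v < V; v++)
    for (int k = 0; k < dim; k++) out(v, k) = syn0[(size_t)v * dim + k];
  return out;
}
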