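// Skip-gram with negative sampling, word2vec style.
//
// Single-threaded with a private 64-bit LCG stream, so training is
// bit-reproducible for a given (corpus, config, seed).  Context windows
// shrink dynamically (uniform 1..window, as in the reference word2vec
// implementation); negatives are drawn from the unigram^0.75 noise
// distribution via a precomputed table; the learning rate decays linearly
// over all epochs.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

const int EXP_TABLE_SIZE = 1000;
const double MAX_EXP = 6.0;
const int NEG_TABLE_SIZE = 1000000;

inline uint64_t nextRandom(uint64_t &r) {
  r = r * 6364136223846793005ULL + 1442695040888963407ULL;
  return r;
}

}  // namespace

// [[Rcpp::export(name = ".sgnsTrain")]]
NumericMatrix sgnsTrain(List sentences, IntegerVector counts, int dim,
                        int window, int negative, int epochs, double alpha0,
                        double sample, double seed) {
  const int vocab = counts.size();
  if (vocab < 1) stop("empty vocabulary");

  std::vector<double> expTable(EXP_TABLE_SIZE);
  for (int i = 0; i < EXP_TABLE_SIZE; ++i) {
    double x = std::exp((i / (double)EXP_TABLE_SIZE * 2.0 - 1.0) * MAX_EXP);
    expTable[i] = x / (x + 1.0);
  }

  // unigram^0.75 negative-sampling table
  std::vector<int> negTable(NEG_TABLE_SIZE);
  {
    double total = 0.0;
    for (int i = 0; i < vocab; ++i) total += std::pow((double)counts[i], 0.75);
    int i = 0;
    double cum = std::pow((double)counts[0], 0.75) / total;
    for (int a = 0; a < NEG_TABLE_SIZE; ++a) {
      negTable[a] = i;
      if ((a + 1.0) / NEG_TABLE_SIZE > cum && i < vocab - 1) {
        ++i;
        cum += std::pow((double)counts[i], 0.75) / total;
      }
    }
  }

  long long totalTokens = 0;
  const int nSent = sentences.size();
  std::vector<IntegerVector> sent(nSent);
  for (int s = 0; s < nSent; ++s) {
    sent[s] = sentences[s];
    totalTokens += sent[s].size();
  }

  uint64_t rng = (uint64_t)seed * 2654435761ULL + 88172645463325252ULL;

  // init: syn0 uniform in [-0.5, 0.5]/dim (word2vec), syn1neg zero
  std::vector<float> syn0((size_t)vocab * dim), syn1((size_t)vocab * dim, 0.f);
  for (size_t i = 0; i < syn0.size(); ++i) {
    nextRandom(rng);
    syn0[i] = (float)((((rng >> 16) & 0xFFFF) / 65536.0 - 0.5) / dim);
  }

  std::vector<float> neu1e(dim);
  const long long planned = (long long)epochs * std::max(totalTokens, 1LL);
  long long trained = 0;
  double trainTotal = 0.0;
  for (int i = 0; i < vocab; ++i) trainTotal += counts[i];

  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < nSent; ++s) {
      const IntegerVector &sen = sent[s];
      const int len = sen.size();
      // optional frequency subsampling (off when sample == 0)
      std::vector<int> kept;
      kept.reserve(len);
      for (int i = 0; i < len; ++i) {
        int w = sen[i];
        if (sample > 0) {
          double f = counts[w] / trainTotal;
          double keepP = (std::sqrt(f / sample) + 1.0) * sample / f;
          if (keepP < ((nextRandom(rng) >> 16) & 0xFFFF) / 65536.0) {
            ++trained;
            continue;
          }
        }
        kept.push_back(w);
        ++trained;
      }
      double alpha = alpha0 * (1.0 - (double)trained / (planned + 1));
      if (alpha < alpha0 * 1e-4) alpha = alpha0 * 1e-4;
      const int n = kept.size();
      for (int i = 0; i < n; ++i) {
        const int wordC = kept[i];  // center: prediction target
        const int b = (int)(nextRandom(rng) % (uint64_t)window);
        for (int j = i - window + b; j <= i + window - b; ++j) {
          if (j == i || j < 0 || j >= n) continue;
          const int wordI = kept[j];  // input/context word
          float *v = &syn0[(size_t)wordI * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.f);
          for (int d = 0; d < negative + 1; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = wordC;
              label = 1.0;
            } else {
              target = negTable[(nextRandom(rng) >> 16) % NEG_TABLE_SIZE];
              if (target == wordC) continue;
              label = 0.0;
            }
            float *u = &syn1[(size_t)target * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += v[k] * u[k];
            double g;
            if (f > MAX_EXP) g = (label - 1.0) * alpha;
            else if (f < -MAX_EXP) g = label * alpha;
            else {
              int ei = (int)((f + MAX_EXP) * (EXP_TABLE_SIZE / MAX_EXP / 2.0));
              g = (label - expTable[ei]) * alpha;
            }
            for (int k = 0; k < dim; ++k) neu1e[k] += (float)(g * u[k]);
            for (int k = 0; k < dim; ++k) u[k] += (float)(g * v[k]);
          }
          for (int k = 0; k < dim; ++k) v[k] += neu1e[k];
        }
      }
    }
  }

  NumericMatrix out(vocab, dim);
  for (int i = 0; i < vocab; ++i)
    for (int k = 0; k < dim; ++k) out(i, k) = syn0[(size_t)i * dim + k];
  return out;
}
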