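#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Sorted-neighbour adjacency; all node ids 0-based.
typedef std::vector<std::vector<int> > Adj;

static Adj as_adj(const List &neighbors) {
  Adj adj(neighbors.size());
  for (int i = 0; i < neighbors.size(); ++i) {
    IntegerVector nb = neighbors[i];
    adj[i] = std::vector<int>(nb.begin(), nb.end());
  }
  return adj;
}

static inline bool is_neighbor(const Adj &adj, int u, int v) {
  const std::vector<int> &nb = adj[u];
  return std::binary_search(nb.begin(), nb.end(), v);
}

// One biased step of a second-order walk. prev < 0 means first step
// (uniform over neighbours). Returns -1 when curr has no neighbours.
// Weights follow the node2vec bias: 1/p back to prev, 1 to common
// neighbours of prev, 1/q outward; edge weights are 1 (unweighted graph).
static int sample_step(const Adj &adj, int prev, int curr,
                       double p, double q) {
  const std::vector<int> &nb = adj[curr];
  const int deg = (int)nb.size();
  if (deg == 0) return -1;
  if (prev < 0) {
    int k = (int)std::floor(unif_rand() * deg);
    if (k == deg) k = deg - 1;
    return nb[k];
  }
  std::vector<double> w(deg);
  double z = 0.0;
  for (int k = 0; k < deg; ++k) {
    int x = nb[k];
    double a;
    if (x == prev) a = 1.0 / p;
    else if (is_neighbor(adj, prev, x)) a = 1.0;
    else a = 1.0 / q;
    w[k] = a;
    z += a;
  }
  double u = unif_rand() * z, acc = 0.0;
  for (int k = 0; k < deg; ++k) {
    acc += w[k];
    if (u <= acc) return nb[k];
  }
  return nb[deg - 1];
}

// [[Rcpp::export]]
List cpp_simulate_walks(List neighbors, int walk_length, int walks_per_node,
                        double p, double q) {
  Adj adj = as_adj(neighbors);
  const int n = (int)adj.size();
  List out(n * walks_per_node);
  int w = 0;
  for (int rep = 0; rep < walks_per_node; ++rep) {
    for (int start = 0; start < n; ++start) {
      std::vector<int> walk;
      walk.reserve(walk_length);
      walk.push_back(start);
      int prev = -1, curr = start;
      while ((int)walk.size() < walk_length) {
        int nxt = sample_step(adj, prev, curr, p, q);
        if (nxt < 0) break; // dead end: terminate early
        walk.push_back(nxt);
        prev = curr;
        curr = nxt;
      }
      out[w++] = IntegerVector(walk.begin(), walk.end());
    }
  }
  return out;
}

// Repeated draws of the next step from (prev, curr); exercises the same
// sampler the walk generator uses. Used for frequency checks.
// [[Rcpp::export]]
IntegerVector cpp_next_steps(List neighbors, int prev, int curr,
                             double p, double q, int n_draws) {
  Adj adj = as_adj(neighbors);
  IntegerVector out(n_draws);
  for (int i = 0; i < n_draws; ++i) {
    out[i] = sample_step(adj, prev, curr, p, q);
  }
  return out;
}

// Skip-gram with negative sampling over walk corpora (word2vec SGNS,
// single-threaded). Vocabulary = node ids 0..n_nodes-1. Dynamic window,
// unigram^0.75 negative table, linearly decayed learning rate.
// [[Rcpp::export]]
NumericMatrix cpp_sgns(List walks, int n_nodes, int dim, int window,
                       int epochs, int negative, double alpha) {
  const int nw = walks.size();
  // frequencies for the negative-sampling table
  std::vector<double> freq(n_nodes, 0.0);
  long long total_tokens = 0;
  for (int i = 0; i < nw; ++i) {
    IntegerVector wk = walks[i];
    total_tokens += wk.size();
    for (int j = 0; j < wk.size(); ++j) freq[wk[j]] += 1.0;
  }
  const int table_size = 100000;
  std::vector<int> table(table_size);
  {
    double z = 0.0;
    for (int i = 0; i < n_nodes; ++i) z += std::pow(freq[i], 0.75);
    if (z <= 0.0) z = 1.0;
    double cum = std::pow(freq[0], 0.75) / z;
    int i = 0;
    for (int a = 0; a < table_size; ++a) {
      table[a] = i;
      if ((a + 1.0) / table_size > cum && i < n_nodes - 1) {
        ++i;
        cum += std::pow(freq[i], 0.75) / z;
      }
    }
  }

  std::vector<double> syn0((size_t)n_nodes * dim);
  std::vector<double> syn1((size_t)n_nodes * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i) {
    syn0[i] = (unif_rand() - 0.5) / dim;
  }

  // precomputed sigmoid table (word2vec-style)
  const int EXP_TABLE = 1000;
  const double MAX_EXP = 6.0;
  std::vector<double> sig_table(EXP_TABLE);
  for (int i = 0; i < EXP_TABLE; ++i) {
    double x = (2.0 * i / EXP_TABLE - 1.0) * MAX_EXP;
    sig_table[i] = 1.0 / (1.0 + std::exp(-x));
  }

  // materialise the corpus once
  std::vector<std::vector<int> > corpus(nw);
  for (int i = 0; i < nw; ++i) {
    IntegerVector wk = walks[i];
    corpus[i] = std::vector<int>(wk.begin(), wk.end());
  }

  const double min_alpha = alpha * 1e-4;
  long long processed = 0;
  const long long budget = (long long)epochs * total_tokens;
  std::vector<double> grad(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = 0; i < nw; ++i) {
      const std::vector<int> &wk = corpus[i];
      const int len = (int)wk.size();
      for (int pos = 0; pos < len; ++pos) {
        double lr = alpha * (1.0 - (double)processed / (budget + 1));
        if (lr < min_alpha) lr = min_alpha;
        ++processed;
        int b = (int)std::floor(unif_rand() * window); // dynamic window
        int center = wk[pos];
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          int cpos = pos + off;
          if (cpos < 0 || cpos >= len) continue;
          int context = wk[cpos];
          double *v = &syn0[(size_t)context * dim];
          std::fill(grad.begin(), grad.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = center;
              label = 1.0;
            } else {
              int r = (int)std::floor(unif_rand() * table_size);
              if (r == table_size) r = table_size - 1;
              target = table[r];
              if (target == center) continue;
              label = 0.0;
            }
            double *u = &syn1[(size_t)target * dim];
            double dot = 0.0;
            for (int d = 0; d < dim; ++d) dot += v[d] * u[d];
            double sig;
            if (dot >= MAX_EXP) sig = 1.0;
            else if (dot <= -MAX_EXP) sig = 0.0;
            else sig = sig_table[(int)((dot + MAX_EXP) *
                                       (EXP_TABLE / MAX_EXP / 2.0))];
            double g = lr * (label - sig);
            for (int d = 0; d < dim; ++d) {
              grad[d] += g * u[d];
              u[d] += g * v[d];
            }
          }
          for (int d = 0; d < dim; ++d) v[d] += grad[d];
        }
      }
    }
  }

  NumericMatrix out(n_nodes, dim);
  for (int i = 0; i < n_nodes; ++i) {
    for (int d = 0; d < dim; ++d) out(i, d) = syn0[(size_t)i * dim + d];
  }
  return out;
}
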