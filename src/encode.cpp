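// Fast integer encodings of DNA fragments for the network, plus the
// Markov-chain genome sampler used by the fragment simulator.
//
// Index conventions (must stay in sync with the R reference encoders):
//  * base one-hot column index: A=3, C=2, G=1, T=0 (so that the one-hot
//    vectors read A=[0,0,0,1], C=[0,0,1,0], G=[0,1,0,0], T=[1,0,0,0]);
//    ambiguous letters -> -1 (all-zero row).
//  * codon one-hot column index: lexicographic over A<C<G<T,
//    AAA=0, AAC=1, ..., TTT=63; any ambiguous base in the codon -> -1.
//  * row order: forward strand first, then reverse complement; codon frames
//    forward offsets 0,1,2 then reverse-complement offsets 0,1,2.
//  * padding positions are -1.

#include <Rcpp.h>
#include <random>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int base_lex(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

// one-hot column of a base under the A=[0,0,0,1] ... T=[1,0,0,0] map
static inline int base_col(char c) {
  int lex = base_lex(c);
  return lex < 0 ? -1 : 3 - lex;
}

static inline char complement_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// [[Rcpp::export]]
std::string revcomp_cpp(std::string s) {
  const size_t L = s.size();
  std::string out(L, 'N');
  for (size_t i = 0; i < L; ++i)
    out[i] = complement_base(s[L - 1 - i]);
  return out;
}

// Integer index encodings, one fragment per column, padded with -1 to the
// group's fixed shape (2*Lmax rows for both matrices).
// [[Rcpp::export]]
List encode_indices_cpp(CharacterVector seqs, int Lmax) {
  const int n = seqs.size();
  const int rows = 2 * Lmax;
  IntegerMatrix boh(rows, n), coh(rows, n);
  std::fill(boh.begin(), boh.end(), -1);
  std::fill(coh.begin(), coh.end(), -1);

  for (int j = 0; j < n; ++j) {
    std::string s = as<std::string>(seqs[j]);
    const int L = (int)s.size();
    if (L < 1 || L > Lmax)
      stop("sequence %d has length %d, outside [1, %d]", j + 1, L, Lmax);
    std::string rc = revcomp_cpp(s);

    for (int i = 0; i < L; ++i) {
      boh(i, j)     = base_col(s[i]);
      boh(L + i, j) = base_col(rc[i]);
    }

    if (L >= 3) {
      int r = 0;
      for (int strand = 0; strand < 2; ++strand) {
        const std::string& q = strand == 0 ? s : rc;
        for (int off = 0; off < 3; ++off) {
          for (int p = off; p + 2 < L; p += 3) {
            int a = base_lex(q[p]), b = base_lex(q[p + 1]), c = base_lex(q[p + 2]);
            coh(r++, j) = (a < 0 || b < 0 || c < 0) ? -1 : 16 * a + 4 * b + c;
          }
        }
      }
      // r == 2*(L-2) by the floor-sum identity; remaining rows stay -1
    }
  }
  return List::create(_["boh"] = boh, _["coh"] = coh);
}

// Sample a sequence from an order-k Markov chain over {A,C,G,T}.
// trans: 4^k x 4 row-stochastic matrix; row index is the lexicographic code
// of the current k-mer context. The first k bases are drawn uniformly.
// [[Rcpp::export]]
std::string markov_sample_cpp(NumericMatrix trans, int len, int order, int seed) {
  if (order < 1) stop("order must be >= 1");
  int nctx = 1;
  for (int i = 0; i < order; ++i) nctx *= 4;
  if (trans.nrow() != nctx || trans.ncol() != 4)
    stop("transition matrix must be %d x 4", nctx);
  if (len < order) stop("length must be >= the model order");

  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  const char bases[4] = {'A', 'C', 'G', 'T'};

  std::string out(len, 'A');
  int ctx = 0;
  for (int i = 0; i < order; ++i) {
    int b = std::min(3, (int)(unif(rng) * 4.0));
    out[i] = bases[b];
    ctx = ctx * 4 + b;
  }
  const int ctx_mod = nctx / 4;
  for (int i = order; i < len; ++i) {
    double u = unif(rng), acc = 0.0;
    int b = 3;
    for (int k = 0; k < 4; ++k) {
      acc += trans(ctx, k);
      if (u < acc) { b = k; break; }
    }
    out[i] = bases[b];
    ctx = (ctx % ctx_mod) * 4 + b;
  }
  return out;
}
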