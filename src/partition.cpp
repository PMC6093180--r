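#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

typedef long double ld;

// Boltzmann partition function over nested secondary structures of a
// single strand.  Energy of a structure = sum of pair energies + a
// stacking bonus whenever (i,j) and (i+1,j-1) are both paired (keyed by
// the outer pair).  Hairpin loops must enclose >= minloop unpaired
// bases.  Recursions are carried out on per-nucleotide rescaled arrays
// in long double so that sequences of several hundred nt neither
// overflow nor underflow; Z is reported in log space.
//
// Grammar (unambiguous):
//   Q(i,j)  = Q(i,j-1) + sum_k Q(i,k-1) * Qb(k,j)      [j unpaired | j pairs k]
//   Qb(i,j) = w(i,j) * ( Q(i+1,j-1) + (sig(i,j)-1) * Qb(i+1,j-1) )
// with Q(i,i-1) = 1 (empty span).  Base-pair probabilities come from
// the matching outside pass.

namespace {

struct PF {
  int n;
  const int *s;            // 1..4 = A,C,G,U; 0 = N (unpairable)
  ld W[5][5];              // exp(-E_pair/kT), 0 if not pairable
  ld SIG[5][5];            // exp(-E_stack/kT) keyed by outer pair
  int minloop;
  ld scale, logscale;
  std::vector<ld> Q, Qb;
  std::vector<char> unp;   // forced-unpaired flags, 1-based

  PF(const int *seq, int len, const NumericMatrix &pairw,
     const NumericMatrix &sigma, int minloop_)
      : n(len), s(seq), minloop(minloop_) {
    ld wmax = 1.0L;
    for (int a = 1; a <= 4; ++a)
      for (int b = 1; b <= 4; ++b) {
        W[a][b] = (ld)pairw(a - 1, b - 1);
        SIG[a][b] = (ld)sigma(a - 1, b - 1);
        ld ws = W[a][b] * (SIG[a][b] > 1.0L ? SIG[a][b] : 1.0L);
        if (ws > wmax) wmax = ws;
      }
    for (int a = 0; a <= 4; ++a) { W[0][a] = W[a][0] = 0.0L; SIG[0][a] = SIG[a][0] = 1.0L; }
    scale = sqrtl(wmax);
    if (scale < 1.0L) scale = 1.0L;
    logscale = logl(scale);
    unp.assign(n + 2, 0);
  }

  inline int id(int i, int j) const { return i * (n + 2) + j; }
  inline ld q(int i, int j) const { return j < i ? 1.0L : Q[id(i, j)]; }
  inline ld qb(int i, int j) const { return j < i ? 0.0L : Qb[id(i, j)]; }

  inline bool can_pair(int i, int j) const {
    if (j - i - 1 < minloop) return false;
    if (unp[i] || unp[j]) return false;
    return W[s[i - 1] == 0 ? 0 : s[i - 1]][s[j - 1] == 0 ? 0 : s[j - 1]] > 0.0L;
  }
  inline ld w(int i, int j) const { return W[s[i - 1]][s[j - 1]]; }
  inline ld sig(int i, int j) const { return SIG[s[i - 1]][s[j - 1]]; }

  void inside() {
    int sz = (n + 2) * (n + 2);
    Q.assign(sz, 0.0L);
    Qb.assign(sz, 0.0L);
    ld s2 = scale * scale;
    for (int len = 1; len <= n; ++len) {
      for (int i = 1; i + len - 1 <= n; ++i) {
        int j = i + len - 1;
        ld b = 0.0L;
        if (can_pair(i, j)) {
          ld inner = q(i + 1, j - 1);
          ld inb = qb(i + 1, j - 1);
          if (inb > 0.0L) inner += (sig(i, j) - 1.0L) * inb;
          b = (w(i, j) / s2) * inner;
        }
        Qb[id(i, j)] = b;
        ld acc = q(i, j - 1) / scale;  // j unpaired
        for (int k = i; k <= j - minloop - 1; ++k) {
          ld bk = qb(k, j);
          if (bk > 0.0L) acc += q(i, k - 1) * bk;
        }
        Q[id(i, j)] = acc;
      }
    }
  }

  double logZ() const { return (double)(logl(q(1, n)) + n * logscale); }

  // Outside pass; fills pair probability matrix (n x n, symmetric).
  void outside(NumericMatrix &bpp) const {
    int sz = (n + 2) * (n + 2);
    std::vector<ld> OQ(sz, 0.0L), OB(sz, 0.0L);
    OQ[id(1, n)] = 1.0L;
    ld s2 = scale * scale;
    ld Zs = q(1, n);
    for (int len = n; len >= 1; --len) {
      for (int i = 1; i + len - 1 <= n; ++i) {
        int j = i + len - 1;
        ld o = (i == 1 && j == n) ? 1.0L : 0.0L;
        if (j + 1 <= n) o += OQ[id(i, j + 1)] / scale;
        for (int J = j + 1; J <= n; ++J) {
          ld bk = qb(j + 1, J);
          if (bk > 0.0L) o += OQ[id(i, J)] * bk;
        }
        if (i - 1 >= 1 && j + 1 <= n && can_pair(i - 1, j + 1))
          o += OB[id(i - 1, j + 1)] * (w(i - 1, j + 1) / s2);
        OQ[id(i, j)] = o;

        ld ob = 0.0L;
        if (qb(i, j) > 0.0L) {
          for (int I = 1; I <= i; ++I) ob += OQ[id(I, j)] * q(I, i - 1);
          if (i - 1 >= 1 && j + 1 <= n && can_pair(i - 1, j + 1)) {
            ld inb = qb(i, j);  // only relevant when inner pair exists
            (void)inb;
            ob += OB[id(i - 1, j + 1)] * (w(i - 1, j + 1) / s2) *
                  (sig(i - 1, j + 1) - 1.0L);
          }
        }
        OB[id(i, j)] = ob;
      }
    }
    for (int i = 1; i <= n; ++i)
      for (int j = i + 1; j <= n; ++j) {
        ld b = qb(i, j);
        if (b <= 0.0L) continue;
        double p = (double)(b * OB[id(i, j)] / Zs);
        if (p < 0) p = 0;
        if (p > 1) p = 1;
        bpp(i - 1, j - 1) = p;
        bpp(j - 1, i - 1) = p;
      }
  }
};

}  // namespace

// [[Rcpp::export(name = ".pf_run")]]
List pf_run(IntegerVector seq, NumericMatrix pairw, NumericMatrix sigma,
            int minloop, IntegerVector forced_unpaired, bool want_bpp) {
  int n = seq.size();
  std::vector<int> s(seq.begin(), seq.end());
  PF pf(s.data(), n, pairw, sigma, minloop);
  for (int k = 0; k < forced_unpaired.size(); ++k) {
    int p = forced_unpaired[k];
    if (p >= 1 && p <= n) pf.unp[p] = 1;
  }
  pf.inside();
  double lz = pf.logZ();
  if (!want_bpp) return List::create(_["logZ"] = lz);
  NumericMatrix bpp(n, n);
  pf.outside(bpp);
  NumericVector unpaired(n);
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int j = 0; j < n; ++j) tot += bpp(i, j);
    double u = 1.0 - tot;
    unpaired[i] = u < 0 ? 0 : (u > 1 ? 1 : u);
  }
  return List::create(_["logZ"] = lz, _["pair_prob"] = bpp,
                      _["unpaired_prob"] = unpaired);
}

// PU of span [i,j] (1-based, inclusive): Z(span forced unpaired)/Z.
// [[Rcpp::export(name = ".pf_pu_span")]]
double pf_pu_span(IntegerVector seq, int i, int j, NumericMatrix pairw,
                  NumericMatrix sigma, int minloop) {
  int n = seq.size();
  std::vector<int> s(seq.begin(), seq.end());
  PF free(s.data(), n, pairw, sigma, minloop);
  free.inside();
  PF con(s.data(), n, pairw, sigma, minloop);
  for (int p = i; p <= j; ++p) con.unp[p] = 1;
  con.inside();
  double pu = (double)expl((ld)con.logZ() - (ld)free.logZ());
  return pu > 1.0 ? 1.0 : pu;
}

// Pentamer PU values for many centers of one sequence at several
// symmetric context lengths.  centers are 1-based indices of pentamer
// middles (center-2 .. center+2 must lie inside seq); the extracted
// context substring is truncated at the sequence ends.
// [[Rcpp::export(name = ".pf_pentamer_batch")]]
NumericMatrix pf_pentamer_batch(IntegerVector seq, IntegerVector centers,
                                NumericMatrix pairw, NumericMatrix sigma,
                                int minloop, IntegerVector context_lens) {
  int n = seq.size();
  int nc = centers.size(), nl = context_lens.size();
  std::vector<int> s(seq.begin(), seq.end());
  NumericMatrix out(nc, nl);
  for (int ci = 0; ci < nc; ++ci) {
    int c = centers[ci];
    if (c - 2 < 1 || c + 2 > n)
      stop("pentamer at center %d is not fully inside the sequence", c);
    for (int li = 0; li < nl; ++li) {
      int L = context_lens[li];
      int lo = c - 2 - L; if (lo < 1) lo = 1;
      int hi = c + 2 + L; if (hi > n) hi = n;
      int m = hi - lo + 1;
      PF free(s.data() + (lo - 1), m, pairw, sigma, minloop);
      free.inside();
      PF con(s.data() + (lo - 1), m, pairw, sigma, minloop);
      for (int p = c - 2; p <= c + 2; ++p) con.unp[p - lo + 1] = 1;
      con.inside();
      double pu = (double)expl((ld)con.logZ() - (ld)free.logZ());
      out(ci, li) = pu > 1.0 ? 1.0 : pu;
    }
  }
  return out;
}
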