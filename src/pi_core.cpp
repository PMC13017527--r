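#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// Block entropies of the delimiter-padded stationary process induced by a
// weighted set of forms.  Symbols are coded 1..K, the delimiter is 0, so a
// window of n symbols is an integer in base (K+1) when that fits in 64 bits.
//
// Each form s contributes |s|+1 windows, one ending at every symbol of s·#,
// left-padded with delimiters; window weight is prob(s)/Z with
// Z = sum_s prob(s) * (|s|+1) (the length reweighting).

static const double W_EPS = 1e-15;

class BlockEntropy {
public:
  BlockEntropy(int base) : base_(base) {}

  // H_n in bits of the n-window distribution.  With ctx = false, windows
  // end at every symbol of s·# (positions 0..len); with ctx = true they are
  // the conditioning contexts, ending one position earlier (-1..len-1,
  // position -1 being the all-delimiter context).
  long double block_h(const std::vector<const int*>& forms,
                      const std::vector<int>& lens,
                      const std::vector<double>& w, int n, bool ctx) {
    if (n == 0) return 0.0L;
    double lb = std::log2((double)base_);
    bool fits64 = (n * lb) < 62.0;
    if (fits64) {
      uint64_t size = 1;
      for (int i = 0; i < n; ++i) size *= (uint64_t)base_;
      if (size <= DENSE_MAX) return dense_h(forms, lens, w, n, ctx, size);
      return map64_h(forms, lens, w, n, ctx);
    }
    return maps_h(forms, lens, w, n, ctx);
  }

private:
  static const uint64_t DENSE_MAX = (1ull << 24);
  int base_;
  std::vector<double> cell_;
  std::vector<uint64_t> touched_;
  std::unordered_map<uint64_t, double> map64_;
  std::unordered_map<std::string, double> maps_;

  static long double entropy_term(long double acc, double w) {
    return acc - (long double)w * std::log2((long double)w);
  }

  long double dense_h(const std::vector<const int*>& forms,
                      const std::vector<int>& lens,
                      const std::vector<double>& w, int n, bool ctx,
                      uint64_t size) {
    if (cell_.size() < size) cell_.resize(size, 0.0);
    touched_.clear();
    uint64_t mask = size / (uint64_t)base_;  // base^(n-1)
    for (size_t f = 0; f < forms.size(); ++f) {
      if (w[f] <= W_EPS) continue;
      const int* s = forms[f];
      int len = lens[f];
      int lo = ctx ? -1 : 0, hi = ctx ? len - 1 : len;
      uint64_t key = 0;  // window of n delimiters
      for (int j = lo; j <= hi; ++j) {
        int sym = (j >= 0 && j < len) ? s[j] : 0;
        key = (key % mask) * (uint64_t)base_ + (uint64_t)sym;
        if (cell_[key] == 0.0) touched_.push_back(key);
        cell_[key] += w[f];
      }
    }
    long double H = 0.0L;
    for (uint64_t k : touched_) {
      H = entropy_term(H, cell_[k]);
      cell_[k] = 0.0;
    }
    return H;
  }

  long double map64_h(const std::vector<const int*>& forms,
                      const std::vector<int>& lens,
                      const std::vector<double>& w, int n, bool ctx) {
    map64_.clear();
    uint64_t mask = 1;
    for (int i = 0; i < n - 1; ++i) mask *= (uint64_t)base_;
    for (size_t f = 0; f < forms.size(); ++f) {
      if (w[f] <= W_EPS) continue;
      const int* s = forms[f];
      int len = lens[f];
      int lo = ctx ? -1 : 0, hi = ctx ? len - 1 : len;
      uint64_t key = 0;
      for (int j = lo; j <= hi; ++j) {
        int sym = (j >= 0 && j < len) ? s[j] : 0;
        key = (key % mask) * (uint64_t)base_ + (uint64_t)sym;
        map64_[key] += w[f];
      }
    }
    long double H = 0.0L;
    for (auto& kv : map64_) H = entropy_term(H, kv.second);
    return H;
  }

  // general path: window key as 2-bytes-per-symbol string (K <= 65535)
  long double maps_h(const std::vector<const int*>& forms,
                     const std::vector<int>& lens,
                     const std::vector<double>& w, int n, bool ctx) {
    maps_.clear();
    std::string key(2 * (size_t)n, '\0');
    for (size_t f = 0; f < forms.size(); ++f) {
      if (w[f] <= W_EPS) continue;
      const int* s = forms[f];
      int len = lens[f];
      int lo = ctx ? -1 : 0, hi = ctx ? len - 1 : len;
      for (int j = lo; j <= hi; ++j) {
        for (int t = 0; t < n; ++t) {
          int pos = j - (n - 1) + t;
          int sym = (pos >= 0 && pos < len) ? s[pos] : 0;
          key[2 * t] = (char)(sym & 0xFF);
          key[2 * t + 1] = (char)((sym >> 8) & 0xFF);
        }
        maps_[key] += w[f];
      }
    }
    long double H = 0.0L;
    for (auto& kv : maps_) H = entropy_term(H, kv.second);
    return H;
  }
};

struct EOut {
  std::vector<long double> h;  // h_1 .. h_{Lmax+3}
  long double E;
  long double hrate;
  int Lmax;
};

// forms coded 1..K (delimiter 0), probs sum to 1 over distinct forms
static EOut compute_E(const std::vector<const int*>& forms,
                      const std::vector<int>& lens,
                      const std::vector<double>& probs,
                      int base, BlockEntropy& be) {
  int Lmax = 0;
  for (int l : lens) if (l > Lmax) Lmax = l;
  double Z = 0.0;
  for (size_t f = 0; f < forms.size(); ++f) Z += probs[f] * (lens[f] + 1);
  std::vector<double> w(probs.size());
  for (size_t f = 0; f < probs.size(); ++f) w[f] = probs[f] / Z;

  int n_max = Lmax + 3;
  EOut out;
  out.Lmax = Lmax;
  out.h.resize(n_max);
  for (int n = 1; n <= n_max; ++n) {
    long double joint = be.block_h(forms, lens, w, n, false);
    long double context = be.block_h(forms, lens, w, n - 1, true);
    out.h[n - 1] = joint - context;
  }
  out.hrate = out.h[Lmax + 1];  // h_{Lmax+2}
  long double conv = out.h[Lmax + 2] - out.hrate;
  if (std::fabs((double)conv) > 1e-12)
    stop("entropy rate failed to converge by window n = L_max + 2 (gap %g)",
         (double)conv);
  long double E = 0.0L;
  for (int n = 1; n <= Lmax + 1; ++n) E += out.h[n - 1] - out.hrate;
  out.E = E < 0 ? 0 : E;
  return out;
}

static void forms_from_list(const List& forms, std::vector<std::vector<int>>& store,
                            std::vector<const int*>& ptrs, std::vector<int>& lens) {
  int nf = forms.size();
  store.resize(nf);
  ptrs.resize(nf);
  lens.resize(nf);
  for (int i = 0; i < nf; ++i) {
    IntegerVector v = forms[i];
    store[i].assign(v.begin(), v.end());
    ptrs[i] = store[i].data();
    lens[i] = store[i].size();
  }
}

// [[Rcpp::export]]
List pi_e_cpp(List forms, NumericVector probs, int base) {
  std::vector<std::vector<int>> store;
  std::vector<const int*> ptrs;
  std::vector<int> lens;
  forms_from_list(forms, store, ptrs, lens);
  std::vector<double> p(probs.begin(), probs.end());
  BlockEntropy be(base);
  EOut out = compute_E(ptrs, lens, p, base, be);
  NumericVector h(out.h.size());
  for (size_t i = 0; i < out.h.size(); ++i) h[i] = (double)out.h[i];
  return List::create(_["E"] = (double)out.E, _["h"] = (double)out.hrate,
                      _["h_series"] = h, _["L_max"] = out.Lmax);
}

// E for every row of `perms`: permutation of the columns of the fixed-length
// form matrix (new position j takes old position perms(r, j), 1-based)
// [[Rcpp::export]]
NumericVector pi_perm_sweep_cpp(IntegerMatrix forms, NumericVector probs,
                                IntegerMatrix perms, int base) {
  int nf = forms.nrow(), L = forms.ncol(), np = perms.nrow();
  if (perms.ncol() != L) stop("permutation length must equal form length");
  std::vector<double> p(probs.begin(), probs.end());
  std::vector<std::vector<int>> store(nf, std::vector<int>(L));
  std::vector<const int*> ptrs(nf);
  std::vector<int> lens(nf, L);
  for (int i = 0; i < nf; ++i) ptrs[i] = store[i].data();
  BlockEntropy be(base);
  NumericVector out(np);
  for (int r = 0; r < np; ++r) {
    for (int i = 0; i < nf; ++i)
      for (int j = 0; j < L; ++j)
        store[i][j] = forms(i, perms(r, j) - 1);
    out[r] = (double)compute_E(ptrs, lens, p, base, be).E;
    if (r % 256 == 0) checkUserInterrupt();
  }
  return out;
}

// E for every row of `assign`: meaning m carries probs[m] and is expressed by
// forms[[assign(r, m)]] (1-based); meanings sharing a form are aggregated
// [[Rcpp::export]]
NumericVector pi_assign_sweep_cpp(List forms, NumericVector probs,
                                  IntegerMatrix assign, int base) {
  std::vector<std::vector<int>> store;
  std::vector<const int*> ptrs;
  std::vector<int> lens;
  forms_from_list(forms, store, ptrs, lens);
  int nf = store.size(), nm = assign.ncol(), ns = assign.nrow();
  if (probs.size() != nm) stop("probs must have one entry per meaning");
  BlockEntropy be(base);
  NumericVector out(ns);
  std::vector<double> w(nf);
  for (int r = 0; r < ns; ++r) {
    std::fill(w.begin(), w.end(), 0.0);
    for (int m = 0; m < nm; ++m) {
      int j = assign(r, m) - 1;
      if (j < 0 || j >= nf) stop("assignment index out of range");
      w[j] += probs[m];
    }
    out[r] = (double)compute_E(ptrs, lens, w, base, be).E;
    if (r % 256 == 0) checkUserInterrupt();
  }
  return out;
}
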