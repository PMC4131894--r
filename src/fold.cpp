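#include <Rcpp.h>
#include <vector>
#include <array>
#include <string>
#include <cmath>
using namespace Rcpp;

// Base codes: A=0, C=1, G=2, T/U=3. Pair types indexed as
// AU=0, UA=1, CG=2, GC=3, GU=4, UG=5; -1 = not pairable.
//
// Stacking free energies (kcal/mol) for pair q stacked immediately inside
// pair p (p closes, q is the next pair towards the loop). Turner-like values,
// symmetrised so that S[p][q] == S[flip(q)][flip(p)] (helix energy is the
// same read from either strand) and clamped to <= 0 so that any structure
// with at least one stack has negative energy.
static const double STACK[6][6] = {
  // inner:   AU     UA     CG     GC     GU     UG      outer
  { -0.93, -1.10, -2.24, -2.08, -0.55, -1.36 }, // AU
  { -1.33, -0.93, -2.35, -2.11, -1.27, -1.00 }, // UA
  { -2.11, -2.08, -3.26, -3.42, -2.51, -1.53 }, // CG
  { -2.35, -2.24, -2.36, -3.26, -1.41, -2.11 }, // GC
  { -1.00, -1.36, -2.11, -1.53, -0.50, -0.30 }, // GU
  { -1.27, -0.55, -1.41, -2.51, -0.30, -0.50 }  // UG
};

static const int MIN_LOOP = 3;

// Loop-closure penalties (kcal/mol, energy mode only): closing a hairpin
// loop or a non-stacked interior (bulge / internal / multibranch) costs a
// flat penalty, so isolated or scattered pairs are not free. Oracle
// (maxpair) mode uses no penalties.
static const double HAIRPIN_PEN = 3.0;
static const double INTERIOR_PEN = 3.0;

static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0; // A:U
  if (a == 3 && b == 0) return 1; // U:A
  if (a == 1 && b == 2) return 2; // C:G
  if (a == 2 && b == 1) return 3; // G:C
  if (a == 2 && b == 3) return 4; // G:U
  if (a == 3 && b == 2) return 5; // U:G
  return -1;
}

// [[Rcpp::export(name = ".stack_table_cpp")]]
NumericMatrix stack_table_cpp() {
  NumericMatrix out(6, 6);
  CharacterVector nm = CharacterVector::create("AU", "UA", "CG", "GC", "GU", "UG");
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) out(i, j) = STACK[i][j];
  out.attr("dimnames") = List::create(nm, nm);
  return out;
}

// [[Rcpp::export(name = ".pair_type_cpp")]]
IntegerVector pair_type_cpp(IntegerVector a, IntegerVector b) {
  int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = pair_type(a[i], b[i]);
  return out;
}

// Minimum-free-energy fold by a Nussinov-style dynamic program scored with
// nearest-neighbor stack energies (loops cost zero). maxpair = TRUE switches
// to -1 per pair (structure oracle mode: |energy| = maximum pairing count).
//
// M[i][j]: best energy of subsequence i..j.
// P[i][j]: best energy of i..j given (i,j) paired.
//   P = min( 0 (hairpin closure),
//            stack(p(i,j), p(i+1,j-1)) + P[i+1][j-1],
//            M[i+1][j-1] (interior without a stacking bonus) )
//   M = min( M[i+1][j], min_k { P[i][k] + M[k+1][j] : canPair(i,k) } )
// [[Rcpp::export(name = ".fold_cpp")]]
List fold_cpp(IntegerVector seq, bool maxpair = false) {
  const int n = seq.size();
  const double INF = 1e9;
  if (n == 0) return List::create(_["pairs"] = IntegerVector(0), _["energy"] = 0.0);

  std::vector<double> M((size_t)n * n, 0.0), P((size_t)n * n, INF);
  auto idx = [n](int i, int j) { return (size_t)i * n + j; };

  for (int span = MIN_LOOP + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int pt = pair_type(seq[i], seq[j]);
      if (pt >= 0) {
        double best = maxpair ? 0.0 : HAIRPIN_PEN; // hairpin closure
        if (j - i - 1 > MIN_LOOP + 1) {
          int qt = pair_type(seq[i + 1], seq[j - 1]);
          if (qt >= 0 && P[idx(i + 1, j - 1)] < INF) {
            double e = (maxpair ? 0.0 : STACK[pt][qt]) + P[idx(i + 1, j - 1)];
            if (e < best) best = e;
          }
          double e2 = M[idx(i + 1, j - 1)] + (maxpair ? 0.0 : INTERIOR_PEN);
          if (e2 < best) best = e2;
        }
        if (maxpair) best += -1.0; // unit score for the closing pair itself
        P[idx(i, j)] = best;
      }
      double m = M[idx(i + 1, j)];
      for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
        if (P[idx(i, k)] >= INF) continue;
        double rest = (k + 1 <= j) ? M[idx(k + 1, j)] : 0.0;
        double e = P[idx(i, k)] + rest;
        if (e < m) m = e;
      }
      M[idx(i, j)] = m;
    }
  }

  // traceback (iterative stack of (i, j, in_P))
  IntegerVector partner(n, 0); // 1-based partner, 0 = unpaired
  std::vector<std::array<int, 3>> st;
  if (n > MIN_LOOP + 1) st.push_back({0, n - 1, 0});
  const double EPS = 1e-7;
  while (!st.empty()) {
    auto fr = st.back();
    st.pop_back();
    int i = fr[0], j = fr[1];
    bool inP = fr[2] != 0;
    if (j - i <= MIN_LOOP) continue;
    if (!inP) {
      double m = M[idx(i, j)];
      if (m >= -EPS) continue; // no energy-lowering pairs in here
      if (std::abs(m - M[idx(i + 1, j)]) < EPS) {
        st.push_back({i + 1, j, 0});
        continue;
      }
      bool found = false;
      for (int k = i + MIN_LOOP + 1; k <= j && !found; ++k) {
        if (P[idx(i, k)] >= INF) continue;
        double rest = (k + 1 <= j) ? M[idx(k + 1, j)] : 0.0;
        if (std::abs(m - (P[idx(i, k)] + rest)) < EPS) {
          st.push_back({i, k, 1});
          if (k + 1 <= j) st.push_back({k + 1, j, 0});
          found = true;
        }
      }
      if (!found) continue; // defensive; should not happen
    } else {
      partner[i] = j + 1;
      partner[j] = i + 1;
      double p = P[idx(i, j)];
      int pt = pair_type(seq[i], seq[j]);
      double closing = maxpair ? -1.0 : 0.0;
      if (j - i - 1 > MIN_LOOP + 1) {
        int qt = pair_type(seq[i + 1], seq[j - 1]);
        if (qt >= 0 && P[idx(i + 1, j - 1)] < INF) {
          double e = (maxpair ? 0.0 : STACK[pt][qt]) + P[idx(i + 1, j - 1)] + closing;
          if (std::abs(p - e) < EPS) {
            st.push_back({i + 1, j - 1, 1});
            continue;
          }
        }
        double intpen = maxpair ? 0.0 : INTERIOR_PEN;
        if (std::abs(p - (M[idx(i + 1, j - 1)] + intpen + closing)) < EPS &&
            M[idx(i + 1, j - 1)] < -EPS) {
          st.push_back({i + 1, j - 1, 0});
          continue;
        }
      }
      // hairpin closure: nothing inside
    }
  }

  double energy = M[idx(0, n - 1)];
  if (n <= MIN_LOOP + 1) energy = 0.0;
  return List::create(_["pairs"] = partner, _["energy"] = energy);
}
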