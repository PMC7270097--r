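// Secondary-structure dynamic programming: a Nussinov pair-maximization
// oracle and a Zuker-style minimum-free-energy folder (hairpin, stack,
// bounded internal/bulge loops, affine multibranch). Energies come from a
// simplified nearest-neighbour parameter table loaded in R and passed down
// as flat vectors.

#include <Rcpp.h>
#include <vector>
#include <limits>
#include <stack>
#include <functional>
#include <tuple>
using namespace Rcpp;

static const double INF = 1e9;
static const int MIN_HAIRPIN = 3;   // minimum unpaired bases in a hairpin
static const int MAX_LOOP = 30;     // max unpaired bases in internal/bulge

// base codes: A=0, C=1, G=2, U=3 (T mapped to U upstream); -1 = other
static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size(), -1);
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': v[i] = 0; break;
      case 'C': v[i] = 1; break;
      case 'G': v[i] = 2; break;
      case 'U': case 'T': v[i] = 3; break;
      default: v[i] = -1;
    }
  }
  return v;
}

// pair-type: 0 = not pairable, 1 = GC-type, 2 = AU-type, 3 = GU-type
static int pair_type(int a, int b) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 1;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 3;
  return 0;
}

// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(std::string seq) {
  std::vector<int> s = encode(seq);
  int n = (int)s.size();
  IntegerVector pairv(n, -1);
  if (n == 0) return List::create(_["pairs"] = pairv, _["npairs"] = 0);
  std::vector<std::vector<int>> N((size_t)n, std::vector<int>((size_t)n, 0));
  for (int span = MIN_HAIRPIN + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = N[i][j - 1]; // j unpaired
      for (int k = i; k <= j - MIN_HAIRPIN - 1; ++k) {
        if (pair_type(s[k], s[j]) == 0) continue;
        int val = 1 + (k > i ? N[i][k - 1] : 0) + (k + 1 <= j - 1 ? N[k + 1][j - 1] : 0);
        if (val > best) best = val;
      }
      N[i][j] = best;
    }
  }
  // traceback, preferring the smallest pairing index k
  int npairs = 0;
  std::stack<std::pair<int,int>> st;
  st.push({0, n - 1});
  while (!st.empty()) {
    auto [i, j] = st.top(); st.pop();
    if (i >= j || j - i < MIN_HAIRPIN + 1) continue;
    bool done = false;
    for (int k = i; k <= j - MIN_HAIRPIN - 1 && !done; ++k) {
      if (pair_type(s[k], s[j]) == 0) continue;
      int val = 1 + (k > i ? N[i][k - 1] : 0) + (k + 1 <= j - 1 ? N[k + 1][j - 1] : 0);
      if (val == N[i][j]) {
        pairv[k] = j; pairv[j] = k; ++npairs;
        if (k > i) st.push({i, k - 1});
        st.push({k + 1, j - 1});
        done = true;
      }
    }
    if (!done) st.push({i, j - 1});
  }
  return List::create(_["pairs"] = pairv, _["npairs"] = npairs);
}

struct EnergyParams {
  double stack[4][4];       // by pair types 1..3
  std::vector<double> hairpin; // by loop size (index = size)
  std::vector<double> bulge;
  std::vector<double> internal_;
  double mb_a, mb_b, mb_c;
};

static EnergyParams read_params(List par) {
  EnergyParams p;
  NumericMatrix st = par["stack"]; // 3x3, pair types 1..3
  for (int a = 1; a <= 3; ++a)
    for (int b = 1; b <= 3; ++b)
      p.stack[a][b] = st(a - 1, b - 1);
  p.hairpin = as<std::vector<double>>(par["hairpin"]);
  p.bulge = as<std::vector<double>>(par["bulge"]);
  p.internal_ = as<std::vector<double>>(par["internal"]);
  NumericVector mb = par["multibranch"];
  p.mb_a = mb[0]; p.mb_b = mb[1]; p.mb_c = mb[2];
  return p;
}

static double loop_e(const std::vector<double>& tab, int size) {
  if (size <= 0) return INF;
  if (size < (int)tab.size()) return tab[size];
  return tab.back();
}

// [[Rcpp::export(name = ".zuker_cpp")]]
List zuker_cpp(std::string seq, List par) {
  EnergyParams P = read_params(par);
  std::vector<int> s = encode(seq);
  int n = (int)s.size();
  IntegerVector pairv(n, -1);
  if (n < MIN_HAIRPIN + 2)
    return List::create(_["pairs"] = pairv, _["energy"] = 0.0);

  std::vector<std::vector<double>> V((size_t)n, std::vector<double>((size_t)n, INF));
  std::vector<std::vector<double>> WM((size_t)n, std::vector<double>((size_t)n, INF));

  for (int span = MIN_HAIRPIN + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int pt_ij = pair_type(s[i], s[j]);
      if (pt_ij != 0) {
        double best = loop_e(P.hairpin, j - i - 1); // hairpin closure
        // stack / internal / bulge to inner pair (k, l)
        int kmax = std::min(i + MAX_LOOP + 1, j - MIN_HAIRPIN - 2);
        for (int k = i + 1; k <= kmax; ++k) {
          int lmin = std::max(k + MIN_HAIRPIN + 1, j - 1 - (MAX_LOOP - (k - i - 1)));
          for (int l = lmin; l <= j - 1; ++l) {
            int pt_kl = pair_type(s[k], s[l]);
            if (pt_kl == 0) continue;
            if (V[k][l] >= INF) continue;
            int u1 = k - i - 1, u2 = j - l - 1;
            double e;
            if (u1 == 0 && u2 == 0) e = P.stack[pt_ij][pt_kl];
            else if (u1 == 0 || u2 == 0) e = loop_e(P.bulge, u1 + u2);
            else e = loop_e(P.internal_, u1 + u2);
            double val = e + V[k][l];
            if (val < best) best = val;
          }
        }
        // multibranch closure: >= 2 branches inside
        for (int k = i + 2; k <= j - 2; ++k) {
          if (WM[i + 1][k - 1] >= INF || WM[k][j - 1] >= INF) continue;
          double val = P.mb_a + P.mb_b + WM[i + 1][k - 1] + WM[k][j - 1];
          if (val < best) best = val;
        }
        V[i][j] = best;
      }
      // WM: segment with >= 1 branch inside a multiloop
      double wbest = INF;
      if (V[i][j] < INF) wbest = V[i][j] + P.mb_b;
      if (i + 1 <= j && WM[i + 1][j] < INF) wbest = std::min(wbest, WM[i + 1][j] + P.mb_c);
      if (j - 1 >= i && WM[i][j - 1] < INF) wbest = std::min(wbest, WM[i][j - 1] + P.mb_c);
      for (int k = i + 1; k <= j; ++k) {
        if (WM[i][k - 1] >= INF || WM[k][j] >= INF) continue;
        wbest = std::min(wbest, WM[i][k - 1] + WM[k][j]);
      }
      WM[i][j] = wbest;
    }
  }

  // external loop
  std::vector<double> W((size_t)n + 1, 0.0);
  for (int j = 1; j <= n; ++j) {
    double best = W[j - 1];
    for (int i = 1; i <= j; ++i) {
      double v = V[i - 1][j - 1];
      if (v >= INF) continue;
      double val = W[i - 1] + v;
      if (val < best) best = val;
    }
    W[j] = best;
  }
  double emin = std::min(W[n], 0.0);

  const double EPS = 1e-6;
  // traceback
  if (emin < 0) {
    std::stack<std::tuple<int,int,int>> st; // (i, j, mode) mode 0=V,1=WM
    // external
    {
      int j = n;
      while (j >= 1) {
        if (std::abs(W[j] - W[j - 1]) < EPS) { --j; continue; }
        bool found = false;
        for (int i = 1; i <= j && !found; ++i) {
          double v = V[i - 1][j - 1];
          if (v >= INF) continue;
          if (std::abs(W[j] - (W[i - 1] + v)) < EPS) {
            st.push({i - 1, j - 1, 0});
            j = i - 1;
            found = true;
          }
        }
        if (!found) --j;
      }
    }
    while (!st.empty()) {
      auto [i, j, mode] = st.top(); st.pop();
      if (mode == 0) {
        pairv[i] = j; pairv[j] = i;
        int pt_ij = pair_type(s[i], s[j]);
        double target = V[i][j];
        if (std::abs(target - loop_e(P.hairpin, j - i - 1)) < EPS) continue;
        bool found = false;
        int kmax = std::min(i + MAX_LOOP + 1, j - MIN_HAIRPIN - 2);
        for (int k = i + 1; k <= kmax && !found; ++k) {
          int lmin = std::max(k + MIN_HAIRPIN + 1, j - 1 - (MAX_LOOP - (k - i - 1)));
          for (int l = lmin; l <= j - 1 && !found; ++l) {
            int pt_kl = pair_type(s[k], s[l]);
            if (pt_kl == 0 || V[k][l] >= INF) continue;
            int u1 = k - i - 1, u2 = j - l - 1;
            double e;
            if (u1 == 0 && u2 == 0) e = P.stack[pt_ij][pt_kl];
            else if (u1 == 0 || u2 == 0) e = loop_e(P.bulge, u1 + u2);
            else e = loop_e(P.internal_, u1 + u2);
            if (std::abs(target - (e + V[k][l])) < EPS) {
              st.push({k, l, 0});
              found = true;
            }
          }
        }
        if (found) continue;
        for (int k = i + 2; k <= j - 2 && !found; ++k) {
          if (WM[i + 1][k - 1] >= INF || WM[k][j - 1] >= INF) continue;
          if (std::abs(target - (P.mb_a + P.mb_b + WM[i + 1][k - 1] + WM[k][j - 1])) < EPS) {
            st.push({i + 1, k - 1, 1});
            st.push({k, j - 1, 1});
            found = true;
          }
        }
      } else { // WM
        double target = WM[i][j];
        if (target >= INF) continue;
        if (V[i][j] < INF && std::abs(target - (V[i][j] + P.mb_b)) < EPS) {
          st.push({i, j, 0});
          continue;
        }
        if (i + 1 <= j && WM[i + 1][j] < INF &&
            std::abs(target - (WM[i + 1][j] + P.mb_c)) < EPS) {
          st.push({i + 1, j, 1});
          continue;
        }
        if (j - 1 >= i && WM[i][j - 1] < INF &&
            std::abs(target - (WM[i][j - 1] + P.mb_c)) < EPS) {
          st.push({i, j - 1, 1});
          continue;
        }
        bool found = false;
        for (int k = i + 1; k <= j && !found; ++k) {
          if (WM[i][k - 1] >= INF || WM[k][j] >= INF) continue;
          if (std::abs(target - (WM[i][k - 1] + WM[k][j])) < EPS) {
            st.push({i, k - 1, 1});
            st.push({k, j, 1});
            found = true;
          }
        }
      }
    }
  }
  return List::create(_["pairs"] = pairv, _["energy"] = emin);
}

// score an arbitrary non-crossing pairing under the same loop decomposition
// (used by tests to bound the MFE from above)
// [[Rcpp::export(name = ".score_structure_cpp")]]
double score_structure_cpp(std::string seq, IntegerVector pairs0, List par) {
  EnergyParams P = read_params(par);
  std::vector<int> s = encode(seq);
  int n = (int)s.size();
  std::vector<int> pr(pairs0.begin(), pairs0.end());
  // recursive scoring of loops closed by each outer pair
  std::function<double(int,int)> score_v = [&](int i, int j) -> double {
    // children: maximal pairs directly inside (i, j)
    std::vector<std::pair<int,int>> kids;
    int unpaired = 0;
    int k = i + 1;
    while (k < j) {
      if (pr[k] > k && pr[k] < j) { kids.push_back({k, pr[k]}); k = pr[k] + 1; }
      else { ++unpaired; ++k; }
    }
    double e;
    if (kids.empty()) {
      e = loop_e(P.hairpin, j - i - 1);
    } else if (kids.size() == 1) {
      int u1 = kids[0].first - i - 1, u2 = j - kids[0].second - 1;
      int pt_ij = pair_type(s[i], s[j]), pt_kl = pair_type(s[kids[0].first], s[kids[0].second]);
      if (pt_ij == 0 || pt_kl == 0) return INF;
      if (u1 == 0 && u2 == 0) e = P.stack[pt_ij][pt_kl];
      else if (u1 == 0 || u2 == 0) e = loop_e(P.bulge, u1 + u2);
      else e = loop_e(P.internal_, u1 + u2);
    } else {
      e = P.mb_a + P.mb_b * (1 + (double)kids.size()) + P.mb_c * unpaired;
    }
    for (auto& kd : kids) e += score_v(kd.first, kd.second);
    return e;
  };
  double total = 0.0;
  int k = 0;
  while (k < n) {
    if (pr[k] > k) {
      if (pair_type(s[k], s[pr[k]]) == 0) return NA_REAL;
      total += score_v(k, pr[k]);
      k = pr[k] + 1;
    } else ++k;
  }
  return total;
}
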