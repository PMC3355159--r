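#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact mean Canberra distance over all pairs of completions of two
// partial lists. r1, r2: length-p vectors giving each feature's rank in
// the respective list, 0 when unlisted. The unlisted features of list k
// are assigned to the bottom positions l_k+1..p in every possible order
// (std::next_permutation over the sorted index vector), and the plain
// Canberra distance between the two full rank vectors is averaged.
// Caller enforces the pair cap.
// [[Rcpp::export]]
double cpp_bruteforce_mean(IntegerVector r1, IntegerVector r2) {
  const int p = r1.size();
  std::vector<int> R1(p), R2(p), m1, m2;
  for (int f = 0; f < p; ++f) {
    R1[f] = r1[f];
    R2[f] = r2[f];
    if (r1[f] == 0) m1.push_back(f);
    if (r2[f] == 0) m2.push_back(f);
  }
  const int l1 = p - (int)m1.size(), l2 = p - (int)m2.size();
  double total = 0.0;
  long long count = 0;
  std::sort(m1.begin(), m1.end());
  std::vector<int> perm1 = m1;
  do {
    for (size_t t = 0; t < perm1.size(); ++t) R1[perm1[t]] = l1 + 1 + (int)t;
    std::vector<int> perm2 = m2;
    do {
      for (size_t t = 0; t < perm2.size(); ++t) R2[perm2[t]] = l2 + 1 + (int)t;
      double d = 0.0;
      for (int f = 0; f < p; ++f)
        d += std::abs((double)(R1[f] - R2[f])) / (double)(R1[f] + R2[f]);
      total += d;
      ++count;
    } while (std::next_permutation(perm2.begin(), perm2.end()));
  } while (std::next_permutation(perm1.begin(), perm1.end()));
  return total / (double)count;
}

// Exhaustive search for a permutation of 1..l maximizing the Canberra
// distance to the identity. Plain lexicographic enumeration; l <= 10
// (10! = 3.6e6 permutations) is enforced by the R wrapper.
// [[Rcpp::export]]
List cpp_max_canberra_perm(int l) {
  std::vector<int> perm(l), best(l);
  for (int i = 0; i < l; ++i) perm[i] = i + 1;
  best = perm;
  double bestd = 0.0;
  do {
    double d = 0.0;
    for (int i = 0; i < l; ++i)
      d += std::abs((double)(perm[i] - (i + 1))) / (double)(perm[i] + i + 1);
    if (d > bestd) {
      bestd = d;
      best = perm;
    }
  } while (std::next_permutation(perm.begin(), perm.end()));
  return List::create(_["perm"] = IntegerVector(best.begin(), best.end()),
                      _["distance"] = bestd);
}
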