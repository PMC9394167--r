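#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>
using namespace Rcpp;

// Optimal-string-alignment ("restricted Damerau-Levenshtein") distance:
// substitutions, insertions, deletions and adjacent transpositions, unit
// cost, no substring edited twice. `cap` allows early abandoning: any
// return value > cap only guarantees the true distance exceeds cap.
static int osa_core(const std::string& a, const std::string& b, int cap) {
  const int n = (int)a.size(), m = (int)b.size();
  if (std::abs(n - m) > cap) return cap + 1;
  if (n == 0) return m;
  if (m == 0) return n;
  // three rolling rows: i-2, i-1, i
  std::vector<int> r0(m + 1), r1(m + 1), r2(m + 1);
  for (int j = 0; j <= m; ++j) r1[j] = j;
  for (int i = 1; i <= n; ++i) {
    r2[0] = i;
    int rowmin = r2[0];
    for (int j = 1; j <= m; ++j) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int v = std::min(std::min(r2[j - 1] + 1, r1[j] + 1), r1[j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        v = std::min(v, r0[j - 2] + 1);
      r2[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (rowmin > cap) return cap + 1;
    std::swap(r0, r1);
    std::swap(r1, r2);
  }
  return r1[m];
}

// [[Rcpp::export(name = ".osa_distance_cpp")]]
IntegerVector osa_distance_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = std::max(a.size(), b.size());
  if (a.size() != n && a.size() != 1) stop("lengths of a and b must match or be 1");
  if (b.size() != n && b.size() != 1) stop("lengths of a and b must match or be 1");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(a[a.size() == 1 ? 0 : i]) ||
        CharacterVector::is_na(b[b.size() == 1 ? 0 : i])) {
      out[i] = NA_INTEGER;
      continue;
    }
    std::string sa = as<std::string>(a[a.size() == 1 ? 0 : i]);
    std::string sb = as<std::string>(b[b.size() == 1 ? 0 : i]);
    out[i] = osa_core(sa, sb, INT_MAX - 1);
  }
  return out;
}

// Pairwise distance matrix with early abandon above `cap` (entries then
// reported as cap + 1). Used for family grouping on small selected sets.
// [[Rcpp::export(name = ".osa_distmat_cpp")]]
IntegerMatrix osa_distmat_cpp(CharacterVector seqs, int cap) {
  int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  IntegerMatrix d(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int v = osa_core(s[i], s[j], cap);
      d(i, j) = v;
      d(j, i) = v;
    }
  return d;
}

// Greedy centroid clustering. `seqs` must already be sorted by priority
// (descending total count, ties lexicographic). Each sequence joins the
// FIRST existing centroid (in creation order) within max_dist, otherwise
// founds a new centroid. Returns the 1-based index (into seqs) of each
// sequence's centroid.
// [[Rcpp::export(name = ".greedy_cluster_cpp")]]
IntegerVector greedy_cluster_cpp(CharacterVector seqs, int max_dist) {
  int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  IntegerVector assign(n);
  std::vector<int> centroids;
  centroids.reserve(n);
  for (int i = 0; i < n; ++i) {
    int hit = -1;
    for (size_t c = 0; c < centroids.size(); ++c) {
      if (osa_core(s[centroids[c]], s[i], max_dist) <= max_dist) {
        hit = centroids[c];
        break;
      }
    }
    if (hit < 0) {
      centroids.push_back(i);
      hit = i;
    }
    assign[i] = hit + 1;
  }
  return assign;
}

// Merge a read pair. r2rc is read2 already reverse-complemented; offsets
// place r2rc at position s (0-based) relative to r1. Candidate offsets
// need overlap >= min_overlap; the offset minimising mismatches wins, ties
// broken toward larger overlap. Overlap conflicts are resolved toward the
// base with higher quality (tie -> read1). Returns NA_STRING on reject.
static String join_one(const std::string& r1, const std::string& r2,
                       const std::string& q1, const std::string& q2,
                       int min_overlap, double max_mismatch_frac) {
  const int n1 = (int)r1.size(), n2 = (int)r2.size();
  if (n1 == 0 || n2 == 0) return NA_STRING;
  int best_s = -1, best_mm = INT_MAX, best_ov = -1;
  const int max_s = n1 - min_overlap;
  for (int s = 0; s <= max_s; ++s) {
    int ov = std::min(n1 - s, n2);
    if (ov < min_overlap) continue;
    int mm = 0;
    for (int k = 0; k < ov; ++k)
      if (r1[s + k] != r2[k]) ++mm;
    if (mm < best_mm || (mm == best_mm && ov > best_ov)) {
      best_mm = mm;
      best_ov = ov;
      best_s = s;
    }
  }
  if (best_s < 0) return NA_STRING;
  if ((double)best_mm / (double)best_ov > max_mismatch_frac) return NA_STRING;
  std::string out = r1.substr(0, best_s);
  for (int k = 0; k < best_ov; ++k) {
    char b1 = r1[best_s + k], b2 = r2[k];
    if (b1 == b2) {
      out.push_back(b1);
    } else {
      char ch = b1;  // tie toward read1
      if (!q1.empty() && !q2.empty() && q2[k] > q1[best_s + k]) ch = b2;
      out.push_back(ch);
    }
  }
  if (n2 > best_ov) out += r2.substr(best_ov);
  return String(out);
}

// [[Rcpp::export(name = ".join_pairs_cpp")]]
CharacterVector join_pairs_cpp(CharacterVector r1, CharacterVector r2rc,
                               CharacterVector q1, CharacterVector q2rev,
                               int min_overlap, double max_mismatch_frac) {
  R_xlen_t n = r1.size();
  if (r2rc.size() != n) stop("r1 and r2rc must have equal length");
  bool have_q = q1.size() == n && q2rev.size() == n;
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(r1[i]);
    std::string s2 = as<std::string>(r2rc[i]);
    std::string a1 = have_q ? as<std::string>(q1[i]) : std::string();
    std::string a2 = have_q ? as<std::string>(q2rev[i]) : std::string();
    out[i] = join_one(s1, s2, a1, a2, min_overlap, max_mismatch_frac);
  }
  return out;
}
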