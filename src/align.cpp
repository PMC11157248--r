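#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Encoding: A,C,G,T -> 0..3, anything else (incl. N) -> 4.
// Code 4 never matches, so assembly N-runs accumulate mismatch cost and
// candidate monomers spanning them fall above the divergence threshold.
static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = enc(s[i]);
  return v;
}

// Plain two-row Levenshtein DP (unit costs).
static int edit_distance_enc(const std::vector<int>& a, const std::vector<int>& b) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0) return m;
  if (m == 0) return n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    const int ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int best = prev[j - 1] + ((ai == b[j - 1] && ai != 4) ? 0 : 1);
      const int del = prev[j] + 1;
      if (del < best) best = del;
      const int ins = cur[j - 1] + 1;
      if (ins < best) best = ins;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

//' @noRd
// [[Rcpp::export(name = ".edit_distance_cpp")]]
int edit_distance_cpp(std::string a, std::string b) {
  std::vector<int> ea = encode(a), eb = encode(b);
  return edit_distance_enc(ea, eb);
}

// All-vs-all raw edit distances (symmetric integer matrix).
// [[Rcpp::export(name = ".edit_distance_matrix_cpp")]]
IntegerMatrix edit_distance_matrix_cpp(CharacterVector seqs) {
  const int n = seqs.size();
  std::vector<std::vector<int> > enc_seqs(n);
  for (int i = 0; i < n; ++i) enc_seqs[i] = encode(as<std::string>(seqs[i]));
  IntegerMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const int d = edit_distance_enc(enc_seqs[i], enc_seqs[j]);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}

// Raw edit distance of each sequence against one reference.
// [[Rcpp::export(name = ".edit_distance_to_ref_cpp")]]
IntegerVector edit_distance_to_ref_cpp(CharacterVector seqs, std::string ref) {
  const int n = seqs.size();
  std::vector<int> eref = encode(ref);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = edit_distance_enc(encode(as<std::string>(seqs[i])), eref);
  return out;
}

// Globally align `member` to `anchor` with unit costs and project the
// member onto anchor coordinates: returns a string of anchor length where
// position i holds the member base aligned to anchor base i ('-' for a
// deletion in the member; member insertions are dropped). Traceback prefers
// diagonal, then anchor-gap, then member-gap moves, deterministically.
// [[Rcpp::export(name = ".project_onto_anchor_cpp")]]
std::string project_onto_anchor_cpp(std::string member, std::string anchor) {
  const std::vector<int> A = encode(anchor), B = encode(member);
  const int n = (int)A.size(), m = (int)B.size();
  std::vector<int> D((n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) D[j] = j;
  for (int i = 1; i <= n; ++i) {
    D[i * (m + 1)] = i;
    for (int j = 1; j <= m; ++j) {
      int best = D[(i - 1) * (m + 1) + j - 1] +
        ((A[i - 1] == B[j - 1] && A[i - 1] != 4) ? 0 : 1);
      const int up = D[(i - 1) * (m + 1) + j] + 1;
      if (up < best) best = up;
      const int left = D[i * (m + 1) + j - 1] + 1;
      if (left < best) best = left;
      D[i * (m + 1) + j] = best;
    }
  }
  std::string out(n, '-');
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int cur = D[i * (m + 1) + j];
    if (i > 0 && j > 0 &&
        cur == D[(i - 1) * (m + 1) + j - 1] +
          ((A[i - 1] == B[j - 1] && A[i - 1] != 4) ? 0 : 1)) {
      out[i - 1] = member[j - 1];
      --i; --j;
    } else if (i > 0 && cur == D[(i - 1) * (m + 1) + j] + 1) {
      out[i - 1] = '-';
      --i;
    } else {
      --j;  // insertion relative to the anchor: dropped
    }
  }
  return out;
}

// Semi-global scan of query against subject on one strand.
//
// Forward pass: D[j] = min edit distance of the full query against some
// subject substring ending at position j (free start in the subject).
// Candidate ends are local minima of D at or below floor(max_div * max_len)
// (normalizing denominator is max(query length, match length) <= max_len, so
// this is the loosest raw bound an acceptable match can attain).
// For each candidate end a reverse DP recovers the edit distance for every
// admissible match length; up to `per_end` (divergence, then longest-match)
// best candidates per end are reported. Final greedy non-overlap selection is
// done by the caller across both strands.
//
// Returns a data.frame: start (0-based), end (exclusive), ed, div.
// [[Rcpp::export(name = ".scan_candidates_cpp")]]
DataFrame scan_candidates_cpp(std::string subject, std::string query,
                              double max_div, int min_len, int max_len,
                              int per_end) {
  const std::vector<int> S = encode(subject);
  const std::vector<int> Q = encode(query);
  const int n = (int)S.size(), m = (int)Q.size();
  std::vector<int> out_start, out_end, out_ed;
  std::vector<double> out_div;

  if (n == 0 || m == 0) {
    return DataFrame::create(_["start"] = IntegerVector(0),
                             _["end"] = IntegerVector(0),
                             _["ed"] = IntegerVector(0),
                             _["div"] = NumericVector(0));
  }

  const int raw_thresh = (int)std::floor(max_div * (double)std::max(m, max_len));

  // forward semi-global pass, record end scores
  std::vector<int> endsc(n + 1);
  {
    std::vector<int> prev(m + 1), cur(m + 1);
    for (int i = 0; i <= m; ++i) prev[i] = i;  // empty subject prefix
    endsc[0] = prev[m];
    for (int j = 1; j <= n; ++j) {
      cur[0] = 0;  // free start in subject
      const int sj = S[j - 1];
      for (int i = 1; i <= m; ++i) {
        int best = prev[i - 1] + ((Q[i - 1] == sj && sj != 4) ? 0 : 1);
        const int del = cur[i - 1] + 1;   // consume query char (gap in subject)
        if (del < best) best = del;
        const int ins = prev[i] + 1;      // consume subject char (gap in query)
        if (ins < best) best = ins;
        cur[i] = best;
      }
      endsc[j] = cur[m];
      std::swap(prev, cur);
    }
  }

  // candidate ends: local minima (rightmost point of a plateau) under threshold
  std::vector<int> cand_ends;
  for (int j = 1; j <= n; ++j) {
    if (endsc[j] > raw_thresh) continue;
    const bool left_ok = endsc[j] <= endsc[j - 1];
    const bool right_ok = (j == n) || (endsc[j] < endsc[j + 1]);
    if (left_ok && right_ok) cand_ends.push_back(j);
  }

  // reversed query, reused across candidate ends
  std::vector<int> RQ(Q.rbegin(), Q.rend());
  std::vector<int> prev(m + 1), cur(m + 1);

  for (size_t c = 0; c < cand_ends.size(); ++c) {
    const int e = cand_ends[c];
    const int L = std::min(max_len, e);
    if (L < min_len) continue;
    // ed_len[len] = edit distance of query vs subject[e-len .. e-1]
    std::vector<int> ed_len(L + 1);
    for (int i = 0; i <= m; ++i) prev[i] = i;
    ed_len[0] = m;
    for (int j = 1; j <= L; ++j) {
      cur[0] = j;
      const int sj = S[e - j];  // reversed window char
      for (int i = 1; i <= m; ++i) {
        int best = prev[i - 1] + ((RQ[i - 1] == sj && sj != 4) ? 0 : 1);
        const int del = cur[i - 1] + 1;
        if (del < best) best = del;
        const int ins = prev[i] + 1;
        if (ins < best) best = ins;
        cur[i] = best;
      }
      ed_len[j] = cur[m];
      std::swap(prev, cur);
    }
    // admissible lengths ranked by raw edit distance, then by closeness to
    // the query length (avoids the length bias a normalized score would
    // give to windows bleeding into a neighbouring monomer)
    std::vector<std::pair<std::pair<int, int>, int> > opts;
    for (int len = min_len; len <= L; ++len) {
      const double dv = (double)ed_len[len] / (double)std::max(m, len);
      if (dv <= max_div) {
        opts.push_back(std::make_pair(
          std::make_pair(ed_len[len], std::abs(len - m)), len));
      }
    }
    std::sort(opts.begin(), opts.end());
    const int keep = std::min((int)opts.size(), per_end);
    for (int k = 0; k < keep; ++k) {
      const int len = opts[k].second;
      out_start.push_back(e - len);
      out_end.push_back(e);
      out_ed.push_back(ed_len[len]);
      out_div.push_back((double)ed_len[len] / (double)std::max(m, len));
    }
  }

  return DataFrame::create(_["start"] = wrap(out_start),
                           _["end"] = wrap(out_end),
                           _["ed"] = wrap(out_ed),
                           _["div"] = wrap(out_div));
}
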