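#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
int cpp_lcp(const std::string& a, const std::string& b) {
  size_t n = std::min(a.size(), b.size());
  size_t i = 0;
  while (i < n && a[i] == b[i]) ++i;
  return (int)i;
}

// [[Rcpp::export]]
int cpp_lcs(const std::string& a, const std::string& b) {
  size_t n = std::min(a.size(), b.size());
  size_t i = 0;
  while (i < n && a[a.size() - 1 - i] == b[b.size() - 1 - i]) ++i;
  return (int)i;
}

// Longest prefix of min(|a|,|b|) whose mismatch count stays within
// floor(rate * L); the prefix must end on a match so trailing noise is
// never absorbed. Returns c(length, mismatches).
// [[Rcpp::export]]
IntegerVector cpp_extend_prefix(const std::string& a, const std::string& b,
                                double max_mm_rate) {
  size_t n = std::min(a.size(), b.size());
  int best_len = 0, best_mm = 0, mm = 0;
  for (size_t i = 0; i < n; ++i) {
    if (a[i] != b[i]) ++mm;
    else if (mm <= max_mm_rate * (double)(i + 1)) {
      best_len = (int)(i + 1);
      best_mm = mm;
    }
  }
  return IntegerVector::create(best_len, best_mm);
}

// Greedy gapless extension: advance through matches; accept a mismatch only
// when the next `min_rematch` bases all match (so extension never bleeds
// through a breakpoint junction on lucky isolated matches) and the running
// mismatch count stays within ceil(rate * length). Returns c(length,
// mismatches); length ends on a match.
// [[Rcpp::export]]
IntegerVector cpp_extend_greedy(const std::string& a, const std::string& b,
                                double max_mm_rate, int min_rematch) {
  size_t n = std::min(a.size(), b.size());
  size_t i = 0; int mm = 0; size_t last_good = 0;
  while (i < n) {
    if (a[i] == b[i]) { ++i; last_good = i; continue; }
    if ((double)(mm + 1) > std::ceil(max_mm_rate * (double)(i + 1))) break;
    bool ok = (i + (size_t)min_rematch < n);
    for (int t = 1; ok && t <= min_rematch; ++t)
      if (a[i + t] != b[i + t]) ok = false;
    if (!ok) break;
    ++mm; ++i;
  }
  // mismatches actually inside the reported prefix
  int mm_in = 0;
  for (size_t j = 0; j < last_good; ++j) if (a[j] != b[j]) ++mm_in;
  return IntegerVector::create((int)last_good, mm_in);
}

// Mirror of cpp_extend_greedy anchored at the string ends, comparing
// backwards from the last characters.
// [[Rcpp::export]]
IntegerVector cpp_extend_greedy_rev(const std::string& a, const std::string& b,
                                    double max_mm_rate, int min_rematch) {
  size_t na = a.size(), nb = b.size();
  size_t n = std::min(na, nb);
  size_t i = 0; int mm = 0; size_t last_good = 0;
  while (i < n) {
    if (a[na - 1 - i] == b[nb - 1 - i]) { ++i; last_good = i; continue; }
    if ((double)(mm + 1) > std::ceil(max_mm_rate * (double)(i + 1))) break;
    bool ok = (i + (size_t)min_rematch < n);
    for (int t = 1; ok && t <= min_rematch; ++t)
      if (a[na - 1 - i - t] != b[nb - 1 - i - t]) ok = false;
    if (!ok) break;
    ++mm; ++i;
  }
  int mm_in = 0;
  for (size_t j = 0; j < last_good; ++j)
    if (a[na - 1 - j] != b[nb - 1 - j]) ++mm_in;
  return IntegerVector::create((int)last_good, mm_in);
}

// Per diagonal of the a-vs-b comparison matrix, the longest ungapped window
// with identity >= min_identity and length >= min_len. Integer scoring
// (matches*10000 >= length*round(min_identity*10000)) keeps the threshold
// exact. 1-based starts in the output.
// [[Rcpp::export]]
DataFrame cpp_diag_hits(const std::string& a, const std::string& b,
                        int min_len, double min_identity) {
  int na = (int)a.size(), nb = (int)b.size();
  long num = (long)(min_identity * 10000.0 + 0.5);
  std::vector<int> a_start, b_start, len_v, match_v;
  for (int d = -(na - 1); d <= nb - 1; ++d) {
    int ia = d < 0 ? -d : 0;          // 0-based start in a
    int ib = d < 0 ? 0 : d;           // 0-based start in b
    int m = std::min(na - ia, nb - ib);
    if (m < min_len) continue;
    // prefix sums: S_j = 10000*matches_j - num*j ; want max j-i with S_j>=S_i
    std::vector<long> S(m + 1);
    std::vector<int> M(m + 1);
    S[0] = 0; M[0] = 0;
    for (int j = 0; j < m; ++j) {
      int mt = (a[ia + j] == b[ib + j]) ? 1 : 0;
      M[j + 1] = M[j] + mt;
      S[j + 1] = S[j] + 10000L * mt - num;
    }
    // monotone stack of strictly decreasing prefix values
    std::vector<int> st;
    for (int i = 0; i <= m; ++i)
      if (st.empty() || S[st.back()] > S[i]) st.push_back(i);
    int best_i = -1, best_j = -1, width = 0;
    for (int j = m; j >= 0; --j) {
      while (!st.empty() && S[st.back()] <= S[j]) {
        int i = st.back(); st.pop_back();
        if (j - i > width) { width = j - i; best_i = i; best_j = j; }
      }
    }
    if (width >= min_len) {
      a_start.push_back(ia + best_i + 1);
      b_start.push_back(ib + best_i + 1);
      len_v.push_back(width);
      match_v.push_back(M[best_j] - M[best_i]);
    }
  }
  return DataFrame::create(_["a_start"] = a_start, _["b_start"] = b_start,
                           _["length"] = len_v, _["matches"] = match_v);
}

// All maximal exact matches of length >= min_len between a and b
// (runs of identity along diagonals). 1-based starts.
// [[Rcpp::export]]
DataFrame cpp_mem_hits(const std::string& a, const std::string& b, int min_len) {
  int na = (int)a.size(), nb = (int)b.size();
  std::vector<int> a_start, b_start, len_v;
  for (int d = -(na - 1); d <= nb - 1; ++d) {
    int ia = d < 0 ? -d : 0;
    int ib = d < 0 ? 0 : d;
    int m = std::min(na - ia, nb - ib);
    int run = 0;
    for (int j = 0; j <= m; ++j) {
      bool mt = (j < m) && (a[ia + j] == b[ib + j]);
      if (mt) ++run;
      else {
        if (run >= min_len) {
          a_start.push_back(ia + j - run + 1);
          b_start.push_back(ib + j - run + 1);
          len_v.push_back(run);
        }
        run = 0;
      }
    }
  }
  return DataFrame::create(_["a_start"] = a_start, _["b_start"] = b_start,
                           _["length"] = len_v);
}

static inline bool is_purine(char c) { return c == 'A' || c == 'G'; }

static void merge_push(std::vector<std::pair<int,int> >& iv,
                       std::vector<int>& s_out, std::vector<int>& e_out) {
  if (iv.empty()) return;
  std::sort(iv.begin(), iv.end());
  int cs = iv[0].first, ce = iv[0].second;
  for (size_t i = 1; i < iv.size(); ++i) {
    if (iv[i].first <= ce) ce = std::max(ce, iv[i].second);
    else { s_out.push_back(cs); e_out.push_back(ce); cs = iv[i].first; ce = iv[i].second; }
  }
  s_out.push_back(cs); e_out.push_back(ce);
}

// G-run list (maximal runs of `g` of length >= min_run); consecutive
// quadruples with loop gaps in [1, max_loop] define quadruplex candidates.
static void g4_candidates(const std::string& s, char g, int min_run, int max_loop,
                          std::vector<std::pair<int,int> >& out) {
  int n = (int)s.size();
  std::vector<int> rs, re; // 0-based run [rs, re]
  int i = 0;
  while (i < n) {
    if (s[i] == g) {
      int j = i;
      while (j < n && s[j] == g) ++j;
      if (j - i >= min_run) { rs.push_back(i); re.push_back(j - 1); }
      i = j;
    } else ++i;
  }
  int R = (int)rs.size();
  for (int q = 0; q + 3 < R; ++q) {
    bool ok = true;
    for (int t = 0; t < 3; ++t) {
      int gap = rs[q + t + 1] - re[q + t] - 1;
      if (gap < 1 || gap > max_loop) { ok = false; break; }
    }
    if (ok) out.push_back(std::make_pair(rs[q] + 1, re[q + 3] + 1)); // 1-based
  }
}

// Non-B DNA motif scan over a vector of sequences. Classes (all optional):
//  ZDNA : maximal alternating purine/pyrimidine tract with no A-T steps,
//         length >= min_z
//  G4   : four G-runs (>= min_grun) with loops of 1..max_loop, either strand
//  IR   : perfect inverted-repeat arms >= min_arm, spacer <= max_spacer
//  MR   : perfect mirror-repeat arms >= min_arm, spacer <= max_spacer
//  DR   : perfect direct repeat, unit >= min_unit, spacer <= max_spacer
// Overlapping candidates of a class (and strand) are merged to maximal
// intervals. Returns 1-based closed intervals.
// [[Rcpp::export]]
DataFrame cpp_scan_nonb(const StringVector& seqs,
                        int min_z, int min_grun, int max_loop,
                        int min_arm, int max_spacer, int min_unit,
                        bool do_z, bool do_g4, bool do_ir, bool do_mr,
                        bool do_dr) {
  std::vector<int> seq_idx, start_v, end_v;
  std::vector<std::string> class_v, strand_v;
  for (int si = 0; si < seqs.size(); ++si) {
    std::string s = as<std::string>(seqs[si]);
    int n = (int)s.size();

    if (do_z) {
      std::vector<std::pair<int,int> > cand;
      int run = 1; // tract length ending at i
      for (int i = 1; i <= n; ++i) {
        bool step_ok = false;
        if (i < n) {
          char a = s[i - 1], b = s[i];
          step_ok = (is_purine(a) != is_purine(b)) &&
                    !((a == 'A' && b == 'T') || (a == 'T' && b == 'A'));
        }
        if (step_ok) ++run;
        else {
          if (run >= min_z) cand.push_back(std::make_pair(i - run + 1, i));
          run = 1;
        }
      }
      std::vector<int> ms, me; merge_push(cand, ms, me);
      for (size_t k = 0; k < ms.size(); ++k) {
        seq_idx.push_back(si + 1); class_v.push_back("ZDNA");
        start_v.push_back(ms[k]); end_v.push_back(me[k]); strand_v.push_back("*");
      }
    }

    if (do_g4) {
      const char strands[2] = {'G', 'C'};
      for (int w = 0; w < 2; ++w) {
        std::vector<std::pair<int,int> > cand;
        g4_candidates(s, strands[w], min_grun, max_loop, cand);
        std::vector<int> ms, me; merge_push(cand, ms, me);
        for (size_t k = 0; k < ms.size(); ++k) {
          seq_idx.push_back(si + 1); class_v.push_back("G4");
          start_v.push_back(ms[k]); end_v.push_back(me[k]);
          strand_v.push_back(w == 0 ? "+" : "-");
        }
      }
    }

    if (do_ir || do_mr) {
      for (int mode = 0; mode < 2; ++mode) {
        if ((mode == 0 && !do_ir) || (mode == 1 && !do_mr)) continue;
        std::vector<std::pair<int,int> > cand;
        for (int sp = 0; sp <= max_spacer; ++sp) {
          for (int e = 0; e < n; ++e) {       // 0-based end of left arm
            int r = e + sp + 1;               // 0-based start of right arm
            if (r >= n) break;
            int t = 0;
            while (e - t >= 0 && r + t < n) {
              char l = s[e - t], rr = s[r + t];
              bool mt;
              if (mode == 0) { // inverted: complement match
                mt = (l == 'A' && rr == 'T') || (l == 'T' && rr == 'A') ||
                     (l == 'C' && rr == 'G') || (l == 'G' && rr == 'C');
              } else {         // mirror: identity match
                mt = (l == rr);
              }
              if (!mt) break;
              ++t;
            }
            if (t >= min_arm)
              cand.push_back(std::make_pair(e - t + 2, r + t)); // 1-based
          }
        }
        std::vector<int> ms, me; merge_push(cand, ms, me);
        for (size_t k = 0; k < ms.size(); ++k) {
          seq_idx.push_back(si + 1);
          class_v.push_back(mode == 0 ? "INVERTED_REPEAT" : "MIRROR_REPEAT");
          start_v.push_back(ms[k]); end_v.push_back(me[k]); strand_v.push_back("*");
        }
      }
    }

    if (do_dr) {
      std::vector<std::pair<int,int> > cand;
      for (int k = min_unit; k <= n - min_unit; ++k) {
        // match runs at offset k; a run of length L starting at i supports
        // units m in [max(min_unit, k - max_spacer), min(L, k)]
        int run = 0;
        for (int j = 0; j <= n - k; ++j) {
          bool mt = (j < n - k) && (s[j] == s[j + k]);
          if (mt) ++run;
          else {
            if (run > 0) {
              int i0 = j - run;               // 0-based run start
              int m_lo = std::max(min_unit, k - max_spacer);
              int m_hi = std::min(run, k);
              if (m_hi >= m_lo)
                cand.push_back(std::make_pair(i0 + 1, i0 + run + k)); // 1-based
            }
            run = 0;
          }
        }
      }
      std::vector<int> ms, me; merge_push(cand, ms, me);
      for (size_t k = 0; k < ms.size(); ++k) {
        seq_idx.push_back(si + 1); class_v.push_back("DIRECT_REPEAT");
        start_v.push_back(ms[k]); end_v.push_back(me[k]); strand_v.push_back("*");
      }
    }
  }
  return DataFrame::create(_["seq"] = seq_idx, _["motif_class"] = class_v,
                           _["start"] = start_v, _["end"] = end_v,
                           _["strand"] = strand_v,
                           _["stringsAsFactors"] = false);
}
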