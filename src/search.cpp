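#include <Rcpp.h>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Symbols are ints: Unicode code points in code-point mode, 0-255 in byte
// mode. Counts are doubles so they cannot overflow on long texts.

static List result_list(const std::vector<int>& starts, double alignments,
                        double anchor, double p2c, double p1c) {
  IntegerVector st(starts.begin(), starts.end());
  return List::create(
    _["starts"]     = st,
    _["alignments"] = alignments,
    _["anchor_cmps"] = anchor,
    _["p2_cmps"]    = p2c,
    _["p1_cmps"]    = p1c,
    _["total_cmps"] = anchor + p2c + p1c);
}

// Split search. Two anchor-scan conventions:
//   p2_scan = false ("window"): one anchor comparison per full-pattern
//     window s = 0..n-m, anchor at text index s+m-1. alignments = n-m+1.
//   p2_scan = true ("p2"): the right half alone slides from the text start,
//     anchor index i0 = m2-1..n-1; a full p2 match is promoted to an
//     occurrence only when the left half fits (i0 >= m-1).
// Both return the identical occurrence set; only the instrumentation and
// the anchor trace differ.
// [[Rcpp::export(name = ".cpp_split_search")]]
List cpp_split_search(IntegerVector pat, IntegerVector txt,
                      bool p2_scan = false, bool trace = false) {
  const int m = pat.size(), n = txt.size();
  const int m1 = m / 2, m2 = m - m1;
  std::vector<int> starts;
  std::vector<int> tr_i0, tr_sym;
  std::vector<int> tr_hit;
  double alignments = 0, anchor = 0, p2c = 0, p1c = 0;
  const int last = m - 1;

  if (m >= 1 && m <= n) {
    const int i0_from = p2_scan ? (m2 - 1) : (m - 1);
    for (int i0 = i0_from; i0 <= n - 1; ++i0) {
      ++alignments;
      ++anchor;
      bool hit = (txt[i0] == pat[last]);
      if (trace) {
        tr_i0.push_back(i0);
        tr_sym.push_back(txt[i0]);
        tr_hit.push_back(hit ? 1 : 0);
      }
      if (!hit) continue;
      // remaining right-half characters, right to left
      bool ok = true;
      for (int j = m - 2; j >= m1; --j) {
        ++p2c;
        if (txt[i0 - (last - j)] != pat[j]) { ok = false; break; }
      }
      if (!ok) continue;
      if (i0 < m - 1) continue;    // p2-scan mode: left half cannot fit
      // left half, right to left from pmap = i0 - m2
      const int pmap = i0 - m2;
      for (int j = m1 - 1; j >= 0; --j) {
        ++p1c;
        if (txt[pmap - (m1 - 1 - j)] != pat[j]) { ok = false; break; }
      }
      if (ok) starts.push_back(i0 - m + 1);
    }
  }
  List out = result_list(starts, alignments, anchor, p2c, p1c);
  if (trace) {
    out["trace"] = DataFrame::create(
      _["i0"] = IntegerVector(tr_i0.begin(), tr_i0.end()),
      _["symbol"] = IntegerVector(tr_sym.begin(), tr_sym.end()),
      _["anchor_hit"] = LogicalVector(tr_hit.begin(), tr_hit.end()));
  }
  return out;
}

// Brute force: left-to-right verification per window, unit shift.
// [[Rcpp::export(name = ".cpp_brute_search")]]
List cpp_brute_search(IntegerVector pat, IntegerVector txt) {
  const int m = pat.size(), n = txt.size();
  std::vector<int> starts;
  double alignments = 0, cmps = 0;
  for (int s = 0; s + m <= n; ++s) {
    ++alignments;
    int j = 0;
    while (j < m) {
      ++cmps;
      if (pat[j] != txt[s + j]) break;
      ++j;
    }
    if (j == m) starts.push_back(s);
  }
  return result_list(starts, alignments, 0, cmps, 0);
}

typedef std::unordered_map<int, int> ShiftMap;

static ShiftMap make_map(IntegerVector keys, IntegerVector shifts) {
  ShiftMap mp;
  for (int i = 0; i < keys.size(); ++i) mp[keys[i]] = shifts[i];
  return mp;
}

static inline int lookup(const ShiftMap& mp, int c, int dflt) {
  ShiftMap::const_iterator it = mp.find(c);
  return it == mp.end() ? dflt : it->second;
}

// Horspool: right-to-left verification; shift keyed on the text character
// under the window's last position.
// [[Rcpp::export(name = ".cpp_horspool_search")]]
List cpp_horspool_search(IntegerVector pat, IntegerVector txt,
                         IntegerVector keys, IntegerVector shifts,
                         int default_shift) {
  const int m = pat.size(), n = txt.size();
  ShiftMap mp = make_map(keys, shifts);
  std::vector<int> starts;
  double alignments = 0, cmps = 0;
  int s = 0;
  while (s + m <= n) {
    ++alignments;
    int j = m - 1;
    while (j >= 0) {
      ++cmps;
      if (pat[j] != txt[s + j]) break;
      --j;
    }
    if (j < 0) starts.push_back(s);
    s += lookup(mp, txt[s + m - 1], default_shift);
  }
  return result_list(starts, alignments, 0, cmps, 0);
}

// Quick Search: left-to-right verification; shift keyed on the text
// character immediately after the window.
// [[Rcpp::export(name = ".cpp_quick_search")]]
List cpp_quick_search(IntegerVector pat, IntegerVector txt,
                      IntegerVector keys, IntegerVector shifts,
                      int default_shift) {
  const int m = pat.size(), n = txt.size();
  ShiftMap mp = make_map(keys, shifts);
  std::vector<int> starts;
  double alignments = 0, cmps = 0;
  int s = 0;
  while (s + m <= n) {
    ++alignments;
    int j = 0;
    while (j < m) {
      ++cmps;
      if (pat[j] != txt[s + j]) break;
      ++j;
    }
    if (j == m) starts.push_back(s);
    if (s + m >= n) break;          // no character after the last window
    s += lookup(mp, txt[s + m], default_shift);
  }
  return result_list(starts, alignments, 0, cmps, 0);
}

// Strong good-suffix table, classical linear-time construction via the
// suffixes array. gs[j] (0-based mismatch position j) is the shift after
// matching pat[j+1..m-1] and mismatching at j; gs[m-1] applies when the
// first comparison fails, and gs is also consulted at j = -1 boundary via
// gs0 (full match) = the pattern period.
static std::vector<int> good_suffix(const IntegerVector& pat) {
  const int m = pat.size();
  std::vector<int> suff(m), gs(m, m);
  suff[m - 1] = m;
  int g = m - 1, f = m - 1;
  for (int i = m - 2; i >= 0; --i) {
    if (i > g && suff[i + m - 1 - f] < i - g) {
      suff[i] = suff[i + m - 1 - f];
    } else {
      if (i < g) g = i;
      f = i;
      while (g >= 0 && pat[g] == pat[g + m - 1 - f]) --g;
      suff[i] = f - g;
    }
  }
  int j = 0;
  for (int i = m - 1; i >= 0; --i) {
    if (suff[i] == i + 1) {
      for (; j < m - 1 - i; ++j) {
        if (gs[j] == m) gs[j] = m - 1 - i;
      }
    }
  }
  for (int i = 0; i <= m - 2; ++i) gs[m - 1 - suff[i]] = m - 1 - i;
  return gs;
}

// [[Rcpp::export(name = ".cpp_good_suffix_table")]]
IntegerVector cpp_good_suffix_table(IntegerVector pat) {
  std::vector<int> gs = good_suffix(pat);
  return IntegerVector(gs.begin(), gs.end());
}

// Boyer-Moore: right-to-left verification; shift = max(good suffix,
// bad character), never below 1. After a full match, shift by the
// pattern period (keeps overlapping occurrences).
// [[Rcpp::export(name = ".cpp_bm_search")]]
List cpp_bm_search(IntegerVector pat, IntegerVector txt,
                   IntegerVector bc_keys, IntegerVector bc_last) {
  const int m = pat.size(), n = txt.size();
  std::vector<int> gs = good_suffix(pat);
  ShiftMap last = make_map(bc_keys, bc_last);  // rightmost index of c in pat
  std::vector<int> starts;
  double alignments = 0, cmps = 0;
  // shift after a full match: smallest period of the pattern
  int full_shift = m;
  {
    std::vector<int> suff(m);
    suff[m - 1] = m;
    int g = m - 1, f = m - 1;
    for (int i = m - 2; i >= 0; --i) {
      if (i > g && suff[i + m - 1 - f] < i - g) {
        suff[i] = suff[i + m - 1 - f];
      } else {
        if (i < g) g = i;
        f = i;
        while (g >= 0 && pat[g] == pat[g + m - 1 - f]) --g;
        suff[i] = f - g;
      }
    }
    for (int i = m - 2; i >= 0; --i) {
      if (suff[i] == i + 1) { full_shift = m - 1 - i; break; }
    }
  }
  int s = 0;
  while (s + m <= n) {
    ++alignments;
    int j = m - 1;
    while (j >= 0) {
      ++cmps;
      if (pat[j] != txt[s + j]) break;
      --j;
    }
    if (j < 0) {
      starts.push_back(s);
      s += full_shift;
    } else {
      int bc = j - lookup(last, txt[s + j], -1);
      int shift = std::max(gs[j], bc);
      if (shift < 1) shift = 1;
      s += shift;
    }
  }
  return result_list(starts, alignments, 0, cmps, 0);
}
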