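#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dictionary view over R vectors. Suffix codes are exact integers stored in
// doubles (20^12 < 2^53). Words are globally sorted by (prefix, suffix);
// blocks of equal hexamer prefix are contiguous and indexed by sorted
// prefix keys with [start, end) offsets.
struct DictView {
  const int *keys;       // sorted occupied prefix codes
  const int *bstart;     // block start (0-based, half-open)
  const int *bend;
  int nkeys;
  const double *suf;     // suffix codes, sorted within blocks
  const int *lab;        // 1-based family index per word
  int n;                 // number of words
};

static DictView as_dict(const List &d) {
  DictView v;
  IntegerVector keys = d["prefix_keys"], bs = d["block_start"],
                be = d["block_end"], lab = d["labels"];
  NumericVector suf = d["suffixes"];
  v.keys = keys.begin(); v.bstart = bs.begin(); v.bend = be.begin();
  v.nkeys = keys.size();
  v.suf = suf.begin(); v.lab = lab.begin(); v.n = suf.size();
  return v;
}

// lower_bound over prefix keys
static inline int key_lower_bound(const DictView &d, int p) {
  int lo = 0, hi = d.nkeys;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (d.keys[mid] < p) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// Global insertion index of (p, s); sets *exact to the word index on an
// exact match, else -1. Empty prefix block: insertion point in the global
// sorted order of all words.
static int dict_insertion(const DictView &d, int p, double s, int *exact) {
  *exact = -1;
  if (d.n == 0) return 0;
  int kpos = key_lower_bound(d, p);
  if (kpos < d.nkeys && d.keys[kpos] == p) {
    int lo = d.bstart[kpos], hi = d.bend[kpos];
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (d.suf[mid] < s) lo = mid + 1; else hi = mid;
    }
    if (lo < d.bend[kpos] && d.suf[lo] == s) *exact = lo;
    return lo;
  }
  // block absent: global insertion = start of next occupied block
  return (kpos < d.nkeys) ? d.bstart[kpos] : d.n;
}

// prefix code of stored word i (via the block that contains i)
static int word_prefix(const DictView &d, int i) {
  int lo = 0, hi = d.nkeys - 1;
  while (lo < hi) {                 // last block with bstart <= i
    int mid = (lo + hi + 1) / 2;
    if (d.bstart[mid] <= i) lo = mid; else hi = mid - 1;
  }
  return d.keys[lo];
}

static inline void code_digits(double code, int len, int *out) {
  for (int i = len - 1; i >= 0; --i) {
    double q = std::floor(code / 20.0);
    out[i] = (int)(code - q * 20.0);
    code = q;
  }
}

// LCP distance over the full word: word length minus longest common prefix
static int lcp_distance(int p1, double s1, int p2, double s2,
                        int plen, int slen) {
  std::vector<int> a(plen + slen), b(plen + slen);
  code_digits((double)p1, plen, a.data());
  code_digits(s1, slen, a.data() + plen);
  code_digits((double)p2, plen, b.data());
  code_digits(s2, slen, b.data() + plen);
  int lcp = 0, k = plen + slen;
  while (lcp < k && a[lcp] == b[lcp]) ++lcp;
  return k - lcp;
}

// [[Rcpp::export]]
List cpp_lookup(List dict, int qprefix, double qsuffix, int prefix_len,
                int suffix_len, bool global_on_empty) {
  DictView d = as_dict(dict);
  if (d.n == 0)
    return List::create(_["kind"] = "none");
  int exact;
  int ins = dict_insertion(d, qprefix, qsuffix, &exact);
  if (exact >= 0)
    return List::create(_["kind"] = "exact",
                        _["index"] = exact + 1,
                        _["label"] = d.lab[exact],
                        _["distance"] = 0);
  int kpos = key_lower_bound(d, qprefix);
  bool empty_block = !(kpos < d.nkeys && d.keys[kpos] == qprefix);
  if (empty_block && !global_on_empty)
    return List::create(_["kind"] = "none");
  std::vector<int> idx;
  if (ins - 1 >= 0) idx.push_back(ins - 1);
  if (ins < d.n) idx.push_back(ins);
  IntegerVector ix(idx.size()), lb(idx.size()), dist(idx.size());
  for (size_t t = 0; t < idx.size(); ++t) {
    ix[t] = idx[t] + 1;
    lb[t] = d.lab[idx[t]];
    dist[t] = lcp_distance(qprefix, qsuffix, word_prefix(d, idx[t]),
                           d.suf[idx[t]], prefix_len, suffix_len);
  }
  return List::create(_["kind"] = "insert", _["index"] = ix,
                      _["label"] = lb, _["distance"] = dist);
}

// One scored word match prior to mosaic combination.
struct Match {
  int fam;        // 1-based family index
  int start;      // 0-based window start on the query
  int dir;        // 1 forward, 2 reverse
  double sc[12];  // scores in increasing query-residue order
};

// Score query window (ranks at word positions 0..k-1, already reversed for
// the reverse direction) against stored word `wi`; returns 12 positional
// scores in suffix-position order. PSSM layout: 20 x 20 x slen array,
// query rank = row, reference rank = column.
static inline void score_against(const DictView &d, int wi, const int *wranks,
                                 const double *pssm, int plen, int slen,
                                 double *out) {
  int rd[16];
  code_digits(d.suf[wi], slen, rd);
  for (int j = 0; j < slen; ++j)
    out[j] = pssm[wranks[plen + j] + 20 * rd[j] + 400 * j];
}

// Classify every valid window of one direction, appending matches.
// For the reverse direction the window is reversed before encoding and
// suffix position j maps back to query residue start + (slen - 1 - j):
// the reversed word's suffix covers the first `slen` residues of the
// original window.
static void classify_direction(const int *ranks, int L, const DictView &d,
                               const double *pssm, int plen, int slen,
                               int dir, bool global_on_empty,
                               std::vector<Match> &out) {
  int k = plen + slen;
  if (d.n == 0 || L < k) return;
  std::vector<int> w(k);
  double sc1[12], sc2[12];
  for (int s = 0; s + k <= L; ++s) {
    bool ok = true;
    for (int t = 0; t < k; ++t) {
      int r = (dir == 1) ? ranks[s + t] : ranks[s + k - 1 - t];
      if (r < 0) { ok = false; break; }
      w[t] = r;
    }
    if (!ok) continue;
    int p = 0;
    for (int t = 0; t < plen; ++t) p = p * 20 + w[t];
    double sfx = 0;
    for (int t = plen; t < k; ++t) sfx = sfx * 20.0 + w[t];
    int exact;
    int ins = dict_insertion(d, p, sfx, &exact);
    Match m;
    m.start = s; m.dir = dir;
    if (exact >= 0) {
      score_against(d, exact, w.data(), pssm, plen, slen, sc1);
      m.fam = d.lab[exact];
      for (int j = 0; j < slen; ++j)
        m.sc[dir == 1 ? j : slen - 1 - j] = sc1[j];
      out.push_back(m);
      continue;
    }
    int kpos = key_lower_bound(d, p);
    bool empty_block = !(kpos < d.nkeys && d.keys[kpos] == p);
    if (empty_block && !global_on_empty) continue;
    int i1 = ins - 1, i2 = ins;
    bool has1 = i1 >= 0, has2 = i2 < d.n;
    if (has1 && has2 && d.lab[i1] == d.lab[i2]) {
      // same family: one match with the per-position maximum
      score_against(d, i1, w.data(), pssm, plen, slen, sc1);
      score_against(d, i2, w.data(), pssm, plen, slen, sc2);
      m.fam = d.lab[i1];
      for (int j = 0; j < slen; ++j) {
        double v = sc1[j] > sc2[j] ? sc1[j] : sc2[j];
        m.sc[dir == 1 ? j : slen - 1 - j] = v;
      }
      out.push_back(m);
    } else {
      if (has1) {
        score_against(d, i1, w.data(), pssm, plen, slen, sc1);
        m.fam = d.lab[i1];
        for (int j = 0; j < slen; ++j)
          m.sc[dir == 1 ? j : slen - 1 - j] = sc1[j];
        out.push_back(m);
      }
      if (has2) {
        score_against(d, i2, w.data(), pssm, plen, slen, sc1);
        m.fam = d.lab[i2];
        for (int j = 0; j < slen; ++j)
          m.sc[dir == 1 ? j : slen - 1 - j] = sc1[j];
        out.push_back(m);
      }
    }
  }
}

static void classify_all(const int *ranks, int L, const DictView &fwd,
                         const DictView &rev, const double *pf,
                         const double *pr, int plen, int slen,
                         bool global_on_empty, bool use_reverse,
                         std::vector<Match> &out) {
  classify_direction(ranks, L, fwd, pf, plen, slen, 1, global_on_empty, out);
  if (use_reverse)
    classify_direction(ranks, L, rev, pr, plen, slen, 2, global_on_empty, out);
}

// Mosaic combination: per family, per residue, the maximum score over all
// covering matches (both directions); uncovered residues contribute 0.
// best: nfam x L work buffer filled with -Inf.
static void mosaic_accumulate(const std::vector<Match> &ms, int nfam, int L,
                              int plen, int slen, std::vector<double> &best) {
  std::fill(best.begin(), best.end(), R_NegInf);
  for (const Match &m : ms) {
    double *row = best.data() + (size_t)(m.fam - 1) * L;
    // first scored residue: forward matches score the suffix (after the
    // hexamer prefix); reverse matches map onto the window's first slen
    int base = m.start + ((m.dir == 1) ? plen : 0);
    for (int j = 0; j < slen; ++j) {
      int pos = base + j;
      if (row[pos] < m.sc[j]) row[pos] = m.sc[j];
    }
  }
}

// [[Rcpp::export]]
List cpp_classify_query(IntegerVector ranks, List fwd, List rev,
                        NumericVector pssm_fwd, NumericVector pssm_rev,
                        int nfam, int prefix_len, int suffix_len,
                        bool global_on_empty, bool use_reverse, bool detail) {
  DictView df = as_dict(fwd), dr = as_dict(rev);
  int L = ranks.size();
  std::vector<Match> ms;
  classify_all(ranks.begin(), L, df, dr, pssm_fwd.begin(), pssm_rev.begin(),
               prefix_len, suffix_len, global_on_empty, use_reverse, ms);
  int slen = suffix_len;
  std::vector<double> best((size_t)nfam * L);
  mosaic_accumulate(ms, nfam, L, prefix_len, slen, best);
  std::vector<int> fam_idx; std::vector<double> tot;
  std::vector<int> nmatch, covered;
  std::vector<int> count(nfam, 0);
  for (const Match &m : ms) count[m.fam - 1]++;
  for (int f = 0; f < nfam; ++f) {
    if (count[f] == 0) continue;
    const double *row = best.data() + (size_t)f * L;
    double s = 0; int cov = 0;
    for (int i = 0; i < L; ++i)
      if (row[i] > R_NegInf) { s += row[i]; ++cov; }
    fam_idx.push_back(f + 1); tot.push_back(s);
    nmatch.push_back(count[f]); covered.push_back(cov);
  }
  List res = List::create(_["family"] = wrap(fam_idx),
                          _["total_score"] = wrap(tot),
                          _["n_matches"] = wrap(nmatch),
                          _["covered_residues"] = wrap(covered));
  if (detail) {
    int nm = ms.size();
    IntegerVector fam(nm), start(nm), dir(nm);
    NumericMatrix scores(nm, slen);
    IntegerMatrix pos(nm, slen);
    for (int i = 0; i < nm; ++i) {
      fam[i] = ms[i].fam; start[i] = ms[i].start; dir[i] = ms[i].dir;
      int base = ms[i].start + ((ms[i].dir == 1) ? prefix_len : 0);
      for (int j = 0; j < slen; ++j) {
        scores(i, j) = ms[i].sc[j];
        pos(i, j) = base + j;
      }
    }
    res["matches"] = List::create(_["family"] = fam, _["start"] = start,
                                  _["direction"] = dir, _["positions"] = pos,
                                  _["scores"] = scores);
  }
  return res;
}

// Maximum per-family mosaic total for each row of a rank matrix (used for
// noise-threshold calibration on random sequences). Rows with no matches
// score 0.
// [[Rcpp::export]]
NumericVector cpp_batch_max_scores(IntegerMatrix seqs, List fwd, List rev,
                                   NumericVector pssm_fwd,
                                   NumericVector pssm_rev, int nfam,
                                   int prefix_len, int suffix_len,
                                   bool global_on_empty, bool use_reverse) {
  DictView df = as_dict(fwd), dr = as_dict(rev);
  int n = seqs.nrow(), L = seqs.ncol();
  NumericVector out(n);
  std::vector<Match> ms;
  std::vector<double> best((size_t)nfam * L);
  std::vector<int> ranks(L);
  int slen = suffix_len;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < L; ++j) ranks[j] = seqs(i, j);
    ms.clear();
    classify_all(ranks.data(), L, df, dr, pssm_fwd.begin(), pssm_rev.begin(),
                 prefix_len, slen, global_on_empty, use_reverse, ms);
    if (ms.empty()) { out[i] = 0.0; continue; }
    mosaic_accumulate(ms, nfam, L, prefix_len, slen, best);
    std::vector<bool> seen(nfam, false);
    for (const Match &m : ms) seen[m.fam - 1] = true;
    double mx = R_NegInf;
    for (int f = 0; f < nfam; ++f) {
      if (!seen[f]) continue;
      const double *row = best.data() + (size_t)f * L;
      double s = 0;
      for (int t = 0; t < L; ++t)
        if (row[t] > R_NegInf) s += row[t];
      if (s > mx) mx = s;
    }
    out[i] = mx;
  }
  return out;
}

// Base-20 digit matrix (n x len) of integer codes; used to recover suffix
// residues for PSSM training features.
// [[Rcpp::export]]
IntegerMatrix cpp_code_digits(NumericVector codes, int len) {
  int n = codes.size();
  IntegerMatrix out(n, len);
  std::vector<int> buf(len);
  for (int i = 0; i < n; ++i) {
    code_digits(codes[i], len, buf.data());
    for (int j = 0; j < len; ++j) out(i, j) = buf[j];
  }
  return out;
}

// Encode every valid window (stride 1) of a rank sequence; windows touching
// an invalid residue (rank < 0) are skipped. Returns 0-based starts and
// (prefix, suffix) codes; reverse = encode the reversed window.
// [[Rcpp::export]]
List cpp_window_codes(IntegerVector ranks, int prefix_len, int suffix_len,
                      bool reverse) {
  int k = prefix_len + suffix_len, L = ranks.size();
  std::vector<int> starts; std::vector<double> pre, suf;
  std::vector<int> w(k);
  for (int s = 0; s + k <= L; ++s) {
    bool ok = true;
    for (int t = 0; t < k; ++t) {
      int r = reverse ? ranks[s + k - 1 - t] : ranks[s + t];
      if (r < 0) { ok = false; break; }
      w[t] = r;
    }
    if (!ok) continue;
    double p = 0, q = 0;
    for (int t = 0; t < prefix_len; ++t) p = p * 20.0 + w[t];
    for (int t = prefix_len; t < k; ++t) q = q * 20.0 + w[t];
    starts.push_back(s); pre.push_back(p); suf.push_back(q);
  }
  return List::create(_["start"] = wrap(starts), _["prefix"] = wrap(pre),
                      _["suffix"] = wrap(suf));
}
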