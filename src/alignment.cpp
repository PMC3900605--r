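// Seeded ungapped local alignment (HSP search) in nucleotide and six-frame
// translated modes, plus batch fragment scoring for whole-genome fragmented
// similarity. Significance is Karlin-Altschul for ungapped scores; the R side
// converts log10(E) into E, bit scores and P-values.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <set>
#include <tuple>
#include <cmath>
using namespace Rcpp;

static const double LN10 = 2.302585092994046;

// ---- encodings -------------------------------------------------------------

// A=0 C=1 G=2 T/U=3, anything else -1
static inline int nt_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return -1;
  }
}

static std::vector<int> encode_nt(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = nt_code(s[i]);
  return v;
}

static std::vector<int> revcomp_codes(const std::vector<int>& v) {
  std::vector<int> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int c = v[v.size() - 1 - i];
    r[i] = (c < 0) ? -1 : 3 - c;
  }
  return r;
}

// Standard genetic code, indexed with bases ordered T,C,A,G.
static const char CODE64[] =
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG";

// amino-acid alphabet order used throughout (X = 20 covers stops/ambiguity)
static const char AA_ORDER[] = "ARNDCQEGHILKMFPSTWYV";

static int aa_index_of(char a) {
  for (int i = 0; i < 20; ++i) if (AA_ORDER[i] == a) return i;
  return 20; // X, stop, unknown
}

// map ACGT code -> TCAG code used by CODE64 indexing
static const int TO_TCAG[4] = {2, 1, 3, 0};

// translate one frame of an encoded nucleotide vector into aa codes 0..20
static std::vector<int> translate_frame(const std::vector<int>& nt, int frame) {
  std::vector<int> aa;
  int n = (int)nt.size();
  aa.reserve((n - frame) / 3);
  for (int p = frame; p + 2 < n; p += 3) {
    int a = nt[p], b = nt[p + 1], c = nt[p + 2];
    if (a < 0 || b < 0 || c < 0) { aa.push_back(20); continue; }
    int idx = 16 * TO_TCAG[a] + 4 * TO_TCAG[b] + TO_TCAG[c];
    aa.push_back(aa_index_of(CODE64[idx]));
  }
  return aa;
}

// BLOSUM62 (A R N D C Q E G H I L K M F P S T W Y V); row/col 20 is X = -1.
static const int B62[20][20] = {
  { 4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0},
  {-1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3},
  {-2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3},
  {-2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3},
  { 0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1},
  {-1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2},
  {-1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2},
  { 0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3},
  {-2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3},
  {-1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3},
  {-1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1},
  {-1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2},
  {-1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1},
  {-2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1},
  {-1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2},
  { 1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2},
  { 0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0},
  {-3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3},
  {-2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-2},
  { 0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-2, 4}
};

static inline int b62(int a, int b) {
  if (a > 19 || b > 19 || a < 0 || b < 0) return -1;
  return B62[a][b];
}

// ---- generic ungapped extension -------------------------------------------
// Extend a seed [qi, qi+len) vs [ti, ti+len) on one diagonal both ways with
// X-drop termination. Returns best score and query bounds (0-based inclusive).
template <typename SCORE>
static void extend_seed(int qi, int ti, int seedlen, int qlen, int tlen,
                        double xdrop, SCORE sc,
                        int& out_qs, int& out_qe, int& out_score) {
  int seed_score = 0;
  for (int k = 0; k < seedlen; ++k) seed_score += sc(qi + k, ti + k);
  // right
  int run = 0, best_r = 0, qe = qi + seedlen - 1;
  for (int q = qi + seedlen, t = ti + seedlen; q < qlen && t < tlen; ++q, ++t) {
    run += sc(q, t);
    if (run > best_r) { best_r = run; qe = q; }
    if (best_r - run > xdrop) break;
  }
  // left
  run = 0;
  int best_l = 0, qs = qi;
  for (int q = qi - 1, t = ti - 1; q >= 0 && t >= 0; --q, --t) {
    run += sc(q, t);
    if (run > best_l) { best_l = run; qs = q; }
    if (best_l - run > xdrop) break;
  }
  out_qs = qs; out_qe = qe;
  out_score = seed_score + best_r + best_l;
}

// ---- nucleotide HSP search -------------------------------------------------

struct Hit {
  int qs, qe, ts, te, score;
  char strand;
};

static void nt_search_one_strand(const std::vector<int>& q,
                                 const std::vector<int>& t,
                                 int w, int match, int mismatch, double xdrop,
                                 char strand, std::vector<Hit>& out) {
  int qlen = (int)q.size(), tlen = (int)t.size();
  if (qlen < w || tlen < w) return;
  int nwords = 1 << (2 * w);
  int mask = nwords - 1;
  std::vector<std::vector<int>> index(nwords);
  // rolling index of target words (skip words containing ambiguity)
  {
    int word = 0, valid = 0;
    for (int j = 0; j < tlen; ++j) {
      if (t[j] < 0) { valid = 0; word = 0; continue; }
      word = ((word << 2) | t[j]) & mask;
      if (++valid >= w) index[word].push_back(j - w + 1);
    }
  }
  std::vector<int> diag_end(qlen + tlen, -1);
  auto sc = [&](int qi, int ti) {
    return (q[qi] >= 0 && q[qi] == t[ti]) ? match : mismatch;
  };
  int word = 0, valid = 0;
  for (int i = 0; i < qlen; ++i) {
    if (q[i] < 0) { valid = 0; word = 0; continue; }
    word = ((word << 2) | q[i]) & mask;
    if (++valid < w) continue;
    int qi = i - w + 1;
    const std::vector<int>& hits = index[word];
    for (size_t h = 0; h < hits.size(); ++h) {
      int ti = hits[h];
      int d = qi - ti + tlen - 1;
      if (qi <= diag_end[d]) continue;
      int qs, qe, score;
      extend_seed(qi, ti, w, qlen, tlen, xdrop, sc, qs, qe, score);
      diag_end[d] = qe;
      Hit hp;
      hp.qs = qs; hp.qe = qe;
      hp.ts = qs - (qi - ti); hp.te = qe - (qi - ti);
      hp.score = score; hp.strand = strand;
      out.push_back(hp);
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_nt_hsps(std::string query, std::string target,
                      int word_size, int match, int mismatch, double xdrop,
                      double max_log10e, double lambda, double K) {
  std::vector<int> q = encode_nt(query), t = encode_nt(target);
  int tlen = (int)t.size();
  std::vector<Hit> hits;
  nt_search_one_strand(q, t, word_size, match, mismatch, xdrop, '+', hits);
  std::vector<int> trc = revcomp_codes(t);
  nt_search_one_strand(q, trc, word_size, match, mismatch, xdrop, '-', hits);
  double log10Kmn = std::log10(K * (double)q.size() * (double)tlen);
  // filter by significance, de-duplicate identical spans
  std::set<std::tuple<int,int,int,int,char>> seen;
  std::vector<Hit> keep;
  std::vector<double> log10e_keep;
  for (size_t h = 0; h < hits.size(); ++h) {
    Hit hp = hits[h];
    if (hp.strand == '-') { // map back to plus-strand coordinates of target
      int ts = tlen - 1 - hp.te;
      int te = tlen - 1 - hp.ts;
      hp.ts = ts; hp.te = te;
    }
    double log10e = log10Kmn - lambda * hp.score / LN10;
    if (log10e > max_log10e) continue;
    auto key = std::make_tuple(hp.qs, hp.qe, hp.ts, hp.te, hp.strand);
    if (seen.count(key)) continue;
    seen.insert(key);
    keep.push_back(hp);
    log10e_keep.push_back(log10e);
  }
  // sort by score descending
  std::vector<size_t> ord(keep.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    return keep[a].score > keep[b].score;
  });
  int n = (int)keep.size();
  IntegerVector qs(n), qe(n), ts(n), te(n), score(n);
  CharacterVector strand(n);
  NumericVector log10e(n);
  for (int i = 0; i < n; ++i) {
    const Hit& hp = keep[ord[i]];
    qs[i] = hp.qs + 1; qe[i] = hp.qe + 1;
    ts[i] = hp.ts + 1; te[i] = hp.te + 1;
    score[i] = hp.score;
    strand[i] = std::string(1, hp.strand);
    log10e[i] = log10e_keep[ord[i]];
  }
  return DataFrame::create(
    _["q_start"] = qs, _["q_end"] = qe,
    _["t_start"] = ts, _["t_end"] = te,
    _["strand"] = strand, _["raw_score"] = score, _["log10_e"] = log10e,
    _["stringsAsFactors"] = false);
}

// ---- translated (six-frame) HSP search ------------------------------------

struct TxFrames {
  std::vector<std::vector<int>> aa; // 6 frames: +1 +2 +3 -1 -2 -3
  int nt_len;
};

static TxFrames six_frames(const std::vector<int>& nt) {
  TxFrames f;
  f.nt_len = (int)nt.size();
  std::vector<int> rc = revcomp_codes(nt);
  for (int fr = 0; fr < 3; ++fr) f.aa.push_back(translate_frame(nt, fr));
  for (int fr = 0; fr < 3; ++fr) f.aa.push_back(translate_frame(rc, fr));
  return f;
}

// nt span (1-based, plus strand) of aa positions [pa, pb] in frame `fi` (0..5)
static void aa_to_nt(int fi, int pa, int pb, int nt_len, int& s, int& e) {
  int fr = fi % 3;
  if (fi < 3) {
    s = fr + 3 * pa + 1;
    e = fr + 3 * pb + 3;
  } else {
    int rc_s = fr + 3 * pa + 1, rc_e = fr + 3 * pb + 3;
    s = nt_len - rc_e + 1;
    e = nt_len - rc_s + 1;
  }
}

static const int FRAME_LABEL[6] = {1, 2, 3, -1, -2, -3};

struct TxHit {
  int qs_aa, qe_aa, diag_off, qframe, tframe, score;
};

// seeds must not contain stop/ambiguity (X = 20): the seed trio is always
// included whole in the extension, so an X inside the first seed hit on a
// diagonal would lock in a window that a trimmed optimum excludes. Extensions
// still cross stops freely.
static inline bool seedable(int a, int b, int c) {
  return a != 20 && b != 20 && c != 20;
}

// core 6x6 frame search; records per-hit aa spans
static void tx_search(const TxFrames& qf, const TxFrames& tf, double xdrop,
                      std::vector<TxHit>& out) {
  // index stop-free 3-mers of all target frames (21-letter alphabet)
  std::vector<std::vector<std::pair<int,int>>> index(21 * 21 * 21);
  for (int fi = 0; fi < 6; ++fi) {
    const std::vector<int>& a = tf.aa[fi];
    for (int j = 0; j + 2 < (int)a.size(); ++j) {
      if (!seedable(a[j], a[j + 1], a[j + 2])) continue;
      int key = a[j] * 441 + a[j + 1] * 21 + a[j + 2];
      index[key].push_back(std::make_pair(fi, j));
    }
  }
  for (int qi_f = 0; qi_f < 6; ++qi_f) {
    const std::vector<int>& q = qf.aa[qi_f];
    int qlen = (int)q.size();
    if (qlen < 3) continue;
    // per-target-frame diagonal bookkeeping
    std::vector<std::vector<int>> diag_end(6);
    for (int fi = 0; fi < 6; ++fi)
      diag_end[fi].assign(qlen + (int)tf.aa[fi].size(), -1);
    for (int i = 0; i + 2 < qlen; ++i) {
      if (!seedable(q[i], q[i + 1], q[i + 2])) continue;
      int key = q[i] * 441 + q[i + 1] * 21 + q[i + 2];
      const std::vector<std::pair<int,int>>& hits = index[key];
      for (size_t h = 0; h < hits.size(); ++h) {
        int fi = hits[h].first, j = hits[h].second;
        const std::vector<int>& t = tf.aa[fi];
        int tlen = (int)t.size();
        int d = i - j + tlen - 1;
        if (i <= diag_end[fi][d]) continue;
        auto sc = [&](int qi, int ti) { return b62(q[qi], t[ti]); };
        int qs, qe, score;
        extend_seed(i, j, 3, qlen, tlen, xdrop, sc, qs, qe, score);
        diag_end[fi][d] = qe;
        TxHit th;
        th.qs_aa = qs; th.qe_aa = qe; th.diag_off = i - j;
        th.qframe = qi_f; th.tframe = fi; th.score = score;
        out.push_back(th);
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_tx_hsps(std::string query, std::string target, double xdrop,
                      double max_log10e, double lambda, double K) {
  TxFrames qf = six_frames(encode_nt(query));
  TxFrames tf = six_frames(encode_nt(target));
  std::vector<TxHit> hits;
  tx_search(qf, tf, xdrop, hits);
  double m_aa = std::max(1.0, (double)qf.nt_len / 3.0);
  double n_aa = std::max(1.0, (double)tf.nt_len / 3.0);
  double log10Kmn = std::log10(K * m_aa * n_aa);
  std::vector<size_t> keep;
  std::vector<double> log10e_all(hits.size());
  std::set<std::tuple<int,int,int,int>> seen;
  for (size_t h = 0; h < hits.size(); ++h) {
    double log10e = log10Kmn - lambda * hits[h].score / LN10;
    log10e_all[h] = log10e;
    if (log10e > max_log10e) continue;
    auto key = std::make_tuple(hits[h].qframe * 7 + hits[h].tframe,
                               hits[h].diag_off,
                               hits[h].qs_aa, hits[h].qe_aa);
    if (seen.count(key)) continue;
    seen.insert(key);
    keep.push_back(h);
  }
  std::sort(keep.begin(), keep.end(), [&](size_t a, size_t b) {
    return hits[a].score > hits[b].score;
  });
  int n = (int)keep.size();
  IntegerVector qs(n), qe(n), ts(n), te(n), qfr(n), tfr(n), score(n);
  NumericVector log10e(n);
  for (int i = 0; i < n; ++i) {
    const TxHit& th = hits[keep[i]];
    int a, b;
    aa_to_nt(th.qframe, th.qs_aa, th.qe_aa, qf.nt_len, a, b);
    qs[i] = a; qe[i] = b;
    // extension is strictly diagonal, so the target aa span is the query span
    // shifted by the seed's diagonal offset
    aa_to_nt(th.tframe, th.qs_aa - th.diag_off, th.qe_aa - th.diag_off,
             tf.nt_len, a, b);
    ts[i] = a; te[i] = b;
    score[i] = th.score;
    qfr[i] = FRAME_LABEL[th.qframe];
    tfr[i] = FRAME_LABEL[th.tframe];
    log10e[i] = log10e_all[keep[i]];
  }
  return DataFrame::create(
    _["q_start"] = qs, _["q_end"] = qe,
    _["t_start"] = ts, _["t_end"] = te,
    _["q_frame"] = qfr, _["t_frame"] = tfr,
    _["raw_score"] = score, _["log10_e"] = log10e,
    _["stringsAsFactors"] = false);
}

// ---- fragment scoring for fragmented whole-genome similarity ---------------

// Best HSP raw score of each fragment against the target (six-frame translated
// both sides); scores below min_score are reported as 0.
// [[Rcpp::export]]
NumericVector cpp_fragment_best_scores(CharacterVector fragments,
                                       std::string target,
                                       double xdrop, double min_score) {
  TxFrames tf = six_frames(encode_nt(target));
  // index stop-free target 3-mers once (see seedable())
  std::vector<std::vector<std::pair<int,int>>> index(21 * 21 * 21);
  for (int fi = 0; fi < 6; ++fi) {
    const std::vector<int>& a = tf.aa[fi];
    for (int j = 0; j + 2 < (int)a.size(); ++j) {
      if (!seedable(a[j], a[j + 1], a[j + 2])) continue;
      int key = a[j] * 441 + a[j + 1] * 21 + a[j + 2];
      index[key].push_back(std::make_pair(fi, j));
    }
  }
  int nf = fragments.size();
  NumericVector best(nf);
  for (int f = 0; f < nf; ++f) {
    std::string frag = as<std::string>(fragments[f]);
    TxFrames qf = six_frames(encode_nt(frag));
    int bst = 0;
    for (int qi_f = 0; qi_f < 6; ++qi_f) {
      const std::vector<int>& q = qf.aa[qi_f];
      int qlen = (int)q.size();
      if (qlen < 3) continue;
      std::vector<std::vector<int>> diag_end(6);
      for (int fi = 0; fi < 6; ++fi)
        diag_end[fi].assign(qlen + (int)tf.aa[fi].size(), -1);
      for (int i = 0; i + 2 < qlen; ++i) {
        if (!seedable(q[i], q[i + 1], q[i + 2])) continue;
        int key = q[i] * 441 + q[i + 1] * 21 + q[i + 2];
        const std::vector<std::pair<int,int>>& hits = index[key];
        for (size_t h = 0; h < hits.size(); ++h) {
          int fi = hits[h].first, j = hits[h].second;
          const std::vector<int>& t = tf.aa[fi];
          int tlen = (int)t.size();
          int d = i - j + tlen - 1;
          if (i <= diag_end[fi][d]) continue;
          auto sc = [&](int qi, int ti) { return b62(q[qi], t[ti]); };
          int qs, qe, score;
          extend_seed(i, j, 3, qlen, tlen, xdrop, sc, qs, qe, score);
          diag_end[fi][d] = qe;
          if (score > bst) bst = score;
        }
      }
    }
    best[f] = (bst >= min_score) ? (double)bst : 0.0;
  }
  return best;
}

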