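// Fragment-based ANI kernels: affine-gap local alignment (exact DP inside a
// diagonal band; the full diagonal range gives the exhaustive reference) and
// 21-mer seeding to locate the band and to prescreen unrelated pairs.
//
// Scoring convention matches Biostrings: a gap of length L costs
// gap_open + L * gap_ext; alignments neither start nor end with a gap.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const int NEG_INF = INT_MIN / 4;

static std::vector<int8_t> encode_seq(const std::string &s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': case 'a': v[i] = 0; break;
      case 'C': case 'c': v[i] = 1; break;
      case 'G': case 'g': v[i] = 2; break;
      case 'T': case 't': v[i] = 3; break;
      default: v[i] = -1;
    }
  }
  return v;
}

struct Aln {
  int score = 0;
  int matches = 0;
  int aln_cols = 0;
  int q_start = 0, q_end = -1;   // 0-based inclusive; empty if score <= 0
  int s_start = 0, s_end = -1;
};

// Banded affine local alignment over diagonals d = j - i in [dlo, dhi].
// States: M (q_i aligned to s_j), X (gap in subject), Y (gap in query).
static Aln sw_banded(const std::vector<int8_t> &q, const std::vector<int8_t> &s,
                     int dlo, int dhi,
                     int match, int mismatch, int gap_open, int gap_ext) {
  const int m = (int)q.size(), n = (int)s.size();
  Aln best;
  if (m == 0 || n == 0) return best;
  dlo = std::max(dlo, -(m - 1));
  dhi = std::min(dhi, n - 1);
  if (dlo > dhi) return best;
  const int W = dhi - dlo + 1;
  const int open_cost = gap_open + gap_ext;

  // rows padded by one sentinel on each side so w-1 / w+1 never leave the
  // buffer; stale cells below the shrinking valid range are re-sentinelled
  // once per row (the range shifts by at most one per row)
  std::vector<int> bufMp(W + 2, NEG_INF), bufXp(W + 2, NEG_INF),
      bufYp(W + 2, NEG_INF), bufMc(W + 2, NEG_INF), bufXc(W + 2, NEG_INF),
      bufYc(W + 2, NEG_INF);
  int *Mprev = bufMp.data() + 1, *Xprev = bufXp.data() + 1,
      *Yprev = bufYp.data() + 1, *Mcur = bufMc.data() + 1,
      *Xcur = bufXc.data() + 1, *Ycur = bufYc.data() + 1;
  // traceback: tbM 0=start,1=M,2=X,3=Y ; tbX 0=M,1=X ; tbY 0=M,1=Y
  std::vector<uint8_t> tbM((size_t)m * W), tbX((size_t)m * W), tbY((size_t)m * W);

  int best_score = 0, best_i = -1, best_w = -1;
  for (int i = 0; i < m; ++i) {
    const int wlo = std::max(0, -(i + dlo));
    const int whi = std::min(W - 1, (n - 1) - (i + dlo));
    if (wlo > whi) { std::swap(Mprev, Mcur); std::swap(Xprev, Xcur);
                     std::swap(Yprev, Ycur); continue; }
    Mcur[wlo - 1] = Xcur[wlo - 1] = Ycur[wlo - 1] = NEG_INF;
    Mcur[whi + 1] = Xcur[whi + 1] = Ycur[whi + 1] = NEG_INF;
    const size_t row = (size_t)i * W;
    const int base_j = i + dlo;
    const int8_t qi = q[i];
    uint8_t *tM = tbM.data() + row, *tX = tbX.data() + row,
        *tY = tbY.data() + row;
    for (int w = wlo; w <= whi; ++w) {
      const int j = base_j + w;
      // M: predecessor (i-1, j-1) = prev row, same w
      const int pm = Mprev[w], px = Xprev[w], py = Yprev[w];
      int b = std::max(std::max(pm, px), std::max(py, 0));
      tM[w] = (uint8_t)((b == 0) ? 0 : (b == pm ? 1 : (b == px ? 2 : 3)));
      const int sub = (qi >= 0 && qi == s[j]) ? match : mismatch;
      const int mval = b + sub;
      Mcur[w] = mval;
      if (mval > best_score) { best_score = mval; best_i = i; best_w = w; }
      // X: gap in subject, predecessor (i-1, j) = prev row, w+1
      const int xm = Mprev[w + 1] - open_cost, xx = Xprev[w + 1] - gap_ext;
      Xcur[w] = std::max(xm, xx);
      tX[w] = (uint8_t)(xm >= xx ? 0 : 1);
      // Y: gap in query, predecessor (i, j-1) = same row, w-1
      const int ym = Mcur[w - 1] - open_cost, yy = Ycur[w - 1] - gap_ext;
      Ycur[w] = std::max(ym, yy);
      tY[w] = (uint8_t)(ym >= yy ? 0 : 1);
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }
  if (best_score <= 0) return best;

  best.score = best_score;
  // traceback from (best_i, best_w) in state M; predecessor cells in
  // (row, band) space: M(i,w) <- (i-1, w); X(i,w) <- (i-1, w+1);
  // Y(i,w) <- (i, w-1)
  int i = best_i, w = best_w, state = 0; // 0=M,1=X,2=Y
  best.q_end = best_i;
  best.s_end = best_i + dlo + best_w;
  while (true) {
    const size_t row = (size_t)i * W;
    if (state == 0) {
      int j = i + dlo + w;
      ++best.aln_cols;
      if (q[i] >= 0 && q[i] == s[j]) ++best.matches;
      uint8_t t = tbM[row + w];
      best.q_start = i; best.s_start = j;
      if (t == 0) break;
      state = (t == 1) ? 0 : (t == 2) ? 1 : 2;
      --i;
    } else if (state == 1) { // X: consumed q[i], gap in subject
      ++best.aln_cols;
      uint8_t t = tbX[row + w];
      state = (t == 0) ? 0 : 1;
      --i; ++w;
    } else { // Y: consumed s[j], gap in query
      ++best.aln_cols;
      uint8_t t = tbY[row + w];
      state = (t == 0) ? 0 : 2;
      --w;
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_sw_align(std::string query, std::string subject,
                  int match = 1, int mismatch = -1,
                  int gap_open = 5, int gap_ext = 1) {
  std::vector<int8_t> q = encode_seq(query), s = encode_seq(subject);
  Aln a = sw_banded(q, s, -(int)q.size(), (int)s.size(), match, mismatch,
                    gap_open, gap_ext);
  return List::create(
    _["score"] = a.score, _["matches"] = a.matches, _["aln_cols"] = a.aln_cols,
    _["q_start"] = a.q_start + 1, _["q_end"] = a.q_end + 1,
    _["s_start"] = a.s_start + 1, _["s_end"] = a.s_end + 1,
    _["identity"] = a.aln_cols > 0 ? 100.0 * a.matches / a.aln_cols : 0.0,
    _["q_aligned"] = a.q_end - a.q_start + 1);
}

// ---- k-mer machinery ------------------------------------------------------

static void seq_kmers(const std::vector<int8_t> &s, int k,
                      std::vector<std::pair<uint64_t, int> > &out) {
  out.clear();
  if ((int)s.size() < k) return;
  uint64_t kmer = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < (int)s.size(); ++i) {
    if (s[i] < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)s[i]) & mask;
    if (++run >= k) out.push_back(std::make_pair(kmer, i - k + 1));
  }
}

static std::vector<uint64_t> sorted_kmer_set(const std::vector<int8_t> &s, int k) {
  std::vector<std::pair<uint64_t, int> > kp;
  seq_kmers(s, k, kp);
  std::vector<uint64_t> v(kp.size());
  for (size_t i = 0; i < kp.size(); ++i) v[i] = kp[i].first;
  std::sort(v.begin(), v.end());
  v.erase(std::unique(v.begin(), v.end()), v.end());
  return v;
}

static bool share_kmer(const std::vector<uint64_t> &a, const std::vector<uint64_t> &b) {
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] == b[j]) return true;
    if (a[i] < b[j]) ++i; else ++j;
  }
  return false;
}

typedef std::unordered_map<uint64_t, std::vector<int> > PosMap;

static void build_pos_map(const std::vector<int8_t> &s, int k, PosMap &map) {
  map.clear();
  std::vector<std::pair<uint64_t, int> > kp;
  seq_kmers(s, k, kp);
  map.reserve(kp.size() * 2);
  for (size_t i = 0; i < kp.size(); ++i) map[kp[i].first].push_back(kp[i].second);
}

// fragment boundaries: starts of consecutive windows; final shorter piece
// kept only if >= min_tail
static void fragment_bounds(int len, int frag, int min_tail,
                            std::vector<std::pair<int, int> > &out) {
  out.clear();
  int pos = 0;
  while (pos + frag <= len) { out.push_back(std::make_pair(pos, frag)); pos += frag; }
  if (len - pos >= min_tail) out.push_back(std::make_pair(pos, len - pos));
}

struct FragAln {
  int offset = 0, frag_len = 0;
  bool aligned = false, retained = false;
  int matches = 0, aln_cols = 0, q_aligned = 0, score = 0;
};

// Align one fragment. mode 0 = seeded band, 1 = exhaustive full range.
static FragAln align_fragment(const std::vector<int8_t> &qfull, int off, int flen,
                              const std::vector<int8_t> &s, const PosMap *smap,
                              int mode, int k, int band_pad,
                              double min_frag_cov, double min_frag_id,
                              int match, int mismatch, int gap_open, int gap_ext) {
  FragAln fa; fa.offset = off; fa.frag_len = flen;
  std::vector<int8_t> frag(qfull.begin() + off, qfull.begin() + off + flen);
  int dlo, dhi;
  if (mode == 1) {
    dlo = -(flen - 1); dhi = (int)s.size() - 1;
  } else {
    // seed: diagonals d = s_pos - frag_pos of shared k-mers
    std::vector<std::pair<uint64_t, int> > kp;
    seq_kmers(frag, k, kp);
    std::vector<int> ds;
    for (size_t i = 0; i < kp.size(); ++i) {
      PosMap::const_iterator it = smap->find(kp[i].first);
      if (it == smap->end()) continue;
      for (size_t t = 0; t < it->second.size(); ++t)
        ds.push_back(it->second[t] - kp[i].second);
    }
    if (ds.empty()) return fa;
    std::sort(ds.begin(), ds.end());
    int med = ds[ds.size() / 2];
    int lo = med, hi = med;
    for (size_t i = 0; i < ds.size(); ++i) {
      if (std::abs(ds[i] - med) <= 1000) { lo = std::min(lo, ds[i]); hi = std::max(hi, ds[i]); }
    }
    dlo = lo - band_pad; dhi = hi + band_pad;
    if (dhi - dlo + 1 > 5000) { dlo = med - 2500; dhi = med + 2500; }
  }
  Aln a = sw_banded(frag, s, dlo, dhi, match, mismatch, gap_open, gap_ext);
  if (a.aln_cols == 0) return fa;
  fa.aligned = true;
  fa.matches = a.matches; fa.aln_cols = a.aln_cols; fa.score = a.score;
  fa.q_aligned = a.q_end - a.q_start + 1;
  double cov = (double)fa.q_aligned / flen;
  double id = (double)fa.matches / fa.aln_cols;
  fa.retained = (cov >= min_frag_cov && id >= min_frag_id);
  return fa;
}

static void summarize_pair(const std::vector<FragAln> &frags, int qlen,
                           double &identity, double &coverage, int &n_retained) {
  long matches = 0, cols = 0, qbases = 0;
  n_retained = 0;
  for (size_t i = 0; i < frags.size(); ++i) {
    if (!frags[i].retained) continue;
    ++n_retained;
    matches += frags[i].matches;
    cols += frags[i].aln_cols;
    qbases += frags[i].q_aligned;
  }
  identity = (cols > 0) ? 100.0 * matches / cols : 0.0;
  coverage = (qlen > 0) ? 100.0 * qbases / qlen : 0.0;
}

// [[Rcpp::export]]
List cpp_ani_pair(std::string query, std::string subject,
                  int fragment_size, int min_tail,
                  double min_frag_cov, double min_frag_id,
                  int match, int mismatch, int gap_open, int gap_ext,
                  int mode, int k, int band_pad) {
  std::vector<int8_t> q = encode_seq(query), s = encode_seq(subject);
  std::vector<std::pair<int, int> > fb;
  fragment_bounds((int)q.size(), fragment_size, min_tail, fb);
  PosMap smap;
  if (mode == 0) build_pos_map(s, k, smap);
  std::vector<FragAln> frags;
  for (size_t f = 0; f < fb.size(); ++f)
    frags.push_back(align_fragment(q, fb[f].first, fb[f].second, s, &smap,
                                   mode, k, band_pad, min_frag_cov, min_frag_id,
                                   match, mismatch, gap_open, gap_ext));
  double identity, coverage; int n_ret;
  summarize_pair(frags, (int)q.size(), identity, coverage, n_ret);
  int nf = (int)frags.size();
  IntegerVector offset(nf), frag_len(nf), matches(nf), aln_cols(nf),
      q_aligned(nf), score(nf);
  LogicalVector aligned(nf), retained(nf);
  NumericVector frag_identity(nf);
  for (int i = 0; i < nf; ++i) {
    offset[i] = frags[i].offset + 1; frag_len[i] = frags[i].frag_len;
    matches[i] = frags[i].matches; aln_cols[i] = frags[i].aln_cols;
    q_aligned[i] = frags[i].q_aligned; score[i] = frags[i].score;
    aligned[i] = frags[i].aligned; retained[i] = frags[i].retained;
    frag_identity[i] = frags[i].aln_cols > 0 ?
        100.0 * frags[i].matches / frags[i].aln_cols : NA_REAL;
  }
  return List::create(
    _["identity"] = identity, _["coverage"] = coverage,
    _["n_fragments"] = nf, _["n_fragments_retained"] = n_ret,
    _["fragments"] = DataFrame::create(
        _["offset"] = offset, _["frag_len"] = frag_len,
        _["aligned"] = aligned, _["retained"] = retained,
        _["identity"] = frag_identity, _["matches"] = matches,
        _["aln_cols"] = aln_cols, _["q_aligned"] = q_aligned,
        _["score"] = score));
}

// [[Rcpp::export]]
List cpp_ani_matrix(CharacterVector seqs,
                    int fragment_size, int min_tail,
                    double min_frag_cov, double min_frag_id,
                    int match, int mismatch, int gap_open, int gap_ext,
                    int mode, int k, int band_pad) {
  const int n = seqs.size();
  std::vector<std::vector<int8_t> > enc(n);
  std::vector<std::vector<uint64_t> > ksets(n);
  for (int i = 0; i < n; ++i) {
    enc[i] = encode_seq(as<std::string>(seqs[i]));
    if (mode == 0) ksets[i] = sorted_kmer_set(enc[i], k);
  }
  NumericMatrix identity(n, n), coverage(n, n);
  IntegerMatrix nfrag(n, n);
  PosMap smap;
  for (int sj = 0; sj < n; ++sj) {
    bool map_built = false;
    for (int qi = 0; qi < n; ++qi) {
      std::vector<std::pair<int, int> > fb;
      fragment_bounds((int)enc[qi].size(), fragment_size, min_tail, fb);
      if (mode == 0 && qi != sj && !share_kmer(ksets[qi], ksets[sj])) {
        identity(qi, sj) = 0.0; coverage(qi, sj) = 0.0; nfrag(qi, sj) = 0;
        continue;
      }
      if (mode == 0 && !map_built) { build_pos_map(enc[sj], k, smap); map_built = true; }
      std::vector<FragAln> frags;
      for (size_t f = 0; f < fb.size(); ++f)
        frags.push_back(align_fragment(enc[qi], fb[f].first, fb[f].second,
                                       enc[sj], &smap, mode, k, band_pad,
                                       min_frag_cov, min_frag_id,
                                       match, mismatch, gap_open, gap_ext));
      double id, cov; int nr;
      summarize_pair(frags, (int)enc[qi].size(), id, cov, nr);
      identity(qi, sj) = id; coverage(qi, sj) = cov; nfrag(qi, sj) = nr;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["identity"] = identity, _["coverage"] = coverage,
                      _["n_fragments_retained"] = nfrag);
}
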