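#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Local pairwise alignment used throughout the pipeline. Two paths share one
// scoring scheme (match/mismatch, affine gaps with cost open + ext * len):
//  - exact: full affine-gap Smith-Waterman with traceback, used when the DP
//    matrix is small enough; reports the single best local alignment.
//  - seeded: exact k-mer seeds extended by ungapped X-drop in both
//    directions, used for large subjects; reports every locally maximal
//    gapless hit above the score floor. The data this package aligns are
//    substitution-dominated, so gapless extension is the operative regime.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'a': c = 'T'; break;
      case 'C': c = 'G'; break; case 'c': c = 'G'; break;
      case 'G': c = 'C'; break; case 'g': c = 'C'; break;
      case 'T': c = 'A'; break; case 't': c = 'A'; break;
      default:  c = 'N';
    }
  }
  return r;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp(s); }

struct Hit {
  int q_start, q_end, s_start, s_end;
  char strand;
  int matches, columns, score;
};

// ---------- exact affine-gap local alignment (best hit, with traceback) ----

// traceback codes
enum { TB_NONE = 0, TB_DIAG = 1, TB_UP = 2, TB_LEFT = 3 };

static bool exact_local(const std::string& q, const std::string& s,
                        int match, int mismatch, int gap_open, int gap_extend,
                        Hit& out) {
  const int n = (int)q.size(), m = (int)s.size();
  const int NEG = -1000000000;
  // three-state affine DP; H = best ending in match/mismatch, E = gap in
  // query (consume subject), F = gap in subject (consume query)
  std::vector<int> Hrow(m + 1, 0), Erow(m + 1, NEG);
  std::vector<int> Hprev(m + 1, 0);
  // traceback matrices: state at (i,j) for H, plus whether E/F extended
  std::vector<uint8_t> tbH((size_t)(n + 1) * (m + 1), TB_NONE);
  std::vector<uint8_t> tbE((size_t)(n + 1) * (m + 1), 0); // 1 = extend
  std::vector<uint8_t> tbF((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> Eprev(m + 1, NEG);

  int best = 0, bi = 0, bj = 0;
  std::vector<int> Fcol(m + 1, NEG);

  // we store H of previous row in Hprev, E previous row in Eprev
  std::vector<int> Hcur(m + 1, 0), Ecur(m + 1, NEG);
  std::vector<std::vector<int>> Hall;  // full H for traceback of F/E states
  // For traceback we only need directions, which we record as we go.
  for (int j = 0; j <= m; ++j) { Hprev[j] = 0; Eprev[j] = NEG; }
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0; Ecur[0] = NEG; int F = NEG;
    for (int j = 1; j <= m; ++j) {
      // E: gap in query, coming from left (consumes subject)
      int e_open = Hcur[j - 1] - gap_open - gap_extend;
      int e_ext  = Ecur[j - 1] - gap_extend;
      int E = std::max(e_open, e_ext);
      tbE[(size_t)i * (m + 1) + j] = (e_ext > e_open) ? 1 : 0;
      // F: gap in subject, coming from above (consumes query)
      int f_open = Hprev[j] - gap_open - gap_extend;
      int f_ext  = F - gap_extend;
      // F here refers to previous j in same row? no: F must be per column.
      // use Fcol[j]: best F ending at (i-1, j) extended down
      f_ext = Fcol[j] - gap_extend;
      int Fv = std::max(f_open, f_ext);
      tbF[(size_t)i * (m + 1) + j] = (f_ext > f_open) ? 1 : 0;
      Fcol[j] = Fv;
      // H
      int qa = base_code(q[i - 1]), sb = base_code(s[j - 1]);
      int sub = (qa >= 0 && sb >= 0 && qa == sb) ? match : mismatch;
      int diag = Hprev[j - 1] + sub;
      int h = 0; uint8_t dir = TB_NONE;
      if (diag > h) { h = diag; dir = TB_DIAG; }
      if (E > h)    { h = E;    dir = TB_LEFT; }
      if (Fv > h)   { h = Fv;   dir = TB_UP; }
      Hcur[j] = h; Ecur[j] = E;
      tbH[(size_t)i * (m + 1) + j] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur);
  }
  if (best <= 0) return false;

  // traceback from (bi, bj); state machine over H/E/F using recorded dirs.
  // Re-run is avoided: tb matrices suffice because E/F extension flags tell
  // how far each gap run goes.
  int i = bi, j = bj, state = 0; // 0=H,1=E(left),2=F(up)
  int matches = 0, columns = 0;
  int qe = bi, se = bj;
  while (i > 0 && j > 0) {
    if (state == 0) {
      uint8_t d = tbH[(size_t)i * (m + 1) + j];
      if (d == TB_NONE) break;
      if (d == TB_DIAG) {
        int qa = base_code(q[i - 1]), sb = base_code(s[j - 1]);
        if (qa >= 0 && qa == sb) ++matches;
        ++columns; --i; --j;
      } else if (d == TB_LEFT) { state = 1; }
      else { state = 2; }
    } else if (state == 1) {
      // gap consumes subject base
      uint8_t ext = tbE[(size_t)i * (m + 1) + j];
      ++columns; --j;
      if (!ext) state = 0;
    } else {
      uint8_t ext = tbF[(size_t)i * (m + 1) + j];
      ++columns; --i;
      if (!ext) state = 0;
    }
  }
  out.q_start = i; out.q_end = qe;
  out.s_start = j; out.s_end = se;
  out.matches = matches; out.columns = columns; out.score = best;
  return true;
}

// ---------- seeded gapless extension ---------------------------------------

// Combined index over all subjects so that each query is scanned once.
// Packed key: kmer (2k bits, k <= 21) << 42 | subject (21 bits) << 21 |
// position (21 bits): subjects up to 2^21 sequences of up to 2 Mb each.
struct SubjectIndex {
  int k;
  std::vector<uint64_t> keys;
};

static void build_combined_index(const std::vector<std::string>& subs,
                                 const std::vector<bool>& include,
                                 int k, SubjectIndex& idx) {
  idx.k = k;
  idx.keys.clear();
  uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t j = 0; j < subs.size(); ++j) {
    if (!include[j]) continue;
    const std::string& s = subs[j];
    const int m = (int)s.size();
    if (m < k) continue;
    uint64_t kmer = 0; int run = 0;
    for (int p = 0; p < m; ++p) {
      int c = base_code(s[p]);
      if (c < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++run >= k) {
        idx.keys.push_back((kmer << 42) | ((uint64_t)j << 21) |
                           (uint64_t)(p - k + 1));
      }
    }
  }
  std::sort(idx.keys.begin(), idx.keys.end());
}

struct Seed { int subj, qpos, spos; };

static void seeded_all(const std::string& q,
                       const std::vector<std::string>& subs,
                       const SubjectIndex& idx,
                       int match, int mismatch, int x_drop, int min_score,
                       int max_occ, char strand, int qlen_fwd,
                       std::vector<std::pair<int, Hit>>& out) {
  const int k = idx.k;
  const int n = (int)q.size();
  if (n < k || idx.keys.empty()) return;
  std::vector<std::pair<int64_t, Seed>> seeds; // key = subj<<40 | diag<<20...
  uint64_t kmer = 0, mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(q[i]);
    if (c < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)c) & mask;
    if (++run < k) continue;
    int qpos = i - k + 1;
    uint64_t lo = (kmer << 42), hi = (kmer << 42) | ((1ULL << 42) - 1);
    auto it0 = std::lower_bound(idx.keys.begin(), idx.keys.end(), lo);
    auto it1 = std::upper_bound(it0, idx.keys.end(), hi);
    if (it1 - it0 > max_occ) continue;
    for (auto it = it0; it != it1; ++it) {
      int subj = (int)((*it >> 21) & 0x1FFFFF);
      int spos = (int)(*it & 0x1FFFFF);
      int64_t diag = (int64_t)spos - qpos + n;   // in [0, n + m)
      int64_t key = ((int64_t)subj << 44) | (diag << 21) | qpos;
      seeds.push_back({key, {subj, qpos, spos}});
    }
  }
  std::sort(seeds.begin(), seeds.end(),
            [](const std::pair<int64_t, Seed>& a,
               const std::pair<int64_t, Seed>& b) {
              return a.first < b.first;
            });
  int64_t cur_group = -1; int covered_end = -1;
  for (auto& sp : seeds) {
    int64_t group = sp.first >> 21;  // subj + diagonal
    int qpos = sp.second.qpos, spos = sp.second.spos;
    const std::string& s = subs[sp.second.subj];
    const int m = (int)s.size();
    if (group != cur_group) { cur_group = group; covered_end = -1; }
    if (qpos < covered_end) continue;
    // ungapped X-drop extension anchored on the exact k-mer
    int score = k * match, best = score;
    int qi = qpos + k, si = spos + k;
    int best_q_end = qi, best_s_end = si;
    while (qi < n && si < m) {
      int a = base_code(q[qi]), b = base_code(s[si]);
      score += (a >= 0 && a == b) ? match : mismatch;
      ++qi; ++si;
      if (score > best) { best = score; best_q_end = qi; best_s_end = si; }
      if (score < best - x_drop) break;
    }
    score = best;
    int qj = qpos, sj = spos;
    int best_q_start = qj, best_s_start = sj;
    while (qj > 0 && sj > 0) {
      int a = base_code(q[qj - 1]), b = base_code(s[sj - 1]);
      score += (a >= 0 && a == b) ? match : mismatch;
      --qj; --sj;
      if (score > best) { best = score; best_q_start = qj; best_s_start = sj; }
      if (score < best - x_drop) break;
    }
    covered_end = best_q_end;
    if (best < min_score) continue;
    int cols = best_q_end - best_q_start;
    int matches = 0;
    for (int t = 0; t < cols; ++t) {
      int a = base_code(q[best_q_start + t]), b = base_code(s[best_s_start + t]);
      if (a >= 0 && a == b) ++matches;
    }
    Hit h;
    if (strand == '+') { h.q_start = best_q_start; h.q_end = best_q_end; }
    else { h.q_start = qlen_fwd - best_q_end; h.q_end = qlen_fwd - best_q_start; }
    h.s_start = best_s_start; h.s_end = best_s_end;
    h.strand = strand; h.matches = matches; h.columns = cols; h.score = best;
    out.push_back({sp.second.subj, h});
  }
}

// Align each query against each subject on both strands.
// mode: 0 = auto, 1 = exact, 2 = seeded
// [[Rcpp::export]]
DataFrame cpp_local_align(CharacterVector queries, CharacterVector subjects,
                          int match, int mismatch, int gap_open, int gap_extend,
                          int k, int min_score, int x_drop, int max_occ,
                          double exact_cells, int mode) {
  std::vector<int> out_q, out_s;
  std::vector<int> qs, qe, ss, se, mt, cols, sc;
  std::vector<char> str;

  int nsub = subjects.size();
  std::vector<std::string> subs(nsub);
  for (int j = 0; j < nsub; ++j) subs[j] = as<std::string>(subjects[j]);

  // decide exact vs seeded per (query, subject); subjects needed by any
  // seeded pair enter one combined index so each query is scanned once
  std::vector<std::string> qf(queries.size()), qr(queries.size());
  for (int i = 0; i < queries.size(); ++i) {
    qf[i] = as<std::string>(queries[i]);
    qr[i] = revcomp(qf[i]);
  }
  std::vector<bool> seeded_subj(nsub, false);
  std::vector<std::vector<bool>> use_exact(queries.size(),
                                           std::vector<bool>(nsub, false));
  // auto mode picks the exact DP only when both the pair and the batch
  // are small; large batches always go through the seeded index
  bool small_batch = (double)qf.size() * nsub <= 256;
  for (int i = 0; i < (int)qf.size(); ++i) {
    for (int j = 0; j < nsub; ++j) {
      bool ex;
      if (mode == 1) ex = true;
      else if (mode == 2) ex = false;
      else ex = small_batch &&
        ((double)qf[i].size() * (double)subs[j].size() <= exact_cells);
      use_exact[i][j] = ex;
      if (!ex) seeded_subj[j] = true;
    }
  }
  SubjectIndex idx;
  bool any_seeded = false;
  for (int j = 0; j < nsub; ++j) if (seeded_subj[j]) any_seeded = true;
  if (any_seeded) build_combined_index(subs, seeded_subj, k, idx);

  auto emit = [&](int i, int j, const Hit& h) {
    out_q.push_back(i + 1); out_s.push_back(j + 1);
    qs.push_back(h.q_start); qe.push_back(h.q_end);
    ss.push_back(h.s_start); se.push_back(h.s_end);
    mt.push_back(h.matches); cols.push_back(h.columns);
    sc.push_back(h.score); str.push_back(h.strand);
  };

  std::vector<std::pair<int, Hit>> shits;
  for (int i = 0; i < (int)qf.size(); ++i) {
    // exact pairs
    for (int j = 0; j < nsub; ++j) {
      if (!use_exact[i][j]) continue;
      Hit h;
      if (exact_local(qf[i], subs[j], match, mismatch, gap_open, gap_extend,
                      h) && h.score >= min_score) {
        h.strand = '+'; emit(i, j, h);
      }
      if (exact_local(qr[i], subs[j], match, mismatch, gap_open, gap_extend,
                      h) && h.score >= min_score) {
        int n = (int)qf[i].size();
        int a = h.q_start, b = h.q_end;
        h.q_start = n - b; h.q_end = n - a; h.strand = '-';
        emit(i, j, h);
      }
    }
    // seeded pairs via the combined index
    if (any_seeded) {
      shits.clear();
      seeded_all(qf[i], subs, idx, match, mismatch, x_drop, min_score,
                 max_occ, '+', (int)qf[i].size(), shits);
      seeded_all(qr[i], subs, idx, match, mismatch, x_drop, min_score,
                 max_occ, '-', (int)qf[i].size(), shits);
      for (auto& sh : shits) {
        if (use_exact[i][sh.first]) continue;  // already handled exactly
        emit(i, sh.first, sh.second);
      }
    }
  }
  int nh = (int)out_q.size();
  CharacterVector strand_out(nh);
  for (int t = 0; t < nh; ++t) strand_out[t] = (str[t] == '+') ? "+" : "-";
  return DataFrame::create(
    _["query"] = wrap(out_q), _["subject"] = wrap(out_s),
    _["q_start"] = wrap(qs), _["q_end"] = wrap(qe),
    _["s_start"] = wrap(ss), _["s_end"] = wrap(se),
    _["strand"] = strand_out,
    _["matches"] = wrap(mt), _["length"] = wrap(cols),
    _["score"] = wrap(sc),
    _["stringsAsFactors"] = false);
}
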