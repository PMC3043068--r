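#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <vector>
#include <string>
#include <array>
#include <algorithm>
using namespace Rcpp;

// Greedy overlap-layout-consensus assembler. Contigs are grown from seed
// reads by repeatedly merging the best-scoring suffix-prefix overlap (both
// strands, substitution-tolerant), with a per-column vote pileup providing a
// majority consensus. Reads are processed in a canonical order (length
// descending, then id), so the result is invariant to input shuffling.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}
static const char CODE2BASE[5] = {'A', 'C', 'G', 'T', 'N'};

static std::string rc(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'C': c = 'G'; break;
      case 'G': c = 'C'; break; case 'T': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

struct KIndex {
  int k, step;
  // sorted keys: kmer<<40 | read<<19 | pos<<1 | strand   (pos < 2^18, read < 2^21)
  std::vector<uint64_t> keys;
};

struct Cand { int read; int strand; long offset; };

// [[Rcpp::export]]
List cpp_greedy_assemble(CharacterVector reads, CharacterVector ids,
                         int min_overlap, double min_identity,
                         int match, int mismatch, int kk, int sample_step) {
  const int n = reads.size();
  std::vector<std::string> fwd(n), rev(n);
  std::vector<std::string> idv(n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = as<std::string>(reads[i]);
    rev[i] = rc(fwd[i]);
    idv[i] = as<std::string>(ids[i]);
  }

  // canonical processing order: longest first, then id ascending
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (fwd[a].size() != fwd[b].size()) return fwd[a].size() > fwd[b].size();
    return idv[a] < idv[b];
  });

  // k-mer index over both strands of every read
  KIndex idx; idx.k = kk; idx.step = sample_step;
  const uint64_t mask = (kk >= 32) ? ~0ULL : ((1ULL << (2 * kk)) - 1);
  for (int i = 0; i < n; ++i) {
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& s = strand ? rev[i] : fwd[i];
      const int m = (int)s.size();
      uint64_t kmer = 0; int run = 0;
      for (int j = 0; j < m; ++j) {
        int c = base_code(s[j]);
        if (c < 0) { run = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)c) & mask;
        if (++run < kk) continue;
        int pos = j - kk + 1;
        if (pos % sample_step != 0) continue;
        idx.keys.push_back((kmer << 40) | ((uint64_t)i << 19) |
                           ((uint64_t)pos << 1) | (uint64_t)strand);
      }
    }
  }
  std::sort(idx.keys.begin(), idx.keys.end());

  std::vector<bool> used(n, false);
  std::vector<std::string> contigs;
  std::vector<std::vector<std::string>> members;

  // contig under construction: votes[pos][base]
  std::vector<std::array<uint16_t, 4>> votes;
  std::string cons;

  auto add_votes = [&](const std::string& r, long offset) {
    // ensure capacity
    long new_start = std::min(0L, offset);
    long new_end = std::max((long)cons.size(), offset + (long)r.size());
    if (new_start < 0) {
      size_t grow = (size_t)(-new_start);
      votes.insert(votes.begin(), grow, {0, 0, 0, 0});
      cons.insert(0, grow, 'N');
      offset += grow; new_end += grow;
    }
    if (new_end > (long)cons.size()) {
      votes.resize(new_end, {0, 0, 0, 0});
      cons.resize(new_end, 'N');
    }
    for (size_t t = 0; t < r.size(); ++t) {
      int c = base_code(r[t]);
      if (c < 0) continue;
      size_t p = (size_t)(offset + t);
      if (votes[p][c] < 65535) votes[p][c]++;
      // majority consensus; ties keep the current base
      int cur = base_code(cons[p]);
      if (cur < 0 || votes[p][c] > votes[p][cur]) cons[p] = CODE2BASE[c];
    }
  };

  // find candidate reads overlapping one end of cons
  auto find_cands = [&](bool right_end, std::vector<Cand>& cands) {
    cands.clear();
    const long clen = (long)cons.size();
    long w0 = right_end ? std::max(0L, clen - 600) : 0;
    long w1 = right_end ? clen : std::min(clen, 600L);
    uint64_t kmer = 0; int run = 0;
    std::vector<uint64_t> seen; // (read<<33)|(strand<<32)|(offset+2^30)
    for (long j = w0; j < w1; ++j) {
      int c = base_code(cons[(size_t)j]);
      if (c < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++run < idx.k) continue;
      long cpos = j - idx.k + 1;
      uint64_t lo = (kmer << 40), hi = (kmer << 40) | ((1ULL << 40) - 1);
      auto it0 = std::lower_bound(idx.keys.begin(), idx.keys.end(), lo);
      auto it1 = std::upper_bound(it0, idx.keys.end(), hi);
      if (it1 - it0 > 2000) continue;
      for (auto it = it0; it != it1; ++it) {
        int read = (int)((*it >> 19) & 0x1FFFFF);
        if (used[read]) continue;
        int pos = (int)((*it >> 1) & 0x3FFFF);
        int strand = (int)(*it & 1);
        long offset = cpos - pos;
        const std::string& r = strand ? rev[read] : fwd[read];
        long rlen = (long)r.size();
        if (right_end) { if (offset + rlen <= clen) continue; }
        else { if (offset >= 0) continue; }
        uint64_t key = ((uint64_t)read << 33) | ((uint64_t)strand << 32) |
                       (uint64_t)(offset + (1L << 30));
        if (std::find(seen.begin(), seen.end(), key) != seen.end()) continue;
        seen.push_back(key);
        cands.push_back({read, strand, offset});
      }
    }
  };

  // evaluate overlap of candidate against consensus; returns score or INT_MIN
  auto eval_cand = [&](const Cand& cd, int& overlap_out) -> long {
    const std::string& r = cd.strand ? rev[cd.read] : fwd[cd.read];
    const long clen = (long)cons.size(), rlen = (long)r.size();
    long o0 = std::max(0L, cd.offset), o1 = std::min(clen, cd.offset + rlen);
    long ov = o1 - o0;
    overlap_out = (int)ov;
    if (ov < min_overlap) return LONG_MIN;
    long mt = 0, mm = 0;
    for (long p = o0; p < o1; ++p) {
      int a = base_code(cons[(size_t)p]);
      int b = base_code(r[(size_t)(p - cd.offset)]);
      if (a < 0 || b < 0) { ++mm; continue; }
      if (a == b) ++mt; else ++mm;
    }
    if ((double)mt / (double)ov < min_identity) return LONG_MIN;
    return (long)match * mt + (long)mismatch * mm;
  };

  std::vector<Cand> cands;
  for (int oi = 0; oi < n; ++oi) {
    int seed = order[oi];
    if (used[seed]) continue;
    used[seed] = true;
    votes.clear(); cons.clear();
    add_votes(fwd[seed], 0);
    std::vector<std::string> mem; mem.push_back(idv[seed]);

    // absorb unused reads fully contained in the current consensus
    auto absorb_contained = [&]() {
      const long clen = (long)cons.size();
      uint64_t kmer = 0; int run = 0;
      std::vector<uint64_t> seen;
      for (long j = 0; j < clen; ++j) {
        int c = base_code(cons[(size_t)j]);
        if (c < 0) { run = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)c) & mask;
        if (++run < idx.k) continue;
        long cpos = j - idx.k + 1;
        uint64_t lo = (kmer << 40), hi = (kmer << 40) | ((1ULL << 40) - 1);
        auto it0 = std::lower_bound(idx.keys.begin(), idx.keys.end(), lo);
        auto it1 = std::upper_bound(it0, idx.keys.end(), hi);
        if (it1 - it0 > 2000) continue;
        for (auto it = it0; it != it1; ++it) {
          int read = (int)((*it >> 19) & 0x1FFFFF);
          if (used[read]) continue;
          int pos = (int)((*it >> 1) & 0x3FFFF);
          int strand = (int)(*it & 1);
          long offset = cpos - pos;
          const std::string& r = strand ? rev[read] : fwd[read];
          long rlen = (long)r.size();
          if (offset < 0 || offset + rlen > clen) continue;
          uint64_t key = ((uint64_t)read << 33) | ((uint64_t)strand << 32) |
                         (uint64_t)(offset + (1L << 30));
          if (std::find(seen.begin(), seen.end(), key) != seen.end())
            continue;
          seen.push_back(key);
          long mt = 0;
          for (long t = 0; t < rlen; ++t) {
            int a = base_code(cons[(size_t)(offset + t)]);
            int b = base_code(r[(size_t)t]);
            if (a >= 0 && b >= 0 && a == b) ++mt;
          }
          if ((double)mt / (double)rlen < min_identity) continue;
          add_votes(r, offset);
          used[read] = true;
          mem.push_back(idv[read]);
        }
      }
    };

    for (int side = 0; side < 2; ++side) {
      bool right_end = (side == 0);
      while (true) {
        find_cands(right_end, cands);
        long best_score = LONG_MIN; int best_ov = -1; int best_i = -1;
        for (size_t t = 0; t < cands.size(); ++t) {
          int ov;
          long sc = eval_cand(cands[t], ov);
          if (sc == LONG_MIN) continue;
          bool better = false;
          if (sc > best_score) better = true;
          else if (sc == best_score && best_i >= 0) {
            if (ov > best_ov) better = true;
            else if (ov == best_ov &&
                     idv[cands[t].read] < idv[cands[best_i].read]) better = true;
          }
          if (better) { best_score = sc; best_ov = ov; best_i = (int)t; }
        }
        if (best_i < 0) break;
        const Cand& cd = cands[best_i];
        const std::string& r = cd.strand ? rev[cd.read] : fwd[cd.read];
        add_votes(r, cd.offset);
        used[cd.read] = true;
        mem.push_back(idv[cd.read]);
      }
    }
    absorb_contained();
    // canonical orientation: lexicographically smaller of cons / rc(cons)
    std::string c2 = rc(cons);
    contigs.push_back(std::min(cons, c2));
    members.push_back(mem);
  }

  // canonical output order: length descending, then sequence
  std::vector<int> co(contigs.size());
  for (size_t i = 0; i < co.size(); ++i) co[i] = (int)i;
  std::sort(co.begin(), co.end(), [&](int a, int b) {
    if (contigs[a].size() != contigs[b].size())
      return contigs[a].size() > contigs[b].size();
    return contigs[a] < contigs[b];
  });
  CharacterVector out_seq(co.size());
  List out_mem(co.size());
  for (size_t i = 0; i < co.size(); ++i) {
    out_seq[i] = contigs[co[i]];
    out_mem[i] = wrap(members[co[i]]);
  }
  return List::create(_["bases"] = out_seq, _["members"] = out_mem);
}
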