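#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Ungapped seed-and-extend search over plus-strand sequence pairs.
// Substitution-only alignments live on a single diagonal, so seeding by
// exact k-mer match and X-drop extension along the diagonal is exact enough
// for the desk-scale searches this package performs. Karlin-Altschul
// parameters below are the blastn ungapped values for match +1 / mismatch -2;
// only the relative ranking of hits matters downstream.
static const double KA_LAMBDA = 1.28;
static const double KA_K = 0.46;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': case 'U': case 'u': return 3;
  default: return -1;
  }
}

static std::vector<std::vector<int8_t>> encode_all(const CharacterVector& seqs) {
  std::vector<std::vector<int8_t>> out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    size_t L = std::strlen(s);
    out[i].resize(L);
    for (size_t j = 0; j < L; ++j) out[i][j] = (int8_t) base_code(s[j]);
  }
  return out;
}

struct RawHit {
  int q, s;
  int qs, qe, ss, se;   // 0-based inclusive
  int len, mism;
  double bit, eval;
};

// [[Rcpp::export(name = ".cpp_seed_extend")]]
DataFrame cpp_seed_extend(CharacterVector query_seq, CharacterVector subject_seq,
                          int word_size, int min_align_len, double max_evalue,
                          int match, int mismatch, int xdrop) {
  if (word_size < 8 || word_size > 31) stop("word_size must be in [8, 31]");
  std::vector<std::vector<int8_t>> Q = encode_all(query_seq);
  std::vector<std::vector<int8_t>> S = encode_all(subject_seq);

  double m_tot = 0, n_tot = 0;
  for (auto& q : Q) m_tot += q.size();
  for (auto& s : S) n_tot += s.size();

  const uint64_t mask = (word_size == 32) ? ~0ULL : ((1ULL << (2 * word_size)) - 1);

  // subject k-mer index: hash -> packed (subject index << 32 | position)
  std::unordered_map<uint64_t, std::vector<uint64_t>> index;
  index.reserve((size_t) n_tot);
  for (size_t si = 0; si < S.size(); ++si) {
    const std::vector<int8_t>& s = S[si];
    if ((int) s.size() < word_size) continue;
    uint64_t h = 0; int run = 0;
    for (size_t j = 0; j < s.size(); ++j) {
      if (s[j] < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t) s[j]) & mask;
      if (++run >= word_size) {
        size_t pos = j - word_size + 1;
        index[h].push_back(((uint64_t) si << 32) | (uint64_t) pos);
      }
    }
  }

  std::vector<RawHit> hits;
  const int64_t DIAG_OFF = 1LL << 30;

  for (size_t qi = 0; qi < Q.size(); ++qi) {
    const std::vector<int8_t>& q = Q[qi];
    int qlen = (int) q.size();
    if (qlen < word_size) continue;

    // diagonal key -> query seed positions
    std::unordered_map<uint64_t, std::vector<int>> seeds;
    uint64_t h = 0; int run = 0;
    for (int j = 0; j < qlen; ++j) {
      if (q[j] < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t) q[j]) & mask;
      if (++run < word_size) continue;
      int qpos = j - word_size + 1;
      auto it = index.find(h);
      if (it == index.end()) continue;
      for (uint64_t packed : it->second) {
        int si = (int) (packed >> 32);
        int spos = (int) (packed & 0xffffffffULL);
        uint64_t key = ((uint64_t) si << 32) |
          (uint64_t) (uint32_t) ((int64_t) qpos - spos + DIAG_OFF);
        seeds[key].push_back(qpos);
      }
    }

    for (auto& kv : seeds) {
      int si = (int) (kv.first >> 32);
      int64_t diag = (int64_t) (uint32_t) (kv.first & 0xffffffffULL) - DIAG_OFF;
      const std::vector<int8_t>& s = S[si];
      int slen = (int) s.size();
      std::vector<int>& qps = kv.second;
      std::sort(qps.begin(), qps.end());
      int covered = -1;
      for (int q0 : qps) {
        if (q0 <= covered) continue;
        int s0 = (int) (q0 - diag);
        // extend right from end of seed
        int score = word_size * match, best = score;
        int i = q0 + word_size, j = s0 + word_size;
        int best_q_r = q0 + word_size - 1;
        while (i < qlen && j < slen) {
          score += (q[i] >= 0 && q[i] == s[j]) ? match : -mismatch;
          if (score > best) { best = score; best_q_r = i; }
          if (best - score > xdrop) break;
          ++i; ++j;
        }
        // extend left from start of seed
        score = best;
        int best_q_l = q0;
        i = q0 - 1; j = s0 - 1;
        while (i >= 0 && j >= 0) {
          score += (q[i] >= 0 && q[i] == s[j]) ? match : -mismatch;
          if (score > best) { best = score; best_q_l = i; }
          if (best - score > xdrop) break;
          --i; --j;
        }
        int qs = best_q_l, qe = best_q_r;
        int len = qe - qs + 1;
        covered = qe;
        if (len < min_align_len) continue;
        int matches = 0;
        for (int t = 0; t < len; ++t)
          if (q[qs + t] >= 0 && q[qs + t] == s[(int) (qs - diag) + t]) ++matches;
        int mism = len - matches;
        double raw = (double) matches * match - (double) mism * mismatch;
        double bit = (KA_LAMBDA * raw - std::log(KA_K)) / std::log(2.0);
        double eval = m_tot * n_tot * std::exp(-bit * std::log(2.0));
        if (eval > max_evalue) continue;
        RawHit hh;
        hh.q = (int) qi; hh.s = si;
        hh.qs = qs; hh.qe = qe;
        hh.ss = (int) (qs - diag); hh.se = (int) (qe - diag);
        hh.len = len; hh.mism = mism; hh.bit = bit; hh.eval = eval;
        hits.push_back(hh);
      }
    }
  }

  size_t N = hits.size();
  IntegerVector qidx(N), sidx(N), alen(N), mismv(N), qstart(N), qend(N),
    sstart(N), send(N);
  NumericVector pident(N), evalv(N), bitv(N);
  for (size_t i = 0; i < N; ++i) {
    const RawHit& hh = hits[i];
    qidx[i] = hh.q + 1; sidx[i] = hh.s + 1;
    pident[i] = 100.0 * (hh.len - hh.mism) / hh.len;
    alen[i] = hh.len; mismv[i] = hh.mism;
    qstart[i] = hh.qs + 1; qend[i] = hh.qe + 1;
    sstart[i] = hh.ss + 1; send[i] = hh.se + 1;
    evalv[i] = hh.eval; bitv[i] = hh.bit;
  }
  return DataFrame::create(
    _["query_idx"] = qidx, _["subject_idx"] = sidx, _["pct_identity"] = pident,
    _["align_len"] = alen, _["mismatches"] = mismv,
    _["q_start"] = qstart, _["q_end"] = qend,
    _["s_start"] = sstart, _["s_end"] = send,
    _["evalue"] = evalv, _["bitscore"] = bitv);
}
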