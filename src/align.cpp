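#include <Rcpp.h>
#include <array>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Nucleotide local/global alignment (Gotoh affine gaps) plus a k-mer seeded
// search.  Scoring convention: the first base of a gap costs `gap_open`,
// every further base `gap_ext` (both negative).  Ambiguity codes and N never
// match anything, including themselves (conservative identity).

namespace {

inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

inline bool is_match(char a, char b) { return a == b && base_idx(a) >= 0; }

const int NEG = -1000000000;

struct Aln {
  bool found = false;
  int score = 0;
  int q_start = 0, q_end = 0, s_start = 0, s_end = 0;
  int aln_len = 0, matches = 0;
  // maximal gapless diagonal runs: q0, q1, s0, s1, matches (half-open)
  std::vector<std::array<int, 5>> blocks;
};

struct Pointers {
  // ph: 0 stop/zero, 1 diag, 2 E (gap in query, consumes subject),
  //     3 F (gap in subject, consumes query)
  // pe/pf: 1 opened from H, 2 extended
  std::vector<unsigned char> ph, pe, pf;
  size_t cols;
  Pointers(size_t n, size_t m) : ph((n + 1) * (m + 1), 0),
                                 pe((n + 1) * (m + 1), 0),
                                 pf((n + 1) * (m + 1), 0),
                                 cols(m + 1) {}
  size_t at(size_t i, size_t j) const { return i * cols + j; }
};

void check_size(size_t n, size_t m) {
  if ((double)(n + 1) * (double)(m + 1) > 3e8)
    stop("sequences too long for exact alignment (use the seeded search)");
}

// Traceback from H-state cell (i, j); fills spans, counts and the gapless
// block decomposition of `out`.
void traceback2(const Pointers& P, const std::string& a, const std::string& b,
                int i, int j, Aln* out) {
  out->q_end = i;
  out->s_end = j;
  int cols = 0, matches = 0;
  // 1 diag-match, 2 diag-mismatch, 3 gap consuming subject, 4 gap consuming query
  std::vector<unsigned char> rev;
  int state = 0;
  while (true) {
    if (state == 0) {
      unsigned char p = P.ph[P.at(i, j)];
      if (p == 0) break;
      if (p == 1) {
        bool mm = is_match(a[i - 1], b[j - 1]);
        rev.push_back(mm ? 1 : 2);
        if (mm) matches++;
        cols++;
        i--; j--;
      } else if (p == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      unsigned char p = P.pe[P.at(i, j)];
      rev.push_back(3);
      cols++;
      j--;
      state = (p == 1) ? 0 : 1;
    } else {
      unsigned char p = P.pf[P.at(i, j)];
      rev.push_back(4);
      cols++;
      i--;
      state = (p == 1) ? 0 : 2;
    }
  }
  out->q_start = i;
  out->s_start = j;
  out->aln_len = cols;
  out->matches = matches;
  out->blocks.clear();
  int qi = i, sj = j;
  int bq0 = -1, bs0 = -1, bm = 0;
  for (auto it = rev.rbegin(); it != rev.rend(); ++it) {
    unsigned char c = *it;
    if (c == 1 || c == 2) {
      if (bq0 < 0) { bq0 = qi; bs0 = sj; bm = 0; }
      if (c == 1) bm++;
      qi++; sj++;
    } else {
      if (bq0 >= 0) {
        out->blocks.push_back({bq0, qi, bs0, sj, bm});
        bq0 = -1;
      }
      if (c == 3) sj++; else qi++;
    }
  }
  if (bq0 >= 0) out->blocks.push_back({bq0, qi, bs0, sj, bm});
}

// Local (Smith-Waterman) alignment.  Ties between equal-scoring optima are
// broken by smallest q_start, then s_start, then q_end, then s_end.
Aln sw_core(const std::string& a, const std::string& b,
            int match, int mismatch, int gap_open, int gap_ext) {
  size_t n = a.size(), m = b.size();
  check_size(n, m);
  Pointers P(n, m);
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  std::vector<int> Fprev(m + 1, NEG), Fcur(m + 1, NEG);
  int best = 0;
  std::vector<std::pair<int, int>> best_cells;
  for (size_t i = 1; i <= n; i++) {
    Hcur[0] = 0;
    int E = NEG;
    for (size_t j = 1; j <= m; j++) {
      int e_open = Hcur[j - 1] + gap_open;
      int e_ext = (E == NEG) ? NEG : E + gap_ext;
      E = std::max(e_open, e_ext);
      P.pe[P.at(i, j)] = (e_open >= e_ext) ? 1 : 2;
      int f_open = Hprev[j] + gap_open;
      int f_ext = (Fprev[j] == NEG) ? NEG : Fprev[j] + gap_ext;
      Fcur[j] = std::max(f_open, f_ext);
      P.pf[P.at(i, j)] = (f_open >= f_ext) ? 1 : 2;
      int diag = Hprev[j - 1] + (is_match(a[i - 1], b[j - 1]) ? match : mismatch);
      int h = std::max(0, std::max(diag, std::max(E, Fcur[j])));
      unsigned char p = 0;
      if (h > 0) {
        if (h == diag) p = 1;
        else if (h == E) p = 2;
        else p = 3;
      }
      P.ph[P.at(i, j)] = p;
      Hcur[j] = h;
      if (h > best) {
        best = h;
        best_cells.clear();
        best_cells.push_back({(int)i, (int)j});
      } else if (h == best && best > 0 && best_cells.size() < 128) {
        best_cells.push_back({(int)i, (int)j});
      }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  Aln out;
  if (best <= 0) return out;
  Aln chosen;
  bool have = false;
  for (auto& c : best_cells) {
    Aln cand;
    traceback2(P, a, b, c.first, c.second, &cand);
    cand.score = best;
    cand.found = true;
    if (!have) { chosen = cand; have = true; continue; }
    std::array<int, 4> k1{cand.q_start, cand.s_start, cand.q_end, cand.s_end};
    std::array<int, 4> k2{chosen.q_start, chosen.s_start, chosen.q_end, chosen.s_end};
    if (k1 < k2) chosen = cand;
  }
  return chosen;
}

// Global (Needleman-Wunsch) alignment with penalised end gaps.
Aln nw_core(const std::string& a, const std::string& b,
            int match, int mismatch, int gap_open, int gap_ext) {
  size_t n = a.size(), m = b.size();
  check_size(n, m);
  Pointers P(n, m);
  std::vector<int> Hprev(m + 1), Hcur(m + 1);
  std::vector<int> Fprev(m + 1, NEG), Fcur(m + 1, NEG);
  Hprev[0] = 0;
  for (size_t j = 1; j <= m; j++) {
    Hprev[j] = gap_open + (int)(j - 1) * gap_ext;
    P.ph[P.at(0, j)] = 2;
    P.pe[P.at(0, j)] = (j == 1) ? 1 : 2;
  }
  for (size_t i = 1; i <= n; i++) {
    Hcur[0] = gap_open + (int)(i - 1) * gap_ext;
    P.ph[P.at(i, 0)] = 3;
    P.pf[P.at(i, 0)] = (i == 1) ? 1 : 2;
    Fcur[0] = Hcur[0];
    int E = NEG;
    for (size_t j = 1; j <= m; j++) {
      int e_open = Hcur[j - 1] + gap_open;
      int e_ext = (E == NEG) ? NEG : E + gap_ext;
      E = std::max(e_open, e_ext);
      P.pe[P.at(i, j)] = (e_open >= e_ext) ? 1 : 2;
      int f_open = Hprev[j] + gap_open;
      int f_ext = (Fprev[j] == NEG) ? NEG : Fprev[j] + gap_ext;
      Fcur[j] = std::max(f_open, f_ext);
      P.pf[P.at(i, j)] = (f_open >= f_ext) ? 1 : 2;
      int diag = Hprev[j - 1] + (is_match(a[i - 1], b[j - 1]) ? match : mismatch);
      int h = std::max(diag, std::max(E, Fcur[j]));
      unsigned char p;
      if (h == diag) p = 1;
      else if (h == E) p = 2;
      else p = 3;
      P.ph[P.at(i, j)] = p;
      Hcur[j] = h;
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  Aln out;
  out.score = Hprev[m];
  // traceback must not stop before (0, 0): boundary ph codes keep it walking
  traceback2(P, a, b, (int)n, (int)m, &out);
  out.found = true;
  return out;
}

// Best ungapped diagonal score through a seed (x-drop bounded in both
// directions); cheap prefilter for short-seed rescue passes.
int ungapped_best(const std::string& a, const std::string& b, int qpos,
                  int spos, int k, int xdrop, int match, int mismatch) {
  int n = (int)a.size(), m = (int)b.size();
  int base = k * match;
  int best_r = 0, run = 0;
  for (int i = qpos + k, j = spos + k; i < n && j < m; i++, j++) {
    run += is_match(a[i], b[j]) ? match : mismatch;
    if (run > best_r) best_r = run;
    if (best_r - run > xdrop) break;
  }
  int best_l = 0; run = 0;
  for (int i = qpos - 1, j = spos - 1; i >= 0 && j >= 0; i--, j--) {
    run += is_match(a[i], b[j]) ? match : mismatch;
    if (run > best_l) best_l = run;
    if (best_l - run > xdrop) break;
  }
  return base + best_r + best_l;
}

List aln_to_list(const Aln& x) {
  IntegerMatrix blocks(x.blocks.size(), 5);
  for (size_t r = 0; r < x.blocks.size(); r++)
    for (int c = 0; c < 5; c++) blocks(r, c) = x.blocks[r][c];
  colnames(blocks) = CharacterVector::create("q0", "q1", "s0", "s1", "matches");
  return List::create(
      _["found"] = x.found, _["score"] = x.score,
      _["q_start"] = x.q_start, _["q_end"] = x.q_end,
      _["s_start"] = x.s_start, _["s_end"] = x.s_end,
      _["aln_len"] = x.aln_len, _["matches"] = x.matches,
      _["blocks"] = blocks);
}

}  // namespace

// [[Rcpp::export]]
List cpp_sw_align(std::string a, std::string b, int match, int mismatch,
                  int gap_open, int gap_ext) {
  Aln x = sw_core(a, b, match, mismatch, gap_open, gap_ext);
  return aln_to_list(x);
}

// [[Rcpp::export]]
List cpp_nw_stats(std::string a, std::string b, int match, int mismatch,
                  int gap_open, int gap_ext) {
  Aln x = nw_core(a, b, match, mismatch, gap_open, gap_ext);
  return aln_to_list(x);
}

// K-mer seeded local search: exact k-mer seeds are clustered by diagonal
// (within `band`) and query position (gaps <= max_gap); each cluster is
// realigned with exact Smith-Waterman inside a window padded by `pad`.
// [[Rcpp::export]]
List cpp_seeded_hits(std::string a, std::string b, int k, int band,
                     int max_gap, int pad, int min_ungapped, int match,
                     int mismatch, int gap_open, int gap_ext) {
  int n = (int)a.size(), m = (int)b.size();
  List hits;
  if (n < k || m < k) return hits;
  if (k < 4 || k > 15) stop("seed length must be in [4, 15]");
  // index subject k-mers
  std::unordered_map<uint32_t, std::vector<int>> idx;
  {
    uint32_t code = 0, mask = (1u << (2 * k)) - 1u;
    int run = 0;
    for (int j = 0; j < m; j++) {
      int bi = base_idx(b[j]);
      if (bi < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)bi) & mask;
      run++;
      if (run >= k) idx[code].push_back(j - k + 1);
    }
  }
  // collect seeds (qpos, diag)
  std::vector<std::pair<int, int>> seeds;  // (diag, qpos)
  {
    uint32_t code = 0, mask = (1u << (2 * k)) - 1u;
    int run = 0;
    for (int i = 0; i < n; i++) {
      int bi = base_idx(a[i]);
      if (bi < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)bi) & mask;
      run++;
      if (run >= k) {
        auto it = idx.find(code);
        if (it != idx.end()) {
          int qpos = i - k + 1;
          for (int spos : it->second) seeds.push_back({spos - qpos, qpos});
        }
      }
    }
  }
  if (seeds.empty()) return hits;
  std::sort(seeds.begin(), seeds.end());
  // pass 1: split on diagonal jumps > band
  std::vector<std::pair<size_t, size_t>> dgroups;
  size_t start = 0;
  for (size_t s = 1; s <= seeds.size(); s++) {
    if (s == seeds.size() || seeds[s].first - seeds[s - 1].first > band) {
      dgroups.push_back({start, s});
      start = s;
    }
  }
  // pass 2: within a diagonal group, sort by qpos and split on gaps > max_gap
  for (auto& g : dgroups) {
    std::vector<std::pair<int, int>> qd;  // (qpos, diag)
    int dlo = seeds[g.first].first, dhi = seeds[g.second - 1].first;
    for (size_t s = g.first; s < g.second; s++)
      qd.push_back({seeds[s].second, seeds[s].first});
    std::sort(qd.begin(), qd.end());
    size_t cs = 0;
    for (size_t s = 1; s <= qd.size(); s++) {
      if (s == qd.size() || qd[s].first - qd[s - 1].first > max_gap) {
        if (min_ungapped > 0) {
          // cheap prefilter: an ungapped x-drop extension through one of
          // up to four cluster seeds must reach min_ungapped
          size_t len = s - cs;
          std::vector<size_t> probe = {cs, cs + len - 1, cs + len / 3,
                                       cs + (2 * len) / 3};
          int best_u = 0;
          for (size_t pi : probe) {
            int qp = qd[pi].first, sp = qd[pi].first + qd[pi].second;
            int u = ungapped_best(a, b, qp, sp, k, 30, match, mismatch);
            if (u > best_u) best_u = u;
            if (best_u >= min_ungapped) break;
          }
          if (best_u < min_ungapped) { cs = s; continue; }
        }
        int qlo = qd[cs].first, qhi = qd[s - 1].first + k;
        int slo = qlo + dlo, shi = qhi + dhi;
        int curpad = pad;
        Aln x;
        int q0 = 0, s0 = 0;
        while (true) {
          q0 = std::max(0, qlo - curpad);
          int q1 = std::min(n, qhi + curpad);
          s0 = std::max(0, slo - curpad);
          int s1 = std::min(m, shi + curpad);
          if (q1 <= q0 || s1 <= s0) { x.found = false; break; }
          x = sw_core(a.substr(q0, q1 - q0), b.substr(s0, s1 - s0),
                      match, mismatch, gap_open, gap_ext);
          // if the optimum presses against a window edge with sequence
          // beyond it, the window may have truncated it: widen and redo.
          // A short run of trailing mismatches can park the optimum a few
          // bases short of the edge, so "pressing" allows a small margin.
          const int edge = 12;
          bool touch = x.found &&
            ((x.q_start <= edge && q0 > 0) ||
             (x.q_end >= q1 - q0 - edge && q1 < n) ||
             (x.s_start <= edge && s0 > 0) ||
             (x.s_end >= s1 - s0 - edge && s1 < m));
          if (!touch || curpad >= 1600) break;
          curpad *= 2;
        }
        if (x.found) {
          x.q_start += q0; x.q_end += q0;
          x.s_start += s0; x.s_end += s0;
          for (auto& bl : x.blocks) {
            bl[0] += q0; bl[1] += q0; bl[2] += s0; bl[3] += s0;
          }
          hits.push_back(aln_to_list(x));
        }
        cs = s;
      }
    }
  }
  return hits;
}
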