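#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <map>
#include <array>
#include <functional>
using namespace Rcpp;

// Affine-gap local alignment core shared by the exhaustive aligner and the
// windowed gapped stage of seed-and-extend. Gap of length g costs
// gap_first + gap_ext * (g - 1); callers encode the chosen convention in
// gap_first (BLAST-style "open + extend for the first residue" passes
// gap_open + gap_extend here).

struct AlnResult {
  int score = 0;
  int q_start = 0, q_end = 0;   // 0-based half-open
  int s_start = 0, s_end = 0;
  int matches = 0;
  int aln_length = 0;
  int n_gaps = 0;      // gapped columns
  int gap_opens = 0;
  std::string cigar;   // ops: M (both), I (query only), D (subject only)
};

static inline bool base_match(char a, char b) {
  // N is a universal mismatch by design
  return a == b && a != 'N';
}

static inline int pair_score(char a, char b, int match, int mismatch) {
  return base_match(a, b) ? match : mismatch;
}

// Traceback byte layout: bits 0-1 H source (0 stop, 1 diag, 2 from E, 3 from F),
// bit 2: E extended (came from E), bit 3: F extended (came from F).
static void traceback_one(const std::vector<uint8_t>& tb, int ncol,
                          const char* q, const char* s,
                          int ei, int ej, AlnResult& out) {
  // walk back from H state at (ei, ej)
  std::string ops;
  int i = ei, j = ej;
  int state = 0; // 0 = H, 1 = E (gap consuming subject), 2 = F (gap consuming query)
  int matches = 0, n_gaps = 0, gap_opens = 0;
  while (true) {
    uint8_t b = tb[(size_t)i * ncol + j];
    if (state == 0) {
      int src = b & 3;
      if (src == 0) break;
      if (src == 1) {
        ops.push_back('M');
        if (base_match(q[i - 1], s[j - 1])) matches++;
        i--; j--;
      } else if (src == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      // E: gap consuming subject (query has a deletion): move left
      ops.push_back('D');
      n_gaps++;
      bool ext = (b & 4) != 0;
      j--;
      if (!ext) { gap_opens++; state = 0; }
    } else {
      // F: gap consuming query: move up
      ops.push_back('I');
      n_gaps++;
      bool ext = (b & 8) != 0;
      i--;
      if (!ext) { gap_opens++; state = 0; }
    }
  }
  std::reverse(ops.begin(), ops.end());
  out.q_start = i; out.q_end = ei;
  out.s_start = j; out.s_end = ej;
  out.matches = matches;
  out.aln_length = (int)ops.size();
  out.n_gaps = n_gaps;
  out.gap_opens = gap_opens;
  // run-length encode
  std::string cig;
  size_t k = 0;
  while (k < ops.size()) {
    size_t k2 = k;
    while (k2 < ops.size() && ops[k2] == ops[k]) k2++;
    cig += std::to_string(k2 - k);
    cig.push_back(ops[k]);
    k = k2;
  }
  out.cigar = cig;
}

// Full DP over q[qlo, qhi) x s[slo, shi); coordinates in the result are
// absolute. Ties on score are broken by lowest subject start, then lowest
// query start (alignments enumerated over max-score end cells).
static AlnResult sw_window(const std::string& q, int qlo, int qhi,
                           const std::string& s, int slo, int shi,
                           int match, int mismatch, int gap_first, int gap_ext) {
  const int m = qhi - qlo, n = shi - slo;
  const int ncol = n + 1;
  std::vector<uint8_t> tb((size_t)(m + 1) * ncol, 0);
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Fcol(n + 1, INT32_MIN / 2);
  int best = 0;
  std::vector<std::pair<int,int>> best_cells;
  const char* qc = q.c_str() + qlo;
  const char* sc = s.c_str() + slo;
  for (int i = 1; i <= m; i++) {
    int Erow = INT32_MIN / 2;
    Hcur[0] = 0;
    for (int j = 1; j <= n; j++) {
      // E[i][j] = max(H[i][j-1] - gap_first, E[i][j-1] - gap_ext)
      int e_open = Hcur[j - 1] - gap_first;
      int e_ext  = Erow - gap_ext;
      bool e_from_ext = e_ext > e_open;
      int e = e_from_ext ? e_ext : e_open;
      // F[i][j] = max(H[i-1][j] - gap_first, F[i-1][j] - gap_ext)
      int f_open = Hprev[j] - gap_first;
      int f_ext  = Fcol[j] - gap_ext;
      bool f_from_ext = f_ext > f_open;
      int f = f_from_ext ? f_ext : f_open;
      int d = Hprev[j - 1] + pair_score(qc[i - 1], sc[j - 1], match, mismatch);
      int h = 0; int src = 0;
      if (d > h) { h = d; src = 1; }
      if (e > h) { h = e; src = 2; }
      if (f > h) { h = f; src = 3; }
      uint8_t b = (uint8_t)src;
      if (e_from_ext) b |= 4;
      if (f_from_ext) b |= 8;
      tb[(size_t)i * ncol + j] = b;
      Hcur[j] = h; Erow = e; Fcol[j] = f;
      if (h > best) {
        best = h; best_cells.clear(); best_cells.emplace_back(i, j);
      } else if (h == best && best > 0 && best_cells.size() < 256) {
        best_cells.emplace_back(i, j);
      }
    }
    std::swap(Hprev, Hcur);
  }
  AlnResult res;
  res.score = best;
  if (best <= 0) return res;
  bool first = true;
  for (auto& cell : best_cells) {
    AlnResult r; r.score = best;
    traceback_one(tb, ncol, qc, sc, cell.first, cell.second, r);
    if (first || r.s_start < res.s_start ||
        (r.s_start == res.s_start && r.q_start < res.q_start)) {
      res = r; first = false;
    }
  }
  res.q_start += qlo; res.q_end += qlo;
  res.s_start += slo; res.s_end += slo;
  return res;
}

static List result_to_list(const AlnResult& r) {
  return List::create(
    _["score"] = r.score,
    _["q_start"] = r.q_start, _["q_end"] = r.q_end,
    _["s_start"] = r.s_start, _["s_end"] = r.s_end,
    _["matches"] = r.matches, _["aln_length"] = r.aln_length,
    _["n_gaps"] = r.n_gaps, _["gap_opens"] = r.gap_opens,
    _["cigar"] = r.cigar);
}

// [[Rcpp::export]]
List sw_full_cpp(std::string q, std::string s, int match, int mismatch,
                 int gap_first, int gap_ext, double max_cells) {
  double cells = (double)(q.size() + 1) * (double)(s.size() + 1);
  if (cells > max_cells)
    stop("alignment problem exceeds the configured cell cap (%.0f > %.0f)",
         cells, max_cells);
  AlnResult r = sw_window(q, 0, (int)q.size(), s, 0, (int)s.size(),
                          match, mismatch, gap_first, gap_ext);
  return result_to_list(r);
}

// ---- seed and extend ----

struct Hsp { int diag; int s_lo; int s_hi; int score; };

// [[Rcpp::export]]
DataFrame seed_extend_cpp(std::string q, std::string s, int word,
                          int match, int mismatch, int gap_first, int gap_ext,
                          int trigger, int xdrop, int pad,
                          int chain_gap, int chain_drift,
                          double max_window_cells, double small_full_area) {
  const int qlen = (int)q.size(), slen = (int)s.size();
  std::vector<int> qs, qe, ss, se, sc, mt, al, ng, go;
  auto emit = [&](const AlnResult& r) {
    if (r.score <= 0) return;
    qs.push_back(r.q_start); qe.push_back(r.q_end);
    ss.push_back(r.s_start); se.push_back(r.s_end);
    sc.push_back(r.score); mt.push_back(r.matches);
    al.push_back(r.aln_length); ng.push_back(r.n_gaps); go.push_back(r.gap_opens);
  };
  auto make_df = [&]() {
    return DataFrame::create(
      _["q_start"] = qs, _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se,
      _["score"] = sc, _["matches"] = mt, _["aln_length"] = al,
      _["n_gaps"] = ng, _["gap_opens"] = go);
  };
  if (qlen < word || slen < word) return make_df();

  // 2-bit encode; -1 marks ambiguous
  auto code = [](char c) -> int {
    switch (c) { case 'A': return 0; case 'C': return 1;
                 case 'G': return 2; case 'T': return 3; default: return -1; }
  };
  const uint32_t mask = (word >= 16) ? 0xFFFFFFFFu : ((1u << (2 * word)) - 1);
  if (word > 15) stop("word size > 15 not supported");
  const size_t nkmer = (size_t)1 << (2 * word);
  std::vector<int32_t> head(nkmer, -1);
  std::vector<int32_t> nxt(qlen, -1);
  {
    uint32_t k = 0; int run = 0;
    for (int i = 0; i < qlen; i++) {
      int c = code(q[i]);
      if (c < 0) { run = 0; k = 0; continue; }
      k = ((k << 2) | (uint32_t)c) & mask;
      if (++run >= word) {
        int pos = i - word + 1;
        nxt[pos] = head[k];
        head[k] = pos;
      }
    }
  }

  // scan subject; per-diagonal reach for seed skipping
  std::vector<int> reach(qlen + slen + 1, -1);
  std::vector<Hsp> hsps;
  {
    uint32_t k = 0; int run = 0;
    for (int j = 0; j < slen; j++) {
      int c = code(s[j]);
      if (c < 0) { run = 0; k = 0; continue; }
      k = ((k << 2) | (uint32_t)c) & mask;
      if (++run < word) continue;
      int spos = j - word + 1;
      for (int32_t qpos = head[k]; qpos >= 0; qpos = nxt[qpos]) {
        int diag = spos - qpos + qlen; // index in [1, qlen+slen]
        if (spos < reach[diag]) continue;
        // ungapped x-drop extension around exact seed
        int score0 = word * match;
        int best_left = 0, cur = 0;
        int qi = qpos - 1, sj = spos - 1;
        while (qi >= 0 && sj >= 0) {
          cur += pair_score(q[qi], s[sj], match, mismatch);
          if (cur > best_left) best_left = cur;
          if (best_left - cur > xdrop) break;
          qi--; sj--;
        }
        int best_right = 0; cur = 0;
        qi = qpos + word; sj = spos + word;
        while (qi < qlen && sj < slen) {
          cur += pair_score(q[qi], s[sj], match, mismatch);
          if (cur > best_right) best_right = cur;
          if (best_right - cur > xdrop) break;
          qi++; sj++;
        }
        int total = score0 + best_left + best_right;
        int s_hi = sj; // rightmost explored subject position (exclusive-ish)
        reach[diag] = s_hi;
        if (total >= trigger) {
          Hsp h; h.diag = diag; h.s_lo = spos; h.s_hi = std::min(s_hi + 1, slen);
          h.score = total;
          hsps.push_back(h);
        }
      }
    }
  }
  if (hsps.empty()) return make_df();

  // cluster trigger-passing HSPs: near in subject and on nearby diagonals
  std::sort(hsps.begin(), hsps.end(), [](const Hsp& a, const Hsp& b) {
    if (a.s_lo != b.s_lo) return a.s_lo < b.s_lo;
    return a.diag < b.diag;
  });
  int nh = (int)hsps.size();
  std::vector<int> parent(nh);
  for (int i = 0; i < nh; i++) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int i = 0; i < nh; i++) {
    for (int j2 = i + 1; j2 < nh; j2++) {
      if (hsps[j2].s_lo - hsps[i].s_hi > chain_gap) break;
      if (std::abs(hsps[j2].diag - hsps[i].diag) <= chain_drift)
        parent[find(i)] = find(j2);
    }
  }
  // bounding boxes per cluster
  std::map<int, std::array<int,4>> box; // root -> {s_lo, s_hi, q_lo, q_hi}
  for (int i = 0; i < nh; i++) {
    int r = find(i);
    int q_lo = hsps[i].s_lo - (hsps[i].diag - qlen);
    int q_hi = hsps[i].s_hi - (hsps[i].diag - qlen);
    q_lo = std::max(0, std::min(q_lo, qlen));
    q_hi = std::max(0, std::min(q_hi, qlen));
    auto it = box.find(r);
    if (it == box.end()) {
      box[r] = { hsps[i].s_lo, hsps[i].s_hi, q_lo, q_hi };
    } else {
      auto& bb = it->second;
      bb[0] = std::min(bb[0], hsps[i].s_lo);
      bb[1] = std::max(bb[1], hsps[i].s_hi);
      bb[2] = std::min(bb[2], q_lo);
      bb[3] = std::max(bb[3], q_hi);
    }
  }

  const int margin = 5, grow = 256;
  auto run_window = [&](int qlo, int qhi, int slo, int shi) {
    AlnResult r;
    for (int iter = 0; iter < 24; iter++) {
      qlo = std::max(0, qlo); qhi = std::min(qlen, qhi);
      slo = std::max(0, slo); shi = std::min(slen, shi);
      r = sw_window(q, qlo, qhi, s, slo, shi, match, mismatch, gap_first, gap_ext);
      if (r.score <= 0) break;
      bool did = false;
      auto try_grow = [&](int& lo, int lim_lo, int touch) {
        if (touch < margin && lo > lim_lo) { lo = std::max(lim_lo, lo - grow); did = true; }
      };
      double area = (double)(qhi - qlo + 1 + grow) * (double)(shi - slo + 1 + grow);
      if (area > max_window_cells) break;
      try_grow(qlo, 0, r.q_start - qlo);
      try_grow(slo, 0, r.s_start - slo);
      if (qhi - r.q_end < margin && qhi < qlen) { qhi = std::min(qlen, qhi + grow); did = true; }
      if (shi - r.s_end < margin && shi < slen) { shi = std::min(slen, shi + grow); did = true; }
      if (!did) break;
    }
    return r;
  };

  for (auto& kv : box) {
    auto& bb = kv.second;
    AlnResult r = run_window(bb[2] - pad, bb[3] + pad, bb[0] - pad, bb[1] + pad);
    emit(r);
  }
  // small problems additionally get one exhaustive pass so the best local
  // alignment is never lost to window truncation
  if ((double)(qlen + 1) * (double)(slen + 1) <= small_full_area) {
    AlnResult r = sw_window(q, 0, qlen, s, 0, slen, match, mismatch, gap_first, gap_ext);
    emit(r);
  }
  return make_df();
}
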