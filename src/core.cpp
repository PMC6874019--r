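// Low-level kernels: 2-bit k-mer hashing, unique-anchor finding, collinear
// chaining DP, banded global and local alignment with traceback statistics,
// k-mer vote read mapping, pileup counting, and RNG-coupled sequence
// mutation/error injection (all randomness flows through R's RNG so that
// set.seed() in R fixes every draw).
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <cstdlib>
#include <array>
#include <vector>
#include <string>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1; // N or anything else: excluded from k-mer space
  }
}
static const char CODE2BASE[4] = {'A', 'C', 'G', 'T'};

// Roll over all k-mers of s, calling f(pos, kmer) for each fully ACGT k-mer.
template <typename F>
static void for_each_kmer(const std::string& s, int k, F f) {
  const int n = (int)s.size();
  if (n < k) return;
  uint64_t kmer = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0; // length of current valid run
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint64_t)c) & mask;
    if (++run >= k) f(i - k + 1, kmer);
  }
}

// ---------------------------------------------------------------------------
// k-mer index over a set of target sequences (external pointer held from R)
// ---------------------------------------------------------------------------

struct KmerIndex {
  int k;
  int max_occ;                       // k-mers seen more often are skipped at query time
  std::vector<std::string> names;
  std::vector<int> lengths;
  // k-mer -> list of (seq_idx, pos); capped at max_occ + 1 entries
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> pos;
};

// [[Rcpp::export(name = ".build_kmer_index_cpp")]]
SEXP build_kmer_index_cpp(CharacterVector seqs, int k, int max_occ) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  idx->max_occ = max_occ;
  CharacterVector nm = seqs.names();
  for (int s = 0; s < seqs.size(); ++s) {
    std::string seq = as<std::string>(seqs[s]);
    idx->names.push_back(nm.size() == seqs.size() ? as<std::string>(nm[s]) : std::to_string(s + 1));
    idx->lengths.push_back((int)seq.size());
    for_each_kmer(seq, k, [&](int p, uint64_t km) {
      auto& v = idx->pos[km];
      if ((int)v.size() <= max_occ) v.push_back({(int32_t)s, (int32_t)p});
    });
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".kmer_index_info_cpp")]]
List kmer_index_info_cpp(SEXP idx_ptr) {
  XPtr<KmerIndex> idx(idx_ptr);
  return List::create(_["k"] = idx->k, _["max_occ"] = idx->max_occ,
                      _["names"] = wrap(idx->names), _["lengths"] = wrap(idx->lengths));
}

// Shared vote-counting: per (target, diagonal) exact-offset votes.
// diagonal = target_pos - query_pos, i.e. the implied query start on target.
static void count_votes(const KmerIndex& idx, const std::string& q,
                        std::unordered_map<int64_t, int>& votes) {
  for_each_kmer(q, idx.k, [&](int qp, uint64_t km) {
    auto it = idx.pos.find(km);
    if (it == idx.pos.end()) return;
    const auto& v = it->second;
    if ((int)v.size() > idx.max_occ) return; // repetitive k-mer
    for (const auto& pr : v) {
      int64_t key = ((int64_t)pr.first << 33) + (int64_t)(pr.second - qp) + (1LL << 32);
      ++votes[key];
    }
  });
}

// Map reads by k-mer votes. A read is placed at the (target, diagonal) with
// the most votes; ties between different targets discard the read, ties
// within one target pick the leftmost diagonal. votes >= min_votes required.
// [[Rcpp::export(name = ".map_reads_cpp")]]
DataFrame map_reads_cpp(SEXP idx_ptr, CharacterVector reads, int min_votes) {
  XPtr<KmerIndex> idx(idx_ptr);
  std::vector<int> out_read, out_target, out_start, out_votes, out_len;
  std::unordered_map<int64_t, int> votes;
  for (int r = 0; r < reads.size(); ++r) {
    std::string q = as<std::string>(reads[r]);
    votes.clear();
    count_votes(*idx, q, votes);
    if (votes.empty()) continue;
    int best = 0;
    for (auto& kv : votes) best = std::max(best, kv.second);
    if (best < min_votes) continue;
    int best_target = -1, best_diag = 0;
    bool ambiguous = false;
    for (auto& kv : votes) {
      if (kv.second != best) continue;
      int tgt = (int)(kv.first >> 33);
      int diag = (int)((kv.first & ((1LL << 33) - 1)) - (1LL << 32));
      if (best_target == -1) { best_target = tgt; best_diag = diag; }
      else if (tgt != best_target) { ambiguous = true; break; }
      else if (diag < best_diag) best_diag = diag;
    }
    if (ambiguous) continue;
    out_read.push_back(r + 1);
    out_target.push_back(best_target + 1);
    out_start.push_back(best_diag);
    out_votes.push_back(best);
    out_len.push_back((int)q.size());
  }
  return DataFrame::create(_["read"] = out_read, _["target"] = out_target,
                           _["start"] = out_start, _["votes"] = out_votes,
                           _["len"] = out_len);
}

// All (target, diagonal) vote entries for one query, sorted by votes desc;
// at most max_hits rows. Used for best-hit lookup of fragments and flanks.
// [[Rcpp::export(name = ".query_hits_cpp")]]
DataFrame query_hits_cpp(SEXP idx_ptr, std::string query, int max_hits) {
  XPtr<KmerIndex> idx(idx_ptr);
  std::unordered_map<int64_t, int> votes;
  count_votes(*idx, query, votes);
  std::vector<std::pair<int, int64_t>> v;
  v.reserve(votes.size());
  for (auto& kv : votes) v.push_back({kv.second, kv.first});
  std::sort(v.begin(), v.end(), [](const std::pair<int, int64_t>& a,
                                   const std::pair<int, int64_t>& b) {
    if (a.first != b.first) return a.first > b.first;
    return a.second < b.second;
  });
  int n = std::min((int)v.size(), max_hits);
  IntegerVector target(n), diag(n), nv(n);
  for (int i = 0; i < n; ++i) {
    target[i] = (int)(v[i].second >> 33) + 1;
    diag[i] = (int)((v[i].second & ((1LL << 33) - 1)) - (1LL << 32));
    nv[i] = v[i].first;
  }
  return DataFrame::create(_["target"] = target, _["diag"] = diag, _["votes"] = nv);
}

// ---------------------------------------------------------------------------
// Anchors: exact k-mer matches unique in the whole target set and the query
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".find_anchors_cpp")]]
DataFrame find_anchors_cpp(CharacterVector targets, std::string query, int k) {
  // k-mer -> (seq, pos) with count; count > 1 marks non-unique
  std::unordered_map<uint64_t, std::pair<int64_t, int>> tmap;
  for (int s = 0; s < targets.size(); ++s) {
    std::string t = as<std::string>(targets[s]);
    for_each_kmer(t, k, [&](int p, uint64_t km) {
      auto it = tmap.find(km);
      if (it == tmap.end()) tmap[km] = {((int64_t)s << 32) | (uint32_t)p, 1};
      else it->second.second++;
    });
  }
  std::unordered_map<uint64_t, int> qcount;
  for_each_kmer(query, k, [&](int, uint64_t km) { ++qcount[km]; });
  std::vector<int> tgt, qp, tp;
  for_each_kmer(query, k, [&](int pos, uint64_t km) {
    auto qc = qcount.find(km);
    if (qc->second != 1) return;
    auto it = tmap.find(km);
    if (it == tmap.end() || it->second.second != 1) return;
    tgt.push_back((int)(it->second.first >> 32) + 1);
    qp.push_back(pos);
    tp.push_back((int)(uint32_t)(it->second.first & 0xffffffffULL));
  });
  return DataFrame::create(_["target"] = tgt, _["qpos"] = qp, _["tpos"] = tp);
}

// ---------------------------------------------------------------------------
// Chaining: collapse same-diagonal consecutive anchors into runs, then DP
// (longest-increasing-subsequence style, score = number of anchors) with a
// max_gap constraint on both axes measured between adjacent anchor starts.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".chain_anchors_cpp")]]
List chain_anchors_cpp(IntegerVector qpos, IntegerVector tpos, int max_gap) {
  const int n = qpos.size();
  if (n == 0) return List::create();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return qpos[a] < qpos[b]; });
  // collapse runs of (q+1, t+1) successors
  std::vector<int> rq, rt, rc; // run q_start, t_start, anchor count
  for (int ii = 0; ii < n; ++ii) {
    int i = ord[ii];
    if (!rq.empty() && qpos[i] == rq.back() + rc.back() && tpos[i] == rt.back() + rc.back())
      rc.back()++;
    else { rq.push_back(qpos[i]); rt.push_back(tpos[i]); rc.push_back(1); }
  }
  const int m = (int)rq.size();
  std::vector<double> dp(m);
  std::vector<int> par(m, -1);
  for (int i = 0; i < m; ++i) {
    dp[i] = rc[i];
    for (int j = i - 1; j >= 0; --j) {
      int qlast = rq[j] + rc[j] - 1, tlast = rt[j] + rc[j] - 1;
      if (rq[i] - qlast > max_gap) break; // runs disjoint & sorted in q: safe stop
      if (qlast >= rq[i] || tlast >= rt[i]) continue;
      if (rt[i] - tlast > max_gap) continue;
      if (dp[j] + rc[i] > dp[i]) { dp[i] = dp[j] + rc[i]; par[i] = j; }
    }
  }
  // extract chains greedily by descending dp, truncating at used runs
  std::vector<int> order2(m);
  for (int i = 0; i < m; ++i) order2[i] = i;
  std::sort(order2.begin(), order2.end(), [&](int a, int b) { return dp[a] > dp[b]; });
  std::vector<bool> used(m, false);
  List chains;
  for (int oi = 0; oi < m; ++oi) {
    int i = order2[oi];
    if (used[i]) continue;
    std::vector<int> members;
    int cur = i;
    while (cur != -1 && !used[cur]) { members.push_back(cur); used[cur] = true; cur = par[cur]; }
    std::reverse(members.begin(), members.end());
    int nm = (int)members.size();
    IntegerMatrix runs(nm, 3);
    double score = 0;
    for (int r = 0; r < nm; ++r) {
      runs(r, 0) = rq[members[r]];
      runs(r, 1) = rt[members[r]];
      runs(r, 2) = rc[members[r]];
      score += rc[members[r]];
    }
    colnames(runs) = CharacterVector::create("q_start", "t_start", "n_anchors");
    chains.push_back(List::create(_["runs"] = runs, _["score"] = score));
  }
  return chains;
}

// ---------------------------------------------------------------------------
// Banded global alignment (Needleman-Wunsch) with traceback statistics
// ---------------------------------------------------------------------------

struct AlnStats { long cols, matches, gapcols; double score; };

// match +1, mismatch -1, gap -2; band widened to fit the length difference
static AlnStats banded_global(const std::string& a, const std::string& b, int band,
                              double match, double mismatch, double gap) {
  const int n = (int)a.size(), m = (int)b.size();
  AlnStats st = {0, 0, 0, 0.0};
  if (n == 0 || m == 0) { st.cols = n + m; st.gapcols = n + m; st.score = gap * (n + m); return st; }
  int lo = std::min(0, m - n) - band, hi = std::max(0, m - n) + band;
  const int W = hi - lo + 1;
  const double NEG = -1e18;
  std::vector<double> prev(W, NEG), cur(W, NEG);
  std::vector<uint8_t> tb((size_t)(n + 1) * W); // 0 diag, 1 up (gap in b), 2 left (gap in a)
  // row 0: j = d - lo where d = j - 0
  for (int d = lo; d <= hi; ++d) {
    int j = d;
    if (j >= 0 && j <= m) { prev[d - lo] = gap * j; tb[d - lo] = 2; }
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), NEG);
    for (int d = lo; d <= hi; ++d) {
      int j = i + d;
      if (j < 0 || j > m) continue;
      double best = NEG; uint8_t dir = 0;
      if (j > 0) { // diagonal: prev row, same d
        double s = prev[d - lo];
        if (s > NEG / 2) {
          s += (a[i - 1] == b[j - 1]) ? match : mismatch;
          if (s > best) { best = s; dir = 0; }
        }
      }
      if (d + 1 <= hi) { // up: prev row, d+1 (gap in b / consume a)
        double s = prev[d + 1 - lo];
        if (s > NEG / 2 && s + gap > best) { best = s + gap; dir = 1; }
      }
      if (j > 0 && d - 1 >= lo) { // left: same row, d-1 (gap in a / consume b)
        double s = cur[d - 1 - lo];
        if (s > NEG / 2 && s + gap > best) { best = s + gap; dir = 2; }
      }
      if (i == 0 && j == 0) { best = 0; dir = 0; }
      cur[d - lo] = best;
      tb[(size_t)i * W + (d - lo)] = dir;
    }
    std::swap(prev, cur);
  }
  int d_end = m - n;
  st.score = prev[d_end - lo];
  // traceback
  int i = n, j = m;
  while (i > 0 || j > 0) {
    uint8_t dir = tb[(size_t)i * W + (j - i - lo)];
    if (i > 0 && j > 0 && dir == 0) {
      st.cols++; if (a[i - 1] == b[j - 1]) st.matches++;
      --i; --j;
    } else if (i > 0 && dir == 1) { st.cols++; st.gapcols++; --i; }
    else { st.cols++; st.gapcols++; --j; }
  }
  return st;
}

// [[Rcpp::export(name = ".banded_global_cpp")]]
NumericVector banded_global_cpp(std::string a, std::string b, int band,
                                double match = 1.0, double mismatch = -1.0,
                                double gap = -2.0) {
  AlnStats st = banded_global(a, b, band, match, mismatch, gap);
  return NumericVector::create(_["n_columns"] = (double)st.cols,
                               _["n_matches"] = (double)st.matches,
                               _["n_gapcols"] = (double)st.gapcols,
                               _["score"] = st.score);
}

// Smith-Waterman local alignment with full traceback (small inputs only).
// [[Rcpp::export(name = ".local_align_cpp")]]
List local_align_cpp(std::string a, std::string b, double match = 1.0,
                     double mismatch = -1.0, double gap = -2.0) {
  const int n = (int)a.size(), m = (int)b.size();
  if ((double)n * (double)m > 1.2e8)
    stop("local alignment input too large (%d x %d)", n, m);
  std::vector<double> prev(m + 1, 0.0), cur(m + 1, 0.0);
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 3); // 3 = stop
  double best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      double sd = prev[j - 1] + ((a[i - 1] == b[j - 1]) ? match : mismatch);
      double su = prev[j] + gap, sl = cur[j - 1] + gap;
      double s = std::max(std::max(sd, su), std::max(sl, 0.0));
      uint8_t dir = 3;
      if (s > 0) { if (s == sd) dir = 0; else if (s == su) dir = 1; else dir = 2; }
      cur[j] = s;
      tb[(size_t)i * (m + 1) + j] = dir;
      if (s > best) { best = s; bi = i; bj = j; }
    }
    std::swap(prev, cur);
  }
  long cols = 0, matches = 0, gapcols = 0;
  int i = bi, j = bj;
  while (i > 0 || j > 0) {
    uint8_t dir = tb[(size_t)i * (m + 1) + j];
    if (dir == 3) break;
    if (dir == 0) { cols++; if (a[i - 1] == b[j - 1]) matches++; --i; --j; }
    else if (dir == 1) { cols++; gapcols++; --i; }
    else { cols++; gapcols++; --j; }
  }
  return List::create(_["score"] = best, _["n_columns"] = (double)cols,
                      _["n_matches"] = (double)matches, _["n_gapcols"] = (double)gapcols,
                      _["a_start"] = i, _["a_end"] = bi, _["b_start"] = j, _["b_end"] = bj);
}

// ---------------------------------------------------------------------------
// Chain extension: anchored runs contribute exact-match columns; inter-run
// gaps are closed by banded global alignment. A block is split where the gap
// length difference exceeds the band.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".extend_chain_cpp")]]
NumericMatrix extend_chain_cpp(std::string target, std::string query,
                               IntegerMatrix runs, int k, int band) {
  std::vector<std::array<double, 7>> blocks;
  long q_s = -1, t_s = -1, q_cov = -1, t_cov = -1; // current block start & covered (exclusive end)
  long cols = 0, matches = 0, gapcols = 0;
  auto close_block = [&]() {
    if (q_s >= 0 && cols > 0)
      blocks.push_back({(double)q_s, (double)q_cov, (double)t_s, (double)t_cov,
                        (double)cols, (double)matches, (double)gapcols});
    q_s = t_s = q_cov = t_cov = -1; cols = matches = gapcols = 0;
  };
  for (int r = 0; r < runs.nrow(); ++r) {
    long q0 = runs(r, 0), t0 = runs(r, 1);
    long len = (long)runs(r, 2) + k - 1; // bases covered by the run
    if (q_s < 0) { q_s = q0; t_s = t0; }
    else {
      long ov = std::max(std::max(q_cov - q0, t_cov - t0), 0L);
      q0 += ov; t0 += ov; len -= ov;
      if (len <= 0) continue;
      long qg = q0 - q_cov, tg = t0 - t_cov;
      if (std::labs(qg - tg) > band) { close_block(); q_s = q0; t_s = t0; }
      else if (qg > 0 || tg > 0) {
        AlnStats st = banded_global(query.substr(q_cov, qg), target.substr(t_cov, tg),
                                    band, 1.0, -1.0, -2.0);
        cols += st.cols; matches += st.matches; gapcols += st.gapcols;
      }
    }
    cols += len; matches += len;
    q_cov = q0 + len; t_cov = t0 + len;
  }
  close_block();
  NumericMatrix out((int)blocks.size(), 7);
  for (int i = 0; i < (int)blocks.size(); ++i)
    for (int j = 0; j < 7; ++j) out(i, j) = blocks[i][j];
  colnames(out) = CharacterVector::create("q_start", "q_end", "t_start", "t_end",
                                          "n_columns", "n_matches", "n_gapcols");
  return out;
}

// ---------------------------------------------------------------------------
// Simulation kernels (R RNG)
// ---------------------------------------------------------------------------

// i.i.d. substitutions at `rate` per site, never to the same base
// [[Rcpp::export(name = ".mutate_sequence_cpp")]]
List mutate_sequence_cpp(std::string seq, double rate) {
  RNGScope scope;
  std::vector<int> pos;
  std::vector<char> from, to;
  for (size_t i = 0; i < seq.size(); ++i) {
    if (unif_rand() >= rate) continue;
    int c = base_code(seq[i]);
    if (c < 0) continue;
    int nc = (c + 1 + (int)(unif_rand() * 3)) & 3;
    if (nc == c) nc = (c + 1) & 3; // guard the unif_rand()==1 edge
    pos.push_back((int)i);
    from.push_back(seq[i]);
    to.push_back(CODE2BASE[nc]);
    seq[i] = CODE2BASE[nc];
  }
  std::vector<std::string> froms, tos;
  for (size_t i = 0; i < from.size(); ++i) {
    froms.push_back(std::string(1, from[i]));
    tos.push_back(std::string(1, to[i]));
  }
  return List::create(_["seq"] = seq,
                      _["sites"] = DataFrame::create(_["pos"] = wrap(pos),
                                                     _["from"] = wrap(froms),
                                                     _["to"] = wrap(tos)));
}

// per-base sequencing errors at `rate`, substitutions only
// [[Rcpp::export(name = ".inject_errors_cpp")]]
CharacterVector inject_errors_cpp(CharacterVector reads, double rate) {
  RNGScope scope;
  if (rate <= 0) return reads;
  CharacterVector out(reads.size());
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    for (size_t i = 0; i < s.size(); ++i) {
      if (unif_rand() >= rate) continue;
      int c = base_code(s[i]);
      if (c < 0) continue;
      int nc = (c + 1 + (int)(unif_rand() * 3)) & 3;
      if (nc == c) nc = (c + 1) & 3;
      s[i] = CODE2BASE[nc];
    }
    out[r] = s;
  }
  return out;
}

// per-position base counts (4 x L matrix, rows A,C,G,T) from placed reads
// [[Rcpp::export(name = ".pileup_cpp")]]
IntegerMatrix pileup_cpp(int L, CharacterVector reads, IntegerVector starts) {
  IntegerMatrix counts(4, L);
  for (int r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    int st = starts[r];
    for (int i = 0; i < (int)s.size(); ++i) {
      int p = st + i;
      if (p < 0 || p >= L) continue;
      int c = base_code(s[i]);
      if (c >= 0) counts(c, p)++;
    }
  }
  rownames(counts) = CharacterVector::create("A", "C", "G", "T");
  return counts;
}
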