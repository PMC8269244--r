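#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// ---- shared helpers --------------------------------------------------------

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// ---- Smith-Waterman (linear gap penalty) -----------------------------------
//
// Exact local alignment with traceback. Among equal-score end cells the one
// with the smallest query end, then subject end, is chosen; traceback prefers
// diagonal over up over left, so results are deterministic.

struct SWResult {
  int score, matches, align_length, q_start, q_end, s_start, s_end;
  bool found;
};

static SWResult sw_core(const std::string& q, const std::string& s,
                        int match, int mismatch, int gap) {
  const int n = (int) q.size(), m = (int) s.size();
  SWResult res{0, 0, 0, 0, 0, 0, 0, false};
  if ((double)(n + 1) * (double)(m + 1) > 2.5e8)
    stop("sequences too large for exact DP (limit ~2.5e8 cells)");
  std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
  auto at = [&](int i, int j) -> int& { return H[(size_t)i * (m + 1) + j]; };
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      bool is_match = base_code(q[i - 1]) >= 0 &&
                      base_code(q[i - 1]) == base_code(s[j - 1]);
      int diag = at(i - 1, j - 1) + (is_match ? match : mismatch);
      int up   = at(i - 1, j) + gap;
      int left = at(i, j - 1) + gap;
      int v = std::max(0, std::max(diag, std::max(up, left)));
      at(i, j) = v;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best <= 0) return res;
  // traceback, diagonal-preferring
  int i = bi, j = bj, matches = 0, alen = 0;
  while (i > 0 && j > 0 && at(i, j) > 0) {
    bool is_match = base_code(q[i - 1]) >= 0 &&
                    base_code(q[i - 1]) == base_code(s[j - 1]);
    int v = at(i, j);
    if (v == at(i - 1, j - 1) + (is_match ? match : mismatch)) {
      matches += is_match ? 1 : 0;
      ++alen; --i; --j;
    } else if (v == at(i - 1, j) + gap) {
      ++alen; --i;
    } else {
      ++alen; --j;
    }
  }
  res.score = best; res.matches = matches; res.align_length = alen;
  res.q_start = i + 1; res.q_end = bi; res.s_start = j + 1; res.s_end = bj;
  res.found = true;
  return res;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string subject,
                  int match = 1, int mismatch = -1, int gap = -2,
                  bool both_strands = true) {
  SWResult fwd = sw_core(query, subject, match, mismatch, gap);
  SWResult rev{0, 0, 0, 0, 0, 0, 0, false};
  if (both_strands) rev = sw_core(revcomp(query), subject, match, mismatch, gap);
  bool use_rev = both_strands && rev.found && (!fwd.found || rev.score > fwd.score);
  SWResult r = use_rev ? rev : fwd;
  if (!r.found)
    return List::create(Named("found") = false);
  int qlen = (int) query.size();
  int q_start = r.q_start, q_end = r.q_end;
  if (use_rev) { // map back onto the original (forward) query coordinates
    q_start = qlen - r.q_end + 1;
    q_end   = qlen - r.q_start + 1;
  }
  return List::create(
    Named("found") = true,
    Named("score") = r.score,
    Named("matches") = r.matches,
    Named("align_length") = r.align_length,
    Named("q_start") = q_start, Named("q_end") = q_end,
    Named("s_start") = r.s_start, Named("s_end") = r.s_end,
    Named("strand") = use_rev ? "-" : "+");
}

// ---- k-mer seeded, ungapped-extension aligner ------------------------------
//
// Index every k-mer of every subject; for a query, vote on (subject, diagonal)
// pairs from exact seed matches on both strands, then score the full ungapped
// overlap implied by each winning diagonal. Designed for substitution-dominated
// short reads and for long exact contigs; indels shift the diagonal and are
// not chased.

// [[Rcpp::export(name = ".seed_align_cpp")]]
DataFrame seed_align_cpp(CharacterVector queries, CharacterVector subjects,
                         int k = 15, int max_targets = 50, int min_votes = 1,
                         int match = 1, int mismatch = -1) {
  const int nsub = subjects.size();
  std::vector<std::string> subj(nsub);
  for (int s = 0; s < nsub; ++s) subj[s] = as<std::string>(subjects[s]);

  std::unordered_map<uint64_t, std::vector<uint64_t>> index;
  {
    size_t total = 0;
    for (int s = 0; s < nsub; ++s) total += subj[s].size();
    index.reserve(total);
  }
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  for (int s = 0; s < nsub; ++s) {
    const std::string& seq = subj[s];
    uint64_t kmer = 0; int run = 0;
    for (size_t p = 0; p < seq.size(); ++p) {
      int c = base_code(seq[p]);
      if (c < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)c) & mask;
      if (++run >= k)
        index[kmer].push_back(((uint64_t)s << 32) | (uint64_t)(p - k + 1));
    }
  }

  std::vector<int> out_q, out_s, out_len, out_mm, out_qs, out_qe, out_ss, out_se,
                   out_score;
  std::vector<double> out_pid;
  std::vector<std::string> out_strand;

  std::unordered_map<uint64_t, int> votes; // (subj<<32 | diag+qlen) -> count
  struct Best { int score, matches, len, qs, qe, ss, se; char strand; bool set; };

  const int nq = queries.size();
  for (int qi = 0; qi < nq; ++qi) {
    std::string qf = as<std::string>(queries[qi]);
    const int qlen = (int) qf.size();
    if (qlen < k) continue;
    std::string qr = revcomp(qf);
    std::vector<Best> best(nsub, Best{0, 0, 0, 0, 0, 0, 0, '+', false});
    // sample seeds at a stride so very long queries stay cheap
    int stride = std::max(1, qlen / 512);

    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = strand == 0 ? qf : qr;
      votes.clear();
      uint64_t kmer = 0; int run = 0;
      for (int p = 0; p < qlen; ++p) {
        int c = base_code(q[p]);
        if (c < 0) { run = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)c) & mask;
        if (++run >= k) {
          int qpos = p - k + 1;
          if (qpos % stride != 0) continue;
          auto it = index.find(kmer);
          if (it == index.end()) continue;
          if (it->second.size() > 2048) continue; // skip hyper-repetitive seeds
          for (uint64_t packed : it->second) {
            int s = (int)(packed >> 32);
            int spos = (int)(packed & 0xffffffffULL);
            uint64_t key = ((uint64_t)s << 32) |
                           (uint64_t)(uint32_t)(spos - qpos + qlen);
            votes[key]++;
          }
        }
      }
      // best-voted diagonal per subject
      std::unordered_map<int, std::pair<int,int>> diag_best; // subj -> (votes, diag)
      for (auto& kv : votes) {
        int s = (int)(kv.first >> 32);
        int diag = (int)(uint32_t)(kv.first & 0xffffffffULL) - qlen;
        auto it = diag_best.find(s);
        if (it == diag_best.end() || kv.second > it->second.first ||
            (kv.second == it->second.first && diag < it->second.second))
          diag_best[s] = {kv.second, diag};
      }
      for (auto& kv : diag_best) {
        if (kv.second.first < min_votes) continue;
        int s = kv.first, diag = kv.second.second;
        const std::string& sseq = subj[s];
        int q_from = std::max(0, -diag);
        int s_from = diag + q_from;
        int len = std::min(qlen - q_from, (int)sseq.size() - s_from);
        if (len < k) continue;
        int matches = 0;
        for (int t = 0; t < len; ++t) {
          int a = base_code(q[q_from + t]), b = base_code(sseq[s_from + t]);
          if (a >= 0 && a == b) ++matches;
        }
        int score = matches * match + (len - matches) * mismatch;
        if (!best[s].set || score > best[s].score) {
          Best b;
          b.score = score; b.matches = matches; b.len = len;
          if (strand == 0) { b.qs = q_from + 1; b.qe = q_from + len; }
          else { b.qs = qlen - (q_from + len) + 1; b.qe = qlen - q_from; }
          b.ss = s_from + 1; b.se = s_from + len;
          b.strand = strand == 0 ? '+' : '-';
          b.set = true;
          best[s] = b;
        }
      }
    }
    // emit up to max_targets subjects, best score first
    std::vector<int> order;
    for (int s = 0; s < nsub; ++s) if (best[s].set) order.push_back(s);
    std::sort(order.begin(), order.end(), [&](int a, int b) {
      if (best[a].score != best[b].score) return best[a].score > best[b].score;
      return a < b;
    });
    if ((int)order.size() > max_targets) order.resize(max_targets);
    for (int s : order) {
      const Best& b = best[s];
      out_q.push_back(qi + 1); out_s.push_back(s + 1);
      out_pid.push_back(100.0 * b.matches / b.len);
      out_len.push_back(b.len); out_mm.push_back(b.len - b.matches);
      out_qs.push_back(b.qs); out_qe.push_back(b.qe);
      out_ss.push_back(b.ss); out_se.push_back(b.se);
      out_score.push_back(b.score);
      out_strand.push_back(std::string(1, b.strand));
    }
  }

  return DataFrame::create(
    Named("query_idx") = out_q, Named("subject_idx") = out_s,
    Named("pident") = out_pid, Named("length") = out_len,
    Named("mismatch") = out_mm,
    Named("qstart") = out_qs, Named("qend") = out_qe,
    Named("sstart") = out_ss, Named("send") = out_se,
    Named("score") = out_score, Named("strand") = out_strand,
    Named("stringsAsFactors") = false);
}
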