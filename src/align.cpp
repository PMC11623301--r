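// Alignment core: exhaustive DP oracles (local and glocal), banded glocal
// extension, seed-and-extend best-hit search, and the exact-seed read mapper.
// Linear gap penalties throughout; N never matches.
#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4; // N or anything else: never a match
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
    case 'A': c = 'T'; break; case 'T': c = 'A'; break;
    case 'C': c = 'G'; break; case 'G': c = 'C'; break;
    case 'a': c = 't'; break; case 't': c = 'a'; break;
    case 'c': c = 'g'; break; case 'g': c = 'c'; break;
    default: c = 'N';
    }
  }
  return r;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp_str(s); }

struct AlnStats {
  int score, qs, qe, ss, se, columns, matches, gaps;
  bool hit;
};

static List aln_to_list(const AlnStats& a) {
  return List::create(
    _["hit"] = a.hit, _["score"] = a.score,
    _["query_start"] = a.qs, _["query_end"] = a.qe,
    _["subject_start"] = a.ss, _["subject_end"] = a.se,
    _["columns"] = a.columns, _["matches"] = a.matches, _["gaps"] = a.gaps);
}

// Exhaustive Smith-Waterman with deterministic tie-breaks:
// among all maximal-score endpoints, traceback each (preferring diagonal,
// then up, then left) and keep the lexicographically smallest
// (subject_start, query_start, columns, subject_end, query_end).
// [[Rcpp::export]]
List cpp_local_align(std::string a, std::string b,
                     int match, int mismatch, int gap) {
  std::vector<int> q = encode(a), s = encode(b);
  int m = q.size(), n = s.size();
  if (m == 0 || n == 0) stop("empty sequence");
  std::vector<std::vector<int>> H(m + 1, std::vector<int>(n + 1, 0));
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int sub = (q[i - 1] == s[j - 1] && q[i - 1] < 4) ? match : mismatch;
      int v = H[i - 1][j - 1] + sub;
      v = std::max(v, H[i - 1][j] + gap);
      v = std::max(v, H[i][j - 1] + gap);
      v = std::max(v, 0);
      H[i][j] = v;
      if (v > best) best = v;
    }
  }
  AlnStats out{0, 0, 0, 0, 0, 0, 0, 0, false};
  if (best <= 0) return aln_to_list(out);
  bool have = false;
  std::vector<long long> key;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      if (H[i][j] != best) continue;
      int ci = i, cj = j, cols = 0, mat = 0, gp = 0;
      while (ci > 0 && cj > 0 && H[ci][cj] > 0) {
        int sub = (q[ci - 1] == s[cj - 1] && q[ci - 1] < 4) ? match : mismatch;
        if (ci > 0 && cj > 0 && H[ci][cj] == H[ci - 1][cj - 1] + sub) {
          if (q[ci - 1] == s[cj - 1] && q[ci - 1] < 4) ++mat;
          ++cols; --ci; --cj;
        } else if (ci > 0 && H[ci][cj] == H[ci - 1][cj] + gap) {
          ++cols; ++gp; --ci;
        } else {
          ++cols; ++gp; --cj;
        }
      }
      std::vector<long long> k{cj, ci, cols, j, i};
      if (!have || k < key) {
        have = true; key = k;
        out = AlnStats{best, ci, i, cj, j, cols, mat, gp, true};
      }
    }
  }
  return aln_to_list(out);
}

// Exhaustive unbanded "glocal" alignment: the whole query must align,
// the subject start/end are free. Used as the full-DP oracle for best_hit.
// [[Rcpp::export]]
List cpp_glocal_align(std::string a, std::string b,
                      int match, int mismatch, int gap) {
  std::vector<int> q = encode(a), s = encode(b);
  int m = q.size(), n = s.size();
  if (m == 0 || n == 0) stop("empty sequence");
  const int NEG = -1000000000;
  std::vector<std::vector<int>> D(m + 1, std::vector<int>(n + 1, NEG));
  for (int j = 0; j <= n; ++j) D[0][j] = 0;
  for (int i = 1; i <= m; ++i) D[i][0] = i * gap;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int sub = (q[i - 1] == s[j - 1] && q[i - 1] < 4) ? match : mismatch;
      int v = D[i - 1][j - 1] + sub;
      v = std::max(v, D[i - 1][j] + gap);
      v = std::max(v, D[i][j - 1] + gap);
      D[i][j] = v;
    }
  }
  int best = NEG, jend = 0;
  for (int j = 0; j <= n; ++j) {
    if (D[m][j] > best) { best = D[m][j]; jend = j; }
  }
  // traceback from (m, jend), preferring diagonal, then up, then left
  int ci = m, cj = jend, cols = 0, mat = 0, gp = 0;
  while (ci > 0) {
    int sub = (cj > 0 && q[ci - 1] == s[cj - 1] && q[ci - 1] < 4) ? match : mismatch;
    if (cj > 0 && D[ci][cj] == D[ci - 1][cj - 1] + sub) {
      if (q[ci - 1] == s[cj - 1] && q[ci - 1] < 4) ++mat;
      ++cols; --ci; --cj;
    } else if (D[ci][cj] == D[ci - 1][cj] + gap) {
      ++cols; ++gp; --ci;
    } else {
      ++cols; ++gp; --cj;
    }
  }
  AlnStats out{best, 0, m, cj, jend, cols, mat, gp, true};
  return aln_to_list(out);
}

// Banded glocal alignment of the full query against subject positions on
// diagonals d0-band..d0+band (d0 = subject offset of query position 0).
static AlnStats banded_glocal(const std::vector<int>& q, const std::vector<int>& s,
                              int d0, int band,
                              int match, int mismatch, int gap) {
  int m = q.size(), n = s.size();
  const int NEG = -1000000000;
  int W = 2 * band + 1; // column t = j - (i + d0 - band), t in [0, W-1]
  std::vector<int> prev(W, NEG), cur(W, NEG);
  std::vector<unsigned char> ptr((size_t)(m + 1) * W, 0); // 0 start,1 diag,2 up,3 left
  // row 0: free subject start at any j in band
  for (int t = 0; t < W; ++t) {
    int j = d0 - band + t;
    if (j >= 0 && j <= n) prev[t] = 0;
  }
  for (int i = 1; i <= m; ++i) {
    int base = i + d0 - band;
    for (int t = 0; t < W; ++t) {
      int j = base + t;
      cur[t] = NEG;
      if (j < 0 || j > n) continue;
      if (j == 0) { // all of query so far is gapped
        cur[t] = i * gap;
        ptr[(size_t)i * W + t] = 2;
        continue;
      }
      int bestv = NEG; unsigned char bp = 0;
      // diagonal: prev row, same t (j-1 = (i-1) + d0 - band + t)
      if (prev[t] > NEG / 2) {
        int sub = (q[i - 1] == s[j - 1] && q[i - 1] < 4) ? match : mismatch;
        int v = prev[t] + sub;
        if (v > bestv) { bestv = v; bp = 1; }
      }
      // up (gap in subject): prev row, t+1
      if (t + 1 < W && prev[t + 1] > NEG / 2) {
        int v = prev[t + 1] + gap;
        if (v > bestv) { bestv = v; bp = 2; }
      }
      // left (gap in query): same row, t-1
      if (t - 1 >= 0 && cur[t - 1] > NEG / 2) {
        int v = cur[t - 1] + gap;
        if (v > bestv) { bestv = v; bp = 3; }
      }
      cur[t] = bestv;
      ptr[(size_t)i * W + t] = bp;
    }
    std::swap(prev, cur);
  }
  // endpoint: smallest j maximizing score on the last row
  int best = NEG, tend = -1;
  for (int t = 0; t < W; ++t) {
    int j = m + d0 - band + t;
    if (j < 0 || j > n) continue;
    if (prev[t] > best) { best = prev[t]; tend = t; }
  }
  AlnStats out{0, 0, 0, 0, 0, 0, 0, 0, false};
  if (tend < 0 || best <= NEG / 2) return out;
  int ci = m, ct = tend, cols = 0, mat = 0, gp = 0;
  while (ci > 0) {
    unsigned char p = ptr[(size_t)ci * W + ct];
    int j = ci + d0 - band + ct;
    if (p == 1) { // diagonal: row down, t unchanged
      if (q[ci - 1] == s[j - 1] && q[ci - 1] < 4) ++mat;
      ++cols; --ci;
    } else if (p == 2) {
      ++cols; ++gp; --ci; ++ct;
    } else if (p == 3) {
      ++cols; ++gp; --ct;
    } else {
      break;
    }
  }
  int jstart = ci + d0 - band + ct;
  int jend = m + d0 - band + tend;
  out = AlnStats{best, 0, m, jstart, jend, cols, mat, gp, true};
  return out;
}

typedef std::unordered_map<uint64_t, std::vector<int>> KmerIndex;

static bool pack_kmer(const std::vector<int>& code, int pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = code[pos + i];
    if (c >= 4) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

static void build_index(const std::vector<int>& code, int k, KmerIndex& idx) {
  int n = code.size();
  idx.clear();
  if (n < k) return;
  for (int p = 0; p + k <= n; ++p) {
    uint64_t key;
    if (pack_kmer(code, p, k, key)) idx[key].push_back(p);
  }
}

struct BestRec {
  bool hit = false;
  int contig = -1, strand = 0; // strand 0:'+', 1:'-'
  AlnStats aln;
};

// ordering: higher score wins; ties by earlier contig, smaller subject start,
// fewer columns, '+' before '-', smaller subject end
static bool better(const BestRec& a, const BestRec& b) {
  if (!b.hit) return a.hit;
  if (!a.hit) return false;
  if (a.aln.score != b.aln.score) return a.aln.score > b.aln.score;
  if (a.contig != b.contig) return a.contig < b.contig;
  if (a.aln.ss != b.aln.ss) return a.aln.ss < b.aln.ss;
  if (a.aln.columns != b.aln.columns) return a.aln.columns < b.aln.columns;
  if (a.strand != b.strand) return a.strand < b.strand;
  return a.aln.se < b.aln.se;
}

// Seed-and-extend best-hit search of each gene against a (multi-contig)
// genome. Exact k-mer seeds anchor diagonals; diagonal clusters are ranked
// by ungapped score and the top max_cand are rescored by banded glocal DP.
// [[Rcpp::export]]
DataFrame cpp_best_hits(CharacterVector genes, CharacterVector genome,
                        int k, int match, int mismatch, int gap,
                        int min_score, int band, int max_cand) {
  int ng = genes.size(), nc = genome.size();
  std::vector<BestRec> best(ng);
  const int max_kmer_hits = 5000; // skip hyper-repetitive seeds

  for (int ci = 0; ci < nc; ++ci) {
    std::string contig_seq = as<std::string>(genome[ci]);
    std::vector<int> scode = encode(contig_seq);
    int n = scode.size();
    if (n < k) continue;
    KmerIndex idx;
    build_index(scode, k, idx);

    for (int gi = 0; gi < ng; ++gi) {
      std::string gseq = as<std::string>(genes[gi]);
      for (int strand = 0; strand < 2; ++strand) {
        std::string qs = (strand == 0) ? gseq : revcomp_str(gseq);
        std::vector<int> qcode = encode(qs);
        int m = qcode.size();
        if (m <= k) continue;
        // seed diagonals
        std::unordered_map<int, int> diag_count;
        for (int qp = 0; qp + k <= m; ++qp) {
          uint64_t key;
          if (!pack_kmer(qcode, qp, k, key)) continue;
          auto it = idx.find(key);
          if (it == idx.end()) continue;
          const std::vector<int>& ps = it->second;
          if ((int)ps.size() > max_kmer_hits) continue;
          for (int p : ps) diag_count[p - qp]++;
        }
        if (diag_count.empty()) continue;
        // cluster diagonals within the band
        std::vector<int> diags;
        diags.reserve(diag_count.size());
        for (auto& kv : diag_count) diags.push_back(kv.first);
        std::sort(diags.begin(), diags.end());
        struct Cluster { int rep; int seeds; int uscore; };
        std::vector<Cluster> clusters;
        size_t i0 = 0;
        while (i0 < diags.size()) {
          size_t i1 = i0;
          int rep = diags[i0], repn = diag_count[diags[i0]];
          int total = repn;
          while (i1 + 1 < diags.size() && diags[i1 + 1] - diags[i1] <= band) {
            ++i1;
            int c = diag_count[diags[i1]];
            total += c;
            if (c > repn) { repn = c; rep = diags[i1]; }
          }
          clusters.push_back({rep, total, 0});
          i0 = i1 + 1;
        }
        // two-hit rule: when any cluster holds >= 2 seeds, single-seed
        // clusters are chance matches and are dropped before scoring
        int max_seeds = 0;
        for (auto& cl : clusters) max_seeds = std::max(max_seeds, cl.seeds);
        if (max_seeds >= 2) {
          std::vector<Cluster> kept;
          kept.reserve(clusters.size());
          for (auto& cl : clusters) if (cl.seeds >= 2) kept.push_back(cl);
          clusters.swap(kept);
        }
        // quick ungapped score along each representative diagonal
        for (auto& cl : clusters) {
          int sc = 0;
          for (int qi2 = 0; qi2 < m; ++qi2) {
            int j = cl.rep + qi2;
            if (j >= 0 && j < n && qcode[qi2] == scode[j] && qcode[qi2] < 4)
              sc += match;
            else
              sc += mismatch;
          }
          cl.uscore = sc;
        }
        std::sort(clusters.begin(), clusters.end(),
                  [](const Cluster& a, const Cluster& b) {
                    if (a.uscore != b.uscore) return a.uscore > b.uscore;
                    return a.rep < b.rep;
                  });
        int ncand = std::min((int)clusters.size(), max_cand);
        for (int t = 0; t < ncand; ++t) {
          AlnStats a = banded_glocal(qcode, scode, clusters[t].rep, band,
                                     match, mismatch, gap);
          if (!a.hit) continue;
          BestRec rec; rec.hit = true; rec.contig = ci; rec.strand = strand;
          rec.aln = a;
          if (better(rec, best[gi])) best[gi] = rec;
        }
      }
    }
  }

  LogicalVector has_hit(ng);
  IntegerVector contig(ng), sstart(ng), send(ng), cols(ng), mats(ng),
      gaps_v(ng), score(ng);
  CharacterVector strand_v(ng);
  NumericVector ident(ng);
  for (int gi = 0; gi < ng; ++gi) {
    const BestRec& b = best[gi];
    bool ok = b.hit && b.aln.score >= min_score;
    has_hit[gi] = ok;
    if (ok) {
      contig[gi] = b.contig + 1;
      strand_v[gi] = (b.strand == 0) ? "+" : "-";
      sstart[gi] = b.aln.ss;
      send[gi] = b.aln.se;
      cols[gi] = b.aln.columns;
      mats[gi] = b.aln.matches;
      gaps_v[gi] = b.aln.gaps;
      score[gi] = b.aln.score;
      ident[gi] = 100.0 * b.aln.matches / b.aln.columns;
    } else {
      contig[gi] = NA_INTEGER; strand_v[gi] = NA_STRING;
      sstart[gi] = NA_INTEGER; send[gi] = NA_INTEGER;
      cols[gi] = NA_INTEGER; mats[gi] = NA_INTEGER;
      gaps_v[gi] = NA_INTEGER; score[gi] = NA_INTEGER;
      ident[gi] = NA_REAL;
    }
  }
  return DataFrame::create(
    _["has_hit"] = has_hit, _["contig_index"] = contig,
    _["strand"] = strand_v, _["subject_start"] = sstart,
    _["subject_end"] = send, _["align_len"] = cols, _["matches"] = mats,
    _["gaps"] = gaps_v, _["score"] = score, _["pct_identity"] = ident,
    _["stringsAsFactors"] = false);
}

// Exact-seed read placement: anchor each read at its first verifying exact
// k-mer match against the reference (forward, then reverse complement);
// verify >= min_ident ungapped identity over the clipped placed span.
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, std::string reference, int k,
                   double min_ident, int max_attempts) {
  std::vector<int> ref = encode(reference);
  int n = ref.size();
  if (n < k) stop("reference shorter than seed length k");
  KmerIndex idx;
  build_index(ref, k, idx);
  int nr = reads.size();
  IntegerVector depth(n, 0);
  LogicalVector mapped(nr);
  IntegerVector start_v(nr);
  CharacterVector strand_v(nr);
  int n_mapped = 0;
  for (int r = 0; r < nr; ++r) {
    std::string rs = as<std::string>(reads[r]);
    bool placed = false;
    int placed_start = NA_INTEGER;
    std::string placed_strand = "*";
    for (int strand = 0; strand < 2 && !placed; ++strand) {
      std::string seq = (strand == 0) ? rs : revcomp_str(rs);
      std::vector<int> rc = encode(seq);
      int len = rc.size();
      if (len < k) break;
      int attempts = 0;
      for (int qp = 0; qp + k <= len && !placed && attempts < max_attempts; ++qp) {
        uint64_t key;
        if (!pack_kmer(rc, qp, k, key)) continue;
        auto it = idx.find(key);
        if (it == idx.end()) continue;
        for (int p : it->second) {
          if (++attempts > max_attempts) break;
          int start = p - qp; // may run off either reference end
          int lo = std::max(0, start), hi = std::min(n, start + len);
          if (hi - lo < k) continue;
          int matches = 0;
          for (int j = lo; j < hi; ++j) {
            int qc = rc[j - start];
            if (qc == ref[j] && qc < 4) ++matches;
          }
          if ((double)matches / (hi - lo) >= min_ident) {
            for (int j = lo; j < hi; ++j) depth[j]++;
            placed = true;
            placed_start = start;
            placed_strand = (strand == 0) ? "+" : "-";
            break;
          }
        }
      }
    }
    mapped[r] = placed;
    start_v[r] = placed ? placed_start : NA_INTEGER;
    strand_v[r] = placed_strand;
    if (placed) ++n_mapped;
  }
  return List::create(
    _["depth"] = depth, _["n_mapped"] = n_mapped, _["n_reads"] = nr,
    _["mapped"] = mapped, _["start"] = start_v, _["strand"] = strand_v);
}
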