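#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

// ---- shared helpers ---------------------------------------------------

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4; // N / anything else: never matches
  }
}

static inline char comp_char(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_char(c);
  return r;
}

static inline bool base_eq(char a, char b) {
  int ca = base_code(a), cb = base_code(b);
  return ca < 4 && ca == cb;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  return out;
}

// ---- global alignment (Needleman-Wunsch, linear gap) -------------------
// identity = matches / alignment columns * 100 from the optimal global
// alignment; traceback preference diag > up > left for determinism.

// [[Rcpp::export]]
List cpp_nw_identity(std::string a, std::string b,
                     int match = 1, int mismatch = -1, int gap = -2) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1)); // 0 diag 1 up 2 left
  for (int j = 0; j <= m; ++j) { prev[j] = j * gap; tb[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    tb[(size_t)i * (m + 1)] = 1;
    for (int j = 1; j <= m; ++j) {
      int sd = prev[j - 1] + (base_eq(a[i - 1], b[j - 1]) ? match : mismatch);
      int su = prev[j] + gap;
      int sl = cur[j - 1] + gap;
      int best = sd; unsigned char d = 0;
      if (su > best) { best = su; d = 1; }
      if (sl > best) { best = sl; d = 2; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = d;
    }
    std::swap(prev, cur);
  }
  // traceback
  int i = n, j = m, cols = 0, matches = 0;
  while (i > 0 || j > 0) {
    unsigned char d = tb[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 && d == 0) {
      if (base_eq(a[i - 1], b[j - 1])) ++matches;
      --i; --j;
    } else if (i > 0 && d == 1) {
      --i;
    } else {
      --j;
    }
    ++cols;
  }
  double ident = cols > 0 ? 100.0 * matches / cols : 0.0;
  return List::create(_["score"] = prev[m], _["identity"] = ident,
                      _["matches"] = matches, _["columns"] = cols);
}

// ---- local alignment (Smith-Waterman, affine gaps) ---------------------
// Returns the optimal local alignment's score, identity over its columns
// and 0-based half-open coordinates on both sequences.  Tie-break: the
// maximal cell first reached in row-major order; traceback prefers
// M > Ix > Iy.

// [[Rcpp::export]]
List cpp_sw_align(std::string q, std::string s,
                  int match = 1, int mismatch = -1,
                  int gap_open = -2, int gap_extend = -1) {
  const int n = (int)q.size(), m = (int)s.size();
  const int NEG = -1000000000;
  size_t W = (size_t)m + 1;
  std::vector<int> M((size_t)(n + 1) * W, 0), Ix((size_t)(n + 1) * W, NEG),
      Iy((size_t)(n + 1) * W, NEG);
  // ptr codes: for M: 0 start, 1 from M, 2 from Ix, 3 from Iy
  //            for Ix: 1 from M, 2 from Ix ; Iy: 1 from M, 3 from Iy
  std::vector<unsigned char> pM((size_t)(n + 1) * W, 0), pX((size_t)(n + 1) * W, 1),
      pY((size_t)(n + 1) * W, 1);
  int best = 0, bi = 0, bj = 0; unsigned char bstate = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      size_t c = (size_t)i * W + j, du = (size_t)(i - 1) * W + j,
             dl = c - 1, dd = du - 1;
      int sub = base_eq(q[i - 1], s[j - 1]) ? match : mismatch;
      int mv = 0; unsigned char mp = 0;
      if (M[dd] > mv) { mv = M[dd]; mp = 1; }
      if (Ix[dd] > mv) { mv = Ix[dd]; mp = 2; }
      if (Iy[dd] > mv) { mv = Iy[dd]; mp = 3; }
      M[c] = mv + sub; pM[c] = mp;
      int xo = M[du] + gap_open, xe = Ix[du] + gap_extend;
      if (xo >= xe) { Ix[c] = xo; pX[c] = 1; } else { Ix[c] = xe; pX[c] = 2; }
      int yo = M[dl] + gap_open, ye = Iy[dl] + gap_extend;
      if (yo >= ye) { Iy[c] = yo; pY[c] = 1; } else { Iy[c] = ye; pY[c] = 3; }
      if (M[c] > best) { best = M[c]; bi = i; bj = j; bstate = 1; }
    }
  }
  int i = bi, j = bj, cols = 0, matches = 0;
  unsigned char st = bstate;
  int qe = bi, se = bj;
  while (st != 0 && best > 0) {
    size_t c = (size_t)i * W + j;
    if (st == 1) { // M
      if (base_eq(q[i - 1], s[j - 1])) ++matches;
      ++cols; unsigned char p = pM[c]; --i; --j; st = p;
    } else if (st == 2) { // Ix: q consumed, gap in s
      ++cols; unsigned char p = pX[c]; --i; st = p;
    } else { // Iy
      ++cols; unsigned char p = pY[c]; --j; st = p;
    }
  }
  double ident = cols > 0 ? 100.0 * matches / cols : 0.0;
  return List::create(_["score"] = best, _["identity"] = ident,
                      _["matches"] = matches, _["columns"] = cols,
                      _["q_start"] = i, _["q_end"] = qe,
                      _["s_start"] = j, _["s_end"] = se);
}

// ---- semi-global alignment (query end-to-end, free subject ends) -------
// Query must be aligned end-to-end; leading/trailing subject bases are
// free.  Internal gaps affine.  Identity over alignment columns (terminal
// free subject bases excluded).

// [[Rcpp::export]]
List cpp_semiglobal(std::string q, std::string s,
                    int match = 1, int mismatch = -1,
                    int gap_open = -2, int gap_extend = -1) {
  const int n = (int)q.size(), m = (int)s.size();
  const int NEG = -1000000000;
  size_t W = (size_t)m + 1;
  std::vector<int> M((size_t)(n + 1) * W, NEG), Ix((size_t)(n + 1) * W, NEG),
      Iy((size_t)(n + 1) * W, NEG);
  std::vector<unsigned char> pM((size_t)(n + 1) * W, 0), pX((size_t)(n + 1) * W, 1),
      pY((size_t)(n + 1) * W, 1);
  // virtual start row: score 0 at every j (free subject prefix)
  for (int j = 0; j <= m; ++j) M[j] = 0; // row i=0 acts as "start" state
  for (int i = 1; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      size_t c = (size_t)i * W + j;
      size_t du = (size_t)(i - 1) * W + j;
      if (j == 0) {
        // query base aligned before any subject base: gap in s
        int xo = M[du] + gap_open, xe = Ix[du] + gap_extend;
        if (xo >= xe) { Ix[c] = xo; pX[c] = 1; } else { Ix[c] = xe; pX[c] = 2; }
        continue;
      }
      size_t dl = c - 1, dd = du - 1;
      int sub = base_eq(q[i - 1], s[j - 1]) ? match : mismatch;
      int mv = NEG; unsigned char mp = 1;
      if (M[dd] > mv) { mv = M[dd]; mp = (i == 1) ? (unsigned char)0 : (unsigned char)1; }
      if (Ix[dd] > mv) { mv = Ix[dd]; mp = 2; }
      if (Iy[dd] > mv) { mv = Iy[dd]; mp = 3; }
      M[c] = mv + sub; pM[c] = mp;
      int xo = M[du] + gap_open, xe = Ix[du] + gap_extend;
      if (xo >= xe) { Ix[c] = xo; pX[c] = 1; } else { Ix[c] = xe; pX[c] = 2; }
      int yo = M[dl] + gap_open, ye = Iy[dl] + gap_extend;
      if (yo >= ye) { Iy[c] = yo; pY[c] = 1; } else { Iy[c] = ye; pY[c] = 3; }
    }
  }
  // end: best over last row, M or Ix (free subject suffix); smallest j wins ties
  int best = NEG, bj = -1; unsigned char bstate = 1;
  for (int j = 0; j <= m; ++j) {
    size_t c = (size_t)n * W + j;
    if (M[c] > best) { best = M[c]; bj = j; bstate = 1; }
    if (Ix[c] > best) { best = Ix[c]; bj = j; bstate = 2; }
  }
  int i = n, j = bj, cols = 0, matches = 0;
  unsigned char st = bstate;
  int se = bj;
  while (i > 0) {
    size_t c = (size_t)i * W + j;
    if (st == 1) {
      if (base_eq(q[i - 1], s[j - 1])) ++matches;
      ++cols; unsigned char p = pM[c]; --i; --j;
      st = (p == 0) ? 1 : p;
      if (p == 0) break; // reached start row
    } else if (st == 2) {
      ++cols; unsigned char p = pX[c]; --i; st = p;
    } else {
      ++cols; unsigned char p = pY[c]; --j; st = p;
    }
  }
  double ident = cols > 0 ? 100.0 * matches / cols : 0.0;
  return List::create(_["score"] = best, _["identity"] = ident,
                      _["matches"] = matches, _["columns"] = cols,
                      _["s_start"] = j, _["s_end"] = se);
}

// ---- protein local alignment score (affine, arbitrary matrix) ----------
// Score-only Smith-Waterman; substitution matrix indexed by residue
// letters in `alphabet` (row/col order).  Unknown residues score `unk`.

// [[Rcpp::export]]
int cpp_protein_sw_score(std::string a, std::string b,
                         IntegerMatrix subst, std::string alphabet,
                         int gap_open = -11, int gap_extend = -1,
                         int unk = -4) {
  int idx[256];
  std::fill(idx, idx + 256, -1);
  for (size_t i = 0; i < alphabet.size(); ++i)
    idx[(unsigned char)alphabet[i]] = (int)i;
  const int n = (int)a.size(), m = (int)b.size();
  const int NEG = -1000000000;
  std::vector<int> M(m + 1, 0), X(m + 1, NEG), Y(m + 1, NEG);
  std::vector<int> Mp(m + 1, 0), Xp(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    std::copy(M.begin(), M.end(), Mp.begin());
    std::copy(X.begin(), X.end(), Xp.begin());
    M[0] = 0; X[0] = NEG; Y[0] = NEG;
    int ia = idx[(unsigned char)a[i - 1]];
    for (int j = 1; j <= m; ++j) {
      int ib = idx[(unsigned char)b[j - 1]];
      int sub = (ia >= 0 && ib >= 0) ? subst(ia, ib) : unk;
      int mv = std::max(0, std::max(Mp[j - 1], std::max(Xp[j - 1], Y[j - 1])));
      int newM = mv + sub;
      X[j] = std::max(Mp[j] + gap_open, Xp[j] + gap_extend);
      Y[j] = std::max(M[j - 1] + gap_open, Y[j - 1] + gap_extend);
      M[j] = newM;
      if (newM > best) best = newM;
    }
  }
  return best;
}

// ---- gapless overlap detection -----------------------------------------
// Dovetail/containment overlaps between reads, both strands, gapless
// (offset-based).  Offset d = start of oriented b in a's coordinates.
// Best qualifying overlap per unordered pair is reported; the score used
// downstream is overlap_length * identity (proportional to match count).

struct Edge {
  int a, b;        // 0-based indices, a < b
  int orient;      // 0 '+', 1 '-'
  int offset;
  int len, matches;
};

static inline void overlap_at(const std::string& A, const std::string& B,
                              int d, int& len, int& matches) {
  int la = (int)A.size(), lb = (int)B.size();
  int lo = std::max(0, d), hi = std::min(la, d + lb);
  len = hi - lo; matches = 0;
  if (len <= 0) { len = 0; return; }
  for (int p = lo; p < hi; ++p)
    if (base_eq(A[p], B[p - d])) ++matches;
}

static inline bool better_edge(int len1, int m1, int or1, int d1,
                               int len2, int m2, int or2, int d2) {
  // is candidate 1 better than 2?  matches desc, len desc, '+' first, d asc
  if (m1 != m2) return m1 > m2;
  if (len1 != len2) return len1 > len2;
  if (or1 != or2) return or1 < or2;
  return d1 < d2;
}

// [[Rcpp::export]]
DataFrame cpp_overlap_edges(CharacterVector seqs, int min_len, double min_ident,
                            bool exhaustive = false, int seed_k = 12,
                            int stride = 4) {
  const int n = seqs.size();
  std::vector<std::string> fw(n), rc(n);
  for (int i = 0; i < n; ++i) {
    fw[i] = as<std::string>(seqs[i]);
    rc[i] = revcomp(fw[i]);
  }
  std::vector<Edge> edges;

  auto consider_pair = [&](int a, int b,
                           const std::vector<std::pair<int,int>>& cand) {
    // cand: (orient, offset) candidates; keep best qualifying
    bool have = false; Edge best{};
    for (auto& co : cand) {
      const std::string& B = co.first == 0 ? fw[b] : rc[b];
      int len, matches;
      overlap_at(fw[a], B, co.second, len, matches);
      if (len < min_len) continue;
      double ident = 100.0 * matches / len;
      if (ident < min_ident) continue;
      if (!have || better_edge(len, matches, co.first, co.second,
                               best.len, best.matches, best.orient, best.offset)) {
        best = Edge{a, b, co.first, co.second, len, matches};
        have = true;
      }
    }
    if (have) edges.push_back(best);
  };

  if (exhaustive || n <= 2) {
    for (int a = 0; a < n; ++a) {
      for (int b = a + 1; b < n; ++b) {
        int la = (int)fw[a].size(), lb = (int)fw[b].size();
        std::vector<std::pair<int,int>> cand;
        for (int orient = 0; orient < 2; ++orient)
          for (int d = -(lb - min_len); d <= la - min_len; ++d)
            cand.push_back({orient, d});
        consider_pair(a, b, cand);
      }
    }
  } else {
    // k-mer seeded: index forward and rc k-mers of every read
    const int k = seed_k;
    std::unordered_map<uint64_t, std::vector<uint64_t>> index; // packed (i,pos,strand)
    index.reserve((size_t)n * 64);
    for (int i = 0; i < n; ++i) {
      for (int strand = 0; strand < 2; ++strand) {
        const std::string& S = strand == 0 ? fw[i] : rc[i];
        int L = (int)S.size();
        uint64_t key = 0; int run = 0;
        for (int p = 0; p < L; ++p) {
          int c = base_code(S[p]);
          if (c >= 4) { run = 0; key = 0; continue; }
          key = ((key << 2) | (uint64_t)c) & ((k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL);
          if (++run >= k) {
            int pos = p - k + 1;
            index[key].push_back(((uint64_t)i << 24) | ((uint64_t)pos << 2) |
                                 (uint64_t)strand);
          }
        }
      }
    }
    // probe each read's forward k-mers; collect candidate (b, orient, d)
    for (int a = 0; a < n; ++a) {
      std::unordered_map<uint64_t, char> seen; // (b,orient,d+offset_bias) -> 1
      std::vector<std::array<int,3>> cands;    // b, orient, d
      const std::string& A = fw[a];
      int L = (int)A.size();
      uint64_t key = 0; int run = 0;
      for (int p = 0; p < L; ++p) {
        int c = base_code(A[p]);
        if (c >= 4) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & ((seed_k < 32) ? ((1ULL << (2 * seed_k)) - 1) : ~0ULL);
        if (++run >= seed_k) {
          int i_pos = p - seed_k + 1;
          if (i_pos % stride != 0) continue;
          auto it = index.find(key);
          if (it == index.end()) continue;
          for (uint64_t packed : it->second) {
            int b = (int)(packed >> 24);
            if (b <= a) continue;
            int j_pos = (int)((packed >> 2) & 0x3FFFFF);
            int strand = (int)(packed & 3);
            int d = i_pos - j_pos; // start of oriented b in a coords
            uint64_t kk = ((uint64_t)b << 24) | ((uint64_t)strand << 23) |
                          (uint64_t)(uint32_t)(d + 4000000);
            if (seen.emplace(kk, 1).second)
              cands.push_back({b, strand, d});
          }
        }
      }
      // group candidates by b and evaluate
      std::sort(cands.begin(), cands.end());
      size_t s0 = 0;
      while (s0 < cands.size()) {
        size_t s1 = s0;
        int b = cands[s0][0];
        std::vector<std::pair<int,int>> co;
        while (s1 < cands.size() && cands[s1][0] == b) {
          co.push_back({cands[s1][1], cands[s1][2]});
          ++s1;
        }
        consider_pair(a, b, co);
        s0 = s1;
      }
    }
  }
  const size_t ne = edges.size();
  IntegerVector ea(ne), eb(ne), off(ne), len(ne), mat(ne);
  CharacterVector orient(ne);
  NumericVector ident(ne);
  for (size_t i = 0; i < ne; ++i) {
    ea[i] = edges[i].a + 1; eb[i] = edges[i].b + 1;
    orient[i] = edges[i].orient == 0 ? "+" : "-";
    off[i] = edges[i].offset; len[i] = edges[i].len; mat[i] = edges[i].matches;
    ident[i] = 100.0 * edges[i].matches / edges[i].len;
  }
  return DataFrame::create(_["a"] = ea, _["b"] = eb, _["orient"] = orient,
                           _["offset"] = off, _["length"] = len,
                           _["matches"] = mat, _["identity"] = ident,
                           _["stringsAsFactors"] = false);
}

// ---- canonical k-mer counting ------------------------------------------

static std::string decode_kmer(uint64_t key, int k) {
  static const char* B = "ACGT";
  std::string s(k, 'A');
  for (int p = k - 1; p >= 0; --p) { s[p] = B[key & 3]; key >>= 2; }
  return s;
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_map<uint64_t, int> counts;
  uint64_t mask = (1ULL << (2 * k)) - 1;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    int L = (int)s.size();
    uint64_t key = 0, rkey = 0; int run = 0;
    for (int p = 0; p < L; ++p) {
      int c = base_code(s[p]);
      if (c >= 4) { run = 0; key = 0; rkey = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      rkey = (rkey >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      if (++run >= k) {
        uint64_t canon = std::min(key, rkey);
        ++counts[canon];
      }
    }
  }
  std::vector<uint64_t> keys;
  keys.reserve(counts.size());
  for (auto& kv : counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector km(keys.size());
  IntegerVector ct(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    km[i] = decode_kmer(keys[i], k);
    ct[i] = counts[keys[i]];
  }
  return List::create(_["kmer"] = km, _["count"] = ct);
}

// ---- bulk read-to-OTU mapping ------------------------------------------
// Exact affine semi-global DP (read end-to-end, free OTU ends) against
// every OTU on both strands.  For large instances a k-mer seeded gapless
// prescreen shortlists candidate (OTU, strand) pairs; candidates within 5
// identity points of the best prescreen hit receive the full DP.  Reads
// with no adequate seed fall back to the exhaustive DP.  OTUs must be
// supplied in the id order used for tie-breaking (identity desc, columns
// desc, OTU index asc, '+' before '-').

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector otus,
                        double min_identity, int min_aligned_len,
                        int match = 1, int mismatch = -1,
                        int gap_open = -2, int gap_extend = -1,
                        bool exhaustive = false, int seed_k = 16,
                        int stride = 8) {
  const int nr = reads.size(), no = otus.size();
  std::vector<std::string> O(no);
  for (int i = 0; i < no; ++i) O[i] = as<std::string>(otus[i]);

  // decide path: exhaustive for small problems
  double total_len = 0;
  for (int i = 0; i < no; ++i) total_len += (double)O[i].size();
  bool big = !exhaustive && (double)nr * total_len * 300.0 > 5e8;

  // OTU k-mer index for the seeded path
  std::unordered_map<uint64_t, std::vector<uint64_t>> oindex; // (otu,pos)
  if (big) {
    uint64_t mask = (1ULL << (2 * seed_k)) - 1;
    for (int i = 0; i < no; ++i) {
      const std::string& S = O[i];
      uint64_t key = 0; int run = 0;
      for (int p = 0; p < (int)S.size(); ++p) {
        int c = base_code(S[p]);
        if (c >= 4) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++run >= seed_k)
          oindex[key].push_back(((uint64_t)i << 24) | (uint64_t)(p - seed_k + 1));
      }
    }
  }

  IntegerVector out_otu(nr);       // 1-based otu index, NA if unmapped
  NumericVector out_ident(nr);
  IntegerVector out_cols(nr), out_score(nr), out_sstart(nr), out_send(nr),
      out_ties(nr);
  CharacterVector out_strand(nr);

  for (int r = 0; r < nr; ++r) {
    std::string q = as<std::string>(reads[r]);
    std::string qr = revcomp(q);
    int Lq = (int)q.size();

    // candidate (otu, strand) set
    std::vector<std::pair<int,int>> cand;
    bool use_all = !big;
    if (big) {
      // prescreen: seeded gapless diagonals
      std::unordered_map<uint64_t, char> seen;
      std::vector<std::array<int,3>> diags; // otu, strand, d (otu pos of read start)
      uint64_t mask = (1ULL << (2 * seed_k)) - 1;
      for (int strand = 0; strand < 2; ++strand) {
        const std::string& Q = strand == 0 ? q : qr;
        uint64_t key = 0; int run = 0;
        for (int p = 0; p < Lq; ++p) {
          int c = base_code(Q[p]);
          if (c >= 4) { run = 0; key = 0; continue; }
          key = ((key << 2) | (uint64_t)c) & mask;
          if (++run >= seed_k) {
            int i_pos = p - seed_k + 1;
            if (i_pos % stride != 0) continue;
            auto it = oindex.find(key);
            if (it == oindex.end()) continue;
            for (uint64_t packed : it->second) {
              int o = (int)(packed >> 24);
              int j_pos = (int)(packed & 0xFFFFFF);
              int d = j_pos - i_pos;
              uint64_t kk = ((uint64_t)o << 34) | ((uint64_t)strand << 33) |
                            (uint64_t)(uint32_t)(d + 1000000000);
              if (seen.emplace(kk, 1).second)
                diags.push_back({o, strand, d});
            }
          }
        }
      }
      // gapless identity per candidate diagonal; keep best per (otu,strand)
      std::unordered_map<int, double> best_gapless; // (otu*2+strand) -> identity
      double best_overall = -1.0;
      for (auto& dg : diags) {
        const std::string& Q = dg[1] == 0 ? q : qr;
        const std::string& S = O[dg[0]];
        int d = dg[2];
        int matches = 0;
        for (int p = 0; p < Lq; ++p) {
          int sp = p + d;
          if (sp >= 0 && sp < (int)S.size() && base_eq(Q[p], S[sp])) ++matches;
        }
        double ident = 100.0 * matches / Lq;
        int kk = dg[0] * 2 + dg[1];
        auto it = best_gapless.find(kk);
        if (it == best_gapless.end() || ident > it->second)
          best_gapless[kk] = ident;
        if (ident > best_overall) best_overall = ident;
      }
      if (best_overall < min_identity - 5.0) {
        use_all = true; // no adequate seed: exhaustive for this read
      } else {
        double floor_id = std::max(best_overall - 5.0, min_identity - 5.0);
        for (auto& kv : best_gapless)
          if (kv.second >= floor_id)
            cand.push_back({kv.first / 2, kv.first % 2});
      }
    }
    if (use_all) {
      cand.clear();
      for (int o = 0; o < no; ++o) {
        cand.push_back({o, 0});
        cand.push_back({o, 1});
      }
    }

    // full DP on candidates; rank by identity desc, cols desc, otu asc, '+' first
    bool have = false;
    double b_ident = -1; int b_cols = -1, b_otu = -1, b_strand = 0,
        b_score = 0, b_ss = 0, b_se = 0, nties = 0;
    std::sort(cand.begin(), cand.end());
    for (auto& cs : cand) {
      const std::string& Q = cs.second == 0 ? q : qr;
      List al = cpp_semiglobal(Q, O[cs.first], match, mismatch, gap_open,
                               gap_extend);
      double ident = as<double>(al["identity"]);
      int cols = as<int>(al["columns"]);
      bool better = false;
      if (!have) better = true;
      else if (ident > b_ident) better = true;
      else if (ident == b_ident && cols > b_cols) better = true;
      // equal (identity, cols): earlier otu / '+' already seen first in sorted order
      if (ident == b_ident && cols == b_cols && have) ++nties;
      if (better) {
        if (have && (ident != b_ident || cols != b_cols)) nties = 0;
        b_ident = ident; b_cols = cols; b_otu = cs.first;
        b_strand = cs.second; b_score = as<int>(al["score"]);
        b_ss = as<int>(al["s_start"]); b_se = as<int>(al["s_end"]);
        have = true;
      }
    }
    if (!have || b_ident < min_identity || b_cols < min_aligned_len) {
      out_otu[r] = NA_INTEGER;
      out_ident[r] = have ? b_ident : NA_REAL;
      out_cols[r] = have ? b_cols : NA_INTEGER;
      out_score[r] = have ? b_score : NA_INTEGER;
      out_sstart[r] = NA_INTEGER; out_send[r] = NA_INTEGER;
      out_strand[r] = NA_STRING; out_ties[r] = 0;
    } else {
      out_otu[r] = b_otu + 1;
      out_ident[r] = b_ident; out_cols[r] = b_cols; out_score[r] = b_score;
      out_sstart[r] = b_ss; out_send[r] = b_se;
      out_strand[r] = b_strand == 0 ? "+" : "-";
      out_ties[r] = nties;
    }
  }
  return DataFrame::create(_["otu_idx"] = out_otu, _["identity"] = out_ident,
                           _["aligned_cols"] = out_cols, _["score"] = out_score,
                           _["s_start"] = out_sstart, _["s_end"] = out_send,
                           _["strand"] = out_strand, _["n_ties"] = out_ties,
                           _["stringsAsFactors"] = false);
}

// ---- greedy OLC layout ---------------------------------------------------
// Union-find layout of reads into contigs following a pre-sorted edge
// list, maintaining per-contig base-count matrices for the
// haplotype-conflict merge guard.  Placement of read r in its contig:
// strand sigma (+1/-1) and offset delta such that forward-read coordinate
// u maps to contig coordinate delta + u (sigma=+1) or
// delta + (len_r - 1 - u) (sigma=-1).  Edges: orient +1/-1 and offset =
// start of oriented b in a's forward coordinates.

// [[Rcpp::export]]
List cpp_olc_greedy(CharacterVector seqs, IntegerVector ea,
                    IntegerVector eb, IntegerVector eorient,
                    IntegerVector eoffset, int max_merge_conflicts,
                    double conflict_rate = 0.02) {
  const int n = seqs.size();
  std::vector<std::vector<int>> codes(n);
  std::vector<int> len(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    len[i] = (int)s.size();
    codes[i].resize(len[i]);
    for (int p = 0; p < len[i]; ++p) codes[i][p] = base_code(s[p]);
  }
  std::vector<int> parent(n), sigma(n, 1), delta(n, 0);
  std::vector<std::vector<int>> members(n), cnt(n);
  for (int i = 0; i < n; ++i) {
    parent[i] = i;
    members[i].push_back(i);
    cnt[i].assign(4 * len[i], 0);
    for (int p = 0; p < len[i]; ++p)
      if (codes[i][p] < 4) cnt[i][4 * p + codes[i][p]] = 1;
  }
  auto find_root = [&](int i) {
    while (parent[i] != i) { parent[i] = parent[parent[i]]; i = parent[i]; }
    return i;
  };
  const R_xlen_t ne = ea.size();
  for (R_xlen_t e = 0; e < ne; ++e) {
    int a = ea[e] - 1, b = eb[e] - 1;
    int ra = find_root(a), rb = find_root(b);
    if (ra == rb) continue;
    int omega = eorient[e], f = eoffset[e];
    int sbA = sigma[a] * omega;
    long dbA = sigma[a] == 1 ? (long)delta[a] + f
                             : (long)delta[a] + len[a] - f - len[b];
    int LA = (int)(cnt[ra].size() / 4), LB = (int)(cnt[rb].size() / 4);
    int tau; long shift = 0, C = 0, b_lo, b_hi;
    if (sbA == sigma[b]) {
      tau = 1; shift = dbA - delta[b];
      b_lo = shift; b_hi = shift + LB;
    } else {
      tau = -1; C = dbA + delta[b] + len[b] - 1;
      b_hi = C + 1; b_lo = C + 1 - LB;
    }
    // conflict guard over overlapping columns: count columns where the
    // two sides' majority calls disagree; a disagreement fraction above
    // conflict_rate (with an absolute floor) is evidence of two
    // haplotypes, whereas isolated sequencing errors stay well below it
    long o_lo = std::max(0L, b_lo), o_hi = std::min((long)LA, b_hi);
    long ovl = o_hi > o_lo ? o_hi - o_lo : 0;
    int allowed = std::max(max_merge_conflicts,
                           (int)std::floor(conflict_rate * (double)ovl));
    int conflicts = 0;
    for (long x = o_lo; x < o_hi && conflicts <= allowed; ++x) {
      const int* colA = &cnt[ra][4 * x];
      long xb = tau == 1 ? x - b_lo : b_hi - 1 - x;
      int colB[4];
      if (tau == 1) {
        const int* cb = &cnt[rb][4 * xb];
        colB[0] = cb[0]; colB[1] = cb[1]; colB[2] = cb[2]; colB[3] = cb[3];
      } else { // complement rows
        const int* cb = &cnt[rb][4 * xb];
        colB[0] = cb[3]; colB[1] = cb[2]; colB[2] = cb[1]; colB[3] = cb[0];
      }
      int da = colA[0] + colA[1] + colA[2] + colA[3];
      int db = colB[0] + colB[1] + colB[2] + colB[3];
      if (da < 1 || db < 1) continue;
      int ta = 0, tb = 0;
      for (int q = 1; q < 4; ++q) {
        if (colA[q] > colA[ta]) ta = q;
        if (colB[q] > colB[tb]) tb = q;
      }
      if (ta != tb) ++conflicts;
    }
    if (conflicts > allowed) continue;
    // commit
    long lo = std::min(0L, b_lo), hi = std::max((long)LA, b_hi);
    int newL = (int)(hi - lo);
    std::vector<int> nm(4 * newL, 0);
    std::copy(cnt[ra].begin(), cnt[ra].end(), nm.begin() + 4 * (0 - lo));
    for (long x = b_lo; x < b_hi; ++x) {
      long xb = tau == 1 ? x - b_lo : b_hi - 1 - x;
      const int* cb = &cnt[rb][4 * xb];
      int* dst = &nm[4 * (x - lo)];
      if (tau == 1) {
        dst[0] += cb[0]; dst[1] += cb[1]; dst[2] += cb[2]; dst[3] += cb[3];
      } else {
        dst[0] += cb[3]; dst[1] += cb[2]; dst[2] += cb[1]; dst[3] += cb[0];
      }
    }
    cnt[ra] = std::move(nm);
    cnt[rb].clear(); cnt[rb].shrink_to_fit();
    for (int m : members[rb]) {
      if (tau == 1) {
        delta[m] += (int)(shift - lo);
      } else {
        sigma[m] = -sigma[m];
        delta[m] = (int)(C - delta[m] - len[m] + 1 - lo);
      }
    }
    for (int m : members[ra]) delta[m] -= (int)lo;
    members[ra].insert(members[ra].end(), members[rb].begin(),
                       members[rb].end());
    members[rb].clear(); members[rb].shrink_to_fit();
    parent[rb] = ra;
  }
  IntegerVector root(n), osig(n), odel(n);
  for (int i = 0; i < n; ++i) {
    root[i] = find_root(i) + 1;
    osig[i] = sigma[i];
    odel[i] = delta[i];
  }
  return List::create(_["root"] = root, _["sigma"] = osig,
                      _["delta"] = odel);
}
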