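#include <Rcpp.h>
#include <unordered_map>
#include <set>
#include <cstdint>
using namespace Rcpp;

// 'N' is a valid residue but never matches anything, itself included, so
// low-confidence base calls cannot fabricate repeats or alignment identities.
static inline bool base_match(char a, char b) {
  return a == b && a != 'N';
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (auto& c : out) c = comp_base(c);
  return out;
}

// Unit-cost Levenshtein distance with the N-never-matches substitution rule.
// [[Rcpp::export]]
int cpp_levenshtein(std::string a, std::string b) {
  const int m = a.size(), n = b.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    for (int j = 1; j <= n; ++j) {
      int sub = prev[j - 1] + (base_match(a[i - 1], b[j - 1]) ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// Semi-global scan: for every read position j where some substring ending at j
// is within d_max edits of the query, report (start, end, edits) with
// edits = the minimum over all substrings ending at j and start = the largest
// start attaining that minimum (shortest span). 0-based half-open coordinates.
// Column i tracks query prefix length, column origin O the maximal start
// among minimum-cost alignments.
// [[Rcpp::export]]
IntegerMatrix cpp_semiglobal_candidates(std::string read, std::string query, int d_max) {
  const int m = query.size(), n = read.size();
  const int INF = d_max + 1;
  std::vector<int> dprev(m + 1, INF), dcur(m + 1, INF),
    oprev(m + 1, -1), ocur(m + 1, -1);
  std::vector<int> starts, ends, edits;
  // j = 0 column: substring is empty; Ukkonen cutoff keeps only the rows
  // that can still reach d_max (last active row lact)
  int lact = std::min(d_max, m);
  for (int i = 0; i <= lact; ++i) { dprev[i] = i; oprev[i] = 0; }
  if (m <= d_max) { starts.push_back(0); ends.push_back(0); edits.push_back(m); }
  for (int j = 1; j <= n; ++j) {
    dcur[0] = 0; ocur[0] = j;           // free start anywhere
    int lim = std::min(lact + 1, m);
    int newlact = 0;
    for (int i = 1; i <= lim; ++i) {
      int csub = dprev[i - 1] + (base_match(query[i - 1], read[j - 1]) ? 0 : 1);
      int cdel = dcur[i - 1] + 1;       // query base unmatched
      int cins = dprev[i] + 1;          // read base inserted
      int best = std::min(csub, std::min(cdel, cins));
      if (best > INF) best = INF;
      int orig = -1;
      if (best < INF) {
        if (csub == best) orig = std::max(orig, oprev[i - 1]);
        if (cdel == best) orig = std::max(orig, ocur[i - 1]);
        if (cins == best) orig = std::max(orig, oprev[i]);
      }
      dcur[i] = best; ocur[i] = orig;
      if (best <= d_max) newlact = i;
    }
    if (lim < m) { dcur[lim + 1] = INF; ocur[lim + 1] = -1; }
    lact = newlact;
    if (lim == m && dcur[m] <= d_max) {
      starts.push_back(ocur[m]); ends.push_back(j); edits.push_back(dcur[m]);
    }
    std::swap(dprev, dcur); std::swap(oprev, ocur);
  }
  IntegerMatrix out(starts.size(), 3);
  for (size_t r = 0; r < starts.size(); ++r) {
    out(r, 0) = starts[r]; out(r, 1) = ends[r]; out(r, 2) = edits[r];
  }
  colnames(out) = CharacterVector::create("start", "end", "edits");
  return out;
}

// Early-exit test used by the background-read rejection sampler: does the read
// contain any query (or, optionally, its reverse complement) within d_max edits?
// [[Rcpp::export]]
bool cpp_has_occurrence(std::string read, CharacterVector queries, int d_max,
                        bool both_strands) {
  const int n = read.size();
  for (int q = 0; q < queries.size(); ++q) {
    std::string qs = as<std::string>(queries[q]);
    for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
      std::string pat = strand == 0 ? qs : revcomp_str(qs);
      const int m = pat.size();
      const int INF = d_max + 1;
      std::vector<int> dprev(m + 1, INF), dcur(m + 1, INF);
      int lact = std::min(d_max, m);
      for (int i = 0; i <= lact; ++i) dprev[i] = i;
      if (m <= d_max) return true;
      for (int j = 1; j <= n; ++j) {
        dcur[0] = 0;
        int lim = std::min(lact + 1, m);
        int newlact = 0;
        for (int i = 1; i <= lim; ++i) {
          int csub = dprev[i - 1] + (base_match(pat[i - 1], read[j - 1]) ? 0 : 1);
          int best = std::min(csub, std::min(dcur[i - 1] + 1, dprev[i] + 1));
          if (best > INF) best = INF;
          dcur[i] = best;
          if (best <= d_max) newlact = i;
        }
        if (lim < m) dcur[lim + 1] = INF;
        lact = newlact;
        if (lim == m && dcur[m] <= d_max) return true;
        std::swap(dprev, dcur);
      }
    }
  }
  return false;
}

// Length of the longest common subsequence (N never matches): the maximum
// number of identical aligned positions over all global alignments.
// [[Rcpp::export]]
int cpp_lcs(std::string a, std::string b) {
  const int m = a.size(), n = b.size();
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      cur[j] = base_match(a[i - 1], b[j - 1]) ? prev[j - 1] + 1
                                              : std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

static inline int encode_base(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; default: return -1; }
}

// Best-scoring ungapped segment (Kadane, leftmost maximal segment on ties)
// on one diagonal; returns {qstart, qend_incl, identities, mismatches},
// score via out parameter. Diagonal d maps query position i to subject i + d.
static bool best_segment(const std::string& q, const std::string& s, int d,
                         double match, double mismatch,
                         int& bs, int& be, double& best) {
  const int qlen = q.size(), slen = s.size();
  int lo = std::max(0, -d), hi = std::min(qlen, slen - d);  // i in [lo, hi)
  if (lo >= hi) return false;
  double cur = 0; int cs = lo; bool have = false;
  best = -1e18;
  for (int i = lo; i < hi; ++i) {
    double v = base_match(q[i], s[i + d]) ? match : mismatch;
    if (cur <= 0) { cur = v; cs = i; } else cur += v;
    if (cur > best) { best = cur; bs = cs; be = i; have = true; }
  }
  return have;
}

// Seed-and-extend ungapped local alignment of a spacer against one subject,
// both strands. Every exact shared seed of length seed_len nominates its
// diagonal; per (strand, diagonal) the maximal-scoring ungapped segment is
// kept. Columns: qstart, qend, sstart, send (0-based half-open, query
// coordinates in the spacer's own forward orientation), strand (1/-1),
// identities, mismatches, score.
// [[Rcpp::export]]
NumericMatrix cpp_ungapped_hits(std::string spacer, std::string subject,
                                int seed_len, double match, double mismatch) {
  std::vector<std::array<double, 8>> rows;
  const int slen = subject.size();
  if ((int)spacer.size() >= seed_len && slen >= seed_len) {
    // index subject seeds
    std::unordered_map<uint64_t, std::vector<int>> idx;
    uint64_t code = 0, mask = (seed_len >= 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);
    int run = 0;
    for (int j = 0; j < slen; ++j) {
      int e = encode_base(subject[j]);
      if (e < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | e) & mask;
      if (++run >= seed_len) idx[code].push_back(j - seed_len + 1);
    }
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? spacer : revcomp_str(spacer);
      const int qlen = q.size();
      std::set<int> diags;
      uint64_t qc = 0; int qrun = 0;
      for (int i = 0; i < qlen; ++i) {
        int e = encode_base(q[i]);
        if (e < 0) { qrun = 0; qc = 0; continue; }
        qc = ((qc << 2) | e) & mask;
        if (++qrun >= seed_len) {
          auto it = idx.find(qc);
          if (it != idx.end()) {
            int qi = i - seed_len + 1;
            for (int sj : it->second) diags.insert(sj - qi);
          }
        }
      }
      for (int d : diags) {
        int bs, be; double score;
        if (!best_segment(q, subject, d, match, mismatch, bs, be, score)) continue;
        int ident = 0, mism = 0;
        for (int i = bs; i <= be; ++i)
          base_match(q[i], subject[i + d]) ? ++ident : ++mism;
        double qstart, qend;
        if (strand == 0) { qstart = bs; qend = be + 1; }
        else { qstart = qlen - 1 - be; qend = qlen - bs; }
        rows.push_back({qstart, qend, (double)(bs + d), (double)(be + d + 1),
                        strand == 0 ? 1.0 : -1.0,
                        (double)ident, (double)mism, score});
      }
    }
  }
  NumericMatrix out(rows.size(), 8);
  for (size_t r = 0; r < rows.size(); ++r)
    for (int c = 0; c < 8; ++c) out(r, c) = rows[r][c];
  colnames(out) = CharacterVector::create("qstart", "qend", "sstart", "send",
                                          "strand", "identities", "mismatches",
                                          "score");
  return out;
}

// FNV-1a 64-bit content hash, hex-encoded: stable content-derived ids.
// [[Rcpp::export]]
CharacterVector cpp_fnv1a64(CharacterVector x) {
  CharacterVector out(x.size());
  for (int k = 0; k < x.size(); ++k) {
    std::string s = as<std::string>(x[k]);
    uint64_t h = 14695981039346656037ULL;
    for (unsigned char c : s) { h ^= c; h *= 1099511628211ULL; }
    char buf[17];
    snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
    out[k] = buf;
  }
  return out;
}
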