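// Seeded Hamming-distance mapper for short reads against small references.
//
// Strategy: pigeonhole seeding. With at most `max_mm` mismatches and
// (max_mm + 1) disjoint k-mer chunks taken from the 5' end of the read, at
// least one chunk must match the reference exactly, so candidate diagonals
// are collected from an exact k-mer index and verified by full Hamming
// comparison. Two indexes are kept (k = 6 and k = 4) so that reads down to
// (max_mm + 1) * 4 nt still take the seeded path; anything shorter falls
// back to a brute-force scan. Minus-strand placements are found by scanning
// the reverse complement of the read against the forward reference.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

// 2-bit encode a k-mer; returns false if it contains a non-ACGT base.
static inline bool kmer_code(const char* s, int k, uint32_t& code) {
  code = 0;
  for (int i = 0; i < k; ++i) {
    int v;
    switch (s[i]) {
      case 'A': v = 0; break;
      case 'C': v = 1; break;
      case 'G': v = 2; break;
      case 'T': v = 3; break;
      default: return false;
    }
    code = (code << 2) | static_cast<uint32_t>(v);
  }
  return true;
}

struct Hit {
  int query;    // 1-based query index
  int subject;  // 1-based subject index
  int start;    // 0-based leftmost position on subject forward strand
  int mm;
  bool minus;
};

// Hamming distance with early exit above max_mm; -1 if exceeded.
static inline int hamming_le(const char* q, const char* s, int len,
                             int max_mm) {
  int mm = 0;
  for (int i = 0; i < len; ++i) {
    if (q[i] != s[i]) {
      if (++mm > max_mm) return -1;
    }
  }
  return mm;
}

typedef std::unordered_map<uint32_t, std::vector<std::pair<int, int> > >
    KmerIndex;

static KmerIndex build_index(const std::vector<std::string>& subjects,
                             int k) {
  KmerIndex index;
  for (size_t sj = 0; sj < subjects.size(); ++sj) {
    const std::string& s = subjects[sj];
    for (int p = 0; p + k <= static_cast<int>(s.size()); ++p) {
      uint32_t code;
      if (kmer_code(s.c_str() + p, k, code))
        index[code].push_back(std::make_pair(static_cast<int>(sj), p));
    }
  }
  return index;
}

static void scan_seeded(const std::string& q, int qi, bool minus,
                        const std::vector<std::string>& subjects,
                        const KmerIndex& index, int k, int max_mm,
                        std::vector<Hit>& out) {
  const int qlen = static_cast<int>(q.size());
  std::unordered_set<int64_t> seen;
  for (int c = 0; c <= max_mm; ++c) {
    const int off = c * k;
    uint32_t code;
    if (!kmer_code(q.c_str() + off, k, code)) continue;
    KmerIndex::const_iterator it = index.find(code);
    if (it == index.end()) continue;
    for (size_t h = 0; h < it->second.size(); ++h) {
      const int sj = it->second[h].first;
      const int start = it->second[h].second - off;
      const std::string& subj = subjects[sj];
      if (start < 0 || start + qlen > static_cast<int>(subj.size())) continue;
      const int64_t key = static_cast<int64_t>(sj) * 100000000LL + start;
      if (!seen.insert(key).second) continue;
      const int mm = hamming_le(q.c_str(), subj.c_str() + start, qlen, max_mm);
      if (mm >= 0) {
        Hit hit = {qi + 1, sj + 1, start, mm, minus};
        out.push_back(hit);
      }
    }
  }
}

static void scan_brute(const std::string& q, int qi, bool minus,
                       const std::vector<std::string>& subjects, int max_mm,
                       std::vector<Hit>& out) {
  const int qlen = static_cast<int>(q.size());
  for (size_t sj = 0; sj < subjects.size(); ++sj) {
    const std::string& subj = subjects[sj];
    const int smax = static_cast<int>(subj.size()) - qlen;
    for (int start = 0; start <= smax; ++start) {
      const int mm = hamming_le(q.c_str(), subj.c_str() + start, qlen, max_mm);
      if (mm >= 0) {
        Hit hit = {qi + 1, static_cast<int>(sj) + 1, start, mm, minus};
        out.push_back(hit);
      }
    }
  }
}

static void scan_one(const std::string& q, int qi, bool minus,
                     const std::vector<std::string>& subjects,
                     const KmerIndex& idx6, const KmerIndex& idx4,
                     int max_mm, std::vector<Hit>& out) {
  const int qlen = static_cast<int>(q.size());
  if (qlen >= (max_mm + 1) * 6)
    scan_seeded(q, qi, minus, subjects, idx6, 6, max_mm, out);
  else if (qlen >= (max_mm + 1) * 4)
    scan_seeded(q, qi, minus, subjects, idx4, 4, max_mm, out);
  else
    scan_brute(q, qi, minus, subjects, max_mm, out);
}

// [[Rcpp::export(name = ".cpp_hamming_map")]]
DataFrame cpp_hamming_map(CharacterVector queries, CharacterVector subjects,
                          int max_mm, int k = 6) {
  std::vector<std::string> subj(subjects.size());
  for (int i = 0; i < subjects.size(); ++i)
    subj[i] = as<std::string>(subjects[i]);

  const KmerIndex idx6 = build_index(subj, 6);
  const KmerIndex idx4 = build_index(subj, 4);

  std::vector<Hit> hits;
  for (int qi = 0; qi < queries.size(); ++qi) {
    const std::string q = as<std::string>(queries[qi]);
    if (q.size() == 0) continue;
    scan_one(q, qi, false, subj, idx6, idx4, max_mm, hits);
    scan_one(revcomp(q), qi, true, subj, idx6, idx4, max_mm, hits);
  }

  const int n = static_cast<int>(hits.size());
  IntegerVector query(n), subject(n), start(n), mm(n);
  LogicalVector minus(n);
  for (int i = 0; i < n; ++i) {
    query[i] = hits[i].query;
    subject[i] = hits[i].subject;
    start[i] = hits[i].start;
    mm[i] = hits[i].mm;
    minus[i] = hits[i].minus;
  }
  return DataFrame::create(_["query"] = query, _["subject"] = subject,
                           _["start"] = start, _["mismatches"] = mm,
                           _["minus"] = minus);
}
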