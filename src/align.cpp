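#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <map>
#include <string>

using namespace Rcpp;

// Alphabet is {A,C,G,T,N}. N never matches anything (including another N):
// an N in the read or the reference counts as a mismatch at any position.

static inline bool valid_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T' || c == 'N';
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
  return r;
}

// Hamming distance with early exit; returns -1 if > vmax.
static inline int hamming_le(const char *a, const char *b, int L, int vmax) {
  int mm = 0;
  for (int i = 0; i < L; ++i) {
    if (a[i] != b[i] || a[i] == 'N') {
      if (++mm > vmax) return -1;
    }
  }
  return mm;
}

struct HitBuf {
  std::vector<int> read, ref, pos, strand, mm;
  void push(int rd, int rf, int p, int st, int m) {
    read.push_back(rd); ref.push_back(rf); pos.push_back(p);
    strand.push_back(st); mm.push_back(m);
  }
};

static inline int base2(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; default: return -1; }
}

// p-mer occurrence index for one reference (p <= 16, 2-bit encoded).
typedef std::unordered_map<uint32_t, std::vector<int> > KmerIndex;

static KmerIndex build_index(const std::string &ref, int p) {
  KmerIndex idx;
  int L = (int) ref.size();
  if (L < p) return idx;
  uint32_t mask = (p == 16) ? 0xFFFFFFFFu : ((1u << (2 * p)) - 1u);
  uint32_t kmer = 0;
  int valid = 0; // length of current run of non-N bases ending here
  for (int i = 0; i < L; ++i) {
    int c = base2(ref[i]);
    if (c < 0) { valid = 0; kmer = 0; continue; }
    kmer = ((kmer << 2) | (uint32_t) c) & mask;
    if (++valid >= p) idx[kmer].push_back(i - p + 1);
  }
  return idx;
}

// encode p-mer starting at s[off]; returns false if it contains N
static inline bool encode_pmer(const std::string &s, int off, int p, uint32_t &out) {
  uint32_t k = 0;
  for (int i = 0; i < p; ++i) {
    int c = base2(s[off + i]);
    if (c < 0) return false;
    k = (k << 2) | (uint32_t) c;
  }
  out = k;
  return true;
}

// Exhaustive alignment of every read against every reference, both strands,
// reporting all (reference, position, strand) with Hamming distance <= max_mm.
// naive = true uses the brute-force double loop (the oracle path);
// naive = false uses pigeonhole seeding on (max_mm + 1) read segments and is
// required to produce the identical hit set.
// [[Rcpp::export]]
DataFrame align_all_cpp(CharacterVector reads, CharacterVector refs,
                        int max_mm, bool naive) {
  int nreads = reads.size(), nrefs = refs.size();
  std::vector<std::string> R(nreads), S(nrefs);
  for (int i = 0; i < nreads; ++i) {
    R[i] = as<std::string>(reads[i]);
    for (char c : R[i])
      if (!valid_base(c))
        stop("read %d contains a non-ACGTN symbol", i + 1);
  }
  for (int j = 0; j < nrefs; ++j) {
    S[j] = as<std::string>(refs[j]);
    for (char c : S[j])
      if (!valid_base(c))
        stop("reference %d contains a non-ACGTN symbol", j + 1);
  }

  HitBuf out;

  if (naive) {
    for (int i = 0; i < nreads; ++i) {
      const std::string &fwd = R[i];
      std::string rev = revcomp(fwd);
      int L = (int) fwd.size();
      for (int j = 0; j < nrefs; ++j) {
        int Lr = (int) S[j].size();
        const char *sp = S[j].c_str();
        for (int p = 0; p + L <= Lr; ++p) {
          int mf = hamming_le(fwd.c_str(), sp + p, L, max_mm);
          if (mf >= 0) out.push(i + 1, j + 1, p, 0, mf);
          int mr = hamming_le(rev.c_str(), sp + p, L, max_mm);
          if (mr >= 0) out.push(i + 1, j + 1, p, 1, mr);
        }
      }
    }
  } else {
    // cache of per-reference indexes, keyed by seed length p
    std::map<int, std::vector<KmerIndex> > cache;
    std::unordered_set<uint64_t> seen;
    int nseg = max_mm + 1;
    for (int i = 0; i < nreads; ++i) {
      const std::string &fwd = R[i];
      int L = (int) fwd.size();
      int k = L / nseg;            // shortest segment length
      int p = k < 16 ? k : 16;     // seed = prefix of each segment
      if (p < 1) {
        // read too short for pigeonhole seeding: brute force it
        std::string rev = revcomp(fwd);
        for (int j = 0; j < nrefs; ++j) {
          int Lr = (int) S[j].size();
          const char *sp = S[j].c_str();
          for (int q = 0; q + L <= Lr; ++q) {
            int mf = hamming_le(fwd.c_str(), sp + q, L, max_mm);
            if (mf >= 0) out.push(i + 1, j + 1, q, 0, mf);
            int mr = hamming_le(rev.c_str(), sp + q, L, max_mm);
            if (mr >= 0) out.push(i + 1, j + 1, q, 1, mr);
          }
        }
        continue;
      }
      if (cache.find(p) == cache.end()) {
        std::vector<KmerIndex> v(nrefs);
        for (int j = 0; j < nrefs; ++j) v[j] = build_index(S[j], p);
        cache[p] = std::move(v);
      }
      std::vector<KmerIndex> &idx = cache[p];
      std::string rev = revcomp(fwd);
      seen.clear();
      for (int st = 0; st < 2; ++st) {
        const std::string &rd = (st == 0) ? fwd : rev;
        for (int seg = 0; seg < nseg; ++seg) {
          int off = (int) (((long long) seg * L) / nseg);
          uint32_t key;
          if (!encode_pmer(rd, off, p, key)) continue;
          for (int j = 0; j < nrefs; ++j) {
            KmerIndex::const_iterator it = idx[j].find(key);
            if (it == idx[j].end()) continue;
            int Lr = (int) S[j].size();
            const char *sp = S[j].c_str();
            for (int hp : it->second) {
              int pos = hp - off;
              if (pos < 0 || pos + L > Lr) continue;
              uint64_t tag = (((uint64_t) j) << 34) |
                             (((uint64_t) (uint32_t) pos) << 1) |
                             (uint64_t) st;
              if (!seen.insert(tag).second) continue;
              int m = hamming_le(rd.c_str(), sp + pos, L, max_mm);
              if (m >= 0) out.push(i + 1, j + 1, pos, st, m);
            }
          }
        }
      }
    }
  }

  return DataFrame::create(
    _["read"] = out.read, _["ref"] = out.ref, _["pos"] = out.pos,
    _["strand"] = out.strand, _["mm"] = out.mm);
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  out.names() = x.names();
  return out;
}
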