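// Exact-seed read placement and strand-resolved pileup accumulation.
//
// The placer indexes every k-mer of the target assembly (sorted array, binary
// search), seeds each read at five offsets on both strands, extends by
// ungapped full-length comparison, and reports the best-scoring placement.
// Ties on the best score are broken uniformly at random (R's RNG) and flagged
// with MAPQ 0; unique best placements get MAPQ 60.  This mirrors the ambiguity
// semantics of a general aligner for the near-identical haplotype copies the
// simulator produces; it is not a gapped aligner.

#include <Rcpp.h>

#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

namespace {

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

std::string revcomp_one(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (std::string::iterator it = r.begin(); it != r.end(); ++it)
    *it = comp_base(*it);
  return r;
}

struct Seed {
  uint64_t kmer;
  uint32_t ref;
  uint32_t pos;
};

struct SeedLess {
  bool operator()(const Seed& a, const Seed& b) const { return a.kmer < b.kmer; }
};

// Mismatch count of `read` aligned ungapped at `start` on `ref`; returns
// max_mm + 1 as soon as the budget is exceeded or the placement leaves bounds.
int count_mm(const std::string& ref, const std::string& read, long start,
             int max_mm) {
  const long L = static_cast<long>(read.size());
  if (start < 0 || start + L > static_cast<long>(ref.size())) return max_mm + 1;
  int mm = 0;
  for (long i = 0; i < L; ++i) {
    if (ref[start + i] != read[i]) {
      if (++mm > max_mm) return mm;
    }
  }
  return mm;
}

struct Cand {
  uint32_t ref;
  uint32_t pos;
  bool fwd;
  int mm;
};

}  // namespace

// [[Rcpp::export(name = ".place_reads_cpp")]]
List place_reads_cpp(CharacterVector ref_seqs, CharacterVector reads, int k,
                     int max_mm) {
  const int nref = ref_seqs.size();
  std::vector<std::string> refs(nref);
  size_t total = 0;
  for (int i = 0; i < nref; ++i) {
    refs[i] = as<std::string>(ref_seqs[i]);
    total += refs[i].size();
  }

  std::vector<Seed> index;
  index.reserve(total);
  const uint64_t mask =
      (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~static_cast<uint64_t>(0);
  for (int r = 0; r < nref; ++r) {
    const std::string& s = refs[r];
    if (static_cast<int>(s.size()) < k) continue;
    uint64_t km = 0;
    int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int c = base_code(s[i]);
      if (c < 0) {  // N resets the rolling k-mer
        run = 0;
        km = 0;
        continue;
      }
      km = ((km << 2) | static_cast<uint64_t>(c)) & mask;
      if (++run >= k) {
        Seed sd;
        sd.kmer = km;
        sd.ref = static_cast<uint32_t>(r);
        sd.pos = static_cast<uint32_t>(i + 1 - k);
        index.push_back(sd);
      }
    }
  }
  std::sort(index.begin(), index.end(), SeedLess());

  const int n = reads.size();
  std::vector<int> o_read, o_ref, o_pos, o_mapq, o_nm;
  std::vector<int> o_fwd;
  std::vector<std::string> o_seq;
  std::vector<Cand> cands;

  for (int i = 0; i < n; ++i) {
    const std::string fw = as<std::string>(reads[i]);
    const int L = static_cast<int>(fw.size());
    if (L < k) continue;
    const std::string rc = revcomp_one(fw);
    cands.clear();
    int best = max_mm;
    int offs[5];
    offs[0] = 0;
    offs[1] = (L - k) / 4;
    offs[2] = (L - k) / 2;
    offs[3] = (3 * (L - k)) / 4;
    offs[4] = L - k;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& rd = (strand == 0) ? fw : rc;
      for (int oi = 0; oi < 5; ++oi) {
        const int off = offs[oi];
        if (oi > 0 && off == offs[oi - 1]) continue;
        uint64_t km = 0;
        bool ok = true;
        for (int j = 0; j < k; ++j) {
          int c = base_code(rd[off + j]);
          if (c < 0) {
            ok = false;
            break;
          }
          km = (km << 2) | static_cast<uint64_t>(c);
        }
        if (!ok) continue;
        Seed key;
        key.kmer = km;
        key.ref = 0;
        key.pos = 0;
        std::vector<Seed>::const_iterator it =
            std::lower_bound(index.begin(), index.end(), key, SeedLess());
        for (; it != index.end() && it->kmer == km; ++it) {
          const long start = static_cast<long>(it->pos) - off;
          const int mm = count_mm(refs[it->ref], rd, start, best);
          if (mm <= best) {
            Cand c;
            c.ref = it->ref;
            c.pos = static_cast<uint32_t>(start);
            c.fwd = (strand == 0);
            c.mm = mm;
            cands.push_back(c);
            if (mm < best) best = mm;
          }
        }
      }
    }
    if (cands.empty()) continue;
    std::vector<Cand> bestc;
    for (size_t ci = 0; ci < cands.size(); ++ci) {
      const Cand& c = cands[ci];
      if (c.mm != best) continue;
      bool dup = false;
      for (size_t bi = 0; bi < bestc.size(); ++bi) {
        const Cand& b = bestc[bi];
        if (b.ref == c.ref && b.pos == c.pos && b.fwd == c.fwd) {
          dup = true;
          break;
        }
      }
      if (!dup) bestc.push_back(c);
    }
    int pick = 0, mapq = 60;
    if (bestc.size() > 1) {
      pick = static_cast<int>(unif_rand() * bestc.size());
      if (pick >= static_cast<int>(bestc.size()))
        pick = static_cast<int>(bestc.size()) - 1;
      mapq = 0;
    }
    const Cand& c = bestc[pick];
    o_read.push_back(i + 1);
    o_ref.push_back(static_cast<int>(c.ref) + 1);
    o_pos.push_back(static_cast<int>(c.pos));
    o_fwd.push_back(c.fwd ? 1 : 0);
    o_mapq.push_back(mapq);
    o_nm.push_back(c.mm);
    o_seq.push_back(c.fwd ? fw : rc);
  }

  return List::create(
      _["read"] = wrap(o_read), _["ref"] = wrap(o_ref), _["pos"] = wrap(o_pos),
      _["fwd"] = wrap(o_fwd), _["mapq"] = wrap(o_mapq), _["nm"] = wrap(o_nm),
      _["seq"] = wrap(o_seq));
}

// Strand-resolved base counts per reference position.  For each scaffold an
// 8 x L integer matrix: rows 1-4 are A,C,G,T counts from forward-strand reads,
// rows 5-8 the same from reverse-strand reads.  `seq` must be reference
// oriented (reverse-strand reads already reverse-complemented).
// [[Rcpp::export(name = ".pileup_counts_cpp")]]
List pileup_counts_cpp(CharacterVector ref_seqs, IntegerVector ref_idx,
                       IntegerVector pos, LogicalVector fwd,
                       CharacterVector seq) {
  const int nref = ref_seqs.size();
  List out(nref);
  std::vector<int*> ptr(nref);
  std::vector<int> len(nref);
  for (int r = 0; r < nref; ++r) {
    const int L = LENGTH(STRING_ELT(ref_seqs, r));
    IntegerMatrix m(8, L);
    out[r] = m;
    ptr[r] = INTEGER(m);
    len[r] = L;
  }
  const int n = ref_idx.size();
  for (int i = 0; i < n; ++i) {
    const int r = ref_idx[i] - 1;
    if (r < 0 || r >= nref) stop("alignment references unknown scaffold");
    const char* s = CHAR(STRING_ELT(seq, i));
    const int L = LENGTH(STRING_ELT(seq, i));
    const int p = pos[i];
    const int add = fwd[i] ? 0 : 4;
    int* m = ptr[r];
    const int reflen = len[r];
    for (int j = 0; j < L; ++j) {
      const int q = p + j;
      if (q < 0 || q >= reflen) continue;
      const int c = base_code(s[j]);
      if (c < 0) continue;
      m[static_cast<size_t>(q) * 8 + c + add] += 1;
    }
  }
  return out;
}

// Per-base substitution errors at `error_rate`, substituting a uniformly
// chosen different base.  Uses R's RNG so results follow set.seed().
// [[Rcpp::export(name = ".add_errors_cpp")]]
CharacterVector add_errors_cpp(CharacterVector reads, double error_rate) {
  if (error_rate <= 0) return reads;
  const int n = reads.size();
  CharacterVector out(n);
  const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(reads[i]);
    for (size_t j = 0; j < s.size(); ++j) {
      if (unif_rand() < error_rate) {
        const int c = base_code(s[j]);
        if (c < 0) continue;
        int nc = static_cast<int>(unif_rand() * 3);
        if (nc > 2) nc = 2;
        s[j] = bases[(c + 1 + nc) % 4];
      }
    }
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  const int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = revcomp_one(as<std::string>(seqs[i]));
  }
  return out;
}
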