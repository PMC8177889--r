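// Translated six-frame seed-and-extend search and host k-mer filter.
//
// The aligner indexes exact amino-acid seeds of the active reference
// entries, translates each read in all six frames, and for every seeded
// (entry, frame, diagonal) scans the full diagonal for its
// maximum-scoring ungapped segment (Kadane). Significance follows the
// ungapped Karlin-Altschul statistics computed on the R side's constants.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

// standard genetic code, codon index 16*b1 + 4*b2 + b3 with T=0 C=1 A=2 G=3
static const char CODON_AA[65] =
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG";

static inline int base_code(char c) {
  switch (c) {
    case 'T': case 't': return 0;
    case 'C': case 'c': return 1;
    case 'A': case 'a': return 2;
    case 'G': case 'g': return 3;
    default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

// translate dna[offset..] dropping the trailing partial codon; codons with
// any non-ACGT base become 'X', stops '*'
static std::string translate_frame(const std::string& dna, int offset) {
  int n = (int)dna.size();
  int naa = (n - offset) / 3;
  if (naa < 0) naa = 0;
  std::string out;
  out.reserve(naa);
  for (int i = 0; i < naa; ++i) {
    int b1 = base_code(dna[offset + 3 * i]);
    int b2 = base_code(dna[offset + 3 * i + 1]);
    int b3 = base_code(dna[offset + 3 * i + 2]);
    out.push_back((b1 < 0 || b2 < 0 || b3 < 0)
                      ? 'X'
                      : CODON_AA[16 * b1 + 4 * b2 + b3]);
  }
  return out;
}

static std::string revcomp(const std::string& dna) {
  std::string rc(dna.rbegin(), dna.rend());
  for (auto& c : rc) c = comp_base(c);
  return rc;
}

static void six_frames(const std::string& dna, std::string out[6]) {
  for (int f = 0; f < 3; ++f) out[f] = translate_frame(dna, f);
  std::string rc = revcomp(dna);
  for (int f = 0; f < 3; ++f) out[3 + f] = translate_frame(rc, f);
}

// [[Rcpp::export]]
CharacterMatrix cpp_six_frames(CharacterVector dna) {
  CharacterMatrix out(dna.size(), 6);
  std::string fr[6];
  for (R_xlen_t i = 0; i < dna.size(); ++i) {
    six_frames(std::string(dna[i]), fr);
    for (int f = 0; f < 6; ++f) out(i, f) = fr[f];
  }
  colnames(out) = CharacterVector::create("+1", "+2", "+3",
                                          "-1", "-2", "-3");
  return out;
}

struct SeedIndex {
  // key -> positions; position packed as (entry << 20) | pos (entries and
  // proteins both far below 2^20 at the scales this package targets)
  std::unordered_map<uint64_t, std::vector<uint32_t> > map;
  int seedLen;
};

// [[Rcpp::export]]
DataFrame cpp_search(CharacterVector readSeqs, CharacterVector readIds,
                     CharacterVector refSeqs, CharacterVector refIds,
                     int seedLen, IntegerMatrix scoreMat,
                     CharacterVector alphabet, double lambda, double karlinK,
                     double evalueCutoff, double minBitScore) {
  int nref = refSeqs.size();
  std::vector<std::string> refs(nref);
  std::vector<std::string> rids(nref);
  double totalRefResidues = 0;
  for (int i = 0; i < nref; ++i) {
    refs[i] = std::string(refSeqs[i]);
    rids[i] = std::string(refIds[i]);
    totalRefResidues += (double)refs[i].size();
  }

  // letter codes: index into alphabet, -1 for letters never seeded (X, *)
  int lc[256];
  for (int i = 0; i < 256; ++i) lc[i] = -1;
  std::string alpha;
  for (R_xlen_t i = 0; i < alphabet.size(); ++i)
    alpha += std::string(alphabet[i]);
  for (size_t i = 0; i < alpha.size(); ++i)
    lc[(unsigned char)alpha[i]] = (int)i;
  int xcode = lc[(unsigned char)'X'];
  int stopcode = lc[(unsigned char)'*'];

  // score lookup by character
  static int sc[256][256];
  int minScore = scoreMat(0, 0);
  for (int i = 0; i < (int)alpha.size(); ++i)
    for (int j = 0; j < (int)alpha.size(); ++j)
      if (scoreMat(i, j) < minScore) minScore = scoreMat(i, j);
  for (int i = 0; i < 256; ++i)
    for (int j = 0; j < 256; ++j) sc[i][j] = minScore;
  for (int i = 0; i < (int)alpha.size(); ++i)
    for (int j = 0; j < (int)alpha.size(); ++j)
      sc[(unsigned char)alpha[i]][(unsigned char)alpha[j]] = scoreMat(i, j);

  SeedIndex idx;
  idx.seedLen = seedLen;
  for (int e = 0; e < nref; ++e) {
    const std::string& R = refs[e];
    int n = (int)R.size();
    for (int p = 0; p + seedLen <= n; ++p) {
      uint64_t key = 0;
      bool ok = true;
      for (int k = 0; k < seedLen; ++k) {
        int c = lc[(unsigned char)R[p + k]];
        if (c < 0 || c == xcode || c == stopcode) { ok = false; break; }
        key = key * 32 + (uint64_t)c;
      }
      if (ok) idx.map[key].push_back(((uint32_t)e << 20) | (uint32_t)p);
    }
  }

  std::vector<std::string> outRead, outEntry;
  std::vector<int> outFrame, outStart, outRaw;
  std::vector<double> outBit, outEval;
  const int frameSign[6] = {1, 2, 3, -1, -2, -3};
  std::unordered_set<int64_t> seen;
  std::string frames[6];

  for (R_xlen_t r = 0; r < readSeqs.size(); ++r) {
    std::string dna(readSeqs[r]);
    six_frames(dna, frames);
    double queryResidues = 0;
    for (int f = 0; f < 6; ++f) queryResidues += (double)frames[f].size();

    int bestRaw = 0, bestEntry = -1, bestFrame = 0, bestStart = 0;
    seen.clear();

    for (int f = 0; f < 6; ++f) {
      const std::string& P = frames[f];
      int lp = (int)P.size();
      for (int qi = 0; qi + seedLen <= lp; ++qi) {
        uint64_t key = 0;
        bool ok = true;
        for (int k = 0; k < seedLen; ++k) {
          int c = lc[(unsigned char)P[qi + k]];
          if (c < 0 || c == xcode || c == stopcode) { ok = false; break; }
          key = key * 32 + (uint64_t)c;
        }
        if (!ok) continue;
        auto it = idx.map.find(key);
        if (it == idx.map.end()) continue;
        for (uint32_t packed : it->second) {
          int e = (int)(packed >> 20);
          int rpos = (int)(packed & 0xFFFFF);
          int d = rpos - qi;
          int64_t dk = ((int64_t)e * 6 + f) * 2000000 + (d + 1000000);
          if (!seen.insert(dk).second) continue;
          const std::string& R = refs[e];
          int lr = (int)R.size();
          int q0 = d < 0 ? -d : 0;
          int q1 = lp < lr - d ? lp : lr - d;
          int cur = 0, curStart = q0, segBest = 0, segStart = q0;
          for (int q = q0; q < q1; ++q) {
            cur += sc[(unsigned char)P[q]][(unsigned char)R[q + d]];
            if (cur <= 0) {
              cur = 0;
              curStart = q + 1;
            } else if (cur > segBest) {
              segBest = cur;
              segStart = curStart;
            }
          }
          if (segBest <= 0) continue;
          bool take = false;
          if (segBest > bestRaw) take = true;
          else if (segBest == bestRaw && bestEntry >= 0 &&
                   rids[e] < rids[bestEntry]) take = true;
          if (take) {
            bestRaw = segBest;
            bestEntry = e;
            bestFrame = f;
            bestStart = segStart + d;  // 0-based offset in the protein
          }
        }
      }
    }

    if (bestRaw > 0 && bestEntry >= 0) {
      double bit = (lambda * (double)bestRaw - std::log(karlinK)) /
                   std::log(2.0);
      double evalue = totalRefResidues * queryResidues *
                      std::pow(2.0, -bit);
      if (evalue <= evalueCutoff && bit >= minBitScore) {
        outRead.push_back(std::string(readIds[r]));
        outEntry.push_back(rids[bestEntry]);
        outFrame.push_back(frameSign[bestFrame]);
        outStart.push_back(bestStart);
        outRaw.push_back(bestRaw);
        outBit.push_back(bit);
        outEval.push_back(evalue);
      }
    }
  }

  return DataFrame::create(
      Named("read_id") = outRead, Named("entry_id") = outEntry,
      Named("frame") = outFrame, Named("alignment_start") = outStart,
      Named("raw_score") = outRaw, Named("bit_score") = outBit,
      Named("evalue") = outEval,
      Named("stringsAsFactors") = false);
}

// canonical 2-bit k-mer hashing for the host filter (k <= 31)
static inline bool kmer_at(const std::string& s, size_t pos, int k,
                           uint64_t& fwd, uint64_t& rev) {
  fwd = 0;
  rev = 0;
  for (int i = 0; i < k; ++i) {
    int c;
    switch (s[pos + i]) {
      case 'A': case 'a': c = 0; break;
      case 'C': case 'c': c = 1; break;
      case 'G': case 'g': c = 2; break;
      case 'T': case 't': c = 3; break;
      default: return false;
    }
    fwd = (fwd << 2) | (uint64_t)c;
    rev = rev | ((uint64_t)(3 - c) << (2 * i));
  }
  return true;
}

// [[Rcpp::export]]
LogicalVector cpp_host_filter(CharacterVector m1, CharacterVector m2,
                              CharacterVector hostSeqs, int k,
                              int minShared) {
  std::unordered_set<uint64_t> host;
  for (R_xlen_t h = 0; h < hostSeqs.size(); ++h) {
    std::string s(hostSeqs[h]);
    if ((int)s.size() < k) continue;
    for (size_t p = 0; p + (size_t)k <= s.size(); ++p) {
      uint64_t f, r;
      if (kmer_at(s, p, k, f, r)) host.insert(f < r ? f : r);
    }
  }
  R_xlen_t n = m1.size();
  LogicalVector drop(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int shared = 0;
    for (int mate = 0; mate < 2 && shared < minShared; ++mate) {
      std::string s(mate == 0 ? m1[i] : m2[i]);
      if ((int)s.size() < k) continue;
      int count = 0;
      for (size_t p = 0; p + (size_t)k <= s.size(); ++p) {
        uint64_t f, r;
        if (kmer_at(s, p, k, f, r) && host.count(f < r ? f : r)) {
          ++count;
          if (count >= minShared) break;
        }
      }
      if (count > shared) shared = count;
    }
    drop[i] = shared >= minShared;
  }
  return drop;
}
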