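// Built-in small-RNA aligner: exhaustive report of all genome placements of
// each read with at most `max_mismatch` substitutions, on both strands.
//
// align_seed_cpp : seed-and-extend. Two disjoint k-mer seeds (k = 10) per
//   read orientation; with <=1 mismatch at least one seed is exact
//   (pigeonhole), so the candidate set is complete. Candidates are verified
//   by bounded Hamming comparison.
// align_brute_cpp: exhaustive scan of every offset on every chromosome and
//   strand. Used only as an independent oracle in the test suite; kept
//   deliberately naive and separate from the seed path.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;  // N and friends never match anything
  }
}

static bool encode_kmer(const std::string &s, size_t pos, int k, uint64_t &out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[pos + i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

// Hamming distance capped at maxmm; -1 if exceeded. N mismatches everything.
static inline int hamming_le(const std::string &g, size_t pos,
                             const std::string &r, int maxmm) {
  int mm = 0;
  for (size_t i = 0; i < r.size(); ++i) {
    char a = g[pos + i], b = r[i];
    if (a != b || base_code(a) < 0) {
      if (++mm > maxmm) return -1;
    }
  }
  return mm;
}

static std::string revcomp(const std::string &s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i];
    switch (c) {
      case 'A': out[i] = 'T'; break;
      case 'C': out[i] = 'G'; break;
      case 'G': out[i] = 'C'; break;
      case 'T': out[i] = 'A'; break;
      default:  out[i] = 'N'; break;
    }
  }
  return out;
}

struct Hit {
  int chrom;
  int start;  // 0-based
  bool minus;
  int mm;
};

static void collect_hits(std::vector<Hit> &hits, int max_positions_guard) {
  (void)max_positions_guard;
  std::sort(hits.begin(), hits.end(), [](const Hit &a, const Hit &b) {
    if (a.chrom != b.chrom) return a.chrom < b.chrom;
    if (a.start != b.start) return a.start < b.start;
    return a.minus < b.minus;
  });
  hits.erase(std::unique(hits.begin(), hits.end(),
                         [](const Hit &a, const Hit &b) {
                           return a.chrom == b.chrom && a.start == b.start &&
                                  a.minus == b.minus;
                         }),
             hits.end());
}

static List hits_to_list(const std::vector<std::vector<Hit> > &all,
                         const LogicalVector &dropped) {
  size_t total = 0;
  for (const auto &h : all) total += h.size();
  IntegerVector read_idx(total), chrom_idx(total), start0(total), mm(total);
  CharacterVector strand(total);
  size_t j = 0;
  for (size_t i = 0; i < all.size(); ++i) {
    for (const Hit &h : all[i]) {
      read_idx[j] = (int)i + 1;
      chrom_idx[j] = h.chrom + 1;
      start0[j] = h.start;
      strand[j] = h.minus ? "-" : "+";
      mm[j] = h.mm;
      ++j;
    }
  }
  return List::create(_["read_idx"] = read_idx, _["chrom_idx"] = chrom_idx,
                      _["start0"] = start0, _["strand"] = strand,
                      _["mismatches"] = mm, _["dropped"] = dropped);
}

// [[Rcpp::export(name = ".align_seed_cpp")]]
List align_seed_cpp(CharacterVector reads, CharacterVector chrom_seqs,
                    int max_mismatch, int max_positions) {
  const int k = 10;
  if (max_mismatch < 0 || max_mismatch > 1)
    stop("max_mismatch must be 0 or 1 for the seed aligner");

  int nchrom = chrom_seqs.size();
  std::vector<std::string> genome(nchrom);
  for (int c = 0; c < nchrom; ++c) genome[c] = as<std::string>(chrom_seqs[c]);

  // k-mer index: packed kmer -> vector of (chrom, pos)
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > index;
  for (int c = 0; c < nchrom; ++c) {
    const std::string &g = genome[c];
    if ((int)g.size() < k) continue;
    for (size_t p = 0; p + k <= g.size(); ++p) {
      uint64_t key;
      if (encode_kmer(g, p, k, key)) index[key].push_back({c, (int)p});
    }
  }

  int nreads = reads.size();
  std::vector<std::vector<Hit> > all(nreads);
  LogicalVector dropped(nreads, false);

  for (int i = 0; i < nreads; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    if ((int)fwd.size() < 2 * k)
      stop("read %d is shorter than %d nt; the seed aligner requires >= %d",
           i + 1, 2 * k, 2 * k);
    std::string rev = revcomp(fwd);
    std::vector<Hit> hits;

    for (int ori = 0; ori < 2; ++ori) {
      const std::string &r = (ori == 0) ? fwd : rev;
      // candidate starts from two disjoint seeds
      std::vector<std::pair<int, int> > cand;
      for (int s = 0; s < 2; ++s) {
        size_t off = (size_t)s * k;
        uint64_t key;
        if (!encode_kmer(r, off, k, key)) continue;
        auto it = index.find(key);
        if (it == index.end()) continue;
        for (auto &cp : it->second) {
          int start = cp.second - (int)off;
          if (start < 0) continue;
          cand.push_back({cp.first, start});
        }
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (auto &cp : cand) {
        const std::string &g = genome[cp.first];
        if ((size_t)cp.second + r.size() > g.size()) continue;
        int mm = hamming_le(g, (size_t)cp.second, r, max_mismatch);
        if (mm >= 0) hits.push_back({cp.first, cp.second, ori == 1, mm});
      }
    }
    collect_hits(hits, max_positions);
    if ((int)hits.size() > max_positions) {
      dropped[i] = true;
      hits.clear();
    }
    all[i] = std::move(hits);
  }
  return hits_to_list(all, dropped);
}

// [[Rcpp::export(name = ".align_brute_cpp")]]
List align_brute_cpp(CharacterVector reads, CharacterVector chrom_seqs,
                     int max_mismatch, int max_positions) {
  int nchrom = chrom_seqs.size();
  std::vector<std::string> genome(nchrom);
  for (int c = 0; c < nchrom; ++c) genome[c] = as<std::string>(chrom_seqs[c]);

  int nreads = reads.size();
  std::vector<std::vector<Hit> > all(nreads);
  LogicalVector dropped(nreads, false);

  for (int i = 0; i < nreads; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    std::string rev = revcomp(fwd);
    std::vector<Hit> hits;
    for (int ori = 0; ori < 2; ++ori) {
      const std::string &r = (ori == 0) ? fwd : rev;
      for (int c = 0; c < nchrom; ++c) {
        const std::string &g = genome[c];
        if (r.size() > g.size()) continue;
        for (size_t p = 0; p + r.size() <= g.size(); ++p) {
          int mm = hamming_le(g, p, r, max_mismatch);
          if (mm >= 0) hits.push_back({c, (int)p, ori == 1, mm});
        }
      }
    }
    collect_hits(hits, max_positions);
    if ((int)hits.size() > max_positions) {
      dropped[i] = true;
      hits.clear();
    }
    all[i] = std::move(hits);
  }
  return hits_to_list(all, dropped);
}
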