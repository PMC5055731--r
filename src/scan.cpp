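#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// IUPAC-as-bitmask base encoding. Genome sequences are expected to contain
// only A, C, G, T, N (N encodes to 0 and never matches anything). Probe
// queries may additionally contain R (purine: A|G) and Y (pyrimidine: C|T).
static inline int basemask(char c) {
  switch (c) {
  case 'A': return 1;
  case 'C': return 2;
  case 'G': return 4;
  case 'T': return 8;
  case 'R': return 1 | 4;
  case 'Y': return 2 | 8;
  default:  return 0;
  }
}

// [[Rcpp::export(name = ".cpp_scan_brute")]]
List cpp_scan_brute(CharacterVector queries, std::string genome, int min_count) {
  const int L = (int) genome.size();
  std::vector<int> gmask(L);
  for (int i = 0; i < L; ++i) gmask[i] = basemask(genome[i]);

  const int nq = queries.size();
  List out(nq);
  for (int q = 0; q < nq; ++q) {
    std::string qs = as<std::string>(queries[q]);
    const int w = (int) qs.size();
    std::vector<int> qmask(w);
    for (int i = 0; i < w; ++i) qmask[i] = basemask(qs[i]);
    std::vector<int> starts, counts;
    const int budget = w - min_count;  // allowed mismatches
    for (int s = 0; s + w <= L; ++s) {
      int mm = 0;
      for (int i = 0; i < w; ++i) {
        if ((qmask[i] & gmask[s + i]) == 0) {
          if (++mm > budget) break;
        }
      }
      if (mm <= budget) {
        starts.push_back(s);
        counts.push_back(w - mm);
      }
    }
    out[q] = List::create(_["start"] = wrap(starts), _["count"] = wrap(counts));
  }
  return out;
}

static inline int code2bit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// Enumerate all exact k-mer codes compatible with a (possibly degenerate)
// query seed. Returns false if expansion exceeds `cap` or a position has an
// empty mask.
static bool expand_seed(const std::vector<int>& qmask, int off, int k,
                        std::vector<uint32_t>& codes, size_t cap) {
  codes.clear();
  codes.push_back(0u);
  for (int i = 0; i < k; ++i) {
    int m = qmask[off + i];
    if (m == 0) return false;
    std::vector<int> opts;
    for (int b = 0; b < 4; ++b) if (m & (1 << b)) opts.push_back(b);
    size_t n = codes.size();
    if (n * opts.size() > cap) return false;
    std::vector<uint32_t> next;
    next.reserve(n * opts.size());
    for (size_t j = 0; j < n; ++j)
      for (size_t o = 0; o < opts.size(); ++o)
        next.push_back((codes[j] << 2) | (uint32_t) opts[o]);
    codes.swap(next);
  }
  return true;
}

// Seed-and-extend scan: exact k-mer seeds at non-overlapping offsets
// 0, k, 2k, ... within the query, hash lookup in the genome, then ungapped
// verification of each candidate window. With s = floor(w/k) seeds, any
// window with at most s-1 mismatches is guaranteed to be found (pigeonhole);
// i.e. completeness holds for min_count >= w - floor(w/k) + 1.
// [[Rcpp::export(name = ".cpp_scan_seeded")]]
List cpp_scan_seeded(CharacterVector queries, std::string genome,
                     int min_count, int k) {
  const int L = (int) genome.size();
  std::vector<int> gmask(L);
  for (int i = 0; i < L; ++i) gmask[i] = basemask(genome[i]);

  // hash index of genome k-mers (skipping windows containing non-ACGT)
  std::unordered_map<uint32_t, std::vector<int> > index;
  index.reserve((size_t) std::max(16, L));
  if (L >= k) {
    uint32_t code = 0;
    const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
    int valid = 0;  // number of consecutive valid bases ending at i
    for (int i = 0; i < L; ++i) {
      int b = code2bit(genome[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t) b) & mask;
      if (++valid >= k) index[code].push_back(i - k + 1);
    }
  }

  const size_t CAP = 4096;
  const int nq = queries.size();
  List out(nq);
  for (int q = 0; q < nq; ++q) {
    std::string qs = as<std::string>(queries[q]);
    const int w = (int) qs.size();
    std::vector<int> qmask(w);
    for (int i = 0; i < w; ++i) qmask[i] = basemask(qs[i]);

    std::vector<int> cand;
    std::vector<uint32_t> codes;
    for (int off = 0; off + k <= w; off += k) {
      if (!expand_seed(qmask, off, k, codes, CAP)) continue;
      for (size_t c = 0; c < codes.size(); ++c) {
        std::unordered_map<uint32_t, std::vector<int> >::const_iterator it =
          index.find(codes[c]);
        if (it == index.end()) continue;
        for (size_t j = 0; j < it->second.size(); ++j) {
          int s = it->second[j] - off;
          if (s >= 0 && s + w <= L) cand.push_back(s);
        }
      }
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

    std::vector<int> starts, counts;
    const int budget = w - min_count;
    for (size_t ci = 0; ci < cand.size(); ++ci) {
      int s = cand[ci];
      int mm = 0;
      for (int i = 0; i < w; ++i) {
        if ((qmask[i] & gmask[s + i]) == 0) {
          if (++mm > budget) break;
        }
      }
      if (mm <= budget) {
        starts.push_back(s);
        counts.push_back(w - mm);
      }
    }
    out[q] = List::create(_["start"] = wrap(starts), _["count"] = wrap(counts));
  }
  return out;
}
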