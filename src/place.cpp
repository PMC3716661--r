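#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Bounded-mismatch placement of short tags on a set of reference sequences.
// Exact k-mer seeding (pigeonhole over max_mm + 1 tag segments) followed by
// full-length Hamming verification. Only A/C/G/T participate in seeds; any
// other character mismatches everything during verification.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char upper_base(char c) {
  if (c >= 'a' && c <= 'z') return c - 32;
  return c;
}

struct SeedIndex {
  int k;
  std::vector<std::vector<std::pair<int32_t, int32_t> > > buckets; // (chrom, pos)
};

static void build_index(const std::vector<std::string>& seqs, int k, SeedIndex& idx) {
  idx.k = k;
  size_t nbuck = (size_t)1 << (2 * k);
  idx.buckets.assign(nbuck, std::vector<std::pair<int32_t, int32_t> >());
  uint32_t mask = (uint32_t)(nbuck - 1);
  for (size_t ci = 0; ci < seqs.size(); ++ci) {
    const std::string& s = seqs[ci];
    if ((int)s.size() < k) continue;
    uint32_t code = 0;
    int valid = 0; // run length of consecutive valid bases ending here
    for (size_t p = 0; p < s.size(); ++p) {
      int b = base_code(s[p]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)b) & mask;
      if (++valid >= k)
        idx.buckets[code].push_back(std::make_pair((int32_t)ci, (int32_t)(p - k + 1)));
    }
  }
}

static inline int hamming_at(const std::string& ref, int32_t start,
                             const std::string& tag, int max_keep) {
  int mm = 0;
  for (size_t i = 0; i < tag.size(); ++i) {
    char a = upper_base(ref[start + i]);
    char b = upper_base(tag[i]);
    if (a != b || base_code(a) < 0) {
      if (++mm > max_keep) return mm;
    }
  }
  return mm;
}

static std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = upper_base(s[s.size() - 1 - i]);
    switch (c) {
      case 'A': r[i] = 'T'; break;
      case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break;
      case 'T': r[i] = 'A'; break;
      default:  r[i] = 'N'; break;
    }
  }
  return r;
}

// Search one oriented query; append hits (chrom, start, mm) avoiding duplicates.
static void search_oriented(const SeedIndex& idx,
                            const std::vector<std::string>& seqs,
                            const std::string& q, int max_mm,
                            std::vector<std::pair<int64_t, int> >& hits) {
  int L = (int)q.size();
  int k = idx.k;
  if (L < k) return;
  int nseg = max_mm + 1;
  int max_segs = L / k;
  if (max_segs < 1) return;
  if (nseg > max_segs) nseg = max_segs; // short tags: reduced guarantee
  uint32_t mask = (idx.buckets.size() > 1)
    ? (uint32_t)(idx.buckets.size() - 1) : 0u;
  for (int s = 0; s < nseg; ++s) {
    int off = (int)(((int64_t)s * L) / nseg); // segment start; first k bases are the seed
    if (off + k > L) off = L - k;
    uint32_t code = 0; bool ok = true;
    for (int i = 0; i < k; ++i) {
      int b = base_code(q[off + i]);
      if (b < 0) { ok = false; break; }
      code = ((code << 2) | (uint32_t)b) & mask;
    }
    if (!ok) continue;
    const std::vector<std::pair<int32_t, int32_t> >& bucket = idx.buckets[code];
    for (size_t h = 0; h < bucket.size(); ++h) {
      int32_t ci = bucket[h].first;
      int64_t start = (int64_t)bucket[h].second - off;
      if (start < 0) continue;
      const std::string& ref = seqs[ci];
      if (start + L > (int64_t)ref.size()) continue;
      int mm = hamming_at(ref, (int32_t)start, q, max_mm);
      if (mm <= max_mm) {
        int64_t key = ((int64_t)ci << 40) | start;
        hits.push_back(std::make_pair(key, mm));
      }
    }
  }
}

// [[Rcpp::export(name = ".place_tags_cpp")]]
List place_tags_cpp(CharacterVector tags, CharacterVector ref_seqs,
                    int seed_len, int max_mm, bool both_strands) {
  if (seed_len < 4 || seed_len > 14)
    stop("seed_len must be between 4 and 14");
  if (max_mm < 0) stop("max_mm must be >= 0");
  std::vector<std::string> seqs(ref_seqs.size());
  for (int i = 0; i < ref_seqs.size(); ++i) seqs[i] = as<std::string>(ref_seqs[i]);
  SeedIndex idx;
  build_index(seqs, seed_len, idx);

  std::vector<int> out_tag, out_chrom, out_mm;
  std::vector<double> out_start;
  std::vector<int> out_strand; // 1 = forward, -1 = reverse

  for (int t = 0; t < tags.size(); ++t) {
    std::string q = as<std::string>(tags[t]);
    for (int strand = 0; strand < (both_strands ? 2 : 1); ++strand) {
      std::string oriented = (strand == 0) ? q : revcomp(q);
      std::vector<std::pair<int64_t, int> > hits;
      search_oriented(idx, seqs, oriented, max_mm, hits);
      // dedupe (same position reachable from several seeds)
      std::sort(hits.begin(), hits.end());
      for (size_t h = 0; h < hits.size(); ++h) {
        if (h > 0 && hits[h].first == hits[h - 1].first) continue;
        int ci = (int)(hits[h].first >> 40);
        int64_t start = hits[h].first & ((((int64_t)1) << 40) - 1);
        out_tag.push_back(t + 1);
        out_chrom.push_back(ci + 1);
        out_start.push_back((double)start);
        out_strand.push_back(strand == 0 ? 1 : -1);
        out_mm.push_back(hits[h].second);
      }
    }
    if (t % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["tag"] = out_tag, _["chrom"] = out_chrom,
                      _["start"] = out_start, _["strand"] = out_strand,
                      _["mismatches"] = out_mm);
}
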