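#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Exhaustive ungapped scanning of short reads against reference sequences.
// The contract is bowtie -v style: full-length read comparison, mismatch
// counting with a hard cap, both strands, all placements in the best
// (minimal-mismatch) stratum. Sequences must be uppercase A/C/G/T; any
// non-ACGT symbol in a read counts as a mismatch at that position.

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
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

static std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp(s[i]);
  return out;
}

// mismatches between read r (length len) and window w, bailing out once the
// count exceeds cap (returns cap + 1 in that case)
static inline int mm_count(const char* r, const char* w, int len, int cap) {
  int mm = 0;
  for (int i = 0; i < len; ++i) {
    char rc = r[i];
    if (rc != w[i] || !is_acgt(rc)) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// branchless full mismatch count; auto-vectorizes. Callers sanitize the read
// first so that non-ACGT read symbols can never equal a reference byte.
static inline int mm_full(const char* r, const char* w, int len) {
  int mm = 0;
  for (int i = 0; i < len; ++i) mm += (r[i] != w[i]);
  return mm;
}

// replace any non-ACGT byte with 0x01, which no reference byte can equal, so
// such positions always count as mismatches under plain byte comparison
static std::string sanitize(const std::string& s) {
  std::string out = s;
  for (char& c : out)
    if (!is_acgt(c)) c = '\x01';
  return out;
}

struct Hit {
  int ref;     // 0-based reference index
  int strand;  // 0 = sense, 1 = antisense
  int start;   // 0-based inclusive
  int mm;
};

// [[Rcpp::export]]
DataFrame cpp_align_best(CharacterVector reads, CharacterVector ref_seqs,
                         int max_mm) {
  int n_reads = reads.size(), n_refs = ref_seqs.size();
  std::vector<std::string> refs(n_refs);
  for (int j = 0; j < n_refs; ++j) refs[j] = as<std::string>(ref_seqs[j]);

  std::vector<int> out_read, out_ref, out_strand, out_start, out_mm;

  for (int i = 0; i < n_reads; ++i) {
    std::string rd = sanitize(as<std::string>(reads[i]));
    std::string rc = sanitize(revcomp(as<std::string>(reads[i])));
    int len = rd.size();
    if (len == 0) continue;
    int best = max_mm + 1;
    std::vector<Hit> hits;
    for (int j = 0; j < n_refs; ++j) {
      const std::string& ref = refs[j];
      int last = (int)ref.size() - len;
      for (int p = 0; p <= last; ++p) {
        int m = mm_full(rd.c_str(), ref.c_str() + p, len);
        if (m <= max_mm) {
          if (m < best) best = m;
          hits.push_back({j, 0, p, m});
        }
        m = mm_full(rc.c_str(), ref.c_str() + p, len);
        if (m <= max_mm) {
          if (m < best) best = m;
          hits.push_back({j, 1, p, m});
        }
      }
    }
    for (const Hit& h : hits) {
      if (h.mm == best) {
        out_read.push_back(i + 1);
        out_ref.push_back(h.ref + 1);
        out_strand.push_back(h.strand);
        out_start.push_back(h.start);
        out_mm.push_back(h.mm);
      }
    }
  }

  return DataFrame::create(
    _["read"] = out_read, _["ref"] = out_ref, _["strand"] = out_strand,
    _["start"] = out_start, _["mismatches"] = out_mm);
}

// First reference (1-based index) carrying any full-length placement of the
// read on either strand within max_mm mismatches; NA when none. References
// shorter than the read are skipped.
// [[Rcpp::export]]
IntegerVector cpp_match_any(CharacterVector reads, CharacterVector ref_seqs,
                            int max_mm) {
  int n_reads = reads.size(), n_refs = ref_seqs.size();
  std::vector<std::string> refs(n_refs);
  for (int j = 0; j < n_refs; ++j) refs[j] = as<std::string>(ref_seqs[j]);

  IntegerVector out(n_reads, NA_INTEGER);
  for (int i = 0; i < n_reads; ++i) {
    std::string rd = sanitize(as<std::string>(reads[i]));
    std::string rc = sanitize(revcomp(as<std::string>(reads[i])));
    int len = rd.size();
    if (len == 0) continue;
    for (int j = 0; j < n_refs && out[i] == NA_INTEGER; ++j) {
      const std::string& ref = refs[j];
      int last = (int)ref.size() - len;
      for (int p = 0; p <= last; ++p) {
        if (mm_full(rd.c_str(), ref.c_str() + p, len) <= max_mm ||
            mm_full(rc.c_str(), ref.c_str() + p, len) <= max_mm) {
          out[i] = j + 1;
          break;
        }
      }
    }
  }
  return out;
}

// Leftmost 3' adapter occurrence: either a full-adapter match anywhere, or an
// adapter prefix of length >= min_overlap ending at the read's 3' terminus,
// within floor(rate * overlap) mismatches. Returns the prefix length before
// the occurrence and a found flag (prefix length = read length when absent).
// [[Rcpp::export]]
List cpp_trim_adapter(CharacterVector reads, std::string adapter,
                      int min_overlap, double max_mismatch_rate) {
  int n = reads.size();
  int alen = adapter.size();
  IntegerVector prefix_len(n);
  LogicalVector found(n);
  for (int i = 0; i < n; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int len = rd.size();
    prefix_len[i] = len;
    found[i] = false;
    for (int p = 0; p < len; ++p) {
      int ov = std::min(alen, len - p);
      bool full = (ov == alen);
      bool at_end = (p + ov == len);
      if (!full && !(at_end && ov >= min_overlap)) continue;
      int cap = (int)std::floor(max_mismatch_rate * ov);
      if (mm_count(adapter.c_str(), rd.c_str() + p, ov, cap) <= cap) {
        prefix_len[i] = p;
        found[i] = true;
        break;
      }
    }
  }
  return List::create(_["prefix_len"] = prefix_len, _["found"] = found);
}
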