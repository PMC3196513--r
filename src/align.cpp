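#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// 2-bit-ish encoding; anything outside ACGT maps to -1 and never matches.
static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': v[i] = 0; break;
      case 'C': v[i] = 1; break;
      case 'G': v[i] = 2; break;
      case 'T': v[i] = 3; break;
      default:  v[i] = -1;
    }
  }
  return v;
}

static std::vector<int> revcomp(const std::vector<int>& v) {
  std::vector<int> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int b = v[v.size() - 1 - i];
    r[i] = (b < 0) ? -1 : 3 - b;
  }
  return r;
}

// Exhaustive ungapped Hamming placement of each read against both strands of
// the reference, with early abandoning above the current best mismatch count.
// Returns, per read, the best-scoring start (1-based), strand, mismatch count
// and the number of positions tied at the best score (across both strands);
// a read is placeable iff tie_count == 1 and mismatches <= max_mismatch.
// [[Rcpp::export]]
DataFrame align_scan_cpp(CharacterVector reads, std::string ref,
                         int max_mismatch) {
  const std::vector<int> R = encode(ref);
  const int L = (int) R.size();
  const int n = reads.size();

  IntegerVector out_pos(n, NA_INTEGER);
  CharacterVector out_strand(n, NA_STRING);
  IntegerVector out_mm(n, NA_INTEGER);
  IntegerVector out_ties(n, 0);
  LogicalVector out_skipped(n, false);

  for (int i = 0; i < n; ++i) {
    const std::string rd = as<std::string>(reads[i]);
    const int len = (int) rd.size();
    if (len > L) { out_skipped[i] = true; continue; }
    const std::vector<int> fwd = encode(rd);
    const std::vector<int> rev = revcomp(fwd);

    int best = max_mismatch + 1, best_pos = -1, ties = 0;
    char best_strand = '+';
    // fast path: census exact matches on both strands with memcmp; nothing
    // can beat a zero-mismatch placement, so the scan is skipped entirely
    for (int strand = 0; strand < 2; ++strand) {
      const std::vector<int>& q = strand == 0 ? fwd : rev;
      for (int p = 0; p + len <= L; ++p) {
        if (std::memcmp(q.data(), R.data() + p, len * sizeof(int)) == 0) {
          if (best > 0) {
            best = 0; best_pos = p; ties = 1;
            best_strand = strand == 0 ? '+' : '-';
          } else {
            ++ties;
          }
        }
      }
    }
    if (best > 0) {
      for (int strand = 0; strand < 2; ++strand) {
        const std::vector<int>& q = strand == 0 ? fwd : rev;
        for (int p = 0; p + len <= L; ++p) {
          int mm = 0;
          for (int k = 0; k < len; ++k) {
            if (q[k] != R[p + k]) {
              if (++mm > best) break;
            }
          }
          if (mm < best && mm > 0) {
            best = mm; best_pos = p; ties = 1;
            best_strand = strand == 0 ? '+' : '-';
          } else if (mm == best && mm > 0 && best <= max_mismatch) {
            ++ties;
          }
        }
      }
    }
    if (best <= max_mismatch) {
      out_pos[i] = best_pos + 1;
      out_strand[i] = std::string(1, best_strand);
      out_mm[i] = best;
      out_ties[i] = ties;
    }
  }
  return DataFrame::create(
    _["pos"] = out_pos, _["strand"] = out_strand, _["mismatch_count"] = out_mm,
    _["ties"] = out_ties, _["skipped"] = out_skipped,
    _["stringsAsFactors"] = false);
}
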