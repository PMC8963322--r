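#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>

using namespace Rcpp;

static inline char comp_base(char b) {
  switch (b) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// Gapless, full-sensitivity placement scan for short (18-31 nt) reads.
// Every offset on both strands is verified with early-exit mismatch
// counting; a placement is reported when matches / read_length >=
// min_fraction. 'N' in either read or reference never counts as a match.
// Coordinates are 0-based half-open on the reference.
// [[Rcpp::export]]
List scan_reads_cpp(CharacterVector read_seqs, CharacterVector read_ids,
                    CharacterVector contig_seqs, CharacterVector contig_ids,
                    double min_fraction) {
  const int nr = read_seqs.size();
  const int nc = contig_seqs.size();

  std::vector<std::string> contigs(nc);
  for (int j = 0; j < nc; ++j) contigs[j] = as<std::string>(contig_seqs[j]);

  std::vector<int> o_read, o_contig, o_start, o_len, o_matches;
  std::vector<int> o_sense;  // 1 = sense, 0 = antisense

  for (int i = 0; i < nr; ++i) {
    const std::string fwd = as<std::string>(read_seqs[i]);
    const int L = (int)fwd.size();
    if (L == 0) continue;
    std::string rev(L, 'N');
    for (int p = 0; p < L; ++p) rev[p] = comp_base(fwd[L - 1 - p]);

    // matches/L >= t  <=>  matches >= ceil(t*L) (guard fp noise)
    const int min_matches = (int)std::ceil(min_fraction * L - 1e-9);
    const int allowed = L - min_matches;

    for (int j = 0; j < nc; ++j) {
      const std::string &C = contigs[j];
      const int last = (int)C.size() - L;
      for (int s = 0; s <= last; ++s) {
        for (int strand = 0; strand < 2; ++strand) {
          const std::string &R = (strand == 0) ? fwd : rev;
          int mism = 0;
          for (int p = 0; p < L; ++p) {
            const char rb = R[p];
            if (rb != C[s + p] || rb == 'N') {
              if (++mism > allowed) break;
            }
          }
          if (mism <= allowed) {
            o_read.push_back(i);
            o_contig.push_back(j);
            o_start.push_back(s);
            o_len.push_back(L);
            o_matches.push_back(L - mism);
            o_sense.push_back(strand == 0 ? 1 : 0);
          }
        }
      }
    }
  }

  const int n = (int)o_read.size();
  CharacterVector rid(n), cid(n), strand(n);
  IntegerVector start(n), end(n), matches(n);
  NumericVector fraction(n);
  for (int k = 0; k < n; ++k) {
    rid[k] = read_ids[o_read[k]];
    cid[k] = contig_ids[o_contig[k]];
    start[k] = o_start[k];
    end[k] = o_start[k] + o_len[k];
    matches[k] = o_matches[k];
    fraction[k] = (double)o_matches[k] / (double)o_len[k];
    strand[k] = o_sense[k] ? "sense" : "antisense";
  }
  return List::create(_["read_id"] = rid, _["contig_id"] = cid,
                      _["start"] = start, _["end"] = end,
                      _["strand"] = strand, _["matches"] = matches,
                      _["match_fraction"] = fraction);
}
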