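#include <Rcpp.h>
using namespace Rcpp;

// Ungapped sliding-offset placement of each read on one reference string.
// Reads and reference are expected in the reduced (C->T) alphabet; ties in
// mismatch count resolve to the smallest offset. Offsets are 0-based.
// [[Rcpp::export]]
DataFrame sliding_align_cpp(CharacterVector reads, std::string ref,
                            double max_mismatch_frac) {
  const int n = reads.size();
  const int L = (int) ref.size();
  IntegerVector offset(n), mism(n);
  LogicalVector accepted(n);
  for (int i = 0; i < n; ++i) {
    SEXP s = STRING_ELT(reads, i);
    const char *r = CHAR(s);
    const int rl = (int) LENGTH(s);
    const int max_off = L - rl;
    if (rl == 0 || max_off < 0) {
      offset[i] = NA_INTEGER; mism[i] = NA_INTEGER; accepted[i] = false;
      continue;
    }
    int best = rl + 1, best_off = 0;
    for (int o = 0; o <= max_off; ++o) {
      int m = 0;
      const char *t = ref.c_str() + o;
      for (int p = 0; p < rl; ++p) {
        if (r[p] != t[p] && ++m >= best) break;
      }
      if (m < best) { best = m; best_off = o; if (best == 0) break; }
    }
    offset[i] = best_off;
    mism[i] = best;
    accepted[i] = best <= (int) std::floor(max_mismatch_frac * rl);
  }
  return DataFrame::create(_["offset"] = offset, _["mismatches"] = mism,
                           _["accepted"] = accepted);
}

// Mismatches of each read against each reference, anchored at the reference
// start (from_end = false) or end (from_end = true), over the overlap only.
// Used for amplicon assignment; returns an n_reads x n_refs integer matrix.
// [[Rcpp::export]]
IntegerMatrix anchored_mismatch_cpp(CharacterVector reads,
                                    CharacterVector refs, bool from_end) {
  const int n = reads.size(), k = refs.size();
  IntegerMatrix out(n, k);
  for (int j = 0; j < k; ++j) {
    SEXP rs = STRING_ELT(refs, j);
    const char *ref = CHAR(rs);
    const int L = (int) LENGTH(rs);
    for (int i = 0; i < n; ++i) {
      SEXP s = STRING_ELT(reads, i);
      const char *r = CHAR(s);
      const int rl = (int) LENGTH(s);
      const int ov = rl < L ? rl : L;
      const char *t = from_end ? ref + (L - ov) : ref;
      const char *q = from_end ? r + (rl - ov) : r;
      int m = rl - ov;  // unaligned read bases count as mismatches
      for (int p = 0; p < ov; ++p) if (q[p] != t[p]) ++m;
      out(i, j) = m;
    }
  }
  return out;
}
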