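#include <Rcpp.h>
using namespace Rcpp;

// FLASh-style overlap merging of read pairs.
//
// For each pair, r1 is compared against the reverse complement of r2 (rc2,
// computed by the caller). Candidate overlaps align the 3' end of r1 with
// the 5' end of rc2; overlap length o runs from min(len1, len2) down to
// min_overlap and the first (i.e. longest) overlap with mismatch rate
// <= max_mismatch_rate is accepted. At disagreeing positions the base with
// the higher quality score wins. Returns NA for pairs with no qualifying
// overlap.
//
// [[Rcpp::export]]
List overlap_merge_cpp(CharacterVector r1, CharacterVector rc2,
                       CharacterVector q1, CharacterVector q2r,
                       int min_overlap, double max_mismatch_rate) {
  int n = r1.size();
  CharacterVector merged(n);
  LogicalVector ok(n);
  IntegerVector overlap(n);
  for (int i = 0; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(r1, i));
    const char *b = CHAR(STRING_ELT(rc2, i));
    const char *qa = CHAR(STRING_ELT(q1, i));
    const char *qb = CHAR(STRING_ELT(q2r, i));
    int la = LENGTH(STRING_ELT(r1, i));
    int lb = LENGTH(STRING_ELT(rc2, i));
    int omax = la < lb ? la : lb;
    int best = -1;
    for (int o = omax; o >= min_overlap; --o) {
      int allowed = (int)(max_mismatch_rate * o);
      int mism = 0;
      const char *pa = a + (la - o);
      bool pass = true;
      for (int k = 0; k < o; ++k) {
        if (pa[k] != b[k]) {
          if (++mism > allowed) { pass = false; break; }
        }
      }
      if (pass) { best = o; break; }
    }
    if (best < 0) {
      merged[i] = NA_STRING;
      ok[i] = false;
      overlap[i] = 0;
      continue;
    }
    int o = best;
    std::string out(a, a + la);
    // overlap region: take the higher-quality base at disagreements
    for (int k = 0; k < o; ++k) {
      int pa = la - o + k;
      if (a[pa] != b[k] && (unsigned char)qb[k] > (unsigned char)qa[pa])
        out[pa] = b[k];
    }
    out.append(b + o, b + lb);
    merged[i] = out;
    ok[i] = true;
    overlap[i] = o;
  }
  return List::create(_["merged"] = merged, _["ok"] = ok,
                      _["overlap"] = overlap);
}
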