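#include <Rcpp.h>
#include <cinttypes>
#include <cstdio>
using namespace Rcpp;

// 64-bit FNV-1a digest of each string, returned as 16-char lower-case hex.
// Used for feature-row deduplication; non-cryptographic by design.
// [[Rcpp::export]]
CharacterVector fnv1a64(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  char buf[17];
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char *s = CHAR(STRING_ELT(x, i));
    uint64_t h = 14695981039346656037ULL;
    for (const unsigned char *p = (const unsigned char*) s; *p; ++p) {
      h ^= (uint64_t) *p;
      h *= 1099511628211ULL;
    }
    std::snprintf(buf, sizeof buf, "%016" PRIx64, h);
    out[i] = buf;
  }
  return out;
}
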