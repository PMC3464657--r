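#include <Rcpp.h>
using namespace Rcpp;

// 32-bit FNV-1a over the UTF-8 bytes of each string, masked to `bits` bits.
// Platform-independent: everything is done in unsigned 32-bit arithmetic.
// [[Rcpp::export(name = ".fnv1a_hash")]]
IntegerVector fnv1a_hash(CharacterVector x, int bits) {
  if (bits < 1 || bits > 30) stop("bits must be in [1, 30]");
  const uint32_t prime = 16777619u;
  const uint32_t mask = (1u << bits) - 1u;
  R_xlen_t n = x.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_INTEGER; continue; }
    const char *s = CHAR(STRING_ELT(x, i));
    uint32_t h = 2166136261u;
    for (const unsigned char *p = (const unsigned char *)s; *p; ++p) {
      h ^= (uint32_t)(*p);
      h *= prime;
    }
    out[i] = (int)(h & mask);
  }
  return out;
}
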