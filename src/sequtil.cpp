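#include <Rcpp.h>
#include <string>
using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) r[j] = comp(s[s.size() - 1 - j]);
    out[i] = r;
  }
  return out;
}
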