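#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

// Two-row dynamic-programming Levenshtein distance (unit costs).
static int lev_one(const std::string &a, const std::string &b) {
  const size_t na = a.size(), nb = b.size();
  if (na == 0) return (int)nb;
  if (nb == 0) return (int)na;
  std::vector<int> prev(nb + 1), cur(nb + 1);
  for (size_t j = 0; j <= nb; ++j) prev[j] = (int)j;
  for (size_t i = 1; i <= na; ++i) {
    cur[0] = (int)i;
    const char ca = a[i - 1];
    for (size_t j = 1; j <= nb; ++j) {
      int sub = prev[j - 1] + (ca == b[j - 1] ? 0 : 1);
      cur[j] = std::min(sub, std::min(prev[j] + 1, cur[j - 1] + 1));
    }
    std::swap(prev, cur);
  }
  return prev[nb];
}

// [[Rcpp::export(name = ".lev_dist_cpp")]]
Rcpp::IntegerVector lev_dist_cpp(Rcpp::CharacterVector a, Rcpp::CharacterVector b) {
  R_xlen_t na = a.size(), nb = b.size();
  R_xlen_t n = std::max(na, nb);
  if (na == 0 || nb == 0) return Rcpp::IntegerVector(0);
  if (na != nb && na != 1 && nb != 1)
    Rcpp::stop("lengths must match or one input must be scalar");
  Rcpp::IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    Rcpp::String sa = a[na == 1 ? 0 : i];
    Rcpp::String sb = b[nb == 1 ? 0 : i];
    if (sa == NA_STRING || sb == NA_STRING) {
      out[i] = NA_INTEGER;
    } else {
      out[i] = lev_one(std::string(sa.get_cstring()), std::string(sb.get_cstring()));
    }
  }
  return out;
}
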