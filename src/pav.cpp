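#include <Rcpp.h>
using namespace Rcpp;

// Pool-adjacent-violators: weighted least-squares isotonic (non-decreasing)
// fit to y in the given order. Uniform weights; O(n).
// [[Rcpp::export]]
NumericVector pav_increasing(NumericVector y) {
  int n = y.size();
  NumericVector out(n);
  if (n == 0) return out;
  std::vector<double> level(n), weight(n);
  std::vector<int> len(n);
  int top = -1;
  for (int i = 0; i < n; ++i) {
    ++top;
    level[top] = y[i];
    weight[top] = 1.0;
    len[top] = 1;
    while (top > 0 && level[top - 1] > level[top]) {
      double w = weight[top - 1] + weight[top];
      level[top - 1] = (weight[top - 1] * level[top - 1] +
                        weight[top] * level[top]) / w;
      weight[top - 1] = w;
      len[top - 1] += len[top];
      --top;
    }
  }
  int pos = 0;
  for (int b = 0; b <= top; ++b)
    for (int k = 0; k < len[b]; ++k) out[pos++] = level[b];
  return out;
}
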