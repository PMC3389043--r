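#include <Rcpp.h>
using namespace Rcpp;

// Semi-global (glocal) alignment statistics for the pairwise identity
// underlying OTU clustering: the pattern is aligned end-to-end against
// the best-scoring region of the subject (free subject overhangs), with
// affine gap costs. Returns c(matches, columns) of the optimal alignment;
// identity = matches / columns. Call with the shorter sequence as the
// pattern so the statistic is symmetric.

// [[Rcpp::export]]
NumericVector glocal_align_stats_cpp(std::string pattern,
                                     std::string subject,
                                     double match, double mismatch,
                                     double gap_open, double gap_ext) {
  const int n = pattern.size(), m = subject.size();
  const double NEG = -1e30;
  const int W = m + 1;
  // states: M (aligned pair), X (gap in subject, consumes pattern),
  // Y (gap in pattern, consumes subject; internal only)
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  std::vector<unsigned char> tM((n + 1) * W, 0), tX((n + 1) * W, 0),
      tY((n + 1) * W, 0);

  for (int j = 0; j <= m; ++j) M[j] = 0.0;  // free subject prefix
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -gap_open - gap_ext * i;
    tX[i * W] = (i == 1) ? 1 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s =
          (pattern[i - 1] == subject[j - 1]) ? match : mismatch;
      double bm = M[(i - 1) * W + (j - 1)];
      unsigned char tm = 1;
      if (X[(i - 1) * W + (j - 1)] > bm) {
        bm = X[(i - 1) * W + (j - 1)]; tm = 2;
      }
      if (Y[(i - 1) * W + (j - 1)] > bm) {
        bm = Y[(i - 1) * W + (j - 1)]; tm = 3;
      }
      M[i * W + j] = bm + s;
      tM[i * W + j] = tm;

      double open = M[(i - 1) * W + j] - gap_open - gap_ext;
      double ext  = X[(i - 1) * W + j] - gap_ext;
      if (open >= ext) { X[i * W + j] = open; tX[i * W + j] = 1; }
      else             { X[i * W + j] = ext;  tX[i * W + j] = 2; }

      open = M[i * W + (j - 1)] - gap_open - gap_ext;
      ext  = Y[i * W + (j - 1)] - gap_ext;
      if (open >= ext) { Y[i * W + j] = open; tY[i * W + j] = 1; }
      else             { Y[i * W + j] = ext;  tY[i * W + j] = 2; }
    }
  }

  // end: pattern fully consumed, best j (free subject suffix); do not end
  // in Y (a trailing pattern gap is a subject overhang, which is free)
  int bj = 0;
  char state = 'M';
  double best = NEG;
  for (int j = 0; j <= m; ++j) {
    if (M[n * W + j] > best) { best = M[n * W + j]; bj = j; state = 'M'; }
    if (X[n * W + j] > best) { best = X[n * W + j]; bj = j; state = 'X'; }
  }

  int i = n, j = bj;
  long matches = 0, columns = 0;
  while (i > 0) {
    if (state == 'M') {
      unsigned char t = tM[i * W + j];
      ++columns;
      if (pattern[i - 1] == subject[j - 1]) ++matches;
      --i; --j;
      state = (t == 1) ? 'M' : (t == 2 ? 'X' : 'Y');
    } else if (state == 'X') {
      unsigned char t = tX[i * W + j];
      ++columns;
      --i;
      state = (t == 1) ? 'M' : 'X';
    } else {
      unsigned char t = tY[i * W + j];
      ++columns;
      --j;
      state = (t == 1) ? 'M' : 'Y';
    }
  }
  return NumericVector::create((double)matches, (double)columns,
                               best);
}
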