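#include <Rcpp.h>
using namespace Rcpp;

// Profile-profile global alignment with affine gaps, used by the
// progressive multiple aligner. Profiles are integer matrices (rows =
// sequences, columns = positions) coded 0 = gap, 1..4 = A,C,G,T. The
// column score is the expected substitution score between residue
// frequency vectors (gap cells contribute nothing). Returns the traceback
// path as a vector of moves: 1 = align columns, 2 = column from the first
// profile (gap in the second), 3 = column from the second profile.
//
// Ties are broken deterministically: match > gap-in-second > gap-in-first.

static inline double colScore(const std::vector<double> &fa,
                              const std::vector<double> &fb,
                              double match, double mismatch) {
  double s = 0.0;
  for (int x = 0; x < 4; ++x) {
    for (int y = 0; y < 4; ++y) {
      s += fa[x] * fb[y] * (x == y ? match : mismatch);
    }
  }
  return s;
}

// [[Rcpp::export]]
IntegerVector align_profiles_cpp(IntegerMatrix a, IntegerMatrix b,
                                 double match, double mismatch,
                                 double gap_open, double gap_ext) {
  const int n = a.ncol(), m = b.ncol();
  const int ra = a.nrow(), rb = b.nrow();
  const double NEG = -1e30;

  // residue frequencies per column (normalized by row count, so columns
  // rich in gaps carry proportionally less signal)
  std::vector< std::vector<double> > fa(n, std::vector<double>(4, 0.0));
  std::vector< std::vector<double> > fb(m, std::vector<double>(4, 0.0));
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < ra; ++i)
      if (a(i, j) > 0) fa[j][a(i, j) - 1] += 1.0 / ra;
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < rb; ++i)
      if (b(i, j) > 0) fb[j][b(i, j) - 1] += 1.0 / rb;

  // DP matrices: M = columns aligned, X = gap in b (consume a), Y = gap
  // in a (consume b), stored row-major with (n+1) x (m+1) cells.
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG);
  std::vector<unsigned char> tbM((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbX((n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbY((n + 1) * (m + 1), 0);
  const int W = m + 1;

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -gap_open - gap_ext * i;
    tbX[i * W] = (i == 1) ? 1 : 2;  // 1: came from M, 2: extended X
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -gap_open - gap_ext * j;
    tbY[j] = (j == 1) ? 1 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = colScore(fa[i - 1], fb[j - 1], match, mismatch);
      // M: diagonal from best of M/X/Y
      double bm = M[(i - 1) * W + (j - 1)];
      unsigned char tm = 1;
      if (X[(i - 1) * W + (j - 1)] > bm) {
        bm = X[(i - 1) * W + (j - 1)]; tm = 2;
      }
      if (Y[(i - 1) * W + (j - 1)] > bm) {
        bm = Y[(i - 1) * W + (j - 1)]; tm = 3;
      }
      M[i * W + j] = bm + s;
      tbM[i * W + j] = tm;
      // X: gap in b, consume column of a
      double open = M[(i - 1) * W + j] - gap_open - gap_ext;
      double ext  = X[(i - 1) * W + j] - gap_ext;
      if (open >= ext) { X[i * W + j] = open; tbX[i * W + j] = 1; }
      else             { X[i * W + j] = ext;  tbX[i * W + j] = 2; }
      // Y: gap in a, consume column of b
      open = M[i * W + (j - 1)] - gap_open - gap_ext;
      ext  = Y[i * W + (j - 1)] - gap_ext;
      if (open >= ext) { Y[i * W + j] = open; tbY[i * W + j] = 1; }
      else             { Y[i * W + j] = ext;  tbY[i * W + j] = 2; }
    }
  }

  // traceback from the best of the three end states
  int i = n, j = m;
  char state = 'M';
  double best = M[n * W + m];
  if (X[n * W + m] > best) { best = X[n * W + m]; state = 'X'; }
  if (Y[n * W + m] > best) { best = Y[n * W + m]; state = 'Y'; }

  std::vector<int> rev;
  while (i > 0 || j > 0) {
    if (state == 'M') {
      unsigned char t = tbM[i * W + j];
      rev.push_back(1);
      --i; --j;
      state = (t == 1) ? 'M' : (t == 2 ? 'X' : 'Y');
    } else if (state == 'X') {
      unsigned char t = tbX[i * W + j];
      rev.push_back(2);
      --i;
      state = (t == 1) ? 'M' : 'X';
    } else {
      unsigned char t = tbY[i * W + j];
      rev.push_back(3);
      --j;
      state = (t == 1) ? 'M' : 'Y';
    }
  }
  return IntegerVector(rev.rbegin(), rev.rend());
}
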