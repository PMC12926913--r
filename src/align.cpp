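#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap (Gotoh) alignment routines used by the profile scanner and the
// similarity-graph clustering. Conventions: scores are additive (bits for
// profiles, half-bits for BLOSUM); the first residue of a gap costs
// gap_open + gap_ext, each further residue gap_ext.

static const double NEG_INF = -1e30;

// Local alignment of a position-specific score matrix against a query.
// scores: n_res x n_cols matrix (rows = alphabet, cols = profile positions).
// query: 1-based alphabet indices (values 1..n_res; 0 = unknown residue,
// scored 0 at every column).
// Returns best score, aligned intervals, and a profile-column -> query
// position mapping (0 where the column is deleted in the query).
// [[Rcpp::export]]
List cpp_pssm_local(NumericMatrix scores, IntegerVector query,
                    double gap_open, double gap_ext) {
  const int P = scores.ncol();
  const int Q = query.size();
  if (P == 0 || Q == 0) stop("empty profile or query");

  // DP matrices (P+1) x (Q+1)
  std::vector<double> M((P + 1) * (Q + 1), 0.0);
  std::vector<double> Ix((P + 1) * (Q + 1), NEG_INF); // gap in query (profile col unmatched)
  std::vector<double> Iy((P + 1) * (Q + 1), NEG_INF); // insertion in query
  std::vector<unsigned char> tbM((P + 1) * (Q + 1), 0); // 0=start,1=M,2=Ix,3=Iy
  std::vector<unsigned char> tbX((P + 1) * (Q + 1), 0); // 1=M,2=Ix
  std::vector<unsigned char> tbY((P + 1) * (Q + 1), 0); // 1=M,3=Iy

  auto idx = [Q](int i, int j) { return i * (Q + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= P; ++i) {
    for (int j = 0; j <= Q; ++j) {
      const int k = idx(i, j);
      // Ix: profile column i aligned to a gap
      double oM = M[idx(i - 1, j)] - (gap_open + gap_ext);
      double oX = Ix[idx(i - 1, j)] - gap_ext;
      if (oM >= oX) { Ix[k] = oM; tbX[k] = 1; } else { Ix[k] = oX; tbX[k] = 2; }
      if (j == 0) { M[k] = 0.0; Iy[k] = NEG_INF; continue; }
      // Iy: query residue j unaligned (insertion)
      double pM = M[idx(i, j - 1)] - (gap_open + gap_ext);
      double pY = Iy[idx(i, j - 1)] - gap_ext;
      if (pM >= pY) { Iy[k] = pM; tbY[k] = 1; } else { Iy[k] = pY; tbY[k] = 3; }
      // M: column i matched to residue j
      int a = query[j - 1];
      double s = (a >= 1 && a <= scores.nrow()) ? scores(a - 1, i - 1) : 0.0;
      double dM = M[idx(i - 1, j - 1)];
      double dX = Ix[idx(i - 1, j - 1)];
      double dY = Iy[idx(i - 1, j - 1)];
      double d = dM; unsigned char t = 1;
      if (dX > d) { d = dX; t = 2; }
      if (dY > d) { d = dY; t = 3; }
      if (d < 0.0) { d = 0.0; t = 0; }
      M[k] = d + s;
      tbM[k] = t;
      if (M[k] > best) { best = M[k]; bi = i; bj = j; }
    }
  }

  IntegerVector mapping(P, 0);
  int q_start = 0, q_end = 0, p_start = 0, p_end = 0;
  if (best > 0.0) {
    p_end = bi; q_end = bj;
    int i = bi, j = bj;
    int state = 1; // in M
    while (i > 0 && j > 0) {
      const int k = idx(i, j);
      if (state == 1) {
        mapping[i - 1] = j;
        p_start = i; q_start = j;
        unsigned char t = tbM[k];
        --i; --j;
        if (t == 0) break;
        state = t;
      } else if (state == 2) {
        unsigned char t = tbX[k];
        --i;
        state = t;
      } else {
        unsigned char t = tbY[k];
        --j;
        state = t;
      }
    }
  }

  return List::create(_["score"] = best,
                      _["q_start"] = q_start, _["q_end"] = q_end,
                      _["p_start"] = p_start, _["p_end"] = p_end,
                      _["mapping"] = mapping);
}

static double global_score(const IntegerVector &a, const IntegerVector &b,
                           const NumericMatrix &sub, double go, double ge) {
  const int n = a.size(), m = b.size();
  // Rolling rows; Ix = gap in b (residue of a vs gap), Iy = gap in a.
  std::vector<double> M(m + 1), Ix(m + 1), Iy(m + 1);
  std::vector<double> Mp(m + 1), Ixp(m + 1), Iyp(m + 1);
  Mp[0] = 0.0; Ixp[0] = NEG_INF; Iyp[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG_INF;
    Ixp[j] = NEG_INF;
    Iyp[j] = -(go + ge * j);
  }
  for (int i = 1; i <= n; ++i) {
    M[0] = NEG_INF;
    Iy[0] = NEG_INF;
    Ix[0] = -(go + ge * i);
    for (int j = 1; j <= m; ++j) {
      double d = std::max(Mp[j - 1], std::max(Ixp[j - 1], Iyp[j - 1]));
      M[j] = d + sub(a[i - 1] - 1, b[j - 1] - 1);
      Ix[j] = std::max(std::max(Mp[j], Iyp[j]) - (go + ge), Ixp[j] - ge);
      Iy[j] = std::max(std::max(M[j - 1], Ix[j - 1]) - (go + ge), Iy[j - 1] - ge);
    }
    std::swap(M, Mp); std::swap(Ix, Ixp); std::swap(Iy, Iyp);
  }
  return std::max(Mp[m], std::max(Ixp[m], Iyp[m]));
}

// Global (Needleman-Wunsch, affine) alignment score of two residue-index
// vectors under a substitution matrix.
// [[Rcpp::export]]
double cpp_global_score(IntegerVector a, IntegerVector b, NumericMatrix sub,
                        double gap_open, double gap_ext) {
  if (a.size() == 0 || b.size() == 0) stop("empty sequence");
  return global_score(a, b, sub, gap_open, gap_ext);
}

// All pairwise global scores for a list of residue-index vectors.
// [[Rcpp::export]]
NumericMatrix cpp_pairwise_global(List seqs, NumericMatrix sub,
                                  double gap_open, double gap_ext) {
  const int n = seqs.size();
  NumericMatrix out(n, n);
  std::vector<IntegerVector> v(n);
  for (int i = 0; i < n; ++i) v[i] = as<IntegerVector>(seqs[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double s = global_score(v[i], v[j], sub, gap_open, gap_ext);
      out(i, j) = s;
      out(j, i) = s;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
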