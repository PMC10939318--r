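#include <Rcpp.h>
#include <limits>
#include <vector>

using namespace Rcpp;

// Subsequence DTW accumulated-cost recursion with free start in the signal:
//   D[1][j] = c[1][j]
//   D[i][j] = c[i][j] + min(D[i-1][j-1], D[i-1][j], D[i][j-1])
// with local cost c[i][j] = (t_i - x_j)^2 on pre-scaled inputs. The start
// column of the best path is propagated alongside the cost. Ties are
// broken deterministically: diagonal, then vertical (template advance),
// then horizontal (signal advance).
//
// Returns the final template row: per signal column j the accumulated cost
// of the best subsequence match ending at j and its 1-based start column.

// [[Rcpp::export]]
List subseq_dtw_cpp(NumericVector tmpl, NumericVector sig) {
  const int M = tmpl.size(), N = sig.size();
  if (M < 1 || N < 1) stop("empty template or signal");
  std::vector<double> Dprev(M), Dcur(M);
  std::vector<int> Sprev(M), Scur(M);
  NumericVector end_cost(N);
  IntegerVector end_start(N);

  for (int j = 0; j < N; ++j) {
    for (int i = 0; i < M; ++i) {
      double d = tmpl[i] - sig[j];
      double c = d * d;
      if (i == 0) {
        Dcur[i] = c;
        Scur[i] = j + 1;
      } else {
        double best;
        int bstart;
        if (j > 0) {  // diagonal
          best = Dprev[i - 1];
          bstart = Sprev[i - 1];
        } else {
          best = std::numeric_limits<double>::infinity();
          bstart = -1;
        }
        if (Dcur[i - 1] < best) {  // vertical (same column)
          best = Dcur[i - 1];
          bstart = Scur[i - 1];
        }
        if (j > 0 && Dprev[i] < best) {  // horizontal (same row)
          best = Dprev[i];
          bstart = Sprev[i];
        }
        Dcur[i] = c + best;
        Scur[i] = bstart;
      }
    }
    end_cost[j] = Dcur[M - 1];
    end_start[j] = Scur[M - 1];
    std::swap(Dprev, Dcur);
    std::swap(Sprev, Scur);
  }
  return List::create(_["cost"] = end_cost, _["start"] = end_start);
}

// Constrained variant: no warping path may contain a run of more than
// max_run consecutive vertical steps or more than max_run consecutive
// horizontal steps. The DP state is split per cell into "arrived by
// diagonal", "arrived by vertical with run r" and "arrived by horizontal
// with run r" (r = 1..max_run). State enumeration order (diagonal, then
// vertical runs ascending, then horizontal runs ascending) breaks ties.

// [[Rcpp::export]]
List subseq_dtw_constrained_cpp(NumericVector tmpl, NumericVector sig,
                                int max_run) {
  const int M = tmpl.size(), N = sig.size();
  if (M < 1 || N < 1) stop("empty template or signal");
  if (max_run < 1) stop("max_local_run must be >= 1");
  const double INF = std::numeric_limits<double>::infinity();
  const int R = max_run;
  // layout per column: [i * (2R + 1) + s], s = 0 diag, 1..R vert, R+1..2R horz
  const int S = 2 * R + 1;
  std::vector<double> Dprev((size_t)M * S, INF), Dcur((size_t)M * S, INF);
  std::vector<int> Pprev((size_t)M * S, -1), Pcur((size_t)M * S, -1);
  NumericVector end_cost(N);
  IntegerVector end_start(N);

  for (int j = 0; j < N; ++j) {
    for (int i = 0; i < M; ++i) {
      double d = tmpl[i] - sig[j];
      double c = d * d;
      double *cur = &Dcur[(size_t)i * S];
      int *curp = &Pcur[(size_t)i * S];
      for (int s = 0; s < S; ++s) { cur[s] = INF; curp[s] = -1; }
      if (i == 0) {
        cur[0] = c;       // free start, counts as fresh (diagonal) state
        curp[0] = j + 1;
        // horizontal arrivals along row 1 are never beneficial (cost >= 0)
        // and are excluded by the free-start initialization.
      } else {
        // diagonal from any state at (i-1, j-1)
        if (j > 0) {
          const double *pd = &Dprev[(size_t)(i - 1) * S];
          const int *pp = &Pprev[(size_t)(i - 1) * S];
          double best = INF; int bs = -1;
          for (int s = 0; s < S; ++s) {
            if (pd[s] < best) { best = pd[s]; bs = pp[s]; }
          }
          if (best < INF) { cur[0] = c + best; curp[0] = bs; }
        }
        // vertical from (i-1, j): diag or horizontal state starts run 1,
        // vertical run r extends to r+1
        const double *vd = &Dcur[(size_t)(i - 1) * S];
        const int *vp = &Pcur[(size_t)(i - 1) * S];
        {
          double best = vd[0]; int bs = vp[0];
          for (int r = 1; r <= R; ++r) {  // horizontal states
            if (vd[R + r] < best) { best = vd[R + r]; bs = vp[R + r]; }
          }
          if (best < INF) { cur[1] = c + best; curp[1] = bs; }
          for (int r = 1; r < R; ++r) {
            if (vd[r] < INF) { cur[r + 1] = c + vd[r]; curp[r + 1] = vp[r]; }
          }
        }
        // horizontal from (i, j-1): diag or vertical state starts run 1,
        // horizontal run r extends to r+1
        if (j > 0) {
          const double *hd = &Dprev[(size_t)i * S];
          const int *hp = &Pprev[(size_t)i * S];
          double best = hd[0]; int bs = hp[0];
          for (int r = 1; r <= R; ++r) {  // vertical states
            if (hd[r] < best) { best = hd[r]; bs = hp[r]; }
          }
          if (best < INF) { cur[R + 1] = c + best; curp[R + 1] = bs; }
          for (int r = 1; r < R; ++r) {
            if (hd[R + r] < INF) {
              cur[R + r + 1] = c + hd[R + r];
              curp[R + r + 1] = hp[R + r];
            }
          }
        }
      }
    }
    const double *fin = &Dcur[(size_t)(M - 1) * S];
    const int *finp = &Pcur[(size_t)(M - 1) * S];
    double best = INF; int bs = -1;
    for (int s = 0; s < S; ++s) {
      if (fin[s] < best) { best = fin[s]; bs = finp[s]; }
    }
    end_cost[j] = best;
    end_start[j] = bs;
    std::swap(Dprev, Dcur);
    std::swap(Pprev, Pcur);
  }
  return List::create(_["cost"] = end_cost, _["start"] = end_start);
}
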