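#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// End-gap-free ("glocal") affine-gap DNA alignment.
//
// The full query is aligned; leading and trailing gaps in the reference are
// free, so the query is matched against its best reference window. A gap of
// length L costs gap_open + L * gap_ext (both passed as positive costs).
// Alignments never start or end in a reference-consuming gap column (such
// paths are dominated by the free end gaps).
//
// Tie-breaking is fully deterministic so that results can be compared
// exactly against an independently coded oracle:
//   * alignment end: scan reference positions left to right, preferring the
//     match state over the query-insertion state; only a strictly greater
//     score displaces the incumbent;
//   * traceback: at equal scores prefer match/mismatch, then reference-gap
//     (deletion from the reference frame), then query-over-gap insertion.

static const double NEG_INF = -1e30;

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export]]
List glocal_align_cpp(std::string q, std::string r,
                      double match, double mismatch,
                      double gap_open, double gap_ext) {
  const int m = q.size(), n = r.size();
  if (m < 1 || n < 1) stop("empty sequence");
  for (auto &c : q) c = toupper(c);
  for (auto &c : r) c = toupper(c);

  const double gape = gap_ext, gapo = gap_open + gap_ext; // cost of first gap column

  // scores: state M = query char vs ref char, I = query char vs gap,
  //         D = ref char vs gap (internal only)
  std::vector<double> M((m + 1) * (n + 1), NEG_INF);
  std::vector<double> I((m + 1) * (n + 1), NEG_INF);
  std::vector<double> D((m + 1) * (n + 1), NEG_INF);
  // traceback pointers: 0 = from M, 1 = from D, 2 = from I, 3 = start
  std::vector<signed char> pM((m + 1) * (n + 1), -1);
  std::vector<signed char> pI((m + 1) * (n + 1), -1);
  std::vector<signed char> pD((m + 1) * (n + 1), -1);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  for (int i = 1; i <= m; ++i) {
    const char qc = q[i - 1];
    // I state exists for j = 0..n (consumes no reference)
    for (int j = 0; j <= n; ++j) {
      if (i == 1) {
        I[at(i, j)] = -gapo; pI[at(i, j)] = 3;
      } else {
        double best = M[at(i - 1, j)] - gapo; signed char p = 0;
        if (I[at(i - 1, j)] - gape > best) { best = I[at(i - 1, j)] - gape; p = 2; }
        if (D[at(i - 1, j)] - gapo > best) { best = D[at(i - 1, j)] - gapo; p = 1; }
        I[at(i, j)] = best; pI[at(i, j)] = p;
      }
    }
    for (int j = 1; j <= n; ++j) {
      const char rc = r[j - 1];
      const double s = (qc == rc && is_base(qc)) ? match : mismatch;
      if (i == 1) {
        M[at(i, j)] = s; pM[at(i, j)] = 3; // free reference prefix
      } else {
        double best = M[at(i - 1, j - 1)]; signed char p = 0;
        if (D[at(i - 1, j - 1)] > best) { best = D[at(i - 1, j - 1)]; p = 1; }
        if (I[at(i - 1, j - 1)] > best) { best = I[at(i - 1, j - 1)]; p = 2; }
        M[at(i, j)] = s + best; pM[at(i, j)] = p;
      }
      // D state: internal reference gap, requires something to its left
      double bestD = M[at(i, j - 1)] - gapo; signed char pd = 0;
      if (D[at(i, j - 1)] - gape > bestD) { bestD = D[at(i, j - 1)] - gape; pd = 1; }
      if (I[at(i, j - 1)] - gapo > bestD) { bestD = I[at(i, j - 1)] - gapo; pd = 2; }
      D[at(i, j)] = bestD; pD[at(i, j)] = pd;
    }
  }

  // choose end: j = 0..n, state M preferred over I, strict improvement only
  double best = NEG_INF; int endj = 0; int endstate = 2; // 0 = M, 2 = I
  for (int j = 0; j <= n; ++j) {
    if (j >= 1 && M[at(m, j)] > best) { best = M[at(m, j)]; endj = j; endstate = 0; }
    if (I[at(m, j)] > best) { best = I[at(m, j)]; endj = j; endstate = 2; }
  }

  // traceback
  int i = m, j = endj, state = endstate;
  int matches = 0, cols = 0;
  int ref_end = (endstate == 0) ? endj : 0, ref_start = 0;
  bool have_ref = false;
  while (true) {
    signed char p;
    if (state == 0) {        // M column consumes q[i], r[j]
      ++cols;
      if (q[i - 1] == r[j - 1] && is_base(q[i - 1])) ++matches;
      ref_start = j; have_ref = true;
      if (ref_end == 0) ref_end = j;
      p = pM[at(i, j)];
      --i; --j;
    } else if (state == 2) { // I column consumes q[i]
      ++cols;
      p = pI[at(i, j)];
      --i;
    } else {                 // D column consumes r[j]
      ++cols;
      ref_start = j; have_ref = true;
      if (ref_end == 0) ref_end = j;
      p = pD[at(i, j)];
      --j;
    }
    if (p == 3) break;
    state = (p == 0) ? 0 : (p == 1 ? 1 : 2);
  }
  if (!have_ref) { ref_start = NA_INTEGER; ref_end = NA_INTEGER; }

  return List::create(
    _["score"] = best,
    _["matches"] = matches,
    _["aligned_cols"] = cols,
    _["ref_start"] = have_ref ? IntegerVector::create(ref_start) : IntegerVector::create(NA_INTEGER),
    _["ref_end"] = have_ref ? IntegerVector::create(ref_end) : IntegerVector::create(NA_INTEGER));
}
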