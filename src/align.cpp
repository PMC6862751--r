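#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global affine-gap pairwise alignment (Gotoh three-state DP) with optional
// banding on the diagonal offset k = j - i. A gap of length L costs
// open + (L - 1) * ext. States: 0 = M (diagonal), 1 = D (gap in the query,
// consumes reference), 2 = I (gap in the reference, consumes query).
// Ties are broken by state preference M > D > I both when maximising a cell
// and during traceback, which makes the reported operations deterministic
// (substitutions preferred over gaps; deletions before insertions).
//
// Substitution scores: match for equal non-N bases, a neutral score of 0 for
// any pairing that involves an N (an N neither helps nor hurts; it is still
// classified as a mismatch operation, so it can never satisfy a
// perfect-match window), mismatch otherwise.
//
// The band always contains the corner-to-corner diagonal shifted by the net
// length difference, so a path exists for any band >= 0; band <= 0 disables
// banding (full DP). Banded results equal the full DP whenever the optimal
// path stays within the band.
//
// Band rows are stored with one sentinel column on each side (value NEG)
// so the inner loop needs no neighbour bounds checks.

static const double NEG = -1e18;
static const double NEGH = -5e17;

// [[Rcpp::export]]
List align_affine_cpp(std::string q, std::string r,
                      double match, double mismatch,
                      double gap_open, double gap_ext,
                      int band, bool score_only = false) {
  const int n = (int) q.size();
  const int m = (int) r.size();
  if (n == 0 || m == 0) stop("empty sequence");

  int lo, hi;
  if (band <= 0) {
    lo = -n; hi = m;
  } else {
    const int d = m - n;
    lo = std::min(0, d) - band;
    hi = std::max(0, d) + band;
    if (lo < -n) lo = -n;
    if (hi > m) hi = m;
  }
  const int W = hi - lo + 1;
  const int Wp = W + 2;  // with sentinels at 0 and W+1

  const size_t tb_size = score_only ? 0 : (size_t)(n + 1) * W;
  std::vector<unsigned char> tbM(tb_size, 255);
  std::vector<unsigned char> tbD(tb_size, 255);
  std::vector<unsigned char> tbI(tb_size, 255);

  std::vector<double> bufMp(Wp, NEG), bufDp(Wp, NEG), bufIp(Wp, NEG);
  std::vector<double> bufMc(Wp, NEG), bufDc(Wp, NEG), bufIc(Wp, NEG);
  double *Mp = bufMp.data() + 1, *Dp = bufDp.data() + 1, *Ip = bufIp.data() + 1;
  double *Mc = bufMc.data() + 1, *Dc = bufDc.data() + 1, *Ic = bufIc.data() + 1;

  const char *qs = q.c_str();
  const char *rs = r.c_str();

  // row 0: M at (0,0); D chain along the reference
  {
    int jmax = std::min(m, hi);
    if (0 >= lo && 0 <= hi) Mc[-lo] = 0.0;
    for (int j = std::max(1, lo); j <= jmax; ++j) {
      const int c = j - lo;
      const double fromM = Mc[c - 1] - gap_open;
      const double fromD = Dc[c - 1] - gap_ext;
      if (fromM >= fromD) {
        Dc[c] = fromM;
        if (!score_only && fromM > NEGH) tbD[c] = 0;
      } else {
        Dc[c] = fromD;
        if (!score_only) tbD[c] = 1;
      }
    }
    std::swap(Mp, Mc); std::swap(Dp, Dc); std::swap(Ip, Ic);
  }

  for (int i = 1; i <= n; ++i) {
    const int jmin = std::max(0, i + lo);
    const int jmax = std::min(m, i + hi);
    const int cmin = jmin - i - lo, cmax = jmax - i - lo;
    for (int c = 0; c < W; ++c) { Mc[c] = NEG; Dc[c] = NEG; Ic[c] = NEG; }
    const char qa = qs[i - 1];
    unsigned char *tbMr = score_only ? 0 : tbM.data() + (size_t) i * W;
    unsigned char *tbDr = score_only ? 0 : tbD.data() + (size_t) i * W;
    unsigned char *tbIr = score_only ? 0 : tbI.data() + (size_t) i * W;

    for (int c = cmin, j = jmin; c <= cmax; ++c, ++j) {
      // M from (i-1, j-1): same band column, previous row
      if (j >= 1) {
        double best = Mp[c]; int w = 0;
        if (Dp[c] > best) { best = Dp[c]; w = 1; }
        if (Ip[c] > best) { best = Ip[c]; w = 2; }
        if (best > NEGH) {
          const char rb = rs[j - 1];
          const double s = (qa == rb)
            ? (qa != 'N' ? match : 0.0)
            : ((qa == 'N' || rb == 'N') ? 0.0 : mismatch);
          Mc[c] = best + s;
          if (!score_only) tbMr[c] = (unsigned char) w;
        }
      }
      // D from (i, j-1): band column c-1, current row (sentinel guards c-1)
      {
        const double fm = Mc[c - 1] - gap_open;
        const double fd = Dc[c - 1] - gap_ext;
        const double fi = Ic[c - 1] - gap_open;
        double best = fm; int w = 0;
        if (fd > best) { best = fd; w = 1; }
        if (fi > best) { best = fi; w = 2; }
        if (best > NEGH) {
          Dc[c] = best;
          if (!score_only) tbDr[c] = (unsigned char) w;
        }
      }
      // I from (i-1, j): band column c+1, previous row (sentinel guards c+1)
      {
        const double fm = Mp[c + 1] - gap_open;
        const double fd = Dp[c + 1] - gap_open;
        const double fi = Ip[c + 1] - gap_ext;
        double best = fm; int w = 0;
        if (fd > best) { best = fd; w = 1; }
        if (fi > best) { best = fi; w = 2; }
        if (best > NEGH) {
          Ic[c] = best;
          if (!score_only) tbIr[c] = (unsigned char) w;
        }
      }
    }
    std::swap(Mp, Mc); std::swap(Dp, Dc); std::swap(Ip, Ic);
  }

  const int cend = m - n - lo;
  if (cend < 0 || cend >= W) stop("band excludes alignment endpoint");
  double score = Mp[cend]; int state = 0;
  if (Dp[cend] > score) { score = Dp[cend]; state = 1; }
  if (Ip[cend] > score) { score = Ip[cend]; state = 2; }
  if (score <= NEGH) stop("no alignment within band");

  if (score_only)
    return List::create(_["score"] = score,
                        _["op"] = std::vector<std::string>(),
                        _["len"] = std::vector<int>());

  // traceback
  std::string ops;
  ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int c = j - i - lo;
    const size_t idx = (size_t) i * W + c;
    if (state == 0) {
      const char a = qs[i - 1], b = rs[j - 1];
      ops.push_back((a == b && a != 'N') ? 'M' : 'X');
      state = tbM[idx];
      --i; --j;
    } else if (state == 1) {
      ops.push_back('D');
      state = tbD[idx];
      --j;
    } else {
      ops.push_back('I');
      state = tbI[idx];
      --i;
    }
  }
  std::reverse(ops.begin(), ops.end());

  // run-length encode
  std::vector<std::string> op_out;
  std::vector<int> len_out;
  for (size_t k = 0; k < ops.size();) {
    size_t e = k;
    while (e < ops.size() && ops[e] == ops[k]) ++e;
    op_out.push_back(std::string(1, ops[k]));
    len_out.push_back((int)(e - k));
    k = e;
  }

  return List::create(_["score"] = score,
                      _["op"] = op_out,
                      _["len"] = len_out);
}
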