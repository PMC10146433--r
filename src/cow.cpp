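#include <Rcpp.h>
#include <climits>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Correlation-optimized warping by dynamic programming.
//
// The target axis is divided into nSeg contiguous segments of seg_len points
// (spacing; the final segment absorbs the remainder). Sample boundary nodes
// are constrained so each sample segment's length differs from its target
// counterpart by at most +/- slack points; endpoints are pinned. The DP
// maximizes the sum of per-segment Pearson correlations of the linearly
// interpolated sample segments against the target segments (zero-variance
// segments contribute 0). On score ties the less-deformed transition
// (stretch closest to zero, compression preferred at equal magnitude) wins.
//
// The interpolation grid for a segment stretched by delta has constant
// fractional step: position j is xs + j + j*delta/tlen, so the integer
// offsets and weights depend only on (tlen, delta) and are precomputed once
// per segment and reused across all node states.

struct InterpPattern {
  std::vector<int> idx;      // integer offset from segment start
  std::vector<double> w;     // fractional weight toward the next point
};

static InterpPattern make_pattern(int tlen, int delta) {
  InterpPattern p;
  int m = tlen + 1;
  p.idx.resize(m);
  p.w.resize(m);
  for (int j = 0; j < m; ++j) {
    long long num = (long long)j * delta;        // offset*tlen
    long long q = num >= 0 ? num / tlen : -((-num + tlen - 1) / tlen);
    p.idx[j] = j + (int)q;
    p.w[j] = (double)(num - q * tlen) / tlen;    // in [0, 1)
  }
  return p;
}

// [[Rcpp::export]]
List cow_dp_cpp(NumericVector sample, NumericVector target,
                int seg_len, int slack) {
  const int Nt = target.size(), Ns = sample.size();
  const int nSeg = (Nt - 1) / seg_len;
  if (nSeg < 1) stop("target too short for one segment");
  const int B = nSeg;                       // boundaries 0..B
  const int D = (Ns - 1) - (Nt - 1);        // required total deviation
  if (std::abs(D) > B * slack) stop("traces cannot be matched within the slack budget");

  // padded copy of the sample so interpolation may touch index xe + 1 with
  // weight zero at the exact final point
  std::vector<double> smp(Ns + 1);
  for (int i = 0; i < Ns; ++i) smp[i] = sample[i];
  smp[Ns] = smp[Ns - 1];
  const double* tgt = REAL(target);

  // target boundary positions
  std::vector<int> tb(B + 1);
  for (int b = 0; b < B; ++b) tb[b] = b * seg_len;
  tb[B] = Nt - 1;

  // feasible deviation window u = x_b - tb[b] at each boundary: the forward
  // and backward slack cones. Interior monotonicity is implied because every
  // segment keeps length >= tlen - slack >= 1 (slack < seg_len).
  std::vector<int> lo(B + 1), hi(B + 1);
  for (int b = 0; b <= B; ++b) {
    lo[b] = std::max(-b * slack, D - (B - b) * slack);
    hi[b] = std::min(b * slack, D + (B - b) * slack);
    if (lo[b] > hi[b]) stop("infeasible slack window");
  }

  const double NEG = -1e18;
  std::vector<std::vector<double>> score(B + 1);
  std::vector<std::vector<int>> from(B + 1);
  for (int b = 0; b <= B; ++b) {
    score[b].assign(hi[b] - lo[b] + 1, NEG);
    from[b].assign(hi[b] - lo[b] + 1, INT_MIN);
  }
  score[0][0] = 0.0;

  // deltas in preference order 0, -1, +1, -2, +2, ... so that on exact score
  // ties the least-deformed segment is kept
  std::vector<int> deltas;
  deltas.push_back(0);
  for (int k = 1; k <= slack; ++k) { deltas.push_back(-k); deltas.push_back(k); }

  for (int b = 1; b <= B; ++b) {
    const int a = tb[b - 1], c = tb[b];
    const int tlen = c - a, m = tlen + 1;
    // target segment statistics
    double sy = 0, syy = 0;
    for (int j = 0; j < m; ++j) { double y = tgt[a + j]; sy += y; syy += y * y; }
    const double vy = syy - sy * sy / m;

    std::vector<double>& cur = score[b];
    std::vector<int>& cfrom = from[b];
    const std::vector<double>& prev = score[b - 1];

    for (int delta : deltas) {
      InterpPattern pat = make_pattern(tlen, delta);
      const int* idx = pat.idx.data();
      const double* wgt = pat.w.data();
      // transition u' -> u = u' + delta
      int u_lo = std::max(lo[b], lo[b - 1] + delta);
      int u_hi = std::min(hi[b], hi[b - 1] + delta);
      for (int u = u_lo; u <= u_hi; ++u) {
        double pscore = prev[u - delta - lo[b - 1]];
        if (pscore <= NEG / 2) continue;
        const double* sp = smp.data() + (a + u - delta);   // xs = tb[b-1] + u'
        double sx = 0, sxx = 0, sxy = 0;
        for (int j = 0; j < m; ++j) {
          double v0 = sp[idx[j]];
          double v = v0 + wgt[j] * (sp[idx[j] + 1] - v0);
          sx += v; sxx += v * v; sxy += v * tgt[a + j];
        }
        double vx = sxx - sx * sx / m;
        double r = (vx <= 0.0 || vy <= 0.0) ? 0.0
                   : (sxy - sx * sy / m) / std::sqrt(vx * vy);
        double s = pscore + r;
        if (s > cur[u - lo[b]]) {
          cur[u - lo[b]] = s;
          cfrom[u - lo[b]] = u - delta;
        }
      }
    }
  }

  const int uB = D;                          // endpoint pinned
  if (uB < lo[B] || uB > hi[B] || score[B][uB - lo[B]] <= NEG / 2)
    stop("no admissible warping path");
  const double total = score[B][uB - lo[B]];

  // backtrack node positions
  IntegerVector nodes(B + 1);
  int u = uB;
  for (int b = B; b >= 1; --b) {
    nodes[b] = tb[b] + u;
    u = from[b][u - lo[b]];
  }
  nodes[0] = 0;

  // build warped trace and per-segment scores
  NumericVector warped(Nt);
  NumericVector seg_scores(B);
  for (int b = 1; b <= B; ++b) {
    const int a = tb[b - 1], c = tb[b];
    const int tlen = c - a, m = tlen + 1;
    const int delta = (nodes[b] - nodes[b - 1]) - tlen;
    InterpPattern pat = make_pattern(tlen, delta);
    const double* sp = smp.data() + nodes[b - 1];
    double sx = 0, sxx = 0, sxy = 0, sy = 0, syy = 0;
    for (int j = 0; j < m; ++j) {
      double v0 = sp[pat.idx[j]];
      double v = v0 + pat.w[j] * (sp[pat.idx[j] + 1] - v0);
      warped[a + j] = v;
      double y = tgt[a + j];
      sx += v; sxx += v * v; sxy += v * y; sy += y; syy += y * y;
    }
    double vx = sxx - sx * sx / m, vy = syy - sy * sy / m;
    seg_scores[b - 1] = (vx <= 0.0 || vy <= 0.0) ? 0.0
                        : (sxy - sx * sy / m) / std::sqrt(vx * vy);
  }

  return List::create(_["nodes"] = nodes, _["score"] = total,
                      _["warped"] = warped, _["segment_scores"] = seg_scores);
}
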