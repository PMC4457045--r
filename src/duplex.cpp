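#include <Rcpp.h>
using namespace Rcpp;

// Plant small-RNA : target duplex scoring.
//
// Penalties per non-paired sRNA position: mismatch 1.0, G:U wobble 0.5,
// single-nucleotide bulge 2.0; every penalty is doubled when it falls at
// sRNA positions 2-13 (1-based from the sRNA 5' end). The sRNA pairs the
// target antiparallel: sRNA position 1 opposite the 3'-most target base
// of the duplex. At most one bulge (on either side) is allowed.

static inline bool is_comp(char s, char t) {
  switch (s) {
    case 'A': return t == 'T';
    case 'C': return t == 'G';
    case 'G': return t == 'C';
    case 'T': return t == 'A';
    default:  return false;
  }
}

static inline bool is_wobble(char s, char t) {
  return (s == 'G' && t == 'T') || (s == 'T' && t == 'G');
}

static inline double base_pen(char s, char t, double wobble) {
  if (is_comp(s, t)) return 0.0;
  if (is_wobble(s, t)) return wobble;
  return 1.0;
}

// All duplex registrations of `srna` against `target` with penalty
// score <= cutoff. Columns: t_start (0-based leftmost target index of
// the duplex span), score, cleavage (0-based target index paired to
// sRNA position 10), variant (0 = ungapped, 1 = target bulge,
// 2 = sRNA bulge), bulge (sRNA-side bulge coordinate, 0 if none).
// `weighted = false` scores every position uniformly (no 2-13
// doubling); `wobble` sets the G:U penalty (1.0 treats wobbles as plain
// mismatches, which makes the score strand-symmetric).
// [[Rcpp::export]]
DataFrame duplex_hits_cpp(std::string srna, std::string target,
                          double cutoff, bool weighted = true,
                          double wobble = 0.5) {
  const int L = (int)srna.size();
  const int T = (int)target.size();
  std::vector<int> o_start, o_var, o_bulge, o_cleav;
  std::vector<double> o_score;
  if (L < 1 || T < L) {
    return DataFrame::create(_["t_start"] = IntegerVector(0),
                             _["score"] = NumericVector(0),
                             _["cleavage"] = IntegerVector(0),
                             _["variant"] = IntegerVector(0),
                             _["bulge"] = IntegerVector(0));
  }
  const double eps = 1e-9;
  auto wt = [weighted](int i) {
    return (weighted && i >= 2 && i <= 13) ? 2.0 : 1.0;
  };
  // pen[f][i]: penalty of sRNA position i (1-based) paired in frame f,
  // where frame f anchors the duplex leftmost target index at f and the
  // pairing is t = f + L - i.
  std::vector<double> pen0(L + 2), pen1(L + 2), cum0(L + 2), cum1(L + 2);

  for (int a = 0; a + L <= T; ++a) {
    bool have1 = (a + L + 1 <= T); // frame a+1 exists (target bulge span L+1)
    for (int i = 1; i <= L; ++i) {
      pen0[i] = base_pen(srna[i - 1], target[a + L - i], wobble) * wt(i);
      pen1[i] = have1 ? base_pen(srna[i - 1], target[a + L + 1 - i], wobble) * wt(i)
                      : 1e30;
    }
    cum0[0] = cum1[0] = 0.0;
    for (int i = 1; i <= L; ++i) {
      cum0[i] = cum0[i - 1] + pen0[i];
      cum1[i] = cum1[i - 1] + pen1[i];
    }
    // ungapped
    double sc = cum0[L];
    if (sc <= cutoff + eps) {
      o_start.push_back(a); o_score.push_back(sc);
      o_cleav.push_back(a + L - 10); o_var.push_back(0); o_bulge.push_back(0);
    }
    // target bulge between sRNA positions b and b+1 (b = 1..L-1):
    // positions 1..b pair in frame a+1, positions b+1..L in frame a;
    // the unpaired target base is at a + L - b.
    if (have1) {
      double best = 1e30; int bb = -1;
      for (int b = 1; b <= L - 1; ++b) {
        double bp = 2.0 * wt(b + 1);
        double s = cum1[b] + (cum0[L] - cum0[b]) + bp;
        if (s < best) { best = s; bb = b; }
      }
      if (best <= cutoff + eps) {
        o_start.push_back(a); o_score.push_back(best);
        o_cleav.push_back(bb >= 10 ? a + L - 9 : a + L - 10);
        o_var.push_back(1); o_bulge.push_back(bb);
      }
    }
    // sRNA bulge at position b (b = 2..L-1), duplex spans L-1 target
    // bases anchored at a: positions 1..b-1 pair t = a + (L-1) - i,
    // positions b+1..L pair t = a + L - 1 - (i - 1) = a + L - i ... both
    // reduce to frames (a-1)-style; evaluate directly with its own arrays
    // reusing pen computed for frame a where possible is error-prone, so
    // compute penalties on the fly (early abort keeps this cheap).
    if (a + (L - 1) <= T) {
      for (int b = 2; b <= L - 1; ++b) {
        double s = 2.0 * wt(b);
        if (s > cutoff + eps) continue;
        bool alive = true;
        for (int i = 1; i < b && alive; ++i) {
          s += base_pen(srna[i - 1], target[a + (L - 1) - i], wobble) * wt(i);
          if (s > cutoff + eps) alive = false;
        }
        for (int i = b + 1; i <= L && alive; ++i) {
          s += base_pen(srna[i - 1], target[a + L - i], wobble) * wt(i);
          if (s > cutoff + eps) alive = false;
        }
        if (alive && s <= cutoff + eps) {
          int cl = (b < 10) ? a + L - 10
                 : (b > 10) ? a + (L - 1) - 10
                            : a + L - 11;
          o_start.push_back(a); o_score.push_back(s);
          o_cleav.push_back(cl); o_var.push_back(2); o_bulge.push_back(b);
        }
      }
    }
  }
  return DataFrame::create(_["t_start"] = wrap(o_start),
                           _["score"] = wrap(o_score),
                           _["cleavage"] = wrap(o_cleav),
                           _["variant"] = wrap(o_var),
                           _["bulge"] = wrap(o_bulge));
}
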