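#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Context-indexed glocal alignment of a k-base encoded read (colors 0..3)
// against a DNA reference (base codes 0..3).
//
// State: three score lattices S (aligned), V (insertion: base in read only)
// and H (deletion: base in reference only), each indexed by
// (colors consumed i, reference position j, context sigma). A context is the
// last k-1 decoded read bases, packed base-4 with the oldest base most
// significant; for k=1 a single-base pseudo-context carries the decoded base
// for traceback (it never influences future scores).
//
// Recursion, with b the newest base of sigma and phi ranging over the four
// predecessor contexts whose trailing k-2 bases equal sigma's leading k-2:
//   S[i][j][sigma] = Delta(b, y_j) + Pi(c_i, Phi(phi.b))
//                    + max_phi max(S,V,H)[i-1][j-1][phi]
//   V[i][j][sigma] = Pi(c_i, Phi(phi.b))
//                    + max_phi max(S[i-1][j][phi]+rho, V[i-1][j][phi]+eps)
//   H[i][j][sigma] = max(S[i][j-1][sigma]+rho, H[i][j-1][sigma]+eps)
// The color substitution is applied before the base operator, hence the Pi
// term inside the phi maximization. V never reads H and H never reads V
// (insertion adjacent to deletion is disallowed); alignments may not begin
// or end with a deletion; the read is consumed in full, the reference is
// local (row 0 scores 0 at every j, for the adaptor context only).
//
// With uniform color scores the V rule simplifies (the "simplified
// insertion" recursion): for a target context sigma with suffix t and newest
// base b, exactly one of the four predecessors phi_f = f.t makes the implied
// color match c_i (f uniquely solves f + sum(t) + b = c_i mod 4); every
// other predecessor costs the single mismatch value CE regardless of which
// color was implied. So
//   V[i][j][sigma] = max( CM + P[phi_match], CE + max_f P[phi_f] ),
//   P[phi] = max(S[i-1][j][phi]+rho, V[i-1][j][phi]+eps),
// and the per-suffix maximum of P is shared across the four sigma values of
// the suffix. Color-matching transitions are preferred at equal score, which
// pushes color errors to the boundaries of insertion runs.
//
// Tie-breaking is deterministic: predecessor states are scanned S, H, V
// (S, V for the V rule) and contexts in ascending (lexicographic) order,
// keeping the first maximum. Termination scans S before V, then reference
// end position, then context, all ascending.

static const int NEG = -(1 << 28);  // -inf sentinel; saturating by margin

struct BP {
  uint8_t state;  // 0=S, 1=V, 2=H, 255=start
  uint8_t phi;    // predecessor context (k <= 5 => at most 256 contexts)
};

// [[Rcpp::export]]
List align_dp_cpp(IntegerVector colors, IntegerVector adaptor,
                  IntegerVector ref, int k,
                  IntegerMatrix Pi, IntegerMatrix Delta,
                  int gap_open, int gap_extend, bool simplified) {
  const int n = colors.size();
  const int m = ref.size();
  if (n < 1 || m < 1) stop("read and reference must be nonempty");
  if (k < 1) stop("k must be >= 1");
  const int cw = (k > 1) ? (k - 1) : 1;  // stored context width
  if (cw > 4) stop("k > 5 exceeds the packed-context limit of this build");
  int K = 1;
  for (int i = 0; i < cw; ++i) K *= 4;

  // adaptor context index (oldest base most significant); 0 when k == 1
  int p_idx = 0;
  if (k > 1) {
    if (adaptor.size() != k - 1) stop("adaptor length must be k-1");
    for (int i = 0; i < k - 1; ++i) p_idx = p_idx * 4 + adaptor[i];
  }

  // phi_sum[ctx]: modulo-4 sum of the k-1 real context bases (0 when k==1)
  std::vector<int> phi_sum(K, 0);
  if (k > 1) {
    for (int ctx = 0; ctx < K; ++ctx) {
      int s = 0, t = ctx;
      for (int i = 0; i < cw; ++i) { s += t & 3; t >>= 2; }
      phi_sum[ctx] = s & 3;
    }
  }

  const int tail_mask = (K >> 2 > 0) ? (K / 4 - 1) : 0;  // unused for cw==1
  const int strideJ = K;
  const int strideI = (m + 1) * K;
  const size_t total = (size_t)(n + 1) * (m + 1) * K;

  std::vector<int> S(total, NEG), V(total, NEG), H(total, NEG);
  std::vector<BP> bpS(total), bpV(total), bpH(total);

  // row 0: alignment may start before any reference position; the first
  // decoded base must use the adaptor context (any pseudo-context for k==1)
  for (int j = 0; j <= m; ++j) {
    if (k == 1) {
      for (int sig = 0; sig < K; ++sig) S[(size_t)j * strideJ + sig] = 0;
    } else {
      S[(size_t)j * strideJ + p_idx] = 0;
    }
  }

  for (int i = 1; i <= n; ++i) {
    const int ci = colors[i - 1];
    const size_t rowi = (size_t)i * strideI;
    const size_t rowp = (size_t)(i - 1) * strideI;

    // V (simplified): per-suffix shared predecessor maximum plus the
    // color-matching special case (exact under uniform color scores)
    if (simplified) {
      const int CM = Pi(0, 0);
      const int CE = Pi(0, 1);  // any off-diagonal entry (uniform scheme)
      const int T = (k == 1) ? 1 : (K / 4);  // suffix groups
      for (int j = 0; j <= m; ++j) {
        const size_t cellp = rowp + (size_t)j * strideJ;
        const size_t cell = rowi + (size_t)j * strideJ;
        for (int t = 0; t < T; ++t) {
          int Pf[4]; uint8_t Sf[4]; int phis[4];
          int bestP = NEG; uint8_t bestSt = 0; int bestPhi = 0;
          for (int f = 0; f < 4; ++f) {
            int phi = (k == 1) ? f : (f * (K / 4) + t);
            int sS = S[cellp + phi], sV = V[cellp + phi];
            int fromS = (sS > NEG) ? sS + gap_open : NEG;
            int fromV = (sV > NEG) ? sV + gap_extend : NEG;
            int p; uint8_t st;
            if (fromS >= fromV) { p = fromS; st = 0; }
            else { p = fromV; st = 1; }
            Pf[f] = p; Sf[f] = st; phis[f] = phi;
            if (p > bestP) { bestP = p; bestSt = st; bestPhi = phi; }
          }
          if (bestP <= NEG) continue;
          if (k == 1) {
            // the implied color is the inserted base itself; every
            // predecessor is equivalent
            for (int b = 0; b < 4; ++b) {
              V[cell + b] = bestP + ((b == ci) ? CM : CE);
              bpV[cell + b] = {bestSt, (uint8_t)bestPhi};
            }
          } else {
            const int tsum = phi_sum[t];
            for (int b = 0; b < 4; ++b) {
              const int sig = (t << 2) | b;
              const int f_m = (ci - b - tsum) & 3;
              const int matchCand = (Pf[f_m] > NEG) ? Pf[f_m] + CM : NEG;
              const int misCand = bestP + CE;
              if (matchCand >= misCand) {
                if (matchCand <= NEG) continue;
                V[cell + sig] = matchCand;
                bpV[cell + sig] = {Sf[f_m], (uint8_t)phis[f_m]};
              } else {
                V[cell + sig] = misCand;
                bpV[cell + sig] = {bestSt, (uint8_t)bestPhi};
              }
            }
          }
        }
      }
    }

    for (int j = 0; j <= m; ++j) {
      const size_t cell = rowi + (size_t)j * strideJ;
      const size_t diag = rowp + (size_t)(j - 1) * strideJ;  // valid if j>=1
      const size_t up = rowp + (size_t)j * strideJ;
      const size_t left = rowi + (size_t)(j - 1) * strideJ;  // valid if j>=1
      const int yj = (j >= 1) ? ref[j - 1] : -1;

      for (int sig = 0; sig < K; ++sig) {
        const int b = sig & 3;
        // predecessor contexts phi = f*4^(cw-1) + (sig >> 2); for cw==1 all 4
        const int base_phi = (k == 1) ? 0 : (sig >> 2);
        const int step_phi = (k == 1) ? 1 : (K / 4);

        // --- S: aligned base (consumes color and reference base) ---
        if (j >= 1) {
          int best = NEG; uint8_t bst = 255, bphi = 0;
          for (uint8_t st = 0; st < 3; ++st) {
            const std::vector<int>& prev = (st == 0) ? S : (st == 1 ? H : V);
            const uint8_t stcode = (st == 0) ? 0 : (st == 1 ? 2 : 1);
            for (int f = 0; f < 4; ++f) {
              int phi = (k == 1) ? f : (f * step_phi + base_phi);
              int sc = prev[diag + phi];
              if (sc <= NEG) continue;
              sc += Pi(ci, (phi_sum[phi] + b) & 3);
              if (sc > best) { best = sc; bst = stcode; bphi = (uint8_t)phi; }
            }
          }
          if (best > NEG) {
            S[cell + sig] = best + Delta(b, yj);
            bpS[cell + sig] = {bst, bphi};
          }
        }

        // --- V: inserted base (consumes color only); general recursion ---
        if (!simplified) {
          int best = NEG; uint8_t bst = 255, bphi = 0;
          for (uint8_t st = 0; st < 2; ++st) {   // S then V
            const std::vector<int>& prev = (st == 0) ? S : V;
            const int pen = (st == 0) ? gap_open : gap_extend;
            for (int f = 0; f < 4; ++f) {
              int phi = (k == 1) ? f : (f * step_phi + base_phi);
              int sc = prev[up + phi];
              if (sc <= NEG) continue;
              sc += pen + Pi(ci, (phi_sum[phi] + b) & 3);
              if (sc > best) { best = sc; bst = st; bphi = (uint8_t)phi; }
            }
          }
          if (best > NEG) {
            V[cell + sig] = best;
            bpV[cell + sig] = {bst, bphi};
          }
        }

        // --- H: deleted reference base (consumes reference only) ---
        if (j >= 1) {
          int fromS = S[left + sig];
          int fromH = H[left + sig];
          int best = NEG; uint8_t bst = 255;
          if (fromS > NEG && fromS + gap_open >= ((fromH > NEG) ? fromH + gap_extend : NEG)) {
            best = fromS + gap_open; bst = 0;
          } else if (fromH > NEG) {
            best = fromH + gap_extend; bst = 2;
          }
          if (bst != 255) {
            H[cell + sig] = best;
            bpH[cell + sig] = {bst, (uint8_t)sig};
          }
        }
      }
    }
  }

  // termination: best S or V sub-cell in row n (no trailing deletion)
  int best = NEG; int bj = -1, bsig = -1; uint8_t bstate = 0;
  const size_t rown = (size_t)n * strideI;
  for (uint8_t st = 0; st < 2; ++st) {
    const std::vector<int>& fin = (st == 0) ? S : V;
    for (int j = 0; j <= m; ++j) {
      for (int sig = 0; sig < K; ++sig) {
        int sc = fin[rown + (size_t)j * strideJ + sig];
        if (sc > best) { best = sc; bj = j; bsig = sig; bstate = st; }
      }
    }
  }
  if (best <= NEG) stop("internal error: no feasible alignment");

  // traceback
  std::vector<int> ev_type, ev_readpos, ev_readbase, ev_refpos, ev_refbase,
      ev_obs, ev_implied;
  int i = n, j = bj, sig = bsig;
  uint8_t st = bstate;
  while (i > 0) {
    const size_t cell = (size_t)i * strideI + (size_t)j * strideJ + sig;
    if (st == 0) {            // S: aligned
      BP bp = bpS[cell];
      int b = sig & 3;
      ev_type.push_back(0);
      ev_readpos.push_back(i);
      ev_readbase.push_back(b);
      ev_refpos.push_back(j);
      ev_refbase.push_back(ref[j - 1]);
      ev_obs.push_back(colors[i - 1]);
      ev_implied.push_back((phi_sum[bp.phi] + b) & 3);
      --i; --j; sig = bp.phi; st = bp.state;
    } else if (st == 1) {     // V: insertion
      BP bp = bpV[cell];
      int b = sig & 3;
      ev_type.push_back(1);
      ev_readpos.push_back(i);
      ev_readbase.push_back(b);
      ev_refpos.push_back(NA_INTEGER);
      ev_refbase.push_back(NA_INTEGER);
      ev_obs.push_back(colors[i - 1]);
      ev_implied.push_back((phi_sum[bp.phi] + b) & 3);
      --i; sig = bp.phi; st = bp.state;
    } else {                  // H: deletion
      BP bp = bpH[cell];
      ev_type.push_back(2);
      ev_readpos.push_back(NA_INTEGER);
      ev_readbase.push_back(NA_INTEGER);
      ev_refpos.push_back(j);
      ev_refbase.push_back(ref[j - 1]);
      ev_obs.push_back(NA_INTEGER);
      ev_implied.push_back(NA_INTEGER);
      --j; st = bp.state;
    }
  }
  const int ref_start = j + 1;  // first reference base consumed (1-based)

  const int ne = ev_type.size();
  IntegerVector type(ne), readpos(ne), readbase(ne), refpos(ne), refbase(ne),
      obs(ne), implied(ne);
  for (int e = 0; e < ne; ++e) {  // reverse into alignment order
    int src = ne - 1 - e;
    type[e] = ev_type[src];
    readpos[e] = ev_readpos[src];
    readbase[e] = ev_readbase[src];
    refpos[e] = ev_refpos[src];
    refbase[e] = ev_refbase[src];
    obs[e] = ev_obs[src];
    implied[e] = ev_implied[src];
  }

  (void)tail_mask;
  return List::create(
      _["score"] = best,
      _["ref_start"] = ref_start,
      _["ref_end"] = bj,
      _["type"] = type,
      _["read_pos"] = readpos,
      _["read_base"] = readbase,
      _["ref_pos"] = refpos,
      _["ref_base"] = refbase,
      _["obs_color"] = obs,
      _["implied_color"] = implied);
}
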