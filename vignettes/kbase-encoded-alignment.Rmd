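---
title: "Methods: aligning generalized k-base encoded reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aligning generalized k-base encoded reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbasealign)
```

## The generalized k-base code

A DNA sequence `x` of length `n` with bases coded A, C, G, T = 0, 1, 2, 3 is
encoded, given an adaptor `p` of k − 1 known bases prepended to it, as `n`
colors

c_i = ( x_{i−k+1} + … + x_i ) mod 4,

where positions ≤ 0 refer to the adaptor. k = 1 is the identity code
(color = base), k = 2 is two-base (SOLiD-style) encoding. Decoding is
sequential: each new base is the color minus the sum of the previous k − 1
bases, modulo 4, so the adaptor anchors the whole read, and without it
exactly 4^(k−1) decodings are consistent with any color string
(`enumerate_decodings()`).

Two structural facts drive everything else:

- **SNP signature.** A single base substitution at position `i` changes the
  min(k, n − i + 1) colors of the windows containing it, all consecutively,
  and all by the same modulo-4 shift. Near the read end the signature
  truncates.
- **Color-error cascade.** A single color substitution at `i`, decoded
  naively, shifts the decoded base at `i` by +d and the base at `i + 1` by
  −d; for k = 2 those positions are adjacent windows and every downstream
  base ends up corrupted, while for k ≥ 3 the +d/−d pair cancels inside
  later windows and the corruption is periodic (offsets 0 and 1 mod k).
  Either way a raw decode is unusable after an error, which is why
  alignment must happen in color space.

## Scoring model

A scheme holds color match/mismatch scores (CM, CE), base match/mismatch
scores (BM, BE) and affine gap scores (gap open ρ, gap extend ϵ), defaults
CM = 0, CE = −125, BM = 50, BE = −150, ρ = −175, ϵ = −50. Validity
(`validate_scheme()`): CM, BM ≥ 0; CE, BE < 0; ρ < ϵ < 0. Per-pair 4×4
matrices Π (color) and Δ (base) are supported in the general recursion;
uniform values are the primary path.

A scheme *prefers SNPs* at width k when one base mismatch with matching
colors beats the color-error explanation: BE + k·CM > BM + k·CE
(`snp_preferred()`, strict inequality). The default scheme satisfies this
for k = 2..5 but not k = 1 (−150 < −75): unencoded alignment cannot prefer
SNP interpretations under these scores, which is consistent with k = 1
reads being aligned as plain base sequences.

For k = 5 the margins D_a = (2a − 5)(CE − CM) + (BM − BE), a = 5..1,
partition uniform schemes into scenarios 1–4 (`classify_scenario()`): how
many consecutive equal-shift color changes it takes before the SNP
interpretation wins. Exact ties are reported in a `boundary` field rather
than silently assigned; the conventional assignment goes to the higher
scenario (CE = −200 classifies as scenario 4 with boundary 3). Scenarios 5
and 6 would require CM + BM < CE + BE, impossible under the sign
constraints; `infeasible_scenarios()` verifies this on a grid and the
algebraic core is asserted in the test suite.

## The dynamic program

`align()` is a glocal aligner: global in the read (all n colors consumed),
local in the reference. Three lattices — S (aligned), V (insertion: base in
read only), H (deletion: base in reference only) — are each indexed by
(i colors consumed, j reference positions, σ), where the *context* σ is the
last k − 1 decoded bases packed base-4 (oldest most significant). With b
the newest base of σ and ϕ ranging over the four predecessor contexts whose
trailing bases match σ's leading bases:

- S[i][j][σ] = Δ(b, y_j) + max over ϕ and state ∈ {S, V, H} of
  { Π(c_i, sum(ϕ) + b mod 4) + state[i−1][j−1][ϕ] }
- V[i][j][σ] = max over ϕ of { Π(c_i, sum(ϕ) + b mod 4) +
  max(S[i−1][j][ϕ] + ρ, V[i−1][j][ϕ] + ϵ) }   (H excluded: insertion and
  deletion are never adjacent)
- H[i][j][σ] = max(S[i][j−1][σ] + ρ, H[i][j−1][σ] + ϵ)   (context
  unchanged: no color consumed)

Initialization: row 0 holds score 0 at the adaptor context for every j
(the alignment may start anywhere in the reference); H is barred at read
start (no leading deletion). Termination: the maximum over S and V in row
n across all j and σ — trailing insertions are allowed, trailing deletions
are not. For k = 1 a single-base pseudo-context carries the decoded base
uniformly through the same machinery.

Numerical conventions, chosen where the model itself is silent:

- **Integer scores only**; no floating point in the DP.
- **−∞ sentinel**: −2^28, far below any reachable score yet safe against
  overflow when per-step penalties are added.
- **Tie-breaking** is deterministic: predecessor states are scanned S, H, V
  (S, V for insertions), contexts in ascending (lexicographic) order, first
  maximum kept; termination scans S before V, then reference position, then
  context. Two runs on the same input always produce the same traceback.
- **Traceback labels**: each consumed color is flagged as a color error
  when its observed value differs from the implied value of the chosen
  decoding; aligned mismatches are SNP calls.

### The simplified insertion recursion

With uniform color scores the V rule collapses
(`align_simplified_insertion()`, used automatically for uniform schemes):
for a target context σ = t·4 + b, exactly one of the four predecessors
ϕ_f = f·4^(k−2) + t implies a matching color (f solves
f + sum(t) + b = c_i mod 4), and every other predecessor costs the single
mismatch value CE. Hence

V[i][j][σ] = max( CM + P[ϕ_match], CE + max_f P[ϕ_f] ),
P[ϕ] = max(S[i−1][j][ϕ] + ρ, V[i−1][j][ϕ] + ϵ),

where the per-suffix maximum of P is shared across the four σ of a suffix.
This is exactly the general V under a uniform scheme — the equality is
property-tested against the general recursion and the brute-force oracle.
The CE branch is essential: optimal solutions sometimes place a color error
*inside* an insertion run to reach a context unreachable by color-matching
insertions (the test suite pins a k = 3 example). Color-matching
transitions are preferred at equal score, which pushes errors to run
boundaries whenever that is score-neutral.

### Complexity

Per interior cell and context, the candidate count is 2 (h) + 3·|Λ| (s) +
3·|Λ| (v), i.e. 26·4^(k−1) candidates per cell for the 4-letter alphabet
(`candidate_count()`). Note this bound counts H among V's predecessors,
which the no-adjacent-gaps rule actually excludes — the implementation
follows the exclusion rule, the accounting function reports the printed
bound. Runtime grows by ≈4× per increment of k (trend-checked in the test
suite, not timed against absolute targets).

## The brute-force oracle

`brute_force_align()` enumerates all 4^n decodings (each color may decode
to any base, at the appropriate Π cost) × all admissible alignment shapes
(DFS over aligned/insertion/deletion interleavings honoring the gap
grammar, at every reference offset), and maximizes. It shares no code or
structure with the DP and is exact by construction; it refuses instances
beyond n, m ≤ 6, k ≤ 3. The oracle-equivalence suite (≥500 random
instances, random schemes, including per-pair matrices) is the aligner's
primary correctness gate.

`adjacent_error_snp_fraction()` answers a related design question by direct
enumeration: of the 9 wrong-value combinations at an adjacent color pair
(k = 2), exactly the 3 equal-shift ones decode to a clean single SNP —
fraction 1/3.

## Simulation study

`run_experiment()` runs one cell of the study grid. The generative model:

1. Sample a read skeleton: the read plus 10 bp flanks on each side, which
   serve as that read's local reference (i.i.d. random DNA by default, or
   windows of a user FASTA; forward strand only).
2. Inject `n_snps` SNPs at distinct uniform positions, each to a uniform
   wrong base.
3. Encode at width k and corrupt each color independently with its
   position's error rate (uniform or per-cycle positional model) to a
   uniform wrong color. For k = 1 the corruption is applied to bases
   directly, avoiding SNP positions (a position never carries both).
4. Score the generative gap-free trace (SNPs as base mismatches with
   matching colors, injected errors as color mismatches) — the *true
   score*.
5. Align; the read counts toward **power** when the optimal score equals
   the true score. **FP rate**: fraction of 0-SNP reads whose traceback
   calls any SNP. **FN rate**: fraction of SNP-bearing reads calling none
   of their injected SNPs (`fn_mode = "none_called"`, default) or missing
   at least one (`"any_missed"`).

For k = 1 the alignment uses a prohibitive color-mismatch score, making the
DP exactly glocal affine-gap alignment of the observed bases — the
appropriate baseline for unencoded reads.

`real_world_error_model()` carries 50 per-cycle rates measured on an ABI
SOLiD v2 run (≈0.5–1.5% early, ≈18% in the last cycles); it applies to
50 bp reads only. Default cell size is 1,000 reads — large enough for the
±2% reproducibility asserted in the acceptance tests at ≈1% binomial
standard error, small enough to keep the k = 5 cells tractable.

### Known limitations

- The per-read local reference (own origin ± 10 bp) measures alignment and
  SNP-labeling fidelity, not genome-scale mapping; candidate location
  search, reverse strands and mapping quality are out of scope.
- The FP rate at k = 2 is *not* exactly zero at appreciable error rates:
  adjacent color errors with equal shifts (1/3 of adjacent wrong-value
  pairs) are mathematically indistinguishable from a clean SNP, giving an
  expected FP rate of roughly (L − 1)·e²/3 at uniform rate e — about 4% at
  e = 0.05 for 50 bp reads. No aligner can remove this floor; larger k
  raises the number of coincident errors required and drives FP down.
- Error-free SNPs can be legitimately missed in two ways: a truncated
  signature within k − 1 bases of the read end (rescored as one cheaper
  color error), and lucky flank realignments absorbing an end-of-read SNP
  into a gap. Both yield strictly better scores than the generative trace.
- Scores are not calibrated probabilities; no base-quality input.

## File formats and tool

FASTA for references (via Biostrings), generalized csfasta for encoded
reads (header line, then the k − 1 adaptor bases immediately followed by
the color digits), TSV for alignment reports and simulation metrics, and a
flat key-value file for scoring schemes. The `exec/kbasealign` tool exposes
`encode`, `decode`, `align` and `simulate` subcommands; logs go to standard
error, results to `--out` or standard output; exit codes are 0 (success),
2 (usage error), 1 (runtime error).
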