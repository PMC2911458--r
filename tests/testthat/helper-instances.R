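# Shared test fixtures: random sequences, schemes and tiny alignment
# instances, plus an independent Gotoh-style glocal affine aligner on plain
# bases, used to cross-check the k = 1 reduction.

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# Random uniform scheme respecting the sign constraints.
random_scheme <- function() {
  scoring_scheme(
    color_match = sample(0:50, 1),
    color_mismatch = -sample(1:300, 1),
    base_match = sample(0:80, 1),
    base_mismatch = -sample(1:300, 1),
    gap_open = -sample(100:300, 1),
    gap_extend = -sample(1:99, 1))
}

# Random per-pair scheme (4x4 Pi and Delta with valid signs).
random_perpair_scheme <- function() {
  pi_m <- -matrix(sample(1:200, 16, replace = TRUE), 4, 4)
  diag(pi_m) <- sample(0:40, 4, replace = TRUE)
  dl <- -matrix(sample(1:200, 16, replace = TRUE), 4, 4)
  diag(dl) <- sample(0:60, 4, replace = TRUE)
  scoring_scheme(gap_open = -sample(100:300, 1), gap_extend = -sample(1:99, 1),
                 pi_matrix = pi_m, delta_matrix = dl)
}

# Random tiny instance: encoded read (possibly corrupted) plus reference.
random_tiny_instance <- function(kmax = 3L, nmax = 6L, mmax = 6L) {
  k <- sample(seq_len(kmax), 1)
  n <- sample(seq_len(nmax), 1)
  m <- sample(seq_len(mmax), 1)
  er <- encode_read(random_seq(n), k = k)
  nflip <- sample(0:2, 1)
  if (nflip > 0) {
    p <- sample(n, min(nflip, n))
    er$colors[p] <- (er$colors[p] + sample(1:3, length(p), replace = TRUE)) %% 4L
  }
  list(read = er, reference = random_seq(m), k = k)
}

# Independent glocal (read-global, reference-local) affine-gap aligner on
# plain base sequences: no leading/trailing deletion, no insertion adjacent
# to a deletion, trailing insertions allowed. Written with plain R loops,
# nothing shared with the package DP.
gotoh_glocal <- function(x, y, scheme) {
  xb <- strsplit(x, "")[[1]]
  yb <- strsplit(y, "")[[1]]
  n <- length(xb); m <- length(yb)
  BM <- scheme$base_match; BE <- scheme$base_mismatch
  go <- scheme$gap_open; ge <- scheme$gap_extend
  NEG <- -1e9
  S <- matrix(NEG, n + 1, m + 1); V <- matrix(NEG, n + 1, m + 1)
  H <- matrix(NEG, n + 1, m + 1)
  S[1, ] <- 0
  for (i in 2:(n + 1)) {
    for (j in 1:(m + 1)) {
      V[i, j] <- max(S[i - 1, j] + go, V[i - 1, j] + ge)
      if (j > 1) {
        sub <- if (xb[i - 1] == yb[j - 1]) BM else BE
        S[i, j] <- sub + max(S[i - 1, j - 1], V[i - 1, j - 1], H[i - 1, j - 1])
        H[i, j] <- max(S[i, j - 1] + go, H[i, j - 1] + ge)
      }
    }
  }
  max(S[n + 1, ], V[n + 1, ])
}

# Build the 10 bp flanked instance used throughout the simulation study.
flanked_instance <- function(read_len = 25L, k = 2L) {
  x <- random_seq(read_len)
  ref <- paste0(random_seq(10L), x, random_seq(10L))
  list(x = x, reference = ref, read = encode_read(x, k = k))
}
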