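# Brute-force reference implementations, used only for testing the dynamic
# program on tiny instances. Deliberately memoization-free and structured
# nothing like the DP: every candidate decoding of the color string is
# enumerated against every admissible alignment shape.

#' Brute-force optimal alignment score by exhaustive enumeration
#'
#' Enumerates every decoded base sequence consistent with the colors
#' (`4^n` of them: each color may be decoded to any base, at a color
#' mismatch cost when it disagrees with its window) and, independently,
#' every alignment shape (monotone interleaving of aligned / insertion /
#' deletion events consuming all n colors, with no leading or trailing
#' deletion and no insertion adjacent to a deletion, starting at any
#' reference offset). The maximum total score over the cross product is
#' exact by construction.
#'
#' Refuses instances beyond `n, m <= 6` or `k > 3`; the enumeration is
#' exponential by design.
#'
#' @param read An [encoded_read()] with at most 6 colors.
#' @param reference DNA string of length at most 6.
#' @param scheme A [scoring_scheme()].
#' @return A list with `score`, the optimal alignment score.
#' @export
brute_force_align <- function(read, reference, scheme = default_scheme()) {
  stopifnot(inherits(read, "encoded_read"), inherits(scheme, "scoring_scheme"))
  n <- length(read$colors)
  ref <- base_to_code(reference)
  m <- length(ref)
  if (n > 6L || m > 6L || read$k > 3L) {
    stop("instance too large for exhaustive enumeration (need n, m <= 6, k <= 3)",
         call. = FALSE)
  }
  k <- read$k
  Pi <- pi_matrix_of(scheme)
  Delta <- delta_matrix_of(scheme)

  # --- all 4^n decodings, as an (4^n x n) matrix of base codes ---
  dec <- as.matrix(do.call(expand.grid, rep(list(0:3), n)))
  storage.mode(dec) <- "integer"

  # color cost of each decoding: per position, the implied color is the
  # modulo-4 window sum over (adaptor, decoded bases)
  pre <- if (k > 1L) base_to_code(read$adaptor) else integer(0)
  color_cost <- integer(nrow(dec))
  for (i in seq_len(n)) {
    win_lo <- i - k + 1L
    implied <- integer(nrow(dec))
    for (w in win_lo:i) {
      implied <- implied + if (w >= 1L) dec[, w] else pre[w + k - 1L]
    }
    implied <- implied %% 4L
    color_cost <- color_cost + Pi[cbind(read$colors[i] + 1L, implied + 1L)]
  }

  # --- all alignment shapes ---
  shapes <- shapes_with_gap_scores(enumerate_alignment_shapes(n, m), scheme)

  best <- -Inf
  for (sh in shapes) {
    sc <- color_cost + sh$gap_score
    if (length(sh$read_pos)) {
      for (a in seq_along(sh$read_pos)) {
        sc <- sc + Delta[cbind(dec[, sh$read_pos[a]] + 1L,
                               ref[sh$ref_pos[a]] + 1L)]
      }
    }
    mx <- max(sc)
    if (mx > best) best <- mx
  }
  list(score = as.integer(best))
}

# Enumerate admissible alignment shapes for n read positions and m reference
# bases: each shape records which read positions are aligned to which
# reference positions and the total affine gap score of its insertion and
# deletion runs. Plain depth-first recursion, no caching.
enumerate_alignment_shapes <- function(n, m) {
  shapes <- list()
  emit <- function(read_pos, ref_pos, n_open, n_ext) {
    shapes[[length(shapes) + 1L]] <<- list(
      read_pos = read_pos, ref_pos = ref_pos,
      n_open = n_open, n_ext = n_ext)
  }
  recurse <- function(i, j, last, read_pos, ref_pos, n_open, n_ext) {
    if (i == n) {
      if (last != "D") emit(read_pos, ref_pos, n_open, n_ext)  # no trailing del
      return(invisible(NULL))
    }
    # aligned
    if (j < m) {
      recurse(i + 1L, j + 1L, "A", c(read_pos, i + 1L), c(ref_pos, j + 1L),
              n_open, n_ext)
    }
    # insertion (not after deletion)
    if (last != "D") {
      recurse(i + 1L, j, "I", read_pos, ref_pos,
              n_open + (last != "I"), n_ext + (last == "I"))
    }
    # deletion (not first event, not after insertion)
    if (j < m && last == "A") {
      recurse(i, j + 1L, "D", read_pos, ref_pos, n_open + 1L, n_ext)
    } else if (j < m && last == "D") {
      recurse(i, j + 1L, "D", read_pos, ref_pos, n_open, n_ext + 1L)
    }
  }
  for (j0 in 0:m) {
    recurse(0L, j0, "", integer(0), integer(0), 0L, 0L)
  }
  shapes
}

# Attach gap scores to shapes for a given scheme (kept separate so shape
# enumeration stays scheme-free).
shapes_with_gap_scores <- function(shapes, scheme) {
  lapply(shapes, function(sh) {
    sh$gap_score <- sh$n_open * scheme$gap_open + sh$n_ext * scheme$gap_extend
    sh
  })
}

#' Fraction of adjacent color-error pairs that fake a clean SNP
#'
#' For two-base encoding, enumerates every pair of adjacent color
#' positions and every combination of wrong values at the two positions
#' (3 x 3 per pair) and counts the combinations whose decoding is exactly
#' one interior base substitution with all downstream bases restored.
#' Under the modulo-sum code this happens precisely when the two color
#' shifts are equal (`d2 = d1`), so the computed fraction is 1/3 of
#' adjacent wrong-value pairs — not the 1/4 sometimes quoted for the
#' physical two-base code.
#'
#' @param k Encoding width; only `k = 2` is supported.
#' @param seq_length Length of the probe sequence used for the
#'   enumeration (any interior length works; the count is
#'   sequence-independent).
#' @return A list with `fraction`, `n_clean_snp` and `n_pairs`.
#' @export
adjacent_error_snp_fraction <- function(k = 2L, seq_length = 8L) {
  if (check_k(k) != 2L) stop("defined for k = 2", call. = FALSE)
  x <- strrep("A", seq_length)  # the count is invariant in the probe sequence
  enc <- encode_read(x, k = 2L)
  n <- seq_length
  n_pairs <- 0L
  n_clean <- 0L
  for (i in seq_len(n - 2L)) {       # interior pairs: downstream must exist
    for (d1 in 1:3) {
      for (d2 in 1:3) {
        n_pairs <- n_pairs + 1L
        colors <- enc$colors
        colors[i] <- (colors[i] + d1) %% 4L
        colors[i + 1L] <- (colors[i + 1L] + d2) %% 4L
        y <- decode_read(encoded_read(enc$adaptor, colors, 2L))
        diff <- which(strsplit(y, "")[[1]] != strsplit(x, "")[[1]])
        if (identical(diff, i)) n_clean <- n_clean + 1L
      }
    }
  }
  list(fraction = n_clean / n_pairs, n_clean_snp = n_clean, n_pairs = n_pairs)
}
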