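# Generalized k-base encoding: each emitted color is the modulo-4 sum of the
# integer codes (A=0, C=1, G=2, T=3) of k consecutive bases. k=2 is SOLiD-style
# two-base encoding; k=1 is the identity (a color *is* a base code).

DNA_BASES <- c("A", "C", "G", "T")

#' Convert DNA bases to integer codes
#'
#' Maps `A, C, G, T` to `0, 1, 2, 3`. Input is case-insensitive. Any other
#' character (including IUPAC ambiguity codes and `N`) is rejected: the
#' encoding is only defined over the four-letter alphabet.
#'
#' @param x A character string of bases, or a character vector of
#'   single-base strings.
#' @return An integer vector of base codes in `0:3`, one per base.
#' @examples
#' base_to_code("ACGT")
#' @export
base_to_code <- function(x) {
  chars <- toupper(unlist(strsplit(x, ""), use.names = FALSE))
  codes <- match(chars, DNA_BASES) - 1L
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    stop("invalid DNA base(s): ", paste(bad, collapse = ", "),
         " (only A, C, G, T are encodable)", call. = FALSE)
  }
  codes
}

#' Convert integer base codes back to a DNA string
#'
#' @param codes Integer vector with values in `0:3`.
#' @return A single character string of bases.
#' @examples
#' code_to_base(c(0L, 1L, 2L, 3L))
#' @export
code_to_base <- function(codes) {
  codes <- as.integer(codes)
  if (length(codes) == 0L) return("")
  if (anyNA(codes) || any(codes < 0L | codes > 3L)) {
    stop("base codes must be integers in 0..3", call. = FALSE)
  }
  paste(DNA_BASES[codes + 1L], collapse = "")
}

#' Encode one window of k bases into a color
#'
#' The color emitted for a window `B_1, ..., B_k` is
#' `(delta(B_1) + ... + delta(B_k)) mod 4`, with `delta` the A=0, C=1, G=2,
#' T=3 base code. The window length determines the encoding width k.
#'
#' @param bases A string of exactly k bases (or vector of single bases).
#' @param k Encoding width; defaults to the window length. Supplying `k`
#'   lets the call fail loudly when the window has the wrong length.
#' @return A single integer color in `0:3`.
#' @examples
#' encode_window("AC")    # (0 + 1) %% 4 = 1
#' encode_window("TTTTT") # 15 %% 4 = 3
#' @export
encode_window <- function(bases, k = NULL) {
  codes <- base_to_code(bases)
  if (!is.null(k) && length(codes) != k) {
    stop("window has ", length(codes), " base(s) but k = ", k, call. = FALSE)
  }
  if (length(codes) < 1L) stop("window must contain at least one base", call. = FALSE)
  sum(codes) %% 4L
}

#' Decode one color into a base, given its k-1 base context
#'
#' Inverts [encode_window()]: returns the unique base `B` such that the
#' window `context + B` encodes to `color`. The solution always exists and
#' is unique modulo 4.
#'
#' @param context String of the k-1 preceding bases (empty string for k=1).
#' @param color Integer color in `0:3`.
#' @return A single base character.
#' @examples
#' decode_window("A", 1L)  # "C"
#' @export
decode_window <- function(context, color) {
  color <- as.integer(color)
  if (length(color) != 1L || is.na(color) || color < 0L || color > 3L) {
    stop("color must be a single integer in 0..3", call. = FALSE)
  }
  ctx_sum <- if (nzchar(paste(context, collapse = ""))) sum(base_to_code(context)) else 0L
  DNA_BASES[((color - ctx_sum) %% 4L) + 1L]
}

#' Default adaptor for a given encoding width
#'
#' The adaptor is the known k-1 base prefix that anchors decoding; SOLiD
#' chemistry uses a primer ending in T, so the default here is a run of T.
#' For k=1 the adaptor is empty.
#'
#' @param k Encoding width (>= 1).
#' @return A character string of k-1 bases.
#' @export
default_adaptor <- function(k) {
  k <- check_k(k)
  strrep("T", k - 1L)
}

check_k <- function(k) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) {
    stop("k must be a single integer >= 1", call. = FALSE)
  }
  k
}

#' Construct an encoded read
#'
#' An encoded read is a k-1 base adaptor plus a string of colors (digits
#' 0-3), one color per base of the underlying DNA sequence.
#'
#' @param adaptor Character string of exactly k-1 bases.
#' @param colors Integer vector of colors in `0:3` (length n >= 1).
#' @param k Encoding width.
#' @param id Optional read identifier (used by the csfasta writer).
#' @return An object of class `encoded_read` with fields `adaptor`,
#'   `colors`, `k`, `id`.
#' @examples
#' encoded_read("T", c(3L, 1L, 3L), k = 2)
#' @export
encoded_read <- function(adaptor, colors, k, id = NULL) {
  k <- check_k(k)
  adaptor <- toupper(paste(adaptor, collapse = ""))
  if (nchar(adaptor) != k - 1L) {
    stop("adaptor must have exactly k-1 = ", k - 1L, " base(s), got \"",
         adaptor, "\"", call. = FALSE)
  }
  if (k > 1L) base_to_code(adaptor)  # validates characters
  colors <- as.integer(colors)
  if (length(colors) < 1L) stop("a read must contain at least one color", call. = FALSE)
  if (anyNA(colors) || any(colors < 0L | colors > 3L)) {
    stop("colors must be integers in 0..3", call. = FALSE)
  }
  structure(list(adaptor = adaptor, colors = colors, k = k, id = id),
            class = "encoded_read")
}

#' @export
print.encoded_read <- function(x, ...) {
  cat(sprintf("<encoded_read k=%d n=%d%s>\n", x$k, length(x$colors),
              if (!is.null(x$id)) paste0(" id=", x$id) else ""))
  cat(" ", x$adaptor, paste(x$colors, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Encode a DNA sequence into color space
#'
#' Applies the k-window encoder iteratively to the concatenation of the
#' adaptor `p` and the sequence `x`: color i is the modulo-4 sum of the
#' window of k bases of `p.x` ending at `x_i`. The output has one color per
#' input base.
#'
#' @param x DNA sequence (character string, A/C/G/T, case-insensitive).
#' @param adaptor Adaptor string of k-1 bases; defaults to
#'   [default_adaptor()].
#' @param k Encoding width (>= 1).
#' @param id Optional read identifier.
#' @return An [encoded_read()].
#' @examples
#' encode_read("ACG", adaptor = "T", k = 2)$colors  # 3 1 3
#' encode_read("ACGT", k = 1)$colors                # 0 1 2 3
#' @export
encode_read <- function(x, adaptor = default_adaptor(k), k = 2L, id = NULL) {
  k <- check_k(k)
  codes <- base_to_code(x)
  if (length(codes) < 1L) stop("sequence must be nonempty", call. = FALSE)
  adaptor <- toupper(paste(adaptor, collapse = ""))
  pre <- if (k > 1L) base_to_code(adaptor) else integer(0)
  if (length(pre) != k - 1L) {
    stop("adaptor must have exactly k-1 = ", k - 1L, " base(s)", call. = FALSE)
  }
  all_codes <- c(pre, codes)
  n <- length(codes)
  # rolling window sum over p.x; cumsum keeps this O(n)
  cs <- cumsum(all_codes)
  upper <- cs[(k - 1L + 1L):(k - 1L + n)]
  lower <- c(0L, cs)[((k - 1L + 1L):(k - 1L + n)) - k + 1L]
  colors <- as.integer((upper - lower) %% 4L)
  encoded_read(adaptor, colors, k, id = id)
}

#' Decode an encoded read back to DNA
#'
#' Iteratively inverts the encoder: each color is decoded against the
#' context of the previous k-1 decoded bases (seeded by the adaptor).
#' `decode_read(encode_read(x, p, k))` is the identity for every x, p, k.
#' Note the cascade property: a single corrupted color shifts every decoded
#' base downstream of it.
#'
#' @param read An [encoded_read()].
#' @return A character string of decoded bases, one per color.
#' @examples
#' decode_read(encode_read("ACG", "T", 2))  # "ACG"
#' @export
decode_read <- function(read) {
  stopifnot(inherits(read, "encoded_read"))
  k <- read$k
  ctx <- if (k > 1L) base_to_code(read$adaptor) else integer(0)
  n <- length(read$colors)
  out <- integer(n)
  ctx_sum <- sum(ctx) %% 4L
  for (i in seq_len(n)) {
    b <- (read$colors[i] - ctx_sum) %% 4L
    out[i] <- b
    if (k > 1L) {
      # slide the context window: drop oldest, append b
      ctx_sum <- (ctx_sum - ctx[1L] + b) %% 4L
      ctx <- c(ctx[-1L], b)
    }
  }
  code_to_base(out)
}

#' Enumerate all decodings of a color string without an adaptor
#'
#' Without the known k-1 base adaptor a color string is ambiguous: one
#' decoding exists per possible adaptor, `4^(k-1)` in total (all distinct).
#'
#' @param colors Integer vector of colors in `0:3`.
#' @param k Encoding width.
#' @return Character vector of `4^(k-1)` distinct DNA sequences, named by
#'   the adaptor that produces each.
#' @examples
#' length(enumerate_decodings(c(0L, 0L), k = 3))  # 16
#' @export
enumerate_decodings <- function(colors, k) {
  k <- check_k(k)
  adaptors <- all_contexts(k)
  out <- vapply(adaptors, function(p) {
    decode_read(encoded_read(p, colors, k))
  }, character(1))
  names(out) <- adaptors
  out
}

# All k-1 base context strings in lexicographic order ("" for k=1).
all_contexts <- function(k) {
  k <- check_k(k)
  if (k == 1L) return("")
  grids <- rep(list(DNA_BASES), k - 1L)
  g <- do.call(expand.grid, c(rev(grids), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reversed columns give
  # lexicographic order with the leftmost base most significant
  apply(g[, rev(seq_len(ncol(g))), drop = FALSE], 1L, paste, collapse = "")
}

#' Color positions at which two same-length sequences encode differently
#'
#' The color-space signature of base substitutions: an interior single-base
#' substitution changes exactly k consecutive colors (fewer when the
#' substituted base lies within k-1 bases of the read end, where the
#' signature truncates).
#'
#' @param x,x_mut Two DNA sequences of equal length.
#' @param adaptor Adaptor string (shared by both encodings).
#' @param k Encoding width.
#' @return Sorted integer vector of 1-based color positions that differ.
#' @examples
#' color_diff_signature("AAAAAAA", "AAACAAA", k = 2)  # 4 5
#' @export
color_diff_signature <- function(x, x_mut, adaptor = default_adaptor(k), k = 2L) {
  k <- check_k(k)
  if (nchar(x) != nchar(x_mut)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  c1 <- encode_read(x, adaptor, k)$colors
  c2 <- encode_read(x_mut, adaptor, k)$colors
  which(c1 != c2)
}
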