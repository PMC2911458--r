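# Glocal alignment of an encoded read to a DNA reference: global in the read
# (every color is consumed), local in the reference (flanks are free). The
# dynamic program carries, per cell, one sub-cell per decoded-base context so
# that each new color can be decoded and charged a color match or mismatch.

#' Align an encoded read to a DNA reference
#'
#' Runs the context-indexed Smith-Waterman recursion with affine gap
#' penalties. Each matrix cell holds `3 * 4^(k-1)` sub-cells (aligned /
#' insertion / deletion, per decoded-base context), so cost grows as
#' `O(n m 4^k)`. Alignments never begin or end with a deletion, never
#' juxtapose an insertion and a deletion, and always consume the entire
#' read; the reference contributes no penalty outside the aligned span.
#'
#' Tie-breaking is deterministic: at equal score the aligned state is
#' preferred over a deletion, which is preferred over an insertion, and
#' lexicographically smaller contexts win.
#'
#' @param read An [encoded_read()].
#' @param reference DNA sequence (character string).
#' @param scheme A [scoring_scheme()]; default [default_scheme()].
#' @param simplified Use the uniform-score insertion simplification: the
#'   insertion search reduces to the one color-matching predecessor plus a
#'   single shared color-mismatch candidate per context suffix, preferring
#'   color matches at ties so errors sit at insertion-run boundaries when
#'   that is score-neutral. Requires a uniform scheme (the call falls back
#'   to the general recursion, with a warning, otherwise). The optimal
#'   score is identical either way.
#' @return An object of class `kb_alignment`: a list with `score`,
#'   `ref_start`/`ref_end` (1-based inclusive span of consumed reference;
#'   `ref_end < ref_start` for a pure-insertion alignment), `events` (a
#'   data frame with one row per alignment event in order: `type` in
#'   `aligned`/`insertion`/`deletion`, `read_pos`, `read_base`, `ref_pos`,
#'   `ref_base`, `obs_color`, `implied_color`, `color_error`), `decoded`
#'   (the decoded read), `snp_positions` and `color_error_positions`
#'   (1-based read positions), and `k`.
#' @examples
#' r <- encode_read("ACGTAC", k = 2)
#' align(r, "TTACGTACTT")$score
#' @export
align <- function(read, reference, scheme = default_scheme(),
                  simplified = FALSE) {
  stopifnot(inherits(read, "encoded_read"))
  stopifnot(inherits(scheme, "scoring_scheme"))
  val <- validate_scheme(scheme)
  if (!val$valid) {
    stop("invalid scoring scheme: ", paste(val$violations, collapse = "; "),
         call. = FALSE)
  }
  ref_codes <- base_to_code(reference)
  if (length(ref_codes) < 1L) stop("reference must be nonempty", call. = FALSE)
  if (simplified && !is_uniform_scheme(scheme)) {
    warning("simplified insertion recursion requires a uniform scheme; ",
            "using the general recursion")
    simplified <- FALSE
  }
  adaptor_codes <- if (read$k > 1L) base_to_code(read$adaptor) else integer(0)
  raw <- align_dp_cpp(read$colors, adaptor_codes, ref_codes, read$k,
                      pi_matrix_of(scheme), delta_matrix_of(scheme),
                      scheme$gap_open, scheme$gap_extend, simplified)
  type <- factor(c("aligned", "insertion", "deletion")[raw$type + 1L],
                 levels = c("aligned", "insertion", "deletion"))
  events <- data.frame(
    type = type,
    read_pos = raw$read_pos,
    read_base = ifelse(is.na(raw$read_base), NA_character_,
                       DNA_BASES[raw$read_base + 1L]),
    ref_pos = raw$ref_pos,
    ref_base = ifelse(is.na(raw$ref_base), NA_character_,
                      DNA_BASES[raw$ref_base + 1L]),
    obs_color = raw$obs_color,
    implied_color = raw$implied_color,
    stringsAsFactors = FALSE
  )
  events$color_error <- !is.na(events$obs_color) &
    events$obs_color != events$implied_color
  consumed <- events$type != "deletion"
  decoded <- paste(events$read_base[consumed], collapse = "")
  aligned_mm <- events$type == "aligned" & events$read_base != events$ref_base
  out <- list(
    score = raw$score,
    ref_start = raw$ref_start,
    ref_end = raw$ref_end,
    events = events,
    decoded = decoded,
    snp_positions = events$read_pos[which(aligned_mm)],
    color_error_positions = events$read_pos[which(events$color_error)],
    k = read$k,
    read_id = read$id
  )
  class(out) <- "kb_alignment"
  out
}

#' Align with the uniform-score insertion simplification
#'
#' Convenience wrapper for `align(..., simplified = TRUE)`. When the color
#' scores are uniform, every color-mismatching insertion costs the same
#' single value, so the insertion sub-cell search collapses to the one
#' color-matching predecessor plus one shared mismatch candidate per
#' context suffix, without changing the optimal score; color errors inside
#' insertion runs move to the run boundary whenever that is score-neutral.
#'
#' @inheritParams align
#' @return A `kb_alignment`; see [align()].
#' @export
align_simplified_insertion <- function(read, reference,
                                       scheme = default_scheme()) {
  align(read, reference, scheme, simplified = TRUE)
}

#' @export
print.kb_alignment <- function(x, ...) {
  cat(sprintf("<kb_alignment k=%d score=%d ref %d..%d>\n",
              x$k, x$score, x$ref_start, x$ref_end))
  cat("  decoded:", x$decoded, "\n")
  cat("  events: ", event_cigar(x), "\n")
  if (length(x$snp_positions)) {
    cat("  SNPs called at read pos:", paste(x$snp_positions, collapse = ","), "\n")
  }
  if (length(x$color_error_positions)) {
    cat("  color errors at read pos:",
        paste(x$color_error_positions, collapse = ","), "\n")
  }
  invisible(x)
}

#' CIGAR-like event string for an alignment
#'
#' Run-length encodes the event trace with operations `=` (aligned match),
#' `X` (aligned mismatch, i.e. SNP call), `I` (insertion) and `D`
#' (deletion).
#'
#' @param x A `kb_alignment`.
#' @return A character string such as `"24=1X25="`.
#' @export
event_cigar <- function(x) {
  ev <- x$events
  op <- ifelse(ev$type == "deletion", "D",
        ifelse(ev$type == "insertion", "I",
        ifelse(ev$read_base == ev$ref_base, "=", "X")))
  r <- rle(op)
  paste0(r$lengths, r$values, collapse = "")
}

#' Per-cell candidate bound of the dynamic program
#'
#' The complexity accounting for one interior matrix cell:
#' maxima over `2` candidates for each of the `|alphabet|^(k-1)` deletion
#' sub-cells and `3 |alphabet|` candidates for each aligned and insertion
#' sub-cell, i.e. `2 |alphabet|^(k-1) (1 + 3 |alphabet|)`, which is
#' `26 * 4^(k-1)` for the DNA alphabet. (The count charges all three
#' predecessor states to insertion sub-cells even though the implemented
#' recursion excludes deletion-into-insertion; it is the conventional upper
#' bound, not the exact operation count.)
#'
#' @param k Encoding width.
#' @param alphabet_size Alphabet size (4 for DNA).
#' @return Integer candidate count.
#' @examples
#' candidate_count(1)  # 26
#' candidate_count(5)  # 6656
#' @export
candidate_count <- function(k, alphabet_size = 4L) {
  k <- check_k(k)
  alphabet_size <- as.integer(alphabet_size)
  2L * alphabet_size^(k - 1L) * (1L + 3L * alphabet_size)
}

#' Re-score an alignment event trace
#'
#' Sums the color, base and affine-gap contributions of an event data
#' frame exactly as the dynamic program assigns them: aligned events score
#' `Delta(read_base, ref_base) + Pi(obs, implied)`; insertions score
#' `Pi(obs, implied)` plus `gap_open` for the first event of a run and
#' `gap_extend` for each extension; deletions likewise gap-only. Used to
#' verify tracebacks and to compute true generative alignment scores in
#' simulation.
#'
#' @param events Event data frame in the layout produced by [align()]
#'   (columns `type`, `read_base`, `ref_base`, `obs_color`,
#'   `implied_color`).
#' @param scheme A [scoring_scheme()].
#' @return Integer score.
#' @export
score_alignment_events <- function(events, scheme) {
  stopifnot(inherits(scheme, "scoring_scheme"))
  need <- c("type", "read_base", "ref_base", "obs_color", "implied_color")
  if (!all(need %in% names(events))) {
    stop("malformed events: need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  Pi <- pi_matrix_of(scheme)
  Delta <- delta_matrix_of(scheme)
  total <- 0L
  prev_type <- ""
  for (e in seq_len(nrow(events))) {
    ty <- as.character(events$type[e])
    if (ty == "aligned") {
      b <- base_to_code(events$read_base[e])
      y <- base_to_code(events$ref_base[e])
      total <- total + Delta[b + 1L, y + 1L] +
        Pi[events$obs_color[e] + 1L, events$implied_color[e] + 1L]
    } else if (ty == "insertion") {
      total <- total +
        Pi[events$obs_color[e] + 1L, events$implied_color[e] + 1L] +
        if (prev_type == "insertion") scheme$gap_extend else scheme$gap_open
    } else if (ty == "deletion") {
      total <- total +
        if (prev_type == "deletion") scheme$gap_extend else scheme$gap_open
    } else {
      stop("malformed event type: ", ty, call. = FALSE)
    }
    prev_type <- ty
  }
  total
}
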