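# Simulation study: sample reads, inject SNPs and encoding errors, align each
# read to its own origin (plus 10 bp flanks) and score power and false
# positive / false negative SNP discovery rates.
#
# Each simulated read knows its generative event trace, so the "true"
# alignment score is available exactly: power counts reads whose best
# alignment score equals that true score.

FLANK <- 10L

#' Uniform color-error model
#'
#' @param rate Per-position error probability in `[0, 1]`.
#' @return An `error_model` object.
#' @export
error_model_uniform <- function(rate) {
  rate <- as.numeric(rate)
  if (length(rate) != 1L || is.na(rate) || rate < 0 || rate > 1) {
    stop("rate must be a single probability in [0, 1]", call. = FALSE)
  }
  structure(list(kind = "uniform", rate = rate), class = "error_model")
}

#' Position-dependent color-error model
#'
#' @param rates Numeric vector of per-position error probabilities; its
#'   length must equal the read length it is used with.
#' @return An `error_model` object.
#' @export
error_model_positional <- function(rates) {
  rates <- as.numeric(rates)
  if (anyNA(rates) || any(rates < 0 | rates > 1)) {
    stop("rates must be probabilities in [0, 1]", call. = FALSE)
  }
  structure(list(kind = "positional", rates = rates), class = "error_model")
}

#' Position-dependent error model measured on an ABI SOLiD v2 run
#'
#' The 50 per-cycle color error rates estimated from aligned 50 bp reads
#' of a SOLiD v2 sequencer run. Error rates rise steeply over the read:
#' from about 0.5-1.5% in the first cycles to about 18% in the last.
#' Usable only with 50 bp reads.
#'
#' @return An `error_model` with 50 positional rates.
#' @export
real_world_error_model <- function() {
  error_model_positional(c(
    0.014, 0.005, 0.006, 0.007, 0.006, 0.006, 0.006, 0.008, 0.008, 0.008,
    0.007, 0.006, 0.009, 0.009, 0.009, 0.009, 0.008, 0.015, 0.015, 0.012,
    0.012, 0.011, 0.021, 0.021, 0.018, 0.019, 0.014, 0.037, 0.033, 0.031,
    0.029, 0.022, 0.055, 0.052, 0.051, 0.043, 0.036, 0.087, 0.084, 0.076,
    0.071, 0.060, 0.125, 0.118, 0.118, 0.108, 0.092, 0.179, 0.175, 0.184))
}

rates_for_length <- function(model, len) {
  stopifnot(inherits(model, "error_model"))
  if (model$kind == "uniform") return(rep(model$rate, len))
  if (length(model$rates) != len) {
    stop("positional error model has ", length(model$rates),
         " rates but read length is ", len, call. = FALSE)
  }
  model$rates
}

#' Simulation configuration
#'
#' Bundles the full description of one experiment cell: encoding width,
#' read length, error model, SNP count, scheme, read count, seed and
#' reference source.
#'
#' @param k Encoding width (1..5 are practical; higher widths work but
#'   cost grows as `4^k`).
#' @param read_length Read length in bases (the study grid uses 25, 50,
#'   75).
#' @param error_model An `error_model`; default no errors.
#' @param n_snps SNPs injected per read (the study grid uses 0, 1, 2).
#' @param n_reads Number of simulated reads. The default of 1000 matches
#'   the reduced scale used for scoring-scheme evaluation; 10000 matches
#'   the full study.
#' @param seed Integer RNG seed; every run is reproducible given the
#'   configuration.
#' @param scheme A [scoring_scheme()].
#' @param reference Either `"random"` (each read's local reference is an
#'   i.i.d. uniform DNA string) or a DNA character string / FASTA path to
#'   sample windows from.
#' @param fn_mode False-negative counting: `"none_called"` (a SNP-bearing
#'   read is a false negative when none of its injected SNP positions is
#'   called; the default) or `"any_missed"` (when at least one injected
#'   SNP is not called).
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(k = 2L, read_length = 50L,
                              error_model = error_model_uniform(0),
                              n_snps = 0L, n_reads = 1000L, seed = 1L,
                              scheme = default_scheme(),
                              reference = "random",
                              fn_mode = c("none_called", "any_missed")) {
  k <- check_k(k)
  if (k > 5L) warning("k > 5: running time grows as 4^k", call. = FALSE)
  read_length <- as.integer(read_length)
  n_snps <- as.integer(n_snps)
  if (n_snps < 0L || n_snps > read_length) {
    stop("n_snps must be in 0..read_length", call. = FALSE)
  }
  structure(list(k = k, read_length = read_length,
                 error_model = error_model, n_snps = n_snps,
                 n_reads = as.integer(n_reads), seed = as.integer(seed),
                 scheme = scheme, reference = reference,
                 fn_mode = match.arg(fn_mode)),
            class = "simulation_config")
}

random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

# Replace non-ACGT characters by random bases (simulation references only).
sanitize_reference <- function(x) {
  chars <- strsplit(toupper(x), "")[[1]]
  bad <- !(chars %in% DNA_BASES)
  if (any(bad)) {
    warning(sum(bad), " non-ACGT character(s) in reference replaced by ",
            "random bases", call. = FALSE)
    chars[bad] <- sample(DNA_BASES, sum(bad), replace = TRUE)
  }
  paste(chars, collapse = "")
}

#' Sample read skeletons from a reference source
#'
#' Draws `n_reads` windows of `length + 20` bases (the read plus 10 bp
#' flanks on each side, which later serve as the local reference) either
#' from a supplied source sequence at uniform random positions (forward
#' strand) or as i.i.d. random DNA.
#'
#' @param source `"random"` or a DNA character string.
#' @param n_reads Number of reads.
#' @param length Read length.
#' @param seed Optional seed; when `NULL` the current RNG state is used.
#' @return A list of skeletons, each with `sequence` (the read),
#'   `reference` (the flanked window) and `source_pos` (1-based start of
#'   the read in the source, `NA` for random mode).
#' @export
sample_reads <- function(source, n_reads, length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  length <- as.integer(length)
  if (identical(source, "random")) {
    return(lapply(seq_len(n_reads), function(i) {
      win <- random_dna(length + 2L * FLANK)
      list(sequence = substr(win, FLANK + 1L, FLANK + length),
           reference = win, source_pos = NA_integer_)
    }))
  }
  src <- sanitize_reference(source)
  need <- length + 2L * FLANK
  if (nchar(src) < need) {
    stop("source sequence (", nchar(src), " bp) shorter than read length + ",
         2L * FLANK, " bp flanks (", need, " bp)", call. = FALSE)
  }
  starts <- sample.int(nchar(src) - need + 1L, n_reads, replace = TRUE)
  lapply(starts, function(s) {
    win <- substr(src, s, s + need - 1L)
    list(sequence = substr(win, FLANK + 1L, FLANK + length),
         reference = win, source_pos = s + FLANK)
  })
}

#' Inject SNPs into a read sequence
#'
#' Chooses `n_snps` distinct uniform positions and substitutes each base
#' by one of its three alternatives, uniformly.
#'
#' @param sequence DNA character string.
#' @param n_snps Number of SNPs.
#' @return A list with `sequence` (mutated) and `snps` (data frame of
#'   `pos`, `from`, `to`; zero rows when `n_snps = 0`).
#' @export
inject_snps <- function(sequence, n_snps) {
  chars <- strsplit(sequence, "")[[1]]
  n_snps <- as.integer(n_snps)
  if (n_snps == 0L) {
    return(list(sequence = sequence,
                snps = data.frame(pos = integer(0), from = character(0),
                                  to = character(0))))
  }
  pos <- sort(sample.int(length(chars), n_snps))
  from <- chars[pos]
  to <- vapply(from, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
  chars[pos] <- to
  list(sequence = paste(chars, collapse = ""),
       snps = data.frame(pos = pos, from = from, to = unname(to)))
}

#' Inject color errors into an encoded read
#'
#' Each color is independently flipped with its position's rate to a
#' uniformly chosen wrong color.
#'
#' @param read An [encoded_read()].
#' @param model An `error_model`.
#' @return A list with `read` (corrupted) and `errors` (data frame of
#'   `pos`, `from`, `to`).
#' @export
inject_color_errors <- function(read, model) {
  stopifnot(inherits(read, "encoded_read"))
  rates <- rates_for_length(model, length(read$colors))
  hit <- which(stats::runif(length(rates)) < rates)
  colors <- read$colors
  from <- colors[hit]
  if (length(hit)) {
    delta <- sample.int(3L, length(hit), replace = TRUE)  # shift in 1..3
    colors[hit] <- (colors[hit] + delta) %% 4L
  }
  list(read = encoded_read(read$adaptor, colors, read$k, id = read$id),
       errors = data.frame(pos = hit, from = from, to = colors[hit]))
}

#' Inject base errors into a sequence (1-base encoding)
#'
#' For unencoded reads, observation errors are base changes. Errors avoid
#' the supplied SNP positions, so a position never carries both a variant
#' and an error.
#'
#' @param sequence DNA character string.
#' @param model An `error_model`.
#' @param exclude Integer positions (injected SNPs) that must stay
#'   error-free.
#' @return A list with `sequence` and `errors` (data frame of `pos`,
#'   `from`, `to`).
#' @export
inject_base_errors <- function(sequence, model, exclude = integer(0)) {
  chars <- strsplit(sequence, "")[[1]]
  rates <- rates_for_length(model, length(chars))
  hit <- setdiff(which(stats::runif(length(rates)) < rates), exclude)
  from <- chars[hit]
  to <- vapply(from, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
  chars[hit] <- to
  list(sequence = paste(chars, collapse = ""),
       errors = data.frame(pos = hit, from = from, to = unname(to)))
}

# A prohibitive color mismatch pins decoding to the observed colors; with it
# the DP is exactly glocal affine-gap Smith-Waterman on the base sequence.
strict_decode_scheme <- function(scheme) {
  scoring_scheme(color_match = scheme$color_match,
                 color_mismatch = -10000000L,
                 base_match = scheme$base_match,
                 base_mismatch = scheme$base_mismatch,
                 gap_open = scheme$gap_open,
                 gap_extend = scheme$gap_extend)
}

#' Build one simulated read
#'
#' Applies the generative model of the study: sample a skeleton, inject
#' SNPs, encode (identity for k = 1), inject errors (color substitutions
#' for k > 1, base changes avoiding SNP positions for k = 1), and score
#' the generative event trace to obtain the true alignment score.
#'
#' @param skeleton One element of [sample_reads()] output.
#' @param k Encoding width.
#' @param n_snps SNPs to inject.
#' @param error_model An `error_model`.
#' @param scheme A [scoring_scheme()].
#' @return A `simulated_read`: list with `original`, `mutated` (post-SNP
#'   sequence), `reference`, `snps`, `errors`, `encoded`
#'   ([encoded_read()] as observed), `true_score`, `k`.
#' @export
simulate_read <- function(skeleton, k, n_snps, error_model,
                          scheme = default_scheme()) {
  k <- check_k(k)
  snp <- inject_snps(skeleton$sequence, n_snps)
  if (k == 1L) {
    err <- inject_base_errors(snp$sequence, error_model, exclude = snp$snps$pos)
    observed <- encode_read(err$sequence, k = 1L)
    # true trace: the observed bases aligned to the reference, gap-free;
    # decoding is the identity so every color matches
    true_events <- data.frame(
      type = "aligned",
      read_base = strsplit(err$sequence, "")[[1]],
      ref_base = strsplit(skeleton$sequence, "")[[1]],
      obs_color = observed$colors,
      implied_color = observed$colors,
      stringsAsFactors = FALSE
    )
    errors <- err$errors
  } else {
    clean <- encode_read(snp$sequence, k = k)
    corrupt <- inject_color_errors(clean, error_model)
    observed <- corrupt$read
    true_events <- data.frame(
      type = "aligned",
      read_base = strsplit(snp$sequence, "")[[1]],
      ref_base = strsplit(skeleton$sequence, "")[[1]],
      obs_color = observed$colors,
      implied_color = clean$colors,
      stringsAsFactors = FALSE
    )
    errors <- corrupt$errors
  }
  structure(list(original = skeleton$sequence,
                 mutated = snp$sequence,
                 reference = skeleton$reference,
                 source_pos = skeleton$source_pos,
                 snps = snp$snps, errors = errors,
                 encoded = observed,
                 true_score = score_alignment_events(true_events, scheme),
                 k = k),
            class = "simulated_read")
}

#' Align one simulated read and compare to its generative truth
#'
#' A read is counted correct when its optimal alignment score over the
#' flanked local reference equals the generative alignment score; SNP
#' calls are the aligned-mismatch read positions of the optimal
#' traceback.
#'
#' @param sim A `simulated_read` from [simulate_read()].
#' @param scheme A [scoring_scheme()]. For `k = 1` the color mismatch is
#'   made prohibitive so the alignment is standard Smith-Waterman on the
#'   observed bases.
#' @return A list with `correct`, `score`, `true_score`, `snps_called`
#'   (read positions) and the alignment object.
#' @export
evaluate_read <- function(sim, scheme = default_scheme()) {
  stopifnot(inherits(sim, "simulated_read"))
  aln_scheme <- if (sim$k == 1L) strict_decode_scheme(scheme) else scheme
  al <- align(sim$encoded, sim$reference, aln_scheme,
              simplified = is_uniform_scheme(aln_scheme))
  list(correct = al$score == sim$true_score,
       score = al$score,
       true_score = sim$true_score,
       snps_called = al$snp_positions,
       alignment = al)
}

#' Run one simulation experiment cell
#'
#' Generates `n_reads` reads under the configuration, aligns each to its
#' own flanked origin, and summarizes power (fraction of reads whose best
#' score equals the true generative score), the false positive SNP
#' discovery rate (fraction of 0-SNP reads whose optimal traceback calls
#' any SNP) and the false negative SNP discovery rate (fraction of
#' SNP-bearing reads that miss their injected SNPs, per `fn_mode`).
#'
#' @param config A [simulation_config()].
#' @param keep_reads Keep the per-read records in the result (memory; off
#'   by default).
#' @return A `simulation_metrics` object: list with `power`,
#'   `fp_snp_rate` (`NA` when no 0-SNP reads), `fn_snp_rate` (`NA` when
#'   no SNP-bearing reads), `counts`, `per_read` (data frame of per-read
#'   outcomes) and `config`.
#' @export
run_experiment <- function(config, keep_reads = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  source <- config$reference
  if (is.character(source) && !identical(source, "random") &&
      file.exists(source)) {
    seqs <- read_fasta(source)
    source <- paste(seqs, collapse = "")
  }
  skeletons <- sample_reads(source, config$n_reads, config$read_length)
  correct <- logical(config$n_reads)
  called_any <- logical(config$n_reads)
  called_true <- integer(config$n_reads)  # injected SNP positions recovered
  n_called <- integer(config$n_reads)
  scores <- integer(config$n_reads)
  true_scores <- integer(config$n_reads)
  reads <- if (keep_reads) vector("list", config$n_reads) else NULL
  for (r in seq_len(config$n_reads)) {
    sim <- simulate_read(skeletons[[r]], config$k, config$n_snps,
                         config$error_model, config$scheme)
    ev <- evaluate_read(sim, config$scheme)
    correct[r] <- ev$correct
    n_called[r] <- length(ev$snps_called)
    called_any[r] <- n_called[r] > 0L
    called_true[r] <- sum(sim$snps$pos %in% ev$snps_called)
    scores[r] <- ev$score
    true_scores[r] <- ev$true_score
    if (keep_reads) reads[[r]] <- sim
  }
  has_snps <- config$n_snps > 0L
  fn <- if (!has_snps) NA_real_ else if (config$fn_mode == "none_called") {
    mean(called_true == 0L)
  } else {
    mean(called_true < config$n_snps)
  }
  per_read <- data.frame(read = seq_len(config$n_reads), correct = correct,
                         score = scores, true_score = true_scores,
                         snps_called = n_called,
                         injected_snps_called = called_true)
  structure(list(
    power = mean(correct),
    fp_snp_rate = if (has_snps) NA_real_ else mean(called_any),
    fn_snp_rate = fn,
    counts = list(n_reads = config$n_reads,
                  n_correct = sum(correct),
                  n_fp = if (has_snps) NA_integer_ else sum(called_any),
                  n_fn = if (!has_snps) NA_integer_ else
                    if (config$fn_mode == "none_called") sum(called_true == 0L)
                    else sum(called_true < config$n_snps)),
    per_read = per_read,
    reads = reads,
    config = config), class = "simulation_metrics")
}

#' @export
print.simulation_metrics <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<simulation_metrics k=%d len=%d snps=%d reads=%d seed=%d>\n",
              cfg$k, cfg$read_length, cfg$n_snps, cfg$n_reads, cfg$seed))
  cat(sprintf("  power       : %.4f\n", x$power))
  cat(sprintf("  FP SNP rate : %s\n",
              if (is.na(x$fp_snp_rate)) "-" else sprintf("%.4f", x$fp_snp_rate)))
  cat(sprintf("  FN SNP rate : %s\n",
              if (is.na(x$fn_snp_rate)) "-" else sprintf("%.4f", x$fn_snp_rate)))
  invisible(x)
}
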