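# File formats: FASTA (references, via Biostrings), generalized csfasta
# (encoded reads; header line then k-1 adaptor bases immediately followed by
# color digits) and TSV alignment reports.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path, call. = FALSE)
  out <- toupper(as.character(set))
  names(out) <- names(set)
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  if (is.null(names(seqs))) names(set) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read encoded reads from a generalized csfasta file
#'
#' Each record is a `>`-prefixed header line followed by one line holding
#' the k-1 adaptor bases immediately followed by the color digits (for
#' k = 1 the line is all digits). The reader and [write_encoded_reads()]
#' roundtrip byte-exactly.
#'
#' @param path Path to the file.
#' @param k Encoding width; the adaptor prefix of every record must have
#'   exactly k-1 bases.
#' @return A list of [encoded_read()] objects.
#' @export
read_encoded_reads <- function(path, k) {
  k <- check_k(k)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  # tolerate csfasta comment lines
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty reads file: ", path, call. = FALSE)
  reads <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], ">")) {
      stop("parse error at line ", i, ": expected header starting with '>'",
           call. = FALSE)
    }
    id <- sub("^>\\s*", "", lines[i])
    if (i + 1L > length(lines) || startsWith(lines[i + 1L], ">")) {
      stop("parse error at line ", i, ": header without sequence line",
           call. = FALSE)
    }
    body <- trimws(lines[i + 1L])
    if (nchar(body) < k) {
      stop("parse error at line ", i + 1L, ": record shorter than adaptor ",
           "(k-1 bases) plus one color", call. = FALSE)
    }
    adaptor <- substr(body, 1L, k - 1L)
    digits <- substr(body, k, nchar(body))
    chars <- strsplit(digits, "")[[1]]
    if (!all(chars %in% c("0", "1", "2", "3"))) {
      stop("parse error at line ", i + 1L, ": color characters must be ",
           "digits 0-3 (is k = ", k, " the right width for this file?)",
           call. = FALSE)
    }
    if (k > 1L && !all(strsplit(toupper(adaptor), "")[[1]] %in% DNA_BASES)) {
      stop("parse error at line ", i + 1L, ": adaptor prefix \"", adaptor,
           "\" is not ", k - 1L, " DNA base(s)", call. = FALSE)
    }
    reads[[length(reads) + 1L]] <-
      encoded_read(adaptor, as.integer(chars), k, id = id)
    i <- i + 2L
  }
  reads
}

#' Write encoded reads as generalized csfasta
#'
#' @param reads A list of [encoded_read()] objects (or a single one).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_encoded_reads <- function(reads, path) {
  if (inherits(reads, "encoded_read")) reads <- list(reads)
  lines <- character(0)
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    stopifnot(inherits(r, "encoded_read"))
    id <- if (!is.null(r$id)) r$id else paste0("read", i)
    lines <- c(lines, paste0(">", id),
               paste0(r$adaptor, paste(r$colors, collapse = "")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write an alignment report as TSV
#'
#' One row per alignment: read id, score, 1-based reference span, a
#' CIGAR-like event string, decoded sequence, and comma-separated 1-based
#' read positions of color errors and SNP calls.
#'
#' @param alignments A list of `kb_alignment` objects (or a single one).
#' @param path Output path, or `""` for standard output.
#' @return Invisibly, the report data frame.
#' @export
write_alignment_report <- function(alignments, path = "") {
  if (inherits(alignments, "kb_alignment")) alignments <- list(alignments)
  df <- data.frame(
    read_id = vapply(seq_along(alignments), function(i) {
      id <- alignments[[i]]$read_id
      if (is.null(id)) paste0("read", i) else id
    }, character(1)),
    score = vapply(alignments, function(a) a$score, integer(1)),
    ref_start = vapply(alignments, function(a) a$ref_start, integer(1)),
    ref_end = vapply(alignments, function(a) a$ref_end, integer(1)),
    events = vapply(alignments, event_cigar, character(1)),
    decoded = vapply(alignments, function(a) a$decoded, character(1)),
    color_errors = vapply(alignments, function(a)
      paste(a$color_error_positions, collapse = ","), character(1)),
    snps = vapply(alignments, function(a)
      paste(a$snp_positions, collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(df)
}
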