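# Scoring schemes for color-space alignment. A scheme scores four event
# families: color match/mismatch (Pi), base match/mismatch (Delta), gap open
# (rho) and gap extension (epsilon). Scores are integers throughout; the DP
# never touches floating point.

#' Construct a scoring scheme
#'
#' Uniform schemes carry one score per event family; per-pair 4x4 matrices
#' `pi_matrix` (rows: observed color, cols: implied color) and
#' `delta_matrix` (rows: decoded read base, cols: reference base) may
#' override the uniform values for the general recursion. Sign conventions
#' (checked by [validate_scheme()]): matches are rewarded or free
#' (`base_match >= 0`, `color_match >= 0`), mismatches penalized
#' (`base_mismatch < 0`, `color_mismatch < 0`), and gaps are affine with
#' `gap_open < gap_extend < 0`.
#'
#' @param color_match Score for a color that agrees with the decoding (CM).
#' @param color_mismatch Score for a color substitution, i.e. an encoding
#'   error (CE).
#' @param base_match Score for a decoded base equal to the reference (BM).
#' @param base_mismatch Score for a decoded base differing from the
#'   reference, i.e. a SNP call (BE).
#' @param gap_open Score for the first base of an insertion or deletion
#'   (rho).
#' @param gap_extend Score for each further base of a gap (epsilon).
#' @param pi_matrix,delta_matrix Optional integer 4x4 matrices for
#'   per-pair color / base scores. When supplied, the uniform values are
#'   ignored by the aligner's general recursion.
#' @return An object of class `scoring_scheme`.
#' @seealso [default_scheme()], [validate_scheme()]
#' @export
scoring_scheme <- function(color_match = 0L, color_mismatch = -125L,
                           base_match = 50L, base_mismatch = -150L,
                           gap_open = -175L, gap_extend = -50L,
                           pi_matrix = NULL, delta_matrix = NULL) {
  as_int1 <- function(v, what) {
    v <- as.integer(v)
    if (length(v) != 1L || is.na(v)) stop(what, " must be a single integer", call. = FALSE)
    v
  }
  s <- list(
    color_match   = as_int1(color_match, "color_match"),
    color_mismatch = as_int1(color_mismatch, "color_mismatch"),
    base_match    = as_int1(base_match, "base_match"),
    base_mismatch = as_int1(base_mismatch, "base_mismatch"),
    gap_open      = as_int1(gap_open, "gap_open"),
    gap_extend    = as_int1(gap_extend, "gap_extend"),
    pi_matrix     = check_score_matrix(pi_matrix, "pi_matrix"),
    delta_matrix  = check_score_matrix(delta_matrix, "delta_matrix")
  )
  structure(s, class = "scoring_scheme")
}

check_score_matrix <- function(m, what) {
  if (is.null(m)) return(NULL)
  if (!is.matrix(m) || !all(dim(m) == c(4L, 4L))) {
    stop(what, " must be a 4x4 matrix", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  if (anyNA(m)) stop(what, " must not contain NA", call. = FALSE)
  m
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme>\n")
  cat(sprintf("  color: match %d / mismatch %d%s\n", x$color_match,
              x$color_mismatch, if (!is.null(x$pi_matrix)) " (per-pair Pi set)" else ""))
  cat(sprintf("  base:  match %d / mismatch %d%s\n", x$base_match,
              x$base_mismatch, if (!is.null(x$delta_matrix)) " (per-pair Delta set)" else ""))
  cat(sprintf("  gap:   open %d / extend %d\n", x$gap_open, x$gap_extend))
  invisible(x)
}

#' The simulation study's default scoring scheme
#'
#' CM = 0, CE = -125, BM = 50, BE = -150, rho = -175, epsilon = -50. Under
#' this scheme a base change plus k color matches outscores a base match
#' plus k consecutive color mismatches for every k >= 2, so true SNPs are
#' preferred over the equivalent run of color errors.
#'
#' @return A [scoring_scheme()].
#' @export
default_scheme <- function() scoring_scheme()

#' Check a scoring scheme's sign constraints
#'
#' A scheme is valid when `base_match >= 0`, `color_match >= 0`,
#' `base_mismatch < 0`, `color_mismatch < 0` and
#' `gap_open < gap_extend < 0`. Per-pair matrices must satisfy the same
#' constraints entrywise (diagonal = match, off-diagonal = mismatch).
#'
#' @param s A [scoring_scheme()].
#' @return A list with `valid` (logical) and `violations` (character
#'   vector describing each failed constraint; empty when valid).
#' @export
validate_scheme <- function(s) {
  stopifnot(inherits(s, "scoring_scheme"))
  v <- character(0)
  if (s$base_match < 0L)  v <- c(v, "base_match must be >= 0")
  if (s$color_match < 0L) v <- c(v, "color_match must be >= 0")
  if (s$base_mismatch >= 0L)  v <- c(v, "base_mismatch must be < 0")
  if (s$color_mismatch >= 0L) v <- c(v, "color_mismatch must be < 0")
  if (s$gap_extend >= 0L) v <- c(v, "gap_extend must be < 0")
  if (s$gap_open >= s$gap_extend) v <- c(v, "gap_open must be < gap_extend")
  for (nm in c("pi_matrix", "delta_matrix")) {
    m <- s[[nm]]
    if (is.null(m)) next
    if (any(diag(m) < 0L)) v <- c(v, paste0(nm, " diagonal (match) must be >= 0"))
    off <- m[row(m) != col(m)]
    if (any(off >= 0L)) v <- c(v, paste0(nm, " off-diagonal (mismatch) must be < 0"))
  }
  list(valid = length(v) == 0L, violations = v)
}

#' Is a scheme uniform in its color and base scores?
#'
#' Uniform means no per-pair matrices, or matrices whose diagonal and
#' off-diagonal entries are each constant. Scenario classification and the
#' simplified insertion recursion require a uniform scheme.
#'
#' @param s A [scoring_scheme()].
#' @return Logical.
#' @export
is_uniform_scheme <- function(s) {
  stopifnot(inherits(s, "scoring_scheme"))
  unif <- function(m) {
    is.null(m) ||
      (length(unique(diag(m))) == 1L &&
         length(unique(m[row(m) != col(m)])) == 1L)
  }
  unif(s$pi_matrix) && unif(s$delta_matrix)
}

# Effective 4x4 matrices the DP consumes.
pi_matrix_of <- function(s) {
  if (!is.null(s$pi_matrix)) return(s$pi_matrix)
  m <- matrix(s$color_mismatch, 4L, 4L)
  diag(m) <- s$color_match
  m
}

delta_matrix_of <- function(s) {
  if (!is.null(s$delta_matrix)) return(s$delta_matrix)
  m <- matrix(s$base_mismatch, 4L, 4L)
  diag(m) <- s$base_match
  m
}

#' Does a scheme prefer a SNP over k consecutive color errors?
#'
#' A single base substitution is indistinguishable from a run of k
#' consistent color errors. The scheme resolves the ambiguity toward the
#' SNP exactly when `BE + k*CM > BM + k*CE` (strict; an exact tie counts
#' as not preferred).
#'
#' @param s A uniform [scoring_scheme()].
#' @param k Encoding width.
#' @return Logical.
#' @export
snp_preferred <- function(s, k) {
  stopifnot(inherits(s, "scoring_scheme"))
  k <- check_k(k)
  if (!is_uniform_scheme(s)) {
    stop("snp_preferred() requires a uniform scheme", call. = FALSE)
  }
  (s$base_mismatch + k * s$color_match) >
    (s$base_match + k * s$color_mismatch)
}

#' Classify a uniform 5-base scheme into SNP-preference scenarios
#'
#' For 5-base encoding, schemes partition into six scenarios according to
#' whether a SNP accompanied by `5-a` color matches is preferred over a
#' base match with `a` color mismatches, for `a = 5 .. 1`:
#' scenario 1 always prefers calling color errors; scenario 6 would prefer
#' a SNP explanation for any color error. Writing
#' `D_a = (a*CE + (5-a)*CM + BM) - ((5-a)*CE + a*CM + BE)`, scenario `s`
#' holds when `D_5, ..., D_{7-s}` are negative and the rest positive.
#' Exact boundary equalities (`D_a == 0`) are reported in `boundary` and
#' assigned to the higher (more SNP-preferring) scenario.
#'
#' Under the sign constraints of [validate_scheme()], scenarios 5 and 6
#' are infeasible: they would require `CM + BM < CE + BE`.
#'
#' @param s A uniform, valid [scoring_scheme()].
#' @param k Encoding width; only `k = 5` is defined.
#' @return A list with `scenario` (integer 1..6), `boundary` (integer
#'   vector of `a` values where `D_a == 0`, empty when the classification
#'   is strict) and `margins` (the five `D_a` values, named `D5` .. `D1`).
#' @export
classify_scenario <- function(s, k = 5L) {
  stopifnot(inherits(s, "scoring_scheme"))
  if (check_k(k) != 5L) stop("scenario classification is defined for k = 5", call. = FALSE)
  if (!is_uniform_scheme(s)) stop("classify_scenario() requires a uniform scheme", call. = FALSE)
  val <- validate_scheme(s)
  if (!val$valid) {
    stop("scheme violates sign constraints: ",
         paste(val$violations, collapse = "; "), call. = FALSE)
  }
  a <- 5:1
  D <- (2 * a - 5) * (s$color_mismatch - s$color_match) +
    (s$base_match - s$base_mismatch)
  names(D) <- paste0("D", a)
  scenario <- 6L - sum(D > 0)
  list(scenario = scenario, boundary = a[D == 0], margins = D)
}

#' Scenarios unreachable under the sign constraints
#'
#' Verifies, by exhaustive grid search over valid uniform schemes plus the
#' algebraic argument, that scenarios 5 and 6 admit no valid scheme: their
#' defining inequality `2CE + 3CM + BM < 3CE + 2CM + BE` rewrites to
#' `CM + BM < CE + BE`, impossible when `BM, CM >= 0 > BE, CE`.
#'
#' @param ce_grid,be_grid Integer grids of mismatch scores (< 0) to search.
#' @param cm_grid,bm_grid Integer grids of match scores (>= 0) to search.
#' @return A list with `infeasible` (`c(5L, 6L)`), `searched` (number of
#'   schemes examined) and `observed` (table of scenarios found on the
#'   grid).
#' @export
infeasible_scenarios <- function(ce_grid = seq(-1L, -300L, by = -7L),
                                 be_grid = seq(-1L, -300L, by = -7L),
                                 cm_grid = seq(0L, 100L, by = 5L),
                                 bm_grid = seq(0L, 100L, by = 5L)) {
  if (any(ce_grid >= 0L) || any(be_grid >= 0L) ||
      any(cm_grid < 0L) || any(bm_grid < 0L)) {
    stop("grids must respect the sign constraints", call. = FALSE)
  }
  # D_a depends only on u = CE - CM and w = BM - BE; enumerate the grid in
  # those coordinates but count every (CE, BE, CM, BM) combination.
  g <- expand.grid(ce = ce_grid, cm = cm_grid, be = be_grid, bm = bm_grid)
  u <- g$ce - g$cm
  w <- g$bm - g$be
  scen <- 6L -
    ((5 * u + w) > 0) - ((3 * u + w) > 0) - ((1 * u + w) > 0) -
    ((-1 * u + w) > 0) - ((-3 * u + w) > 0)
  observed <- table(factor(scen, levels = 1:6))
  list(infeasible = c(5L, 6L)[!(c(5L, 6L) %in% scen)],
       searched = nrow(g),
       observed = observed)
}

#' Read a flat key-value scoring configuration file
#'
#' The file holds one `key = value` (or `key: value`, or whitespace
#' separated) pair per line with keys `color_match`, `color_mismatch`,
#' `base_match`, `base_mismatch`, `gap_open`, `gap_extend`. Missing keys
#' take the default scheme's values. Lines starting with `#` are comments.
#'
#' @param path Path to the configuration file.
#' @return A [scoring_scheme()].
#' @export
read_scoring_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  keys <- c("color_match", "color_mismatch", "base_match",
            "base_mismatch", "gap_open", "gap_extend")
  vals <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[=:[:space:]]+")[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) != 2L) {
      stop("malformed scoring config line: \"", ln, "\"", call. = FALSE)
    }
    if (!(parts[1] %in% keys)) {
      stop("unknown scoring key: ", parts[1], call. = FALSE)
    }
    num <- suppressWarnings(as.integer(parts[2]))
    if (is.na(num)) stop("non-integer score for ", parts[1], call. = FALSE)
    vals[[parts[1]]] <- num
  }
  do.call(scoring_scheme, vals)
}

#' Write a scoring scheme as a flat key-value configuration file
#'
#' @param s A uniform [scoring_scheme()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scoring_config <- function(s, path) {
  stopifnot(inherits(s, "scoring_scheme"))
  keys <- c("color_match", "color_mismatch", "base_match",
            "base_mismatch", "gap_open", "gap_extend")
  writeLines(sprintf("%s = %d", keys,
                     vapply(keys, function(kk) s[[kk]], integer(1))),
             path)
  invisible(path)
}
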