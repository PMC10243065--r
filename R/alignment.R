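# Pairwise alignment layer: banded local alignment with affine gaps plus an
# E-value / perfect-match acceptance rule (used on bulge flanks and
# branches), and a global alignment with a normalized relative score (used
# to confirm inversion candidates).

#' Alignment parameters
#'
#' Scoring follows common nucleotide defaults (match +2, mismatch -3, gap
#' open 5, gap extend 2) with Karlin-Altschul constants `lambda = 0.625`,
#' `K = 0.41` for ungapped-style E-values.  An alignment is accepted when
#' its E-value is at most `evalue_max` and at least `n_match_min`
#' nucleotides match perfectly; the latter implicitly sets the minimum
#' useful alignment length.  `a_tilde` is the relative-score threshold for
#' the global alignment used in inversion confirmation.
#'
#' @param match,mismatch Substitution scores (`match > 0 > mismatch`).
#' @param gap_open,gap_extend Affine gap costs (>= 0); a gap of length `g`
#'   costs `gap_open + g * gap_extend`.
#' @param band_halfwidth Band half-width in nt, or `NULL` to use
#'   `max(16, ceiling(0.1 * max(length)))` plus the length difference.
#' @param evalue_max E-value acceptance threshold (default `1e-5`).
#' @param n_match_min Minimum count of perfectly matching nucleotides
#'   (default 20).
#' @param karlin_lambda,karlin_K E-value constants.
#' @param a_tilde Relative global-score acceptance threshold in `[0, 1]`
#'   (default 0.8).
#' @return List of class `alignment_params`.
#' @export
alignment_params <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                             gap_extend = 2L, band_halfwidth = NULL,
                             evalue_max = 1e-5, n_match_min = 20L,
                             karlin_lambda = 0.625, karlin_K = 0.41,
                             a_tilde = 0.8) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0,
            a_tilde >= 0, a_tilde <= 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 band_halfwidth = band_halfwidth, evalue_max = evalue_max,
                 n_match_min = as.integer(n_match_min),
                 karlin_lambda = karlin_lambda, karlin_K = karlin_K,
                 a_tilde = a_tilde),
            class = "alignment_params")
}

default_band <- function(n1, n2, params) {
  bw <- params$band_halfwidth %||% max(16L, ceiling(0.1 * max(n1, n2)))
  as.integer(bw + abs(n1 - n2))
}

#' Banded local alignment with affine gap costs
#'
#' Smith-Waterman restricted to diagonals within `band` of the main
#' diagonal.  Traceback ties are resolved deterministically (diagonal over
#' gap-in-`s1` over gap-in-`s2`).
#'
#' @param s1,s2 Nucleotide strings (non-empty).
#' @param params [alignment_params()].
#' @param band Band half-width; defaults to the `params` rule.
#' @return Object of class `alignment_result`: `score`, 0-based half-open
#'   offsets `begin1`/`end1`/`begin2`/`end2`, `n_perfect` (exactly matching
#'   columns), `evalue`, and the column `trace` (`M`/`X`/`I`/`D`).
#' @export
banded_local_align <- function(s1, s2, params = alignment_params(),
                               band = NULL) {
  if (!nzchar(s1) || !nzchar(s2)) stop("empty sequence")
  band <- as.integer(band %||% default_band(nchar(s1), nchar(s2), params))
  stopifnot(band >= 1L)
  r <- banded_local_align_cpp(s1, s2, params$match, params$mismatch,
                              params$gap_open, params$gap_extend, band)
  structure(list(score = r$score,
                 begin1 = r$begin1 - 1L, end1 = r$end1,
                 begin2 = r$begin2 - 1L, end2 = r$end2,
                 n_perfect = r$n_perfect, trace = r$trace,
                 evalue = evalue(r$score, nchar(s1), nchar(s2), params)),
            class = "alignment_result")
}

#' E-value of a local alignment score
#'
#' `K * m * n * exp(-lambda * score)`; monotone decreasing in the score and
#' linear in each sequence length.
#'
#' @param score Alignment score (>= 0).
#' @param m,n Lengths of the compared sequences.
#' @param params [alignment_params()].
#' @return Expected number of chance alignments of at least this score.
#' @export
evalue <- function(score, m, n, params = alignment_params()) {
  params$karlin_K * m * n * exp(-params$karlin_lambda * score)
}

#' Acceptance rule for local alignments
#'
#' @param result An [banded_local_align()] result.
#' @param params [alignment_params()].
#' @return `TRUE` iff `evalue <= evalue_max` and
#'   `n_perfect >= n_match_min`.
#' @export
accept_local <- function(result, params = alignment_params()) {
  result$evalue <= params$evalue_max && result$n_perfect >= params$n_match_min
}

#' Normalized global alignment score
#'
#' Needleman-Wunsch with unit scores (match +1, mismatch -1, gap -1), scaled
#' to `[0, 1]` by the analytic bounds `a_max = min(n, m) - (max(n, m) -
#' min(n, m))` and `a_min = -max(n, m)`.  Equals 1 iff the two sequences are
#' identical.
#'
#' @param s1,s2 Nucleotide strings (non-empty).
#' @param params [alignment_params()] (used only for `a_tilde` by callers).
#' @return `(a - a_min) / (a_max - a_min)`.
#' @export
global_relative_score <- function(s1, s2, params = alignment_params()) {
  if (!nzchar(s1) || !nzchar(s2)) stop("empty sequence")
  n <- nchar(s1); m <- nchar(s2)
  a <- global_align_score_cpp(s1, s2, 1L, -1L, -1L)
  a_max <- min(n, m) - (max(n, m) - min(n, m))
  a_min <- -max(n, m)
  (a - a_min) / (a_max - a_min)
}
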