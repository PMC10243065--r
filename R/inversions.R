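# Gene inversion breakpoint detection on the two-stranded graph.
#
# An inverted segment produces 2-color paths formed by (k+1)-mer matches of
# opposite strands ("broken bulges"): one genome contributes plus-strand
# edges with increasing positions while the other contributes minus-strand
# edges with decreasing positions.  Each inverted block appears twice (once
# for the segment and once for its reverse complement); the two
# complementary broken bulges are paired, their spans compared, and the
# confined subsequences confirmed by a normalized global alignment.

#' Configuration for inversion detection
#'
#' @param k k-mer size or `NULL` for [auto_k()].
#' @param delta_max Maximum relative deviation between the spans of the two
#'   paired broken bulges (default 0.10).
#' @param min_run Minimum number of opposite-strand (k+1)-mer matches in a
#'   run (default 3; suppresses isolated random hits).
#' @param max_gap Maximum number of consecutive unmatched positions bridged
#'   within a run (default 60 nt).  A single substitution shadows `k+1`
#'   edges and clustered substitutions produce dead stretches of several
#'   shadows inside a true block, so the bridge must cover a few shadows;
#'   it stays below the shortest-gene scale, the smallest stretch that
#'   could hide independent structure, and random opposite-strand matches
#'   are far too sparse (about `L^2/4^(k+1)` genome-wide) for spurious
#'   joins at this range.
#' @param align [alignment_params()] (supplies `a_tilde`).
#' @return List of class `inversion_config`.
#' @export
inversion_config <- function(k = NULL, delta_max = 0.10, min_run = 3L,
                             max_gap = 60L, align = alignment_params()) {
  stopifnot(delta_max > 0, delta_max < 1, min_run >= 1, max_gap >= 0)
  structure(list(k = k, delta_max = delta_max, min_run = as.integer(min_run),
                 max_gap = as.integer(max_gap), align = align),
            class = "inversion_config")
}

#' Find opposite-strand 2-color paths (broken bulges)
#'
#' Maximal runs of (k+1)-mer matches where genome `a` contributes
#' plus-strand edges with increasing positions and genome `b` minus-strand
#' edges with decreasing positions.  Runs may bridge short unmatched
#' stretches (substitution shadows).  Each run is reported twice -- once
#' per orientation (the segment and its reverse complement), sharing a
#' `run_id` -- mirroring the two complementary broken bulges in the graph.
#'
#' @param graph Two-stranded [build_graph()] result.
#' @param id_a,id_b Genome pair.
#' @param config [inversion_config()].
#' @return `data.table` with `run_id`, `orient` (`"fwd"`/`"rc"`), `p_lo`,
#'   `p_hi` (plus-strand end-position span in `a`), `q_lo`, `q_hi` (the
#'   matched plus-strand end-position span in `b`), `n_match`.
#' @export
find_opposite_strand_paths <- function(graph, id_a, id_b,
                                       config = inversion_config()) {
  stopifnot(graph$two_stranded)
  k <- graph$k
  max_gap <- config$max_gap %||% 60L
  ga <- graph$genomes[[id_a]]; gb <- graph$genomes[[id_b]]
  # x matches the minus strand of b iff x equals the reverse complement of
  # a plus-strand (k+1)-mer of b; qb is that plus-strand end position.
  dta <- data.table(kmer = graph$kmers_plus[[id_a]],
                    pa = graph$positions[[id_a]])
  dtb <- data.table(kmer = graph$kmers_minus[[id_b]],
                    qb = graph$positions[[id_b]])
  m <- merge(dta, dtb, by = "kmer", allow.cartesian = TRUE)
  empty <- data.table(run_id = integer(), orient = character(),
                      p_lo = integer(), p_hi = integer(),
                      q_lo = integer(), q_hi = integer(),
                      n_match = integer())
  if (nrow(m) == 0L) return(empty)
  setorder(m, pa, qb)
  # run extension along the anti-diagonal (pa increasing, qb decreasing);
  # both coordinate gaps must stay within max_gap + 1.  A pool of active
  # runs is kept so isolated random matches cannot split a genuine run.
  runs <- list(); active <- list()
  for (i in seq_len(nrow(m))) {
    pa_i <- m$pa[i]; qb_i <- m$qb[i]
    if (length(active)) {
      expired <- vapply(active, function(r)
        pa_i - r$p_hi > max_gap + 1L, TRUE)
      runs <- c(runs, active[expired])
      active <- active[!expired]
    }
    best <- 0L; best_fit <- .Machine$integer.max
    for (a in seq_along(active)) {
      dp <- pa_i - active[[a]]$p_hi
      dq <- active[[a]]$q_lo - qb_i
      if (dp >= 1L && dq >= 1L && dq <= max_gap + 1L) {
        fit <- abs(dp - dq)
        if (fit < best_fit) { best_fit <- fit; best <- a }
      }
    }
    if (best > 0L) {
      active[[best]]$p_hi <- pa_i
      active[[best]]$q_lo <- qb_i
      active[[best]]$n_match <- active[[best]]$n_match + 1L
    } else {
      active <- c(active, list(list(p_lo = pa_i, p_hi = pa_i, q_lo = qb_i,
                                    q_hi = qb_i, n_match = 1L)))
    }
  }
  runs <- c(runs, active)
  # merge runs that continue each other across the circular origin
  if (length(runs) > 1L) {
    La <- ga$length; Lb <- gb$length
    merged <- TRUE
    while (merged && length(runs) > 1L) {
      merged <- FALSE
      for (i in seq_along(runs)) {
        for (j in seq_along(runs)) {
          if (i == j) next
          dp <- (runs[[j]]$p_lo - runs[[i]]$p_hi) %% La
          dq <- (runs[[i]]$q_lo - runs[[j]]$q_hi) %% Lb
          if (dp >= 1L && dp <= max_gap + 1L && dq >= 1L &&
              dq <= max_gap + 1L &&
              runs[[j]]$p_lo < runs[[i]]$p_lo) {  # only across the origin
            runs[[i]]$p_hi <- runs[[j]]$p_hi
            runs[[i]]$q_lo <- runs[[j]]$q_lo
            runs[[i]]$n_match <- runs[[i]]$n_match + runs[[j]]$n_match
            runs[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
  }
  runs <- Filter(function(r) r$n_match >= config$min_run, runs)
  if (length(runs) == 0L) return(empty)
  fwd <- rbindlist(lapply(seq_along(runs), function(i)
    c(list(run_id = i, orient = "fwd"), runs[[i]])))
  rc <- copy(fwd)[, orient := "rc"]
  out <- rbind(fwd, rc)
  setorder(out, run_id, orient)
  out[]
}

#' Pair complementary broken bulges into IB candidates
#'
#' The two broken bulges describing one putative inverted block are paired
#' and their segment spans compared; candidates whose relative span
#' deviation exceeds `delta_max` are rejected.  The confined intervals are
#' the sequence spans of the matched runs (`[first match - k, last match]`
#' on each genome's plus strand).
#'
#' @param bulges [find_opposite_strand_paths()] output.
#' @param graph The graph.
#' @param id_a,id_b Genome pair.
#' @param config [inversion_config()].
#' @return `data.table` of candidates: intervals `a_start`, `a_end`,
#'   `b_start`, `b_end` (0-based half-open, plus-strand coordinates) and
#'   `deviation`.
#' @export
pair_broken_bulges <- function(bulges, graph, id_a, id_b,
                               config = inversion_config()) {
  empty <- data.table(genome_a = character(), genome_b = character(),
                      a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      n_match = integer(), deviation = numeric())
  if (nrow(bulges) == 0L) return(empty)
  k <- graph$k
  ga <- graph$genomes[[id_a]]; gb <- graph$genomes[[id_b]]
  ctx_a <- pos_context(ga); ctx_b <- pos_context(gb)
  one <- bulges[orient == "fwd"]
  span_a <- forward_distance(one$p_lo, one$p_hi, ctx_a)
  span_b <- forward_distance(one$q_lo, one$q_hi, ctx_b)
  dev <- abs(span_a - span_b) / pmax(1L, pmin(span_a, span_b))
  keep <- dev <= config$delta_max
  a_start <- pred(one$p_lo, k, ctx_a)
  a_end <- succ(one$p_hi, 1L, ctx_a)
  b_start <- pred(one$q_lo, k, ctx_b)
  b_end <- succ(one$q_hi, 1L, ctx_b)
  # a block spanning the whole circle is represented as [x, x)
  full_a <- span_a + k + 1L >= ga$length
  full_b <- span_b + k + 1L >= gb$length
  a_end[full_a] <- a_start[full_a]
  b_end[full_b] <- b_start[full_b]
  out <- data.table(genome_a = id_a, genome_b = id_b,
                    a_start = a_start, a_end = a_end,
                    b_start = b_start, b_end = b_end,
                    n_match = one$n_match, deviation = dev)[keep]
  setorder(out, a_start)
  out
}

# Refine the confined block boundaries by banded local alignment.  The
# exact-match runs necessarily stop at the outermost clean (k+1)-mer, at
# least one substitution shadow inside the true block; aligning the block
# with flanking windows attached follows the homology to where it ends.
# Iterated while the footprint keeps touching a window edge.
refine_ib_bounds <- function(cand, ga, gb, config, ext = 80L) {
  La <- ga$length; Lb <- gb$length
  as <- cand$a_start; ae <- cand$a_end
  bs <- cand$b_start; be <- cand$b_end
  for (round in 1:5) {
    span_a <- (ae - as) %% La; if (span_a == 0L) span_a <- La
    span_b <- (be - bs) %% Lb; if (span_b == 0L) span_b <- Lb
    if (span_a + 2L * ext >= La || span_b + 2L * ext >= Lb) break
    sa <- circ_substr(ga, as - ext, ae - 1L + ext)
    sb <- reverse_complement(circ_substr(gb, bs - ext, be - 1L + ext))
    al <- banded_local_align(sa, sb, config$align)
    if (al$score <= 0) break
    as2 <- (as - ext + al$begin1) %% La
    ae2 <- (as - ext + al$end1) %% La
    bs2 <- (be + ext - al$end2) %% Lb
    be2 <- (be + ext - al$begin2) %% Lb
    grew <- al$begin1 < ext || al$end1 > nchar(sa) - ext ||
      al$begin2 < ext || al$end2 > nchar(sb) - ext
    as <- as2; ae <- ae2; bs <- bs2; be <- be2
    if (!grew) break
  }
  list(a_start = as, a_end = ae, b_start = bs, b_end = be)
}

#' Confirm an inversion-block candidate by global alignment (or reject)
#'
#' The candidate's confined intervals are first refined by local alignment
#' (exact-match confinement stops inside the true block under substitution
#' noise); the two subsequences are then extracted (the second reverse
#' complemented so both read 5' to 3') and their normalized global
#' alignment score compared against `a_tilde`.
#'
#' @param cand One-row candidate from [pair_broken_bulges()].
#' @param genomes Named list of genomes.
#' @param config [inversion_config()].
#' @return One-row `data.table` (`InversionBlock`: intervals, strands,
#'   `rel_score`) or `NULL`.
#' @export
confirm_ib <- function(cand, genomes, config = inversion_config()) {
  ga <- genomes[[cand$genome_a]]; gb <- genomes[[cand$genome_b]]
  bounds <- refine_ib_bounds(cand, ga, gb, config)
  sa <- circ_substr(ga, bounds$a_start, bounds$a_end - 1L)
  sb <- reverse_complement(circ_substr(gb, bounds$b_start,
                                       bounds$b_end - 1L))
  rel <- global_relative_score(sa, sb, config$align)
  if (rel < config$align$a_tilde) return(NULL)
  data.table(genome_a = cand$genome_a, a_start = bounds$a_start,
             a_end = bounds$a_end, a_strand = "+",
             genome_b = cand$genome_b, b_start = bounds$b_start,
             b_end = bounds$b_end, b_strand = "-",
             rel_score = rel)
}

#' Detect inverted sequence blocks
#'
#' Full pipeline over every genome pair: opposite-strand run detection on
#' the two-stranded graph, complementary-bulge pairing with the span
#' deviation rule, and global-alignment confirmation.
#'
#' @param genomes Named list of [genome()] objects (>= 2).
#' @param config [inversion_config()].
#' @return `data.table` of inversion blocks: `genome_a`, `a_start`,
#'   `a_end`, `a_strand`, `genome_b`, `b_start`, `b_end`, `b_strand`,
#'   `rel_score` (0-based half-open plus-strand intervals; the `b` segment
#'   is the reverse complement of the `a` segment).  k-mer size attached as
#'   attribute `k`.
#' @export
detect_inversions <- function(genomes, config = inversion_config()) {
  stopifnot(length(genomes) >= 2L)
  if (is.null(names(genomes)) || any(!nzchar(names(genomes))))
    names(genomes) <- vapply(genomes, `[[`, "", "id")
  k <- config$k %||% auto_k(genomes)
  graph <- build_graph(genomes, k, two_stranded = TRUE)
  ids <- names(genomes)
  out <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    bulges <- find_opposite_strand_paths(graph, ids[i], ids[j], config)
    cands <- pair_broken_bulges(bulges, graph, ids[i], ids[j], config)
    for (r in seq_len(nrow(cands))) {
      ib <- confirm_ib(cands[r], genomes, config)
      if (!is.null(ib)) out <- c(out, list(ib))
    }
  }
  res <- if (length(out)) rbindlist(out) else
    data.table(genome_a = character(), a_start = integer(),
               a_end = integer(), a_strand = character(),
               genome_b = character(), b_start = integer(),
               b_end = integer(), b_strand = character(),
               rel_score = numeric())
  setorder(res, genome_a, genome_b, a_start)
  setattr(res, "k", k)
  res[]
}
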