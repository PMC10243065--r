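# Position-annotated colored de Bruijn graph.
#
# Vertices are k-mers (kept implicit); edges are (k+1)-mer occurrences
# annotated with genome ("color"), end position and strand.  On the plus
# strand the edge for the (k+1)-mer ending at position p spans [p-k, p]
# (circularly); a circular genome of length L contributes exactly L plus-
# strand edges.  In two-stranded mode the reverse complement of the edge at
# p is added on the minus strand at position p-k, so consecutive minus-
# strand edges have decreasing positions.

# (k+1)-mers of one genome, indexed by end position.
# Circular: one per position 0..L-1.  Linear: end positions k..L-1.
genome_kmers <- function(g, k) {
  L <- g$length
  if (L <= k) stop("genome '", g$id, "' shorter than k+1")
  if (g$topology == "circular") {
    dd <- paste0(g$seq, substr(g$seq, 1L, k))
    starts <- ((0:(L - 1L)) - k) %% L
    substring(dd, starts + 1L, starts + k + 1L)
  } else {
    starts <- 0:(L - k - 1L)
    substring(g$seq, starts + 1L, starts + k + 1L)
  }
}

# End positions matching genome_kmers() order.
genome_kmer_positions <- function(g, k) {
  if (g$topology == "circular") 0:(g$length - 1L) else k:(g$length - 1L)
}

#' Build a position-annotated colored de Bruijn graph
#'
#' @param genomes Named list of [genome()] objects (the colors).
#' @param k k-mer (vertex) size; edges are (k+1)-mers.  `k >= 2`.
#' @param two_stranded Also index the reverse-complement (minus-strand)
#'   edges, as needed for inversion detection.
#' @return Object of class `position_dbg` with an edge table `edges`
#'   (columns `kmer`, `genome`, `strand`, `pos`, sorted lexicographically)
#'   and per-genome dense position-to-(k+1)-mer arrays.
#' @export
build_graph <- function(genomes, k, two_stranded = FALSE) {
  stopifnot(is.list(genomes), length(genomes) >= 1L)
  if (is.null(names(genomes)) || any(!nzchar(names(genomes))))
    names(genomes) <- vapply(genomes, `[[`, "", "id")
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  lens <- vapply(genomes, `[[`, 0L, "length")
  if (k >= min(lens)) stop("k must be smaller than the shortest genome")
  kp <- lapply(genomes, genome_kmers, k = k)
  pp <- lapply(genomes, genome_kmer_positions, k = k)
  km <- NULL
  if (two_stranded) km <- lapply(kp, reverse_complement)
  tabs <- lapply(names(genomes), function(id) {
    t1 <- data.table(kmer = kp[[id]], genome = id, strand = "+",
                     pos = pp[[id]])
    if (!two_stranded) return(t1)
    ctx <- pos_context(genomes[[id]])
    t2 <- data.table(kmer = km[[id]], genome = id, strand = "-",
                     pos = pred(pp[[id]], k, ctx))
    rbind(t1, t2)
  })
  edges <- rbindlist(tabs)
  setkey(edges, kmer, genome, pos, strand)
  structure(list(k = k, two_stranded = two_stranded, genomes = genomes,
                 kmers_plus = kp, kmers_minus = km, positions = pp,
                 edges = edges),
            class = "position_dbg")
}

#' @export
print.position_dbg <- function(x, ...) {
  cat(sprintf("<position_dbg> k=%d, %d genome(s), %d edges%s\n",
              x$k, length(x$genomes), nrow(x$edges),
              if (x$two_stranded) " (two-stranded)" else ""))
  invisible(x)
}

#' Look up the occurrences of a (k+1)-mer
#'
#' @param graph A [build_graph()] result.
#' @param kmer1 (k+1)-mer string.
#' @return `data.table` of matching edges (possibly empty), in deterministic
#'   (genome, position, strand) order.
#' @export
dbg_lookup <- function(graph, kmer1) {
  graph$edges[.(kmer1), nomatch = NULL, on = "kmer"]
}

#' (k+1)-mer repeat rate of a genome
#'
#' `1 - distinct/total` over the genome's (k+1)-mer multiset (circular
#' genomes contribute one (k+1)-mer per position).
#'
#' @param g A [genome()].
#' @param k k-mer size.
#' @return Fraction in `[0, 1]`.
#' @export
repeat_rate <- function(g, k) {
  km <- genome_kmers(g, k)
  1 - length(unique(km)) / length(km)
}

#' Automatic k-mer size selection
#'
#' Chooses the minimum `k` in `[k_min, k_max]` such that every genome's
#' (k+1)-mer repeat rate is at most `max_rate`.  Feasibility is monotone in
#' `k`, so the first feasible value is returned.  The default `k_min = 10`
#' keeps the expected number of random (k+1)-mer collisions between
#' mitogenome-sized (~16 kb) sequences negligible (roughly
#' `L^2 / 4^(k+1)` < 100); it can be lowered for short test sequences.
#'
#' @param genomes Named list of [genome()] objects.
#' @param max_rate Maximum tolerated repeat rate (default 0.15).
#' @param k_min,k_max Search range.
#' @return Selected `k` (integer).
#' @export
auto_k <- function(genomes, max_rate = 0.15, k_min = 10L, k_max = 32L) {
  stopifnot(length(genomes) >= 1L)
  lens <- vapply(genomes, `[[`, 0L, "length")
  for (k in seq.int(k_min, k_max)) {
    if (k >= min(lens)) break
    rates <- vapply(genomes, repeat_rate, 0, k = k)
    if (max(rates) <= max_rate) return(as.integer(k))
  }
  stop("no k in [", k_min, ", ", k_max, "] achieves repeat rate <= ",
       max_rate, "; set k manually")
}

#' Pairwise (k+1)-mer match rate
#'
#' Number of distinct (k+1)-mers present in both genomes divided by the
#' total (k+1)-mer count of the shorter genome.  With
#' `mode = "inversion_only"` only matches between opposite strands are
#' counted (a (k+1)-mer of `g1`'s plus strand that occurs on `g2`'s minus
#' strand).
#'
#' @param g1,g2 [genome()] objects.
#' @param k k-mer size.
#' @param mode `"all"` or `"inversion_only"`.
#' @return Fraction.
#' @export
match_rate <- function(g1, g2, k, mode = c("all", "inversion_only")) {
  mode <- match.arg(mode)
  k1 <- unique(genome_kmers(g1, k))
  k2 <- unique(genome_kmers(g2, k))
  if (mode == "inversion_only") k2 <- unique(reverse_complement(k2))
  shorter <- min(length(genome_kmers(g1, k)), length(genome_kmers(g2, k)))
  length(intersect(k1, k2)) / shorter
}

#' Count edges of one genome absent from another
#'
#' The number of (k+1)-mer occurrences (edges) of `g_target` whose
#' (k+1)-mer does not occur in `g_other`.  An isolated substitution in a
#' locally repeat-free region leaves exactly `k+1` unmatched edges in each
#' genome; an isolated deletion leaves `k+1` in the unaffected genome and
#' `k` in the genome carrying the deletion.
#'
#' @param g_target,g_other [genome()] objects.
#' @param k k-mer size.
#' @return Integer count.
#' @export
edges_unique_to <- function(g_target, g_other, k) {
  kt <- genome_kmers(g_target, k)
  ko <- unique(genome_kmers(g_other, k))
  sum(!(kt %in% ko))
}

#' Condense an edge walk to a (genome, first, last) tuple
#'
#' A single-color path following succeeding positions is uniquely determined
#' by the end positions of its first and last edges.
#'
#' @param positions Integer vector of consecutive edge end positions (must
#'   follow `succ` steps of one).
#' @param genome_id Genome label.
#' @param ctx [pos_context()] of that genome.
#' @param strand Strand of the walk.
#' @return Object of class `condensed_path` with fields `genome`, `strand`,
#'   `first`, `last`, `length`.
#' @export
condense <- function(positions, genome_id, ctx, strand = "+") {
  n <- length(positions)
  stopifnot(n >= 1L)
  if (n > 1L) {
    step <- if (strand == "+") 1L else -1L
    expect <- if (strand == "+") succ(positions[-n], 1, ctx)
              else pred(positions[-n], 1, ctx)
    if (!all(positions[-1L] == expect))
      stop("condense: positions are not contiguous")
    invisible(step)
  }
  structure(list(genome = genome_id, strand = strand,
                 first = positions[1L], last = positions[n], length = n),
            class = "condensed_path")
}

#' Expand a condensed path back to its edge positions
#'
#' @param cp A [condense()] result (or a list with the same fields).
#' @param ctx [pos_context()] of the path's genome.
#' @return Integer vector of edge end positions.
#' @export
expand_path <- function(cp, ctx) {
  n <- if (!is.null(cp$length)) cp$length else {
    forward_distance(cp$first, cp$last, ctx) + 1L
  }
  if (cp$strand == "+") succ(cp$first, 0:(n - 1L), ctx)
  else pred(cp$first, 0:(n - 1L), ctx)
}

#' Dump the edge table
#'
#' @param graph A [build_graph()] result.
#' @param path Optional TSV output file.
#' @return The edge `data.table`, invisibly when writing to a file.
#' @export
dump_edges <- function(graph, path = NULL) {
  if (is.null(path)) return(graph$edges[])
  write.table(graph$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(graph$edges[])
}
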