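# Dislocation breakpoint detection.
#
# For every genome pair the position-annotated graph is scanned for
# breakpoint bulges (BBs): a short single-color branch (the breakpoint
# genome's transition (k+1)-mers) paired against a long color-alternating
# branch.  The staged workflow is:
#   1. branch points: initiation points (IP), where a 2-color path splits
#      into two single-color paths, and termination points (TP), where two
#      single-color paths merge;
#   2. candidate enumeration from IP-TP combinations with branch-length
#      filters;
#   3. completion of the color-alternating branch from the candidates of
#      the entangled breakpoints;
#   4. banded local alignment of the rho-length bulge flanks;
#   5. anchor detection + chaining on the color-alternating branch, with an
#      overlap check against the flank regions;
#   6. homology screen of long single-color branches (which must NOT align);
#   7. complete-linkage clustering to remove shifted duplicates.

#' Configuration for dislocation detection
#'
#' @param k k-mer size, or `NULL` to select automatically ([auto_k()]).
#' @param g_min Length (nt) of the shortest gene expected in the input
#'   class of species; 60 nt covers mitochondrial tRNAs (~70 nt) with
#'   margin.  The color-alternating branch of a real bulge must contain at
#'   least one gene, so branches shorter than this are discarded.
#' @param epsilon Flank slack (nt); flank/subpath length is
#'   `rho = g_min + epsilon`.
#' @param max_single_branch Maximum single-color branch length (edges);
#'   `NULL` means `2 * rho`.  Real single-color branches are on the order
#'   of `k`, but poor conservation and intergenic sequence stretch them by
#'   the distance to the nearest conserved (k+1)-mer on either side; the
#'   cap only bounds the quadratic IP-TP pairing -- the principled guard
#'   against long branches hiding a synteny block is the Step-6 homology
#'   screen.
#' @param overlap_max Maximum tolerated overlap fraction between a
#'   homologous region found on the alternating branch and a flank region
#'   (default 0.10; fraction of the shorter region).
#' @param align [alignment_params()].
#' @return List of class `dislocation_config`.
#' @export
dislocation_config <- function(k = NULL, g_min = 60L, epsilon = 20L,
                               max_single_branch = NULL, overlap_max = 0.10,
                               align = alignment_params()) {
  stopifnot(g_min > 0, epsilon >= 0, overlap_max > 0, overlap_max < 1)
  structure(list(k = k, g_min = as.integer(g_min),
                 epsilon = as.integer(epsilon),
                 rho = as.integer(g_min + epsilon),
                 max_single_branch = max_single_branch,
                 overlap_max = overlap_max, align = align),
            class = "dislocation_config")
}

# position -> kmer-vector index (1-based), NA when absent (linear ends)
pos_index <- function(g, k, pos) {
  if (g$topology == "circular") return(pos %% g$length + 1L)
  idx <- pos - k + 1L
  idx[pos < k | pos >= g$length] <- NA_integer_
  idx
}

#' Find bulge initiation and termination points (Step 1)
#'
#' An IP is a shared (k+1)-mer occurrence pair whose successor edges
#' diverge (with the four involved k-mer vertices pairwise distinct); a TP
#' is the mirror image on the predecessor side.
#'
#' @param graph A one-stranded [build_graph()] over (at least) the pair.
#' @param id_a,id_b Genome ids of the pair.
#' @return List with `ip` and `tp` `data.table`s; columns `p2a`, `p2b`
#'   (positions of the shared 2-color edge in each genome) and `sa`, `sb`
#'   (positions of the adjacent single-color edges).
#' @export
find_branch_points <- function(graph, id_a, id_b) {
  k <- graph$k
  ga <- graph$genomes[[id_a]]; gb <- graph$genomes[[id_b]]
  ka <- graph$kmers_plus[[id_a]]; kb <- graph$kmers_plus[[id_b]]
  dta <- data.table(kmer = ka, pa = graph$positions[[id_a]])
  dtb <- data.table(kmer = kb, pb = graph$positions[[id_b]])
  m <- merge(dta, dtb, by = "kmer", allow.cartesian = TRUE)
  if (nrow(m) == 0L)
    return(list(ip = empty_bp(), tp = empty_bp()))
  ia_n <- pos_index(ga, k, m$pa + 1L); ib_n <- pos_index(gb, k, m$pb + 1L)
  ia_p <- pos_index(ga, k, m$pa - 1L); ib_p <- pos_index(gb, k, m$pb - 1L)
  kan <- ifelse(is.na(ia_n), NA, ka[ia_n])
  kbn <- ifelse(is.na(ib_n), NA, kb[ib_n])
  kap <- ifelse(is.na(ia_p), NA, ka[ia_p])
  kbp <- ifelse(is.na(ib_p), NA, kb[ib_p])
  v1 <- substr(m$kmer, 1L, k); v2 <- substr(m$kmer, 2L, k + 1L)
  ip_raw <- !is.na(kan) & !is.na(kbn) & kan != kbn
  if (any(ip_raw)) {
    v3 <- substr(kan[ip_raw], 2L, k + 1L); v4 <- substr(kbn[ip_raw], 2L, k + 1L)
    w1 <- v1[ip_raw]; w2 <- v2[ip_raw]
    ok <- v3 != v4 & w1 != w2 & w1 != v3 & w1 != v4 & w2 != v3 & w2 != v4
    ip_raw[ip_raw] <- ok
  }
  tp_raw <- !is.na(kap) & !is.na(kbp) & kap != kbp
  if (any(tp_raw)) {
    u3 <- substr(kap[tp_raw], 1L, k); u4 <- substr(kbp[tp_raw], 1L, k)
    w1 <- v1[tp_raw]; w2 <- v2[tp_raw]
    ok <- u3 != u4 & w1 != w2 & u3 != w1 & u3 != w2 & u4 != w1 & u4 != w2
    tp_raw[tp_raw] <- ok
  }
  ctx_a <- pos_context(ga); ctx_b <- pos_context(gb)
  ip <- data.table(p2a = m$pa[ip_raw], p2b = m$pb[ip_raw])
  ip[, c("sa", "sb") := .(succ(p2a, 1L, ctx_a), succ(p2b, 1L, ctx_b))]
  tp <- data.table(p2a = m$pa[tp_raw], p2b = m$pb[tp_raw])
  tp[, c("sa", "sb") := .(pred(p2a, 1L, ctx_a), pred(p2b, 1L, ctx_b))]
  setorder(ip, p2a, p2b); setorder(tp, p2a, p2b)
  list(ip = ip, tp = tp)
}

empty_bp <- function() {
  data.table(p2a = integer(), p2b = integer(), sa = integer(),
             sb = integer())
}

empty_candidates <- function() {
  data.table(r_b = character(), r_o = character(), sb_start = integer(),
             sb_end = integer(), sb_len = integer(), a1 = integer(),
             a2 = integer(), alt_len = integer(), ip2b = integer(),
             ip2o = integer(), tp2b = integer(), tp2o = integer())
}

#' Enumerate breakpoint-bulge candidates (Step 2)
#'
#' Each IP-TP combination of a genome pair yields up to two candidates
#' (breakpoint in either genome).  A candidate is kept when its
#' single-color branch is short (at most `max_single_branch` edges) and
#' the forward span of its color-alternating branch is at least `g_min`.
#'
#' @param bp [find_branch_points()] result.
#' @param graph The graph.
#' @param id_a,id_b The pair.
#' @param config [dislocation_config()].
#' @return Candidate `data.table` (see fields in the source); deduplicated
#'   and deterministically ordered.
#' @export
enumerate_candidates <- function(bp, graph, id_a, id_b, config) {
  k <- graph$k
  max_single <- config$max_single_branch %||% (2L * config$rho)
  ctx_a <- pos_context(graph$genomes[[id_a]])
  ctx_b <- pos_context(graph$genomes[[id_b]])
  one_role <- function(rb, ro, ctx_rb, ctx_ro, swap) {
    ip <- bp$ip; tp <- bp$tp
    if (nrow(ip) == 0L || nrow(tp) == 0L) return(empty_candidates())
    # role columns: s_b/single positions in the breakpoint genome
    ip_sb <- if (swap) ip$sb else ip$sa
    ip_so <- if (swap) ip$sa else ip$sb
    ip_2b <- if (swap) ip$p2b else ip$p2a
    ip_2o <- if (swap) ip$p2a else ip$p2b
    tp_sb <- if (swap) tp$sb else tp$sa
    tp_so <- if (swap) tp$sa else tp$sb
    tp_2b <- if (swap) tp$p2b else tp$p2a
    tp_2o <- if (swap) tp$p2a else tp$p2b
    idx <- CJ(i = seq_len(nrow(ip)), j = seq_len(nrow(tp)))
    sb_len <- forward_distance(ip_sb[idx$i], tp_sb[idx$j], ctx_rb) + 1L
    keep1 <- sb_len <= max_single
    idx <- idx[keep1]; sb_len <- sb_len[keep1]
    if (nrow(idx) == 0L) return(empty_candidates())
    alt_len <- forward_distance(ip_so[idx$i], tp_so[idx$j], ctx_ro) + 1L
    keep2 <- alt_len >= config$g_min
    idx <- idx[keep2]; sb_len <- sb_len[keep2]; alt_len <- alt_len[keep2]
    if (nrow(idx) == 0L) return(empty_candidates())
    out <- data.table(
      r_b = rb, r_o = ro,
      sb_start = ip_sb[idx$i], sb_end = tp_sb[idx$j], sb_len = sb_len,
      a1 = ip_so[idx$i], a2 = tp_so[idx$j], alt_len = alt_len,
      ip2b = ip_2b[idx$i], ip2o = ip_2o[idx$i],
      tp2b = tp_2b[idx$j], tp2o = tp_2o[idx$j])
    unique(out)
  }
  out <- rbind(one_role(id_a, id_b, ctx_a, ctx_b, swap = FALSE),
               one_role(id_b, id_a, ctx_b, ctx_a, swap = TRUE))
  setorder(out, r_b, sb_start, sb_end, a1, a2)
  out
}

#' Complete the color-alternating branches (Step 3)
#'
#' The first and last edges of a candidate's color-alternating branch are
#' known from its IP and TP.  The missing paths are taken from the
#' candidates of the entangled breakpoints: a candidate whose single-color
#' branch lies in the other genome and starts at the known first position
#' completes the opening path, one ending at the known last position
#' completes the closing path.  Candidates lacking either completion cannot
#' be true bulges and are dropped.  Among several options the pair whose
#' paths are furthest apart is chosen (ties: smallest start positions).
#'
#' @param cands [enumerate_candidates()] output for one genome pair.
#' @param graph The graph.
#' @return Candidates with added columns `pa1_end`, `pa2_start`,
#'   `branch_total` (single + defining alternating path lengths).
#' @export
complete_alternating_paths <- function(cands, graph) {
  if (nrow(cands) == 0L) {
    cands <- copy(cands)
    cands[, c("pa1_end", "pa2_start", "branch_total", "interior") :=
            .(integer(), integer(), integer(), integer())]
    return(cands)
  }
  start_key <- split(seq_len(nrow(cands)),
                     paste(cands$r_b, cands$sb_start, sep = "\r"))
  end_key <- split(seq_len(nrow(cands)),
                   paste(cands$r_b, cands$sb_end, sep = "\r"))
  n <- nrow(cands)
  pa1_end <- rep(NA_integer_, n); pa2_start <- rep(NA_integer_, n)
  total <- rep(NA_integer_, n); interior <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ro <- cands$r_o[i]
    ctx_o <- pos_context(graph$genomes[[ro]])
    opt1 <- start_key[[paste(ro, cands$a1[i], sep = "\r")]]
    opt2 <- end_key[[paste(ro, cands$a2[i], sep = "\r")]]
    if (is.null(opt1) || is.null(opt2)) next
    span <- forward_distance(cands$a1[i], cands$a2[i], ctx_o)
    e1s <- unique(cands$sb_end[opt1])   # P_a1 = (r_o, a1, e1)
    s2s <- unique(cands$sb_start[opt2]) # P_a2 = (r_o, s2, a2)
    # completions must stay within the alternating-branch span; "furthest
    # apart" is the largest interior between the end of P_a1 and the start
    # of P_a2 (negative when the paths cross, never wrapped around)
    e1s <- e1s[forward_distance(cands$a1[i], e1s, ctx_o) <= span]
    s2s <- s2s[forward_distance(s2s, cands$a2[i], ctx_o) <= span]
    if (length(e1s) == 0L || length(s2s) == 0L) next
    best <- c(NA_integer_, NA_integer_); best_d <- -.Machine$integer.max
    for (s2 in sort(s2s)) for (e1 in sort(e1s)) {
      d <- span - forward_distance(cands$a1[i], e1, ctx_o) -
        forward_distance(s2, cands$a2[i], ctx_o)
      if (d > best_d) { best_d <- d; best <- c(e1, s2) }
      # ties keep the first (smallest s2, then e1) by iteration order
    }
    if (best_d < 1L) next  # no room for a synteny block between the paths
    pa1_end[i] <- best[1L]; pa2_start[i] <- best[2L]
    interior[i] <- best_d
    total[i] <- cands$sb_len[i] +
      (forward_distance(cands$a1[i], best[1L], ctx_o) + 1L) +
      (forward_distance(best[2L], cands$a2[i], ctx_o) + 1L)
  }
  out <- copy(cands)
  out[, c("pa1_end", "pa2_start", "branch_total", "interior") :=
        .(pa1_end, pa2_start, total, interior)]
  out[!is.na(pa1_end) & !is.na(pa2_start)]
}

# Align one flank pair; returns acceptance + absolute footprints.
# Memoized on the window coordinates: many candidates share an IP or TP.
align_flank <- function(gX, gO, startX, startO, rho, k, ap, cache = NULL) {
  key <- paste(gX$id, gO$id, startX, startO, sep = "\r")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  sX <- circ_substr(gX, startX, startX + rho - 1L)
  sO <- circ_substr(gO, startO, startO + rho - 1L)
  al <- banded_local_align(sX, sO, ap)
  res <- list(ok = accept_local(al, ap), evalue = al$evalue,
              x_fp = c((startX + al$begin1) %% gX$length,
                       al$end1 - al$begin1),
              o_fp = c((startO + al$begin2) %% gO$length,
                       al$end2 - al$begin2))
  if (!is.null(cache)) cache[[key]] <- res
  res
}

#' Check bulge-flank homology (Step 4)
#'
#' Every true bulge is flanked by a maximal synteny block on each end, so
#' the `rho`-length subsequences entering the bulge (ending at the IP's
#' 2-color edge) and leaving it (starting at the TP's 2-color edge) must
#' align in the two genomes.
#'
#' @param cands Completed candidates (Step 3).
#' @param graph The graph.
#' @param config [dislocation_config()].
#' @param cache Optional environment for memoizing shared-window
#'   alignments across candidates.
#' @return Candidates that pass, with flank footprint columns attached.
#' @export
check_flanks <- function(cands, graph, config, cache = NULL) {
  n <- nrow(cands)
  rho <- config$rho; ap <- config$align
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  keep <- logical(n)
  fp <- matrix(NA_integer_, n, 8L)
  colnames(fp) <- c("lf_xs", "lf_xl", "lf_os", "lf_ol",
                    "rf_xs", "rf_xl", "rf_os", "rf_ol")
  for (i in seq_len(n)) {
    gX <- graph$genomes[[cands$r_b[i]]]
    gO <- graph$genomes[[cands$r_o[i]]]
    lf <- align_flank(gX, gO, (cands$ip2b[i] - rho + 1L) %% gX$length,
                      (cands$ip2o[i] - rho + 1L) %% gO$length,
                      rho, graph$k, ap, cache)
    if (!lf$ok) next
    rf <- align_flank(gX, gO, cands$tp2b[i] %% gX$length,
                      cands$tp2o[i] %% gO$length, rho, graph$k, ap, cache)
    if (!rf$ok) next
    keep[i] <- TRUE
    fp[i, ] <- c(lf$x_fp, lf$o_fp, rf$x_fp, rf$o_fp)
  }
  out <- copy(cands)
  out <- cbind(out, as.data.table(fp))
  out[keep]
}

#' Find alignment anchors on a path segment (Step 5, anchor detection)
#'
#' For each edge of the query segment the (k+1)-mer is looked up in the
#' target genome; occurrence pairs that are consecutive in both genomes
#' (same diagonal) are merged into anchors.  No graph traversal is needed.
#'
#' @param graph The graph.
#' @param seg_genome Genome id carrying the segment.
#' @param first,last First/last edge end-positions of the segment.
#' @param target Genome id to search in.
#' @return `data.table` of anchors: `o_lo`, `o_hi` (absolute segment
#'   positions), `x_lo`, `x_hi` (absolute target positions), `len`.
#' @export
find_alignment_anchors <- function(graph, seg_genome, first, last, target) {
  gO <- graph$genomes[[seg_genome]]; gX <- graph$genomes[[target]]
  ctx_o <- pos_context(gO)
  n <- forward_distance(first, last, ctx_o) + 1L
  posO <- succ(first, 0:(n - 1L), ctx_o)
  kms <- graph$kmers_plus[[seg_genome]][pos_index(gO, graph$k, posO)]
  dtq <- data.table(kmer = kms, iseg = 0:(n - 1L))
  dtx <- data.table(kmer = graph$kmers_plus[[target]],
                    px = graph$positions[[target]])
  m <- merge(dtq, dtx, by = "kmer", allow.cartesian = TRUE)
  if (nrow(m) == 0L)
    return(data.table(o_lo = integer(), o_hi = integer(),
                      x_lo = integer(), x_hi = integer(), len = integer()))
  Lx <- gX$length
  m[, diag := (px - iseg) %% Lx]
  setorder(m, diag, iseg)
  brk <- c(TRUE, diff(m$iseg) != 1L | m$diag[-1L] != m$diag[-nrow(m)])
  grp <- cumsum(brk)
  res <- m[, .(o_lo = posO[iseg[1L] + 1L], o_hi = posO[iseg[.N] + 1L],
               x_lo = px[1L], x_hi = px[.N], len = .N,
               i_lo = iseg[1L], i_hi = iseg[.N]), by = .(g = grp)]
  res[, g := NULL]
  setorder(res, i_lo, x_lo)
  res
}

#' Chain anchors and align the extended region (Step 5, chaining)
#'
#' Anchors that are collinear (increasing in both genomes) with gaps of at
#' most `rho` are chained; the highest-coverage chain is extended linearly
#' to the full segment bounds and the corresponding subsequences are
#' aligned and tested with the usual acceptance rule.
#'
#' @param anchors [find_alignment_anchors()] output.
#' @param graph The graph.
#' @param seg_genome,first,last The query segment (as for anchor finding).
#' @param target Target genome id.
#' @param config [dislocation_config()].
#' @return `NULL` when no accepted alignment exists, else a list with the
#'   footprints `o_fp`/`x_fp` (`c(start, len)` in absolute coordinates),
#'   `score` and `evalue`.
#' @export
chain_and_extend <- function(anchors, graph, seg_genome, first, last,
                             target, config) {
  if (nrow(anchors) == 0L) return(NULL)
  gO <- graph$genomes[[seg_genome]]; gX <- graph$genomes[[target]]
  ctx_o <- pos_context(gO); ctx_x <- pos_context(gX)
  k <- graph$k; rho <- config$rho; ap <- config$align
  n <- nrow(anchors)
  cov <- anchors$len; prev <- rep(0L, n)
  if (n > 1L) {
    for (i in 2:n) {
      for (j in 1:(i - 1L)) {
        gs <- anchors$i_lo[i] - anchors$i_hi[j]
        if (gs < 1L || gs > rho) next
        gx <- forward_distance(anchors$x_hi[j], anchors$x_lo[i], ctx_x)
        if (gx < 1L || gx > rho) next
        cand <- cov[j] + anchors$len[i]
        if (cand > cov[i]) { cov[i] <- cand; prev[i] <- j }
      }
    }
  }
  best <- which.max(cov)
  chain <- best
  while (prev[chain[1L]] != 0L) chain <- c(prev[chain[1L]], chain)
  o_lo <- anchors$o_lo[chain[1L]]; o_hi <- anchors$o_hi[chain[length(chain)]]
  x_lo <- anchors$x_lo[chain[1L]]; x_hi <- anchors$x_hi[chain[length(chain)]]
  # extend linearly to the segment bounds
  ext_l <- forward_distance(first, o_lo, ctx_o)
  ext_r <- forward_distance(o_hi, last, ctx_o)
  x_start <- pred(x_lo, ext_l, ctx_x)
  x_end <- succ(x_hi, ext_r, ctx_x)
  sO <- circ_substr(gO, first - k, last)
  sX <- circ_substr(gX, x_start - k, x_end)
  al <- banded_local_align(sO, sX, ap)
  if (!accept_local(al, ap)) return(NULL)
  list(o_fp = c((first - k + al$begin1) %% gO$length, al$end1 - al$begin1),
       x_fp = c((x_start - k + al$begin2) %% gX$length, al$end2 - al$begin2),
       score = al$score, evalue = al$evalue)
}

# min-normalized overlap of two (x-interval, o-interval) region pairs
region_overlap <- function(a_x, a_o, b_x, b_o, Lx, Lo) {
  fx <- circ_overlap_len(a_x[1], a_x[2], b_x[1], b_x[2], Lx) /
    max(1L, min(a_x[2], b_x[2]))
  fo <- circ_overlap_len(a_o[1], a_o[2], b_o[1], b_o[2], Lo) /
    max(1L, min(a_o[2], b_o[2]))
  min(fx, fo)
}

# Memoized Step-5 machinery on one segment.
segment_homology <- function(graph, seg_genome, first, last, target,
                             config, cache = NULL) {
  key <- paste("seg", seg_genome, first, last, target, sep = "\r")
  if (!is.null(cache)) {
    hit <- cache[[key]]
    if (!is.null(hit)) return(if (isTRUE(hit$none)) NULL else hit)
  }
  res <- chain_and_extend(
    find_alignment_anchors(graph, seg_genome, first, last, target),
    graph, seg_genome, first, last, target, config)
  if (!is.null(cache)) cache[[key]] <- res %||% list(none = TRUE)
  res
}

#' Check the color-alternating branch for homologous regions (Step 5)
#'
#' The putative 2-color path components following the opening path and
#' preceding the closing path (each truncated to `rho` edges) are searched
#' for alignable homologous regions in the breakpoint genome.  Candidates
#' where only low-quality alignments are found (no accepted region on
#' either component) are discarded; an accepted region that largely
#' coincides with a flank region means the candidate is not shaped like a
#' bulge and is rejected as well.
#'
#' @param cands Candidates that passed Step 4.
#' @param graph The graph.
#' @param config [dislocation_config()].
#' @param cache Optional memoization environment.
#' @return Surviving candidates.
#' @export
check_alternating_branch <- function(cands, graph, config, cache = NULL) {
  n <- nrow(cands); rho <- config$rho
  keep <- logical(n)
  for (i in seq_len(n)) {
    ro <- cands$r_o[i]; rb <- cands$r_b[i]
    gO <- graph$genomes[[ro]]; gX <- graph$genomes[[rb]]
    ctx_o <- pos_context(gO)
    # the putative 2-color components live between the end of the opening
    # and the start of the closing path; use at most rho edges of each
    len <- min(rho, cands$interior[i])
    seg1_first <- succ(cands$pa1_end[i], 1L, ctx_o)
    seg1_last <- succ(cands$pa1_end[i], len, ctx_o)
    seg2_first <- pred(cands$pa2_start[i], len, ctx_o)
    seg2_last <- pred(cands$pa2_start[i], 1L, ctx_o)
    r1 <- segment_homology(graph, ro, seg1_first, seg1_last, rb, config,
                           cache)
    r2 <- segment_homology(graph, ro, seg2_first, seg2_last, rb, config,
                           cache)
    regions <- Filter(Negate(is.null), list(r1, r2))
    if (length(regions) == 0L) next
    Lx <- gX$length; Lo <- gO$length
    lf_x <- c(cands$lf_xs[i], cands$lf_xl[i])
    lf_o <- c(cands$lf_os[i], cands$lf_ol[i])
    rf_x <- c(cands$rf_xs[i], cands$rf_xl[i])
    rf_o <- c(cands$rf_os[i], cands$rf_ol[i])
    ovs <- unlist(lapply(regions, function(r)
      c(region_overlap(r$x_fp, r$o_fp, lf_x, lf_o, Lx, Lo),
        region_overlap(r$x_fp, r$o_fp, rf_x, rf_o, Lx, Lo))))
    if (any(ovs > config$overlap_max)) next
    keep[i] <- TRUE
  }
  cands[keep]
}

#' Screen long single-color branches (Step 6)
#'
#' A true single-color branch holds no synteny block, so it must not
#' contain a region homologous to a NEW location of the other genome.
#' Branches shorter than `n_match_min` cannot yield a trustworthy
#' alignment and pass unconditionally.  Longer branches are discarded when
#' an accepted alignment is found whose location in the other genome does
#' not coincide with the flank regions identified in Step 4 -- an
#' alignment that merely re-finds a flank synteny-block fragment (the
#' branch overshooting into a noisy block end) is no evidence of a hidden
#' block inside the branch.
#'
#' @param cands Candidates that passed Step 5.
#' @param graph The graph.
#' @param config [dislocation_config()].
#' @param cache Optional memoization environment.
#' @return Surviving candidates.
#' @export
check_single_branch <- function(cands, graph, config, cache = NULL) {
  n <- nrow(cands)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (cands$sb_len[i] < config$align$n_match_min) { keep[i] <- TRUE; next }
    rb <- cands$r_b[i]; ro <- cands$r_o[i]
    hit <- segment_homology(graph, rb, cands$sb_start[i], cands$sb_end[i],
                            ro, config, cache)
    if (is.null(hit)) { keep[i] <- TRUE; next }
    # hit$x_fp is the footprint in r_o.  Tolerate flank-block overshoot:
    # the found region is explained by a flanking synteny block only when
    # the majority of the region itself lies inside a flank region.  A
    # hidden block (or a collinear non-bulge) produces a region mostly
    # outside both flanks and discards the candidate.
    Lo <- graph$genomes[[ro]]$length
    cont_l <- circ_overlap_len(hit$x_fp[1], hit$x_fp[2],
                               cands$lf_os[i], cands$lf_ol[i], Lo) /
      max(1L, hit$x_fp[2])
    cont_r <- circ_overlap_len(hit$x_fp[1], hit$x_fp[2],
                               cands$rf_os[i], cands$rf_ol[i], Lo) /
      max(1L, hit$x_fp[2])
    keep[i] <- max(cont_l, cont_r) > 0.5
  }
  cands[keep]
}

#' Remove shifted duplicate candidates (Step 7)
#'
#' Within each ordered genome pair, candidates are clustered by
#' complete-linkage agglomerative clustering under the maximum circular
#' distance between their related position predictions at the two bulge
#' ends (single-branch start/end in the breakpoint genome, alternating
#' branch first/last position in the other genome);
#' the dendrogram is cut at `rho` and within every multi-member cluster
#' only the candidate with the shortest total branch length is kept (ties:
#' smallest break start).
#'
#' @param cands Candidates that passed Step 6.
#' @param graph The graph.
#' @param config [dislocation_config()].
#' @return Final candidates.
#' @export
remove_shifted <- function(cands, graph, config) {
  if (nrow(cands) <= 1L) return(cands)
  out <- vector("list", 0L)
  for (key in unique(paste(cands$r_b, cands$r_o, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- cands[r_b == parts[1] & r_o == parts[2]]
    if (nrow(sub) == 1L) { out <- c(out, list(sub)); next }
    L <- graph$genomes[[parts[1]]]$length
    Lo <- graph$genomes[[parts[2]]]$length
    ds <- outer(sub$sb_start, sub$sb_start,
                function(p, q) circ_dist(p, q, L))
    de <- outer(sub$sb_end, sub$sb_end, function(p, q) circ_dist(p, q, L))
    da1 <- outer(sub$a1, sub$a1, function(p, q) circ_dist(p, q, Lo))
    da2 <- outer(sub$a2, sub$a2, function(p, q) circ_dist(p, q, Lo))
    dmat <- pmax(ds, de, da1, da2)
    # cut strictly inside rho: shifted duplicates sit closer than the
    # flank scale, while distinct true breakpoints can be exactly a
    # shortest-gene length apart
    cl <- cutree(hclust(as.dist(dmat), method = "complete"),
                 h = config$rho - 0.5)
    picked <- vapply(split(seq_len(nrow(sub)), cl), function(ix) {
      s <- sub[ix]
      ord <- order(s$branch_total, s$sb_start)
      ix[ord[1L]]
    }, 0L)
    out <- c(out, list(sub[sort(picked)]))
  }
  res <- rbindlist(out)
  setorder(res, r_b, r_o, sb_start)
  res
}

# Refine the other-genome association points of final candidates by local
# alignment.  The exact (k+1)-mer anchors stop one substitution shadow
# (about k+1 nt) or more before the true junction; a local alignment of
# the flank extended through the single-color branch follows the homology
# to the point where it actually ends, which localizes the junction to a
# few nucleotides even under heavy substitution noise.
refine_associations <- function(cands, graph, config) {
  n <- nrow(cands)
  rho <- config$rho; k <- graph$k; ap <- config$align
  left <- integer(n); right <- integer(n)
  for (i in seq_len(n)) {
    gX <- graph$genomes[[cands$r_b[i]]]
    gO <- graph$genomes[[cands$r_o[i]]]
    Lo <- gO$length
    ext <- cands$sb_len[i] + k
    # left bulge end: homology runs up to g_i's end in both genomes
    sx0 <- (cands$ip2b[i] - rho + 1L) %% gX$length
    so0 <- (cands$ip2o[i] - rho + 1L) %% Lo
    al <- banded_local_align(
      circ_substr(gX, sx0, sx0 + rho + ext - 1L),
      circ_substr(gO, so0, so0 + rho + ext - 1L), ap)
    left[i] <- if (al$score > 0) (so0 + al$end2) %% Lo
               else cands$a1[i]
    # right bulge end: homology starts at g_j's start in both genomes
    sx1 <- (cands$tp2b[i] - ext) %% gX$length
    so1 <- (cands$tp2o[i] - ext) %% Lo
    al <- banded_local_align(
      circ_substr(gX, sx1, sx1 + rho + ext - 1L),
      circ_substr(gO, so1, so1 + rho + ext - 1L), ap)
    right[i] <- if (al$score > 0) (so1 + al$begin2) %% Lo
                else (cands$a2[i] - k + 1L) %% Lo
  }
  list(left = left, right = right)
}

#' Detect dislocation breakpoints
#'
#' Runs the full seven-step workflow for every genome pair (both
#' orderings).  Predictions report, per breakpoint, the break interval on
#' the breakpoint genome (the sequence span of the single-color branch,
#' which brackets the gene junction) and the associated positions at both
#' bulge ends on the other genome.
#'
#' @param genomes Named list of [genome()] objects (>= 2).
#' @param config [dislocation_config()].
#' @return `data.table` of class `breakpoint_predictions`: columns `r_b`,
#'   `r_o`, `break_start`, `break_end` (0-based half-open, circular),
#'   `break_len`, `other_left`, `other_right`, `sb_len`.  The per-step
#'   candidate funnel is attached as attribute `funnel`, the k-mer size as
#'   `k`.
#' @export
detect_dislocations <- function(genomes, config = dislocation_config()) {
  stopifnot(length(genomes) >= 2L)
  if (is.null(names(genomes)) || any(!nzchar(names(genomes))))
    names(genomes) <- vapply(genomes, `[[`, "", "id")
  k <- config$k %||% auto_k(genomes)
  graph <- build_graph(genomes, k)
  ids <- names(genomes)
  preds <- list(); funnel <- list()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    cache <- new.env(parent = emptyenv())
    bp <- find_branch_points(graph, ids[i], ids[j])
    s2 <- enumerate_candidates(bp, graph, ids[i], ids[j], config)
    s3 <- complete_alternating_paths(s2, graph)
    s4 <- check_flanks(s3, graph, config, cache)
    s5 <- check_alternating_branch(s4, graph, config, cache)
    s6 <- check_single_branch(s5, graph, config, cache)
    s7 <- remove_shifted(s6, graph, config)
    funnel[[paste(ids[i], ids[j])]] <- data.table(
      pair = paste(ids[i], ids[j]),
      step = c("ip", "tp", paste0("step", 2:7)),
      n = c(nrow(bp$ip), nrow(bp$tp), nrow(s2), nrow(s3), nrow(s4),
            nrow(s5), nrow(s6), nrow(s7)))
    preds[[paste(ids[i], ids[j])]] <- s7
  }
  all <- rbindlist(preds)
  if (nrow(all) == 0L) {
    res <- data.table(r_b = character(), r_o = character(),
                      break_start = integer(), break_end = integer(),
                      break_len = integer(), other_left = integer(),
                      other_right = integer(), sb_len = integer())
  } else {
    Lb <- vapply(all$r_b, function(id) genomes[[id]]$length, 0L)
    Lo <- vapply(all$r_o, function(id) genomes[[id]]$length, 0L)
    refined <- refine_associations(all, graph, config)
    res <- data.table(
      r_b = all$r_b, r_o = all$r_o,
      break_start = (all$sb_start - k) %% Lb,
      break_end = (all$sb_end + 1L) %% Lb,
      break_len = all$sb_len + k,
      other_left = refined$left,
      other_right = refined$right,
      sb_len = all$sb_len)
    setorder(res, r_b, r_o, break_start)
  }
  setattr(res, "funnel", rbindlist(funnel))
  setattr(res, "k", k)
  setattr(res, "class", c("breakpoint_predictions", class(res)))
  res[]
}
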