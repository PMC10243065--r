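# Scoring predictions against ground truth: one-to-one matching with a
# strict (max-aggregated) circular positional error, empirical
# distribution functions of those errors, overlap-based inversion-block
# correctness, and a breakpoint plot.

#' Match breakpoint predictions to true breakpoints
#'
#' Greedy one-to-one matching in order of increasing distance.  The
#' distance between a prediction and a truth is the maximum of (i) the
#' circular distance from the true break location to the predicted break
#' interval (0 when contained) and (ii, iii) the circular distances at the
#' two associated positions on the other genome.  The maximum is the
#' strictest aggregation: a prediction only counts as close if every
#' reported coordinate is close.
#'
#' @param predictions [detect_dislocations()] rows of ONE ordered genome
#'   pair.
#' @param truths [true_breakpoints()] rows of the same ordered pair (with
#'   positions).
#' @param L_b,L_o Genome lengths of the breakpoint/other genome.
#' @return List of class `match_report`: `pairs` (`truth_id`, `pred_id`,
#'   `distance`), `n_true`, `n_pred`.
#' @export
match_predictions <- function(predictions, truths, L_b, L_o) {
  if (nrow(predictions) > 0L &&
      (length(unique(predictions$r_b)) > 1L ||
       length(unique(predictions$r_o)) > 1L))
    stop("predictions span more than one ordered genome pair")
  if (nrow(truths) > 0L && length(unique(truths$r_b)) > 1L)
    stop("truths span more than one ordered genome pair")
  np <- nrow(predictions); nt <- nrow(truths)
  if (np == 0L || nt == 0L)
    return(structure(list(pairs = data.table(truth_id = integer(),
                                             pred_id = integer(),
                                             distance = numeric()),
                          n_true = nt, n_pred = np),
                     class = "match_report"))
  cand <- CJ(truth_id = seq_len(nt), pred_id = seq_len(np))
  d_interval <- function(point, start, len, L) {
    # circular distance from a point to the interval [start, start+len)
    off <- (point - start) %% L
    ifelse(off < len, 0, pmin(L - off, off - len + 1))
  }
  blen <- (predictions$break_end - predictions$break_start) %%
    pmax(1L, L_b)
  blen[blen == 0L] <- predictions$break_len[blen == 0L]
  d1 <- d_interval(truths$pos_b[cand$truth_id],
                   predictions$break_start[cand$pred_id],
                   blen[cand$pred_id], L_b)
  d2 <- circ_dist(truths$pos_o_left[cand$truth_id],
                  predictions$other_left[cand$pred_id], L_o)
  d3 <- circ_dist(truths$pos_o_right[cand$truth_id],
                  predictions$other_right[cand$pred_id], L_o)
  cand[, distance := pmax(d1, d2, d3)]
  setorder(cand, distance, truth_id, pred_id)
  used_t <- logical(nt); used_p <- logical(np)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    t <- cand$truth_id[i]; p <- cand$pred_id[i]
    if (!used_t[t] && !used_p[p]) {
      used_t[t] <- TRUE; used_p[p] <- TRUE; keep[i] <- TRUE
    }
  }
  structure(list(pairs = cand[keep], n_true = nt, n_pred = np),
            class = "match_report")
}

#' Empirical distribution function of breakpoint positional errors
#'
#' `EDF(d)` is the fraction of true breakpoints matched with positional
#' error at most `d`, normalized by the total number of true breakpoints
#' (so the value at infinity is the recall).
#'
#' @param reports A `match_report` or list of them (pooled).
#' @return A function `d -> fraction` of class `breakpoint_edf`, with
#'   attributes `distances` (sorted matched distances) and `n_true`.
#' @export
breakpoint_edf <- function(reports) {
  if (inherits(reports, "match_report")) reports <- list(reports)
  n_true <- sum(vapply(reports, `[[`, 0L, "n_true"))
  if (n_true == 0L) stop("no true breakpoints to normalize by")
  d <- sort(unlist(lapply(reports, function(r) r$pairs$distance)))
  f <- function(x) vapply(x, function(xi) sum(d <= xi) / n_true, 0)
  structure(f, distances = d, n_true = n_true, class = "breakpoint_edf")
}

#' @export
print.breakpoint_edf <- function(x, ...) {
  cat(sprintf("<breakpoint_edf> %d/%d matched; EDF(0)=%.3f EDF(50)=%.3f\n",
              length(attr(x, "distances")), attr(x, "n_true"), x(0), x(50)))
  invisible(x)
}

#' Is a predicted inversion block correct?
#'
#' A prediction is correct when it shares at least `threshold` of its
#' positions with the true block on BOTH genomes; the shared fraction is
#' `|intersection| / max(|prediction|, |truth|)` (symmetric, penalizing
#' both over- and under-calling).
#'
#' @param pred,truth One-row tables with `a_start`, `a_end`, `b_start`,
#'   `b_end` (0-based half-open).
#' @param L_a,L_b Genome lengths.
#' @param threshold Default 0.75.
#' @return Logical.
#' @export
ib_correct <- function(pred, truth, L_a, L_b, threshold = 0.75) {
  frac <- function(s1, e1, s2, e2, L) {
    l1 <- (e1 - s1) %% L; if (l1 == 0L) l1 <- L
    l2 <- (e2 - s2) %% L; if (l2 == 0L) l2 <- L
    circ_overlap_len(s1 %% L, l1, s2 %% L, l2, L) / max(l1, l2)
  }
  fa <- frac(pred$a_start, pred$a_end, truth$a_start, truth$a_end, L_a)
  fb <- frac(pred$b_start, pred$b_end, truth$b_start, truth$b_end, L_b)
  fa >= threshold && fb >= threshold
}

#' Count correctly identified inversion blocks
#'
#' Each true block is matched to at most one prediction of the same genome
#' pair under the [ib_correct()] criterion.
#'
#' @param predictions [detect_inversions()] output.
#' @param truth Truth table from [make_inversion_benchmark()].
#' @param genomes Named list of genomes (for lengths).
#' @param threshold Overlap threshold (default 0.75).
#' @return Integer: number of true blocks correctly identified.
#' @export
evaluate_inversions <- function(predictions, truth, genomes,
                                threshold = 0.75) {
  if (nrow(truth) == 0L) return(0L)
  used <- logical(nrow(predictions))
  correct <- 0L
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i]
    L_a <- genomes[[tr$genome_a]]$length
    L_b <- genomes[[tr$genome_b]]$length
    for (j in seq_len(nrow(predictions))) {
      if (used[j]) next
      pr <- predictions[j]
      same <- pr$genome_a == tr$genome_a && pr$genome_b == tr$genome_b
      swapped <- pr$genome_a == tr$genome_b && pr$genome_b == tr$genome_a
      if (!same && !swapped) next
      if (swapped)
        pr <- data.table(a_start = pr$b_start, a_end = pr$b_end,
                         b_start = pr$a_start, b_end = pr$a_end)
      if (ib_correct(pr, tr, L_a, L_b, threshold)) {
        used[j] <- TRUE; correct <- correct + 1L
        break
      }
    }
  }
  correct
}

#' Breakpoint plot
#'
#' Two annotated gene tracks with predicted break intervals (red) and
#' connector lines to the associated sites on the other genome (solid for
#' the start, dashed for the end association).  Connectors that are not
#' parallel to a gene block boundary indicate predictions that cannot be
#' allocated to a putative breakpoint.
#'
#' @param predictions [detect_dislocations()] rows for the two genomes (in
#'   either direction).
#' @param ann_a,ann_b Annotation data.frames of the top/bottom genome.
#' @param path Output image file (`.pdf` or `.png`).
#' @return The ggplot object, invisibly; the file is written.
#' @export
breakpoint_plot <- function(predictions, ann_a, ann_b, path) {
  id_a <- ann_a$genome_id[1]; id_b <- ann_b$genome_id[1]
  genes <- rbind(
    data.frame(y = 1, xs = ann_a$start, xe = ann_a$end, gene = ann_a$gene),
    data.frame(y = 0, xs = ann_b$start, xe = ann_b$end, gene = ann_b$gene))
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(data = genes,
                       ggplot2::aes(xmin = xs, xmax = xe, ymin = y - 0.08,
                                    ymax = y + 0.08, fill = gene),
                       show.legend = FALSE, color = "grey30",
                       linewidth = 0.1) +
    ggplot2::scale_y_continuous(breaks = c(0, 1), labels = c(id_b, id_a),
                                limits = c(-0.35, 1.35)) +
    ggplot2::labs(x = "position (nt)", y = NULL) +
    ggplot2::theme_minimal()
  if (nrow(predictions) > 0L) {
    top <- predictions$r_b == id_a
    bands <- data.frame(
      y = ifelse(top, 1, 0),
      xs = predictions$break_start,
      xe = ifelse(predictions$break_end >= predictions$break_start,
                  predictions$break_end,
                  predictions$break_start + predictions$break_len))
    p <- p + ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = xs, xmax = xe,
                   ymin = y + ifelse(y == 1, 0.12, -0.2),
                   ymax = y + ifelse(y == 1, 0.2, -0.12)),
      fill = "red")
    conn <- rbind(
      data.frame(x = predictions$break_start,
                 xend = predictions$other_left,
                 y = ifelse(top, 1.12, -0.12),
                 yend = ifelse(top, -0.12, 1.12), type = "start"),
      data.frame(x = ifelse(predictions$break_end >=
                              predictions$break_start,
                            predictions$break_end,
                            predictions$break_start + predictions$break_len),
                 xend = predictions$other_right,
                 y = ifelse(top, 1.12, -0.12),
                 yend = ifelse(top, -0.12, 1.12), type = "end"))
    p <- p + ggplot2::geom_segment(
      data = conn,
      ggplot2::aes(x = x, xend = xend, y = y, yend = yend, linetype = type),
      linewidth = 0.3, show.legend = FALSE) +
      ggplot2::scale_linetype_manual(values = c(start = "solid",
                                                end = "dashed"))
  }
  ggplot2::ggsave(path, p, width = 9, height = 3.2)
  invisible(p)
}
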