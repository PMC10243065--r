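toy <- toy_gene_pair(k = 7, gene_len = 80, seed = 11)
toy_graph <- build_graph(list(r1 = toy$r1, r2 = toy$r2), 7)
toy_cfg <- dislocation_config(k = 7)

test_that("identical repeat-free genomes yield no branch points", {
  s <- repeat_free_seq(300, 6, seed = 31)
  gr <- build_graph(list(a = genome("a", s), b = genome("b", s)), 6)
  bp <- find_branch_points(gr, "a", "b")
  expect_equal(nrow(bp$ip), 0)
  expect_equal(nrow(bp$tp), 0)
})

test_that("an isolated substitution produces one IP and one TP", {
  k <- 6
  s <- repeat_free_seq(300, k, seed = 32)
  s2 <- s
  ch <- substr(s, 150, 150)
  substr(s2, 150, 150) <- setdiff(c("A", "C", "G", "T"), ch)[1]
  gr <- build_graph(list(a = genome("a", s), b = genome("b", s2)), k)
  bp <- find_branch_points(gr, "a", "b")
  expect_equal(nrow(bp$ip), 1)
  expect_equal(nrow(bp$tp), 1)
  # the inconsistency bulge spans the k+1 unmatched edges
  expect_equal(forward_distance(bp$ip$sa, bp$tp$sa, pos_context(300)),
               k)
})

test_that("the gene-order toy yields one IP/TP per synteny block junction", {
  bp <- find_branch_points(toy_graph, "r1", "r2")
  expect_equal(nrow(bp$ip), 4)
  expect_equal(nrow(bp$tp), 4)
})

test_that("candidate enumeration applies both branch-length filters", {
  bp <- find_branch_points(toy_graph, "r1", "r2")
  cands <- enumerate_candidates(bp, toy_graph, "r1", "r2", toy_cfg)
  # one candidate per breakpoint: 4 with the break in r1, 4 in r2
  expect_equal(nrow(cands[sb_len <= 10]), 8)
  expect_equal(nrow(cands[r_b == "r1" & sb_len <= 10]), 4)
  # swapped-role partners of those IP-TP pairs have gene-length branches;
  # with a small cap they are filtered out
  tight <- dislocation_config(k = 7, max_single_branch = 10L)
  cands_tight <- enumerate_candidates(bp, toy_graph, "r1", "r2", tight)
  expect_equal(nrow(cands_tight), 8)
  # alt-branch spans below g_min are rejected
  big_gmin <- dislocation_config(k = 7, g_min = 400L)
  expect_equal(nrow(enumerate_candidates(bp, toy_graph, "r1", "r2",
                                         big_gmin)), 0)
})

test_that("alternating-path completion picks the widest interior", {
  g1 <- genome("r1", random_seq(100, 41)); g2 <- genome("r2", random_seq(100, 42))
  gr <- build_graph(list(r1 = g1, r2 = g2), 4)
  base <- data.table::data.table(
    r_b = c("r1", "r2", "r2", "r2", "r2"),
    r_o = c("r2", "r1", "r1", "r1", "r1"),
    sb_start = c(5L, 10L, 10L, 45L, 20L),
    sb_end = c(7L, 13L, 30L, 50L, 50L),
    sb_len = c(3L, 4L, 21L, 6L, 31L),
    a1 = c(10L, 0L, 0L, 0L, 0L),
    a2 = c(50L, 0L, 0L, 0L, 0L),
    alt_len = c(41L, 10L, 10L, 10L, 10L),
    ip2b = 0L, ip2o = 0L, tp2b = 0L, tp2o = 0L)
  done <- complete_alternating_paths(base, gr)
  row <- done[r_b == "r1"]
  expect_equal(nrow(row), 1)
  # options: P_a1 end in {13, 30}, P_a2 start in {45, 20};
  # interior = 40 - |P_a1| - |P_a2| is maximal for (13, 45)
  expect_equal(row$pa1_end, 13L)
  expect_equal(row$pa2_start, 45L)
  expect_equal(row$interior, 40L - 3L - 5L)
  # candidates without both completions are dropped
  no_comp <- base[c(1, 4, 5)]
  expect_equal(nrow(complete_alternating_paths(no_comp, gr)[r_b == "r1"]), 0)
})

test_that("toy completions reconstruct the alternating branch ends", {
  bp <- find_branch_points(toy_graph, "r1", "r2")
  s2 <- enumerate_candidates(bp, toy_graph, "r1", "r2", toy_cfg)
  s3 <- complete_alternating_paths(s2[sb_len <= 10], toy_graph)
  expect_equal(nrow(s3), 8)
  # single branch of the (g1,g2) breakpoint in r1: transition k-mers after
  # gene g1, i.e. near position 80; its completions are the entangled
  # branches in r2 starting/ending at the same alternating positions
  b1 <- s3[r_b == "r1"][which.min(abs(sb_start - 80))]
  expect_lt(abs(b1$a1 - 80), 3)
  expect_lt(abs(b1$a2 - 240 - toy_cfg$k + 1) %% toy$r2$length, 8)
  expect_equal(b1$pa1_end, b1$a1 + b1$sb_len - 1L)
})

test_that("flank checks accept homologous flanks and reject noise", {
  bp <- find_branch_points(toy_graph, "r1", "r2")
  s3 <- complete_alternating_paths(
    enumerate_candidates(bp, toy_graph, "r1", "r2", toy_cfg), toy_graph)
  s4 <- check_flanks(s3, toy_graph, toy_cfg)
  # all 8 true bulges (short single branches) pass on noise-free data;
  # whole-gene "skip" combinations also have synteny-block flanks here and
  # are eliminated later by the single-branch homology screen
  expect_equal(nrow(s4[sb_len <= 10]), 8)
  # scattered substitutions at ~10% leave flanks acceptable
  p <- toy_cfg$align
  s <- random_seq(80, 51)
  noisy <- evolve_hky(s, 10, seed = 52)
  al <- banded_local_align(s, noisy, p)
  expect_true(accept_local(al, p))
  # unrelated sequence fails
  al2 <- banded_local_align(s, random_seq(80, 53), p)
  expect_false(accept_local(al2, p))
})

test_that("anchors merge diagonal runs and split at substitutions", {
  k <- 6
  s <- repeat_free_seq(400, k, seed = 61)
  s2 <- s
  substr(s2, 200, 200) <- setdiff(c("A", "C", "G", "T"),
                                  substr(s, 200, 200))[1]
  gr <- build_graph(list(a = genome("a", s), b = genome("b", s2)), k)
  # fully shared segment -> single anchor
  a0 <- find_alignment_anchors(gr, "a", 50, 100, "b")
  expect_equal(nrow(a0), 1)
  expect_equal(a0$len, 51L)
  # segment spanning the SNP -> two anchors separated by k+1 positions
  a1 <- find_alignment_anchors(gr, "a", 170, 230, "b")
  expect_equal(nrow(a1), 2)
  expect_equal(a1$o_lo[2] - a1$o_hi[1] - 1L, k + 1L)
  # all matches against a brute-force occurrence scan
  brute <- 0L
  kma <- oracle_kmers(s, k); kmb <- oracle_kmers(s2, k)
  for (p in 170:230) brute <- brute + sum(kmb == kma[p + 1])
  expect_equal(sum(a1$len), brute)
})

test_that("anchors report every diagonal for repeated (k+1)-mers", {
  k <- 4
  core <- repeat_free_seq(60, k, seed = 71)
  dup <- substr(core, 20, 32)
  sb <- paste0(core, random_seq(15), dup, random_seq(15))
  ga <- genome("a", core); gb <- genome("b", sb)
  gr <- build_graph(list(a = ga, b = gb), k)
  an <- find_alignment_anchors(gr, "a", 19 + k, 31, "b")
  expect_gte(nrow(an), 2)  # the original diagonal and the duplicate
  expect_equal(length(unique((an$x_lo - an$i_lo) %% gb$length)), nrow(an))
})

test_that("chaining selects the higher-coverage diagonal and extends", {
  k <- 6
  s <- repeat_free_seq(400, k, seed = 81)
  s2 <- s
  substr(s2, 200, 200) <- setdiff(c("A", "C", "G", "T"),
                                  substr(s, 200, 200))[1]
  gr <- build_graph(list(a = genome("a", s), b = genome("b", s2)), k)
  cfg <- dislocation_config(k = k)
  an <- find_alignment_anchors(gr, "a", 170, 230, "b")
  res <- chain_and_extend(an, gr, "a", 170, 230, "b", cfg)
  expect_false(is.null(res))
  expect_equal(res$o_fp[2], res$x_fp[2])  # same length, gapless homologs
  expect_gte(res$o_fp[2], 55)
  # no anchors -> none
  none <- find_alignment_anchors(gr, "a", 170, 230, "a")[0]
  expect_null(chain_and_extend(none, gr, "a", 170, 230, "b", cfg))
})

test_that("short single branches pass unconditionally (Step 6 gate)", {
  cand <- data.table::data.table(
    r_b = "r1", r_o = "r2", sb_start = 5L, sb_end = 9L, sb_len = 5L,
    a1 = 1L, a2 = 2L, alt_len = 10L, ip2b = 0L, ip2o = 0L, tp2b = 0L,
    tp2o = 0L, pa1_end = 1L, pa2_start = 2L, branch_total = 10L,
    interior = 10L, lf_xs = 0L, lf_xl = 0L, lf_os = 0L, lf_ol = 0L,
    rf_xs = 0L, rf_xl = 0L, rf_os = 0L, rf_ol = 0L)
  out <- check_single_branch(cand, toy_graph, toy_cfg)
  expect_equal(nrow(out), 1)
})

test_that("shifted-candidate clustering keeps the shortest branches", {
  rho <- toy_cfg$rho
  mk <- function(start, len, a1, a2, total) data.table::data.table(
    r_b = "r1", r_o = "r2", sb_start = start, sb_end = start + len - 1L,
    sb_len = len, a1 = a1, a2 = a2, alt_len = 100L, ip2b = 0L, ip2o = 0L,
    tp2b = 0L, tp2o = 0L, pa1_end = a1, pa2_start = a2,
    branch_total = total, interior = 50L)
  # correct bulge B and shifted B' within rho at both ends
  cands <- rbind(mk(100L, 5L, 10L, 60L, 15L),
                 mk(130L, 40L, 12L, 62L, 60L))
  out <- remove_shifted(cands, toy_graph, toy_cfg)
  expect_equal(nrow(out), 1)
  expect_equal(out$sb_start, 100L)
  # candidates pairwise farther than rho survive untouched
  far <- rbind(mk(0L, 5L, 10L, 60L, 15L),
               mk(200L, 5L, 150L, 250L, 15L))
  expect_equal(nrow(remove_shifted(far, toy_graph, toy_cfg)), 2)
  # 3-candidate chain with distances (rho-1, rho-1, 2rho-2) splits exactly
  # as the reference complete-linkage clustering does
  chain <- rbind(mk(0L, 5L, 10L, 60L, 15L),
                 mk(0L + rho - 1L, 5L, 10L, 60L, 16L),
                 mk(0L + 2L * (rho - 1L), 5L, 10L, 60L, 17L))
  L <- toy$r1$length
  d <- outer(chain$sb_start, chain$sb_start,
             function(p, q) pmin(abs(p - q), L - abs(p - q)))
  lab <- oracle_complete_linkage(pmax(d, 0), toy_cfg$rho)
  out3 <- remove_shifted(chain, toy_graph, toy_cfg)
  expect_equal(nrow(out3), length(unique(lab)))
})

test_that("the full detector reproduces the toy's eight breakpoint bulges", {
  preds <- detect_dislocations(list(r1 = toy$r1, r2 = toy$r2), toy_cfg)
  expect_equal(nrow(preds), 8)
  expect_equal(nrow(preds[r_b == "r1"]), 4)
  expect_equal(nrow(preds[r_b == "r2"]), 4)
  # junctions sit at multiples of the gene length
  truth_pos <- c(0, 80, 160, 240)
  for (i in seq_len(nrow(preds))) {
    L <- 320
    dist <- min(abs(outer(c(preds$break_start[i] + toy_cfg$k), truth_pos,
                          function(a, b) pmin(abs(a - b), L - abs(a - b)))))
    expect_lte(dist, toy_cfg$k + 2)
  }
  # identical genomes produce nothing
  same <- list(x = genome("x", toy$r1$seq), y = genome("y", toy$r1$seq))
  expect_equal(nrow(detect_dislocations(same, toy_cfg)), 0)
})

test_that("candidate funnel is monotone across steps 2-7", {
  preds <- detect_dislocations(list(r1 = toy$r1, r2 = toy$r2), toy_cfg)
  fun <- attr(preds, "funnel")
  counts <- fun[grepl("^step", step)]$n
  expect_true(all(diff(counts) <= 0))
})

test_that("a noise-free single-gene transposition gives 6 exact breakpoints", {
  fx <- noise_free_move_pair()
  genomes <- list(ga = fx$ga, gb = fx$gb)
  preds <- detect_dislocations(genomes)
  k <- attr(preds, "k")
  truth <- true_breakpoints(gene_order(fx$ann_a), gene_order(fx$ann_b),
                            fx$ann_a, fx$ann_b, names = c("ga", "gb"),
                            lens = c(fx$ga$length, fx$gb$length))
  expect_equal(nrow(truth), 6)
  expect_equal(nrow(preds), 6)
  expect_equal(nrow(preds[r_b == "ga"]), nrow(preds[r_b == "gb"]))
  for (ids in list(c("ga", "gb"), c("gb", "ga"))) {
    rep <- match_predictions(preds[r_b == ids[1] & r_o == ids[2]],
                             truth[r_b == ids[1] & r_o == ids[2]],
                             genomes[[ids[1]]]$length,
                             genomes[[ids[2]]]$length)
    expect_equal(nrow(rep$pairs), rep$n_true)
    expect_true(all(rep$pairs$distance <= k))
  }
})

test_that("entangled closure holds on the noise-free toy output", {
  preds <- detect_dislocations(list(r1 = toy$r1, r2 = toy$r2), toy_cfg)
  # every predicted breakpoint's entangled partners are also predicted:
  # with 4 breakpoints per direction covering all junctions, closure means
  # each direction's association positions appear as break positions of the
  # other direction (within k)
  k <- toy_cfg$k
  for (dir in list(c("r1", "r2"), c("r2", "r1"))) {
    fwd <- preds[r_b == dir[1]]
    rev <- preds[r_b == dir[2]]
    for (i in seq_len(nrow(fwd))) {
      d1 <- min(pmin(abs(rev$break_start + k - fwd$other_left[i]),
                     320 - abs(rev$break_start + k - fwd$other_left[i])))
      expect_lte(d1, 2 * k)
    }
  }
})
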