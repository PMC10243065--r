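test_that("the parental genome has the canonical composition", {
  par <- make_parental(1)
  ann <- par$annotations
  expect_equal(nrow(ann), 37)
  expect_equal(sum(ann$category == "protein"), 13)
  expect_equal(sum(ann$category == "tRNA"), 22)
  expect_equal(sum(ann$category == "rRNA"), 2)
  expect_false(anyDuplicated(ann$gene) > 0)
  # genes tile without overlap
  ord <- ann[order(ann$start), ]
  expect_true(all(ord$start[-1] >= ord$end[-nrow(ord)]))
  expect_lte(max(ord$end), par$genome$length)
  # deterministic under the seed
  par2 <- make_parental(1)
  expect_identical(par2$genome$seq, par$genome$seq)
  expect_identical(par2$annotations, par$annotations)
  # graph stays usable at the default k
  expect_lte(auto_k(list(par$genome)), 12)
})

test_that("HKY evolution recovers its rate and ti/tv parameters", {
  par <- make_parental(2)
  s <- par$genome$seq
  expect_identical(evolve_hky(s, 0, seed = 1), s)
  m <- evolve_hky(s, 5, seed = 3)
  a <- strsplit(s, "")[[1]]; b <- strsplit(m, "")[[1]]
  frac <- mean(a != b)
  se <- sqrt(0.05 * 0.95 / nchar(s))
  expect_lt(abs(frac - 0.05), 3 * se)
  ti <- c(A = "G", G = "A", C = "T", T = "C")
  sub <- which(a != b)
  n_ti <- sum(ti[a[sub]] == b[sub])
  ratio <- n_ti / (length(sub) - n_ti)
  expect_gt(ratio, 2.2)
  expect_lt(ratio, 4.0)
})

test_that("dislocations preserve gene content and change the order", {
  par <- make_parental(3)
  g <- par$genome; ann <- par$annotations
  id0 <- apply_dislocations(g, ann, 0L, seed = 1)
  expect_identical(gene_order(id0$annotations), gene_order(ann))
  expect_identical(id0$genome$seq, g$seq)
  for (seed in 1:3) {
    mv <- apply_dislocations(g, ann, 1L, seed = seed)
    o1 <- gene_order(ann); o2 <- gene_order(mv$annotations)
    expect_setequal(o1, o2)
    expect_equal(mv$genome$length, g$length)
    # order differs by exactly one gene move: removing some gene makes the
    # circular orders identical, and they differ before removal
    rot_eq <- function(x, y) {
      if (length(x) != length(y)) return(FALSE)
      any(vapply(seq_along(y), function(r)
        identical(x, y[((seq_along(y) + r - 2) %% length(y)) + 1]), TRUE))
    }
    expect_false(rot_eq(o1, o2))
    fixable <- vapply(unique(o1), function(gn)
      rot_eq(o1[o1 != gn], o2[o2 != gn]), TRUE)
    expect_true(any(fixable))
    # every gene's sequence is conserved
    s1 <- setNames(substring(g$seq, ann$start + 1, ann$end), ann$gene)
    a2 <- mv$annotations
    s2 <- setNames(substring(mv$genome$seq, a2$start + 1, a2$end), a2$gene)
    expect_identical(s1[sort(names(s1))], s2[sort(names(s2))])
  }
  expect_equal(sum(nchar(apply_dislocations(g, ann, 5L, seed = 9)$genome$seq)),
               g$length)
})

test_that("inversions flip strands in place and are involutive", {
  par <- make_parental(4)
  g <- par$genome; ann <- par$annotations
  inv <- apply_inversions(g, ann, "tRNA", 2L, seed = 5)
  sel <- inv$inverted
  expect_length(sel, 2)
  a2 <- inv$annotations
  expect_true(all(a2$strand[a2$gene %in% sel] == "-"))
  expect_true(all(a2$strand[!a2$gene %in% sel] == "+"))
  # untouched segments are byte-identical
  for (i in which(!a2$gene %in% sel))
    expect_identical(substring(inv$genome$seq, a2$start[i] + 1, a2$end[i]),
                     substring(g$seq, a2$start[i] + 1, a2$end[i]))
  # inverting the same genes again restores the original sequence
  back <- inv$genome$seq
  for (gn in sel) {
    i <- match(gn, a2$gene)
    substr(back, a2$start[i] + 1, a2$end[i]) <-
      reverse_complement(substring(back, a2$start[i] + 1, a2$end[i]))
  }
  expect_identical(back, g$seq)
})

test_that("toy gene orders give exactly the eight known breakpoints", {
  tb <- true_breakpoints(c("g1", "g2", "g3", "g4"),
                         c("g1", "g4", "g3", "g2"))
  expect_equal(nrow(tb), 8)
  got <- sort(paste(tb$r_b, tb$g_i, tb$g_j))
  want <- sort(c("1 g1 g2", "1 g2 g3", "1 g3 g4", "1 g4 g1",
                 "2 g1 g4", "2 g4 g3", "2 g3 g2", "2 g2 g1"))
  expect_identical(got, want)
  expect_equal(nrow(true_breakpoints(letters[1:5], letters[1:5])), 0)
})

test_that("breakpoints equal brute force and twice the breakpoint distance", {
  set.seed(12)
  for (i in 1:15) {
    n <- sample(4:7, 1)
    o1 <- sample(letters[1:n])
    o2 <- sample(letters[1:n])
    tb <- true_breakpoints(o1, o2)
    b12 <- oracle_breakpoints_one_dir(o1, o2)
    b21 <- oracle_breakpoints_one_dir(o2, o1)
    expect_equal(nrow(tb), length(b12) + length(b21))
    expect_equal(length(b12), length(b21))  # duplicate-free symmetry
    expect_equal(nrow(tb), 2 * length(b12))
    got12 <- tb[tb$r_b == "1", ]
    expect_setequal(paste(got12$g_i, got12$g_j),
                    vapply(b12, paste, "", collapse = " "))
  }
})

test_that("entangled breakpoints follow the successor/predecessor rule", {
  o1 <- c("g1", "g2", "g3", "g4"); o2 <- c("g1", "g4", "g3", "g2")
  ent <- entangled("g1", "g2", o1, o2)
  expect_identical(ent[[1]], c("g1", "g4"))
  expect_identical(ent[[2]], c("g3", "g2"))
  # closure: both partners are breakpoints of the opposite direction
  tb21 <- true_breakpoints(o2, o1)
  keys <- paste(tb21[tb21$r_b == "1", ]$g_i, tb21[tb21$r_b == "1", ]$g_j)
  expect_true(all(c("g1 g4", "g3 g2") %in% keys))
  expect_error(entangled("g1", "g3", o1, o2), "not adjacent")
  # random orders against brute-force successor/predecessor lookup
  set.seed(13)
  for (i in 1:10) {
    n <- sample(4:7, 1)
    p1 <- sample(letters[1:n]); p2 <- sample(letters[1:n])
    bps <- oracle_breakpoints_one_dir(p1, p2)
    for (bp in bps) {
      e <- entangled(bp[1], bp[2], p1, p2)
      i1 <- match(bp[1], p2); i2 <- match(bp[2], p2)
      expect_identical(e[[1]][2], p2[i1 %% n + 1])
      expect_identical(e[[2]][1], p2[(i2 - 2) %% n + 1])
    }
  }
})

test_that("benchmark sets are self-consistent", {
  set0 <- make_dislocation_benchmark(0, 0, n_children = 2, seed = 7)
  expect_identical(set0$children[[1]]$seq, set0$parent$genome$seq)
  expect_equal(nrow(set0$truth), 0)
  set1 <- make_dislocation_benchmark(1, 3, n_children = 3, seed = 8)
  expect_equal(length(set1$children), 3)
  # truth recomputable from the emitted annotations alone
  ann <- set1$annotations
  ids <- names(set1$children)
  re <- data.table::rbindlist(lapply(1:2, function(i)
    lapply((i + 1):3, function(j) {
      ai <- ann[ann$genome_id == ids[i], ]; aj <- ann[ann$genome_id == ids[j], ]
      true_breakpoints(gene_order(ai), gene_order(aj), ai, aj,
                       names = c(ids[i], ids[j]),
                       lens = c(set1$children[[i]]$length,
                                set1$children[[j]]$length))
    })[[1]]))
  sub <- set1$truth[set1$truth$r_b %in% ids[1:3] & set1$truth$r_o %in% ids[1:3]]
  expect_equal(nrow(set1$truth),
               nrow(unique(set1$truth)))
})

test_that("the inversion benchmark always carries eight true blocks", {
  for (seed in c(1, 5)) {
    set <- make_inversion_benchmark(1, seed = seed)
    expect_equal(nrow(set$truth), 8)
    expect_equal(nrow(set$truth[genome_a == "invA" & genome_b == "invC"]), 2)
    expect_equal(nrow(set$truth[genome_a == "invB" & genome_b == "invC"]), 2)
    expect_equal(nrow(set$truth[genome_a == "invA" & genome_b == "invB"]), 4)
  }
  # at zero substitution rate the paired segments are exact reverse
  # complements wherever exactly one side is inverted
  set0 <- make_inversion_benchmark(0, seed = 2)
  tr <- set0$truth
  for (i in seq_len(nrow(tr))) {
    if (tr$a_strand[i] == tr$b_strand[i]) next
    sa <- substring(set0$children[[tr$genome_a[i]]]$seq,
                    tr$a_start[i] + 1, tr$a_end[i])
    sb <- substring(set0$children[[tr$genome_b[i]]]$seq,
                    tr$b_start[i] + 1, tr$b_end[i])
    expect_identical(sa, reverse_complement(sb))
  }
})
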