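# Shared fixtures and independent oracles.  Oracles are deliberately
# written as plain loops, independent of the package's code paths.

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random sequence whose circular (k+1)-mers are all distinct, built
# greedily (base by base, avoiding any previously used (k+1)-mer).
repeat_free_seq <- function(n, k, seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  for (attempt in 1:50) {
    chars <- sample(bases, k + 1, replace = TRUE)
    seen <- new.env(parent = emptyenv())
    assign(paste(chars, collapse = ""), TRUE, envir = seen)
    ok <- TRUE
    while (length(chars) < n && ok) {
      ok <- FALSE
      for (b in sample(bases)) {
        km <- paste(c(tail(chars, k), b), collapse = "")
        if (is.null(seen[[km]])) {
          chars <- c(chars, b)
          seen[[km]] <- TRUE
          ok <- TRUE
          break
        }
      }
    }
    if (!ok) next
    s <- paste(chars, collapse = "")
    if (!anyDuplicated(oracle_kmers(s, k))) return(s)  # check wrap k-mers
  }
  stop("could not build repeat-free sequence")
}

# Independent circular (k+1)-mer enumeration (loop on the doubled string).
oracle_kmers <- function(s, k) {
  L <- nchar(s)
  dd <- paste0(s, s)
  out <- character(L)
  for (p in 0:(L - 1)) {
    st <- (p - k) %% L
    out[p + 1] <- substr(dd, st + 1, st + k + 1)
  }
  out
}

# Fig-1-style toy: four unique genes, orders (g1,g2,g3,g4) vs
# (g1,g4,g3,g2); regenerated until each genome is repeat-free at k.
toy_gene_pair <- function(k = 7, gene_len = 80, seed = 11) {
  set.seed(seed)
  for (i in 1:100) {
    genes <- lapply(setNames(1:4, paste0("g", 1:4)), function(i)
      paste(sample(c("A", "C", "G", "T"), gene_len, TRUE), collapse = ""))
    r1 <- genome("r1", paste(unlist(genes[c("g1", "g2", "g3", "g4")]),
                             collapse = ""))
    r2 <- genome("r2", paste(unlist(genes[c("g1", "g4", "g3", "g2")]),
                             collapse = ""))
    if (!anyDuplicated(oracle_kmers(r1$seq, k)) &&
        !anyDuplicated(oracle_kmers(r2$seq, k)))
      return(list(r1 = r1, r2 = r2, genes = genes, gene_len = gene_len))
  }
  stop("no repeat-free toy")
}

# Fixture with an isolated substitution and an isolated deletion in a
# locally repeat-free context: every (k+1)-mer spanning the variant must
# occur exactly once across both genomes, so the unmatched-edge counts
# are exactly those of a clean inconsistency bulge.
isolated_variant_fixture <- function(k = 3, L = 60, seed = 1) {
  spanning_unique <- function(s_a, s_b, ends_a, ends_b) {
    ka <- oracle_kmers(s_a, k); kb <- oracle_kmers(s_b, k)
    span <- unique(c(ka[ends_a + 1], kb[ends_b + 1]))
    cnt <- table(c(ka, kb))
    all(cnt[span] == 1)
  }
  for (try in 0:200) {
    s <- repeat_free_seq(L, k, seed + 1000 * try)
    m <- L %/% 2  # 1-based substitution position
    s_snp <- s
    substr(s_snp, m, m) <- setdiff(c("A", "C", "G", "T"),
                                   substr(s, m, m))[1]
    s_del <- paste0(substr(s, 1, m - 1), substr(s, m + 1, L))
    m0 <- m - 1  # 0-based
    ok_snp <- !anyDuplicated(oracle_kmers(s_snp, k)) &&
      spanning_unique(s, s_snp, m0:(m0 + k), m0:(m0 + k))
    ok_del <- !anyDuplicated(oracle_kmers(s_del, k)) &&
      spanning_unique(s, s_del, m0:(m0 + k), m0:(m0 + k - 1))
    if (ok_snp && ok_del)
      return(list(ref = s, snp = s_snp, del = s_del, k = k))
  }
  stop("no isolated-variant fixture found")
}

# Unbanded Smith-Waterman with affine gaps, plain-R reference.
oracle_local_align <- function(s1, s2, match = 2, mismatch = -3,
                               gap_open = 5, gap_extend = 2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                   E[i, j - 1] - gap_extend)
    F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                   F[i - 1, j] - gap_extend)
    sub <- if (a[i - 1] == b[j - 1]) match else mismatch
    H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# Complete-linkage agglomerative clustering, plain-R reference.
# Returns cluster labels after refusing merges above height h.
oracle_complete_linkage <- function(d, h) {
  n <- nrow(d)
  cl <- as.list(seq_len(n))
  repeat {
    best <- Inf; bi <- 0; bj <- 0
    if (length(cl) > 1) {
      for (i in 1:(length(cl) - 1)) for (j in (i + 1):length(cl)) {
        lk <- max(d[cl[[i]], cl[[j]]])
        if (lk < best) { best <- lk; bi <- i; bj <- j }
      }
    }
    if (!is.finite(best) || best > h) break
    cl[[bi]] <- c(cl[[bi]], cl[[bj]])
    cl[[bj]] <- NULL
  }
  lab <- integer(n)
  for (i in seq_along(cl)) lab[cl[[i]]] <- i
  lab
}

# Brute-force dislocation breakpoints: adjacencies of o1 (circular) whose
# gene pair is not an adjacency of o2.
oracle_breakpoints_one_dir <- function(o1, o2) {
  n1 <- length(o1); n2 <- length(o2)
  adj2 <- paste(o2, o2[c(2:n2, 1)])
  out <- list()
  for (i in seq_len(n1)) {
    gi <- o1[i]; gj <- o1[i %% n1 + 1]
    if (gi %in% o2 && gj %in% o2 && !(paste(gi, gj) %in% adj2))
      out[[length(out) + 1]] <- c(gi, gj)
  }
  out
}

# Cached mid-size fixtures (built once per test run).
.fixture_env <- new.env()

noise_free_move_pair <- function() {
  if (is.null(.fixture_env$nfmp)) {
    par <- make_parental(21, mito_composition(spacer_len = c(0L, 0L)))
    a1 <- par$annotations; a1$genome_id <- "ga"
    ga <- genome("ga", par$genome$seq)
    moved <- apply_dislocations(ga, a1, 1L, seed = 22)
    gb <- genome("gb", par$genome$seq)
    a2 <- par$annotations; a2$genome_id <- "gb"
    .fixture_env$nfmp <- list(ga = moved$genome, ann_a = moved$annotations,
                              gb = gb, ann_b = a2)
  }
  .fixture_env$nfmp
}
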