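# Synthetic rearranged-mitogenome benchmark generator.
#
# A parental genome of typical metazoan composition (13 protein genes,
# 22 tRNAs, 2 rRNAs, short intergenic spacers) is evolved into children by
# per-site HKY substitutions; gene dislocations and inversions are then
# applied with exact ground truth.  Only substitutions are simulated, so
# gene boundaries -- and hence the true breakpoint locations -- are never
# shifted by the noise process.

MITO_PROTEINS <- c("nad1", "nad2", "cox1", "cox2", "atp8", "atp6", "cox3",
                   "nad3", "nad4l", "nad4", "nad5", "nad6", "cob")
MITO_TRNAS <- c("trnF", "trnV", "trnL1", "trnI", "trnQ", "trnM", "trnW",
                "trnA", "trnN", "trnC", "trnY", "trnS1", "trnD", "trnK",
                "trnG", "trnR", "trnH", "trnS2", "trnL2", "trnE", "trnT",
                "trnP")
MITO_RRNAS <- c("rrnS", "rrnL")

# Gene order loosely following the typical vertebrate arrangement; all
# genes are generated on the plus strand (inversions are introduced
# explicitly by apply_inversions()).
MITO_ORDER <- c("trnF", "rrnS", "trnV", "rrnL", "trnL1", "nad1", "trnI",
                "trnQ", "trnM", "nad2", "trnW", "trnA", "trnN", "trnC",
                "trnY", "cox1", "trnS1", "trnD", "cox2", "trnK", "atp8",
                "atp6", "cox3", "trnG", "nad3", "trnR", "nad4l", "nad4",
                "trnH", "trnS2", "trnL2", "nad5", "nad6", "trnE", "cob",
                "trnT", "trnP")

#' Composition of the simulated parental mitogenome
#'
#' Defaults give a ~16 kb genome: 13 protein genes of 300-1500 nt,
#' 22 tRNAs of 65-75 nt, rRNAs of 950 and 1600 nt, and intergenic spacers
#' of 0-20 nt.
#'
#' @param protein_len,trna_len Length ranges (nt) sampled uniformly.
#' @param rrna_len Lengths of the two rRNAs.
#' @param spacer_len Intergenic spacer length range; set to `c(0, 0)` for
#'   genomes with directly abutting genes.
#' @return List of composition settings.
#' @export
mito_composition <- function(protein_len = c(300L, 1500L),
                             trna_len = c(65L, 75L),
                             rrna_len = c(950L, 1600L),
                             spacer_len = c(0L, 20L)) {
  list(protein_len = protein_len, trna_len = trna_len,
       rrna_len = rrna_len, spacer_len = spacer_len)
}

random_dna <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Internal segment representation: alternating gene and spacer rows
# (one spacer after every gene, possibly of length 0), circular order.
new_segments <- function(ann_names, categories, strands, gene_seqs,
                         spacer_seqs) {
  data.table(
    name = as.vector(rbind(ann_names, paste0("spacer", seq_along(ann_names)))),
    type = rep(c("gene", "spacer"), length(ann_names)),
    category = as.vector(rbind(categories, "")),
    strand = as.vector(rbind(strands, "+")),
    seq = as.vector(rbind(gene_seqs, spacer_seqs)))
}

segments_to_genome <- function(segs, id, topology = "circular") {
  lens <- nchar(segs$seq)
  starts <- cumsum(c(0L, head(lens, -1L)))
  gk <- segs$type == "gene"
  ann <- data.frame(genome_id = id, gene = segs$name[gk],
                    category = segs$category[gk],
                    start = starts[gk], end = starts[gk] + lens[gk],
                    strand = segs$strand[gk], stringsAsFactors = FALSE)
  g <- genome(id, paste(segs$seq, collapse = ""), topology)
  list(genome = g, annotations = ann)
}

# Rebuild the segment representation from a genome + annotation table.
annotations_to_segments <- function(g, ann) {
  ann <- ann[order(ann$start), , drop = FALSE]
  n <- nrow(ann)
  gene_seqs <- substring(g$seq, ann$start + 1L, ann$end)
  sp_start <- ann$end
  sp_end <- c(ann$start[-1L], g$length)
  spacer_seqs <- substring(g$seq, sp_start + 1L, sp_end)
  spacer_seqs[sp_start >= sp_end] <- ""
  if (ann$start[1L] > 0L)  # leading spacer folds onto the final one
    spacer_seqs[n] <- paste0(spacer_seqs[n], substr(g$seq, 1L, ann$start[1L]))
  new_segments(ann$gene, ann$category, ann$strand, gene_seqs, spacer_seqs)
}

#' Generate a parental mitogenome
#'
#' @param seed RNG seed.
#' @param composition [mito_composition()].
#' @return List with `genome` (a circular [genome()]) and `annotations`
#'   (data.frame with `genome_id`, `gene`, `category`, `start`, `end`,
#'   `strand`; genes tile the genome without overlap).
#' @export
make_parental <- function(seed = 1L, composition = mito_composition()) {
  for (attempt in 0:9) {
    res <- with_seed(seed + attempt * 1000L, {
      lens <- integer(length(MITO_ORDER))
      cats <- character(length(MITO_ORDER))
      for (i in seq_along(MITO_ORDER)) {
        nm <- MITO_ORDER[i]
        if (nm %in% MITO_PROTEINS) {
          lens[i] <- sample(composition$protein_len[1]:composition$protein_len[2], 1L)
          cats[i] <- "protein"
        } else if (nm %in% MITO_TRNAS) {
          lens[i] <- sample(composition$trna_len[1]:composition$trna_len[2], 1L)
          cats[i] <- "tRNA"
        } else {
          lens[i] <- composition$rrna_len[match(nm, MITO_RRNAS)]
          cats[i] <- "rRNA"
        }
      }
      sp <- composition$spacer_len
      sp_lens <- if (sp[2] > sp[1]) sample(sp[1]:sp[2], length(lens),
                                           replace = TRUE)
                 else rep(sp[1], length(lens))
      gene_seqs <- vapply(lens, random_dna, "")
      spacer_seqs <- vapply(sp_lens, random_dna, "")
      segs <- new_segments(MITO_ORDER, cats, rep("+", length(lens)),
                           gene_seqs, spacer_seqs)
      segments_to_genome(segs, "parent")
    })
    # keep the graph usable at the default k
    ok <- tryCatch(auto_k(list(res$genome), k_min = 10L, k_max = 12L) <= 12L,
                   error = function(e) FALSE)
    if (ok) return(res)
  }
  stop("could not generate a low-repeat parental genome")  # nocov
}

#' Apply HKY nucleotide substitutions
#'
#' Per-site substitution with probability `r_sub / 100` (so `r_sub` is the
#' expected number of substitutions per 100 sites on this branch) and a
#' transition:transversion count ratio of `titv` under equal base
#' frequencies.  Length is always preserved: the generator introduces no
#' indels, so gene boundaries stay exact.
#'
#' @param seq Nucleotide string.
#' @param r_sub Substitution rate per 100 sites (>= 0).
#' @param titv Expected transition/transversion count ratio (default 3).
#' @param seed RNG seed (`NULL` to use the current RNG state).
#' @return Mutated string of the same length.
#' @export
evolve_hky <- function(seq, r_sub, titv = 3.0, seed = NULL) {
  stopifnot(r_sub >= 0)
  with_seed(seed, {
    n <- nchar(seq)
    hit <- which(runif(n) < r_sub / 100)
    if (length(hit) == 0L) return(seq)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    transversions <- list(A = c("C", "T"), G = c("C", "T"),
                          C = c("A", "G"), T = c("A", "G"))
    is_ti <- runif(length(hit)) < titv / (titv + 1)
    for (i in seq_along(hit)) {
      b <- chars[hit[i]]
      chars[hit[i]] <- if (is_ti[i]) transition[[b]]
                       else sample(transversions[[b]], 1L)
    }
    paste(chars, collapse = "")
  })
}

#' Apply random gene dislocations
#'
#' Repeats `n_ra` times: pick a gene uniformly, excise its encoding
#' segment, and reinsert it at a position chosen uniformly among all
#' intergenic insertion slots outside the gene's original (merged) spacer
#' -- so every move changes the gene order.  Gene content and all gene
#' sequences are preserved.
#'
#' @param g A [genome()].
#' @param ann Its annotation data.frame (genes tiling with spacers).
#' @param n_ra Number of dislocations.
#' @param seed RNG seed.
#' @return List with updated `genome` and `annotations`.
#' @export
apply_dislocations <- function(g, ann, n_ra, seed = NULL) {
  with_seed(seed, {
    segs <- normalize_segments(annotations_to_segments(g, ann))
    for (r in seq_len(n_ra)) {
      # rows alternate gene (odd), spacer (even) after normalization
      gene_rows <- which(segs$type == "gene")
      i <- gene_rows[sample(length(gene_rows), 1L)]
      gene_row <- segs[i]
      if (i == 1L) {
        # the wrapping spacer (last row) absorbs the following one (row 2)
        segs$seq[nrow(segs)] <- paste0(segs$seq[nrow(segs)], segs$seq[2L])
        segs <- segs[-c(1L, 2L)]
        blocked <- nrow(segs)
      } else {
        segs$seq[i - 1L] <- paste0(segs$seq[i - 1L], segs$seq[i + 1L])
        segs <- segs[-c(i, i + 1L)]
        blocked <- i - 1L
      }
      sp_idx <- setdiff(which(segs$type == "spacer"), blocked)
      if (length(sp_idx) == 0L) stop("no intergenic position available")
      slots <- nchar(segs$seq[sp_idx]) + 1L  # insertion slots per spacer
      slot <- sample(sum(slots), 1L)
      cs <- cumsum(slots)
      j <- which(slot <= cs)[1L]
      target <- sp_idx[j]
      offset <- slot - c(0L, cs)[j] - 1L  # 0..len within the spacer
      left <- substr(segs$seq[target], 1L, offset)
      right <- substr(segs$seq[target], offset + 1L, nchar(segs$seq[target]))
      before <- segs[seq_len(target - 1L)]
      after <- if (target < nrow(segs)) segs[(target + 1L):nrow(segs)]
               else segs[0L]
      mid <- data.table(
        name = c("spacerL", gene_row$name, "spacerR"),
        type = c("spacer", "gene", "spacer"),
        category = c("", gene_row$category, ""),
        strand = c("+", gene_row$strand, "+"),
        seq = c(left, gene_row$seq, right))
      segs <- normalize_segments(rbind(before, mid, after))
    }
    segments_to_genome(segs, g$id)
  })
}

# Merge runs of adjacent spacers (circularly) and rename them; ensure the
# table alternates gene, spacer, gene, spacer, ...
normalize_segments <- function(segs) {
  # rotate so the table starts with a gene
  first_gene <- which(segs$type == "gene")[1L]
  if (first_gene > 1L)
    segs <- rbind(segs[first_gene:nrow(segs)], segs[1:(first_gene - 1L)])
  out <- vector("list", sum(segs$type == "gene") * 2L)
  oi <- 0L
  i <- 1L
  n <- nrow(segs)
  while (i <= n) {
    stopifnot(segs$type[i] == "gene")
    oi <- oi + 1L
    out[[oi]] <- segs[i]
    i <- i + 1L
    sp <- ""
    while (i <= n && segs$type[i] == "spacer") {
      sp <- paste0(sp, segs$seq[i])
      i <- i + 1L
    }
    oi <- oi + 1L
    out[[oi]] <- data.table(name = paste0("spacer", oi %/% 2L),
                            type = "spacer", category = "", strand = "+",
                            seq = sp)
  }
  rbindlist(out[seq_len(oi)])
}

#' Apply gene inversions
#'
#' Replaces each selected gene's encoding segment by its reverse complement
#' in place and flips the annotation strand.  Selected genes are pairwise
#' non-adjacent in the gene order, so each inversion yields one separate
#' inverted block.
#'
#' @param g A [genome()].
#' @param ann Its annotations.
#' @param category Gene category to draw from (`"tRNA"`, `"protein"`,
#'   `"rRNA"`), or `NULL` for any.
#' @param n_inv Number of genes to invert.
#' @param seed RNG seed.
#' @return List with updated `genome`, `annotations`, and `inverted` (the
#'   gene names inverted).
#' @export
apply_inversions <- function(g, ann, category = NULL, n_inv = 2L,
                             seed = NULL) {
  with_seed(seed, {
    ord <- ann[order(ann$start), , drop = FALSE]
    pool <- if (is.null(category)) seq_len(nrow(ord))
            else which(ord$category == category)
    if (length(pool) < n_inv) stop("not enough genes of category ", category)
    for (try in 1:100) {
      sel <- sort(sample(pool, n_inv))
      adj <- any(diff(sel) == 1L) ||
        (1L %in% sel && nrow(ord) %in% sel && n_inv > 1L)
      if (!adj) break
      if (try == 100) stop("cannot select pairwise non-adjacent genes")
    }
    seq <- g$seq
    for (i in sel) {
      sub <- substr(seq, ord$start[i] + 1L, ord$end[i])
      substr(seq, ord$start[i] + 1L, ord$end[i]) <- reverse_complement(sub)
      ord$strand[i] <- if (ord$strand[i] == "+") "-" else "+"
    }
    list(genome = genome(g$id, seq, g$topology), annotations = ord,
         inverted = ord$gene[sel])
  })
}

#' Gene order of an annotation table
#'
#' @param ann Annotation data.frame of one genome.
#' @return Character vector of gene names in genomic order.
#' @export
gene_order <- function(ann) ann$gene[order(ann$start)]

#' Enumerate true dislocation breakpoints between two gene orders
#'
#' An adjacent gene pair `(g_i, g_j)` of one circular order is a
#' dislocation breakpoint with respect to the other order if both genes
#' occur there but not consecutively in that order.  Both directions are
#' enumerated; for duplicate-free orders the total count is twice the
#' classical breakpoint distance.
#'
#' @param order1,order2 Character vectors of gene names (circular orders).
#' @param ann1,ann2 Optional annotation data.frames; when given, nucleotide
#'   locations are attached: `pos_b` (midpoint of the intergenic gap
#'   between `g_i` and `g_j` in the breakpoint genome), `pos_o_left` (end
#'   of `g_i` in the other genome) and `pos_o_right` (start of `g_j`).
#' @param names Labels for the two genomes (defaults `"1"`, `"2"`).
#' @param lens Optional genome lengths (needed for midpoints when
#'   annotations are given); taken from the annotation span otherwise.
#' @return `data.table` with columns `r_b`, `r_o`, `g_i`, `g_j` and, with
#'   annotations, `pos_b`, `pos_o_left`, `pos_o_right`.
#' @export
true_breakpoints <- function(order1, order2, ann1 = NULL, ann2 = NULL,
                             names = c("1", "2"), lens = NULL) {
  if (anyDuplicated(order1) || anyDuplicated(order2))
    stop("duplicate gene names are not supported")
  one_dir <- function(ob, oo, nb, no, annb, anno, Lb, Lo) {
    nb_genes <- length(ob)
    gi <- ob
    gj <- ob[c(2:nb_genes, 1L)]
    keep <- gi %in% oo & gj %in% oo
    succ_o <- setNames(oo[c(2:length(oo), 1L)], oo)
    broken <- keep & (succ_o[gi] != gj)
    res <- data.table(r_b = nb, r_o = no, g_i = gi[broken], g_j = gj[broken])
    if (!is.null(annb) && nrow(res) > 0L) {
      sb <- setNames(annb$start, annb$gene); eb <- setNames(annb$end, annb$gene)
      so <- setNames(anno$start, anno$gene); eo <- setNames(anno$end, anno$gene)
      ctx <- pos_context(Lb)
      gap <- forward_distance(eb[res$g_i] %% Lb, sb[res$g_j] %% Lb, ctx)
      res[, pos_b := succ(eb[res$g_i] %% Lb, gap %/% 2L, ctx)]
      res[, c("pos_o_left", "pos_o_right") :=
            .(unname(eo[res$g_i] %% Lo), unname(so[res$g_j] %% Lo))]
    }
    res
  }
  Lb <- Lo <- NULL
  if (!is.null(ann1)) {
    Lb <- if (!is.null(lens)) lens[1] else max(ann1$end)
    Lo <- if (!is.null(lens)) lens[2] else max(ann2$end)
  }
  rbind(one_dir(order1, order2, names[1], names[2], ann1, ann2, Lb, Lo),
        one_dir(order2, order1, names[2], names[1], ann2, ann1, Lo, Lb),
        fill = TRUE)
}

#' Entangled breakpoints of a dislocation breakpoint
#'
#' A breakpoint `(g_i, g_j)` of order 1 with respect to order 2 is always
#' accompanied by the two breakpoints `(g_i, g_m)` and `(g_n, g_j)` of
#' order 2 with respect to order 1, where `g_m` succeeds `g_i` and `g_n`
#' precedes `g_j` in order 2.
#'
#' @param g_i,g_j The breakpoint gene pair (adjacent in `order1`).
#' @param order1,order2 Circular gene orders.
#' @return List of two character pairs, `c(g_i, g_m)` and `c(g_n, g_j)`.
#' @export
entangled <- function(g_i, g_j, order1, order2) {
  n1 <- length(order1); n2 <- length(order2)
  i <- match(g_i, order1)
  if (is.na(i) || order1[i %% n1 + 1L] != g_j)
    stop("(", g_i, ",", g_j, ") is not adjacent in order1")
  j <- match(g_i, order2); jj <- match(g_j, order2)
  if (is.na(j) || is.na(jj)) stop("genes missing from order2")
  g_m <- order2[j %% n2 + 1L]
  g_n <- order2[(jj - 2L) %% n2 + 1L]
  if (g_m == g_j) stop("(", g_i, ",", g_j, ") is not a breakpoint")
  list(c(g_i, g_m), c(g_n, g_j))
}

#' Generate a dislocation benchmark set
#'
#' A parental genome is evolved into `n_children` HKY children at rate
#' `r_sub`; each child then receives `n_ra` random gene dislocations.
#' Ground-truth breakpoint tables are computed for every ordered pair of
#' children.
#'
#' @param r_sub Substitution rate per 100 sites.
#' @param n_ra Dislocations per child.
#' @param n_children Number of children (the paper-scale default is 10).
#' @param seed RNG seed.
#' @param composition [mito_composition()].
#' @return Object of class `simulated_set`: `parent` (genome +
#'   annotations), `children` (named list of genomes), `annotations`
#'   (combined data.frame), `truth` (breakpoint `data.table`), `params`.
#' @export
make_dislocation_benchmark <- function(r_sub, n_ra, n_children = 10L,
                                       seed = 1L,
                                       composition = mito_composition()) {
  par <- make_parental(seed, composition)
  ids <- sprintf("child%02d", seq_len(n_children))
  children <- vector("list", n_children); names(children) <- ids
  anns <- vector("list", n_children)
  for (i in seq_len(n_children)) {
    mseq <- evolve_hky(par$genome$seq, r_sub, seed = seed + 7919L * i)
    gm <- genome(ids[i], mseq, "circular")
    ann <- par$annotations; ann$genome_id <- ids[i]
    moved <- apply_dislocations(gm, ann, n_ra, seed = seed + 104729L * i)
    children[[i]] <- moved$genome
    anns[[i]] <- moved$annotations
  }
  names(anns) <- ids
  truth <- rbindlist(lapply(seq_len(n_children), function(i) {
    rbindlist(lapply(seq_len(n_children), function(j) {
      if (i >= j) return(NULL)
      true_breakpoints(gene_order(anns[[i]]), gene_order(anns[[j]]),
                       anns[[i]], anns[[j]], names = c(ids[i], ids[j]),
                       lens = c(children[[i]]$length, children[[j]]$length))
    }))
  }))
  structure(list(parent = par, children = children,
                 annotations = do.call(rbind, anns), truth = truth,
                 params = list(r_sub = r_sub, n_ra = n_ra,
                               n_children = n_children, seed = seed,
                               titv = 3.0)),
            class = "simulated_set")
}

#' Generate an inversion benchmark subset
#'
#' Three HKY children of one parent: one receives two tRNA inversions, one
#' two protein inversions, one is left unaltered -- eight true inverted
#' sequence blocks (IBs) over the three genome pairs.
#'
#' @param r_sub Substitution rate per 100 sites.
#' @param seed RNG seed.
#' @param composition [mito_composition()].
#' @return Object of class `simulated_set` with `truth` holding one row per
#'   true IB (`genome_a`, `genome_b`, `gene`, intervals and strands).
#' @export
make_inversion_benchmark <- function(r_sub, seed = 1L,
                                     composition = mito_composition()) {
  par <- make_parental(seed, composition)
  ids <- c("invA", "invB", "invC")
  children <- list(); anns <- list(); inverted <- list()
  specs <- list(c("tRNA", 2L), c("protein", 2L), NULL)
  for (i in 1:3) {
    mseq <- evolve_hky(par$genome$seq, r_sub, seed = seed + 7919L * i)
    gm <- genome(ids[i], mseq, "circular")
    ann <- par$annotations; ann$genome_id <- ids[i]
    if (!is.null(specs[[i]])) {
      res <- apply_inversions(gm, ann, specs[[i]][1],
                              as.integer(specs[[i]][2]),
                              seed = seed + 104729L * i)
      gm <- res$genome; ann <- res$annotations
      inverted[[ids[i]]] <- res$inverted
    } else inverted[[ids[i]]] <- character(0)
    children[[ids[i]]] <- gm
    anns[[ids[i]]] <- ann
  }
  pairs <- list(c("invA", "invB"), c("invA", "invC"), c("invB", "invC"))
  truth <- rbindlist(lapply(pairs, function(p) {
    genes <- union(inverted[[p[1]]], inverted[[p[2]]])
    if (length(genes) == 0L) return(NULL)
    a <- anns[[p[1]]]; b <- anns[[p[2]]]
    ia <- match(genes, a$gene); ib <- match(genes, b$gene)
    data.table(genome_a = p[1], genome_b = p[2], gene = genes,
               a_start = a$start[ia], a_end = a$end[ia],
               a_strand = a$strand[ia],
               b_start = b$start[ib], b_end = b$end[ib],
               b_strand = b$strand[ib])
  }))
  structure(list(parent = par, children = children,
                 annotations = do.call(rbind, anns), truth = truth,
                 params = list(r_sub = r_sub, seed = seed, titv = 3.0)),
            class = "simulated_set")
}
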