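# Sequence and annotation input/output, plus the circular-coordinate
# arithmetic used throughout the package.
#
# Coordinate convention: all positions are 0-based; intervals are half-open
# [start, end).  BED files share this convention directly.  Circular genomes
# wrap modulo the genome length.

#' Construct a genome object
#'
#' A genome is a named nucleotide sequence with a topology.  Sequences are
#' normalized to upper-case `A`/`C`/`G`/`T`; the method is exact
#' k-mer based, so ambiguity codes must be resolved (see `ambiguity`).
#'
#' @param id Character label, unique within a genome set.
#' @param seq Nucleotide string.
#' @param topology `"circular"` (default, as for most mitogenomes) or
#'   `"linear"`.
#' @param ambiguity How to treat non-ACGT residues: `"randomize"` replaces
#'   each with a base chosen by a deterministic hash of `(id, position)`, so
#'   the result is reproducible and no spurious shared k-mers are created;
#'   `"reject"` raises an error naming the record.
#' @return An object of class `genome` with fields `id`, `seq`, `topology`,
#'   `length`.
#' @export
genome <- function(id, seq, topology = c("circular", "linear"),
                   ambiguity = c("randomize", "reject")) {
  topology <- match.arg(topology)
  ambiguity <- match.arg(ambiguity)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop("genome '", id, "': empty sequence")
  bad <- gregexpr("[^ACGT]", seq)[[1]]
  if (bad[1] != -1L) {
    if (ambiguity == "reject")
      stop("genome '", id, "': non-ACGT residue at position ", bad[1] - 1L)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    h <- sum(utf8ToInt(id)) %% 97L
    idx <- ((h + as.integer(bad) * 2654435761) %% 4L) + 1L
    chars[bad] <- c("A", "C", "G", "T")[idx]
    seq <- paste(chars, collapse = "")
  }
  structure(list(id = id, seq = seq, topology = topology,
                 length = nchar(seq)),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %d nt, %s\n", x$id, x$length, x$topology))
  invisible(x)
}

#' Read genomes from a FASTA file
#'
#' @param path FASTA file.
#' @param topology Topology assigned to every record.
#' @param ambiguity See [genome()].
#' @return Named list of [genome()] objects in file order.
#' @export
read_fasta <- function(path, topology = c("circular", "linear"),
                       ambiguity = c("randomize", "reject")) {
  topology <- match.arg(topology)
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- lapply(seq_along(set), function(i)
    genome(ids[i], as.character(set[[i]]), topology, ambiguity))
  names(out) <- ids
  out
}

#' Write genomes to a FASTA file
#'
#' @param genomes Named list of [genome()] objects.
#' @param path Output file.
#' @export
write_fasta <- function(genomes, path) {
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "seq"))
  names(seqs) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Plain-character convenience wrapper; an involution on ACGT strings.
#'
#' @param seq Character vector of ACGT strings (may contain `""`).
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  if (length(seq) == 0L) return(character(0))
  out <- seq
  nz <- nzchar(seq)
  if (any(nz)) {
    if (any(grepl("[^ACGTacgt]", seq[nz])))
      stop("reverse_complement: non-ACGT character")
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seq[nz])))
  }
  out
}

#' Position-arithmetic context
#'
#' Bundles a genome length and topology for the modular position helpers.
#' All positions live in `[0, L)`.
#'
#' @param L Genome length (nt) or a [genome()] object.
#' @param topology Ignored when `L` is a genome.
#' @return List with `L` and `topology`.
#' @export
pos_context <- function(L, topology = c("circular", "linear")) {
  if (inherits(L, "genome")) return(list(L = L$length, topology = L$topology))
  list(L = as.integer(L), topology = match.arg(topology))
}

#' The l-th position succeeding p
#'
#' @param p Position(s) in `[0, L)`.
#' @param l Step count(s), `>= 0`.
#' @param ctx A [pos_context()].
#' @return `(p + l) mod L` for circular genomes; `p + l` for linear genomes,
#'   erroring past the end.
#' @export
succ <- function(p, l, ctx) {
  if (ctx$topology == "circular") return((p + l) %% ctx$L)
  out <- p + l
  if (any(out >= ctx$L)) stop("succ: position beyond linear genome end")
  out
}

#' The l-th position preceding p
#' @inheritParams succ
#' @export
pred <- function(p, l, ctx) {
  if (ctx$topology == "circular") return((p - l) %% ctx$L)
  out <- p - l
  if (any(out < 0)) stop("pred: position before linear genome start")
  out
}

#' Forward distance from p to p'
#'
#' @param p,p2 Positions in `[0, L)`.
#' @param ctx A [pos_context()].
#' @return Number of forward steps from `p` to `p2` (`(p2 - p) mod L` on a
#'   circle).
#' @export
forward_distance <- function(p, p2, ctx) {
  if (ctx$topology == "circular") return((p2 - p) %% ctx$L)
  d <- p2 - p
  if (any(d < 0)) stop("forward_distance: negative distance on linear genome")
  d
}

# Shortest circular distance between two positions.
circ_dist <- function(p, q, L) {
  d <- abs(p - q) %% L
  pmin(d, L - d)
}

# Inclusive 0-based circular substring [start, end] of a genome sequence.
circ_substr <- function(g, start, end) {
  L <- g$length
  s <- start %% L
  e <- end %% L
  if (g$topology == "linear" && start > end)
    stop("circ_substr: inverted interval on linear genome")
  if (s <= e) return(substr(g$seq, s + 1L, e + 1L))
  paste0(substr(g$seq, s + 1L, L), substr(g$seq, 1L, e + 1L))
}

# Length of the intersection of circular intervals [s1, s1+l1) and
# [s2, s2+l2) on a circle of size L.
circ_overlap_len <- function(s1, l1, s2, l2, L) {
  if (l1 <= 0 || l2 <= 0) return(0L)
  ov <- 0L
  d <- (s2 - s1) %% L
  if (d < l1) ov <- ov + min(l1 - d, l2)
  e <- (s1 - s2) %% L
  if (e > 0 && e < l2) ov <- ov + min(l2 - e, l1)
  min(ov, min(l1, l2))
}

#' Read gene annotations from a BED6 file
#'
#' The BED name column holds the gene name; the strand column is used.
#' Wrap-around (start > end) features are not representable in BED and are
#' therefore not supported internally.
#'
#' @param path BED6 file.
#' @param genomes Optional named list of [genome()] objects; when given,
#'   coordinates are validated against the genome lengths.
#' @return `data.frame` with columns `genome_id`, `gene`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @export
read_annotations <- function(path, genomes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0L) stop("empty BED file: ", path)
  ann <- data.frame(
    genome_id = as.character(GenomicRanges::seqnames(gr)),
    gene = if (!is.null(gr$name)) as.character(gr$name) else
      paste0("feature", seq_along(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  ann$strand[ann$strand == "*"] <- "+"
  if (any(ann$end <= ann$start))
    stop("annotation with end <= start: ",
         ann$gene[which(ann$end <= ann$start)[1]])
  if (!is.null(genomes)) {
    for (i in seq_len(nrow(ann))) {
      g <- genomes[[ann$genome_id[i]]]
      if (is.null(g))
        stop("annotation references unknown genome: ", ann$genome_id[i])
      if (ann$start[i] < 0 || ann$end[i] > g$length)
        stop("annotation outside genome bounds: ", ann$gene[i])
    }
  }
  ann
}

#' Write gene annotations to a BED6 file
#'
#' @param ann Annotation `data.frame` as returned by [read_annotations()].
#' @param path Output file.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(all(c("genome_id", "gene", "start", "end", "strand") %in%
                  names(ann)))
  gr <- GenomicRanges::GRanges(
    seqnames = ann$genome_id,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand)
  gr$name <- ann$gene
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
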