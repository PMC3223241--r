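# Dot-plot genome comparison and gene-order conservation analysis
# (conserved runs across a panel, breakpoint distances).

#' Exact k-mer dot plot of two sequences
#'
#' Reports every exact shared word of length `word_size` between the two
#' sequences, on both strands. A reverse-strand match at (pos_a, pos_b) means
#' the word at `pos_a` of A equals the reverse complement of the word starting
#' at `pos_b` of B. Words containing N are skipped.
#'
#' @param seq_a,seq_b Nucleotide sequences (strings) or [genome_record()]s.
#' @param word_size Word length in nt (>= 4; default 8).
#' @return A `dotplot` object: list with `matches` (tibble `pos_a`, `pos_b`,
#'   `strand`), `len_a`, `len_b`, `word_size`, `id_a`, `id_b`.
#' @export
dotplot <- function(seq_a, seq_b, word_size = 8L) {
  stopifnot(word_size >= 4L)
  ga <- if (inherits(seq_a, "genome_record")) seq_a else genome_record(seq_a, id = "A", circular = FALSE)
  gb <- if (inherits(seq_b, "genome_record")) seq_b else genome_record(seq_b, id = "B", circular = FALSE)
  ka <- kmer_table(ga$sequence, word_size)
  kb <- kmer_table(gb$sequence, word_size)
  fwd <- dplyr::inner_join(ka, kb, by = "word", suffix = c("_a", "_b"),
                           relationship = "many-to-many")
  kbr <- kmer_table(revcomp(gb$sequence), word_size)
  # map reverse-complement positions back to B's forward coordinates
  kbr$pos <- nchar(gb$sequence) - (kbr$pos + word_size - 1L) + 1L
  rev <- dplyr::inner_join(ka, kbr, by = "word", suffix = c("_a", "_b"),
                           relationship = "many-to-many")
  matches <- dplyr::bind_rows(
    tibble::tibble(pos_a = fwd$pos_a, pos_b = fwd$pos_b, strand = "+"),
    tibble::tibble(pos_a = rev$pos_a, pos_b = rev$pos_b, strand = "-")
  )
  matches <- dplyr::arrange(matches, .data$pos_a, .data$pos_b)
  structure(list(matches = matches, len_a = nchar(ga$sequence),
                 len_b = nchar(gb$sequence), word_size = as.integer(word_size),
                 id_a = ga$id, id_b = gb$id),
            class = "dotplot")
}

kmer_table <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(tibble::tibble(word = character(), pos = integer()))
  words <- substring(seq, 1:(n - k + 1L), k:n)
  keep <- !grepl("N", words, fixed = TRUE)
  tibble::tibble(word = words[keep], pos = which(keep))
}

#' @export
print.dotplot <- function(x, ...) {
  cat(sprintf("<dotplot> %s (%d bp) vs %s (%d bp), word %d: %d matches\n",
              x$id_a, x$len_a, x$id_b, x$len_b, x$word_size, nrow(x$matches)))
  invisible(x)
}

#' Collapse dot-plot matches into maximal diagonal runs
#'
#' Consecutive forward matches on the same diagonal (and reverse matches on
#' the same anti-diagonal) are merged into runs of exact contiguous identity.
#'
#' @param dp A `dotplot` object.
#' @param min_len Minimum run length in nt to report.
#' @return Tibble `strand`, `start_a`, `end_a`, `start_b`, `end_b`, `length`.
#' @export
dotplot_runs <- function(dp, min_len = dp$word_size) {
  m <- dp$matches
  if (nrow(m) == 0L) {
    return(tibble::tibble(strand = character(), start_a = integer(),
                          end_a = integer(), start_b = integer(),
                          end_b = integer(), length = integer()))
  }
  k <- dp$word_size
  m$diag <- ifelse(m$strand == "+", m$pos_a - m$pos_b, m$pos_a + m$pos_b)
  m <- dplyr::arrange(m, .data$strand, .data$diag, .data$pos_a)
  new_run <- c(TRUE, diff(m$pos_a) != 1L | diff(m$diag) != 0L |
                 m$strand[-1] != m$strand[-nrow(m)])
  m$run <- cumsum(new_run)
  runs <- dplyr::summarise(
    dplyr::group_by(m, .data$run),
    strand = .data$strand[1],
    start_a = min(.data$pos_a), end_a = max(.data$pos_a) + k - 1L,
    start_b = min(.data$pos_b), end_b = max(.data$pos_b) + k - 1L,
    length = max(.data$pos_a) - min(.data$pos_a) + k,
    .groups = "drop"
  )
  runs <- dplyr::filter(runs, .data$length >= min_len)
  dplyr::arrange(runs[, -1], dplyr::desc(.data$length))
}

#' Signed gene-order vector of one genome
#'
#' Orthologs of the focal gene list are sorted by their order index along the
#' genome; each is represented by its (1-based) index in `focal_genes`, signed
#' by strand relative to the anchored focal genome.
#'
#' @param ortho Ortholog table from [ortholog_table()].
#' @param genome Genome id to extract.
#' @param focal_genes Character vector of focal genes in focal-genome order
#'   (defines the indices).
#' @return Named integer vector (names = focal gene, values = signed index),
#'   ordered along the genome. Each focal gene appears at most once.
#' @export
gene_order_vector <- function(ortho, genome, focal_genes) {
  d <- ortho[ortho$genome == genome & ortho$gene %in% focal_genes, ]
  d <- d[!duplicated(d$gene), ]
  d <- d[order(d$order_index), ]
  stats::setNames(as.integer(d$strand) * match(d$gene, focal_genes), d$gene)
}

# canonical key of a signed adjacency: (a,b) and (-b,-a) are the same adjacency
adj_keys <- function(v) {
  if (length(v) < 2L) return(character(0))
  a <- v[-length(v)]
  b <- v[-1]
  k1 <- paste(a, b)
  k2 <- paste(-b, -a)
  ifelse(k1 <= k2, k1, k2)
}

#' Maximal gene-order runs conserved across all genomes
#'
#' Restricts all vectors to the genes shared by every genome, then finds the
#' maximal blocks of the first (focal) vector whose gene order and relative
#' orientation are preserved in every other vector — each block may appear
#' forward or reversed (with flipped signs) in a given genome. Runs are
#' reported in focal-genome order; a gene conserved with neither neighbour
#' forms a singleton run.
#'
#' @param vectors List of signed gene-order vectors (from
#'   [gene_order_vector()]); the first is the focal genome.
#' @return Tibble `run`, `gene`, `index` (signed focal index), in focal order.
#' @export
conserved_runs <- function(vectors) {
  stopifnot(length(vectors) >= 2L)
  shared <- Reduce(intersect, lapply(vectors, function(v) abs(v)))
  if (length(shared) == 0L) {
    return(tibble::tibble(run = integer(), gene = character(), index = integer()))
  }
  restr <- lapply(vectors, function(v) v[abs(v) %in% shared])
  focal <- restr[[1]]
  others <- restr[-1]
  other_keys <- lapply(others, adj_keys)
  fk <- adj_keys(focal)
  conserved <- vapply(seq_along(fk), function(i) {
    all(vapply(other_keys, function(k) fk[i] %in% k, logical(1)))
  }, logical(1))
  run_id <- cumsum(c(TRUE, !conserved))
  tibble::tibble(run = run_id, gene = names(focal), index = unname(focal))
}

#' Breakpoint distance between two signed gene orders
#'
#' Both vectors are restricted to their shared genes; the distance is the
#' number of (orientation-aware) adjacencies present in the first vector but
#' not the second. It is symmetric, non-negative, and zero iff the two orders
#' are identical up to a global reversal.
#'
#' @param v1,v2 Signed gene-order vectors.
#' @return Integer distance.
#' @export
breakpoint_distance <- function(v1, v2) {
  shared <- intersect(abs(v1), abs(v2))
  if (length(shared) == 0L) {
    rlang::abort("undefined distance: the two vectors share no genes")
  }
  a <- v1[abs(v1) %in% shared]
  b <- v2[abs(v2) %in% shared]
  sum(!(adj_keys(a) %in% adj_keys(b)))
}
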