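# ORF enumeration and selection on circular genomes, plus genome summary
# statistics and the adjacent-overlap table.

#' Enumerate maximal ORFs in all six frames
#'
#' An ORF is the first ATG after the previous in-frame stop, read through the
#' next in-frame stop codon (TAA/TAG/TGA). The reported length includes the
#' stop codon, so "50 or more codons" equals `min_codons = 50`, i.e. >= 150 nt.
#' On circular genomes ORFs may cross the origin (`wraps = TRUE`, `end <
#' start`); an ORF never covers more than one full turn of the circle. Codons
#' containing N are never starts or stops.
#'
#' @param record A [genome_record()].
#' @param min_codons Minimum ORF length in codons, stop included (>= 2).
#' @return Tibble of candidates: `start`, `end`, `strand`, `frame`,
#'   `length_nt`, `wraps`, sorted by `start`.
#' @export
enumerate_orfs <- function(record, min_codons = 50L) {
  stopifnot(min_codons >= 2L)
  L <- genome_length(record)
  fwd <- orf_scan_strand(record$sequence, L, record$circular)
  rcs <- orf_scan_strand(revcomp(record$sequence), L, record$circular)
  out <- list()
  if (nrow(fwd) > 0L) {
    out$fwd <- tibble::tibble(
      start = fwd$p,
      end = wrap_pos(fwd$p + fwd$len - 1L, L),
      strand = 1L, frame = (fwd$p - 1L) %% 3L, length_nt = fwd$len
    )
  }
  if (nrow(rcs) > 0L) {
    # map a reverse-complement interval [p, p+len-1] back to original coordinates
    out$rev <- tibble::tibble(
      start = L - wrap_pos(rcs$p + rcs$len - 1L, L) + 1L,
      end = L - rcs$p + 1L,
      strand = -1L, frame = (rcs$p - 1L) %% 3L, length_nt = rcs$len
    )
  }
  cand <- dplyr::bind_rows(out)
  if (nrow(cand) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(), strand = integer(),
                          frame = integer(), length_nt = integer(), wraps = logical()))
  }
  cand$wraps <- cand$end < cand$start
  cand <- cand[cand$length_nt >= 3L * min_codons, ]
  dplyr::arrange(cand, .data$start, .data$strand)
}

# scan one strand; returns tibble(p, len) in the strand's own coordinates,
# where p is the first nt of the ATG and len includes the stop codon
orf_scan_strand <- function(seq, L, circular) {
  w <- if (circular) paste0(seq, seq) else seq
  cod <- codons_at(w)
  m <- length(cod)
  if (m == 0L) return(tibble::tibble(p = integer(), len = integer()))
  is_stop <- cod %in% STOP_CODONS
  is_atg <- cod == "ATG"
  # firststop[p] = position of the first stop codon at p, p+3, p+6, ...
  firststop <- rep(NA_integer_, m)
  for (off in 0:2) {
    idx <- seq.int(off + 1L, m, by = 3L)
    if (length(idx) == 0L) next
    hit <- ifelse(is_stop[idx], seq_along(idx), NA_integer_)
    nxt <- rev(cummin(rev(replace(hit, is.na(hit), .Machine$integer.max))))
    ok <- nxt != .Machine$integer.max
    firststop[idx[ok]] <- idx[nxt[ok]]
  }
  starts <- which(is_atg)
  if (circular) starts <- starts[starts <= L]
  if (length(starts) == 0L) return(tibble::tibble(p = integer(), len = integer()))
  st <- firststop[starts]
  keep <- !is.na(st)
  starts <- starts[keep]; st <- st[keep]
  len <- st - starts + 3L
  keep <- len <= L
  starts <- starts[keep]; st <- st[keep]; len <- len[keep]
  if (length(starts) == 0L) return(tibble::tibble(p = integer(), len = integer()))
  # maximality: keep the longest ORF per (normalised) stop codon
  d <- tibble::tibble(p = starts, len = len, stop_norm = wrap_pos(st, L))
  d <- dplyr::slice_max(dplyr::group_by(d, .data$stop_norm), .data$len,
                        n = 1L, with_ties = FALSE)
  dplyr::ungroup(d)[, c("p", "len")]
}

#' Select ORFs by the minimal-overlap rule
#'
#' Greedy selection in order of decreasing length (ties: smaller start first,
#' then plus strand first). A candidate is admitted iff its circular overlap
#' with every already admitted ORF is at most `max_overlap_bp`, or it carries a
#' homology-rescue flag (candidates with significant similarity to known genes
#' are kept regardless of overlap). The default threshold of 47 bp is "less
#' than 16 codons". Selected ORFs are named `prefix1..prefixN` in genome order.
#'
#' @param candidates Candidate tibble from [enumerate_orfs()].
#' @param genome_length Genome length in bp.
#' @param circular Topology flag (overlaps and adjacency wrap the origin).
#' @param max_overlap_bp Maximum tolerated overlap with any admitted ORF.
#' @param rescued Logical vector along `candidates` marking homology-rescued
#'   candidates (recycled; default none).
#' @param name_prefix Prefix for assigned ORF names.
#' @return The selected ORF set: `name`, `start`, `end`, `strand`, `wraps`,
#'   `length_nt`, sorted by `start`.
#' @export
select_orfs <- function(candidates, genome_length, circular = TRUE,
                        max_overlap_bp = 47L, rescued = FALSE,
                        name_prefix = "orf") {
  L <- genome_length
  cand <- tibble::as_tibble(candidates)
  cand$rescued <- rep_len(rescued, nrow(cand))
  ord <- order(-cand$length_nt, cand$start, -cand$strand)
  cand <- cand[ord, ]
  admitted <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (cand$rescued[i]) {
      admitted <- c(admitted, i)
      next
    }
    ok <- TRUE
    for (j in admitted) {
      if (circ_overlap(cand$start[i], cand$end[i], cand$start[j], cand$end[j], L) >
          max_overlap_bp) {
        ok <- FALSE
        break
      }
    }
    if (ok) admitted <- c(admitted, i)
  }
  sel <- cand[sort(admitted), ]
  sel <- dplyr::arrange(sel, .data$start, .data$strand)
  tibble::tibble(
    name = paste0(name_prefix, seq_len(nrow(sel))),
    start = sel$start, end = sel$end, strand = sel$strand,
    wraps = sel$end < sel$start, length_nt = sel$length_nt
  )
}

#' Overlaps between adjacent ORFs
#'
#' ORFs are ordered by start coordinate along the (anchored) genome; adjacency
#' is consecutive in this order, closing the circle between the last and first
#' ORF on circular genomes. The overlap is the size of the coordinate
#' intersection on the circle (0 for disjoint neighbours).
#'
#' @param orfset ORF tibble (`name`, `start`, `end`, ...).
#' @param genome_length Genome length in bp.
#' @param circular Whether the last ORF is adjacent to the first.
#' @return Tibble `name_a`, `name_b`, `overlap_bp`, one row per adjacent pair.
#' @export
overlap_table <- function(orfset, genome_length, circular = TRUE) {
  o <- dplyr::arrange(tibble::as_tibble(orfset), .data$start, .data$strand)
  n <- nrow(o)
  if (n < 2L) {
    return(tibble::tibble(name_a = character(), name_b = character(),
                          overlap_bp = integer()))
  }
  # with two ORFs on a circle the two adjacencies coincide; report one
  n_pairs <- if (!circular) n - 1L else if (n == 2L) 1L else n
  i <- seq_len(n_pairs)
  j <- c(seq_len(n)[-1], 1L)[i]
  ov <- vapply(seq_along(i), function(k) {
    circ_overlap(o$start[i[k]], o$end[i[k]], o$start[j[k]], o$end[j[k]], genome_length)
  }, integer(1))
  tibble::tibble(name_a = o$name[i], name_b = o$name[j], overlap_bp = ov)
}

#' Genome summary statistics
#'
#' Computes the headline numbers used to characterise a genome: length, A+T
#' percent (rounded half-up to one decimal, over the full sequence), ORF count
#' and strand split, coding percentage both sum-based (sum of ORF lengths over
#' genome length; overlaps counted twice) and union-based (covered positions
#' over genome length), and the number of adjacent pairs with a "minimal"
#' overlap of 1 to `max_minimal_overlap` bp.
#'
#' @param record A [genome_record()].
#' @param orfset ORF tibble (typically from [select_orfs()]).
#' @param max_minimal_overlap Upper bound (bp) of a "minimal" overlap;
#'   default 47 (less than 16 codons).
#' @return One-row tibble: `id`, `length_bp`, `at_pct`, `n_orfs`,
#'   `coding_pct_sum`, `coding_pct_union`, `n_fwd`, `n_rev`,
#'   `n_minimal_overlaps`, and the full adjacency table as the list-column
#'   `overlap_pairs`.
#' @export
genome_stats <- function(record, orfset, max_minimal_overlap = 47L) {
  L <- genome_length(record)
  bases <- strsplit(record$sequence, NULL)[[1]]
  at_pct <- round_half_up(100 * sum(bases %in% c("A", "T")) / L, 1)
  o <- tibble::as_tibble(orfset)
  n <- nrow(o)
  if (n > 0L) {
    covered <- logical(L)
    for (i in seq_len(n)) covered[circ_positions(o$start[i], o$end[i], L)] <- TRUE
    sum_pct <- 100 * sum(o$length_nt) / L
    union_pct <- 100 * sum(covered) / L
    ovl <- overlap_table(o, L, circular = record$circular)
    n_min <- sum(ovl$overlap_bp >= 1L & ovl$overlap_bp <= max_minimal_overlap)
  } else {
    sum_pct <- union_pct <- 0
    ovl <- overlap_table(o, L, circular = record$circular)
    n_min <- 0L
  }
  tibble::tibble(
    id = record$id, length_bp = L, at_pct = at_pct, n_orfs = n,
    coding_pct_sum = round_half_up(sum_pct, 1),
    coding_pct_union = round_half_up(union_pct, 1),
    n_fwd = sum(o$strand > 0L), n_rev = sum(o$strand < 0L),
    n_minimal_overlaps = n_min,
    overlap_pairs = list(ovl)
  )
}
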