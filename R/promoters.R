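# Early/late promoter motif association for ORF upstream regions.

#' Default baculovirus promoter motif definitions
#'
#' Late transcription starts within a (A/T/G)TAAG motif; early promoters are
#' taken as a TATA box with a CAGT initiator 20-40 nt downstream of the TATA
#' box's end. Patterns are IUPAC strings and fully configurable.
#'
#' @param late IUPAC pattern of the late motif.
#' @param tata IUPAC pattern of the early TATA element.
#' @param inr IUPAC pattern of the early initiator.
#' @param spacing Length-2 integer vector: allowed gap (nt) between the end of
#'   the TATA match and the start of the initiator.
#' @return A named list understood by [scan_promoters()].
#' @export
promoter_motifs <- function(late = "DTAAG", tata = "TATAA", inr = "CAGT",
                            spacing = c(20L, 40L)) {
  stopifnot(length(spacing) == 2L, spacing[1] <= spacing[2])
  list(late = late, tata = tata, inr = inr, spacing = as.integer(spacing))
}

# all (overlapping) match start positions of an IUPAC pattern in a string
find_iupac <- function(s, pattern) {
  rx <- paste0("(?=", iupac_to_regex(pattern), ")")
  m <- gregexpr(rx, s, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Scan ORF upstream regions for early/late promoter motifs
#'
#' For each ORF the `window_nt` nucleotides immediately 5' of its start codon
#' are extracted on the coding strand (wrapping the origin on circular
#' genomes; clipped at the sequence end on linear ones) and searched for the
#' late motif and for the TATA + initiator early arrangement. Upstream regions
#' are scanned as-is even where they overlap a neighbouring ORF.
#'
#' @param record A [genome_record()].
#' @param orfset ORF tibble (`name`, `start`, `end`, `strand`).
#' @param window_nt Upstream window length in nt (default 120).
#' @param motifs Motif definitions from [promoter_motifs()].
#' @return Tibble with one row per ORF: `orf_name`, `class` (`early`, `late`,
#'   `both`, `none`), `n_early`, `n_late`, and list-column `hits`
#'   (`motif_id`, `offset_upstream` = nt between motif start and the ATG,
#'   `match` = matched sequence on the coding strand).
#' @export
scan_promoters <- function(record, orfset, window_nt = 120L,
                           motifs = promoter_motifs()) {
  stopifnot(window_nt >= 1L)
  L <- genome_length(record)
  window_nt <- min(as.integer(window_nt), L - 3L)
  o <- tibble::as_tibble(orfset)
  late_len <- nchar(motifs$late)
  tata_len <- nchar(motifs$tata)

  calls <- purrr::map_dfr(seq_len(nrow(o)), function(i) {
    win <- upstream_window(record, o$start[i], o$end[i], o$strand[i], window_nt, L)
    W <- nchar(win)
    hits <- list()
    lp <- find_iupac(win, motifs$late)
    if (length(lp) > 0L) {
      hits$late <- tibble::tibble(
        motif_id = "late", offset_upstream = W - lp + 1L,
        match = substring(win, lp, lp + late_len - 1L)
      )
    }
    tp <- find_iupac(win, motifs$tata)
    ip <- find_iupac(win, motifs$inr)
    if (length(tp) > 0L && length(ip) > 0L) {
      good <- purrr::keep(tp, function(t0) {
        gap <- ip - (t0 + tata_len)
        any(gap >= motifs$spacing[1] & gap <= motifs$spacing[2])
      })
      if (length(good) > 0L) {
        hits$early <- tibble::tibble(
          motif_id = "early", offset_upstream = W - good + 1L,
          match = substring(win, good, good + tata_len - 1L)
        )
      }
    }
    hits <- if (length(hits) > 0L) dplyr::bind_rows(hits) else {
      tibble::tibble(motif_id = character(), offset_upstream = integer(),
                     match = character())
    }
    n_early <- sum(hits$motif_id == "early")
    n_late <- sum(hits$motif_id == "late")
    cls <- if (n_early > 0L && n_late > 0L) "both"
           else if (n_early > 0L) "early"
           else if (n_late > 0L) "late" else "none"
    tibble::tibble(orf_name = o$name[i], class = cls,
                   n_early = n_early, n_late = n_late, hits = list(hits))
  })
  calls
}

# the window_nt bases immediately 5' of the start codon, on the coding strand;
# position 1 of the returned string is farthest from the ATG
upstream_window <- function(record, start, end, strand, window_nt, L) {
  if (strand > 0L) {
    from <- start - window_nt
    to <- start - 1L
    if (!record$circular) {
      from <- max(1L, from)
      if (to < from) return("")
    }
    circ_substr(record$sequence, from, to, L)
  } else {
    from <- end + 1L
    to <- end + window_nt
    if (!record$circular) {
      to <- min(L, to)
      if (to < from) return("")
    }
    revcomp(circ_substr(record$sequence, from, to, L))
  }
}
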