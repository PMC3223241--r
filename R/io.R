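# FASTA and GFF3 I/O, plus the local-RefSeq lookup hook used by the
# paper-number checks.

#' Write sequences as FASTA
#'
#' 60-column wrapped FASTA via Biostrings. Accepts a named character vector or
#' a tibble with `name` and a sequence column (`protein` or `sequence`).
#'
#' @param seqs Named character vector, or tibble as described.
#' @param path Output path.
#' @param type `"AA"` or `"DNA"` (controls the sequence container used).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (is.data.frame(seqs)) {
    col <- intersect(c("protein", "sequence", "seq"), names(seqs))[1]
    seqs <- stats::setNames(seqs[[col]], seqs$name)
  }
  set <- if (type == "AA") Biostrings::AAStringSet(seqs) else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file path.
#' @param type `"AA"` or `"DNA"`.
#' @return A tibble with columns `name` and `sequence`.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path) else Biostrings::readDNAStringSet(path)
  tibble::tibble(name = sub("\\s.*$", "", names(set)),
                 sequence = unname(as.character(set)))
}

#' Write an ORF set as GFF3
#'
#' One `CDS` line per ORF; an origin-wrapping ORF becomes two lines sharing an
#' `ID` (parts `start..L` and `1..end`). Coordinates are 1-based inclusive.
#'
#' @param record The `genome_record` the ORFs belong to (provides seqid/length).
#' @param orfset Tibble of ORFs (`name`, `start`, `end`, `strand`, `wraps`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(record, orfset, path) {
  L <- genome_length(record)
  if (nrow(orfset) == 0L) {
    writeLines(c("##gff-version 3",
                 sprintf("##sequence-region %s 1 %d", record$id, L)), path)
    return(invisible(path))
  }
  parts <- purrr::pmap_dfr(orfset, function(name, start, end, strand, wraps, ...) {
    if (isTRUE(wraps)) {
      tibble::tibble(name = name, start = c(start, 1L), end = c(L, end), strand = strand)
    } else {
      tibble::tibble(name = name, start = start, end = end, strand = strand)
    }
  })
  gr <- GenomicRanges::GRanges(
    seqnames = record$id,
    ranges = IRanges::IRanges(start = parts$start, end = parts$end),
    strand = ifelse(parts$strand > 0L, "+", "-")
  )
  gr$source <- "baculoannot"
  gr$type <- "CDS"
  gr$phase <- 0L
  gr$ID <- parts$name
  gr$Name <- parts$name
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 ORF set written by [write_gff3()]
#'
#' Reassembles two-part features sharing an `ID` into a single wrapping ORF.
#'
#' @param path GFF3 path.
#' @param circular_length Genome length (needed to recognise wrapping parts).
#' @return An ORF tibble (`name`, `start`, `end`, `strand`, `wraps`, `length_nt`).
#' @export
read_gff3 <- function(path, circular_length) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(empty_features())
  d <- tibble::tibble(
    name = as.character(gr$ID),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-", -1L, 1L)
  )
  d <- dplyr::summarise(
    dplyr::group_by(d, .data$name, .data$strand),
    new_start = if (dplyr::n() == 2L) .data$start[.data$end == circular_length]
                else .data$start[1],
    new_end = if (dplyr::n() == 2L) .data$end[.data$start == 1L] else .data$end[1],
    .groups = "drop"
  )
  d <- tibble::tibble(name = d$name, start = d$new_start, end = d$new_end,
                      strand = d$strand)
  validate_features(d, circular_length)
}

#' Locate a locally provided RefSeq GenBank file
#'
#' The comparative checks against published genomes need the corresponding
#' RefSeq flat files, which are not distributed with the package. This helper
#' looks for `<accession>.gb` under, in order: `inst/extdata/refseq` of the
#' installed package, the directory named by
#' `options(baculoannot.refseq_dir = ...)`, and `./refseq`.
#'
#' @param accession RefSeq accession, e.g. `"NC_009503"`.
#' @return The path if found, otherwise `NA_character_`.
#' @export
refseq_path <- function(accession) {
  fn <- paste0(accession, ".gb")
  cands <- c(system.file("extdata", "refseq", fn, package = "baculoannot"),
             file.path(getOption("baculoannot.refseq_dir", ""), fn),
             file.path("refseq", fn))
  cands <- cands[nzchar(cands) & file.exists(cands)]
  if (length(cands) == 0L) NA_character_ else cands[1]
}
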