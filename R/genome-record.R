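#' Construct a genome record
#'
#' A genome record bundles a nucleotide sequence (over A, C, G, T, N), its
#' topology (circular or linear) and a table of ORF/CDS annotations. It is the
#' unit every annotation and comparison step operates on. Coordinates are
#' 1-based and inclusive throughout, as in GenBank and GFF3; a feature on a
#' circular genome may wrap past the origin, in which case `end < start` and
#' `wraps` is `TRUE`.
#'
#' @param sequence Nucleotide sequence as a single uppercase string.
#' @param id Identifier (accession or label).
#' @param circular Logical topology flag.
#' @param features Tibble of ORF annotations with columns `name`, `start`,
#'   `end`, `strand` (+1/-1), and optionally `wraps` (recomputed if absent).
#'   The biological start codon begins at `start` for +1 features and at `end`
#'   (reading towards `start`) for -1 features.
#'
#' @return An object of class `genome_record`.
#' @export
#' @examples
#' gr <- genome_record("ATGAAATAAACGT", id = "toy", circular = TRUE)
genome_record <- function(sequence, id = "genome", circular = TRUE,
                          features = empty_features()) {
  sequence <- toupper(sequence)
  check_alphabet(sequence)
  features <- validate_features(features, nchar(sequence))
  structure(
    list(id = id, sequence = sequence, circular = circular, features = features),
    class = "genome_record"
  )
}

empty_features <- function() {
  tibble::tibble(name = character(), start = integer(), end = integer(),
                 strand = integer(), wraps = logical(), length_nt = integer())
}

validate_features <- function(features, L) {
  features <- tibble::as_tibble(features)
  if (nrow(features) == 0L) return(empty_features())
  stopifnot(all(c("name", "start", "end", "strand") %in% names(features)))
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$strand <- as.integer(features$strand)
  if (!all(features$strand %in% c(-1L, 1L))) {
    rlang::abort("feature strand must be +1 or -1")
  }
  if (any(features$start < 1L | features$start > L | features$end < 1L | features$end > L)) {
    rlang::abort("feature coordinates must lie within [1, genome length]")
  }
  features$wraps <- features$end < features$start
  features$length_nt <- as.integer(circ_span(features$start, features$end, L))
  features[, c("name", "start", "end", "strand", "wraps", "length_nt")]
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, %s, %d feature(s)\n",
              x$id, format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear", nrow(x$features)))
  if (nrow(x$features) > 0L) print(utils::head(x$features, 5))
  invisible(x)
}

#' Genome length in bp
#' @param record A `genome_record`.
#' @return Integer length.
#' @export
genome_length <- function(record) nchar(record$sequence)

# extract the nucleotide sequence of one feature, 5'->3' on its own strand
feature_seq <- function(record, start, end, strand) {
  L <- genome_length(record)
  s <- circ_substr(record$sequence, start, end, L)
  if (strand < 0L) revcomp(s) else s
}

#' Rotate a circular genome so a position becomes nucleotide 1
#'
#' @param record A circular `genome_record`.
#' @param new_origin Position that becomes nucleotide 1.
#' @return A rotated `genome_record` with remapped features.
#' @export
rotate_genome <- function(record, new_origin) {
  L <- genome_length(record)
  if (!record$circular) rlang::abort("only circular genomes can be rotated")
  new_origin <- wrap_pos(as.integer(new_origin), L)
  if (new_origin == 1L) return(record)
  seq2 <- paste0(substr(record$sequence, new_origin, L),
                 substr(record$sequence, 1L, new_origin - 1L))
  f <- record$features
  remap <- function(p) wrap_pos(p - new_origin + 1L, L)
  if (nrow(f) > 0L) {
    f$start <- remap(f$start)
    f$end <- remap(f$end)
  }
  genome_record(seq2, id = record$id, circular = TRUE, features = f)
}

#' Reverse-complement a genome record
#'
#' Flips the sequence and remaps all features (coordinates mirrored, strands
#' inverted). Useful when anchoring on a reverse-strand gene.
#'
#' @param record A `genome_record`.
#' @return The flipped `genome_record`.
#' @export
flip_genome <- function(record) {
  L <- genome_length(record)
  f <- record$features
  if (nrow(f) > 0L) {
    new_start <- L - f$end + 1L
    new_end <- L - f$start + 1L
    f$start <- new_start
    f$end <- new_end
    f$strand <- -f$strand
  }
  genome_record(revcomp(record$sequence), id = record$id,
                circular = record$circular, features = f)
}

#' Anchor a circular genome on a named gene
#'
#' Re-coordinates the genome so the first nucleotide of the named gene's start
#' codon is nucleotide 1 on the plus strand, numbering in the gene's direction
#' of transcription. This is the standard convention for baculovirus genomes,
#' where the granulin (or polyhedrin) start codon defines position 1. The
#' returned sequence is a rotation (and reverse complement, if the gene lies on
#' the minus strand) of the input; feature coordinates are remapped
#' consistently. Anchoring is idempotent.
#'
#' @param record A circular `genome_record` whose features include `gene`.
#' @param gene Feature name to anchor on (e.g. `"granulin"`).
#' @return The anchored `genome_record`.
#' @export
anchor_to_gene <- function(record, gene) {
  f <- record$features
  i <- which(f$name == gene)
  if (length(i) == 0L) rlang::abort(paste0("gene not found among features: '", gene, "'"))
  i <- i[1]
  if (f$strand[i] < 0L) {
    record <- flip_genome(record)
    f <- record$features
    i <- which(f$name == gene)[1]
  }
  rotate_genome(record, f$start[i])
}

#' Translate all annotated features to proteins
#'
#' Applies the standard genetic code to every feature of the record, reading
#' through the origin for wrapping features. The trailing stop codon is not
#' included in the protein. Codons containing N translate to X. A stop codon
#' before the annotated end triggers a warning and the protein is truncated at
#' that stop.
#'
#' @param record A `genome_record` with features.
#' @return A tibble with columns `name` and `protein`.
#' @export
extract_proteins <- function(record) {
  f <- record$features
  prot <- vapply(seq_len(nrow(f)), function(i) {
    nt <- feature_seq(record, f$start[i], f$end[i], f$strand[i])
    translate_cds(nt, name = f$name[i])
  }, character(1))
  tibble::tibble(name = f$name, protein = prot)
}

# translate a CDS nucleotide string; drop trailing stop; internal stop warns + truncates
translate_cds <- function(nt, name = "CDS") {
  if (nchar(nt) %% 3L != 0L) {
    rlang::warn(paste0(name, ": length not a multiple of 3; trailing bases ignored"))
    nt <- substr(nt, 1L, nchar(nt) - nchar(nt) %% 3L)
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           if.fuzzy.codon = "X"))
  # drop terminal stop if present
  if (substring(aa, nchar(aa)) == "*") aa <- substr(aa, 1L, nchar(aa) - 1L)
  star <- regexpr("*", aa, fixed = TRUE)
  if (star > 0L) {
    rlang::warn(paste0(name, ": internal stop codon; protein truncated at position ", star))
    aa <- substr(aa, 1L, star - 1L)
  }
  aa
}
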