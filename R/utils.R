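# Internal helpers shared across modules: circular-coordinate arithmetic,
# reverse complement, rounding.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @importFrom rlang abort warn
NULL

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(strsplit(x, NULL), function(s) paste(rev(s), collapse = ""), ""))
}

# round half away from zero (printed-precision convention); base round() is banker's
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# 1-based modular position on a circle of size L
wrap_pos <- function(p, L) as.integer(((p - 1) %% L) + 1)

# substring on a circular sequence; from..to inclusive, wrapping allowed
circ_substr <- function(seq, from, to, L = nchar(seq)) {
  from <- wrap_pos(from, L)
  to <- wrap_pos(to, L)
  if (from <= to) {
    substr(seq, from, to)
  } else {
    paste0(substr(seq, from, L), substr(seq, 1L, to))
  }
}

# span length of circular interval start..end (wrapping iff end < start)
circ_span <- function(start, end, L) {
  ifelse(end >= start, end - start + 1L, L - start + 1L + end)
}

# positions covered by circular interval, as integer vector
circ_positions <- function(start, end, L) {
  if (end >= start) seq.int(start, end) else c(seq.int(start, L), seq.int(1L, end))
}

# overlap (bp) of two circular intervals given as (start, end) with wrap iff end < start
circ_overlap <- function(s1, e1, s2, e2, L) {
  segs <- function(s, e) {
    if (e >= s) list(c(s, e)) else list(c(s, L), c(1L, e))
  }
  a <- segs(s1, e1)
  b <- segs(s2, e2)
  ov <- 0L
  for (x in a) {
    for (y in b) {
      lo <- max(x[1], y[1])
      hi <- min(x[2], y[2])
      if (hi >= lo) ov <- ov + (hi - lo + 1L)
    }
  }
  ov
}

# vector of codon strings starting at every position of a (linear) string
codons_at <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(character(0))
  substring(seq, 1:(n - 2L), 3:n)
}

check_alphabet <- function(seq) {
  if (nchar(seq) == 0L) abort("sequence must be non-empty")
  bad <- gsub("[ACGTN]", "", seq)
  if (nchar(bad) > 0L) {
    abort(paste0("sequence contains characters outside {A,C,G,T,N}: '",
                 substr(bad, 1, 10), "'"))
  }
  invisible(TRUE)
}

iupac_to_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  chars <- strsplit(toupper(pattern), NULL)[[1]]
  if (!all(chars %in% names(map))) {
    abort(paste0("malformed IUPAC pattern: '", pattern, "'"))
  }
  paste(map[chars], collapse = "")
}
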